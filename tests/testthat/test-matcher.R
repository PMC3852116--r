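toy_mapk_dict <- function() {
  pathway_dictionary(sprintf("T:%d", 1:6),
                     c("MAPK signalling pathway", "p53 signalling pathway",
                       "Wnt cascade", "Apoptosis", "Glucose metabolism",
                       "Regulation of adhesion by TP53"))
}

test_that("lookup ranks a verbatim entry first with score 1", {
  d <- toy_mapk_dict()
  m <- tfidf_model(d)
  res <- lookup(c("mapk", "signalling", "pathway"), d, m, theta = 0.9)
  expect_identical(res$entry_id[1], "T:1")
  expect_equal(res$score[1], 1)
  expect_identical(nrow(lookup(c("zz", "qq"), d, m, theta = 0.4)), 0L)
})

test_that("indexed lookup equals brute-force scoring of every entry", {
  set.seed(19)
  d <- random_toy_dictionary(40)
  m <- tfidf_model(d)
  vocab <- names(d$doc_freq)
  for (i in 1:60) {
    q <- sample(vocab, sample(1:4, 1), replace = TRUE)
    theta <- sample(c(0.4, 0.7, 0.9), 1)
    res <- lookup(q, d, m, theta = theta)
    brute <- vapply(seq_len(d$n_entries), function(e) {
      oracle_softtfidf(q, d$tokens[[e]], m$n_docs, as.list(m$doc_freq))
    }, 0)
    keep <- which(brute >= theta)
    keep <- keep[order(-brute[keep], d$entries$entry_id[keep])]
    expect_identical(res$entry_id, d$entries$entry_id[keep])
    expect_equal(res$score, unname(brute[keep]), tolerance = 1e-9)
  }
})

test_that("start points are tokens resembling dictionary content", {
  d <- toy_mapk_dict()
  m <- tfidf_model(d)
  doc <- path_document("The MAPK signalling pathway is active near Wnt.")
  sp <- find_start_points(doc, d, m)
  started <- doc$tokens$text[sp]
  expect_true(all(c("MAPK", "Wnt") %in% started))
  expect_false(any(c("The", "is", "active", ".") %in% started))
  # a sentence of dictionary-free stop words has no start points
  doc2 <- path_document("The and with under it.")
  expect_identical(length(find_start_points(doc2, d, m)), 0L)
})

test_that("verbatim names are matched exactly with score 1", {
  d <- toy_mapk_dict()
  m <- tfidf_model(d)
  doc <- path_document("We examined the MAPK signalling pathway, twice.")
  anns <- scan_document(doc, d, m)
  expect_identical(nrow(anns), 1L)
  expect_identical(anns$surface, "MAPK signalling pathway")
  expect_equal(anns$score, 1)
  expect_identical(anns$entry_id, "T:1")
  expect_identical(anns$source, "dictionary")
})

test_that("permuted names are recovered by soft matching but not by the baseline", {
  d <- synthetic_dictionary(250, seed = 1)
  m <- tfidf_model(d)
  nm <- d$entries$name[grepl("signalling pathway$", d$entries$name)][1]
  gene <- sub(" .*$", "", nm)
  txt <- sprintf("Changes in the signalling pathway of %s were reported, as shown.", gene)
  doc <- path_document(txt, "perm")
  anns <- scan_document(doc, d, m)
  g0 <- regexpr(paste("signalling pathway of", gene), txt, fixed = TRUE)
  expect_gt(nrow(anns), 0)
  # overlap with the permuted mention span
  expect_true(any(anns$start < g0 - 1 + attr(g0, "match.length") &
                  anns$end > g0 - 1))
  expect_identical(nrow(exact_match_baseline(doc, d)), 0L)
})

test_that("ambiguous keyword phrases are not soft-matched", {
  d <- synthetic_dictionary(250, seed = 1)
  m <- tfidf_model(d)
  doc <- path_document("The diagnostic pathway was followed by clinicians.")
  expect_identical(nrow(scan_document(doc, d, m)), 0L)
})

test_that("exact baseline is case-insensitive with longest-match-wins", {
  d <- pathway_dictionary(c("A:1", "A:2", "A:3"),
                          c("MAPK signalling", "MAPK signalling pathway",
                            "p53 pathway"))
  doc <- path_document("the mapk signalling pathway and P53 PATHWAY data")
  anns <- exact_match_baseline(doc, d)
  expect_identical(anns$surface,
                   c("mapk signalling pathway", "P53 PATHWAY"))
  expect_identical(anns$entry_id[1], "A:2")
})

test_that("matcher respects thresholds, window bound and monotonicity", {
  d <- synthetic_dictionary(150, seed = 5)
  m <- tfidf_model(d)
  corp <- generate_synthetic_corpus(d, 40, perturbation_config(
    p_stopword_insert = 0.5, p_permute = 0.3, seed = 9))
  cfg_low <- matcher_config(upper_threshold = 0.9)
  cfg_high <- matcher_config(upper_threshold = 0.95)
  n_low <- 0L; n_high <- 0L
  for (doc in corp$documents) {
    a_low <- scan_document(doc, d, m, cfg_low)
    a_high <- scan_document(doc, d, m, cfg_high)
    n_low <- n_low + nrow(a_low); n_high <- n_high + nrow(a_high)
    if (nrow(a_low)) {
      expect_true(all(a_low$score >= 0.9))
      expect_true(all(lengths(lapply(a_low$surface,
                                     function(s) tokenize(s)$text)) <=
                        cfg_low$max_window))
    }
    expect_annotation_invariants(a_low, corp$documents)
  }
  expect_lte(n_high, n_low)
})

test_that("soft matching output spans subsume exact baseline spans on fixtures", {
  d <- synthetic_dictionary(150, seed = 5)
  m <- tfidf_model(d)
  corp <- generate_synthetic_corpus(d, 40, perturbation_config(seed = 10))
  for (doc in corp$documents) {
    soft <- scan_document(doc, d, m)
    base <- exact_match_baseline(doc, d)
    soft_key <- paste(soft$start, soft$end)
    expect_true(all(paste(base$start, base$end) %in% soft_key))
  }
})

test_that("matcher configuration enforces dual-threshold ordering", {
  expect_error(matcher_config(lower_threshold = 0.95, upper_threshold = 0.9))
  expect_error(matcher_config(max_window = 0))
})
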