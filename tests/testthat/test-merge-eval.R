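ann <- function(start, end, source = "dictionary", score = NA_real_,
                doc_id = "d1", entry_id = NA_character_) {
  annotation_frame(doc_id = doc_id, start = start, end = end,
                   surface = strrep("x", end - start),
                   type = "pathway_mention", score = score, source = source,
                   entry_id = entry_id)
}

test_that("disjoint annotation sets pass through ordered by position", {
  res <- merge_annotations(ann(20, 30), ann(0, 10, "rule"))
  expect_identical(res$start, c(0L, 20L))
  expect_identical(res$source, c("rule", "dictionary"))
})

test_that("overlapping annotations merge into a covering span", {
  res <- merge_annotations(ann(10, 25, score = 0.93, entry_id = "K:1"),
                           ann(18, 40, "rule"))
  expect_identical(nrow(res), 1L)
  expect_identical(c(res$start, res$end), c(10L, 40L))
  expect_identical(res$source, "merged")
  expect_equal(res$score, 0.93)
  expect_identical(res$entry_id, "K:1")
})

test_that("overlap chains close transitively", {
  chain <- rbind(ann(0, 10), ann(8, 20, "rule"), ann(18, 30))
  res <- merge_annotations(chain)
  expect_identical(nrow(res), 1L)
  expect_identical(c(res$start, res$end), c(0L, 30L))
})

test_that("merging is idempotent and outputs are pairwise non-overlapping", {
  set.seed(23)
  for (i in 1:25) {
    n <- sample(1:12, 1)
    st <- sample(0:80, n, replace = TRUE)
    a <- ann(st, st + sample(2:15, n, replace = TRUE),
             source = sample(c("dictionary", "rule"), n, replace = TRUE),
             score = ifelse(stats::runif(n) < 0.5, stats::runif(n), NA))
    res <- merge_annotations(a)
    if (nrow(res) > 1) {
      expect_true(all(res$start[-1] >= res$end[-nrow(res)]))
    }
    again <- merge_annotations(res, annotation_frame())
    expect_identical(again[, c("start", "end")], res[, c("start", "end")])
  }
})

test_that("precision/recall/F1 follow the standard equations", {
  r <- compute_prf(list(TP = 8, FP = 2, FN = 2))
  expect_equal(c(r$P, r$R, r$F1), c(0.8, 0.8, 0.8))
  expect_equal(unlist(compute_prf(list(TP = 5, FP = 0, FN = 0))[, c("P", "R", "F1")]),
               c(P = 1, R = 1, F1 = 1))
  expect_equal(unlist(compute_prf(list(TP = 0, FP = 0, FN = 3))[, c("P", "R", "F1")]),
               c(P = 0, R = 0, F1 = 0))
})

test_that("strict requires exact spans; lenient accepts one-to-one overlap", {
  gold <- ann(0, 10, "gold")
  expect_equal(match_annotations(gold, ann(0, 10), "strict")$TP, 1)
  p <- ann(2, 8)
  s <- match_annotations(gold, p, "strict")
  l <- match_annotations(gold, p, "lenient")
  expect_identical(c(s$TP, s$FP, s$FN), c(0L, 1L, 1L))
  expect_identical(c(l$TP, l$FP, l$FN), c(1L, 0L, 0L))
  # one prediction overlapping two gold spans counts once
  gold2 <- rbind(ann(0, 10, "gold"), ann(20, 30, "gold"))
  l2 <- match_annotations(gold2, ann(5, 25), "lenient")
  expect_identical(c(l2$TP, l2$FP, l2$FN), c(1L, 0L, 1L))
})

test_that("counts stay consistent and strict never beats lenient", {
  set.seed(29)
  for (i in 1:25) {
    ng <- sample(0:8, 1); np <- sample(0:8, 1)
    gs <- sort(sample(0:60, ng))
    ps <- sort(sample(0:60, np))
    gold <- if (ng) ann(gs, gs + sample(3:10, ng, replace = TRUE), "gold") else
      annotation_frame()
    pred <- if (np) ann(ps, ps + sample(3:10, np, replace = TRUE)) else
      annotation_frame()
    s <- match_annotations(gold, pred, "strict")
    l <- match_annotations(gold, pred, "lenient")
    expect_lte(s$TP, l$TP)
    expect_identical(s$TP + s$FP, nrow(pred))
    expect_identical(l$TP + l$FN, nrow(gold))
    expect_lte(s$F1, l$F1 + 1e-12)
  }
})

test_that("evaluation report has one strict and one lenient block per method", {
  gold <- rbind(ann(0, 10, "gold"), ann(20, 30, "gold"))
  rep <- evaluation_report(gold, list(baseline = ann(0, 10),
                                      hybrid = rbind(ann(0, 10), ann(21, 29))))
  expect_identical(rep$method, c("baseline", "hybrid"))
  expect_equal(rep$strict_R, c(0.5, 0.5))
  expect_equal(rep$lenient_R, c(0.5, 1.0))
})

test_that("mention aggregation counts totals, uniques and singletons", {
  a <- annotation_frame(doc_id = c("d1", "d1", "d1", "d2"),
                        start = c(0, 10, 20, 0), end = c(5, 15, 25, 5),
                        surface = c("A", "A", "B", "B"),
                        type = "pathway_mention", source = "gold")
  agg <- aggregate_mentions(a, n_documents = 3)
  expect_identical(c(agg$total, agg$unique, agg$singletons), c(4L, 2L, 0L))
  expect_equal(agg$mentions_per_doc, 4 / 3, tolerance = 1e-9)
  empty <- aggregate_mentions(annotation_frame())
  expect_identical(empty$total, 0L)
  # case-insensitive mode folds case variants
  a$surface[1] <- "a"
  expect_identical(aggregate_mentions(a, 3, case_sensitive = FALSE)$unique, 2L)
  expect_identical(aggregate_mentions(a, 3, case_sensitive = TRUE)$unique, 3L)
})

test_that("inline-XML gold corpora are read with exact offsets", {
  xml <- paste0('<corpus><document id="g1">Cells use the ',
                "<pathway>MAPK signalling pathway</pathway> and ",
                "<gene>p53</gene> daily.</document>",
                '<document id="g2">Nothing here.</document></corpus>')
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(xml, f)
  gc <- read_gold_corpus(f, "gate_xml", label = "pathway")
  expect_identical(names(gc$documents), c("g1", "g2"))
  expect_identical(nrow(gc$gold), 1L)
  expect_identical(gc$gold$surface, "MAPK signalling pathway")
  d <- gc$documents[["g1"]]
  expect_identical(substr(d$text, gc$gold$start + 1, gc$gold$end),
                   "MAPK signalling pathway")
})

test_that("standoff annotations round-trip and invalid offsets error", {
  dir <- withr::local_tempdir()
  writeLines("The p53 pathway is active.", file.path(dir, "s1.txt"))
  anns <- annotation_frame(doc_id = "s1", start = 4, end = 15,
                           surface = "p53 pathway", type = "pathway_mention",
                           score = 0.97, source = "dictionary",
                           entry_id = "K:9")
  write_annotations(anns, file.path(dir, "s1.ann"))
  gc <- read_gold_corpus(dir, "standoff")
  expect_equal(gc$gold$score, 0.97)
  expect_identical(gc$gold[, c("doc_id", "start", "end", "surface")],
                   anns[, c("doc_id", "start", "end", "surface")])
  bad <- annotation_frame(doc_id = "s1", start = 4, end = 999,
                          surface = "x", type = "pathway_mention",
                          source = "gold")
  write_annotations(bad, file.path(dir, "s1.ann"))
  expect_error(read_gold_corpus(dir, "standoff"), "exceeds text length")
})
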