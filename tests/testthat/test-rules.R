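test_that("keyword occurrences prefer the longest combination", {
  doc <- path_document("the MAPK signalling pathway controls a gene regulatory network")
  kw <- find_keywords(doc)
  expect_identical(kw$surface, c("signalling pathway", "network"))
  expect_identical(nrow(find_keywords(path_document("no relevant words here"))), 0L)
})

test_that("backward extension stops at the five stop-token classes", {
  doc <- path_document("Activation of the p53 signalling pathway occurred.")
  kw <- find_keywords(doc)
  seg <- backward_extend(doc, kw[1, ])
  toks <- doc$tokens
  expect_identical(substring(doc$text, toks$start[seg$first] + 1,
                             toks$end[seg$last]),
                   "p53 signalling pathway")
  doc2 <- path_document("cells activate the Wnt cascade")
  seg2 <- backward_extend(doc2, find_keywords(doc2)[1, ])
  expect_identical(substring(doc2$text, doc2$tokens$start[seg2$first] + 1,
                             doc2$tokens$end[seg2$last]),
                   "Wnt cascade")
  # anchor at sentence start stays anchor-only
  doc3 <- path_document("Pathways of interest were listed.")
  seg3 <- backward_extend(doc3, find_keywords(doc3)[1, ])
  expect_identical(seg3$first, find_keywords(doc3)$first[1])
})

test_that("noun-phrase-internal 'of' does not stop the backward scan", {
  doc <- path_document("They disrupted the mammalian target of rapamycin signalling pathway.")
  seg <- backward_extend(doc, find_keywords(doc)[1, ])
  expect_identical(substring(doc$text, doc$tokens$start[seg$first] + 1,
                             doc$tokens$end[seg$last]),
                   "mammalian target of rapamycin signalling pathway")
})

test_that("forward extension follows verb phrases up to punctuation", {
  doc <- path_document("They saw the pathway regulated by MDM2, however briefly.")
  kw <- find_keywords(doc)
  seg <- forward_extend(doc, backward_extend(doc, kw[1, ]))
  expect_identical(substring(doc$text, doc$tokens$start[seg$first] + 1,
                             doc$tokens$end[seg$last]),
                   "pathway regulated by MDM2")
  # immediate punctuation or absent verb phrase leaves the segment unchanged
  doc2 <- path_document("We mapped the pathway. It was long.")
  seg2 <- forward_extend(doc2, backward_extend(doc2, find_keywords(doc2)[1, ]))
  expect_identical(seg2$last, find_keywords(doc2)$last[1])
  doc3 <- path_document("We mapped the pathway that we studied.")
  seg3 <- forward_extend(doc3, backward_extend(doc3, find_keywords(doc3)[1, ]))
  expect_identical(seg3$last, find_keywords(doc3)$last[1])
})

test_that("complex coordinated pathway mentions yield one gated annotation", {
  s <- paste0("Western blots revealed activation of the ras/raf/MAPK kinase ",
              "(MEK)/ERK and phosphatidylinositol 3-kinase (PI-3K)/AKT/",
              "mammalian target of rapamycin (mTOR) signalling pathways.")
  doc <- path_document(s, "pmid_example")
  anns <- apply_rules(doc)
  expect_identical(nrow(anns), 1L)
  expect_match(anns$surface, "signalling pathways$")
  expect_match(anns$surface, "^ras/raf/MAPK")
  genes <- gene_recognizer()(doc)
  inside <- genes[genes$start >= anns$start & genes$end <= anns$end, ]
  expect_gte(nrow(inside), 2)
})

test_that("segments without contained gene mentions are rejected", {
  expect_identical(nrow(apply_rules(path_document(
    "The diagnostic pathway was followed by the clinicians."))), 0L)
  expect_identical(nrow(apply_rules(path_document(
    "In the brain, microglial activation occurred rapidly."))), 0L)
  # same sentence with a gene inside the segment is accepted
  anns <- apply_rules(path_document("MEK1 signalling pathway analysis."))
  expect_identical(nrow(anns), 1L)
})

test_that("gene gating is the only difference when mentions are removed", {
  d <- synthetic_dictionary(150, seed = 5)
  corp <- generate_synthetic_corpus(d, 30, perturbation_config(
    rule_only_rate = 1, seed = 31))
  no_genes <- function(doc) annotation_frame()
  for (doc in corp$documents) {
    with_g <- apply_rules(doc)
    expect_gt(nrow(with_g), 0)
    expect_identical(nrow(apply_rules(doc, recognizer = no_genes)), 0L)
  }
})

test_that("rule annotations contain a keyword and a gene and stay in-sentence", {
  d <- synthetic_dictionary(150, seed = 5)
  corp <- generate_synthetic_corpus(d, 30, perturbation_config(
    rule_only_rate = 0.5, carrier_genes = TRUE, seed = 32))
  kw <- keyword_set()
  for (doc in corp$documents) {
    anns <- apply_rules(doc)
    genes <- gene_recognizer()(doc)
    occ <- find_keywords(doc, kw)
    for (i in seq_len(nrow(anns))) {
      expect_true(any(genes$start >= anns$start[i] & genes$end <= anns$end[i]))
      expect_true(any(occ$start >= anns$start[i] & occ$end <= anns$end[i]))
      sent <- doc$sentences
      inside <- sent$start <= anns$start[i] & sent$end >= anns$end[i]
      expect_true(any(inside))
    }
    expect_annotation_invariants(anns, corp$documents)
  }
})

test_that("lexicon and morphology gene recognition behave as specified", {
  rec <- gene_recognizer()
  doc <- path_document("The p53 protein and MEK1 but not the cells.")
  g <- rec(doc)
  expect_setequal(g$surface, c("p53", "MEK1"))
  expect_true(all(g$type == "gene_mention"))
  # multi-token lexicon names are matched as token sequences
  doc2 <- path_document("Binding of mammalian target of rapamycin was seen.")
  expect_true("mammalian target of rapamycin" %in% rec(doc2)$surface)
  # custom lexicons and imported standoff annotations are accepted
  rec2 <- gene_recognizer(lexicon = c("FOXO"))
  expect_identical(rec2(path_document("FOXO acts here."))$surface, "FOXO")
  pre <- annotation_frame(doc_id = "doc", start = 4, end = 7, surface = "p53",
                          type = "gene_mention", source = "rule")
  anns <- apply_rules(path_document("The p53 pathway responds."), recognizer = pre)
  expect_identical(nrow(anns), 1L)
})
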