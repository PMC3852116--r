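# Synthetic dictionary and corpus generation.
#
# The generator emulates the variation typology that motivates soft matching:
# stop-word insertion/deletion, word permutation via prepositions
# ("p53 signalling pathway" ~ "signalling pathway of p53"), spelling variants
# (signalling/signaling) and alternative keywords (pathway/cascade/network),
# plus ambiguous-keyword distractor sentences ("the diagnostic pathway").
# Name templates mirror the lexical make-up of public pathway databases:
# gene-headed signalling names, "Regulation of X by GENE" / "Activation of
# the GENE cascade" phrasings (which give function words realistic document
# frequencies), metabolic "X metabolism/biosynthesis/degradation" names and
# keyword-free process names.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.synth_pools <- local({
  processes <- c("apoptosis", "autophagy", "glycolysis", "proteolysis",
                 "adhesion", "migration", "differentiation", "proliferation",
                 "inflammation", "angiogenesis", "phagocytosis", "senescence",
                 "chemotaxis", "exocytosis", "mitophagy", "ferroptosis")
  compounds <- c("glucose", "cholesterol", "pyruvate", "glutamate",
                 "serotonin", "dopamine", "retinol", "histidine", "arginine",
                 "sphingolipid", "glycogen", "urea", "purine", "folate",
                 "heme", "lactate", "fructose", "galactose", "tyrosine",
                 "tryptophan", "leucine", "proline", "ceramide", "inositol")
  modifiers <- c("microglial", "complement", "platelet", "lymphocyte",
                 "neutrophil", "astrocyte", "macrophage", "monocyte",
                 "fibroblast", "endothelial", "epithelial", "mitochondrial")
  list(processes = processes, compounds = compounds, modifiers = modifiers)
})

.make_symbols <- function(n, digits = TRUE) {
  cons <- c("B", "C", "D", "F", "G", "H", "J", "K", "L", "M", "N", "P", "Q",
            "R", "S", "T", "V", "W", "X", "Z")
  out <- character(0)
  while (length(out) < n) {
    sym <- paste0(paste(sample(cons, 3, replace = TRUE), collapse = ""),
                  if (digits) sample(1:9, 1) else "")
    out <- unique(c(out, sym))
  }
  out[seq_len(n)]
}

#' Generate a synthetic pathway-name dictionary
#'
#' Deterministic in `seed`. Names follow templates whose proportions emulate
#' curated pathway databases (signalling names headed by a gene symbol,
#' regulation/activation phrasings, metabolic names, keyword-free process
#' names), split across two synthetic source databases. Gene symbols are
#' generated and disjoint from the carrier symbols used by
#' [generate_synthetic_corpus()], so corpus text never contains a dictionary
#' gene outside an embedded name.
#'
#' @param n_entries Number of entries (default 250).
#' @param seed Integer seed.
#' @return A `pathway_dictionary`.
#' @export
synthetic_dictionary <- function(n_entries = 250, seed = 1) {
  stopifnot(n_entries >= 50)
  .with_seed(seed, {
    genes <- .make_symbols(ceiling(n_entries), digits = TRUE)
    pr <- .synth_pools$processes
    cp <- .synth_pools$compounds
    md <- .synth_pools$modifiers
    # proportions emulate database composition: mostly gene-headed
    # signalling names, some regulation/activation phrasings (providing
    # realistic frequencies for "of"/"the"/"by"), short "<modifier>
    # activation/regulation" entries as curated by process-oriented sources,
    # metabolic names and keyword-free process names
    frac <- c(g_pathway = 0.088, g_cascade = 0.088, sig_network = 0.072,
              regulation = 0.048, activation = 0.048, act_boost = 0.048,
              reg_boost = 0.048, metabolism = 0.088, biosynthesis = 0.056,
              degradation = 0.040, process = 0.056)
    counts <- stats::setNames(pmax(1L, round(frac * n_entries)), names(frac))
    caps <- c(act_boost = length(md), reg_boost = length(md),
              metabolism = length(cp), biosynthesis = length(cp),
              degradation = length(cp), process = length(pr))
    counts[names(caps)] <- pmin(counts[names(caps)], caps)
    counts <- c(sig_pathway = n_entries - sum(counts), counts)
    gi <- 0L
    next_gene <- function() {
      gi <<- gi + 1L
      genes[gi]
    }
    cap1 <- function(x) paste0(toupper(substring(x, 1, 1)), substring(x, 2))
    names_out <- character(0)
    add <- function(x) names_out <<- c(names_out, x)
    for (i in seq_len(counts["sig_pathway"]))
      add(paste(next_gene(), "signalling pathway"))
    for (i in seq_len(counts["g_pathway"])) add(paste(next_gene(), "pathway"))
    for (i in seq_len(counts["g_cascade"])) add(paste(next_gene(), "cascade"))
    for (i in seq_len(counts["sig_network"]))
      add(paste(next_gene(), "signalling network"))
    for (i in seq_len(counts["regulation"]))
      add(paste("Regulation of", sample(pr, 1), "by", next_gene()))
    for (i in seq_len(counts["activation"]))
      add(paste("Activation of the", next_gene(), "cascade"))
    for (m in sample(md, counts["act_boost"])) add(cap1(paste(m, "activation")))
    for (m in sample(md, counts["reg_boost"])) add(cap1(paste(m, "regulation")))
    for (x in sample(cp, counts["metabolism"])) add(cap1(paste(x, "metabolism")))
    for (x in sample(cp, counts["biosynthesis"])) add(cap1(paste(x, "biosynthesis")))
    for (x in sample(cp, counts["degradation"])) add(cap1(paste(x, "degradation")))
    for (x in sample(pr, counts["process"])) add(cap1(x))
    names_out <- unique(names_out)
    src <- rep(c("SYNA", "SYNB"), length.out = length(names_out))
    ids <- sprintf("%s:%04d", src, seq_along(names_out))
    pathway_dictionary(ids, names_out)
  })
}

#' Perturbation and generation settings for synthetic corpora
#'
#' Probabilities act independently per embedded mention. `distractor_rate` is
#' the fraction of sentences carrying an ambiguous pathway keyword but no
#' actual pathway mention; `rule_only_rate` is the fraction of mention
#' sentences embedding a keyword + gene name that is absent from the
#' dictionary (reachable only by the rule component);
#' `keywordless_mentions` restricts dictionary mentions to keyword-free
#' names (reachable only by the dictionary component). `carrier_genes`
#' switches gene symbols in the carrier clauses on or off so the rule
#' engine's gene gate can be exercised independently.
#'
#' @param p_stopword_insert,p_stopword_delete,p_permute,p_keyword_swap,p_spelling_swap
#'   Perturbation probabilities in `[0, 1]`.
#' @param distractor_rate,rule_only_rate Fractions in `[0, 1]`.
#' @param keywordless_mentions,carrier_genes Logical switches.
#' @param distinct_mentions Sample dictionary entries without replacement
#'   (each embedded at most once)? Default `FALSE`: pathways recur in real
#'   corpora.
#' @param sentences_per_doc Sentences grouped into one document (default 10).
#' @param seed Integer seed; generation is a pure function of (dictionary,
#'   config, seed).
#' @return List of class `perturbation_config`.
#' @export
perturbation_config <- function(p_stopword_insert = 0, p_stopword_delete = 0,
                                p_permute = 0, p_keyword_swap = 0,
                                p_spelling_swap = 0, distractor_rate = 0,
                                rule_only_rate = 0,
                                keywordless_mentions = FALSE,
                                carrier_genes = FALSE,
                                distinct_mentions = FALSE,
                                sentences_per_doc = 10L, seed = 1L) {
  probs <- c(p_stopword_insert, p_stopword_delete, p_permute, p_keyword_swap,
             p_spelling_swap, distractor_rate, rule_only_rate)
  stopifnot(all(probs >= 0), all(probs <= 1), sentences_per_doc >= 1)
  structure(list(p_stopword_insert = p_stopword_insert,
                 p_stopword_delete = p_stopword_delete,
                 p_permute = p_permute, p_keyword_swap = p_keyword_swap,
                 p_spelling_swap = p_spelling_swap,
                 distractor_rate = distractor_rate,
                 rule_only_rate = rule_only_rate,
                 keywordless_mentions = isTRUE(keywordless_mentions),
                 carrier_genes = isTRUE(carrier_genes),
                 distinct_mentions = isTRUE(distinct_mentions),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 seed = as.integer(seed)),
            class = "perturbation_config")
}

# standard English closed-class list shipped with the package
.synth_stopwords <- function() {
  f <- system.file("extdata", "stopwords_en.txt", package = "pathtag")
  sw <- readLines(f, encoding = "UTF-8", warn = FALSE)
  sw[!grepl("^\\s*(#|$)", sw)]
}

.base_keywords_regex <- "^(pathway|pathways|signalling|signaling|cascade|cascades|network|networks|transduction)$"

.perturb_name <- function(name, cfg, stopwords = .synth_stopwords()) {
  toks <- tokenize(name)$text
  applied <- character(0)
  if (cfg$p_stopword_insert > 0 && length(toks) >= 2 &&
      stats::runif(1) < cfg$p_stopword_insert) {
    pos <- sample(length(toks) - 1L, 1)
    toks <- append(toks, sample(stopwords, 1), after = pos)
    applied <- c(applied, "stopword_insert")
  }
  if (cfg$p_stopword_delete > 0 && stats::runif(1) < cfg$p_stopword_delete) {
    drop <- which(tolower(toks) %in% stopwords)
    if (length(drop) && length(toks) > 1) {
      toks <- toks[-sample(rep(drop, 2), 1)]
      applied <- c(applied, "stopword_delete")
    }
  }
  if (cfg$p_permute > 0 && stats::runif(1) < cfg$p_permute) {
    kw <- grep(.base_keywords_regex, tolower(toks))
    if (length(kw) && kw[1] > 1) {
      toks <- c(toks[kw[1]:length(toks)], "of", toks[1:(kw[1] - 1L)])
      applied <- c(applied, "permute")
    }
  }
  if (cfg$p_keyword_swap > 0 && stats::runif(1) < cfg$p_keyword_swap) {
    heads <- c("pathway", "cascade", "network")
    at <- which(tolower(toks) %in% heads)
    if (length(at)) {
      i <- at[length(at)]
      toks[i] <- sample(setdiff(heads, tolower(toks[i])), 1)
      applied <- c(applied, "keyword_swap")
    }
  }
  if (cfg$p_spelling_swap > 0 && stats::runif(1) < cfg$p_spelling_swap) {
    sw <- c(signalling = "signaling", signaling = "signalling")
    at <- which(tolower(toks) %in% names(sw))
    if (length(at)) {
      toks[at] <- unname(sw[tolower(toks[at])])
      applied <- c(applied, "spelling_swap")
    }
  }
  list(text = paste(toks, collapse = " "), applied = applied)
}

.carriers_plain <- c(
  "We studied the %s, and the results were reproducible.",
  "Previous reports described the %s, which remains controversial.",
  "Several groups investigated the %s; replication is pending.",
  "This study examined the %s.",
  "Recent experiments implicated the %s, although the mechanism is unclear."
)

.carriers_gene <- c(
  "Treatment with %s activated the %s, while %s remained unchanged.",
  "Experiments showed that %s regulates the %s, and %s was unaffected.",
  "Knockdown of %s disrupted the %s, whereas %s did not."
)

.distractors <- c(
  "The diagnostic pathway was followed by the clinicians.",
  "A clinical care pathway was described for elderly patients.",
  "The referral network was examined across participating hospitals.",
  "Such administrative cascades were reported in the survey.",
  "The audit pathway remained unchanged throughout the trial."
)

#' Generate a synthetic annotated corpus from a pathway dictionary
#'
#' Each non-distractor sentence embeds one dictionary name (perturbed
#' according to the configuration) or, at `rule_only_rate`, a keyword + gene
#' name absent from the dictionary, inside a carrier sentence; the exact gold
#' span of the embedded (possibly perturbed) mention is recorded. Identical
#' inputs and seed give byte-identical output.
#'
#' @param dict A `pathway_dictionary` (the original, non-variant entries are
#'   sampled).
#' @param n_sentences Number of sentences to generate.
#' @param cfg A [perturbation_config()].
#' @return List with `documents` (named list of tagged [path_document()]),
#'   `gold` (annotation data frame, `source = "gold"`) and `manifest` (one
#'   row per sentence: kind, entry id, perturbations applied).
#' @export
generate_synthetic_corpus <- function(dict, n_sentences,
                                      cfg = perturbation_config()) {
  stopifnot(inherits(dict, "pathway_dictionary"), n_sentences >= 1,
            inherits(cfg, "perturbation_config"))
  entries <- dict$entries[!dict$entries$is_variant, , drop = FALSE]
  if (cfg$keywordless_mentions) {
    kw <- keyword_set()$base
    keep <- vapply(strsplit(tolower(entries$name), " ", fixed = TRUE),
                   function(tk) !any(tk %in% kw), TRUE)
    entries <- entries[keep, , drop = FALSE]
  }
  if (!nrow(entries)) stop("dictionary has no eligible entries")
  .with_seed(cfg$seed, {
    stopwords <- .synth_stopwords()
    carrier_syms <- .make_symbols(200, digits = TRUE)
    dict_toks <- unique(unlist(dict$tokens, use.names = FALSE))
    carrier_syms <- setdiff(carrier_syms, toupper(dict_toks))
    unused <- sample(nrow(entries))
    sent <- character(n_sentences)
    kind <- character(n_sentences)
    entry_id <- rep(NA_character_, n_sentences)
    perturb <- rep("", n_sentences)
    mention <- rep(NA_character_, n_sentences)
    m_start <- rep(NA_integer_, n_sentences)
    for (i in seq_len(n_sentences)) {
      if (stats::runif(1) < cfg$distractor_rate) {
        sent[i] <- sample(.distractors, 1)
        kind[i] <- "distractor"
        next
      }
      if (stats::runif(1) < cfg$rule_only_rate) {
        g <- sample(carrier_syms, 1)
        m <- paste(g, sample(c("signalling pathway", "signalling cascade",
                               "signalling network"), 1))
        kind[i] <- "rule_only"
      } else {
        if (cfg$distinct_mentions) {
          if (!length(unused)) stop("not enough distinct dictionary entries ",
                                    "for n_sentences = ", n_sentences)
          row <- unused[1L]
          unused <- unused[-1L]
        } else {
          row <- sample(nrow(entries), 1)
        }
        p <- .perturb_name(entries$name[row], cfg, stopwords)
        m <- p$text
        entry_id[i] <- entries$entry_id[row]
        perturb[i] <- paste(p$applied, collapse = "+")
        kind[i] <- "mention"
      }
      if (cfg$carrier_genes || kind[i] == "rule_only") {
        tpl <- sample(.carriers_gene, 1)
        gs <- sample(carrier_syms, 2)
        s <- sprintf(tpl, gs[1], m, gs[2])
      } else {
        tpl <- sample(.carriers_plain, 1)
        s <- sprintf(tpl, m)
      }
      sent[i] <- s
      mention[i] <- m
      m_start[i] <- as.integer(regexpr(m, s, fixed = TRUE)) - 1L
    }
    n_docs <- ceiling(n_sentences / cfg$sentences_per_doc)
    doc_of <- rep(seq_len(n_docs), each = cfg$sentences_per_doc,
                  length.out = n_sentences)
    doc_ids <- sprintf("synth%03d", seq_len(n_docs))
    documents <- list()
    gold <- list()
    for (d in seq_len(n_docs)) {
      ix <- which(doc_of == d)
      text <- paste(sent[ix], collapse = " ")
      offs <- cumsum(c(0L, nchar(sent[ix]) + 1L))[seq_along(ix)]
      doc <- path_document(text, doc_id = doc_ids[d])
      documents[[doc_ids[d]]] <- doc
      has_m <- !is.na(mention[ix])
      if (any(has_m)) {
        st <- offs[has_m] + m_start[ix][has_m]
        en <- st + nchar(mention[ix][has_m])
        gold[[d]] <- annotation_frame(doc_id = doc_ids[d], start = st,
                                      end = en,
                                      surface = mention[ix][has_m],
                                      type = "pathway_mention",
                                      source = "gold",
                                      entry_id = entry_id[ix][has_m])
      }
    }
    manifest <- data.frame(sentence = seq_len(n_sentences),
                           doc_id = doc_ids[doc_of], kind = kind,
                           entry_id = entry_id, perturbations = perturb,
                           mention = mention, stringsAsFactors = FALSE)
    list(documents = documents, gold = .bind_annotations(gold),
         manifest = manifest)
  })
}
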