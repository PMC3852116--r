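#' Pathway keyword set for the rule engine
#'
#' Base keywords are single tokens; combinations are multi-token phrases that
#' are preferred over their parts (longest match at a position, consumed
#' tokens are not rematched). Matching is token-based and case-insensitive,
#' accepting both British and American spellings and plural forms.
#'
#' @param base Character vector of single-token keywords.
#' @param combinations Character vector of multi-token keyword phrases.
#' @return List of class `keyword_set` with `base` and tokenized
#'   `combinations` (ordered longest first).
#' @export
keyword_set <- function(base = NULL, combinations = NULL) {
  if (is.null(base)) {
    base <- c("pathway", "pathways", "signalling", "signaling",
              "transduction", "cascade", "cascades", "network", "networks")
  }
  if (is.null(combinations)) {
    spell <- c("signalling", "signaling")
    heads <- c("pathway", "pathways", "cascade", "cascades",
               "network", "networks")
    combinations <- c(as.vector(outer(spell, heads, paste)),
                      "signal transduction",
                      "signal transduction pathway",
                      "signal transduction pathways")
  }
  combo_toks <- lapply(tolower(combinations), function(x) tokenize(x)$text)
  if (any(lengths(combo_toks) < 2L)) {
    stop("keyword combinations must contain at least 2 tokens")
  }
  combo_toks <- combo_toks[order(-lengths(combo_toks))]
  structure(list(base = tolower(base), combinations = combo_toks),
            class = "keyword_set")
}

#' Find keyword occurrences in a document
#'
#' @param doc A [path_document()].
#' @param keywords A [keyword_set()].
#' @return Data frame with token row range (`first`, `last` into
#'   `doc$tokens`), character span (`start`, `end`) and `surface`.
#' @export
find_keywords <- function(doc, keywords = keyword_set()) {
  stopifnot(inherits(doc, "path_document"), inherits(keywords, "keyword_set"))
  toks <- doc$tokens
  low <- tolower(toks$text)
  hits <- list()
  for (rows in .sentence_token_rows(doc)) {
    n <- length(rows)
    si <- 1L
    while (si <= n) {
      len <- 0L
      for (cmb in keywords$combinations) {
        L <- length(cmb)
        if (si + L - 1L <= n &&
            identical(low[rows[si:(si + L - 1L)]], cmb)) {
          len <- L
          break
        }
      }
      if (len == 0L && low[rows[si]] %in% keywords$base) len <- 1L
      if (len > 0L) {
        hits[[length(hits) + 1L]] <-
          data.frame(first = rows[si], last = rows[si + len - 1L])
        si <- si + len
      } else {
        si <- si + 1L
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(first = integer(), last = integer(), start = integer(),
                      end = integer(), surface = character(),
                      stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  h$start <- toks$start[h$first]
  h$end <- toks$end[h$last]
  h$surface <- substring(doc$text, h$start + 1L, h$end)
  h
}

#' Extend a keyword anchor backwards to a stop token
#'
#' Scans left from the token before the anchor and stops at the first token
#' whose [token_class()] is a determiner, separator, preposition/
#' subordinating conjunction, wh-word or verb, or at the sentence start. The
#' segment begins at the token after the stop token and ends at the anchor
#' end. Prepositions listed in `transparent` (by default `"of"`) do not stop
#' the scan: `"of"` is noun-phrase-internal and ubiquitous inside pathway
#' names ("mammalian target of rapamycin (mTOR) signalling pathways"), unlike
#' the clausal prepositions that genuinely delimit mentions.
#'
#' @param doc A POS-tagged [path_document()].
#' @param anchor One row of [find_keywords()] output (list or single-row data
#'   frame with `first` and `last`).
#' @param transparent Preposition surfaces that never stop the scan.
#' @return List with token rows `first`, `last` delimiting the segment.
#' @export
backward_extend <- function(doc, anchor, transparent = "of") {
  toks <- doc$tokens
  if (any(is.na(toks$pos))) stop("document must be POS-tagged; run pos_tag()")
  first <- anchor$first
  sent <- toks$sentence[first]
  i <- first - 1L
  while (i >= 1L && toks$sentence[i] == sent) {
    cls <- token_class(toks$text[i], toks$pos[i])
    stopper <- cls %in% c("determiner", "separator", "preposition_subconj",
                          "wh_word", "verb") &&
      !(cls == "preposition_subconj" && tolower(toks$text[i]) %in% transparent)
    if (stopper) break
    i <- i - 1L
  }
  list(first = i + 1L, last = anchor$last, anchor_last = anchor$last)
}

#' Extend a rule segment forward through pathway verb phrases
#'
#' If the tokens immediately following the keyword anchor begin with one of
#' the pathway-specific verb phrases (e.g. "regulated by"), the segment is
#' extended rightward through subsequent tokens up to (excluding) the first
#' punctuation token or the sentence end; otherwise it is returned unchanged.
#'
#' @param doc A [path_document()].
#' @param segment Output of [backward_extend()].
#' @param verb_phrases Character vector of phrases.
#' @return Segment list with possibly extended `last`.
#' @export
forward_extend <- function(doc, segment,
                           verb_phrases = c("induced by", "regulated by",
                                            "mediated by", "mediated through",
                                            "activated by", "triggered by")) {
  toks <- doc$tokens
  low <- tolower(toks$text)
  after <- segment$anchor_last + 1L
  sent <- toks$sentence[segment$anchor_last]
  n_tok <- nrow(toks)
  vp <- lapply(tolower(verb_phrases), function(x) tokenize(x)$text)
  started <- FALSE
  for (p in vp) {
    L <- length(p)
    idx <- after + seq_len(L) - 1L
    if (max(idx) <= n_tok && all(toks$sentence[idx] == sent) &&
        identical(low[idx], p)) {
      started <- TRUE
      break
    }
  }
  if (!started) return(segment)
  i <- after
  while (i <= n_tok && toks$sentence[i] == sent && !.is_punct(toks$text[i])) {
    i <- i + 1L
  }
  segment$last <- i - 1L
  segment
}

#' Apply keyword-anchored rules gated on gene/protein mentions
#'
#' For every keyword occurrence, a segment is built by backward and forward
#' extension; a segment becomes a pathway-mention annotation only when at
#' least one gene/protein mention lies fully inside it. Rule annotations
#' carry no score and no entry id.
#'
#' @param doc A POS-tagged [path_document()].
#' @param keywords A [keyword_set()].
#' @param recognizer Either a function mapping the document to gene-mention
#'   annotations (see [gene_recognizer()]) or a precomputed annotation data
#'   frame (e.g. imported from standoff output of an external tagger).
#' @param transparent Passed to [backward_extend()].
#' @param verb_phrases Passed to [forward_extend()].
#' @return Annotation data frame with `source = "rule"`.
#' @export
apply_rules <- function(doc, keywords = keyword_set(),
                        recognizer = gene_recognizer(),
                        transparent = "of", verb_phrases = NULL) {
  stopifnot(inherits(doc, "path_document"))
  genes <- if (is.function(recognizer)) {
    tryCatch(recognizer(doc),
             error = function(e) stop("gene recognizer failed on document '",
                                      doc$doc_id, "': ", conditionMessage(e)))
  } else if (is.data.frame(recognizer)) {
    recognizer[recognizer$doc_id == doc$doc_id, , drop = FALSE]
  } else {
    stop("`recognizer` must be a function or an annotation data frame")
  }
  genes <- genes[genes$type == "gene_mention", , drop = FALSE]
  anchors <- find_keywords(doc, keywords)
  if (!nrow(anchors)) return(annotation_frame())
  toks <- doc$tokens
  segs <- list()
  for (k in seq_len(nrow(anchors))) {
    seg <- backward_extend(doc, anchors[k, ], transparent = transparent)
    seg <- if (is.null(verb_phrases)) forward_extend(doc, seg) else
      forward_extend(doc, seg, verb_phrases = verb_phrases)
    s0 <- toks$start[seg$first]
    s1 <- toks$end[seg$last]
    gated <- nrow(genes) > 0 && any(genes$start >= s0 & genes$end <= s1)
    if (gated) segs[[length(segs) + 1L]] <- c(s0, s1)
  }
  if (!length(segs)) return(annotation_frame())
  sp <- unique(do.call(rbind, segs))
  annotation_frame(doc_id = doc$doc_id, start = sp[, 1], end = sp[, 2],
                   surface = substring(doc$text, sp[, 1] + 1L, sp[, 2]),
                   type = "pathway_mention", source = "rule")
}

.gene_stoplist <- c("the", "a", "an", "of", "in", "and", "or", "is", "was",
                    "for", "to", "by", "with", "at", "on", "we", "it", "as",
                    "fig", "figs", "table", "eq")

#' Deterministic lexicon + morphology gene/protein recognizer
#'
#' A reproducible stand-in for trained gene taggers: case-sensitive
#' token-sequence matches of a lexicon of gene/protein symbols and names,
#' plus a morphology heuristic tagging tokens that mix uppercase letters and
#' digits (length at least 2, not in a stop list), such as `"MEK1"`.
#' External taggers can replace it entirely: [apply_rules()] accepts any
#' function or precomputed standoff annotations.
#'
#' @param lexicon Character vector of gene symbols/names, or `NULL` for the
#'   bundled synthetic lexicon (`inst/extdata/gene_lexicon_synthetic.txt`).
#' @param stoplist Tokens never tagged by the morphology heuristic.
#' @return A function mapping a [path_document()] to gene-mention
#'   annotations.
#' @export
gene_recognizer <- function(lexicon = NULL, stoplist = .gene_stoplist) {
  if (is.null(lexicon)) {
    f <- system.file("extdata", "gene_lexicon_synthetic.txt",
                     package = "pathtag")
    if (!nzchar(f)) stop("bundled gene lexicon not found")
    lexicon <- readLines(f, encoding = "UTF-8", warn = FALSE)
    lexicon <- lexicon[!grepl("^\\s*(#|$)", lexicon)]
  }
  if (!length(lexicon)) stop("gene lexicon is empty")
  lex_toks <- lapply(lexicon, function(x) tokenize(x)$text)
  lex_toks <- lex_toks[order(-lengths(lex_toks))]
  function(doc) recognize_genes(doc, lex_toks, stoplist)
}

recognize_genes <- function(doc, lex_toks, stoplist) {
  toks <- doc$tokens
  n <- nrow(toks)
  used <- logical(n)
  out <- list()
  for (rows in .sentence_token_rows(doc)) {
    m <- length(rows)
    si <- 1L
    while (si <= m) {
      len <- 0L
      for (lt in lex_toks) {
        L <- length(lt)
        if (si + L - 1L <= m &&
            identical(toks$text[rows[si:(si + L - 1L)]], lt)) {
          len <- L
          break
        }
      }
      if (len > 0L) {
        idx <- rows[si:(si + len - 1L)]
        used[idx] <- TRUE
        out[[length(out) + 1L]] <- c(toks$start[idx[1]], toks$end[idx[len]])
        si <- si + len
      } else {
        si <- si + 1L
      }
    }
  }
  morph <- !used & nchar(toks$text) >= 2 &
    grepl("[A-Z]", toks$text) & grepl("[0-9]", toks$text) &
    !tolower(toks$text) %in% stoplist
  for (i in which(morph)) {
    out[[length(out) + 1L]] <- c(toks$start[i], toks$end[i])
  }
  if (!length(out)) return(annotation_frame())
  sp <- do.call(rbind, out)
  ord <- order(sp[, 1])
  sp <- sp[ord, , drop = FALSE]
  annotation_frame(doc_id = doc$doc_id, start = sp[, 1], end = sp[, 2],
                   surface = substring(doc$text, sp[, 1] + 1L, sp[, 2]),
                   type = "gene_mention", source = "rule")
}
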