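#' Merge dictionary and rule annotations
#'
#' Annotations overlapping nothing else pass through unchanged. Overlapping
#' annotations are grouped by transitive closure of the overlap relation and
#' each group is replaced by a single annotation spanning from the minimum
#' start to the maximum end, with `source = "merged"`, score equal to the
#' maximum member score (`NA` if none) and the dictionary entry id kept when
#' exactly one distinct member id exists. The output is pairwise
#' non-overlapping within each document and sorted by position.
#'
#' @param dict_anns,rule_anns Annotation data frames (either may be empty;
#'   the two arguments are symmetric and may in fact hold any sources).
#' @return Merged annotation data frame.
#' @export
merge_annotations <- function(dict_anns, rule_anns = annotation_frame()) {
  anns <- .bind_annotations(list(dict_anns, rule_anns))
  if (!nrow(anns)) return(anns)
  out <- lapply(split(anns, anns$doc_id), .merge_one_doc)
  res <- .bind_annotations(out)
  res[order(res$doc_id, res$start), , drop = FALSE]
}

.merge_one_doc <- function(a) {
  a <- a[order(a$start, a$end), , drop = FALSE]
  n <- nrow(a)
  grp <- integer(n)
  g <- 0L
  cur_end <- -Inf
  for (i in seq_len(n)) {
    if (a$start[i] < cur_end) {
      grp[i] <- g
      cur_end <- max(cur_end, a$end[i])
    } else {
      g <- g + 1L
      grp[i] <- g
      cur_end <- a$end[i]
    }
  }
  pieces <- lapply(split(seq_len(n), grp), function(ix) {
    if (length(ix) == 1L) return(a[ix, , drop = FALSE])
    s0 <- min(a$start[ix]); s1 <- max(a$end[ix])
    sc <- a$score[ix]
    ids <- unique(a$entry_id[ix][!is.na(a$entry_id[ix])])
    surf <- a$surface[ix][1]
    # reconstruct covering surface when members come from one document text:
    # members are substrings, so the union surface spans min..max; rebuild it
    # from the widest member when possible, else leave the leftmost surface.
    wide <- which(a$start[ix] == s0 & a$end[ix] == s1)
    if (length(wide)) surf <- a$surface[ix][wide[1]]
    annotation_frame(doc_id = a$doc_id[ix][1], start = s0, end = s1,
                     surface = surf, type = "pathway_mention",
                     score = if (all(is.na(sc))) NA_real_ else max(sc, na.rm = TRUE),
                     source = "merged",
                     entry_id = if (length(ids) == 1L) ids else NA_character_)
  })
  .bind_annotations(pieces)
}

#' Merge annotations with surfaces recovered from document text
#'
#' Convenience wrapper over [merge_annotations()] that re-derives the surface
#' of covering annotations from the document text.
#'
#' @param dict_anns,rule_anns Annotation data frames.
#' @param documents Named list of [path_document()] objects.
#' @return Merged annotation data frame with exact surfaces.
#' @export
merge_with_text <- function(dict_anns, rule_anns, documents) {
  res <- merge_annotations(dict_anns, rule_anns)
  if (!nrow(res)) return(res)
  for (i in seq_len(nrow(res))) {
    d <- documents[[res$doc_id[i]]]
    if (!is.null(d)) {
      res$surface[i] <- substring(d$text, res$start[i] + 1L, res$end[i])
    }
  }
  res
}

#' Fill precision, recall and F1 from TP/FP/FN counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, each defined as 0
#' when its denominator is 0.
#'
#' @param counts List or data frame with `TP`, `FP`, `FN`.
#' @return The input as a one-row data frame with `P`, `R`, `F1` added.
#' @export
compute_prf <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  P <- if (TP + FP > 0) TP / (TP + FP) else 0
  R <- if (TP + FN > 0) TP / (TP + FN) else 0
  F1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  data.frame(TP = TP, FP = FP, FN = FN, P = P, R = R, F1 = F1)
}

#' Score predictions against gold annotations
#'
#' Strict matching counts one-to-one pairs with identical spans; lenient
#' matching pairs predictions (in offset order) greedily with the first
#' unmatched overlapping gold span, so one prediction can never count twice.
#' Counts are consistent: `TP + FP = |pred|`, `TP + FN = |gold|`.
#'
#' @param gold,pred Annotation data frames (matched per document).
#' @param mode `"strict"` or `"lenient"`.
#' @return One-row data frame `TP`, `FP`, `FN`, `P`, `R`, `F1`.
#' @export
match_annotations <- function(gold, pred, mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  docs <- union(unique(gold$doc_id), unique(pred$doc_id))
  TP <- 0L
  for (d in docs) {
    g <- gold[gold$doc_id == d, , drop = FALSE]
    p <- pred[pred$doc_id == d, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    p <- p[order(p$start, p$end), , drop = FALSE]
    taken <- logical(nrow(g))
    for (i in seq_len(nrow(p))) {
      hit <- if (mode == "strict") {
        which(!taken & g$start == p$start[i] & g$end == p$end[i])
      } else {
        which(!taken & g$start < p$end[i] & p$start[i] < g$end)
      }
      if (length(hit)) {
        taken[hit[1]] <- TRUE
        TP <- TP + 1L
      }
    }
  }
  compute_prf(list(TP = TP, FP = nrow(pred) - TP, FN = nrow(gold) - TP))
}

#' Strict and lenient evaluation table for several prediction sets
#'
#' Produces the conventional benchmark-shaped table: one row per method, with
#' recall, precision and F1 under both strict and lenient span matching.
#'
#' @param gold Gold annotation data frame.
#' @param predictions Named list of annotation data frames.
#' @return Data frame with columns `method`, `strict_R`, `strict_P`,
#'   `strict_F1`, `lenient_R`, `lenient_P`, `lenient_F1`.
#' @export
evaluation_report <- function(gold, predictions) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  rows <- lapply(names(predictions), function(nm) {
    s <- match_annotations(gold, predictions[[nm]], "strict")
    l <- match_annotations(gold, predictions[[nm]], "lenient")
    data.frame(method = nm, strict_R = s$R, strict_P = s$P, strict_F1 = s$F1,
               lenient_R = l$R, lenient_P = l$P, lenient_F1 = l$F1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Corpus-level mention statistics
#'
#' @param anns Annotation data frame.
#' @param n_documents Number of documents in the corpus (defaults to the
#'   number of distinct `doc_id`s carrying annotations).
#' @param case_sensitive Treat surfaces case-sensitively when counting
#'   unique mentions? Default `TRUE` ("lexicographically unique").
#' @return One-row data frame: `total`, `unique`, `singletons` (surfaces
#'   occurring exactly once), `mentions_per_doc`, `unique_per_doc`.
#' @export
aggregate_mentions <- function(anns, n_documents = NULL,
                               case_sensitive = TRUE) {
  if (is.null(n_documents)) n_documents <- length(unique(anns$doc_id))
  if (!nrow(anns) || n_documents == 0) {
    return(data.frame(total = 0L, unique = 0L, singletons = 0L,
                      mentions_per_doc = 0, unique_per_doc = 0))
  }
  surf <- if (case_sensitive) anns$surface else tolower(anns$surface)
  tab <- table(surf)
  data.frame(total = nrow(anns), unique = length(tab),
             singletons = sum(tab == 1L),
             mentions_per_doc = nrow(anns) / n_documents,
             unique_per_doc = length(tab) / n_documents)
}
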