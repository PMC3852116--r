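#' Configuration of the soft dictionary matcher
#'
#' @param lower_threshold Score below which candidate matches are discarded
#'   during start-point detection and window growth (default 0.40).
#' @param upper_threshold Score a window must reach to be annotated
#'   (default 0.90).
#' @param max_window Maximum window length in tokens (default 25, allowing
#'   stop-word insertions beyond the longest dictionary names).
#' @param miss_limit Number of consecutive empty window lengths tolerated
#'   before a check stops; growth aborts after `miss_limit + 1` consecutive
#'   empties, i.e. when *more than* `miss_limit` lengths found nothing
#'   (default 4).
#' @return List of class `matcher_config`.
#' @export
matcher_config <- function(lower_threshold = 0.40, upper_threshold = 0.90,
                           max_window = 25L, miss_limit = 4L) {
  stopifnot(lower_threshold >= 0, upper_threshold <= 1,
            lower_threshold <= upper_threshold,
            max_window >= 1, miss_limit >= 1)
  structure(list(lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold,
                 max_window = as.integer(max_window),
                 miss_limit = as.integer(miss_limit)),
            class = "matcher_config")
}

# Per-run cache: for each query token, the dictionary vocabulary tokens whose
# Jaro-Winkler similarity reaches the inner threshold (with their JW values).
.matcher_context <- function(dict, model, mcfg) {
  env <- new.env(parent = emptyenv())
  env$vocab <- names(dict$doc_freq)
  env$close <- new.env(parent = emptyenv())
  env$start <- new.env(parent = emptyenv())
  env$dict <- dict
  env$model <- model
  env$mcfg <- mcfg
  env$entry_tokens <- lapply(model$entry_weights, names)
  env
}

.close_set <- function(ctx, token) {
  hit <- get0(token, envir = ctx$close, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  jw <- as.numeric(.jw_cross(token, ctx$vocab, ctx$mcfg$jw_prefix_scale,
                             ctx$mcfg$jw_prefix_max))
  keep <- jw >= ctx$mcfg$inner_jw_threshold
  out <- stats::setNames(jw[keep], ctx$vocab[keep])
  assign(token, out, envir = ctx$close)
  out
}

# Score of one entry against precomputed query weights and close sets.
.score_entry <- function(vs, closes, vt) {
  tn <- names(vt)
  total <- 0
  for (i in seq_along(vs)) {
    cl <- closes[[i]]
    if (!length(cl)) next
    pos <- match(names(cl), tn)
    ok <- !is.na(pos)
    if (!any(ok)) next
    cl <- cl[ok]; pos <- pos[ok]
    best <- max(cl)
    cand <- which(cl == best)
    if (length(cand) > 1L) cand <- cand[order(-vt[pos[cand]], tn[pos[cand]])]
    j <- pos[cand[1L]]
    total <- total + vs[i] * vt[j] * best
  }
  min(1, max(0, unname(total)))
}

.lookup_ctx <- function(ctx, query_tokens, theta, first_only = FALSE) {
  vs <- tfidf_vector(query_tokens, ctx$model)
  if (!length(vs)) return(integer())
  closes <- lapply(names(vs), .close_set, ctx = ctx)
  cand_tok <- unique(unlist(lapply(closes, names), use.names = FALSE))
  if (!length(cand_tok)) return(integer())
  cand <- sort(unique(unlist(ctx$dict$token_index[cand_tok], use.names = FALSE)))
  scores <- numeric(length(cand))
  for (k in seq_along(cand)) {
    scores[k] <- .score_entry(vs, closes, ctx$model$entry_weights[[cand[k]]])
    if (first_only && scores[k] >= theta) {
      return(stats::setNames(scores[k], cand[k]))
    }
  }
  keep <- scores >= theta
  cand <- cand[keep]; scores <- scores[keep]
  if (!length(cand)) return(integer())
  ord <- order(-scores, ctx$dict$entries$entry_id[cand])
  stats::setNames(scores[ord], cand[ord])
}

#' Rank dictionary entries by SoftTFIDF similarity to a query
#'
#' Candidate entries are restricted through the inverted token index to those
#' sharing a token (or a Jaro-Winkler-close token) with the query; the
#' restriction is exact — the result equals brute-force scoring of every
#' entry at the same threshold, because an entry with no close token pair
#' scores zero.
#'
#' @param query_tokens Character vector, the query token bag (lowercased
#'   internally).
#' @param dict A `pathway_dictionary`.
#' @param model A [tfidf_model()] built from `dict`.
#' @param theta Minimum score to report.
#' @param mcfg A [metric_config()].
#' @return Data frame `entry_id`, `score`, descending by score with ties
#'   broken by id. `entry_id` is the stored entry identifier (variants carry
#'   their `#v` suffix).
#' @export
lookup <- function(query_tokens, dict, model, theta = 0.40,
                   mcfg = metric_config()) {
  stopifnot(inherits(dict, "pathway_dictionary"), inherits(model, "tfidf_model"))
  ctx <- .matcher_context(dict, model, mcfg)
  res <- .lookup_ctx(ctx, tolower(query_tokens), theta)
  data.frame(entry_id = dict$entries$entry_id[as.integer(names(res))],
             score = as.numeric(res), stringsAsFactors = FALSE)
}

.sentence_token_rows <- function(doc) {
  split(seq_len(nrow(doc$tokens)), doc$tokens$sentence)
}

.is_punct <- function(tok) grepl("^[^\\p{L}\\p{N}]+$", tok, perl = TRUE)

#' Find candidate start points for soft matching in a document
#'
#' A token is a start point when a single-token lookup at the lower threshold
#' returns at least one entry, which prunes matching attempts from tokens
#' that resemble nothing in the dictionary.
#'
#' @inheritParams scan_document
#' @return Integer vector of row indices into `doc$tokens`.
#' @export
find_start_points <- function(doc, dict, model, cfg = matcher_config(),
                              mcfg = metric_config()) {
  ctx <- .matcher_context(dict, model, mcfg)
  which(.start_flags(ctx, tolower(doc$tokens$text), cfg))
}

.start_flags <- function(ctx, lower_tokens, cfg) {
  vapply(lower_tokens, function(tk) {
    hit <- get0(tk, envir = ctx$start, inherits = FALSE)
    if (is.null(hit)) {
      hit <- length(.lookup_ctx(ctx, tk, cfg$lower_threshold,
                                first_only = TRUE)) > 0
      assign(tk, hit, envir = ctx$start)
    }
    hit
  }, TRUE, USE.NAMES = FALSE)
}

#' Soft dictionary matching over a document
#'
#' For every start point, windows of growing length (1 to `max_window`) are
#' scored against the dictionary at the lower threshold; a run of more than
#' `miss_limit` consecutive empty window lengths aborts the check. The
#' longest window whose best score reaches the upper threshold becomes a
#' dictionary annotation carrying that score and entry id. Windows never
#' cross sentence boundaries and stop growing at separator tokens (comma,
#' period, semicolon, colon). Overlapping annotations from different start
#' points are resolved by score, then span length, then leftmost position.
#'
#' @param doc A [path_document()].
#' @param dict A `pathway_dictionary`.
#' @param model A [tfidf_model()] built from `dict`.
#' @param cfg A [matcher_config()].
#' @param mcfg A [metric_config()].
#' @return Annotation data frame with `source = "dictionary"`; `entry_id`
#'   reports the parent dictionary id (variants resolve to their original
#'   entry).
#' @export
scan_document <- function(doc, dict, model, cfg = matcher_config(),
                          mcfg = metric_config()) {
  stopifnot(inherits(doc, "path_document"))
  ctx <- .matcher_context(dict, model, mcfg)
  toks <- doc$tokens
  low <- tolower(toks$text)
  is_start <- .start_flags(ctx, low, cfg)
  found <- list()
  for (rows in .sentence_token_rows(doc)) {
    n <- length(rows)
    for (si in seq_len(n)) {
      r0 <- rows[si]
      if (!is_start[r0]) next
      misses <- 0L
      best <- NULL
      max_len <- min(cfg$max_window, n - si + 1L)
      for (L in seq_len(max_len)) {
        r_last <- rows[si + L - 1L]
        if (token_class(toks$text[r_last], "")[1] == "separator") break
        res <- .lookup_ctx(ctx, low[rows[si:(si + L - 1L)]], cfg$lower_threshold)
        if (!length(res)) {
          misses <- misses + 1L
          if (misses > cfg$miss_limit) break
        } else {
          misses <- 0L
          if (res[1] >= cfg$upper_threshold) {
            best <- list(len = L, entry = as.integer(names(res)[1]),
                         score = unname(res[1]))
          }
        }
      }
      if (!is.null(best)) {
        r_end <- rows[si + best$len - 1L]
        found[[length(found) + 1L]] <-
          data.frame(start = toks$start[r0], end = toks$end[r_end],
                     score = best$score, entry = best$entry)
      }
    }
  }
  if (!length(found)) return(annotation_frame())
  cand <- do.call(rbind, found)
  keep <- .resolve_overlaps(cand)
  annotation_frame(doc_id = doc$doc_id, start = keep$start, end = keep$end,
                   surface = substring(doc$text, keep$start + 1L, keep$end),
                   type = "pathway_mention", score = keep$score,
                   source = "dictionary",
                   entry_id = dict$entries$parent_id[keep$entry])
}

# highest score wins; ties -> longer span; ties -> leftmost
.resolve_overlaps <- function(cand) {
  ord <- order(-cand$score, -(cand$end - cand$start), cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    if (any(kept)) {
      k <- which(kept)
      ok <- all(cand$end[i] <= cand$start[k] | cand$start[i] >= cand$end[k])
    }
    kept[i] <- ok
  }
  out <- cand[kept, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Exact dictionary matching baseline
#'
#' Case-insensitive verbatim token-sequence matching of dictionary names,
#' longest match wins at each position — the conventional dictionary NER
#' lookup that soft matching is designed to improve upon.
#'
#' @inheritParams scan_document
#' @return Annotation data frame with `source = "dictionary"` and score 1.
#' @export
exact_match_baseline <- function(doc, dict) {
  stopifnot(inherits(doc, "path_document"), inherits(dict, "pathway_dictionary"))
  toks <- doc$tokens
  low <- tolower(toks$text)
  first <- vapply(dict$tokens, `[[`, "", 1L)
  by_first <- split(seq_along(dict$tokens), first)
  lens <- lengths(dict$tokens)
  out <- list()
  for (rows in .sentence_token_rows(doc)) {
    n <- length(rows)
    si <- 1L
    while (si <= n) {
      cand <- by_first[[low[rows[si]]]]
      best_len <- 0L; best_entry <- NA_integer_
      if (!is.null(cand)) {
        for (e in cand) {
          L <- lens[e]
          if (L <= best_len || si + L - 1L > n) next
          if (identical(low[rows[si:(si + L - 1L)]], dict$tokens[[e]])) {
            best_len <- L; best_entry <- e
          }
        }
      }
      if (best_len > 0L) {
        r0 <- rows[si]; r1 <- rows[si + best_len - 1L]
        out[[length(out) + 1L]] <-
          data.frame(start = toks$start[r0], end = toks$end[r1],
                     entry = best_entry)
        si <- si + best_len
      } else {
        si <- si + 1L
      }
    }
  }
  if (!length(out)) return(annotation_frame())
  m <- do.call(rbind, out)
  annotation_frame(doc_id = doc$doc_id, start = m$start, end = m$end,
                   surface = substring(doc$text, m$start + 1L, m$end),
                   type = "pathway_mention", score = 1,
                   source = "dictionary",
                   entry_id = dict$entries$parent_id[m$entry])
}
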