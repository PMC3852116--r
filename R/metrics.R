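#' Configuration of the string-similarity metrics
#'
#' @param jw_prefix_scale Winkler prefix boost scale `p` (default 0.1;
#'   must lie in `[0, 0.25]` so the boosted score stays in `[0, 1]`).
#' @param jw_prefix_max Maximum common-prefix length rewarded (default 4).
#' @param inner_jw_threshold Jaro-Winkler threshold above which two tokens are
#'   considered "close" inside SoftTFIDF (default 0.9).
#' @return List of class `metric_config`.
#' @export
metric_config <- function(jw_prefix_scale = 0.1, jw_prefix_max = 4L,
                          inner_jw_threshold = 0.9) {
  stopifnot(jw_prefix_scale >= 0, jw_prefix_scale <= 0.25,
            jw_prefix_max >= 0,
            inner_jw_threshold >= 0, inner_jw_threshold <= 1)
  structure(list(jw_prefix_scale = jw_prefix_scale,
                 jw_prefix_max = as.integer(jw_prefix_max),
                 inner_jw_threshold = inner_jw_threshold),
            class = "metric_config")
}

#' Jaro similarity
#'
#' Character-level similarity in `[0, 1]` based on matching characters within
#' a window of `floor(max(|s|,|t|)/2) - 1` and half-counted transpositions.
#' Returns 0 when either string is empty or no characters match.
#'
#' @param s,t Character vectors (recycled pairwise).
#' @return Numeric vector of similarities.
#' @examples
#' jaro("MARTHA", "MARHTA") # 0.9444...
#' @export
jaro <- function(s, t) {
  .jaro_pairs(enc2utf8(as.character(s)), enc2utf8(as.character(t)))
}

#' Jaro-Winkler similarity
#'
#' `J + l * p * (1 - J)` where `J` is the Jaro similarity and `l` the length
#' of the common prefix capped at `jw_prefix_max`; never smaller than `J`.
#'
#' @param s,t Character vectors (recycled pairwise).
#' @param cfg A [metric_config()].
#' @return Numeric vector of similarities in `[0, 1]`.
#' @examples
#' jaro_winkler("DIXON", "DICKSONX") # 0.8133...
#' @export
jaro_winkler <- function(s, t, cfg = metric_config()) {
  .jw_pairs(enc2utf8(as.character(s)), enc2utf8(as.character(t)),
            cfg$jw_prefix_scale, cfg$jw_prefix_max)
}

#' Build a TFIDF model over a pathway dictionary
#'
#' The "documents" of the model are dictionary entries: `N` is the number of
#' entries and `df[t]` the number of entries containing token `t`. Unseen
#' tokens are smoothed with `df_floor`. Per-entry unit-normalized weight
#' vectors are precomputed for the matcher.
#'
#' @param dict A `pathway_dictionary`.
#' @param df_floor Document frequency assumed for unseen tokens (default 1).
#' @return List of class `tfidf_model` with `n_docs`, `doc_freq`, `df_floor`
#'   and `entry_weights`.
#' @export
tfidf_model <- function(dict, df_floor = 1) {
  stopifnot(inherits(dict, "pathway_dictionary"), df_floor >= 1)
  model <- structure(list(n_docs = dict$n_entries, doc_freq = dict$doc_freq,
                          df_floor = df_floor, entry_weights = NULL),
                     class = "tfidf_model")
  model$entry_weights <- lapply(dict$tokens, tfidf_vector, model = model)
  model
}

#' TFIDF weight vector of a token bag
#'
#' Raw weight `V'(w) = log(TF_w + 1) * log(N / df_w)` per distinct token,
#' scaled to unit Euclidean norm. A bag whose raw weights are all zero (every
#' token occurs in every entry) returns all-zero weights.
#'
#' @param tokens Character vector: the token bag (repetitions are the term
#'   frequencies).
#' @param model A [tfidf_model()].
#' @return Named numeric vector of normalized weights over distinct tokens.
#' @export
tfidf_vector <- function(tokens, model) {
  stopifnot(inherits(model, "tfidf_model"))
  if (!length(tokens)) return(stats::setNames(numeric(), character()))
  tf <- table(tokens)
  df <- model$doc_freq[names(tf)]
  df[is.na(df)] <- model$df_floor
  raw <- log(as.numeric(tf) + 1) * log(model$n_docs / as.numeric(df))
  nrm <- sqrt(sum(raw^2))
  w <- if (nrm > 0) raw / nrm else raw
  stats::setNames(w, names(tf))
}

#' SoftTFIDF similarity between two token bags
#'
#' For each token `w` of `S`, its best Jaro-Winkler partner `v*(w)` in `T` is
#' found; pairs with `JW >= inner_jw_threshold` contribute
#' `V_S(w) * V_T(v*(w)) * JW(w, v*(w))` and the sum is clamped to `[0, 1]`.
#' Ties for the best partner are broken by larger `T` weight, then
#' lexicographically, making the score deterministic. A bag compared to
#' itself scores 1 whenever its weight vector is nonzero.
#'
#' @param s_tokens,t_tokens Token bags (character vectors, typically
#'   lowercased).
#' @param model A [tfidf_model()].
#' @param cfg A [metric_config()].
#' @param t_weights Optional precomputed `tfidf_vector(t_tokens, model)`.
#' @return Similarity in `[0, 1]`.
#' @export
soft_tfidf <- function(s_tokens, t_tokens, model, cfg = metric_config(),
                       t_weights = NULL) {
  vs <- tfidf_vector(s_tokens, model)
  vt <- if (is.null(t_weights)) tfidf_vector(t_tokens, model) else t_weights
  if (!length(vs) || !length(vt)) return(0)
  jw <- .jw_cross(names(vs), names(vt), cfg$jw_prefix_scale, cfg$jw_prefix_max)
  total <- 0
  tn <- names(vt)
  for (i in seq_along(vs)) {
    row <- jw[i, ]
    best <- max(row)
    if (best < cfg$inner_jw_threshold) next
    cand <- which(row == best)
    if (length(cand) > 1L) {
      cand <- cand[order(-vt[cand], tn[cand])]
    }
    j <- cand[1L]
    total <- total + vs[i] * vt[j] * best
  }
  min(1, max(0, unname(total)))
}
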