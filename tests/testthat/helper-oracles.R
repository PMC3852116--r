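# Independent reference implementations used as oracles. These are literal
# transcriptions of the published formulas, written without the indexing,
# caching or vectorization of the package code paths they check.

oracle_jaro <- function(s, t) {
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0 || lb == 0) return(0)
  win <- max(0L, max(la, lb) %/% 2L - 1L)
  am <- logical(la); bm <- logical(lb)
  for (i in seq_len(la)) {
    lo <- max(1L, i - win); hi <- min(lb, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!bm[j] && a[i] == b[j]) {
        am[i] <- TRUE; bm[j] <- TRUE
        break
      }
    }
  }
  m <- sum(am)
  if (m == 0) return(0)
  t2 <- 0
  bs <- b[bm]
  as_ <- a[am]
  for (k in seq_len(m)) if (as_[k] != bs[k]) t2 <- t2 + 1
  tau <- t2 / 2
  (m / la + m / lb + (m - tau) / m) / 3
}

oracle_jw <- function(s, t, p = 0.1, max_prefix = 4) {
  j <- oracle_jaro(s, t)
  a <- strsplit(s, "")[[1]]
  b <- strsplit(t, "")[[1]]
  l <- 0
  for (i in seq_len(min(length(a), length(b), max_prefix))) {
    if (a[i] == b[i]) l <- l + 1 else break
  }
  j + l * p * (1 - j)
}

# TFIDF weights recomputed from first principles (N, df) rather than through
# the package model object.
oracle_weights <- function(tokens, n_docs, doc_freq, df_floor = 1) {
  tf <- table(tokens)
  w <- vapply(names(tf), function(tk) {
    df <- if (tk %in% names(doc_freq)) doc_freq[[tk]] else df_floor
    log(tf[[tk]] + 1) * log(n_docs / df)
  }, 0)
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w / nrm else w
}

# Brute-force SoftTFIDF: nested loop over all token pairs, no pruning.
oracle_softtfidf <- function(s_tokens, t_tokens, n_docs, doc_freq,
                             df_floor = 1, theta_jw = 0.9) {
  vs <- oracle_weights(s_tokens, n_docs, doc_freq, df_floor)
  vt <- oracle_weights(t_tokens, n_docs, doc_freq, df_floor)
  if (!length(vs) || !length(vt)) return(0)
  total <- 0
  for (w in names(vs)) {
    best_jw <- -1; best_v <- -1; best_tok <- ""
    for (v in names(vt)) {
      jw <- oracle_jw(w, v)
      better <- jw > best_jw ||
        (jw == best_jw && (vt[[v]] > best_v ||
                           (vt[[v]] == best_v && v < best_tok)))
      if (better) {
        best_jw <- jw; best_v <- vt[[v]]; best_tok <- v
      }
    }
    if (best_jw >= theta_jw) total <- total + vs[[w]] * best_v * best_jw
  }
  min(1, max(0, total))
}

random_token <- function(alpha = letters[1:6], len = 2:6) {
  paste(sample(alpha, sample(len, 1), replace = TRUE), collapse = "")
}

random_toy_dictionary <- function(n_entries = 50, vocab_size = 40) {
  vocab <- head(unique(replicate(vocab_size * 3, random_token())), vocab_size)
  names_out <- head(unique(replicate(n_entries * 3, {
    paste(sample(vocab, sample(1:4, 1), replace = TRUE), collapse = " ")
  })), n_entries)
  pathway_dictionary(sprintf("TOY:%03d", seq_along(names_out)), names_out)
}

expect_annotation_invariants <- function(anns, documents) {
  for (i in seq_len(nrow(anns))) {
    d <- documents[[anns$doc_id[i]]]
    expect_identical(substr(d$text, anns$start[i] + 1, anns$end[i]),
                     anns$surface[i])
  }
}
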