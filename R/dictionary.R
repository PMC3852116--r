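#' Load a pathway-name dictionary from a tab-separated file
#'
#' Dictionary files are UTF-8 TSV: one entry per line, `entry_id<TAB>name`,
#' `#`-prefixed comment lines and blank lines ignored. The source database is
#' parsed from the identifier prefix (`KEGG:hsa04010` has source `KEGG`).
#' With `expand_variants = TRUE`, names carrying parenthesized
#' acronyms/synonyms generate additional lookup entries (see
#' [generate_variants()]); variants keep their parent's identifier for
#' annotation provenance. Duplicate `(id, name)` pairs are collapsed.
#'
#' @param path TSV file path.
#' @param expand_variants Generate acronym/synonym variants? Default `TRUE`.
#' @param stop_entries Optional character vector of names (case-insensitive)
#'   to exclude, e.g. overly generic entries such as `"Disease"`.
#' @return A `pathway_dictionary`: entries data frame (`entry_id`, `parent_id`,
#'   `name`, `source_db`, `is_variant`), a lowercased token list per entry, an
#'   inverted token index, per-token entry frequencies (`doc_freq`) and both
#'   the raw (pre-expansion) and final entry counts.
#' @export
load_dictionary <- function(path, expand_variants = TRUE, stop_entries = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) stop("dictionary file is empty: ", path)
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 2L)
  if (length(bad)) {
    stop("malformed dictionary line ", idx[bad[1]], " (expected at least 2 ",
         "tab-separated fields): ", lines[idx[bad[1]]])
  }
  ids <- vapply(parts, `[[`, "", 1L)
  names_ <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(ids))) {
    stop("empty entry id at line ", idx[which(!nzchar(ids))[1]])
  }
  df <- data.frame(entry_id = ids, parent_id = ids, name = names_,
                   source_db = sub(":.*$", "", ids), is_variant = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[, c("entry_id", "name")]), , drop = FALSE]
  n_raw <- nrow(df)
  if (expand_variants) {
    extra <- lapply(seq_len(nrow(df)), function(i) {
      v <- generate_variants(df$name[i])
      if (!length(v)) return(NULL)
      data.frame(entry_id = paste0(df$entry_id[i], "#v", seq_along(v)),
                 parent_id = df$entry_id[i], name = v,
                 source_db = df$source_db[i], is_variant = TRUE,
                 stringsAsFactors = FALSE)
    })
    df <- rbind(df, do.call(rbind, extra))
    # a variant identical to an existing name of the same parent is redundant
    df <- df[!duplicated(df[, c("parent_id", "name")]), , drop = FALSE]
  }
  if (!is.null(stop_entries)) {
    df <- df[!tolower(df$name) %in% tolower(stop_entries), , drop = FALSE]
  }
  if (!nrow(df)) stop("dictionary has no entries after filtering")
  rownames(df) <- NULL
  .build_dictionary(df, n_raw = n_raw)
}

.build_dictionary <- function(df, n_raw = nrow(df)) {
  tokens <- lapply(df$name, function(nm) tolower(tokenize(nm)$text))
  empty <- !vapply(tokens, length, 0L)
  if (any(empty)) {
    df <- df[!empty, , drop = FALSE]
    tokens <- tokens[!empty]
    rownames(df) <- NULL
  }
  uniq <- lapply(tokens, unique)
  tok_flat <- unlist(uniq, use.names = FALSE)
  ent_flat <- rep(seq_along(uniq), lengths(uniq))
  token_index <- split(ent_flat, tok_flat)
  structure(list(entries = df, tokens = tokens, token_index = token_index,
                 doc_freq = lengths(token_index), n_entries = nrow(df),
                 n_raw = n_raw),
            class = "pathway_dictionary")
}

#' Build a dictionary from ids and names in memory
#'
#' @param entry_id,name Equal-length character vectors.
#' @param expand_variants As in [load_dictionary()].
#' @return A `pathway_dictionary`.
#' @export
pathway_dictionary <- function(entry_id, name, expand_variants = FALSE) {
  stopifnot(length(entry_id) == length(name), length(name) > 0)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(entry_id, name, sep = "\t"), tmp, useBytes = TRUE)
  load_dictionary(tmp, expand_variants = expand_variants)
}

#' @export
print.pathway_dictionary <- function(x, ...) {
  cat("<pathway_dictionary> ", x$n_entries, " entries (", x$n_raw,
      " before variant expansion), ", length(x$doc_freq), " distinct tokens, ",
      length(unique(x$entries$source_db)), " source database(s)\n", sep = "")
  invisible(x)
}

#' Write a dictionary back to TSV
#'
#' Writing the original (non-variant) entries and reloading reproduces the
#' dictionary exactly; with `variants = TRUE` variant rows are written too.
#'
#' @param dict A `pathway_dictionary`.
#' @param path Output file.
#' @param variants Include generated variant entries? Default `FALSE`.
#' @export
write_dictionary <- function(dict, path, variants = FALSE) {
  df <- dict$entries
  if (!variants) df <- df[!df$is_variant, , drop = FALSE]
  writeLines(paste(df$entry_id, df$name, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Generate acronym/synonym variants of a pathway name
#'
#' A name of the shape `"Long form (ACRO)"` yields the stripped long form and
#' each parenthesized group as additional lookup strings, e.g.
#' `"Cell adhesion molecules (CAMs)"` yields `"Cell adhesion molecules"` and
#' `"CAMs"`. Names without parenthesized material yield nothing. Parenthesized
#' groups that are part of a larger chain (not preceded by a space, as in
#' `"(MEK)/ERK"`) are left alone only insofar as the stripped base is still
#' non-empty.
#'
#' @param name Pathway name string.
#' @return Character vector of variant names (possibly empty).
#' @export
generate_variants <- function(name) {
  m <- gregexpr("\\(([^()]*)\\)", name, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  groups <- regmatches(name, list(m))[[1]]
  inner <- trimws(sub("^\\(", "", sub("\\)$", "", groups)))
  base <- gsub("\\s*\\([^()]*\\)", "", name)
  base <- trimws(gsub("\\s+", " ", base))
  out <- c(base, inner)
  out <- out[nzchar(out)]
  unique(out[tolower(out) != tolower(name)])
}

#' Lexical profile of dictionary tokens
#'
#' Ranks lowercased tokens of pathway names by relative frequency (token
#' occurrences over all token occurrences) within one source database or the
#' whole dictionary. Variant entries are excluded so each name is counted
#' once.
#'
#' @param dict A `pathway_dictionary`.
#' @param source_db A source database name or `"all"`.
#' @param top Number of rows to keep (`Inf` for all).
#' @return Data frame `token`, `count`, `percent`, descending by count.
#' @export
profile_tokens <- function(dict, source_db = "all", top = 10) {
  stopifnot(inherits(dict, "pathway_dictionary"))
  keep <- !dict$entries$is_variant
  if (!identical(source_db, "all")) {
    known <- unique(dict$entries$source_db)
    if (!source_db %in% known) {
      stop("unknown source_db '", source_db, "'; known sources: ",
           paste(sort(known), collapse = ", "))
    }
    keep <- keep & dict$entries$source_db == source_db
  }
  toks <- unlist(dict$tokens[keep], use.names = FALSE)
  if (!length(toks)) {
    return(data.frame(token = character(), count = integer(), percent = numeric()))
  }
  tab <- sort(table(toks), decreasing = TRUE)
  out <- data.frame(token = names(tab), count = as.integer(tab),
                    percent = 100 * as.integer(tab) / length(toks),
                    stringsAsFactors = FALSE)
  utils::head(out[order(-out$count, out$token), , drop = FALSE], top)
}

#' Keyword and gene/protein composition of dictionary entries
#'
#' For each source database, counts entries whose name contains at least one
#' pathway keyword, and among those, entries in which the gene/protein
#' recognizer finds at least one mention — the profile motivating the
#' keyword + gene rule design.
#'
#' @param dict A `pathway_dictionary`.
#' @param keywords A [keyword_set()].
#' @param recognizer A gene recognizer: function mapping a `path_document` to
#'   an annotation data frame (see [gene_recognizer()]).
#' @return Data frame per source: `source_db`, `total`, `with_keyword`,
#'   `with_keyword_and_gene`, `percent` (share of keyword entries that also
#'   contain a gene mention; 0 when there are no keyword entries).
#' @export
keyword_gene_composition <- function(dict, keywords = keyword_set(),
                                     recognizer = gene_recognizer()) {
  stopifnot(inherits(dict, "pathway_dictionary"))
  df <- dict$entries[!dict$entries$is_variant, , drop = FALSE]
  toks <- dict$tokens[!dict$entries$is_variant]
  has_kw <- vapply(toks, function(tk) any(tk %in% keywords$base), TRUE)
  has_gene <- rep(FALSE, nrow(df))
  check <- which(has_kw)
  for (i in check) {
    d <- path_document(df$name[i], doc_id = "entry", tag = FALSE)
    has_gene[i] <- nrow(recognizer(d)) > 0
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$source_db), function(ix) {
    wk <- sum(has_kw[ix])
    wkg <- sum(has_kw[ix] & has_gene[ix])
    data.frame(total = length(ix), with_keyword = wk,
               with_keyword_and_gene = wkg,
               percent = if (wk > 0) 100 * wkg / wk else 0)
  }))
  out <- cbind(data.frame(source_db = rownames(out), stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out[order(-out$percent, out$source_db), , drop = FALSE]
}
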