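#' Tokenize text into word and punctuation tokens with character offsets
#'
#' Tokens are maximal runs of letters/digits; every other non-whitespace
#' character (including `/`, `(`, `)`, `-`, `,`, `.`) becomes a single-character
#' token, so gene names inside slash chains such as `"ras/raf/MAPK"` are exposed
#' as separate tokens. Offsets are 0-based, half-open and counted in Unicode
#' code points; `substr(text, start + 1, end)` always reproduces the surface.
#'
#' @param text Character scalar (UTF-8).
#' @return A data frame with columns `start`, `end` (integer offsets) and
#'   `text` (token surface). Empty input yields zero rows.
#' @examples
#' tokenize("ras/raf/MAPK kinase (MEK)/ERK")$text
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer(), text = character(),
                      stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text)) return(empty)
  text <- enc2utf8(text)
  m <- gregexpr("[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(empty)
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  data.frame(start = start, end = start + len,
             text = substring(text, start + 1L, start + len),
             stringsAsFactors = FALSE)
}

#' Split text into sentence spans
#'
#' A sentence boundary is placed after a run of `.`, `!` or `?` that is
#' followed by whitespace and then an uppercase letter, a digit or the end of
#' the text. Text without a terminator is one sentence. Note that this means
#' abbreviations followed by a number ("Fig. 1") do split; the behaviour is
#' fixed and exercised in the test fixtures.
#'
#' @param text Character scalar.
#' @return Data frame with columns `start`, `end`: 0-based half-open sentence
#'   spans covering all non-whitespace text.
#' @export
split_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(start = integer(), end = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  text <- enc2utf8(text)
  m <- gregexpr("[.!?]+(?=\\s+[A-Z0-9])|[.!?]+(?=\\s*$)", text, perl = TRUE)[[1]]
  bounds <- if (m[1] == -1L) integer() else as.integer(m) + attr(m, "match.length") - 1L
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, nchar(text))
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  spans <- lapply(seq_along(starts), function(i) {
    seg <- substring(text, starts[i], ends[i])
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    c(starts[i] - 1L + lead, ends[i] - trail)
  })
  out <- do.call(rbind, spans)
  out <- out[out[, 1] < out[, 2], , drop = FALSE]
  data.frame(start = as.integer(out[, 1]), end = as.integer(out[, 2]))
}

# Closed-class lexicons for the bundled rule tagger. Verb inflections are
# generated from base forms; the domain verbs cover the carrier vocabulary of
# the synthetic corpora and common reporting verbs of abstracts.
.tagger_lexicon <- local({
  dt <- c("the", "a", "an", "this", "these", "those", "all", "such", "each",
          "every", "some", "any", "no", "both", "another", "either", "neither")
  inx <- c("of", "in", "on", "at", "by", "with", "from", "about", "into",
           "through", "during", "after", "before", "between", "under", "over",
           "because", "since", "although", "while", "if", "as", "via", "within",
           "without", "upon", "among", "against", "toward", "towards", "per",
           "than", "despite", "throughout")
  wh <- c(which = "WDT", what = "WDT", whatever = "WDT", who = "WP",
          whom = "WP", whoever = "WP", whose = "WP$", when = "WRB",
          where = "WRB", why = "WRB", how = "WRB", whenever = "WRB",
          wherever = "WRB")
  md <- c("can", "could", "may", "might", "must", "will", "would", "shall",
          "should")
  cc <- c("and", "or", "but", "nor", "yet", "so")
  prp <- c("we", "they", "it", "he", "she", "i", "you", "its", "their", "our")
  verbs <- c("activate", "regulate", "mediate", "induce", "trigger", "involve",
             "show", "demonstrate", "suggest", "indicate", "observe", "study",
             "examine", "investigate", "report", "describe", "require",
             "modulate", "inhibit", "promote", "suppress", "enhance",
             "contribute", "associate", "link", "express", "identify",
             "detect", "reveal", "remain", "include", "result", "play",
             "occur", "follow", "affect", "alter", "disrupt", "depend",
             "appear", "confirm", "implicate", "stimulate", "block", "drive",
             "control", "phosphorylate", "analyse", "analyze", "consider",
             "signal")
  tags <- c(is = "VBZ", are = "VBP", was = "VBD", were = "VBD", be = "VB",
            been = "VBN", being = "VBG", has = "VBZ", have = "VBP",
            had = "VBD", does = "VBZ", do = "VBP", did = "VBD",
            found = "VBD", find = "VB", led = "VBD", lead = "VB",
            shown = "VBN", seen = "VBN", bind = "VB", bound = "VBN")
  for (v in verbs) {
    stem <- sub("e$", "", v)
    forms <- c(v, if (grepl("(s|sh|ch)$", v)) paste0(v, "es") else paste0(v, "s"),
               paste0(stem, "ed"), paste0(stem, "ing"))
    doubled <- c(occur = "occurr", block = "block", signal = "signall")
    if (v %in% names(doubled)) {
      forms <- c(v, paste0(v, "s"), paste0(doubled[[v]], "ed"),
                 paste0(doubled[[v]], "ing"))
    }
    new <- c("VB", "VBZ", "VBD", "VBG")
    names(new) <- forms
    tags <- c(tags, new[!names(new) %in% names(tags)])
  }
  # domain nouns that a suffix heuristic would mistag
  nn <- c("signalling", "signaling", "pathway", "cascade", "network",
          "transduction", "processing", "binding")
  list(dt = dt, inx = inx, wh = wh, md = md, cc = cc, prp = prp,
       verb_tags = tags, nn = nn)
})

.tag_one <- function(tok) {
  lex <- .tagger_lexicon
  lw <- tolower(tok)
  if (grepl("^[^\\p{L}\\p{N}]+$", tok, perl = TRUE)) {
    return(switch(tok, "." = ".", "!" = ".", "?" = ".", "," = ",",
                  ";" = ":", ":" = ":", "(" = "-LRB-", ")" = "-RRB-", "SYM"))
  }
  if (grepl("^[0-9]+([.,][0-9]+)?$", tok)) return("CD")
  if (lw %in% lex$nn) return(if (grepl("s$", lw)) "NNS" else "NN")
  if (lw %in% lex$dt) return("DT")
  if (lw %in% names(lex$wh)) return(unname(lex$wh[[lw]]))
  if (lw %in% lex$inx) return("IN")
  if (lw %in% lex$md) return("MD")
  if (lw %in% lex$cc) return("CC")
  if (lw %in% lex$prp) return("PRP")
  if (lw %in% names(lex$verb_tags)) return(unname(lex$verb_tags[[lw]]))
  if (grepl("ly$", lw) && nchar(lw) > 3) return("RB")
  if (grepl("^[A-Z]", tok) && grepl("[a-z]", tok)) {
    return(if (grepl("s$", tok)) "NNPS" else "NNP")
  }
  if (grepl("s$", lw) && nchar(lw) > 3) return("NNS")
  "NN"
}

#' Assign Penn-Treebank part-of-speech tags to a document's tokens
#'
#' The default backend is a deterministic rule tagger built from closed-class
#' lexicons (determiners, prepositions, wh-words, modals, pronouns), a verb
#' lexicon with generated inflections, punctuation mapping and noun-biased
#' suffix defaults. It is intentionally reproducible: no model files, identical
#' output on every run. Any function `f(tokens) -> character` of Penn tags can
#' be supplied instead (e.g. wrapping an external tagger).
#'
#' @param doc A [path_document()].
#' @param backend `"rules"` or a function mapping a character vector of token
#'   surfaces to a character vector of Penn-Treebank tags.
#' @return The document with the `pos` column of `doc$tokens` filled.
#' @export
pos_tag <- function(doc, backend = "rules") {
  stopifnot(inherits(doc, "path_document"))
  if (is.character(backend)) {
    if (!identical(backend, "rules")) {
      stop("unknown POS backend '", backend, "'; available: \"rules\" or a function")
    }
    tags <- vapply(doc$tokens$text, .tag_one, character(1), USE.NAMES = FALSE)
  } else if (is.function(backend)) {
    tags <- backend(doc$tokens$text)
  } else {
    stop("`backend` must be \"rules\" or a function")
  }
  if (length(tags) != nrow(doc$tokens) || any(is.na(tags) | !nzchar(tags))) {
    stop("POS backend returned invalid tags")
  }
  doc$tokens$pos <- as.character(tags)
  doc
}

#' Classify a tagged token into the rule engine's stop-token classes
#'
#' The backward rules stop leftward extension at five token classes:
#' determiners (`DT`/`PDT`), separators (comma, period, semicolon, colon),
#' prepositions/subordinating conjunctions (`IN`), wh-words
#' (`WDT`/`WP`/`WP$`/`WRB`) and verbs (any `VB*`). Everything else is `other`.
#'
#' @param text Token surface(s).
#' @param pos Penn-Treebank tag(s).
#' @return Character vector over
#'   `{"determiner","separator","preposition_subconj","wh_word","verb","other"}`.
#' @export
token_class <- function(text, pos) {
  stopifnot(length(text) == length(pos))
  out <- rep("other", length(text))
  out[pos %in% c("DT", "PDT")] <- "determiner"
  out[text %in% c(",", ".", ";", ":")] <- "separator"
  out[pos == "IN"] <- "preposition_subconj"
  out[pos %in% c("WDT", "WP", "WP$", "WRB")] <- "wh_word"
  out[grepl("^VB", pos)] <- "verb"
  out
}

#' Build a preprocessed document
#'
#' Runs sentence splitting and tokenization and (optionally) POS tagging,
#' producing the container consumed by the matcher and the rule engine.
#'
#' @param text Document text (UTF-8).
#' @param doc_id Document identifier.
#' @param tag Tag tokens with [pos_tag()]? Default `TRUE`.
#' @param backend POS backend passed to [pos_tag()].
#' @return An object of class `path_document`: a list with `doc_id`, `text`,
#'   `sentences` (data frame of sentence spans) and `tokens` (data frame with
#'   `sentence`, `start`, `end`, `text`, `pos`).
#' @export
path_document <- function(text, doc_id = "doc", tag = TRUE, backend = "rules") {
  stopifnot(is.character(text), length(text) == 1L)
  text <- enc2utf8(text)
  sents <- split_sentences(text)
  toks <- tokenize(text)
  sentence <- if (nrow(toks)) {
    findInterval(toks$start, sents$start)
  } else integer()
  toks$sentence <- as.integer(sentence)
  toks$pos <- NA_character_
  doc <- structure(list(doc_id = as.character(doc_id), text = text,
                        sentences = sents,
                        tokens = toks[, c("sentence", "start", "end", "text", "pos")]),
                   class = "path_document")
  if (tag && nrow(toks)) doc <- pos_tag(doc, backend = backend)
  doc
}

#' @export
print.path_document <- function(x, ...) {
  cat("<path_document> ", x$doc_id, ": ", nrow(x$sentences), " sentence(s), ",
      nrow(x$tokens), " token(s), ", nchar(x$text), " characters\n", sep = "")
  invisible(x)
}

#' Read a directory of plain-text documents
#'
#' One document per `.txt` file; the document id is the file stem.
#'
#' @param dir Directory path.
#' @param ... Passed to [path_document()].
#' @return Named list of `path_document` objects, sorted by id.
#' @export
read_documents <- function(dir, ...) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(files)) stop("no .txt files in ", dir)
  docs <- lapply(files, function(f) {
    txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    path_document(txt, doc_id = tools::file_path_sans_ext(basename(f)), ...)
  })
  names(docs) <- vapply(docs, `[[`, "", "doc_id")
  docs
}
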