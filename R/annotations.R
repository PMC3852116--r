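#' Construct an annotation data frame
#'
#' Annotations are plain data frames shared by every component: typed character
#' spans with optional score and dictionary provenance. Offsets are 0-based,
#' half-open, in Unicode code points.
#'
#' @param doc_id,start,end,surface,type,score,source,entry_id Column vectors
#'   (recycled to a common length). `type` is one of `pathway_mention`,
#'   `gene_mention`, `keyword`; `source` one of `dictionary`, `rule`, `merged`,
#'   `gold`.
#' @return Data frame with columns `doc_id`, `start`, `end`, `surface`, `type`,
#'   `score`, `source`, `entry_id`.
#' @export
annotation_frame <- function(doc_id = character(), start = integer(),
                             end = integer(), surface = character(),
                             type = character(), score = NA_real_,
                             source = character(), entry_id = NA_character_) {
  n <- max(length(doc_id), length(start), length(end), length(surface),
           length(type), length(source))
  if (n == 0L) {
    return(data.frame(doc_id = character(), start = integer(), end = integer(),
                      surface = character(), type = character(),
                      score = numeric(), source = character(),
                      entry_id = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                    start = rep_len(as.integer(start), n),
                    end = rep_len(as.integer(end), n),
                    surface = rep_len(as.character(surface), n),
                    type = rep_len(as.character(type), n),
                    score = rep_len(as.numeric(score), n),
                    source = rep_len(as.character(source), n),
                    entry_id = rep_len(as.character(entry_id), n),
                    stringsAsFactors = FALSE)
  bad_type <- setdiff(unique(out$type), c("pathway_mention", "gene_mention", "keyword"))
  if (length(bad_type)) stop("invalid annotation type: ", paste(bad_type, collapse = ", "))
  bad_src <- setdiff(unique(out$source), c("dictionary", "rule", "merged", "gold"))
  if (length(bad_src)) stop("invalid annotation source: ", paste(bad_src, collapse = ", "))
  if (any(out$end <= out$start)) stop("annotation spans must satisfy end > start")
  out
}

.bind_annotations <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (!length(lst)) return(annotation_frame())
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Write annotations as standoff TSV
#'
#' The native interchange format: one annotation per line with columns
#' `doc_id`, `start`, `end`, `surface`, `type`, `score`, `source`, `entry_id`.
#' Missing scores/ids are written as empty fields.
#'
#' @param anns Annotation data frame.
#' @param path Output file.
#' @export
write_annotations <- function(anns, path) {
  out <- anns[, c("doc_id", "start", "end", "surface", "type", "score",
                  "source", "entry_id")]
  out$score <- ifelse(is.na(out$score), "", format(out$score, digits = 12))
  out$entry_id[is.na(out$entry_id)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read annotations from standoff TSV
#'
#' @param path File written by [write_annotations()] (or any TSV with the same
#'   columns).
#' @return Annotation data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                           colClasses = "character")
  need <- c("doc_id", "start", "end", "surface", "type", "score", "source",
            "entry_id")
  missing <- setdiff(need, names(raw))
  if (length(missing)) stop("standoff file lacks columns: ", paste(missing, collapse = ", "))
  annotation_frame(doc_id = raw$doc_id, start = as.integer(raw$start),
                   end = as.integer(raw$end), surface = raw$surface,
                   type = raw$type,
                   score = suppressWarnings(as.numeric(ifelse(raw$score == "", NA, raw$score))),
                   source = raw$source,
                   entry_id = ifelse(raw$entry_id == "", NA_character_, raw$entry_id))
}

#' Read a gold corpus: inline XML or standoff text/TSV pairs
#'
#' `format = "gate_xml"` reads inline-XML documents in which annotations are
#' embedded as elements around the annotated text (the convention used by
#' text-engineering frameworks when exporting with inline markup). The
#' document text is the concatenation of all text nodes; every element whose
#' name equals `label` becomes a gold annotation over the span of its text
#' content. `format = "standoff"` reads a directory pairing `<id>.txt` with
#' `<id>.ann` standoff TSVs.
#'
#' @param path A file (inline XML) or directory (standoff).
#' @param format `"gate_xml"` or `"standoff"`.
#' @param label Element name marking a pathway mention in inline XML.
#' @return List with `documents` (list of [path_document()]) and `gold`
#'   (annotation data frame with `source = "gold"`).
#' @export
read_gold_corpus <- function(path, format = c("gate_xml", "standoff"),
                             label = "pathway") {
  format <- match.arg(format)
  if (format == "standoff") {
    docs <- read_documents(path)
    anns <- list()
    for (id in names(docs)) {
      f <- file.path(path, paste0(id, ".ann"))
      if (file.exists(f)) anns[[id]] <- read_annotations(f)
    }
    gold <- .bind_annotations(anns)
    .check_gold_offsets(docs, gold)
    return(list(documents = docs, gold = gold))
  }
  if (!file.exists(path)) stop("no such file: ", path)
  xml <- xml2::read_xml(path)
  docs <- list()
  anns <- list()
  doc_nodes <- xml2::xml_find_all(xml, ".//document")
  if (!length(doc_nodes)) doc_nodes <- list(xml2::xml_root(xml))
  for (nd in doc_nodes) {
    id <- xml2::xml_attr(nd, "id")
    if (is.na(id)) id <- paste0("doc", length(docs) + 1L)
    walk <- function(node, offset) {
      text <- ""
      spans <- list()
      for (ch in xml2::xml_contents(node)) {
        if (inherits(ch, "xml_node") && xml2::xml_type(ch) == "text") {
          text <- paste0(text, xml2::xml_text(ch))
        } else if (xml2::xml_type(ch) == "element") {
          inner <- walk(ch, offset + nchar(text))
          if (xml2::xml_name(ch) == label) {
            spans <- c(spans, list(c(offset + nchar(text),
                                     offset + nchar(text) + nchar(inner$text))))
          }
          spans <- c(spans, inner$spans)
          text <- paste0(text, inner$text)
        }
      }
      list(text = text, spans = spans)
    }
    res <- walk(nd, 0L)
    doc <- path_document(res$text, doc_id = id)
    docs[[id]] <- doc
    if (length(res$spans)) {
      sp <- do.call(rbind, res$spans)
      anns[[id]] <- annotation_frame(doc_id = id, start = sp[, 1], end = sp[, 2],
                                     surface = substring(res$text, sp[, 1] + 1, sp[, 2]),
                                     type = "pathway_mention", source = "gold")
    }
  }
  gold <- .bind_annotations(anns)
  .check_gold_offsets(docs, gold)
  list(documents = docs, gold = gold)
}

.check_gold_offsets <- function(docs, gold) {
  if (!nrow(gold)) return(invisible())
  for (i in seq_len(nrow(gold))) {
    d <- docs[[gold$doc_id[i]]]
    if (is.null(d)) stop("gold annotation references unknown document ", gold$doc_id[i])
    if (gold$end[i] > nchar(d$text)) {
      stop("annotation [", gold$start[i], ",", gold$end[i], ") in document '",
           gold$doc_id[i], "' exceeds text length ", nchar(d$text))
    }
  }
  invisible()
}
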