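# Readers and writers for the BioNLP'09 standoff dialect plus sidecar
# layers (CoNLL-style tokens, dependency arcs, MeSH descriptors).
#
# Offset discipline: all offsets are 0-based, half-open character offsets
# into the document text, and every parsed annotation must satisfy
# substr(text, start + 1, end) == surface.

text_slice <- function(text, start, end) substr(text, start + 1L, end)

empty_span_df <- function() {
  data.frame(ann_id = character(), type = character(),
             char_start = integer(), char_end = integer(),
             surface = character(), stringsAsFactors = FALSE)
}

empty_trigger_df <- function() {
  data.frame(ann_id = character(), event_class = character(),
             char_start = integer(), char_end = integer(),
             surface = character(), stringsAsFactors = FALSE)
}

empty_dep_df <- function() {
  data.frame(head = integer(), dependent = integer(),
             relation = character(), layer = character(),
             stringsAsFactors = FALSE)
}

new_document <- function(doc_id, text) {
  structure(
    list(doc_id = doc_id, text = text, sentences = list(),
         proteins = empty_span_df(), triggers = empty_trigger_df(),
         mesh = character()),
    class = "ts_document"
  )
}

#' @export
print.ts_document <- function(x, ...) {
  cat(sprintf("<ts_document %s: %d chars, %d sentences, %d proteins, %d triggers>\n",
              x$doc_id, nchar(x$text), length(x$sentences),
              nrow(x$proteins), nrow(x$triggers)))
  invisible(x)
}

# Parse one "Tn<TAB>Type start end<TAB>surface" term line, validating the
# surface string against the text slice it claims to cover.
parse_term_line <- function(line, text, path, lineno) {
  where <- sprintf("%s:%d", path, lineno)
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) != 3L)
    stop(sprintf("parse error at %s: expected 3 tab-separated fields, got %d",
                 where, length(fields)), call. = FALSE)
  head <- strsplit(fields[2], " ", fixed = TRUE)[[1]]
  if (length(head) != 3L)
    stop(sprintf("parse error at %s: expected 'Type start end' in field 2",
                 where), call. = FALSE)
  start <- suppressWarnings(as.integer(head[2]))
  end <- suppressWarnings(as.integer(head[3]))
  if (is.na(start) || is.na(end) || start < 0L || end <= start)
    stop(sprintf("parse error at %s: bad offsets '%s %s'", where,
                 head[2], head[3]), call. = FALSE)
  if (end > nchar(text))
    stop(sprintf("integrity error at %s: span [%d,%d) outside text of length %d",
                 where, start, end, nchar(text)), call. = FALSE)
  slice <- text_slice(text, start, end)
  if (!identical(slice, fields[3]))
    stop(sprintf("integrity error at %s: text[%d:%d) is '%s' but annotation says '%s'",
                 where, start, end, slice, fields[3]), call. = FALSE)
  list(ann_id = fields[1], type = head[1],
       char_start = start, char_end = end, surface = fields[3])
}

#' Read a BioNLP'09 standoff document
#'
#' Reads a document's text plus its protein term annotations (`.a1`) and,
#' optionally, its event trigger term annotations (`.a2`). Only term lines
#' (id starting with `T`) are consumed from the `.a2` file; event (`E`),
#' modification (`M`) and equivalence (`*`) lines are skipped, as are term
#' lines whose type is not one of the nine event classes. Every span is
#' validated against the text.
#'
#' @param txt_path Path to the plain-text `.txt` file.
#' @param a1_path Optional path to the `.a1` protein term file.
#' @param a2_path Optional path to the `.a2` event annotation file.
#' @return A `ts_document`: a list with `doc_id`, `text`, `sentences`
#'   (empty until [read_token_layer()] is applied), `proteins`, `triggers`
#'   and `mesh`.
#' @seealso [read_token_layer()], [align_triggers_to_tokens()]
#' @export
read_standoff <- function(txt_path, a1_path = NULL, a2_path = NULL) {
  text <- paste(readLines(txt_path, warn = FALSE), collapse = "\n")
  doc <- new_document(sub("\\.txt$", "", basename(txt_path)), text)

  if (!is.null(a1_path)) {
    lines <- readLines(a1_path, warn = FALSE)
    terms <- list()
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i])) next
      if (!startsWith(lines[i], "T"))
        stop(sprintf("parse error at %s:%d: .a1 lines must be term lines",
                     a1_path, i), call. = FALSE)
      terms[[length(terms) + 1L]] <- parse_term_line(lines[i], text, a1_path, i)
    }
    if (length(terms))
      doc$proteins <- do.call(rbind, lapply(terms, function(t)
        data.frame(ann_id = t$ann_id, type = t$type,
                   char_start = t$char_start, char_end = t$char_end,
                   surface = t$surface, stringsAsFactors = FALSE)))
  }

  if (!is.null(a2_path)) {
    lines <- readLines(a2_path, warn = FALSE)
    terms <- list()
    for (i in seq_along(lines)) {
      if (!nzchar(lines[i]) || !startsWith(lines[i], "T")) next
      t <- parse_term_line(lines[i], text, a2_path, i)
      if (!(t$type %in% EVENT_CLASSES)) next   # e.g. Entity terms
      terms[[length(terms) + 1L]] <- t
    }
    if (length(terms))
      doc$triggers <- do.call(rbind, lapply(terms, function(t)
        data.frame(ann_id = t$ann_id, event_class = t$type,
                   char_start = t$char_start, char_end = t$char_end,
                   surface = t$surface, stringsAsFactors = FALSE)))
  }

  doc
}

split_blank_groups <- function(lines) {
  lines <- sub("\r$", "", lines)
  nonblank <- nzchar(lines)
  if (!any(nonblank)) return(list())
  grp <- cumsum(!nonblank)
  unname(split(lines[nonblank], grp[nonblank]))
}

#' Attach a token sidecar layer to a document
#'
#' The token layer is a CoNLL-style TSV with blank-line-separated sentences
#' and seven columns per token: form, lemma, POS, chunk, protein tag
#' (`B-PROT`/`I-PROT`/`O`), character start and character end. Spans must
#' slice the document text to exactly the form, and must be strictly
#' increasing and non-overlapping.
#'
#' @param path Path to the token layer file.
#' @param document A `ts_document` from [read_standoff()].
#' @return The document with `sentences` populated; each sentence holds a
#'   `tokens` data frame (0-based `index` column) and an empty `deps` frame.
#' @export
read_token_layer <- function(path, document) {
  groups <- split_blank_groups(readLines(path, warn = FALSE))
  prev_end <- -1L
  sentences <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    rows <- strsplit(groups[[s]], "\t", fixed = TRUE)
    n <- length(rows)
    bad <- which(lengths(rows) != 7L)
    if (length(bad))
      stop(sprintf("parse error in %s, sentence %d: expected 7 columns, got %d",
                   path, s, length(rows[[bad[1]]])), call. = FALSE)
    m <- matrix(unlist(rows), nrow = n, byrow = TRUE)
    start <- suppressWarnings(as.integer(m[, 6]))
    end <- suppressWarnings(as.integer(m[, 7]))
    if (anyNA(start) || anyNA(end))
      stop(sprintf("parse error in %s, sentence %d: non-integer offsets",
                   path, s), call. = FALSE)
    if (any(end > nchar(document$text)))
      stop(sprintf("integrity error in %s, sentence %d: span outside text",
                   path, s), call. = FALSE)
    for (i in seq_len(n)) {
      if (start[i] >= end[i])
        stop(sprintf("integrity error in %s, sentence %d token %d: empty or inverted span",
                     path, s, i - 1L), call. = FALSE)
      if (start[i] < prev_end)
        stop(sprintf("integrity error in %s, sentence %d token %d: spans must be increasing and non-overlapping",
                     path, s, i - 1L), call. = FALSE)
      slice <- text_slice(document$text, start[i], end[i])
      if (!identical(slice, m[i, 1]))
        stop(sprintf("integrity error in %s, sentence %d token %d: text slice '%s' != form '%s'",
                     path, s, i - 1L, slice, m[i, 1]), call. = FALSE)
      prev_end <- end[i]
    }
    sentences[[s]] <- list(
      tokens = data.frame(index = seq_len(n) - 1L, form = m[, 1],
                          lemma = m[, 2], pos = m[, 3], chunk = m[, 4],
                          protein = m[, 5], char_start = start,
                          char_end = end, stringsAsFactors = FALSE),
      deps = empty_dep_df()
    )
  }
  document$sentences <- sentences
  document
}

#' Attach a dependency parse layer to a document
#'
#' Each sentence of the layer file must contain exactly one `head<TAB>relation`
#' row per token of the corresponding token-layer sentence (so the token layer
#' must be loaded first). `head` is the 0-based index of the governing token,
#' or `-1` / `ROOT` for the sentence root. Several layers (one per parser) may
#' coexist on a document under distinct `layer_id`s.
#'
#' @param path Path to the dependency layer file.
#' @param layer_id Identifier for this parser layer.
#' @param document A `ts_document` with sentences populated.
#' @return The document, with arcs appended to each sentence's `deps`.
#' @export
read_dependency_layer <- function(path, layer_id, document) {
  groups <- split_blank_groups(readLines(path, warn = FALSE))
  if (length(groups) != length(document$sentences))
    stop(sprintf("misalignment in %s: %d sentences in layer vs %d in token layer",
                 path, length(groups), length(document$sentences)), call. = FALSE)
  for (s in seq_along(groups)) {
    ntok <- nrow(document$sentences[[s]]$tokens)
    rows <- strsplit(groups[[s]], "\t", fixed = TRUE)
    if (length(rows) != ntok)
      stop(sprintf("misalignment in %s, sentence %d: %d rows vs %d tokens",
                   path, s, length(rows), ntok), call. = FALSE)
    if (any(lengths(rows) != 2L))
      stop(sprintf("parse error in %s, sentence %d: expected 2 columns",
                   path, s), call. = FALSE)
    m <- matrix(unlist(rows), ncol = 2L, byrow = TRUE)
    head_raw <- m[, 1]
    head_idx <- suppressWarnings(as.integer(ifelse(head_raw == "ROOT", "-1", head_raw)))
    if (anyNA(head_idx))
      stop(sprintf("parse error in %s, sentence %d: non-integer head index",
                   path, s), call. = FALSE)
    dep_idx <- seq_len(ntok) - 1L
    if (any(head_idx >= ntok) || any(head_idx < -1L))
      stop(sprintf("integrity error in %s, sentence %d: head index outside sentence",
                   path, s), call. = FALSE)
    if (any(head_idx == dep_idx))
      stop(sprintf("integrity error in %s, sentence %d: token is its own head",
                   path, s), call. = FALSE)
    arcs <- data.frame(head = head_idx, dependent = dep_idx,
                       relation = m[, 2], layer = layer_id,
                       stringsAsFactors = FALSE)
    document$sentences[[s]]$deps <- rbind(document$sentences[[s]]$deps, arcs)
  }
  document
}

#' Read a MeSH descriptor sidecar
#'
#' Each line is `doc_id<TAB>descriptor`. Descriptors are grouped per
#' document in file order with duplicates removed.
#'
#' @param path Path to the sidecar file.
#' @return A named list mapping document ids to character vectors of
#'   descriptors; documents absent from the sidecar simply have no entry
#'   (look up with `map[[id]]` and treat `NULL` as empty).
#' @export
read_mesh_sidecar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(list())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop(sprintf("parse error at %s:%d: expected 'doc_id<TAB>descriptor'",
                 path, bad[1]), call. = FALSE)
  ids <- vapply(fields, `[`, "", 1L)
  desc <- vapply(fields, `[`, "", 2L)
  lapply(split(desc, factor(ids, levels = unique(ids))), unique)
}

#' Flatten a document's tokens into one data frame
#'
#' @param document A `ts_document` with sentences populated.
#' @return A data frame with a 1-based `sentence` column prepended to the
#'   per-sentence token columns (token `index` stays 0-based within its
#'   sentence).
#' @export
doc_tokens <- function(document) {
  if (!length(document$sentences))
    return(cbind(sentence = integer(),
                 data.frame(index = integer(), form = character(),
                            lemma = character(), pos = character(),
                            chunk = character(), protein = character(),
                            char_start = integer(), char_end = integer())))
  do.call(rbind, lapply(seq_along(document$sentences), function(s)
    cbind(sentence = s, document$sentences[[s]]$tokens)))
}

#' Project trigger spans onto token-level class labels
#'
#' A token whose character range intersects a trigger span receives that
#' trigger's event class; every token of a multi-token trigger receives the
#' class; all other tokens receive [NON_EVENT]. When a token is overlapped
#' by triggers of two or more distinct classes the conflict is resolved
#' deterministically — earliest trigger start, then alphabetical class
#' name — and a warning is issued.
#'
#' @param document A `ts_document` with sentences and triggers loaded.
#' @return A character vector of labels aligned with the rows of
#'   [doc_tokens()].
#' @export
align_triggers_to_tokens <- function(document) {
  toks <- doc_tokens(document)
  labels <- rep(NON_EVENT, nrow(toks))
  trg <- document$triggers
  if (!nrow(trg) || !nrow(toks)) return(labels)
  trg <- trg[order(trg$char_start, trg$event_class), , drop = FALSE]
  conflict <- FALSE
  for (r in seq_len(nrow(toks))) {
    hit <- trg$char_start < toks$char_end[r] & trg$char_end > toks$char_start[r]
    if (any(hit)) {
      cls <- trg$event_class[hit]
      if (length(unique(cls)) > 1L) conflict <- TRUE
      labels[r] <- cls[1L]   # triggers pre-sorted: earliest start, then class
    }
  }
  if (conflict)
    warning(sprintf("document %s: token overlapped by triggers of distinct classes; resolved by earliest start, then alphabetical class",
                    document$doc_id), call. = FALSE)
  labels
}

#' Write predicted token labels as .a2 trigger terms
#'
#' Maximal runs of adjacent tokens (consecutive indices within one
#' sentence) sharing the same non-[NON_EVENT] label are merged into a
#' single trigger term spanning from the first token's start to the last
#' token's end. Term ids are sequential from `T1000` so they cannot clash
#' with `.a1` ids.
#'
#' @param document A `ts_document` with sentences populated.
#' @param labels Character labels aligned with [doc_tokens()] rows.
#' @param path Optional path; when given the lines are also written there.
#' @return The `.a2` term lines as a character vector (possibly empty),
#'   invisibly when `path` is given.
#' @export
write_a2_triggers <- function(document, labels, path = NULL) {
  toks <- doc_tokens(document)
  if (length(labels) != nrow(toks))
    stop("labels must align 1:1 with doc_tokens(document)", call. = FALSE)
  lines <- character()
  if (nrow(toks)) {
    new_run <- c(TRUE, diff(toks$sentence) != 0L | diff(toks$index) != 1L |
                         labels[-1L] != labels[-length(labels)])
    run_id <- cumsum(new_run)
    tid <- 1000L
    for (rid in unique(run_id)) {
      rows <- which(run_id == rid)
      if (labels[rows[1L]] == NON_EVENT) next
      start <- toks$char_start[rows[1L]]
      end <- toks$char_end[rows[length(rows)]]
      lines <- c(lines, sprintf("T%d\t%s %d %d\t%s", tid, labels[rows[1L]],
                                start, end, text_slice(document$text, start, end)))
      tid <- tid + 1L
    }
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
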