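# Grouping token occurrences into word types (lemma + coarse POS) and
# selecting disambiguation targets by training frequency and class skew.

#' Collapse a Penn Treebank tag to a coarse part of speech
#'
#' `NN*` maps to `N` (noun), `VB*` to `V` (verb), `JJ*` to `J` (adjective),
#' `RB*` to `R` (adverb); everything else maps to `OTHER`. Only the four
#' content-word classes take part in word-type grouping.
#'
#' @param tag Character vector of Penn-style tags.
#' @return Character vector over `{"N","V","J","R","OTHER"}`.
#' @export
coarse_pos <- function(tag) {
  out <- rep("OTHER", length(tag))
  out[startsWith(tag, "NN")] <- "N"
  out[startsWith(tag, "VB")] <- "V"
  out[startsWith(tag, "JJ")] <- "J"
  out[startsWith(tag, "RB")] <- "R"
  out
}

CONTENT_POS <- c("J", "N", "R", "V")

#' Group labeled token occurrences into word-type instances
#'
#' Every token whose coarse POS is a content-word class becomes one
#' disambiguation instance under the word type `lemma.POS` (lemma
#' lowercased); tokens with `OTHER` POS are skipped. Gold classes come
#' from [align_triggers_to_tokens()].
#'
#' @param docs Named list of `ts_document`s (names are doc ids).
#' @param split Named character vector mapping doc ids to `"train"` or
#'   `"test"`; when `NULL` every instance is assigned to `"train"`.
#' @return A data frame with one row per instance: `doc_id`, `sentence`,
#'   `token`, `lemma`, `pos`, `word_type`, `gold_class`, `split`.
#' @export
group_instances <- function(docs, split = NULL) {
  rows <- lapply(docs, function(doc) {
    toks <- doc_tokens(doc)
    if (!nrow(toks)) return(NULL)
    labs <- align_triggers_to_tokens(doc)
    cp <- coarse_pos(toks$pos)
    keep <- cp %in% CONTENT_POS
    if (!any(keep)) return(NULL)
    lem <- tolower(toks$lemma[keep])
    data.frame(doc_id = doc$doc_id, sentence = toks$sentence[keep],
               token = toks$index[keep], lemma = lem, pos = cp[keep],
               word_type = paste0(lem, ".", cp[keep]),
               gold_class = labs[keep],
               split = if (is.null(split)) "train" else unname(split[doc$doc_id]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(), sentence = integer(),
                      token = integer(), lemma = character(),
                      pos = character(), word_type = character(),
                      gold_class = character(), split = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Majority-class fraction of a class count table
#'
#' @param class_counts Non-empty numeric vector (possibly named) of
#'   per-class instance counts.
#' @return The fraction of the majority class, in `(0, 1]`.
#' @export
compute_bias <- function(class_counts) {
  class_counts <- class_counts[class_counts > 0]
  if (!length(class_counts) || sum(class_counts) <= 0)
    stop("compute_bias: empty class counts", call. = FALSE)
  max(class_counts) / sum(class_counts)
}

#' Per-word-type instance statistics
#'
#' Class counts and bias are computed on the training split only; test
#' instances of a word type are counted but do not influence the bias.
#'
#' @param instances Instance data frame from [group_instances()].
#' @return A data frame sorted by training count (descending) with columns
#'   `word_type`, `n_train`, `n_test`, `n_classes`, `bias` (`NA` for word
#'   types with no training instances).
#' @export
word_type_stats <- function(instances) {
  sp <- split(instances, instances$word_type)
  rows <- lapply(sp, function(g) {
    tr <- g$gold_class[g$split == "train"]
    counts <- table(tr)
    data.frame(word_type = g$word_type[1L],
               n_train = length(tr),
               n_test = sum(g$split == "test"),
               n_classes = length(counts),
               bias = if (length(tr)) compute_bias(counts) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(word_type = character(), n_train = integer(),
                      n_test = integer(), n_classes = integer(),
                      bias = double(), stringsAsFactors = FALSE))
  out <- out[order(-out$n_train, out$word_type, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select word types worth disambiguating
#'
#' Keeps word types with at least `min_train` training instances and a
#' majority-class bias strictly below `max_bias` (high-skew types leave
#' little room for improvement over the majority-class baseline), sorted
#' by training count descending.
#'
#' @param stats Data frame from [word_type_stats()].
#' @param min_train Minimum number of training instances (default 50).
#' @param max_bias Exclusive upper bound on the majority-class fraction
#'   (default 0.90).
#' @return The filtered, sorted subset of `stats`.
#' @export
select_targets <- function(stats, min_train = 50, max_bias = 0.90) {
  keep <- !is.na(stats$bias) & stats$n_train >= min_train & stats$bias < max_bias
  out <- stats[keep, , drop = FALSE]
  out <- out[order(-out$n_train, out$word_type, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
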