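# Class-entropy profiling of features. The "one sense per collocation"
# heuristic predicts that a collocational feature should mostly co-occur
# with a single class; the class entropy of a feature measures how far a
# corpus deviates from that ideal, and averaging it per family and per
# word type predicts where disambiguation is likely to pay off.

#' Class entropy of one feature
#'
#' Given the class counts of the instances in which a feature is active,
#' returns the Shannon entropy of the class distribution. Base 2 (bits) is
#' the default; the bin thresholds used elsewhere assume base 2.
#'
#' @param class_counts Numeric vector of per-class counts (zeros allowed).
#' @param base Logarithm base (default 2).
#' @return Entropy, a non-negative number.
#' @export
feature_class_entropy <- function(class_counts, base = 2) {
  class_counts <- class_counts[class_counts > 0]
  total <- sum(class_counts)
  if (total <= 0) stop("feature_class_entropy: empty counts", call. = FALSE)
  p <- class_counts / total
  -sum(p * log(p, base = base))
}

#' Per-feature entropy table for one word type
#'
#' Counts, for every feature, the training instances in which it is active
#' per gold class (binary presence, not raw multiplicity), keeps features
#' active in at least `min_count` instances, and computes each survivor's
#' class entropy.
#'
#' @param features List of feature-key vectors (train instances of one
#'   word type).
#' @param labels Gold classes aligned with `features`.
#' @param min_count Minimum number of instances a feature must be active
#'   in to qualify (default 2).
#' @param base Logarithm base (default 2).
#' @return A data frame with columns `feature`, `family`, `n`
#'   (occurrence count) and `H`.
#' @export
feature_entropy_table <- function(features, labels, min_count = 2, base = 2) {
  empty <- data.frame(feature = character(), family = character(),
                      n = integer(), H = double(), stringsAsFactors = FALSE)
  if (!length(features)) return(empty)
  feats <- unlist(features, use.names = FALSE)
  if (!length(feats)) return(empty)
  cls <- rep(labels, lengths(features))
  tab <- table(feats, cls)
  tot <- rowSums(tab)
  keep <- tot >= min_count
  if (!any(keep)) return(empty)
  tab <- tab[keep, , drop = FALSE]
  H <- apply(tab, 1L, feature_class_entropy, base = base)
  keys <- rownames(tab)
  out <- data.frame(feature = keys, family = feature_family(keys),
                    n = as.integer(tot[keep]), H = unname(H),
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean feature entropy per family
#'
#' Unweighted mean of the per-feature entropies, pooled over the supplied
#' entropy tables (typically one per word type). Families with no
#' qualifying features are reported as `NA` (a table would print a dash).
#'
#' @param entropy_tables A single data frame from
#'   [feature_entropy_table()] or a list of them to pool.
#' @param families Families to report (default all four).
#' @return A data frame with columns `family`, `n_features`, `mean_H`.
#' @export
family_mean_entropy <- function(entropy_tables,
                                families = FEATURE_FAMILIES) {
  if (is.data.frame(entropy_tables)) entropy_tables <- list(entropy_tables)
  pooled <- do.call(rbind, entropy_tables)
  rows <- lapply(families, function(fam) {
    h <- pooled$H[pooled$family == fam]
    data.frame(family = fam, n_features = length(h),
               mean_H = if (length(h)) mean(h) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean feature entropy of one word type
#'
#' Unweighted mean over all the word type's qualifying features, across
#' all families.
#'
#' @param entropy_table Data frame from [feature_entropy_table()].
#' @return A single number, or `NA` if no feature qualifies.
#' @export
word_mean_entropy <- function(entropy_table) {
  if (!nrow(entropy_table)) return(NA_real_)
  mean(entropy_table$H)
}

#' Assign an entropy bin
#'
#' Bins are left-closed at the upper thresholds: `LOW` is `H < t1`, `MID`
#' is `t1 <= H < t2`, `HIGH` is `H >= t2` (so `H` exactly at a threshold
#' falls in the upper bin).
#'
#' @param H Numeric vector of mean entropies.
#' @param thresholds Two increasing cut points (default `c(0.3, 0.4)`).
#' @return Character vector over `{"LOW","MID","HIGH"}` (`NA` stays `NA`).
#' @export
entropy_bin <- function(H, thresholds = c(0.3, 0.4)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  out <- rep(NA_character_, length(H))
  out[!is.na(H) & H < thresholds[1]] <- "LOW"
  out[!is.na(H) & H >= thresholds[1] & H < thresholds[2]] <- "MID"
  out[!is.na(H) & H >= thresholds[2]] <- "HIGH"
  out
}

#' Bin word types by mean feature entropy
#'
#' @param profiles Data frame with columns `word_type` and `mean_H` (as
#'   produced by [run_trigger_wsd()]'s `entropy` element).
#' @param stats Optional [word_type_stats()] frame; when given, each bin
#'   also reports the mean training frequency of its word types.
#' @param thresholds Bin cut points, see [entropy_bin()].
#' @return A data frame with one row per non-empty bin: `bin`, `n_words`,
#'   `avg_train_freq` (`NA` without `stats`) and a list column `words`.
#' @export
bin_words <- function(profiles, stats = NULL, thresholds = c(0.3, 0.4)) {
  bins <- entropy_bin(profiles$mean_H, thresholds)
  rows <- lapply(c("LOW", "MID", "HIGH"), function(b) {
    wt <- profiles$word_type[!is.na(bins) & bins == b]
    if (!length(wt)) return(NULL)
    freq <- NA_real_
    if (!is.null(stats))
      freq <- mean(stats$n_train[match(wt, stats$word_type)])
    out <- data.frame(bin = b, n_words = length(wt), avg_train_freq = freq,
                      stringsAsFactors = FALSE)
    out$words <- list(wt)
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(bin = character(), n_words = integer(),
                      avg_train_freq = double(), stringsAsFactors = FALSE)
  out
}
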