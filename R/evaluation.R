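# Scoring: accuracy over all instances, micro-averaged P/R/F pooled over
# the nine event classes (the non-event class never counts as a true
# positive), per-class and grouped breakdowns, and a paired approximate
# randomization test for system comparisons.

check_aligned <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("gold and predicted label sequences differ in length", call. = FALSE)
}

#' Classification accuracy
#'
#' Share of exact label matches over all instances, the non-event class
#' included. Note that under a strong non-event skew this number is driven
#' by the majority class and says little about trigger recall.
#'
#' @param gold,pred Aligned character label vectors.
#' @return A fraction in `[0, 1]`.
#' @export
accuracy <- function(gold, pred) {
  check_aligned(gold, pred)
  if (!length(gold)) return(NA_real_)
  mean(gold == pred)
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}

#' Micro-averaged precision, recall and F-score over the event classes
#'
#' Counts are pooled over the event classes: a true positive is an
#' instance where prediction and gold agree on an event class; a predicted
#' event class that differs from the gold label is a false positive; a
#' gold event class that was not matched is a false negative (so a
#' cross-class confusion counts once as FP and once as FN). Zero
#' denominators yield 0, keeping F always defined.
#'
#' @param gold,pred Aligned character label vectors.
#' @param event_classes The classes that count as events (default
#'   [EVENT_CLASSES]).
#' @return A list with `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
micro_prf <- function(gold, pred, event_classes = EVENT_CLASSES) {
  check_aligned(gold, pred)
  gold_ev <- gold %in% event_classes
  pred_ev <- pred %in% event_classes
  tp <- sum(gold_ev & pred == gold)
  fp <- sum(pred_ev & pred != gold)
  fn <- sum(gold_ev & pred != gold)
  c(list(tp = tp, fp = fp, fn = fn), prf(tp, fp, fn))
}

#' Per-event-class precision, recall and F-score
#'
#' One-vs-rest counts for every event class present in the gold or
#' predicted labels; classes absent from both are omitted. Sorted by
#' F-score descending for reporting.
#'
#' @inheritParams micro_prf
#' @return A data frame with columns `class`, `gold_freq`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f`.
#' @export
per_class_prf <- function(gold, pred, event_classes = EVENT_CLASSES) {
  check_aligned(gold, pred)
  present <- intersect(event_classes, union(gold, pred))
  rows <- lapply(sort_c(present), function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(pred == cl & gold != cl)
    fn <- sum(gold == cl & pred != cl)
    s <- prf(tp, fp, fn)
    data.frame(class = cl, gold_freq = sum(gold == cl), tp = tp, fp = fp,
               fn = fn, precision = s$precision, recall = s$recall, f = s$f,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(class = character(), gold_freq = integer(),
                      tp = integer(), fp = integer(), fn = integer(),
                      precision = double(), recall = double(), f = double(),
                      stringsAsFactors = FALSE))
  out <- out[order(-out$f, out$class, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full evaluation report
#'
#' @inheritParams micro_prf
#' @return A list with `n`, `accuracy`, `micro` (from [micro_prf()]) and
#'   `per_class` (from [per_class_prf()]).
#' @export
eval_report <- function(gold, pred, event_classes = EVENT_CLASSES) {
  check_aligned(gold, pred)
  list(n = length(gold), accuracy = accuracy(gold, pred),
       micro = micro_prf(gold, pred, event_classes),
       per_class = per_class_prf(gold, pred, event_classes))
}

#' Evaluation broken down by instance groups
#'
#' Produces one full [eval_report()] per level of a grouping variable
#' (POS, entropy bin, word type, ...); empty groups are omitted.
#'
#' @inheritParams micro_prf
#' @param group Character vector aligned with `gold` giving each
#'   instance's group.
#' @return A named list of reports, one per group level.
#' @export
report_by_group <- function(gold, pred, group, event_classes = EVENT_CLASSES) {
  check_aligned(gold, pred)
  if (length(group) != length(gold))
    stop("group must align with gold", call. = FALSE)
  idx <- split(seq_along(gold), group)
  lapply(idx, function(i) eval_report(gold[i], pred[i], event_classes))
}

eval_metric_fun <- function(metric) {
  switch(metric,
    accuracy = function(g, p) accuracy(g, p),
    micro_f = function(g, p) micro_prf(g, p)$f,
    micro_p = function(g, p) micro_prf(g, p)$precision,
    micro_r = function(g, p) micro_prf(g, p)$recall,
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}

#' Paired approximate randomization test
#'
#' Tests whether the observed difference in a metric between two systems'
#' predictions over the same gold labels could arise by chance. In each of
#' `rounds` randomization rounds the two systems' predictions are swapped
#' independently per instance with probability 1/2 and the absolute metric
#' difference recomputed; the p-value is `(b + 1) / (rounds + 1)` where
#' `b` counts rounds whose difference is at least the observed one.
#'
#' @param gold Gold labels.
#' @param pred_a,pred_b The two systems' aligned predictions.
#' @param metric One of `"accuracy"`, `"micro_f"`, `"micro_p"`, `"micro_r"`.
#' @param rounds Number of randomization rounds (default 10000).
#' @param seed Mandatory integer seed; the result is deterministic given
#'   the seed. The caller's RNG state is left untouched.
#' @return The p-value, a number in `(0, 1]`.
#' @export
randomization_test <- function(gold, pred_a, pred_b, metric = "micro_f",
                               rounds = 10000, seed) {
  check_aligned(gold, pred_a)
  check_aligned(gold, pred_b)
  if (rounds < 1) stop("rounds must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  m <- eval_metric_fun(metric)
  n <- length(gold)
  d_obs <- abs(m(gold, pred_a) - m(gold, pred_b))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  hits <- 0L
  eps <- 1e-12
  for (r in seq_len(rounds)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, pred_b, pred_a)
    b <- ifelse(swap, pred_a, pred_b)
    if (abs(m(gold, a) - m(gold, b)) >= d_obs - eps) hits <- hits + 1L
  }
  (hits + 1) / (rounds + 1)
}
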