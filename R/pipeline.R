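# End-to-end convenience wrapper: corpus -> target selection -> features
# -> per-word-type models -> test predictions + evaluation + entropy
# profiles. This is the experiment the rest of the package exists for.

#' Run the word-type disambiguation experiment on a corpus
#'
#' Groups labeled tokens into word types, selects disambiguation targets
#' by training frequency and majority-class bias, extracts the requested
#' feature families, trains one vector space model and one majority-class
#' baseline per target, predicts the targets' test instances, and
#' computes evaluation reports and entropy profiles.
#'
#' @param corpus A list with `docs` (named list of `ts_document`s) and
#'   `split` (named character vector), as returned by [load_corpus()].
#' @param min_train,max_bias Target selection thresholds, see
#'   [select_targets()].
#' @param families Feature families to use, see [instance_features()].
#' @param entropy_min_count Occurrence filter for entropy profiling.
#' @return A list with:
#'   \describe{
#'     \item{stats, targets}{word-type statistics and the selected targets}
#'     \item{train, test}{instance frames of the selected types, with the
#'       feature lists attached as attributes}
#'     \item{predictions}{test instance frame plus `vsm`, `score`,
#'       `fallback` and `mc` columns}
#'     \item{report_vsm, report_mc}{[eval_report()]s over the test split}
#'     \item{by_pos}{per-POS breakdown of the VSM report}
#'     \item{entropy}{per-word-type profile: `word_type`, `n_features`,
#'       `mean_H`, `bin`}
#'     \item{entropy_tables, models, vocabularies}{per-word-type detail}
#'   }
#' @export
run_trigger_wsd <- function(corpus, min_train = 50, max_bias = 0.90,
                            families = FEATURE_FAMILIES,
                            entropy_min_count = 2) {
  instances <- group_instances(corpus$docs, corpus$split)
  stats <- word_type_stats(instances)
  targets <- select_targets(stats, min_train, max_bias)
  train <- instances[instances$split == "train" &
                       instances$word_type %in% targets$word_type, , drop = FALSE]
  test <- instances[instances$split == "test" &
                      instances$word_type %in% targets$word_type, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  feat_train <- extract_features(corpus$docs, train, families)
  feat_test <- extract_features(corpus$docs, test, families)

  models <- list()
  vocabularies <- list()
  entropy_tables <- list()
  prof_rows <- list()
  pred <- test
  pred$vsm <- character(nrow(test))
  pred$score <- double(nrow(test))
  pred$fallback <- logical(nrow(test))
  pred$mc <- character(nrow(test))
  for (wt in targets$word_type) {
    tr <- which(train$word_type == wt)
    te <- which(test$word_type == wt)
    vocab <- build_vocabulary(feat_train[tr])
    model <- train_vsm(vectorize(feat_train[tr], vocab),
                       train$gold_class[tr], length(vocab))
    mc <- train_mc(train$gold_class[tr])
    models[[wt]] <- model
    vocabularies[[wt]] <- vocab
    tab <- feature_entropy_table(feat_train[tr], train$gold_class[tr],
                                 min_count = entropy_min_count)
    entropy_tables[[wt]] <- tab
    prof_rows[[wt]] <- data.frame(word_type = wt, n_features = nrow(tab),
                                  mean_H = word_mean_entropy(tab),
                                  stringsAsFactors = FALSE)
    if (length(te)) {
      p <- predict(model, vectorize(feat_test[te], vocab))
      pred$vsm[te] <- p$predicted
      pred$score[te] <- p$score
      pred$fallback[te] <- p$fallback
      pred$mc[te] <- predict(mc, length(te))
    }
  }
  profiles <- do.call(rbind, unname(prof_rows))
  if (is.null(profiles))
    profiles <- data.frame(word_type = character(), n_features = integer(),
                           mean_H = double(), stringsAsFactors = FALSE)
  profiles$bin <- entropy_bin(profiles$mean_H)
  attr(train, "features") <- feat_train
  attr(test, "features") <- feat_test
  list(stats = stats, targets = targets, train = train, test = test,
       predictions = pred,
       report_vsm = eval_report(pred$gold_class, pred$vsm),
       report_mc = eval_report(pred$gold_class, pred$mc),
       by_pos = if (nrow(pred)) report_by_group(pred$gold_class, pred$vsm,
                                                pred$pos) else list(),
       entropy = profiles, entropy_tables = entropy_tables,
       models = models, vocabularies = vocabularies)
}

#' One-line textual summary of an evaluation report
#'
#' Percentages to one decimal, the convention of the field's result
#' tables.
#'
#' @param report A list from [eval_report()].
#' @return A character string.
#' @export
format_report <- function(report) {
  sprintf("n=%d  Acc=%.1f  P=%.1f  R=%.1f  F=%.1f", report$n,
          100 * report$accuracy, 100 * report$micro$precision,
          100 * report$micro$recall, 100 * report$micro$f)
}
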