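# Bridge to a downstream sequence tagger: cross-validated disambiguation
# predictions as an extra per-token feature column, and export of the
# corpus as a CoNLL/CRF++-compatible training file with BIO gold labels.
# Training or running the CRF itself is out of scope; the contract ends
# at a well-formed input file plus feature template.

# Class-stratified fold ids for one word type. Within each class the
# (seeded, shuffled) instances are dealt to folds cyclically, so no fold
# can lack a class unless the class has fewer instances than folds.
make_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (n < k) k <- n                     # leave-one-out for tiny types
  folds <- integer(n)
  set.seed(seed)
  for (cl in sort_c(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- (seq_along(idx) - 1L) %% k + 1L
  }
  folds
}

# blank token->"NULL" column over a set of documents
null_column <- function(docs) {
  rows <- lapply(docs, function(doc) {
    toks <- doc_tokens(doc)
    if (!nrow(toks)) return(NULL)
    data.frame(doc_id = doc$doc_id, sentence = toks$sentence,
               token = toks$index, wsd = "NULL", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

column_key <- function(doc_id, sentence, token) {
  paste(doc_id, sentence, token, sep = "\r")
}

fill_column <- function(column, instances, preds) {
  at <- match(column_key(instances$doc_id, instances$sentence, instances$token),
              column_key(column$doc_id, column$sentence, column$token))
  column$wsd[at] <- preds
  column
}

#' Cross-validated WSD feature column over the training split
#'
#' For each word type the training instances are split into `k`
#' class-stratified folds (seeded); each fold is predicted by a vector
#' space model trained on the other folds only, so no instance is ever
#' predicted by a model that saw it. Word types with fewer than `k`
#' instances fall back to leave-one-out (a message is emitted). Tokens of
#' the training documents that are not instances of any given word type
#' carry the value `"NULL"`.
#'
#' @param docs Named list of `ts_document`s (the training documents).
#' @param instances Training-split instance data frame (the selected word
#'   types' rows from [group_instances()]).
#' @param features Feature-key list aligned with `instances` rows.
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the fold cuts.
#' @return A list with `column` (data frame `doc_id`, `sentence`, `token`,
#'   `wsd` covering every token of `docs`), `predictions` (the instance
#'   frame plus `fold` and `wsd` columns) and `folds`, a per-word-type
#'   manifest of the train/test index sets of every fold (indices into
#'   `instances`).
#' @export
cv_wsd_feature <- function(docs, instances, features, k = 3, seed) {
  if (missing(seed)) stop("cv_wsd_feature: a seed is required", call. = FALSE)
  column <- null_column(docs)
  preds <- character(nrow(instances))
  fold_of <- integer(nrow(instances))
  manifest <- list()
  types <- sort_c(unique(instances$word_type))
  for (ti in seq_along(types)) {
    wt <- types[ti]
    idx <- which(instances$word_type == wt)
    labs <- instances$gold_class[idx]
    if (length(idx) < k)
      message(sprintf("cv_wsd_feature: %s has %d < %d instances; leave-one-out",
                      wt, length(idx), k))
    folds <- make_folds(labs, k, seed + ti)
    manifest[[wt]] <- lapply(sort(unique(folds)), function(f)
      list(train = idx[folds != f], held_out = idx[folds == f]))
    for (f in sort(unique(folds))) {
      tr <- idx[folds != f]
      te <- idx[folds == f]
      if (!length(tr)) {           # single-instance type: nothing to train on
        preds[te] <- "NULL"
        fold_of[te] <- f
        next
      }
      vocab <- build_vocabulary(features[tr])
      model <- train_vsm(vectorize(features[tr], vocab),
                         instances$gold_class[tr], length(vocab))
      preds[te] <- predict(model, vectorize(features[te], vocab))$predicted
      fold_of[te] <- f
    }
  }
  out_inst <- instances
  out_inst$fold <- fold_of
  out_inst$wsd <- preds
  list(column = fill_column(column, instances, preds),
       predictions = out_inst, folds = manifest)
}

#' WSD feature column over the test split
#'
#' One vector space model per word type, trained on all of that type's
#' training instances, predicts the type's test instances; test tokens of
#' types without a training model stay `"NULL"`.
#'
#' @param docs Named list of `ts_document`s (the test documents).
#' @param train_instances,train_features Training instances of the
#'   selected word types and their features.
#' @param test_instances,test_features Test instances and features.
#' @return A list with `column` (over every token of `docs`) and
#'   `predictions` (the test instance frame plus a `wsd` column).
#' @export
test_wsd_feature <- function(docs, train_instances, train_features,
                             test_instances, test_features) {
  column <- null_column(docs)
  preds <- rep("NULL", nrow(test_instances))
  for (wt in sort_c(unique(test_instances$word_type))) {
    tr <- which(train_instances$word_type == wt)
    te <- which(test_instances$word_type == wt)
    if (!length(tr)) {
      message(sprintf("test_wsd_feature: no training model for %s; NULL", wt))
      next
    }
    vocab <- build_vocabulary(train_features[tr])
    model <- train_vsm(vectorize(train_features[tr], vocab),
                       train_instances$gold_class[tr], length(vocab))
    preds[te] <- predict(model, vectorize(test_features[te], vocab))$predicted
  }
  out_inst <- test_instances
  out_inst$wsd <- preds
  keep <- preds != "NULL"
  list(column = fill_column(column, test_instances[keep, , drop = FALSE],
                            preds[keep]),
       predictions = out_inst)
}

bio_encode <- function(labels, sentence, index) {
  n <- length(labels)
  if (!n) return(character())
  new_run <- c(TRUE, diff(sentence) != 0L | diff(index) != 1L |
                       labels[-1L] != labels[-n])
  run_id <- cumsum(new_run)
  out <- rep("O", n)
  for (rid in unique(run_id)) {
    rows <- which(run_id == rid)
    if (labels[rows[1L]] == NON_EVENT) next
    out[rows] <- c(paste0("B-", labels[rows[1L]]),
                   rep(paste0("I-", labels[rows[1L]]), length(rows) - 1L))
  }
  out
}

#' Export a corpus as CRF++-ready CoNLL with a WSD feature column
#'
#' One line per token with tab-separated columns: form, lemma, POS, chunk,
#' protein tag, dependency function (the relation of the arc in which the
#' token is the dependent, from the designated parser layer; `_` when
#' none), the WSD prediction column, and the gold label in BIO encoding.
#' Sentences are separated by blank lines and documents follow each other
#' in the order given. A CRF++ template file declaring unigram features
#' over a window of four tokens either side is written to
#' `<path>.template`.
#'
#' @param docs Named list of `ts_document`s.
#' @param wsd_column Data frame from [cv_wsd_feature()] or
#'   [test_wsd_feature()] (`doc_id`, `sentence`, `token`, `wsd`); it must
#'   cover every token of `docs`.
#' @param path Output file path.
#' @param dep_layer Parser layer supplying the dependency function column.
#' @return Invisibly, `path`.
#' @export
export_conll <- function(docs, wsd_column, path, dep_layer = "synthparse") {
  keys <- column_key(wsd_column$doc_id, wsd_column$sentence, wsd_column$token)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (doc in docs) {
    toks <- doc_tokens(doc)
    if (!nrow(toks)) next
    labs <- align_triggers_to_tokens(doc)
    bio <- bio_encode(labs, toks$sentence, toks$index)
    at <- match(column_key(doc$doc_id, toks$sentence, toks$index), keys)
    if (anyNA(at))
      stop(sprintf("export_conll: wsd column does not cover document %s",
                   doc$doc_id), call. = FALSE)
    wsd <- wsd_column$wsd[at]
    row <- 0L
    for (s in seq_along(doc$sentences)) {
      sen <- doc$sentences[[s]]
      deps <- sen$deps[sen$deps$layer == dep_layer, , drop = FALSE]
      for (j in seq_len(nrow(sen$tokens))) {
        row <- row + 1L
        depfn <- deps$relation[match(sen$tokens$index[j], deps$dependent)]
        if (length(depfn) != 1L || is.na(depfn)) depfn <- "_"
        writeLines(paste(sen$tokens$form[j], sen$tokens$lemma[j],
                         sen$tokens$pos[j], sen$tokens$chunk[j],
                         sen$tokens$protein[j], depfn, wsd[row], bio[row],
                         sep = "\t"), con)
      }
      writeLines("", con)
    }
  }
  template <- unlist(lapply(0:6, function(col)
    sprintf("U%d%02d:%%x[%d,%d]", col, seq(-4, 4) + 4, -4:4, col)))
  writeLines(c(template, "B"), paste0(path, ".template"))
  invisible(path)
}

#' Read back a CoNLL export
#'
#' @param path File written by [export_conll()].
#' @return A data frame with the eight columns (`form`, `lemma`, `pos`,
#'   `chunk`, `protein`, `depfn`, `wsd`, `bio`) plus a 1-based `sentence`
#'   column, and the decoded token label in `label` (`B-`/`I-` stripped,
#'   `O` mapped to [NON_EVENT]).
#' @export
read_conll <- function(path) {
  groups <- split_blank_groups(readLines(path, warn = FALSE))
  rows <- lapply(seq_along(groups), function(s) {
    m <- matrix(unlist(strsplit(groups[[s]], "\t", fixed = TRUE)),
                ncol = 8L, byrow = TRUE)
    data.frame(sentence = s, form = m[, 1], lemma = m[, 2], pos = m[, 3],
               chunk = m[, 4], protein = m[, 5], depfn = m[, 6],
               wsd = m[, 7], bio = m[, 8], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$label <- ifelse(out$bio == "O", NON_EVENT, sub("^[BI]-", "", out$bio))
  rownames(out) <- NULL
  out
}
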