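small_cv_corpus <- function(seed = 17) {
  cfg <- synth_config(seed = seed, n_docs = 8, sentences_per_doc = 6,
                      n_word_types = 2, train_fraction = 1)
  load_corpus(generate_corpus(cfg, tempfile("cv"))$dir)
}

test_that("cross-validated predictions never come from a model that saw the instance", {
  corp <- small_cv_corpus()
  inst <- group_instances(corp$docs, corp$split)
  inst <- inst[startsWith(inst$word_type, "trig"), , drop = FALSE]
  rownames(inst) <- NULL
  feats <- extract_features(corp$docs, inst)
  cv <- cv_wsd_feature(corp$docs, inst, feats, k = 3, seed = 4)
  # every instance predicted exactly once, by a fold excluding it
  seen <- integer(0)
  for (wt in names(cv$folds)) {
    for (fold in cv$folds[[wt]]) {
      expect_length(intersect(fold$train, fold$held_out), 0L)
      seen <- c(seen, fold$held_out)
    }
  }
  expect_setequal(seen, seq_len(nrow(inst)))
  expect_false(any(duplicated(seen)))
  # predictions drawn from the 10-label set
  expect_true(all(cv$predictions$wsd %in% c(EVENT_CLASSES, NON_EVENT)))
  # column totality: one value per corpus token, non-targets NULL
  n_tokens <- sum(vapply(corp$docs, function(d) nrow(doc_tokens(d)), 0L))
  expect_equal(nrow(cv$column), n_tokens)
  expect_equal(sum(cv$column$wsd != "NULL"), nrow(inst))
  # deterministic given the seed
  cv2 <- cv_wsd_feature(corp$docs, inst, feats, k = 3, seed = 4)
  expect_identical(cv$column, cv2$column)
})

test_that("tiny word types fall back to leave-one-out", {
  corp <- small_cv_corpus()
  inst <- group_instances(corp$docs, corp$split)
  inst <- inst[startsWith(inst$word_type, "trig"), , drop = FALSE]
  inst <- inst[inst$word_type == inst$word_type[1], , drop = FALSE][1:2, ]
  rownames(inst) <- NULL
  feats <- extract_features(corp$docs, inst)
  expect_message(cv <- cv_wsd_feature(corp$docs, inst, feats, k = 3, seed = 1),
                 "leave-one-out")
  wt <- inst$word_type[1]
  # two instances -> two folds, each trained on the other instance only
  expect_length(cv$folds[[wt]], 2L)
  expect_true(all(cv$predictions$wsd %in% c(EVENT_CLASSES, NON_EVENT)))
})

test_that("test-split feature column uses full-train models and NULL elsewhere", {
  cfg <- synth_config(seed = 23, n_docs = 10, sentences_per_doc = 6,
                      n_word_types = 2, train_fraction = 0.6)
  corp <- load_corpus(generate_corpus(cfg, tempfile("tw"))$dir)
  inst <- group_instances(corp$docs, corp$split)
  targets <- inst[startsWith(inst$word_type, "trig"), , drop = FALSE]
  tr <- targets[targets$split == "train", , drop = FALSE]
  te <- targets[targets$split == "test", , drop = FALSE]
  rownames(tr) <- rownames(te) <- NULL
  f_tr <- extract_features(corp$docs, tr)
  f_te <- extract_features(corp$docs, te)
  test_docs <- corp$docs[names(corp$split)[corp$split == "test"]]
  out <- test_wsd_feature(test_docs, tr, f_tr, te, f_te)
  expect_true(all(out$predictions$wsd %in% c(EVENT_CLASSES, NON_EVENT)))
  expect_equal(sum(out$column$wsd != "NULL"), nrow(te))
  # a word type with no training model stays NULL
  te_extra <- te
  te_extra$word_type[1] <- "unknown.N"
  expect_message(out2 <- test_wsd_feature(test_docs, tr, f_tr, te_extra, f_te),
                 "no training model")
  expect_equal(out2$predictions$wsd[1], "NULL")
})

test_that("the CoNLL export round-trips BIO labels and carries eight columns", {
  doc <- build_doc(
    list(sent(c("gene", "expression", "level", "rises"),
              c("NN", "NN", "NN", "VBZ")),
         sent(c("binding", "occurs"), c("NN", "VBZ"))),
    triggers = data.frame(class = c("Gene_expression", "Binding"),
                          sentence = c(1L, 2L), from = c(0L, 0L),
                          to = c(1L, 0L), stringsAsFactors = FALSE),
    deps = list(synthparse = list(
      data.frame(head = c(3, 3, 3, -1), rel = c("nsubj", "nmod", "nmod", "root")),
      data.frame(head = c(1, -1), rel = c("nsubj", "root"))
    )),
    id = "C1"
  )
  docs <- list(C1 = doc)
  col <- data.frame(doc_id = "C1",
                    sentence = doc_tokens(doc)$sentence,
                    token = doc_tokens(doc)$index,
                    wsd = c("Gene_expression", "Gene_expression", "NULL",
                            "NULL", "Binding", "NULL"),
                    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".conll")
  export_conll(docs, col, path)
  back <- read_conll(path)
  expect_equal(back$bio, c("B-Gene_expression", "I-Gene_expression", "O",
                           "O", "B-Binding", "O"))
  expect_equal(back$label, align_triggers_to_tokens(doc))
  expect_equal(back$wsd, col$wsd)
  expect_equal(back$depfn, c("nsubj", "nmod", "nmod", "root", "nsubj", "root"))
  expect_true(file.exists(paste0(path, ".template")))
  # misaligned column -> error
  expect_error(export_conll(docs, col[-1, ], path), "does not cover")
})
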