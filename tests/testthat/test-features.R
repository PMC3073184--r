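make_feature_doc <- function() {
  build_doc(list(
    sent(c("no", "relevant", "changes", "in", "expression"),
         c("DT", "JJ", "NNS", "IN", "NN"),
         lemma = c("no", "relevant", "change", "in", "expression"))
  ), mesh = c("Humans", "Transcription, Genetic"), id = "F1")
}

test_that("local features cover n-grams over four streams and content neighbours", {
  doc <- make_feature_doc()
  f <- extract_local(doc, 1, 2)   # target "changes"
  expect_true("LOCAL:ng:form:-1,0=relevant|changes" %in% f)
  expect_true("LOCAL:ng:lemma:-1,0=relevant|change" %in% f)
  expect_false("LOCAL:ng:pos:-2,-1,0=no|relevant|changes" %in% f)
  expect_true("LOCAL:ng:pos:-2,-1,0=DT|JJ|NNS" %in% f)
  expect_true("LOCAL:ng:protein:0,1=O|O" %in% f)
  expect_true("LOCAL:cw:prev:form=relevant" %in% f)
  expect_true("LOCAL:cw:next:lemma=expression" %in% f)

  # target at sentence start: no (-1,0) or (-2,-1,0) n-grams
  f0 <- extract_local(doc, 1, 0)
  expect_false(any(grepl(":-1,0=", f0, fixed = TRUE)))
  expect_false(any(grepl(":-2,-1,0=", f0, fixed = TRUE)))
  expect_true(any(grepl(":0,1=", f0, fixed = TRUE)))

  # one-token sentence: no n-grams and no neighbour features
  doc1 <- build_doc(list(sent("expression", "NN")))
  expect_length(extract_local(doc1, 1, 0), 0L)
})

test_that("dependency features are layered, directional, and optional", {
  doc <- build_doc(
    list(sent(c("proteins", "inhibit", "binding"), c("NNS", "VBP", "NN"))),
    deps = list(
      gdep = list(data.frame(head = c(1, -1, 1), rel = c("nsubj", "root", "dobj"))),
      mcc  = list(data.frame(head = c(1, -1, 1), rel = c("nsubj", "root", "dobj")))
    )
  )
  f <- extract_dependency(doc, 1, 2)   # "binding", dependent of "inhibit"
  expect_true("DEP:rel:gdep:dobj:up" %in% f)
  expect_true("DEP:lex:gdep:dobj:up=inhibit" %in% f)
  # same arc in two layers -> two distinct features
  expect_true("DEP:rel:mcc:dobj:up" %in% f)
  # head side: the verb governs two dependents, direction "down"
  fv <- extract_dependency(doc, 1, 1)
  expect_true("DEP:lex:gdep:nsubj:down=protein" %in% fv ||
              "DEP:lex:gdep:nsubj:down=proteins" %in% fv)
  expect_true("DEP:lex:gdep:root:up=ROOT" %in% fv)
  # no layers loaded -> empty set
  doc0 <- build_doc(list(sent(c("a", "b"), c("DT", "NN"))))
  expect_length(extract_dependency(doc0, 1, 1), 0L)
})

test_that("bag-of-words splits sentence and window sub-families", {
  doc <- build_doc(list(
    sent(c("alpha", "of", "beta", "of", "of", "of", "target", "gamma"),
         c("NN", "IN", "NN", "IN", "IN", "IN", "NN", "NN"))
  ))
  f <- extract_bow(doc, 1, 6)
  # content word 6 tokens away: sentence feature only, no window feature
  expect_true("BOW:sent=alpha" %in% f)
  expect_false("BOW:win4=alpha" %in% f)
  expect_true("BOW:win4=beta" %in% f)
  expect_true("BOW:win4=gamma" %in% f)

  # the target's own lemma elsewhere in the sentence is kept
  doc2 <- build_doc(list(sent(c("expression", "and", "expression"),
                              c("NN", "CC", "NN"))))
  expect_true("BOW:sent=expression" %in% extract_bow(doc2, 1, 0))

  # function words only -> empty
  doc3 <- build_doc(list(sent(c("of", "the", "in"), c("IN", "DT", "IN"))))
  expect_length(extract_bow(doc3, 1, 1), 0L)
})

test_that("MeSH features mirror the document's descriptor list", {
  doc <- make_feature_doc()
  expect_setequal(extract_mesh(doc),
                  c("MESH=Humans", "MESH=Transcription, Genetic"))
  doc$mesh <- character()
  expect_length(extract_mesh(doc), 0L)
})

test_that("vectorization is binary over a closed train-built vocabulary", {
  feats <- list(c("LOCAL:a", "BOW:sent=x"), c("BOW:sent=x", "BOW:sent=y"))
  vocab <- build_vocabulary(feats)
  expect_equal(vocab, sort(unique(unlist(feats))))
  # duplicate feature in one instance is active once
  v <- vectorize(list(c("BOW:sent=x", "BOW:sent=x")), vocab)
  expect_length(v[[1]], 1L)
  # unseen test feature silently dropped; nothing known -> all-zero vector
  v2 <- vectorize(list(c("BOW:sent=z"), character()), vocab)
  expect_length(v2[[1]], 0L)
  expect_length(v2[[2]], 0L)
  # removing any test instance never changes the vocabulary
  expect_equal(build_vocabulary(feats[1]), sort(unique(feats[[1]])))
})

test_that("family ablation restricts the active sets exactly", {
  doc <- make_feature_doc()
  full <- instance_features(doc, 1, 2)
  for (fam in c("LOCAL", "DEP", "BOW", "MESH")) {
    sub <- instance_features(doc, 1, 2, families = fam)
    expect_setequal(sub, full[startsWith(full, fam)])
  }
  both <- instance_features(doc, 1, 2, families = c("LOCAL", "MESH"))
  expect_setequal(both, full[startsWith(full, "LOCAL") |
                               startsWith(full, "MESH")])
})

test_that("identical corpus and config give identical features and vectors", {
  cfg <- synth_config(seed = 9, n_docs = 4, sentences_per_doc = 3)
  d1 <- generate_corpus(cfg, tempfile("det"))$dir
  corp <- load_corpus(d1)
  inst <- group_instances(corp$docs, corp$split)
  f1 <- extract_features(corp$docs, inst)
  f2 <- extract_features(corp$docs, inst)
  expect_identical(f1, f2)
  expect_identical(build_vocabulary(f1), build_vocabulary(f2))
})
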