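test_that("standoff term lines parse and validate against the text", {
  dir <- tempfile("std"); dir.create(dir)
  writeLines(c("IL-2 induces expression strongly.", "Second line here."),
             file.path(dir, "D1.txt"))
  writeLines("T1\tProtein 0 4\tIL-2", file.path(dir, "D1.a1"))
  writeLines(c("T10\tGene_expression 13 23\texpression",
               "E1\tGene_expression:T10",
               "M1\tNegation E1"),
             file.path(dir, "D1.a2"))
  doc <- read_standoff(file.path(dir, "D1.txt"), file.path(dir, "D1.a1"),
                       file.path(dir, "D1.a2"))
  expect_equal(doc$proteins$char_start, 0L)
  expect_equal(doc$proteins$char_end, 4L)
  expect_equal(doc$proteins$surface, "IL-2")
  expect_equal(nrow(doc$triggers), 1L)
  expect_equal(doc$triggers$event_class, "Gene_expression")

  # a2 with only event lines -> no triggers
  writeLines("E1\tBinding:T3 Theme:T1", file.path(dir, "D2.a2"))
  writeLines("IL-2 induces expression strongly.", file.path(dir, "D2.txt"))
  doc2 <- read_standoff(file.path(dir, "D2.txt"),
                        a2_path = file.path(dir, "D2.a2"))
  expect_equal(nrow(doc2$triggers), 0L)

  # surface/slice mismatch -> integrity error naming the file
  writeLines("T10\tGene_expression 13 23\texpressYon", file.path(dir, "D3.a2"))
  expect_error(read_standoff(file.path(dir, "D1.txt"),
                             a2_path = file.path(dir, "D3.a2")),
               "integrity error.*D3\\.a2")

  # malformed line -> parse error naming file and line
  writeLines(c("T1\tProtein 0 4\tIL-2", "garbage line"), file.path(dir, "D4.a1"))
  expect_error(read_standoff(file.path(dir, "D1.txt"), file.path(dir, "D4.a1")),
               "parse error.*D4\\.a1:2")
})

test_that("token layer attaches blank-separated sentences with validated spans", {
  doc <- build_doc(list(
    sent(c("The", "gene", "is", "expressed", "here"),
         c("DT", "NN", "VBZ", "VBN", "RB")),
    sent(c("It", "works", "."), c("PRP", "VBZ", "."))
  ))
  expect_length(doc$sentences, 2L)
  expect_equal(nrow(doc_tokens(doc)), 8L)
  expect_equal(doc$sentences[[1]]$tokens$index, 0:4)

  # span slice != form -> integrity error
  dir <- tempfile("tok"); dir.create(dir)
  writeLines("gene works", file.path(dir, "D1.txt"))
  writeLines("gene\tgene\tNN\tO\tO\t0\t4\nworkz\tworkz\tVBZ\tO\tO\t5\t10",
             file.path(dir, "D1.tok"))
  base <- read_standoff(file.path(dir, "D1.txt"))
  expect_error(read_token_layer(file.path(dir, "D1.tok"), base),
               "integrity error")

  # empty file -> zero sentences
  writeLines(character(), file.path(dir, "empty.tok"))
  expect_length(read_token_layer(file.path(dir, "empty.tok"), base)$sentences, 0L)
})

test_that("dependency layers align per token and may coexist", {
  doc <- build_doc(
    list(sent(c("proteins", "inhibit", "binding"), c("NNS", "VBP", "NN"))),
    deps = list(
      gdep = list(data.frame(head = c(1, -1, 1), rel = c("nsubj", "root", "dobj"))),
      bikel = list(data.frame(head = c(1, -1, 1), rel = c("sbj", "root", "obj")))
    )
  )
  arcs <- doc$sentences[[1]]$deps
  expect_setequal(unique(arcs$layer), c("gdep", "bikel"))
  expect_equal(arcs$head[arcs$layer == "gdep" & arcs$dependent == 0L], 1L)
  expect_equal(arcs$relation[arcs$layer == "gdep" & arcs$dependent == 2L], "dobj")

  dir <- tempfile("dep"); dir.create(dir)
  base <- build_doc(list(sent(c("a", "b"), c("DT", "NN"))), dir = dir)
  writeLines(c("5\tnsubj", "-1\troot"), file.path(dir, "bad.dep"))
  expect_error(read_dependency_layer(file.path(dir, "bad.dep"), "x", base),
               "head index outside sentence")
  writeLines(c("1\tnsubj"), file.path(dir, "short.dep"))
  expect_error(read_dependency_layer(file.path(dir, "short.dep"), "x", base),
               "misalignment")
})

test_that("mesh sidecar groups descriptors per document without duplicates", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("d1\tHumans", "d1\tTranscription, Genetic", "d2\tHumans",
               "d1\tHumans"), p)
  m <- read_mesh_sidecar(p)
  expect_equal(m$d1, c("Humans", "Transcription, Genetic"))
  expect_equal(m$d2, "Humans")
  expect_null(m$d3)
})

test_that("trigger-token alignment uses overlap with deterministic conflicts", {
  doc <- build_doc(
    list(sent(c("gene", "expression", "level", "binding", "site"),
              c("NN", "NN", "NN", "NN", "NN"))),
    triggers = data.frame(class = c("Gene_expression", "Binding"),
                          sentence = c(1L, 1L), from = c(0L, 3L),
                          to = c(1L, 3L), stringsAsFactors = FALSE)
  )
  labs <- align_triggers_to_tokens(doc)
  # multi-token trigger labels both tokens; non-overlap -> NON-EVENT
  expect_equal(labs, c("Gene_expression", "Gene_expression", NON_EVENT,
                       "Binding", NON_EVENT))

  # a token overlapped by two distinct classes: earliest start wins, warning
  doc2 <- build_doc(
    list(sent(c("alpha", "beta"), c("NN", "NN"))),
    triggers = data.frame(class = c("Transcription", "Binding"),
                          sentence = c(1L, 1L), from = c(0L, 1L),
                          to = c(1L, 1L), stringsAsFactors = FALSE)
  )
  expect_warning(labs2 <- align_triggers_to_tokens(doc2), "distinct classes")
  expect_equal(labs2, c("Transcription", "Transcription"))
})

test_that("predicted labels export as merged a2 trigger terms and round-trip", {
  doc <- build_doc(list(sent(c("no", "relevant", "changes", "seen"),
                             c("DT", "JJ", "NNS", "VBN"))))
  # all NON-EVENT -> empty output
  expect_length(write_a2_triggers(doc, rep(NON_EVENT, 4)), 0L)

  # adjacent same-class tokens merge into one term with sequential ids
  labs <- c(NON_EVENT, "Transcription", "Transcription", NON_EVENT)
  lines <- write_a2_triggers(doc, labs)
  expect_length(lines, 1L)
  expect_match(lines, "^T1000\tTranscription 3 19\trelevant changes$")

  # write -> read -> align is the identity on random label sequences
  set.seed(42)
  pool <- c(NON_EVENT, "Binding", "Transcription")
  for (i in 1:20) {
    labs <- sample(pool, 4, replace = TRUE)
    a2 <- tempfile(fileext = ".a2")
    txt <- tempfile(fileext = ".txt")
    writeLines(strsplit(doc$text, "\n")[[1]], txt)
    write_a2_triggers(doc, labs, a2)
    back <- read_standoff(txt, a2_path = a2)
    back$sentences <- doc$sentences
    expect_equal(align_triggers_to_tokens(back), labs)
  }
})
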