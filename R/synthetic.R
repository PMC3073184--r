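# Seeded synthetic standoff corpora with the statistical structure the
# method assumes: per-word-type class distributions with a controllable
# majority-class skew, and a class-specific cue token placed immediately
# before the target with controllable determinism (the "one sense per
# collocation" premise as a dial). Everything else in a sentence is
# closed-vocabulary filler, so the naive identity-lemma tagging the
# generator writes into the token sidecar is exact by construction.

SYNTH_VERBS <- c("induces", "measures", "observes", "reports")
SYNTH_FILLER_POS <- c("NN", "JJ", "DT", "IN")

#' Configuration for the synthetic corpus generator
#'
#' @param n_docs Number of documents (ignored when `occurrences_per_type`
#'   is given, in which case it is derived).
#' @param sentences_per_doc Sentences per document; each sentence carries
#'   exactly one target occurrence.
#' @param n_word_types Number of target word types (nouns and verbs,
#'   alternating).
#' @param classes_per_type Classes per word type, 2-10, counting the
#'   non-event majority class; the minority classes are event classes
#'   sampled per type.
#' @param skew Majority-class probability per type, in `(0, 1]`; a scalar
#'   or a vector recycled to `n_word_types`.
#' @param collocation_determinism Probability that the cue token placed
#'   before a target matches the sampled class (otherwise a cue of one of
#'   the type's other classes is drawn uniformly); must lie in
#'   `[1/classes_per_type, 1]`. At the lower bound the cue carries no
#'   information about the class.
#' @param filler_vocab_size Size of the closed filler vocabulary.
#' @param protein_rate Probability that a sentence contains a protein
#'   mention (written to `.a1` and the token layer's protein column).
#' @param mesh_signal Probability, per event class present in a document,
#'   that a class-indicative MeSH descriptor is attached to the document.
#' @param train_fraction Fraction of documents assigned to the training
#'   split (split is by document).
#' @param seed Mandatory integer seed; generation is deterministic.
#' @param occurrences_per_type Optional integer vector giving the exact
#'   number of occurrences of each word type; occurrences are interleaved
#'   round-robin across sentences.
#' @param exact_class_counts When `TRUE`, each type's class counts are
#'   fixed at their expectations (majority = `round(skew * n)`, remainder
#'   spread evenly) instead of sampled i.i.d.; occurrence order is still
#'   shuffled.
#' @return A validated `ts_synth_config` list.
#' @export
synth_config <- function(n_docs = 100, sentences_per_doc = 12,
                         n_word_types = 4, classes_per_type = 3,
                         skew = 0.6, collocation_determinism = 1.0,
                         filler_vocab_size = 40, protein_rate = 0.1,
                         mesh_signal = 0.5, train_fraction = 0.7,
                         seed, occurrences_per_type = NULL,
                         exact_class_counts = FALSE) {
  if (missing(seed) || !is.numeric(seed))
    stop("synth_config: an integer seed is required", call. = FALSE)
  if (n_word_types < 1 || n_word_types > 26)
    stop("synth_config: n_word_types must be in 1..26", call. = FALSE)
  if (classes_per_type < 2 || classes_per_type > length(EVENT_CLASSES) + 1)
    stop(sprintf("synth_config: classes_per_type must be in 2..%d (cue vocabulary per type has one cue per class)",
                 length(EVENT_CLASSES) + 1), call. = FALSE)
  skew <- rep_len(skew, n_word_types)
  if (any(skew <= 0 | skew > 1))
    stop("synth_config: skew must lie in (0, 1]", call. = FALSE)
  pi_min <- 1 / classes_per_type
  if (collocation_determinism < pi_min - 1e-9 || collocation_determinism > 1)
    stop(sprintf("synth_config: collocation_determinism must lie in [%.3f, 1]",
                 pi_min), call. = FALSE)
  stopifnot(protein_rate >= 0, protein_rate <= 1,
            mesh_signal >= 0, mesh_signal <= 1,
            train_fraction >= 0, train_fraction <= 1,
            filler_vocab_size >= 4, sentences_per_doc >= 1)
  if (!is.null(occurrences_per_type)) {
    occurrences_per_type <- as.integer(rep_len(occurrences_per_type, n_word_types))
    if (any(occurrences_per_type < 1))
      stop("synth_config: occurrences_per_type must be positive", call. = FALSE)
    n_docs <- ceiling(sum(occurrences_per_type) / sentences_per_doc)
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 n_word_types = as.integer(n_word_types),
                 classes_per_type = as.integer(classes_per_type),
                 skew = skew,
                 collocation_determinism = collocation_determinism,
                 filler_vocab_size = as.integer(filler_vocab_size),
                 protein_rate = protein_rate, mesh_signal = mesh_signal,
                 train_fraction = train_fraction, seed = as.integer(seed),
                 occurrences_per_type = occurrences_per_type,
                 exact_class_counts = isTRUE(exact_class_counts)),
            class = "ts_synth_config")
}

# Deterministic layout shared by generate_corpus() and truth_table():
# word types, their class sets, their cue lemmas, the filler vocabulary.
# Consumes RNG state seeded from config$seed; callers that keep sampling
# continue from the state this leaves behind.
synth_layout <- function(config) {
  set.seed(config$seed)
  k <- config$n_word_types
  lemmas <- paste0("trig", letters[seq_len(k)])
  pos <- ifelse(seq_len(k) %% 2L == 1L, "NN", "VB")
  cpos <- coarse_pos(pos)
  types <- vector("list", k)
  for (i in seq_len(k)) {
    minors <- sort_c(sample(EVENT_CLASSES, config$classes_per_type - 1L))
    classes <- c(NON_EVENT, minors)          # majority class first
    cues <- sprintf("cue%s%02d", letters[i], seq_along(classes))
    types[[i]] <- list(word_type = paste0(lemmas[i], ".", cpos[i]),
                       lemma = lemmas[i], pos = pos[i],
                       classes = classes, cues = stats::setNames(cues, classes),
                       skew = config$skew[i])
  }
  fillers <- sprintf("filler%02d", seq_len(config$filler_vocab_size))
  filler_pos <- SYNTH_FILLER_POS[(seq_len(config$filler_vocab_size) - 1L) %%
                                   length(SYNTH_FILLER_POS) + 1L]
  list(types = types, fillers = fillers, filler_pos = filler_pos)
}

#' Generator ground truth for a configuration
#'
#' Returns, per word type, the expected majority-class bias and the class
#' set, plus the cue-to-class map — everything a test needs to assert
#' against the generator without re-deriving its internals.
#'
#' @param config A `ts_synth_config`.
#' @return A list with `types` (data frame: `word_type`, `lemma`, `pos`,
#'   `majority_class`, `n_classes`, `expected_bias`) and `cues` (data
#'   frame: `word_type`, `class`, `cue`).
#' @export
truth_table <- function(config) {
  layout <- synth_layout(config)
  types <- do.call(rbind, lapply(layout$types, function(t)
    data.frame(word_type = t$word_type, lemma = t$lemma, pos = t$pos,
               majority_class = t$classes[1L],
               n_classes = length(t$classes), expected_bias = t$skew,
               stringsAsFactors = FALSE)))
  cues <- do.call(rbind, lapply(layout$types, function(t)
    data.frame(word_type = t$word_type, class = t$classes,
               cue = unname(t$cues), stringsAsFactors = FALSE)))
  rownames(types) <- rownames(cues) <- NULL
  list(types = types, cues = cues)
}

# class counts fixed at expectation: majority = round(skew*n), remainder
# spread as evenly as possible over the minority classes
exact_class_vector <- function(classes, skew, n) {
  maj <- min(n, max(1L, as.integer(round(skew * n))))
  rest <- n - maj
  k <- length(classes) - 1L
  counts <- c(maj, rep(rest %/% k, k))
  if (rest %% k > 0L)
    counts[1L + seq_len(rest %% k)] <- counts[1L + seq_len(rest %% k)] + 1L
  rep(classes, counts)
}

#' Generate a synthetic standoff corpus
#'
#' Writes, under `dir`, one `.txt`/`.a1`/`.a2`/`.tok`/`.dep` file set per
#' document plus the corpus-level `mesh.tsv` and `split.tsv` sidecars.
#' Each sentence holds filler tokens, a main verb (the head of every
#' other token in the dependency layer), a cue token and one target
#' occurrence; the cue sits immediately before the target so the local
#' bigram family alone suffices to recover a deterministic cue-class
#' association. Event-class occurrences are written as `.a2` trigger
#' terms. Output is byte-identical across runs with the same config.
#'
#' @param config A `ts_synth_config`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, `doc_ids`, `split` (named
#'   vector) and `truth` (see [truth_table()]).
#' @export
generate_corpus <- function(config, dir) {
  stopifnot(inherits(config, "ts_synth_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  layout <- synth_layout(config)          # seeds the RNG
  k <- config$n_word_types
  occ <- config$occurrences_per_type
  if (is.null(occ)) {
    total <- config$n_docs * config$sentences_per_doc
    occ <- rep(total %/% k, k)
    if (total %% k > 0L) occ[seq_len(total %% k)] <- occ[seq_len(total %% k)] + 1L
  }
  total <- sum(occ)
  n_docs <- ceiling(total / config$sentences_per_doc)

  # round-robin interleave of type occurrences across the sentence stream
  frac <- unlist(lapply(seq_len(k), function(t) (seq_len(occ[t]) - 0.5) / occ[t]))
  sched_type <- rep(seq_len(k), occ)[order(frac, rep(seq_len(k), occ))]

  # classes per occurrence, grouped by type
  sched_class <- character(total)
  for (t in seq_len(k)) {
    ty <- layout$types[[t]]
    pos_t <- which(sched_type == t)
    if (config$exact_class_counts) {
      sched_class[pos_t] <- sample(exact_class_vector(ty$classes, ty$skew,
                                                      length(pos_t)))
    } else {
      probs <- c(ty$skew, rep((1 - ty$skew) / (length(ty$classes) - 1L),
                              length(ty$classes) - 1L))
      sched_class[pos_t] <- sample(ty$classes, length(pos_t),
                                   replace = TRUE, prob = probs)
    }
  }

  # cue per occurrence: matching with probability pi, else another class's cue
  sched_cue <- character(total)
  for (s in seq_len(total)) {
    ty <- layout$types[[sched_type[s]]]
    if (stats::runif(1) < config$collocation_determinism) {
      sched_cue[s] <- ty$cues[[sched_class[s]]]
    } else {
      others <- ty$cues[names(ty$cues) != sched_class[s]]
      sched_cue[s] <- if (length(others) == 1L) others[[1L]] else sample(unname(others), 1L)
    }
  }

  doc_ids <- sprintf("SYN%04d", seq_len(n_docs))
  mesh_lines <- character()
  s_global <- 0L
  for (d in seq_len(n_docs)) {
    n_sent <- min(config$sentences_per_doc, total - s_global)
    tok_lines <- character()
    dep_lines <- character()
    a1_lines <- character()
    a2_lines <- character()
    text_lines <- character(n_sent)
    offset <- 0L
    a1_id <- 0L
    a2_id <- 500L
    doc_classes <- character()
    for (sn in seq_len(n_sent)) {
      s_global <- s_global + 1L
      ty <- layout$types[[sched_type[s_global]]]
      cls <- sched_class[s_global]
      doc_classes <- c(doc_classes, cls)
      pre <- sample.int(config$filler_vocab_size, sample(1:3, 1L), replace = TRUE)
      mid <- sample.int(config$filler_vocab_size, sample(0:2, 1L), replace = TRUE)
      post <- sample.int(config$filler_vocab_size, sample(0:2, 1L), replace = TRUE)
      forms <- c(layout$fillers[pre], sample(SYNTH_VERBS, 1L),
                 layout$fillers[mid], sched_cue[s_global], ty$lemma,
                 layout$fillers[post], ".")
      pos <- c(layout$filler_pos[pre], "VBZ", layout$filler_pos[mid],
               "JJ", ty$pos, layout$filler_pos[post], ".")
      n_tok <- length(forms)
      verb_i <- length(pre) + 1L
      target_i <- verb_i + length(mid) + 2L
      protein <- rep("O", n_tok)
      if (length(pre) && stats::runif(1) < config$protein_rate) {
        pr <- sample(seq_along(pre), 1L)
        protein[pr] <- "B-PROT"
      }
      starts <- offset + c(0L, cumsum(nchar(forms) + 1L))[seq_len(n_tok)]
      ends <- starts + nchar(forms)
      text_lines[sn] <- paste(forms, collapse = " ")
      tok_lines <- c(tok_lines,
                     paste(forms, tolower(forms), pos, "O", protein,
                           starts, ends, sep = "\t"),
                     "")
      heads <- rep(verb_i - 1L, n_tok)
      heads[verb_i] <- -1L
      rels <- character(n_tok)
      for (j in seq_len(n_tok)) {
        rels[j] <- if (j == verb_i) "root"
          else if (j == target_i) sample(c("nsubj", "dobj"), 1L)
          else if (j == target_i - 1L) "amod"
          else if (pos[j] == ".") "punct"
          else sample(c("nmod", "det", "case"), 1L)
      }
      dep_lines <- c(dep_lines, paste(heads, rels, sep = "\t"), "")
      if (any(protein == "B-PROT")) {
        pr <- which(protein == "B-PROT")
        a1_id <- a1_id + 1L
        a1_lines <- c(a1_lines, sprintf("T%d\tProtein %d %d\t%s", a1_id,
                                        starts[pr], ends[pr], forms[pr]))
      }
      if (cls != NON_EVENT) {
        a2_id <- a2_id + 1L
        a2_lines <- c(a2_lines, sprintf("T%d\t%s %d %d\t%s", a2_id, cls,
                                        starts[target_i], ends[target_i],
                                        forms[target_i]))
      }
      offset <- ends[n_tok] + 1L   # the newline joining sentences
    }
    base <- file.path(dir, doc_ids[d])
    writeLines(text_lines, paste0(base, ".txt"))
    writeLines(a1_lines, paste0(base, ".a1"))
    writeLines(a2_lines, paste0(base, ".a2"))
    writeLines(tok_lines, paste0(base, ".tok"))
    writeLines(dep_lines, paste0(base, ".dep"))
    mesh_lines <- c(mesh_lines, sprintf("%s\tD_synthetic", doc_ids[d]))
    for (cls in sort_c(unique(doc_classes[doc_classes != NON_EVENT])))
      if (stats::runif(1) < config$mesh_signal)
        mesh_lines <- c(mesh_lines, sprintf("%s\tD_%s", doc_ids[d], cls))
  }
  writeLines(mesh_lines, file.path(dir, "mesh.tsv"))
  n_train <- ceiling(config$train_fraction * n_docs)
  split <- stats::setNames(ifelse(seq_len(n_docs) <= n_train, "train", "test"),
                           doc_ids)
  writeLines(paste(doc_ids, split, sep = "\t"), file.path(dir, "split.tsv"))
  invisible(list(dir = dir, doc_ids = doc_ids, split = split,
                 truth = truth_table(config)))
}

#' Load a corpus directory produced by [generate_corpus()]
#'
#' Reads every `<id>.txt` (with its `.a1`, `.a2`, `.tok` and `.dep`
#' companions where present) plus the `mesh.tsv` and `split.tsv`
#' sidecars. The dependency layer is attached under layer id
#' `"synthparse"` by default.
#'
#' @param dir Corpus directory.
#' @param dep_layer Layer id for the `.dep` files.
#' @return A list with `docs` (named list of `ts_document`s) and `split`
#'   (named character vector; `NULL` when `split.tsv` is absent).
#' @export
load_corpus <- function(dir, dep_layer = "synthparse") {
  txts <- sort_c(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (!length(txts)) stop(sprintf("no .txt files under %s", dir), call. = FALSE)
  mesh_path <- file.path(dir, "mesh.tsv")
  mesh <- if (file.exists(mesh_path)) read_mesh_sidecar(mesh_path) else list()
  docs <- lapply(txts, function(txt) {
    base <- sub("\\.txt$", "", txt)
    has <- function(ext) if (file.exists(paste0(base, ext))) paste0(base, ext) else NULL
    doc <- read_standoff(txt, has(".a1"), has(".a2"))
    if (!is.null(has(".tok"))) doc <- read_token_layer(has(".tok"), doc)
    if (!is.null(has(".dep"))) doc <- read_dependency_layer(has(".dep"), dep_layer, doc)
    doc$mesh <- mesh[[doc$doc_id]] %||% character()
    doc
  })
  names(docs) <- vapply(docs, function(d) d$doc_id, "")
  split_path <- file.path(dir, "split.tsv")
  split <- NULL
  if (file.exists(split_path)) {
    tab <- utils::read.table(split_path, sep = "\t", header = FALSE,
                             col.names = c("doc_id", "split"),
                             stringsAsFactors = FALSE)
    split <- stats::setNames(tab$split, tab$doc_id)
  }
  list(docs = docs, split = split)
}
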