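# The four feature families. Every feature is a flat namespaced string
# whose prefix (up to the first ':' or '=') names its family, so a plain
# radix sort yields the family-then-key vocabulary ordering.
#
#   LOCAL  n-grams over four attribute streams + nearest content words
#   DEP    (un)lexicalised dependency arcs touching the target
#   BOW    content-word lemmas in the sentence / a +-4 token window
#   MESH   document-level MeSH descriptors

FEATURE_FAMILIES <- c("LOCAL", "DEP", "BOW", "MESH")

feature_family <- function(keys) sub("^([A-Z]+)[:=].*$", "\\1", keys)

#' Local collocational features of a target token
#'
#' For each of the four attribute streams (lemma, word form, POS tag,
#' protein tag): the bigrams at relative offsets (-1,0) and (0,+1) and the
#' trigrams at (-2,-1,0), (-1,0,+1) and (0,+1,+2) containing the target,
#' skipping any n-gram that would cross the sentence boundary. In addition,
#' the lemma and word form of the nearest preceding and nearest following
#' content word in the sentence, direction-marked.
#'
#' @param document A `ts_document` with sentences populated.
#' @param sentence 1-based sentence index.
#' @param token 0-based token index of the target within the sentence.
#' @return Character vector of feature keys (a set: no duplicates).
#' @export
extract_local <- function(document, sentence, token) {
  toks <- document$sentences[[sentence]]$tokens
  n <- nrow(toks)
  i <- token + 1L
  feats <- character()
  streams <- list(lemma = toks$lemma, form = toks$form,
                  pos = toks$pos, protein = toks$protein)
  windows <- list(c(-1L, 0L), c(0L, 1L), c(-2L, -1L, 0L),
                  c(-1L, 0L, 1L), c(0L, 1L, 2L))
  for (sname in names(streams)) {
    vals <- streams[[sname]]
    for (offs in windows) {
      idx <- i + offs
      if (idx[1L] < 1L || idx[length(idx)] > n) next
      feats <- c(feats, sprintf("LOCAL:ng:%s:%s=%s", sname,
                                paste(offs, collapse = ","),
                                paste(vals[idx], collapse = "|")))
    }
  }
  content <- which(coarse_pos(toks$pos) %in% CONTENT_POS)
  prev <- content[content < i]
  if (length(prev)) {
    p <- max(prev)
    feats <- c(feats, sprintf("LOCAL:cw:prev:lemma=%s", toks$lemma[p]),
               sprintf("LOCAL:cw:prev:form=%s", toks$form[p]))
  }
  nxt <- content[content > i]
  if (length(nxt)) {
    p <- min(nxt)
    feats <- c(feats, sprintf("LOCAL:cw:next:lemma=%s", toks$lemma[p]),
               sprintf("LOCAL:cw:next:form=%s", toks$form[p]))
  }
  unique(feats)
}

#' Dependency features of a target token
#'
#' For every arc touching the target, in every loaded parser layer, two
#' features are produced: an unlexicalised one (layer + relation +
#' direction) and a lexicalised one that appends the lemma of the token at
#' the other end of the arc (`ROOT` when the target is the sentence root).
#' Direction is `up` when the target is the dependent and `down` when it
#' is the head.
#'
#' @inheritParams extract_local
#' @return Character vector of feature keys.
#' @export
extract_dependency <- function(document, sentence, token) {
  sen <- document$sentences[[sentence]]
  deps <- sen$deps
  if (!nrow(deps)) return(character())
  feats <- character()
  touch <- deps$head == token | deps$dependent == token
  for (r in which(touch)) {
    if (deps$dependent[r] == token) {
      dir <- "up"
      other <- deps$head[r]
    } else {
      dir <- "down"
      other <- deps$dependent[r]
    }
    lemma <- if (other < 0L) "ROOT" else sen$tokens$lemma[other + 1L]
    feats <- c(feats,
               sprintf("DEP:rel:%s:%s:%s", deps$layer[r], deps$relation[r], dir),
               sprintf("DEP:lex:%s:%s:%s=%s", deps$layer[r], deps$relation[r],
                       dir, lemma))
  }
  unique(feats)
}

#' Bag-of-words features of a target token
#'
#' Two sub-families with distinct keys: `sent`, the lemma of every content
#' word in the sentence other than the target token itself; and `win4`,
#' the lemma of every content word among the four tokens either side of
#' the target (window counted in tokens, truncated at the sentence
#' boundary).
#'
#' @inheritParams extract_local
#' @return Character vector of feature keys.
#' @export
extract_bow <- function(document, sentence, token) {
  toks <- document$sentences[[sentence]]$tokens
  i <- token + 1L
  content <- which(coarse_pos(toks$pos) %in% CONTENT_POS)
  content <- content[content != i]
  feats <- character()
  if (length(content))
    feats <- sprintf("BOW:sent=%s", toks$lemma[content])
  win <- content[abs(content - i) <= 4L]
  if (length(win))
    feats <- c(feats, sprintf("BOW:win4=%s", toks$lemma[win]))
  unique(feats)
}

#' MeSH descriptor features of an instance's document
#'
#' One feature per descriptor attached to the document; identical
#' descriptors on different documents yield identical keys.
#'
#' @param document A `ts_document` (its `mesh` field holds descriptors).
#' @return Character vector of feature keys.
#' @export
extract_mesh <- function(document) {
  if (!length(document$mesh)) return(character())
  unique(sprintf("MESH=%s", document$mesh))
}

#' All features of one instance
#'
#' @inheritParams extract_local
#' @param families Subset of `c("LOCAL","DEP","BOW","MESH")`.
#' @return Character vector of feature keys.
#' @export
instance_features <- function(document, sentence, token,
                              families = FEATURE_FAMILIES) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  feats <- character()
  if ("LOCAL" %in% families)
    feats <- c(feats, extract_local(document, sentence, token))
  if ("DEP" %in% families)
    feats <- c(feats, extract_dependency(document, sentence, token))
  if ("BOW" %in% families)
    feats <- c(feats, extract_bow(document, sentence, token))
  if ("MESH" %in% families)
    feats <- c(feats, extract_mesh(document))
  feats
}

#' Extract features for a table of instances
#'
#' @param docs Named list of `ts_document`s.
#' @param instances Instance data frame from [group_instances()] (or any
#'   frame with `doc_id`, `sentence`, `token` columns).
#' @param families Feature families to extract.
#' @return A list, aligned with the rows of `instances`, of character
#'   vectors of feature keys.
#' @export
extract_features <- function(docs, instances, families = FEATURE_FAMILIES) {
  lapply(seq_len(nrow(instances)), function(r)
    instance_features(docs[[instances$doc_id[r]]], instances$sentence[r],
                      instances$token[r], families))
}

#' Build a closed feature vocabulary from training instances
#'
#' The vocabulary is the sorted set of all feature keys seen on the given
#' (training) instances; the radix sort makes the ordering byte-stable
#' across locales. Test-time features outside the vocabulary are dropped
#' by [vectorize()].
#'
#' @param features List of feature-key vectors (training instances only).
#' @return Character vector: the ordered vocabulary.
#' @export
build_vocabulary <- function(features) {
  keys <- unlist(features, use.names = FALSE)
  if (is.null(keys)) return(character())
  sort_c(unique(keys))
}

#' Vectorize instances against a vocabulary
#'
#' Vectors are binary with set semantics: a feature is active or not,
#' multiplicity is discarded, and features absent from the vocabulary are
#' silently dropped.
#'
#' @param features List of feature-key vectors.
#' @param vocabulary Character vector from [build_vocabulary()].
#' @return A list of sorted integer index vectors (the active positions).
#' @export
vectorize <- function(features, vocabulary) {
  lapply(features, function(f) {
    idx <- match(unique(f), vocabulary)
    sort.int(idx[!is.na(idx)])
  })
}
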