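# Builders used across the suite. Documents are constructed through the
# package's own readers (write temp standoff + sidecar files, read them
# back) so every fixture also exercises the I/O path.

sent <- function(forms, pos, lemma = tolower(forms), protein = NULL,
                 chunk = NULL) {
  data.frame(form = forms, pos = pos, lemma = lemma,
             protein = protein %||% rep("O", length(forms)),
             chunk = chunk %||% rep("O", length(forms)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# sentences: list of data frames from sent()
# triggers: data.frame(class, sentence, from, to)  (0-based token range)
# deps: named list (layer id -> list of per-sentence data.frame(head, rel))
build_doc <- function(sentences, triggers = NULL, deps = NULL,
                      mesh = character(), id = "DOC1", dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("doc")
    dir.create(dir, recursive = TRUE)
  }
  off <- 0L
  lines <- character(length(sentences))
  tok_lines <- character()
  spans <- vector("list", length(sentences))
  for (s in seq_along(sentences)) {
    df <- sentences[[s]]
    n <- nrow(df)
    starts <- off + c(0L, cumsum(nchar(df$form) + 1L))[seq_len(n)]
    ends <- starts + nchar(df$form)
    spans[[s]] <- cbind(starts, ends)
    lines[s] <- paste(df$form, collapse = " ")
    tok_lines <- c(tok_lines,
                   paste(df$form, df$lemma, df$pos, df$chunk, df$protein,
                         starts, ends, sep = "\t"), "")
    off <- ends[n] + 1L
  }
  text <- paste(lines, collapse = "\n")
  writeLines(lines, file.path(dir, paste0(id, ".txt")))
  writeLines(tok_lines, file.path(dir, paste0(id, ".tok")))
  a2 <- character()
  if (!is.null(triggers)) {
    for (r in seq_len(nrow(triggers))) {
      st <- spans[[triggers$sentence[r]]][triggers$from[r] + 1L, 1L]
      en <- spans[[triggers$sentence[r]]][triggers$to[r] + 1L, 2L]
      a2 <- c(a2, sprintf("T%d\t%s %d %d\t%s", 500L + r, triggers$class[r],
                          st, en, substr(text, st + 1L, en)))
    }
  }
  writeLines(a2, file.path(dir, paste0(id, ".a2")))
  doc <- read_standoff(file.path(dir, paste0(id, ".txt")),
                       a2_path = file.path(dir, paste0(id, ".a2")))
  doc <- read_token_layer(file.path(dir, paste0(id, ".tok")), doc)
  if (!is.null(deps)) {
    for (layer in names(deps)) {
      p <- file.path(dir, paste0(id, ".", layer, ".dep"))
      writeLines(unlist(lapply(deps[[layer]], function(df)
        c(paste(df$head, df$rel, sep = "\t"), ""))), p)
      doc <- read_dependency_layer(p, layer, doc)
    }
  }
  doc$mesh <- mesh
  doc
}

# Brute-force nearest-centroid oracle: dense vectors, explicit loops,
# same tie rules (max score -> max prior -> alphabetically first class).
# Kept deliberately independent of the package's matrix code path.
oracle_predict <- function(train_idx, labels, test_idx, n_feat) {
  classes <- sort(unique(labels))
  centroids <- list()
  for (cl in classes) {
    rows <- which(labels == cl)
    cen <- numeric(n_feat)
    for (r in rows) for (j in train_idx[[r]]) cen[j] <- cen[j] + 1
    centroids[[cl]] <- cen / length(rows)
  }
  x <- numeric(n_feat)
  for (j in test_idx) x[j] <- 1
  scores <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    cen <- centroids[[cl]]
    dot <- 0; nc <- 0; nx <- 0
    for (j in seq_len(n_feat)) {
      dot <- dot + x[j] * cen[j]
      nc <- nc + cen[j]^2
      nx <- nx + x[j]^2
    }
    scores[cl] <- if (nc == 0 || nx == 0) 0 else dot / (sqrt(nx) * sqrt(nc))
  }
  best <- names(scores)[scores == max(scores)]
  if (length(best) > 1) {
    pr <- table(labels)[best]
    best <- sort(names(pr)[pr == max(pr)])
  }
  best[1]
}

random_vsm_problem <- function() {
  n_feat <- sample(1:10, 1)
  k <- sample(2:4, 1)
  classes <- paste0("C", seq_len(k))
  n <- sample(k:30, 1)
  labels <- c(classes, sample(classes, n - k, replace = TRUE))
  train_idx <- lapply(seq_len(n), function(i) {
    m <- sample(0:n_feat, 1)
    sort(sample.int(n_feat, m))
  })
  list(n_feat = n_feat, labels = labels, train_idx = train_idx)
}
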