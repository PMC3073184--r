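# Nearest-prototype vector space classifier and the majority-class
# baseline. One model per word type; training builds one centroid (the
# unweighted mean of the class's binary vectors) per observed class, and
# prediction assigns the class of the cosine-closest centroid.

#' Cosine similarity of two vectors
#'
#' Defined as 0 when either vector has zero norm, so the value is always a
#' number; for non-negative inputs it lies in `[0, 1]`.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A single number.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v))
    stop("cosine_similarity: dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Train a nearest-prototype vector space model
#'
#' For each class observed in training, the centroid is the arithmetic
#' mean of that class's binary vectors: position `j` holds the fraction of
#' the class's training instances in which feature `j` is active. Class
#' priors are the raw training counts, used only for tie-breaking and the
#' zero-vector fallback.
#'
#' @param vectors List of sorted integer index vectors from [vectorize()].
#' @param labels Character vector of gold classes aligned with `vectors`.
#' @param n_features Size of the vocabulary the vectors index into.
#' @return An object of class `ts_vsm` with `classes` (sorted), a
#'   `centroids` matrix (classes x features), and integer `priors`.
#' @export
train_vsm <- function(vectors, labels, n_features) {
  if (!length(vectors))
    stop("train_vsm: empty training set", call. = FALSE)
  if (length(vectors) != length(labels))
    stop("train_vsm: vectors and labels misaligned", call. = FALSE)
  classes <- sort_c(unique(labels))
  centroids <- matrix(0, nrow = length(classes), ncol = n_features,
                      dimnames = list(classes, NULL))
  priors <- integer(length(classes))
  names(priors) <- classes
  for (cl in classes) {
    idx <- which(labels == cl)
    priors[[cl]] <- length(idx)
    if (n_features > 0L)
      centroids[cl, ] <- tabulate(unlist(vectors[idx], use.names = FALSE),
                                  nbins = n_features) / length(idx)
  }
  structure(list(classes = classes, centroids = centroids, priors = priors,
                 n_features = n_features),
            class = "ts_vsm")
}

# deterministic argmax: highest score, then largest prior, then the
# alphabetically first class (classes are kept sorted)
vsm_pick <- function(scores, classes, priors) {
  cand <- which(scores == max(scores))
  if (length(cand) > 1L) {
    p <- priors[cand]
    cand <- cand[p == max(p)]
  }
  classes[cand[1L]]
}

#' Predict with a vector space model
#'
#' Each instance is assigned the class of the centroid with the highest
#' cosine similarity to its binary vector. Exact score ties — including
#' the all-zero vector, whose similarity to every centroid is 0 — are
#' broken by the larger training prior, then the alphabetically first
#' class; `fallback` flags instances whose vector had no active feature.
#'
#' @param object A `ts_vsm` model.
#' @param newdata List of sorted integer index vectors over the model's
#'   vocabulary.
#' @param ... Unused.
#' @return A data frame with one row per instance: `predicted`, `score`
#'   (cosine to the winning centroid) and `fallback`.
#' @export
predict.ts_vsm <- function(object, newdata, ...) {
  cnorm <- sqrt(rowSums(object$centroids^2))
  k <- length(object$classes)
  predicted <- character(length(newdata))
  top <- double(length(newdata))
  fallback <- logical(length(newdata))
  for (i in seq_along(newdata)) {
    x <- newdata[[i]]
    if (!length(x)) {
      scores <- rep(0, k)
      fallback[i] <- TRUE
    } else {
      dot <- rowSums(object$centroids[, x, drop = FALSE])
      scores <- ifelse(cnorm > 0, dot / (sqrt(length(x)) * cnorm), 0)
    }
    predicted[i] <- vsm_pick(scores, object$classes, object$priors)
    top[i] <- max(scores)
  }
  data.frame(predicted = predicted, score = top, fallback = fallback,
             stringsAsFactors = FALSE)
}

#' @export
print.ts_vsm <- function(x, ...) {
  cat(sprintf("<ts_vsm: %d classes, %d features, %d training instances>\n",
              length(x$classes), x$n_features, sum(x$priors)))
  invisible(x)
}

#' Train the majority-class baseline
#'
#' @param labels Non-empty character vector of training classes.
#' @return An object of class `ts_mc` holding the modal class
#'   (alphabetical tie-break) and the training counts.
#' @export
train_mc <- function(labels) {
  if (!length(labels)) stop("train_mc: empty training set", call. = FALSE)
  counts <- table(labels)
  cls <- sort_c(names(counts)[counts == max(counts)])[1L]
  structure(list(class = cls, counts = counts), class = "ts_mc")
}

#' Predict with the majority-class baseline
#'
#' @param object A `ts_mc` model.
#' @param newdata Either an integer (the number of instances) or a list or
#'   vector whose length is used.
#' @param ... Unused.
#' @return Character vector repeating the modal training class.
#' @export
predict.ts_mc <- function(object, newdata, ...) {
  n <- if (is.numeric(newdata) && length(newdata) == 1L) newdata else length(newdata)
  rep(object$class, n)
}
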