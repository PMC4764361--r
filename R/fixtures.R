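#' Simulate the five-cluster Gaussian testbed
#'
#' Draws a three-dimensional dataset from five multivariate normal
#' distributions arranged as two groups in opposite corners of the data
#' cube: clusters 1-3 near one corner and clusters 4-5 near the opposite
#' corner. With the default unit-variance isotropic noise the nearest pair
#' of cluster centers is 7 noise standard deviations apart, so the clusters
#' are well separated but the two corner groups dominate the large-scale
#' geometry. This is the standard testbed for checking that a topographic
#' projection preserves cluster structure and for exercising interactions.
#'
#' @param centers optional C x p matrix of cluster centers; the default is
#'   the 5 x 3 opposite-corner layout described above.
#' @param sizes per-cluster sample sizes (recycled; default 30).
#' @param sd isotropic noise standard deviation per cluster (recycled;
#'   default 1). Alternatively `covariances` may give one p x p SPD matrix
#'   per cluster.
#' @param covariances optional list of per-cluster covariance matrices.
#' @param seed RNG seed; draws are deterministic given the seed.
#' @return List with `data` (N x p matrix, observations named `obs...`),
#'   `labels` (integer cluster labels) and `spec` (the arguments used).
#' @examples
#' sim <- simulate_clusters(seed = 7)
#' table(sim$labels)
#' @export
simulate_clusters <- function(centers = NULL, sizes = 30L, sd = 1,
                              covariances = NULL, seed = 1L) {
  if (is.null(centers)) {
    centers <- rbind(c(2, 2, 2), c(9, 2, 2), c(2, 9, 2),
                     c(18, 18, 18), c(18, 11, 18))
  }
  centers <- as.matrix(centers)
  C <- nrow(centers); p <- ncol(centers)
  sizes <- rep_len(as.integer(sizes), C)
  if (any(sizes < 1L)) stop("cluster sizes must be positive")
  if (is.null(covariances)) {
    sd <- rep_len(sd, C)
    covariances <- lapply(sd, function(s) diag(s^2, p))
  }
  if (length(covariances) != C) stop("one covariance per cluster required")
  roots <- lapply(covariances, function(S) {
    S <- as.matrix(S)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) stop("covariances must be symmetric positive definite")
    ch
  })
  data <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(C), function(cl) {
      Z <- matrix(stats::rnorm(sizes[cl] * p), sizes[cl], p)
      sweep(Z %*% roots[[cl]], 2L, centers[cl, ], "+")
    }))
  })
  labels <- rep(seq_len(C), sizes)
  dimnames(data) <- list(sprintf("obs%03d", seq_len(nrow(data))),
                         paste0("x", seq_len(p)))
  list(data = data, labels = labels,
       spec = list(centers = centers, sizes = sizes,
                   covariances = covariances, seed = seed))
}

#' Generate a topic-structured synthetic corpus
#'
#' Emulates a small collection of abstracts with planted topic structure:
#' each topic owns a disjoint set of planted terms that its documents use
#' heavily (counts drawn Poisson with mean `lambda_hi`), while every
#' document sprinkles low background counts (Poisson mean `lambda_lo`)
#' over the whole vocabulary. Only the count structure of real text is
#' modeled, not its semantics; the vocabulary consists of synthetic
#' letter-only words that are stable under stemming.
#'
#' @param n_topics number of planted topics (default 4).
#' @param docs_per_topic documents per topic (default 15).
#' @param vocab_per_topic planted terms per topic (default 10).
#' @param background_vocab number of additional background terms
#'   (default 60).
#' @param lambda_hi,lambda_lo Poisson means for planted and background
#'   counts (defaults 8 and 1).
#' @param seed RNG seed.
#' @return List with `documents` (named character vector of space-separated
#'   pseudo-texts), `counts` (terms x documents matrix), `topics` (list of
#'   planted term sets per topic) and `doc_topics` (topic of each
#'   document).
#' @export
synthetic_corpus <- function(n_topics = 4L, docs_per_topic = 15L,
                             vocab_per_topic = 10L, background_vocab = 60L,
                             lambda_hi = 8, lambda_lo = 1, seed = 1L) {
  stopifnot(n_topics >= 1L, docs_per_topic >= 1L, vocab_per_topic >= 1L,
            background_vocab >= 0L, lambda_hi > 0, lambda_lo >= 0)
  n_terms <- n_topics * vocab_per_topic + background_vocab
  vocab <- synthetic_words(n_terms)
  topics <- lapply(seq_len(n_topics), function(t)
    vocab[(t - 1L) * vocab_per_topic + seq_len(vocab_per_topic)])
  doc_topics <- rep(seq_len(n_topics), each = docs_per_topic)
  n_docs <- length(doc_topics)
  counts <- with_seed(seed, {
    m <- matrix(stats::rpois(n_terms * n_docs, lambda_lo), n_terms, n_docs)
    for (d in seq_len(n_docs)) {
      planted <- (doc_topics[d] - 1L) * vocab_per_topic + seq_len(vocab_per_topic)
      m[planted, d] <- stats::rpois(vocab_per_topic, lambda_hi)
    }
    m
  })
  doc_ids <- sprintf("doc%02d", seq_len(n_docs))
  dimnames(counts) <- list(vocab, doc_ids)
  documents <- vapply(seq_len(n_docs), function(d) {
    paste(rep(vocab, counts[, d]), collapse = " ")
  }, character(1))
  names(documents) <- doc_ids
  list(documents = documents, counts = counts, topics = topics,
       doc_topics = doc_topics)
}

# deterministic letter-only pseudo-words (CVCVC) that Porter stemming leaves
# unchanged: no s/e/y/d/g endings, no recognized suffixes
synthetic_words <- function(n) {
  cons <- c("b", "c", "f", "k", "m", "p", "r", "t", "v", "w")
  vows <- c("a", "o", "u")
  words <- character(0)
  for (c1 in cons) for (v1 in vows) for (c2 in cons) for (v2 in vows) for (c3 in cons) {
    words <- c(words, paste0(c1, v1, c2, v2, c3))
    if (length(words) >= n) return(words)
  }
  stop("requested vocabulary too large")
}
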