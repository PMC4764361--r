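#' Tag a latent point with its top manifold terms
#'
#' Maps an arbitrary latent location `r_plus` through the model's basis
#' expansion (including any interaction attractors) to its manifold point
#' `y_plus = W' Phi(r_plus)` and reports the highest-scoring variables.
#' When the model was fitted to ImpI-weighted term frequencies, the result
#' reads as the keywords that characterize that region of the view.
#'
#' @param model a fitted `gtm`.
#' @param r_plus length-2 latent coordinates.
#' @param vocabulary optional character vector naming the p data variables;
#'   defaults to the model's stored variable names.
#' @param m number of terms to report (default 10). Ties are broken
#'   lexicographically.
#' @return List of class `gtm_tag`: `r_plus`, `y_plus` (full p-vector) and
#'   `top_terms` (data frame with columns `term`, `score`, sorted
#'   descending).
#' @export
tag_latent_point <- function(model, r_plus, vocabulary = NULL, m = 10L) {
  r_plus <- as.numeric(r_plus)
  if (length(r_plus) != 2L || any(!is.finite(r_plus)))
    stop("'r_plus' must be 2 finite coordinates")
  if (is.null(vocabulary)) vocabulary <- model$var_names
  p <- ncol(model$W)
  if (is.null(vocabulary)) vocabulary <- paste0("v", seq_len(p))
  if (length(vocabulary) != p)
    stop("'vocabulary' must have one entry per data variable")
  y_plus <- drop(eval_manifold(model, matrix(r_plus, 1L)))
  names(y_plus) <- vocabulary
  ord <- order(-y_plus, vocabulary, method = "radix")
  top <- ord[seq_len(min(m, p))]
  structure(list(r_plus = r_plus, y_plus = y_plus,
                 top_terms = data.frame(term = vocabulary[top],
                                        score = unname(y_plus[top]))),
            class = "gtm_tag")
}

#' @export
print.gtm_tag <- function(x, ...) {
  cat(sprintf("Tag at latent point (%.3f, %.3f):\n", x$r_plus[1L], x$r_plus[2L]))
  print(x$top_terms, row.names = FALSE)
  invisible(x)
}

#' Cluster the view and extract per-cluster keywords
#'
#' Applies k-means to the 2-D projection coordinates, then ranks terms
#' within each cluster by the sum of their ImpI-weighted frequencies over
#' the member documents. The `top_m` list of each cluster is reported after
#' deleting the terms that appear in every cluster's list; those are
#' returned separately as the shared vocabulary.
#'
#' @param coordinates N x 2 matrix of projected document coordinates.
#' @param weighted a `weighted_termdoc` (or terms x documents matrix of
#'   ImpI-weighted frequencies) aligned with the rows of `coordinates`.
#' @param k number of clusters (default 4).
#' @param top_m list length per cluster before shared-term deletion
#'   (default 10).
#' @param seed k-means seed; the run uses Lloyd's algorithm with 10
#'   restarts. If a restart yields an empty cluster the seed is bumped and
#'   the run retried, up to `retries` times.
#' @param retries retry cap for empty clusters.
#' @return List of class `cluster_keywords`: `assignments` (integer
#'   N-vector), `clusters` (list of data frames `term`, `score`),
#'   `shared` (character vector), `centers`.
#' @export
cluster_keywords <- function(coordinates, weighted, k = 4L, top_m = 10L,
                             seed = 1L, retries = 5L) {
  coords <- as.matrix(coordinates)
  vals <- if (inherits(weighted, "weighted_termdoc")) weighted$values else as.matrix(weighted)
  if (ncol(vals) != nrow(coords))
    stop("'weighted' must have one document column per coordinate row")
  if (k < 2L) stop("'k' must be at least 2")
  # cluster in a canonical row order so the result is invariant to the
  # order documents arrive in (the seeded restarts sample row indices)
  canon <- order(coords[, 1L], coords[, 2L], method = "radix")
  km <- NULL
  for (try in seq_len(retries)) {
    km <- with_seed(seed + try - 1L, tryCatch(
      stats::kmeans(coords[canon, , drop = FALSE], centers = k,
                    nstart = 10L, iter.max = 100L, algorithm = "Lloyd"),
      error = function(e) e, warning = function(w) w))
    if (inherits(km, "kmeans") && all(km$size > 0L)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce k non-empty clusters")
  km$cluster <- km$cluster[order(canon)]
  terms <- rownames(vals)
  if (is.null(terms)) terms <- paste0("t", seq_len(nrow(vals)))
  ranked <- lapply(seq_len(k), function(cl) {
    score <- rowSums(vals[, km$cluster == cl, drop = FALSE])
    ord <- order(-score, terms, method = "radix")[seq_len(min(top_m, length(terms)))]
    data.frame(term = terms[ord], score = unname(score[ord]))
  })
  shared <- Reduce(intersect, lapply(ranked, `[[`, "term"))
  clusters <- lapply(ranked, function(df) df[!df$term %in% shared, , drop = FALSE])
  names(clusters) <- LETTERS[seq_len(k)]
  structure(list(assignments = km$cluster, clusters = clusters,
                 shared = shared, centers = km$centers),
            class = "cluster_keywords")
}

#' @export
print.cluster_keywords <- function(x, ...) {
  for (nm in names(x$clusters))
    cat(sprintf("Cluster %s: %s\n", nm,
                paste(x$clusters[[nm]]$term, collapse = ", ")))
  cat("Shared:", paste(x$shared, collapse = ", "), "\n")
  invisible(x)
}

# evaluate an expression under a temporary RNG seed, restoring state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
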