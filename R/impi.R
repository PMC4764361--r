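#' Importance index (ImpI) of terms across documents
#'
#' Scores each term by a Gini-style dispersion of its frequencies across
#' documents: the mean absolute pairwise difference of the term's counts,
#' normalized by its mean frequency,
#' `ImpI_i = sum_jk |f_ij - f_ik| / (2 N^2 mu_i)`.
#' Terms that occur equally often in every document score 0; terms
#' concentrated in a single document score maximally. The score is invariant
#' to rescaling a term's counts.
#'
#' Two denominator dialects are available. `"printed"` uses `2 N^2 mu_i`,
#' under which a single-document term scores `(N-1)/N`; `"corrected"` uses
#' the sample form `2 N (N-1) mu_i`, under which it scores exactly 1 (the
#' usual endpoint of the index's stated [0, 1] range).
#'
#' @param counts terms x documents matrix of nonnegative frequencies
#'   (`TermDocCounts$counts` or any numeric matrix with term rownames).
#' @param dialect `"printed"` (default) or `"corrected"`.
#' @return Object of class `impi`: list with `scores` (named numeric vector,
#'   `NA` for all-zero terms) and `dialect`.
#' @examples
#' f <- rbind(even = c(3, 3, 3, 3), ramp = 0:3)
#' impi_scores(f)$scores  # even = 0, ramp = 5/12
#' @export
impi_scores <- function(counts, dialect = c("printed", "corrected")) {
  dialect <- match.arg(dialect)
  f <- as.matrix(counts)
  if (any(f < 0) || any(!is.finite(f))) stop("counts must be finite and nonnegative")
  N <- ncol(f)
  if (N < 2L) stop("need at least 2 documents")
  denom_n <- if (dialect == "printed") 2 * N^2 else 2 * N * (N - 1)
  scores <- apply(f, 1L, function(fi) {
    mu <- mean(fi)
    if (mu == 0) return(NA_real_)
    sum(abs(outer(fi, fi, "-"))) / (denom_n * mu)
  })
  names(scores) <- rownames(f)
  structure(list(scores = scores, dialect = dialect), class = "impi")
}

#' Select the top-ranked terms by ImpI
#'
#' @param impi an `impi` object (or a named numeric vector of scores).
#' @param n number of terms to keep (default 1000); capped at the vocabulary
#'   size. Ties are broken lexicographically by term.
#' @return Integer vector of term indices in rank order.
#' @export
select_top <- function(impi, n = 1000L) {
  scores <- if (inherits(impi, "impi")) impi$scores else impi
  if (n < 1L) stop("'n' must be at least 1")
  keep <- which(!is.na(scores))
  terms <- names(scores)
  if (is.null(terms)) terms <- as.character(seq_along(scores))
  ord <- unname(keep[order(-scores[keep], terms[keep], method = "radix")])
  ord[seq_len(min(n, length(ord)))]
}

#' ImpI-weighted term frequencies
#'
#' Replaces raw counts by importance-weighted relative frequencies. Under
#' the default `"lift"` reading,
#' `f*_ij = ImpI_i * f_ij * F / (||d_j|| * ||e_i||)`,
#' where `||d_j||` is the column (document) total, `||e_i||` the row (term)
#' total and `F` the grand total: the observed-over-expected lift of the
#' count, scaled by the term's importance. The alternative `"inverse"`
#' reading divides by `F` instead of multiplying. Zero counts stay zero, so
#' the sparsity pattern is preserved.
#'
#' @param counts terms x documents count matrix.
#' @param impi an `impi` object aligned with the rows of `counts`.
#' @param reading `"lift"` (default) or `"inverse"`.
#' @return List of class `weighted_termdoc`: `values` (terms x documents),
#'   `doc_norms`, `term_norms`, `total`, `reading`.
#' @export
weighted_frequencies <- function(counts, impi, reading = c("lift", "inverse")) {
  reading <- match.arg(reading)
  f <- as.matrix(counts)
  scores <- if (inherits(impi, "impi")) impi$scores else impi
  if (length(scores) != nrow(f)) stop("one ImpI score per term row required")
  dnorm <- colSums(f)
  tnorm <- rowSums(f)
  total <- sum(f)
  drop_docs <- dnorm == 0
  if (any(drop_docs)) {
    warning(sprintf("dropping %d document(s) with zero norm", sum(drop_docs)))
    f <- f[, !drop_docs, drop = FALSE]
    dnorm <- dnorm[!drop_docs]
  }
  s <- ifelse(is.na(scores), 0, scores)
  base <- (f * s) / (tnorm * rep(dnorm, each = nrow(f)))
  values <- if (reading == "lift") base * total else base / total
  values[f == 0] <- 0  # 0/0 guards; zero counts stay exactly zero
  dimnames(values) <- dimnames(f)
  structure(list(values = values, doc_norms = dnorm, term_norms = tnorm,
                 total = total, reading = reading),
            class = "weighted_termdoc")
}
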