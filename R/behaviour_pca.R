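#' Convert raw test scores to percentages
#'
#' Each test is rescaled as `100 * raw / max`. Tests without a published
#' maximum (open-ended measures such as tokens produced) use the observed
#' group maximum instead, signalled by `NA` in `max_scores`.
#'
#' @param raw_scores patients x tests numeric matrix or data frame.
#' @param max_scores per-test maximum; a positive number, or `NA` for
#'   "use the group maximum".
#' @return A `behaviour_matrix`: `scores` (patients x tests, 0-100),
#'   `test_names`, `max_used` (the maximum actually applied per test).
#' @export
to_percentages <- function(raw_scores, max_scores) {
  X <- as.matrix(raw_scores)
  if (length(max_scores) != ncol(X))
    stop("need one max score (or NA) per test")
  mx <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    if (is.na(max_scores[j])) {
      mx[j] <- max(X[, j])
      if (mx[j] <= 0)
        stop("degenerate group maximum (<= 0) for test ",
             colnames(X)[j] %||% j)
    } else {
      if (max_scores[j] <= 0)
        stop("non-positive declared maximum for test ", colnames(X)[j] %||% j)
      if (any(X[, j] > max_scores[j] + 1e-12))
        stop("raw score exceeds declared maximum for test ",
             colnames(X)[j] %||% j)
      mx[j] <- max_scores[j]
    }
  }
  pct <- sweep(X, 2, mx, "/") * 100
  structure(list(scores = pct,
                 test_names = colnames(X) %||% paste0("test_", seq_len(ncol(X))),
                 max_used = mx),
            class = "behaviour_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Varimax-rotated principal-component factor analysis of a test battery
#'
#' PCA of the tests x tests correlation matrix. Components with eigenvalue
#' above `retention_eigenvalue` (default 1.0, the Kaiser rule) are retained
#' and varimax-rotated (Kaiser row-normalized). Patient factor scores use
#' the regression method: standardized data times `R^-1 A` with `R` the
#' correlation matrix and `A` the rotated loadings. Factors are ordered by
#' rotated explained variance; each factor's sign is fixed so its
#' largest-|loading| test loads positively.
#'
#' @param behaviour_matrix a `behaviour_matrix` or patients x tests matrix.
#' @param retention_eigenvalue eigenvalue retention threshold (default 1.0).
#' @return A `factor_solution`: `n_factors`, `loadings` (tests x factors),
#'   `eigenvalues`, `scores` (patients x factors), `communalities`,
#'   `variance_explained`.
#' @export
behaviour_factor_analysis <- function(behaviour_matrix,
                                      retention_eigenvalue = 1.0) {
  X <- if (inherits(behaviour_matrix, "behaviour_matrix"))
    behaviour_matrix$scores else as.matrix(behaviour_matrix)
  n <- nrow(X); m <- ncol(X)
  if (n < 10) stop("need at least 10 patients, got ", n)
  if (anyNA(X)) stop("missing scores are not supported")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant test column(s): ", paste(which(sds == 0), collapse = ","))
  Z <- scale(X)
  R <- stats::cor(X)
  eg <- eigen(R, symmetric = TRUE)
  keep <- which(eg$values > retention_eigenvalue)
  if (length(keep) == 0) stop("no component exceeds the retention eigenvalue")
  k <- max(keep)
  A <- eg$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(eg$values[seq_len(k)]), each = m)
  if (k > 1) A <- varimax_rotate(A)$loadings
  expl <- colSums(A^2)
  ord <- order(expl, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  sgn <- vapply(seq_len(k), function(j) {
    s <- sign(A[which.max(abs(A[, j])), j]); if (s == 0) 1 else s
  }, 0)
  A <- sweep(A, 2, sgn, "*")
  Rinv <- tryCatch(solve(R), error = function(e) {
    warning("singular correlation matrix; applying ridge 1e-8")
    solve(R + diag(1e-8, m))
  })
  scores <- Z %*% Rinv %*% A
  rownames(A) <- colnames(X) %||% paste0("test_", seq_len(m))
  colnames(A) <- colnames(scores) <- paste0("factor_", seq_len(k))
  structure(list(n_factors = k, loadings = A, eigenvalues = eg$values,
                 scores = scores, communalities = rowSums(A^2),
                 variance_explained = expl[ord] / m),
            class = "factor_solution")
}

#' @export
print.factor_solution <- function(x, ...) {
  cat(sprintf("<factor solution: %d factors, %.1f%% variance explained>\n",
              x$n_factors, 100 * sum(x$variance_explained)))
  invisible(x)
}

#' Format a loading table with salient loadings flagged
#'
#' Mirrors the conventional published layout in which loadings of absolute
#' value at least `salient` are emphasised.
#'
#' @param solution a `factor_solution`.
#' @param salient salience threshold (default 0.5).
#' @return Character matrix; salient loadings wrapped in `*`.
#' @export
format_loading_table <- function(solution, salient = 0.5) {
  A <- solution$loadings
  out <- matrix(sprintf("%.3f", A), nrow(A), ncol(A),
                dimnames = dimnames(A))
  out[abs(A) >= salient] <- paste0("*", out[abs(A) >= salient], "*")
  out
}

#' Tucker congruence coefficient between two loading vectors
#'
#' `sum(a b) / sqrt(sum(a^2) sum(b^2))`, the standard factor-similarity
#' index.
#'
#' @param a,b numeric vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
tucker_congruence <- function(a, b) {
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}
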