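#' Assemble the patients x voxels lesion matrix
#'
#' Stacks the in-mask voxels of each patient's abnormality map into one row
#' per patient. Column (voxel) means are recorded and subtracted, so `values`
#' is the centered matrix used by all decompositions.
#'
#' @param abnormality_volumes list of abnormality [volume()]s on one grid.
#' @param mask a [brain_mask()] or binary [volume()].
#' @param center subtract column means (default TRUE).
#' @return A `lesion_matrix`: `values` (patients x voxels, centered),
#'   `col_means`, `voxel_index` (linear indices of columns), `affine`,
#'   `grid_shape`, `patient_ids`.
#' @export
assemble_lesion_matrix <- function(abnormality_volumes, mask, center = TRUE) {
  if (is_volume(mask)) mask <- brain_mask(mask)
  stopifnot(inherits(mask, "brain_mask"))
  n <- length(abnormality_volumes)
  if (n < 3) stop("need at least 3 patients, got ", n)
  d <- dim(mask$mask$data)
  X <- matrix(NA_real_, n, mask$n_voxels)
  for (p in seq_len(n)) {
    v <- abnormality_volumes[[p]]
    stopifnot(is_volume(v))
    if (!all(dim(v$data) == d)) stop("grid mismatch for patient ", p)
    X[p, ] <- v$data[mask$index]
  }
  if (!all(is.finite(X))) stop("non-finite values in lesion data")
  mu <- if (center) colMeans(X) else numeric(ncol(X))
  structure(list(values = sweep(X, 2, mu), col_means = mu,
                 voxel_index = mask$index, affine = mask$mask$affine,
                 grid_shape = d,
                 patient_ids = paste0("patient_", seq_len(n))),
            class = "lesion_matrix")
}

#' Rebuild a volume from one lesion-matrix column set
#'
#' @param lesion_matrix a `lesion_matrix`.
#' @param values numeric vector, one value per matrix column.
#' @param tag volume tag for the result.
#' @return A [volume()] with `values` written at the in-mask voxels.
#' @export
matrix_to_volume <- function(lesion_matrix, values, tag = "stat") {
  stopifnot(length(values) == length(lesion_matrix$voxel_index))
  arr <- array(0, lesion_matrix$grid_shape)
  arr[lesion_matrix$voxel_index] <- values
  volume(arr, lesion_matrix$affine, tag = tag)
}

#' Estimate the number of lesion components (MDL / KIC)
#'
#' Eigenvalue-sphericity information criteria on the patients-direction
#' covariance spectrum. For candidate order q the log-likelihood term is
#' `N (p - q) log(a/g)` with `a` and `g` the arithmetic and geometric means
#' of the trailing eigenvalues, N the number of in-mask voxels and p the
#' number of non-null spectrum points (patients minus the one rank lost to
#' centering). With `m(q) = q (2p - q) + 1` free parameters the criteria are
#' `MDL(q) = N (p-q) log(a/g) + m(q)/2 log N` and
#' `KIC(q) = 2 N (p-q) log(a/g) + 3 m(q)`; the estimate is the arg-min over
#' q, ties broken toward the smaller order.
#'
#' @param lesion_matrix a `lesion_matrix` (or bare numeric matrix, rows =
#'   patients).
#' @return An `order_estimate`: `k_mdl`, `k_kic`, `eigenvalues`, and a
#'   `curves` data frame (q, mdl, kic).
#' @export
estimate_order <- function(lesion_matrix) {
  X <- if (inherits(lesion_matrix, "lesion_matrix")) lesion_matrix$values
       else as.matrix(lesion_matrix)
  n <- nrow(X); N <- ncol(X)
  if (n < 4) stop("need at least 4 patients for order estimation")
  ev <- eigen(tcrossprod(X) / N, symmetric = TRUE, only.values = TRUE)$values
  p <- n - 1L                       # centering removes one rank
  lam <- pmax(ev[seq_len(p)], 0)
  if (diff(range(lam)) <= 1e-12 * max(lam, 1e-300)) {
    warning("degenerate (flat) eigenvalue spectrum; returning order 0")
    return(structure(list(k_mdl = 0L, k_kic = 0L, eigenvalues = lam,
                          curves = data.frame(q = integer(), mdl = numeric(),
                                              kic = numeric())),
                     class = "order_estimate"))
  }
  eps <- 1e-12 * max(lam)
  lam <- pmax(lam, eps)
  qs <- seq_len(p - 1L)
  mdl <- kic <- numeric(length(qs))
  for (i in seq_along(qs)) {
    q <- qs[i]
    tail_lam <- lam[(q + 1L):p]
    a <- mean(tail_lam)
    g <- exp(mean(log(tail_lam)))
    ll <- N * (p - q) * log(a / g)
    m <- q * (2 * p - q) + 1
    mdl[i] <- ll + m / 2 * log(N)
    kic[i] <- 2 * ll + 3 * m
  }
  structure(list(k_mdl = qs[which.min(mdl)], k_kic = qs[which.min(kic)],
                 eigenvalues = lam,
                 curves = data.frame(q = qs, mdl = mdl, kic = kic)),
            class = "order_estimate")
}

#' @export
print.order_estimate <- function(x, ...) {
  cat(sprintf("<order estimate: MDL %d, KIC %d (%d spectrum points)>\n",
              x$k_mdl, x$k_kic, length(x$eigenvalues)))
  invisible(x)
}

#' Varimax simplicity criterion
#'
#' The quantity varimax maximizes: the summed variance of squared loadings
#' per column, `sum_j [ mean(a_j^4) - mean(a_j^2)^2 ]`, optionally after
#' Kaiser row-normalization.
#'
#' @param loadings numeric matrix (variables x components).
#' @param normalize apply Kaiser row-normalization first (default TRUE).
#' @return Scalar criterion value.
#' @export
varimax_criterion <- function(loadings, normalize = TRUE) {
  A <- as.matrix(loadings)
  if (normalize) {
    h <- sqrt(rowSums(A^2))
    h[h == 0] <- 1
    A <- A / h
  }
  sum(apply(A^2, 2, function(c2) mean(c2^2) - mean(c2)^2))
}

#' Varimax rotation of a loading matrix
#'
#' Kaiser-normalized varimax with a tight convergence tolerance; the
#' rotation used by all decompositions in the package.
#'
#' @param loadings variables x components matrix (k >= 2).
#' @return List with `loadings` (rotated) and `rotation` (k x k orthogonal).
#' @export
varimax_rotate <- function(loadings) {
  A <- as.matrix(loadings)
  stopifnot(ncol(A) >= 2)
  rot <- stats::varimax(A, normalize = TRUE, eps = 1e-12)
  R <- unclass(rot$rotmat)
  list(loadings = A %*% R, rotation = R)
}

#' Varimax-rotated PCA of the lesion matrix
#'
#' Extracts the top-k principal directions of the centered patients x voxels
#' matrix (via the patients-side Gram matrix, since voxels far outnumber
#' patients) and applies a varimax rotation with Kaiser row-normalization to
#' the voxels x k coefficient matrix. Loadings keep orthonormal columns (the
#' rotated principal-axis coefficients), so `scores %*% t(loadings)` is the
#' rank-k reconstruction of the centered matrix. Patient component scores
#' are the centered matrix projected on the rotated loadings. Components are
#' ordered by post-rotation explained variance, and each component's sign is
#' fixed so its largest-|loading| voxel is positive.
#'
#' @param lesion_matrix a `lesion_matrix`.
#' @param k number of components (1 <= k <= min(n_patients - 1, n_voxels)).
#' @param rotate apply varimax (default TRUE; FALSE gives the unrotated PCA).
#' @return A `component_solution`: `k`, `eigenvalues` (full spectrum),
#'   `loadings` (voxels x k), `rotation` (k x k), `scores` (patients x k),
#'   `variance_explained` (fraction of total variance per component).
#' @export
pca_varimax <- function(lesion_matrix, k, rotate = TRUE) {
  X <- lesion_matrix$values
  n <- nrow(X); N <- ncol(X)
  kmax <- min(n - 1L, N)
  if (k < 1 || k > kmax) stop("k must be in 1..", kmax, ", got ", k)
  G <- tcrossprod(X)                     # n x n
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0) / (n - 1)    # eigenvalues of the voxel covariance
  dvals <- sqrt(pmax(eg$values[seq_len(k)], .Machine$double.eps))
  A <- crossprod(X, eg$vectors[, seq_len(k), drop = FALSE]) /
    rep(dvals, each = N)                 # voxels x k, orthonormal columns
  if (rotate && k > 1) {
    rot <- varimax_rotate(A)
    A <- rot$loadings
    R <- rot$rotation
  } else {
    R <- diag(k)
  }
  expl <- colSums((X %*% A)^2) / (n - 1) # per-component variance after rotation
  ord <- order(expl, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  R <- R[, ord, drop = FALSE]
  # sign convention applies to loadings and scores; `rotation` stays the pure
  # varimax rotation (so k = 1 reports the identity)
  sgn <- vapply(seq_len(k), function(j) {
    s <- sign(A[which.max(abs(A[, j])), j]); if (s == 0) 1 else s
  }, 0)
  A <- sweep(A, 2, sgn, "*")
  scores <- X %*% A
  colnames(A) <- colnames(scores) <- paste0("comp_", seq_len(k))
  structure(list(k = as.integer(k), eigenvalues = lam, loadings = A,
                 rotation = R, scores = scores,
                 variance_explained = expl[ord] / sum(lam)),
            class = "component_solution")
}

#' @export
print.component_solution <- function(x, ...) {
  cat(sprintf("<component solution: k = %d, %.1f%% variance explained>\n",
              x$k, 100 * sum(x$variance_explained)))
  invisible(x)
}

#' Project component loadings back into brain space as z maps
#'
#' Each component's voxel loadings are standardized across in-mask voxels
#' (mean 0, SD 1) and written into the volume grid; the z map is thresholded
#' two-sided at `|z| > z_cut` and clusters with `min_cluster_voxels` or fewer
#' voxels are removed.
#'
#' @param solution a `component_solution`.
#' @param lesion_matrix the `lesion_matrix` the solution was fitted on
#'   (provides the voxel index map and affine).
#' @param z_cut two-sided z threshold (default 3.29, i.e. p < 0.001).
#' @param min_cluster_voxels cluster-extent cut-off; surviving clusters have
#'   strictly more voxels than this (default 500).
#' @param connectivity neighbourhood (default 26).
#' @return List (one element per component) of lists with `z` (z [volume()]),
#'   `mask` (binary [volume()]), `clusters` (cluster table).
#' @export
component_maps <- function(solution, lesion_matrix, z_cut = 3.29,
                           min_cluster_voxels = 500, connectivity = 26) {
  stopifnot(inherits(solution, "component_solution"))
  lapply(seq_len(solution$k), function(j) {
    a <- solution$loadings[, j]
    s <- stats::sd(a)
    if (!is.finite(s) || s == 0)
      stop("component ", j, " has constant loadings (zero SD)")
    z <- (a - mean(a)) / s
    zvol <- matrix_to_volume(lesion_matrix, z, tag = "z")
    ec <- extract_clusters(zvol, z_cut,
                           min_cluster_voxels = min_cluster_voxels + 1L,
                           connectivity = connectivity, two_sided = TRUE)
    list(z = zvol, mask = ec$mask, clusters = ec$clusters)
  })
}

#' Component-order stability under patient subsampling
#'
#' Repeatedly subsamples the cohort without replacement at each requested
#' sample size, re-estimates the MDL component order on every subsample, and
#' reports the distribution and median per size.
#'
#' @param lesion_matrix a `lesion_matrix` (uncentered values are re-centered
#'   within each subsample).
#' @param sample_sizes vector of subsample sizes (sizes < 4 are skipped with
#'   a warning).
#' @param reps subsamples per size (default 100).
#' @param seed RNG seed.
#' @return A data frame (sample_size, rep, k_mdl) with attribute `medians`
#'   (named vector of per-size medians).
#' @export
stability_analysis <- function(lesion_matrix, sample_sizes, reps = 100,
                               seed = 1) {
  X0 <- sweep(lesion_matrix$values, 2, -lesion_matrix$col_means)  # uncenter
  n <- nrow(X0)
  if (max(sample_sizes) > n)
    stop("sample size exceeds available patients (", n, ")")
  ok <- sample_sizes >= 4
  if (!all(ok)) warning("skipping sample sizes < 4: ",
                        paste(sample_sizes[!ok], collapse = ","))
  sample_sizes <- sample_sizes[ok]
  set.seed(seed)
  rows <- list()
  for (s in sample_sizes) {
    for (r in seq_len(reps)) {
      sub <- X0[sample.int(n, s), , drop = FALSE]
      sub <- sweep(sub, 2, colMeans(sub))
      rows[[length(rows) + 1L]] <-
        data.frame(sample_size = s, rep = r, k_mdl = estimate_order(sub)$k_mdl)
    }
  }
  out <- do.call(rbind, rows)
  med <- tapply(out$k_mdl, out$sample_size, stats::median)
  attr(out, "medians") <- med
  out
}
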