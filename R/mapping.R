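#' Lesion-symptom mapping configuration
#'
#' Thresholds of the three mapping procedures: voxel-wise p threshold and
#' cluster-level alpha of the permutation-corrected VBCM, the Bonferroni
#' family alpha of the component-factor correlation screen, the entry /
#' removal p-values of stepwise regression, and the z / extent thresholds of
#' the regression back-projection maps.
#'
#' @param voxel_p voxel-level two-sided p threshold (default 0.001).
#' @param cluster_alpha cluster-level alpha of the permutation correction
#'   (default 0.01).
#' @param n_permutations permutations for the max-cluster-size null
#'   (default 1000, minimum 100).
#' @param bonferroni_family_alpha family-wise alpha of the correlation
#'   screen (default 0.05).
#' @param stepwise_p_enter,stepwise_p_remove stepwise entry/removal p-values
#'   (defaults 0.05 / 0.10; entry must not exceed removal).
#' @param regression_map_z_cut two-sided z cut of back-projected maps
#'   (default 3.29).
#' @param regression_map_min_cluster extent cut-off of back-projected maps:
#'   clusters must exceed this many voxels (default 200).
#' @param seed RNG seed for the permutation null.
#' @return A `mapping_config` list.
#' @export
mapping_config <- function(voxel_p = 0.001, cluster_alpha = 0.01,
                           n_permutations = 1000,
                           bonferroni_family_alpha = 0.05,
                           stepwise_p_enter = 0.05, stepwise_p_remove = 0.10,
                           regression_map_z_cut = 3.29,
                           regression_map_min_cluster = 200, seed = 1) {
  stopifnot(voxel_p > 0, voxel_p < 1, cluster_alpha > 0, cluster_alpha < 1,
            bonferroni_family_alpha > 0, bonferroni_family_alpha < 1,
            stepwise_p_enter > 0, stepwise_p_remove < 1,
            stepwise_p_enter <= stepwise_p_remove, n_permutations >= 100)
  structure(list(voxel_p = voxel_p, cluster_alpha = cluster_alpha,
                 n_permutations = as.integer(n_permutations),
                 bonferroni_family_alpha = bonferroni_family_alpha,
                 stepwise_p_enter = stepwise_p_enter,
                 stepwise_p_remove = stepwise_p_remove,
                 regression_map_z_cut = regression_map_z_cut,
                 regression_map_min_cluster = as.integer(regression_map_min_cluster),
                 seed = as.integer(seed)),
            class = "mapping_config")
}

# t statistics of every factor at every voxel for a joint linear model of
# abnormality on all factor scores; returns f x V matrix
vbcm_tstats <- function(Y, design, inv_xtx) {
  txy <- crossprod(design, Y)                 # (f+1) x V
  beta <- inv_xtx %*% txy
  df <- nrow(Y) - ncol(design)
  ssres <- pmax(colSums(Y^2) - colSums(beta * txy), 0)
  sigma2 <- ssres / df
  se <- sqrt(outer(diag(inv_xtx), sigma2))
  t <- beta / pmax(se, .Machine$double.xmin)
  t[-1, , drop = FALSE]                       # drop intercept row
}

#' Voxel-based correlational mapping with permutation cluster correction
#'
#' At every in-mask voxel the abnormality values are regressed jointly on
#' all behavioural factor scores; each factor's t statistic is converted to
#' a partial correlation `r = t / sqrt(t^2 + df)`. Voxels significant at the
#' two-sided voxel threshold are clustered, and clusters are retained when
#' their size exceeds the `(1 - cluster_alpha)` quantile of the maximum
#' null cluster size obtained by jointly permuting the rows of the factor
#' score matrix.
#'
#' @param lesion_matrix a `lesion_matrix`.
#' @param factor_scores patients x factors matrix (near-orthogonal; a
#'   warning is issued when any pairwise |r| exceeds 0.3).
#' @param config a [mapping_config()].
#' @param connectivity cluster neighbourhood (default 26).
#' @return List (one element per factor) of mapping results: `statistic`
#'   (partial-r [volume()]), `p` (p [volume()]), `mask` (significant binary
#'   [volume()]), `clusters` (cluster table of surviving clusters),
#'   `cluster_size_crit`, `method = "vbcm"`.
#' @export
vbcm <- function(lesion_matrix, factor_scores, config = mapping_config(),
                 connectivity = 26) {
  Y <- lesion_matrix$values                    # patients x voxels
  F0 <- as.matrix(factor_scores)
  n <- nrow(Y)
  stopifnot(nrow(F0) == n)
  if (n < 10) stop("need at least 10 patients for VBCM")
  if (any(apply(F0, 2, stats::sd) == 0)) stop("zero-variance factor score")
  if (ncol(F0) > 1) {
    cc <- stats::cor(F0)
    if (max(abs(cc[upper.tri(cc)])) > 0.3)
      warning("factor scores are not near-orthogonal (max |r| > 0.3)")
  }
  design <- cbind(1, F0)
  if (qr(design)$rank < ncol(design)) stop("rank-deficient design")
  inv_xtx <- solve(crossprod(design))
  nf <- ncol(F0)
  df <- n - ncol(design)
  tcrit <- stats::qt(1 - config$voxel_p / 2, df)
  tobs <- vbcm_tstats(Y, design, inv_xtx)
  # permutation null of the maximum suprathreshold cluster size, per factor
  set.seed(config$seed)
  null_max <- matrix(0L, config$n_permutations, nf)
  d <- lesion_matrix$grid_shape
  for (b in seq_len(config$n_permutations)) {
    Fp <- F0[sample.int(n), , drop = FALSE]
    tp <- vbcm_tstats(Y, cbind(1, Fp), inv_xtx)
    for (j in seq_len(nf)) {
      sup <- abs(tp[j, ]) > tcrit
      if (!any(sup)) next
      arr <- array(FALSE, d)
      arr[lesion_matrix$voxel_index[sup]] <- TRUE
      lab <- label_components(arr, connectivity)
      null_max[b, j] <- max(tabulate(lab[lab > 0L]))
    }
  }
  lapply(seq_len(nf), function(j) {
    t_j <- tobs[j, ]
    r_j <- t_j / sqrt(t_j^2 + df)
    p_j <- 2 * stats::pt(-abs(t_j), df)
    crit <- stats::quantile(null_max[, j], 1 - config$cluster_alpha, type = 1,
                            names = FALSE)
    sup <- abs(t_j) > tcrit
    arr <- array(FALSE, d)
    arr[lesion_matrix$voxel_index[sup]] <- TRUE
    lab <- label_components(arr, connectivity)
    keep_mask <- array(FALSE, d)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
      keep <- which(sizes > crit)
      if (length(keep)) keep_mask[lab %in% keep] <- TRUE
    }
    rvol <- matrix_to_volume(lesion_matrix, r_j, tag = "stat")
    tab <- extract_clusters(
      volume(array(abs(rvol$data) * keep_mask, d), lesion_matrix$affine,
             tag = "stat"),
      0, min_cluster_voxels = 1, connectivity = connectivity)$clusters
    list(statistic = rvol,
         p = matrix_to_volume(lesion_matrix, p_j, tag = "stat"),
         mask = volume(array(as.numeric(keep_mask), d),
                       lesion_matrix$affine, tag = "binary"),
         clusters = tab, cluster_size_crit = crit, method = "vbcm")
  })
}

#' Pearson screen of lesion components against behavioural factors
#'
#' Every component-factor pair is tested with a two-sided Pearson
#' correlation; significance is Bonferroni-controlled at
#' `family_alpha / (n_components * n_factors)`.
#'
#' @param component_scores patients x components matrix.
#' @param factor_scores patients x factors matrix.
#' @param config a [mapping_config()].
#' @return Data frame (component, factor, r, p, significant) with attribute
#'   `per_test_alpha`.
#' @export
component_behaviour_correlations <- function(component_scores, factor_scores,
                                             config = mapping_config()) {
  C <- as.matrix(component_scores); F0 <- as.matrix(factor_scores)
  if (nrow(C) != nrow(F0)) stop("patient counts differ")
  if (any(apply(C, 2, stats::sd) == 0) || any(apply(F0, 2, stats::sd) == 0))
    stop("constant column in scores")
  n <- nrow(C)
  r <- stats::cor(C, F0)
  t <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), n - 2)
  alpha <- config$bonferroni_family_alpha / (ncol(C) * ncol(F0))
  out <- data.frame(
    component = rep(colnames(C) %||% paste0("comp_", seq_len(ncol(C))),
                    times = ncol(F0)),
    factor = rep(colnames(F0) %||% paste0("factor_", seq_len(ncol(F0))),
                 each = ncol(C)),
    r = as.numeric(r), p = as.numeric(p),
    significant = as.numeric(p) < alpha)
  attr(out, "per_test_alpha") <- alpha
  out
}

fit_ols <- function(y, X) {
  Xd <- cbind(1, X)
  fit <- stats::lm.fit(Xd, y)
  sse <- sum(fit$residuals^2)
  list(coef = fit$coefficients, sse = sse, df = length(y) - ncol(Xd))
}

# two-sided p of predictor j's coefficient within the model X
coef_p_value <- function(y, X, j) {
  Xd <- cbind(1, X)
  qrd <- qr(Xd)
  beta <- qr.coef(qrd, y)
  res <- y - Xd %*% beta
  df <- length(y) - ncol(Xd)
  if (df <= 0) return(NA_real_)
  sigma2 <- sum(res^2) / df
  xtxinv <- chol2inv(qr.R(qrd))
  se <- sqrt(sigma2 * diag(xtxinv))
  t <- beta / se
  2 * stats::pt(-abs(t[j + 1]), df)
}

#' Stepwise regression of a behavioural factor on lesion component scores
#'
#' Classical forward-entry / backward-removal stepwise selection on
#' partial-F p-values: at each cycle the candidate with the smallest
#' entry p is added if `p <= p_enter`, then any included predictor whose
#' p within the current model is `>= p_remove` is dropped (worst first),
#' iterated to a fixed point. An empty model (no candidate meets entry)
#' is a valid result.
#'
#' @param factor_scores numeric response vector (one behavioural factor) or
#'   single-column matrix.
#' @param component_scores patients x components candidate matrix.
#' @param config a [mapping_config()].
#' @return A `stepwise_model`: `selected` (column indices in entry order),
#'   `betas` (standardized), `coefficients` (raw, with intercept),
#'   `f_statistic`, `df`, `adj_r_squared`, `steps` (log data frame).
#' @export
stepwise_regression <- function(factor_scores, component_scores,
                                config = mapping_config()) {
  y <- as.numeric(as.matrix(factor_scores)[, 1])
  X <- as.matrix(component_scores)
  n <- length(y)
  steps <- list()
  selected <- integer(0)
  repeat {
    changed <- FALSE
    cand <- setdiff(seq_len(ncol(X)), selected)
    if (length(cand) && n >= length(selected) + 3) {
      pv <- vapply(cand, function(j) {
        Xt <- X[, c(selected, j), drop = FALSE]
        coef_p_value(y, Xt, ncol(Xt))
      }, 0)
      best <- which.min(pv)
      if (is.finite(pv[best]) && pv[best] <= config$stepwise_p_enter) {
        selected <- c(selected, cand[best])
        steps[[length(steps) + 1L]] <-
          data.frame(action = "enter", variable = cand[best], p = pv[best])
        changed <- TRUE
      }
    }
    if (length(selected)) {
      pin <- vapply(seq_along(selected), function(i)
        coef_p_value(y, X[, selected, drop = FALSE], i), 0)
      worst <- which.max(pin)
      if (pin[worst] >= config$stepwise_p_remove) {
        steps[[length(steps) + 1L]] <-
          data.frame(action = "remove", variable = selected[worst],
                     p = pin[worst])
        selected <- selected[-worst]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  log_df <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(), variable = integer(), p = numeric())
  if (length(selected) == 0) {
    return(structure(list(selected = integer(0), betas = numeric(0),
                          coefficients = c(intercept = mean(y)),
                          f_statistic = NA_real_, df = c(0, n - 1),
                          adj_r_squared = NA_real_, steps = log_df),
                     class = "stepwise_model"))
  }
  Xs <- X[, selected, drop = FALSE]
  fit <- fit_ols(y, Xs)
  k <- length(selected)
  sst <- sum((y - mean(y))^2)
  r2 <- 1 - fit$sse / sst
  fstat <- (r2 / k) / ((1 - r2) / fit$df)
  betas <- fit$coef[-1] * apply(Xs, 2, stats::sd) / stats::sd(y)
  names(betas) <- colnames(X)[selected] %||% paste0("comp_", selected)
  structure(list(selected = selected, betas = betas,
                 coefficients = fit$coef, f_statistic = fstat,
                 df = c(k, fit$df),
                 adj_r_squared = 1 - (1 - r2) * (n - 1) / fit$df,
                 steps = log_df),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("<stepwise model: empty (no predictor met entry)>\n")
  } else {
    cat(sprintf("<stepwise model: %s; F(%d,%d) = %.3f, adj R^2 = %.3f>\n",
                paste(names(x$betas), collapse = " + "),
                x$df[1], x$df[2], x$f_statistic, x$adj_r_squared))
  }
  invisible(x)
}

#' Back-project a stepwise model onto the brain
#'
#' The voxel map is the beta-weighted sum of the selected components'
#' loading maps, standardized to z across in-mask voxels, thresholded
#' two-sided at the configured z cut, with clusters at or below the extent
#' cut-off removed.
#'
#' @param component_solution a `component_solution`.
#' @param stepwise_model a non-empty `stepwise_model`.
#' @param lesion_matrix the `lesion_matrix` behind the solution.
#' @param config a [mapping_config()].
#' @param connectivity neighbourhood (default 26).
#' @return Mapping result list: `statistic` (z [volume()]), `mask`,
#'   `clusters`, `method = "pca-regression"`.
#' @export
regression_component_map <- function(component_solution, stepwise_model,
                                     lesion_matrix,
                                     config = mapping_config(),
                                     connectivity = 26) {
  if (length(stepwise_model$selected) == 0)
    stop("stepwise model is empty; nothing to map")
  A <- component_solution$loadings[, stepwise_model$selected, drop = FALSE]
  map <- as.numeric(A %*% stepwise_model$betas)
  s <- stats::sd(map)
  if (s == 0) stop("degenerate (constant) back-projection map")
  z <- (map - mean(map)) / s
  zvol <- matrix_to_volume(lesion_matrix, z, tag = "z")
  ec <- extract_clusters(zvol, config$regression_map_z_cut,
                         min_cluster_voxels = config$regression_map_min_cluster + 1L,
                         connectivity = connectivity, two_sided = TRUE)
  list(statistic = zvol, mask = ec$mask, clusters = ec$clusters,
       method = "pca-regression")
}
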