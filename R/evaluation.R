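#' Benjamini-Hochberg step-up significance flags
#'
#' Standard step-up rule: with sorted p-values, find the largest rank k with
#' `p_(k) <= k q / m`; all hypotheses of rank <= k are flagged.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @param q FDR level.
#' @return Logical vector of flags.
#' @export
bh_fdr <- function(p_values, q) {
  stopifnot(all(p_values >= 0 & p_values <= 1), q > 0, q < 1)
  m <- length(p_values)
  o <- order(p_values)
  ok <- p_values[o] <= q * seq_len(m) / m
  flags <- logical(m)
  if (any(ok)) flags[o[seq_len(max(which(ok)))]] <- TRUE
  flags
}

# two-sided Fisher exact p for all voxels at once: with n patients, K with a
# deficit, and per voxel n1 damaged / a damaged-with-deficit, p is the sum of
# hypergeometric point masses not exceeding the observed one (the fisher.test
# convention, with its relative tolerance)
fisher_p_lookup <- function(n, K) {
  P <- matrix(NA_real_, n + 1L, n + 1L)   # [n1 + 1, a + 1]
  for (n1 in 0:n) {
    lo <- max(0L, n1 - (n - K)); hi <- min(n1, K)
    dens <- stats::dhyper(lo:hi, K, n - K, n1)
    for (a in lo:hi)
      P[n1 + 1L, a + 1L] <- sum(dens[dens <= dens[a - lo + 1L] * (1 + 1e-7)])
  }
  pmin(P, 1)
}

#' Mass-univariate Fisher-exact lesion-deficit mapping with FDR control
#'
#' At every voxel the 2x2 table of damaged-by-deficit patient counts is
#' tested with a two-sided Fisher exact test; the map of p-values is
#' thresholded by Benjamini-Hochberg FDR at `fdr_q` (default 0.01).
#'
#' @param binary_lesion_matrix a `lesion_matrix` built from binary lesion
#'   masks (`center = FALSE`, or centered - the column means are added back),
#'   or a bare patients x voxels 0/1 matrix (then supply `mask_index`,
#'   `affine`, `grid_shape` via a `lesion_matrix`).
#' @param deficit_labels 0/1 vector, one per patient; both classes must be
#'   present.
#' @param fdr_q FDR level (default 0.01).
#' @return Mapping result: `p` (p [volume()]), `mask` (significant binary
#'   [volume()]), `p_values`, `significant` (flags over matrix columns),
#'   `clusters`, `method = "fisher-fdr"`.
#' @export
fisher_mass_univariate <- function(binary_lesion_matrix, deficit_labels,
                                   fdr_q = 0.01) {
  lm <- binary_lesion_matrix
  stopifnot(inherits(lm, "lesion_matrix"))
  L <- sweep(lm$values, 2, lm$col_means, "+")
  if (max(abs(L - round(L))) > 1e-8)
    stop("lesion matrix is not binary")
  L <- round(L)
  y <- as.integer(deficit_labels)
  n <- nrow(L)
  stopifnot(length(y) == n, all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("deficit labels are single-class")
  K <- sum(y)
  n1 <- colSums(L)
  a <- as.numeric(y %*% L)
  P <- fisher_p_lookup(n, K)
  p <- P[cbind(n1 + 1L, a + 1L)]
  sig <- bh_fdr(p, fdr_q)
  mask <- matrix_to_volume(lm, as.numeric(sig), tag = "binary")
  clusters <- extract_clusters(mask, 0.5)$clusters
  list(p = matrix_to_volume(lm, p, tag = "stat"), mask = mask,
       p_values = p, significant = sig, clusters = clusters,
       method = "fisher-fdr")
}

#' Welch's unequal-variance t-test
#'
#' @param sample_a,sample_b numeric vectors (each of length >= 2).
#' @return List with `t`, `df` (Welch-Satterthwaite), `p` (two-sided).
#' @export
welch_ttest <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0)
    stop("zero variance in both samples")
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Sparse CCA configuration
#'
#' @param sparseness fraction of voxel weights allowed nonzero (default
#'   0.045, the fixed value used in prior lesion-mapping work).
#' @param cv_lower,cv_upper cross-validation search bounds (default
#'   0.005-0.9).
#' @param cv_folds folds (default 5).
#' @param cv_grid_length log-spaced grid points across the bounds.
#' @param max_iter,tol alternating-update convergence controls.
#' @param seed RNG seed (fold assignment).
#' @return A `sccan_config` list.
#' @export
sccan_config <- function(sparseness = 0.045, cv_lower = 0.005, cv_upper = 0.9,
                         cv_folds = 5, cv_grid_length = 10, max_iter = 100,
                         tol = 1e-6, seed = 1) {
  stopifnot(sparseness > 0, sparseness <= 1, cv_lower > 0, cv_upper <= 1,
            cv_lower < cv_upper, cv_folds >= 2)
  structure(list(sparseness = sparseness, cv_lower = cv_lower,
                 cv_upper = cv_upper, cv_folds = as.integer(cv_folds),
                 cv_grid_length = as.integer(cv_grid_length),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "sccan_config")
}

scca_weights <- function(Xc, yc, sparseness, max_iter, tol) {
  # rank-1 penalized decomposition; the behavioural view is one-dimensional,
  # so its weight reduces to a sign and the voxel update is
  # v = normalize(hard_threshold(X' y w)), alternated with w = sign(y' X v)
  V <- ncol(Xc)
  m <- max(1L, ceiling(sparseness * V))
  shrink <- function(v) {
    if (m < V && any(v != 0)) {
      cut <- sort(abs(v), decreasing = TRUE)[m]
      v[abs(v) < cut] <- 0
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) v / nv else v
  }
  w <- 1
  v <- shrink(as.numeric(crossprod(Xc, yc * w)))
  if (all(v == 0)) return(v)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w_new <- sign(sum(yc * (Xc %*% v)))
    if (w_new == 0) w_new <- 1
    v_new <- shrink(as.numeric(crossprod(Xc, yc * w_new)))
    delta <- sqrt(sum((v_new - v)^2))
    v <- v_new; w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("sparse CCA did not converge; returning last iterate")
  v
}

#' Sparse canonical correlation between lesions and a behavioural label
#'
#' Rank-1 penalized decomposition between the voxel matrix and the label
#' vector: alternating normalized updates of the voxel weight vector with
#' hard thresholding that retains the top `ceiling(sparseness * n_voxels)`
#' absolute weights. The significant mask is the nonzero-weight set. In CV
#' mode the sparseness is chosen on a log-spaced grid by the mean held-out
#' correlation between projected lesion scores and labels.
#'
#' @param lesion_matrix a `lesion_matrix` (binary or continuous).
#' @param deficit_labels numeric (or 0/1) vector, non-constant.
#' @param config a [sccan_config()].
#' @param cv select sparseness by cross-validation instead of the fixed
#'   value (default FALSE).
#' @return List: `weights`, `mask` (binary [volume()]), `cancor`,
#'   `sparseness` (value used), and in CV mode `cv_table`.
#' @export
sparse_cca <- function(lesion_matrix, deficit_labels,
                       config = sccan_config(), cv = FALSE) {
  lm <- lesion_matrix
  stopifnot(inherits(lm, "lesion_matrix"))
  y <- as.numeric(deficit_labels)
  if (stats::sd(y) == 0) stop("deficit labels are constant")
  Xc <- lm$values                       # column-centered
  yc <- y - mean(y)
  cv_table <- NULL
  s_use <- config$sparseness
  if (cv) {
    grid <- exp(seq(log(config$cv_lower), log(config$cv_upper),
                    length.out = config$cv_grid_length))
    set.seed(config$seed)
    fold <- sample(rep_len(seq_len(config$cv_folds), nrow(Xc)))
    perf <- vapply(grid, function(s) {
      cors <- vapply(seq_len(config$cv_folds), function(f) {
        tr <- fold != f
        if (stats::sd(y[!tr]) == 0 || stats::sd(y[tr]) == 0) return(NA_real_)
        Xtr <- sweep(Xc[tr, , drop = FALSE], 2,
                     colMeans(Xc[tr, , drop = FALSE]))
        v <- scca_weights(Xtr, y[tr] - mean(y[tr]), s,
                          config$max_iter, config$tol)
        proj <- Xc[!tr, , drop = FALSE] %*% v
        if (stats::sd(proj) == 0) return(NA_real_)
        stats::cor(proj, y[!tr])
      }, 0)
      mean(cors, na.rm = TRUE)
    }, 0)
    cv_table <- data.frame(sparseness = grid, mean_heldout_cor = perf)
    s_use <- grid[which.max(perf)]
  }
  v <- scca_weights(Xc, yc, s_use, config$max_iter, config$tol)
  proj <- as.numeric(Xc %*% v)
  cancor <- if (stats::sd(proj) > 0) stats::cor(proj, y) else 0
  list(weights = v,
       mask = matrix_to_volume(lm, as.numeric(v != 0), tag = "binary"),
       cancor = cancor, sparseness = s_use, cv_table = cv_table)
}

#' Ground-truth simulation specification
#'
#' Parameters of the simulated critical substrate and its deficit rule: a
#' region counts as damaged in a patient when at least `damage_fraction` of
#' it is lesioned, and damaged patients show a deficit with probability
#' `deficit_prob`. Voxel-level truths are deterministic by default (deficit
#' if and only if the voxel is damaged). Truths with `min_damaged_patients`
#' or fewer damaged patients are ineligible (strictly more are required).
#'
#' @param damage_fraction region fraction that must be lesioned (default 0.2).
#' @param deficit_prob deficit probability among damaged (default 0.9).
#' @param min_damaged_patients eligibility cut-off, strict (default 3).
#' @param voxel_deterministic voxel-kind truths use deficit == damaged
#'   (default TRUE); FALSE applies `deficit_prob` there too.
#' @param n_truths optional cap on the number of voxel truths (subsampled).
#' @param label_draws independent deficit-label simulations per region truth
#'   (default 1); lets region-kind arms accumulate as many ground truths as
#'   desired from a finite set of regions.
#' @param fdr_q FDR level of the mapping step (default 0.01).
#' @param largest_cluster_only centre of mass over the largest significant
#'   cluster instead of all significant voxels (default FALSE).
#' @param seed RNG seed.
#' @return A `ground_truth_spec` list.
#' @export
ground_truth_spec <- function(damage_fraction = 0.2, deficit_prob = 0.9,
                              min_damaged_patients = 3,
                              voxel_deterministic = TRUE, n_truths = NULL,
                              label_draws = 1, fdr_q = 0.01,
                              largest_cluster_only = FALSE, seed = 1) {
  stopifnot(damage_fraction > 0, damage_fraction <= 1,
            deficit_prob >= 0, deficit_prob <= 1, min_damaged_patients >= 0,
            label_draws >= 1)
  structure(list(damage_fraction = damage_fraction,
                 deficit_prob = deficit_prob,
                 min_damaged_patients = as.integer(min_damaged_patients),
                 voxel_deterministic = voxel_deterministic,
                 n_truths = n_truths, label_draws = as.integer(label_draws),
                 fdr_q = fdr_q,
                 largest_cluster_only = largest_cluster_only,
                 seed = as.integer(seed)),
            class = "ground_truth_spec")
}

#' Spatial displacement error of a lesion model
#'
#' Iterates candidate ground truths defined by the lesion model - every
#' eligible voxel, every atlas region, or every component territory (the
#' thresholded component map) - simulates deficit labels, maps them with the
#' Fisher/FDR mass-univariate procedure, and measures the Euclidean
#' distance between the centre of mass of the significant voxels and the
#' ground-truth reference point (the voxel itself, or the region's centre
#' of mass). Truths with no significant voxels are recorded as
#' non-localized and excluded from the mean.
#'
#' @param binary_lesion_matrix a `lesion_matrix` of binary lesions
#'   (`center = FALSE` recommended).
#' @param lesion_model one of `list(kind = "voxel")`,
#'   `list(kind = "atlas", atlas = <label volume>)`, or
#'   `list(kind = "components", solution = <component_solution>,
#'   z_cut = 3.29, min_cluster_mm3 = 4000)` (the extent rule expressed in
#'   mm^3 so it transfers across voxel sizes).
#' @param spec a [ground_truth_spec()].
#' @return List with `records` (one row per eligible truth: reference and
#'   recovered mm coordinates, displacement, significant voxel count,
#'   localized flag), `summary` (mean, sd, counts), `model` tag.
#' @export
displacement_experiment <- function(binary_lesion_matrix, lesion_model,
                                    spec = ground_truth_spec()) {
  lm <- binary_lesion_matrix
  stopifnot(inherits(lm, "lesion_matrix"))
  L <- round(sweep(lm$values, 2, lm$col_means, "+"))
  n <- nrow(L)
  kind <- lesion_model$kind
  truths <- list()   # each: list(id, damaged (logical), ref (mm))
  if (kind == "voxel") {
    dmg_count <- colSums(L)
    elig <- which(dmg_count > spec$min_damaged_patients &
                    dmg_count < n)           # a universal voxel cannot split
    if (length(elig) == 0) stop("lesion model yields zero eligible truths")
    if (!is.null(spec$n_truths) && length(elig) > spec$n_truths) {
      set.seed(spec$seed)
      elig <- sort(sample(elig, spec$n_truths))
    }
    ijk <- arrayInd(lm$voxel_index[elig], lm$grid_shape) - 1L
    mm <- voxel_to_mm(lm$affine, ijk)
    truths <- lapply(seq_along(elig), function(i)
      list(id = paste0("voxel_", elig[i]), damaged = L[, elig[i]] > 0,
           ref = mm[i, ]))
  } else {
    regions <- if (kind == "atlas") {
      at <- lesion_model$atlas
      labs <- sort(unique(at$data[at$data > 0]))
      lapply(labs, function(l) {
        arr <- array(as.numeric(at$data == l), dim(at$data))
        list(id = paste0("region_", l),
             mask = volume(arr, at$affine, tag = "binary"))
      })
    } else if (kind == "components") {
      sol <- lesion_model$solution
      zc <- lesion_model$z_cut %||% 3.29
      mm3 <- lesion_model$min_cluster_mm3 %||% 4000
      minvox <- max(1L, round(mm3 / voxel_volume(lm$affine)))
      maps <- component_maps(sol, lm, z_cut = zc, min_cluster_voxels = minvox)
      keep <- which(vapply(maps, function(m) sum(m$mask$data) > 0, TRUE))
      lapply(keep, function(j)
        list(id = paste0("component_", j), mask = maps[[j]]$mask))
    } else stop("unknown lesion model kind: ", kind)
    if (length(regions) == 0) stop("lesion model yields zero candidate regions")
    truths <- lapply(regions, function(rg) {
      reg_idx <- which(rg$mask$data > 0)
      cols <- which(lm$voxel_index %in% reg_idx)
      frac <- rowSums(L[, cols, drop = FALSE]) / length(reg_idx)
      list(id = rg$id, damaged = frac >= spec$damage_fraction,
           ref = mask_centre_of_mass(rg$mask))
    })
  }
  truths <- Filter(function(tr) sum(tr$damaged) > spec$min_damaged_patients &&
                     sum(tr$damaged) < n, truths)
  if (length(truths) == 0) stop("lesion model yields zero eligible truths")
  deterministic <- kind == "voxel" && spec$voxel_deterministic
  draws <- if (deterministic) 1L else spec$label_draws
  if (draws > 1L)
    truths <- do.call(c, lapply(seq_len(draws), function(dd)
      lapply(truths, function(tr) {
        tr$id <- paste0(tr$id, "_draw", dd); tr
      })))
  rows <- vector("list", length(truths))
  for (i in seq_along(truths)) {
    tr <- truths[[i]]
    if (deterministic) {
      y <- as.integer(tr$damaged)
    } else {
      set.seed((spec$seed + i) %% .Machine$integer.max)
      y <- integer(n)
      y[tr$damaged] <- stats::rbinom(sum(tr$damaged), 1L, spec$deficit_prob)
    }
    if (length(unique(y)) < 2) {
      rows[[i]] <- data.frame(truth_id = tr$id, ref_x = tr$ref[1],
                              ref_y = tr$ref[2], ref_z = tr$ref[3],
                              com_x = NA_real_, com_y = NA_real_,
                              com_z = NA_real_, displacement = NA_real_,
                              n_significant = 0L, localized = FALSE)
      next
    }
    res <- fisher_mass_univariate(lm, y, fdr_q = spec$fdr_q)
    com <- mask_centre_of_mass(res$mask,
                               largest_cluster_only = spec$largest_cluster_only)
    if (is.null(com)) {
      rows[[i]] <- data.frame(truth_id = tr$id, ref_x = tr$ref[1],
                              ref_y = tr$ref[2], ref_z = tr$ref[3],
                              com_x = NA_real_, com_y = NA_real_,
                              com_z = NA_real_, displacement = NA_real_,
                              n_significant = 0L, localized = FALSE)
    } else {
      rows[[i]] <- data.frame(truth_id = tr$id, ref_x = tr$ref[1],
                              ref_y = tr$ref[2], ref_z = tr$ref[3],
                              com_x = com[1], com_y = com[2], com_z = com[3],
                              displacement = euclidean_displacement(com, tr$ref),
                              n_significant = sum(res$mask$data),
                              localized = TRUE)
    }
  }
  records <- do.call(rbind, rows)
  loc <- records$displacement[records$localized]
  list(records = records,
       summary = list(model = kind, mean = mean(loc), sd = stats::sd(loc),
                      n_localized = sum(records$localized),
                      n_non_localized = sum(!records$localized)),
       model = kind)
}

#' Compare mapping methods by Dice overlap with ground-truth regions
#'
#' For each ground-truth region, deficit labels are simulated under the
#' damage-fraction / deficit-probability rule and five methods are run:
#' mass-univariate Fisher/FDR, sparse CCA at the fixed sparseness, sparse
#' CCA with cross-validated sparseness, lesion-PCA plus stepwise regression
#' back-projection, and lesion-PCA plus Bonferroni-screened component
#' correlations (union of the significant components' thresholded maps).
#' Each method's significant mask is scored by Dice against the truth.
#'
#' @param binary_lesion_matrix a `lesion_matrix` of binary lesions.
#' @param ground_truth_regions list of binary [volume()] region masks
#'   (possibly composite unions of atlas labels).
#' @param k number of lesion components for the PCA-based methods (default:
#'   MDL estimate).
#' @param spec a [ground_truth_spec()].
#' @param mapping_cfg a [mapping_config()].
#' @param scca_cfg a [sccan_config()].
#' @param component_z_cut,component_min_cluster_mm3 threshold and extent of
#'   the component maps used by the correlation method.
#' @return Data frame with one row per region x method: `truth_id`,
#'   `method`, `dice`, `n_significant`.
#' @export
method_comparison_experiment <- function(binary_lesion_matrix,
                                         ground_truth_regions,
                                         k = NULL,
                                         spec = ground_truth_spec(),
                                         mapping_cfg = mapping_config(),
                                         scca_cfg = sccan_config(),
                                         component_z_cut = 3.29,
                                         component_min_cluster_mm3 = 4000) {
  lm <- binary_lesion_matrix
  stopifnot(inherits(lm, "lesion_matrix"), length(ground_truth_regions) >= 1)
  L <- round(sweep(lm$values, 2, lm$col_means, "+"))
  if (is.null(k)) k <- max(1L, estimate_order(lm)$k_mdl)
  sol <- pca_varimax(lm, k)
  minvox <- max(1L, round(component_min_cluster_mm3 / voxel_volume(lm$affine)))
  comp_masks <- lapply(component_maps(sol, lm, z_cut = component_z_cut,
                                      min_cluster_voxels = minvox),
                       `[[`, "mask")
  empty_mask <- matrix_to_volume(lm, numeric(ncol(L)), tag = "binary")
  rows <- list()
  for (i in seq_along(ground_truth_regions)) {
    reg <- ground_truth_regions[[i]]
    id <- names(ground_truth_regions)[i] %||% paste0("region_", i)
    if (id == "") id <- paste0("region_", i)
    lab <- simulate_deficit_labels(reg, L, spec$damage_fraction,
                                   spec$deficit_prob,
                                   seed = spec$seed + i,
                                   mask_index = lm$voxel_index)
    y <- lab$deficit
    if (length(unique(y)) < 2)
      stop("simulated labels single-class for region ", id)
    masks <- list()
    masks[["mass-univariate"]] <- fisher_mass_univariate(lm, y, spec$fdr_q)$mask
    masks[["sparse-cca-fixed"]] <- sparse_cca(lm, y, scca_cfg)$mask
    masks[["sparse-cca-cv"]] <- sparse_cca(lm, y, scca_cfg, cv = TRUE)$mask
    sw <- stepwise_regression(y, sol$scores, mapping_cfg)
    masks[["pca-regression"]] <- if (length(sw$selected))
      regression_component_map(sol, sw, lm, mapping_cfg)$mask else empty_mask
    cors <- component_behaviour_correlations(sol$scores, matrix(y, ncol = 1),
                                             mapping_cfg)
    sig_comp <- which(cors$significant)
    msk <- empty_mask
    for (j in sig_comp) msk$data <- pmax(msk$data, comp_masks[[j]]$data)
    masks[["pca-correlation"]] <- msk
    for (m in names(masks)) {
      dc <- suppressWarnings(dice(masks[[m]], reg))
      rows[[length(rows) + 1L]] <-
        data.frame(truth_id = id, method = m, dice = dc,
                   n_significant = sum(masks[[m]]$data > 0))
    }
  }
  do.call(rbind, rows)
}
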