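# Shared fixture builders; everything is generated in code at test time.

# small all-ones mask on an isotropic grid
tiny_mask <- function(gs = c(10, 10, 10), voxel_mm = 2) {
  volume(array(1, gs), default_affine(gs, voxel_mm), tag = "binary")
}

# cohort of random abnormality volumes on a shared grid
random_abnormality_cohort <- function(n, gs = c(8, 8, 8), voxel_mm = 2,
                                      seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(p)
    volume(array(runif(prod(gs)), gs), default_affine(gs, voxel_mm),
           tag = "abnormality"))
}

# lesion matrix directly from a patients x voxels matrix (1-D grid trick)
matrix_as_lesion_matrix <- function(M, center = FALSE, voxel_mm = 1) {
  V <- ncol(M)
  aff <- default_affine(c(V, 1, 1), voxel_mm)
  mask <- volume(array(1, c(V, 1, 1)), aff, tag = "binary")
  vols <- lapply(seq_len(nrow(M)), function(p)
    volume(array(M[p, ], c(V, 1, 1)), aff, tag = "abnormality"))
  assemble_lesion_matrix(vols, mask, center = center)
}

# small vascular cohort used across modules
small_vascular_cohort <- function(n_patients = 30, gs = c(14, 14, 14),
                                  n_terr = 5, seed = 7, noise = 0.02,
                                  jitter = 0, internal_weight = 0.5) {
  aff <- default_affine(gs, 4)
  mask <- default_brain_mask(gs, aff)
  va <- make_vascular_atlas(gs, aff, mask, n_terr, seed = seed,
                            internal_weight = internal_weight)
  les <- simulate_patient_lesions(
    va$tree, va$atlas,
    cohort_spec(n_patients = n_patients, background_noise = noise,
                boundary_jitter_mm = jitter, seed = seed + 1))
  list(atlas = va$atlas, tree = va$tree, mask = mask, lesions = les,
       affine = aff)
}

# independent flood-fill connected components (recursive queue), oracle for
# label_components
flood_fill_labels <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, ]
  lab <- array(0L, d)
  cur <- 0L
  for (start in which(mask > 0)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      idx <- arrayInd(q, d)
      for (r in seq_len(nrow(offs))) {
        nb <- idx + as.integer(offs[r, ])
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1L) * d[1] * d[2] + (nb[2] - 1L) * d[1] + nb[1]
        if (mask[lin] > 0 && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}

# literal BH step-up oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[o[i]] <= i * q / m) k <- i
  flags <- logical(m)
  if (k > 0) flags[o[seq_len(k)]] <- TRUE
  flags
}

# brute-force two-sided Fisher p by hypergeometric enumeration
fisher_oracle_p <- function(a, n1, K, n) {
  lo <- max(0, n1 - (n - K)); hi <- min(n1, K)
  dens <- dhyper(lo:hi, K, n - K, n1)
  sum(dens[dens <= dens[a - lo + 1] * (1 + 1e-7)])
}
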