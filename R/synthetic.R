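#' Random arterial branching tree
#'
#' Samples a rooted binary tree whose leaves supply vascular territories,
#' emulating the branching of the middle cerebral artery: an occlusion at an
#' internal node damages every territory downstream of it, which is what
#' induces the block covariance structure of stroke lesions. Each node
#' carries an occlusion weight; occlusion sites are drawn proportional to
#' these weights, so leaves (distal branch occlusions) can be made more or
#' less likely than trunk occlusions.
#'
#' @param n_terminal_branches number of leaves / territories (>= 2).
#' @param seed RNG seed.
#' @param leaf_weight occlusion weight given to each leaf (default 1).
#' @param internal_weight occlusion weight of internal nodes (default 0.5;
#'   set 0 for leaf-only occlusion).
#' @return A `vascular_tree`: data frame `nodes` (id, parent, weight, leaf,
#'   territory) plus `n_territories`.
#' @export
vascular_tree <- function(n_terminal_branches, seed = 1, leaf_weight = 1,
                          internal_weight = 0.5) {
  stopifnot(n_terminal_branches >= 2, leaf_weight >= 0, internal_weight >= 0,
            leaf_weight + internal_weight > 0)
  set.seed(seed)
  parent <- c(NA_integer_)
  is_leaf <- c(TRUE)
  while (sum(is_leaf) < n_terminal_branches) {
    leaves <- which(is_leaf)
    split <- if (length(leaves) == 1L) leaves else sample(leaves, 1L)
    is_leaf[split] <- FALSE
    parent <- c(parent, split, split)
    is_leaf <- c(is_leaf, TRUE, TRUE)
  }
  n <- length(parent)
  territory <- rep(NA_integer_, n)
  territory[is_leaf] <- seq_len(sum(is_leaf))
  nodes <- data.frame(id = seq_len(n), parent = parent,
                      weight = ifelse(is_leaf, leaf_weight, internal_weight),
                      leaf = is_leaf, territory = territory)
  structure(list(nodes = nodes, n_territories = sum(is_leaf)),
            class = "vascular_tree")
}

#' Territories supplied downstream of a tree node
#'
#' @param tree a [vascular_tree()].
#' @param node node id.
#' @return Sorted territory labels of all leaves in the node's subtree.
#' @export
territories_under <- function(tree, node) {
  nd <- tree$nodes
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    cur <- stack[1]; stack <- stack[-1]
    if (nd$leaf[cur]) acc <- c(acc, nd$territory[cur])
    stack <- c(stack, nd$id[!is.na(nd$parent) & nd$parent == cur])
  }
  sort(acc)
}

#' Default desk-scale brain mask
#'
#' An ellipsoid inscribed in the grid (semi-axes 0.45 of each dimension),
#' giving roughly 10k in-mask voxels on the default 32 x 38 x 32 grid of
#' 4-mm voxels.
#'
#' @param grid_shape 3 positive integers.
#' @param affine 4x4 voxel-to-mm matrix.
#' @return A binary [volume()].
#' @export
default_brain_mask <- function(grid_shape = c(32, 38, 32),
                               affine = default_affine(grid_shape)) {
  ctr <- (grid_shape - 1) / 2
  semi <- 0.45 * grid_shape
  i <- slice.index(array(0, grid_shape), 1) - 1
  j <- slice.index(array(0, grid_shape), 2) - 1
  k <- slice.index(array(0, grid_shape), 3) - 1
  inside <- ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
    ((k - ctr[3]) / semi[3])^2 <= 1
  volume(array(as.numeric(inside), grid_shape), affine, tag = "binary")
}

#' @rdname default_brain_mask
#' @param voxel_mm isotropic voxel size (mm) of the default affine.
#' @export
default_affine <- function(grid_shape = c(32, 38, 32), voxel_mm = 4) {
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- -voxel_mm * (grid_shape - 1) / 2
  aff
}

#' Synthetic vascular-territory atlas
#'
#' Grows a Voronoi-style partition of the brain mask from seed voxels placed
#' by farthest-point sampling, one seed per leaf of a sampled arterial tree.
#' Every in-mask voxel is assigned to the nearest seed (in mm), so on a
#' convex mask each territory is a connected region. Deterministic given the
#' seed.
#'
#' @param grid_shape 3 positive integers.
#' @param affine 4x4 voxel-to-mm matrix.
#' @param mask binary [volume()] brain mask (default: inscribed ellipsoid).
#' @param n_terminal_branches number of territories (>= 2).
#' @param seed RNG seed.
#' @param ... passed to [vascular_tree()].
#' @return List with `tree` ([vascular_tree()]), `atlas` (label [volume()]),
#'   `names` (territory names), `seeds` (territory seed voxel indices,
#'   0-based).
#' @export
make_vascular_atlas <- function(grid_shape = c(32, 38, 32),
                                affine = default_affine(grid_shape),
                                mask = default_brain_mask(grid_shape, affine),
                                n_terminal_branches = 14, seed = 1, ...) {
  stopifnot(n_terminal_branches >= 2)
  bm <- brain_mask(mask)
  if (n_terminal_branches > bm$n_voxels)
    stop("more terminal branches than in-mask voxels")
  tree <- vascular_tree(n_terminal_branches, seed = seed, ...)
  set.seed(seed + 1L)
  ijk <- arrayInd(bm$index, grid_shape) - 1L
  mm <- voxel_to_mm(affine, ijk)
  # farthest-point sampling keeps seeds spread, giving comparable territory sizes
  chosen <- sample.int(nrow(mm), 1L)
  mind <- sqrt(rowSums(sweep(mm, 2, mm[chosen, ], "-")^2))
  while (length(chosen) < n_terminal_branches) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    d <- sqrt(rowSums(sweep(mm, 2, mm[nxt, ], "-")^2))
    mind <- pmin(mind, d)
  }
  seeds_mm <- mm[chosen, , drop = FALSE]
  lab <- nearest_seed_labels(mm, seeds_mm)
  arr <- array(0, grid_shape)
  arr[bm$index] <- lab
  list(tree = tree,
       atlas = volume(arr, affine, tag = "label"),
       names = paste0("territory_", seq_len(n_terminal_branches)),
       seeds = ijk[chosen, , drop = FALSE])
}

nearest_seed_labels <- function(points_mm, seeds_mm) {
  d2 <- outer(rowSums(points_mm^2), rep(1, nrow(seeds_mm))) -
    2 * points_mm %*% t(seeds_mm) +
    outer(rep(1, nrow(points_mm)), rowSums(seeds_mm^2))
  max.col(-d2, ties.method = "first")
}

#' Lesion cohort specification
#'
#' Parameters of the synthetic stroke cohort. Damaged voxels draw their
#' abnormality from Beta(`beta_a`, `beta_b`) (default mean 0.75, emulating
#' mostly-destroyed tissue with partial-damage tails); watershed variability
#' is emulated by a smooth random boundary displacement of RMS magnitude
#' `boundary_jitter_mm`; `background_noise` is the SD of additive Gaussian
#' noise applied in-mask before clipping to \[0, 1\].
#'
#' @param n_patients cohort size (>= 2), default 80.
#' @param beta_a,beta_b Beta parameters of damaged-voxel intensity.
#' @param boundary_jitter_mm RMS boundary displacement in mm (default 2).
#' @param background_noise additive noise SD (default 0.05).
#' @param fwhm_mm optional smoothing of the finished map (default 0).
#' @param seed RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 80, beta_a = 6, beta_b = 2,
                        boundary_jitter_mm = 2, background_noise = 0.05,
                        fwhm_mm = 0, seed = 1) {
  stopifnot(n_patients >= 2, beta_a > 0, beta_b > 0, boundary_jitter_mm >= 0,
            background_noise >= 0, fwhm_mm >= 0)
  structure(list(n_patients = as.integer(n_patients), beta_a = beta_a,
                 beta_b = beta_b, boundary_jitter_mm = boundary_jitter_mm,
                 background_noise = background_noise, fwhm_mm = fwhm_mm,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of stroke lesion abnormality maps
#'
#' Per patient: an occlusion node is drawn from the arterial tree in
#' proportion to the node occlusion weights; every territory downstream of
#' that node receives voxel-wise damage intensity drawn from
#' Beta(`beta_a`, `beta_b`); territory boundaries are jittered by a smooth
#' random displacement field (watershed variability); background noise is
#' added in-mask; the map is optionally smoothed and clipped to \[0, 1\].
#' Bit-reproducible given the spec seed.
#'
#' @param tree a [vascular_tree()].
#' @param atlas label [volume()] consistent with the tree (one label per
#'   leaf territory).
#' @param spec a [cohort_spec()].
#' @param occlusion_nodes optional integer vector (length `n_patients`)
#'   forcing the occlusion node per patient instead of sampling.
#' @return List of abnormality [volume()]s with attribute `occlusion_nodes`.
#' @export
simulate_patient_lesions <- function(tree, atlas, spec = cohort_spec(),
                                     occlusion_nodes = NULL) {
  stopifnot(inherits(tree, "vascular_tree"), is_volume(atlas))
  labs <- sort(unique(atlas$data[atlas$data > 0]))
  if (!setequal(labs, seq_len(tree$n_territories)))
    stop("atlas labels do not match the tree's territories")
  set.seed(spec$seed)
  d <- dim(atlas$data)
  in_mask <- which(atlas$data > 0)
  ijk <- arrayInd(in_mask, d)
  vdim <- voxel_dims(atlas$affine)
  nd <- tree$nodes
  if (is.null(occlusion_nodes)) {
    occlusion_nodes <- sample(nd$id, spec$n_patients, replace = TRUE,
                              prob = nd$weight)
  } else stopifnot(length(occlusion_nodes) == spec$n_patients)
  out <- vector("list", spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    lab_p <- atlas$data
    if (spec$boundary_jitter_mm > 0) {
      disp <- jitter_field(d, atlas$affine, spec$boundary_jitter_mm)
      src <- ijk + round(sweep(disp[in_mask, , drop = FALSE], 2, vdim, "/"))
      for (ax in 1:3) src[, ax] <- pmin(pmax(src[, ax], 1L), d[ax])
      lin <- (src[, 3] - 1L) * d[1] * d[2] + (src[, 2] - 1L) * d[1] + src[, 1]
      moved <- atlas$data[lin]
      keep <- moved > 0              # displaced outside the mask: keep own label
      lab_p[in_mask[keep]] <- moved[keep]
    }
    affected <- territories_under(tree, occlusion_nodes[p])
    a <- array(0, d)
    dmg <- in_mask[lab_p[in_mask] %in% affected]
    a[dmg] <- stats::rbeta(length(dmg), spec$beta_a, spec$beta_b)
    if (spec$background_noise > 0)
      a[in_mask] <- a[in_mask] + stats::rnorm(length(in_mask), 0,
                                              spec$background_noise)
    v <- volume(pmin(pmax(a, 0), 1), atlas$affine, tag = "abnormality")
    if (spec$fwhm_mm > 0) {
      v <- gaussian_smooth(v, spec$fwhm_mm)
      v$data[-in_mask] <- 0
      v$data[in_mask] <- pmin(pmax(v$data[in_mask], 0), 1)
    }
    out[[p]] <- v
  }
  attr(out, "occlusion_nodes") <- occlusion_nodes
  out
}

jitter_field <- function(d, affine, sigma_mm, smooth_fwhm_mm = 16) {
  disp <- matrix(0, prod(d), 3)
  for (ax in 1:3) {
    f <- gaussian_smooth(volume(array(stats::rnorm(prod(d)), d), affine),
                         smooth_fwhm_mm)$data
    rms <- sqrt(mean(f^2))
    disp[, ax] <- if (rms > 0) as.numeric(f) / rms * sigma_mm else 0
  }
  disp
}

#' Canonical 21-test aphasia battery loading pattern
#'
#' The published four-factor structure of a comprehensive aphasia battery:
#' phonology, semantics, executive and fluency. Salient loadings (>= 0.5 in
#' the published varimax solution) are kept at their printed values; all
#' remaining loadings are set to a weak 0.2 background, giving a generating
#' matrix with clear simple structure for simulation.
#'
#' @return 21 x 4 numeric matrix with test rownames and factor colnames.
#' @export
aphasia_battery_loadings <- function() {
  tests <- c("delayed_repetition_words", "delayed_repetition_nonwords",
             "immediate_repetition_nonwords", "immediate_repetition_words",
             "boston_naming", "naming_64item", "forward_digit_span",
             "backward_digit_span", "spoken_sentence_comprehension",
             "spoken_word_picture_matching", "type_token_ratio",
             "written_word_picture_matching", "camel_cactus_pictures",
             "synonym_judgement_96", "minimal_pairs_nonwords",
             "ravens_matrices", "minimal_pairs_words", "brixton_spatial",
             "speech_tokens", "mean_length_utterance", "words_per_minute")
  W <- matrix(0.2, 21, 4, dimnames = list(tests,
              c("phonology", "semantics", "executive", "fluency")))
  W[1:9, "phonology"] <- c(0.888, 0.883, 0.881, 0.858, 0.823, 0.813,
                           0.746, 0.595, 0.521)
  W[10:14, "semantics"] <- c(0.801, 0.718, 0.713, 0.688, 0.658)
  W["written_word_picture_matching", "executive"] <- 0.504
  W[15:18, "executive"] <- c(0.814, 0.735, 0.705, 0.698)
  W[19:21, "fluency"] <- c(0.885, 0.831, 0.768)
  W
}

#' Behavioural battery generating specification
#'
#' @param loadings tests x factors generating matrix (default
#'   [aphasia_battery_loadings()]).
#' @param uniqueness per-test unique noise SD on the \[0, 1\] latent scale
#'   (recycled; default 0.1).
#' @param score_scale maximum score (default 100).
#' @param seed RNG seed.
#' @return A `behaviour_gen_spec` list.
#' @export
behaviour_gen_spec <- function(loadings = aphasia_battery_loadings(),
                               uniqueness = 0.1, score_scale = 100, seed = 1) {
  loadings <- as.matrix(loadings)
  stopifnot(all(is.finite(loadings)), score_scale > 0)
  uniqueness <- rep_len(uniqueness, nrow(loadings))
  stopifnot(all(uniqueness >= 0))
  structure(list(loadings = loadings, uniqueness = uniqueness,
                 score_scale = score_scale, seed = as.integer(seed)),
            class = "behaviour_gen_spec")
}

behaviour_scores_from_factors <- function(factors, spec) {
  W <- spec$loadings
  stopifnot(ncol(factors) == ncol(W))
  n <- nrow(factors)
  noise <- matrix(stats::rnorm(n * nrow(W), 0, rep(spec$uniqueness, each = n)),
                  n, nrow(W))
  raw <- factors %*% t(W) + noise
  scores <- spec$score_scale * pmin(pmax(raw, 0), 1)
  colnames(scores) <- rownames(W)
  scores
}

#' Simulate a behavioural battery from a lesion cohort
#'
#' Each behavioural factor is driven by the preserved tissue of its critical
#' territories: factor value `f = 1 - mean abnormality` over the factor's
#' critical-territory voxels (1 = intact, 0 = destroyed). Test scores are
#' `score_scale * clip(W f + noise, 0, 1)`.
#'
#' @param lesions list of abnormality [volume()]s.
#' @param atlas label [volume()].
#' @param critical_territories_per_factor list (one element per factor) of
#'   territory labels driving that factor.
#' @param spec a [behaviour_gen_spec()].
#' @return List with `scores` (patients x tests matrix) and `factors`
#'   (patients x factors latent matrix).
#' @export
simulate_behaviour <- function(lesions, atlas, critical_territories_per_factor,
                               spec = behaviour_gen_spec()) {
  stopifnot(is_volume(atlas))
  k <- ncol(spec$loadings)
  if (length(critical_territories_per_factor) != k)
    stop("need one critical-territory set per factor (", k, ")")
  labs <- atlas$data
  idx <- lapply(critical_territories_per_factor, function(terr) {
    if (!all(terr %in% labs)) stop("unknown territory label: ",
                                   paste(setdiff(terr, labs), collapse = ","))
    which(labs %in% terr)
  })
  set.seed(spec$seed)
  factors <- t(vapply(lesions, function(v)
    vapply(idx, function(ii) 1 - mean(v$data[ii]), 0), numeric(k)))
  list(scores = behaviour_scores_from_factors(factors, spec),
       factors = factors)
}

#' Simulate a standalone behavioural battery
#'
#' Draws latent factor values uniformly on \[0, 1\] (the range factors take
#' when driven by lesion load) and generates test scores through the same
#' loading-plus-unique-noise rule as [simulate_behaviour()].
#'
#' @param n_patients number of patients.
#' @param spec a [behaviour_gen_spec()].
#' @return List with `scores` and `factors` as in [simulate_behaviour()].
#' @export
simulate_behaviour_battery <- function(n_patients, spec = behaviour_gen_spec()) {
  set.seed(spec$seed)
  k <- ncol(spec$loadings)
  factors <- matrix(stats::runif(n_patients * k), n_patients, k)
  list(scores = behaviour_scores_from_factors(factors, spec),
       factors = factors)
}

#' Simulate behavioural deficit labels from regional damage
#'
#' A patient counts as "damaged" when the lesioned fraction of the
#' ground-truth region reaches `damage_fraction` (default 20% of the area);
#' damaged patients then exhibit a deficit with probability `deficit_prob`
#' (default 90%); intact patients never do.
#'
#' @param region_mask binary [volume()] of the critical region.
#' @param binary_lesions list of binary [volume()]s, or a patients x voxels
#'   0/1 matrix paired with `mask_index` (linear voxel indices per column).
#' @param damage_fraction fraction of region voxels that must be lesioned
#'   (0 < f <= 1, default 0.2); the comparison is "at least".
#' @param deficit_prob deficit probability among damaged patients
#'   (default 0.9).
#' @param seed RNG seed.
#' @param mask_index linear indices of matrix columns when `binary_lesions`
#'   is a matrix.
#' @return List with `deficit` (0/1 per patient) and `damaged` (logical).
#' @export
simulate_deficit_labels <- function(region_mask, binary_lesions,
                                    damage_fraction = 0.2, deficit_prob = 0.9,
                                    seed = 1, mask_index = NULL) {
  stopifnot(damage_fraction > 0, damage_fraction <= 1,
            deficit_prob >= 0, deficit_prob <= 1)
  reg <- which(region_mask$data > 0)
  if (length(reg) == 0L) stop("ground-truth region is empty")
  if (is.matrix(binary_lesions)) {
    stopifnot(!is.null(mask_index))
    cols <- which(mask_index %in% reg)
    frac <- rowSums(binary_lesions[, cols, drop = FALSE]) / length(reg)
  } else {
    frac <- vapply(binary_lesions, function(v) sum(v$data[reg] > 0), 0) /
      length(reg)
  }
  damaged <- frac >= damage_fraction
  set.seed(seed)
  deficit <- integer(length(damaged))
  deficit[damaged] <- stats::rbinom(sum(damaged), 1L, deficit_prob)
  list(deficit = deficit, damaged = damaged)
}
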