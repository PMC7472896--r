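#' Brain volume container
#'
#' A `volume` holds one 3-D scalar field together with its voxel-index to
#' millimetre affine transform and a role tag. Tags constrain the payload:
#' `"abnormality"` maps live in \[0, 1\], `"binary"` maps in \{0, 1\}, and
#' `"label"` volumes hold non-negative integers (0 = background). Untyped
#' scalar fields (statistics, z maps, counts) use the `"stat"`, `"z"` or
#' `"count"` tags, which are unconstrained.
#'
#' @param data numeric 3-D array.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to mm.
#' @param tag character role tag; one of `"intensity"`, `"abnormality"`,
#'   `"binary"`, `"label"`, `"stat"`, `"z"`, `"count"`.
#' @return An object of class `volume` with fields `data`, `affine`, `tag`.
#' @export
volume <- function(data, affine = diag(4), tag = "intensity") {
  tag <- match.arg(tag, c("intensity", "abnormality", "binary", "label",
                          "stat", "z", "count"))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3-D array, got ", length(dim(data)), " dimensions")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  d3 <- det(affine[1:3, 1:3, drop = FALSE])
  if (!is.finite(d3) || abs(d3) < .Machine$double.eps)
    stop("affine is not invertible (zero voxel volume)")
  data <- array(as.numeric(data), dim(data))
  if (tag == "abnormality" && (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("abnormality volume must have values in [0, 1]")
  if (tag == "binary" && !all(data %in% c(0, 1)))
    stop("binary volume must have values in {0, 1}")
  if (tag == "label" && (any(data < 0) || any(data != round(data))))
    stop("label volume must hold non-negative integers")
  structure(list(data = data, affine = affine, tag = tag), class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  cat(sprintf("<volume [%s] %s, voxel %s mm, vol %.3f mm^3>\n", x$tag,
              paste(dim(x$data), collapse = "x"),
              paste(signif(voxel_dims(x$affine), 4), collapse = "x"),
              voxel_volume(x$affine)))
  invisible(x)
}

#' @rdname volume
#' @param x object to test.
#' @export
is_volume <- function(x) inherits(x, "volume")

#' Voxel sizes and voxel volume from an affine
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @return `voxel_dims`: length-3 vector of per-axis voxel sizes (mm).
#'   `voxel_volume`: scalar voxel volume in mm^3 (|det| of the 3x3 block).
#' @export
voxel_dims <- function(affine) sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))

#' @rdname voxel_dims
#' @export
voxel_volume <- function(affine) abs(det(affine[1:3, 1:3, drop = FALSE]))

#' Convert 0-based voxel indices to mm coordinates
#'
#' @param affine 4x4 voxel-to-mm matrix.
#' @param ijk integer vector of length 3 (one voxel, 0-based) or an n x 3
#'   matrix of voxel indices.
#' @return mm coordinates, same shape as the input.
#' @export
voxel_to_mm <- function(affine, ijk) {
  if (is.null(dim(ijk))) {
    as.numeric(affine %*% c(ijk, 1))[1:3]
  } else {
    t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
  }
}

#' Read and write single NIfTI-1 volumes
#'
#' Thin wrappers around \pkg{RNifti} that enforce the package's volume
#' contract: single 3-D payloads with an invertible affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tag role tag assigned to the volume on read (see [volume()]).
#' @return `read_volume` returns a [volume()].
#' @export
read_volume <- function(path, tag = "intensity") {
  if (!file.exists(path)) stop("file not found: ", path)
  im <- RNifti::readNifti(path)
  d <- dim(im)
  if (length(d) != 3L)
    stop("expected a single 3-D volume, got a ", length(d), "-D image: ", path)
  aff <- unclass(RNifti::xform(im))
  attributes(aff) <- list(dim = c(4L, 4L))
  volume(array(as.numeric(im), d), aff, tag = tag)
}

#' @rdname read_volume
#' @param vol a [volume()].
#' @param datatype on-disk NIfTI datatype: `"double"`, `"float"` or `"uint8"`.
#' @export
write_volume <- function(vol, path, datatype = "double") {
  stopifnot(is_volume(vol))
  datatype <- match.arg(datatype, c("double", "float", "uint8"))
  im <- RNifti::asNifti(vol$data)
  im <- RNifti::`sform<-`(im, structure(vol$affine, code = 2L))
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Lesion identification configuration
#'
#' Parameters of the abnormality-to-binary-lesion step: voxels whose
#' abnormality likelihood exceeds the U-threshold are candidates, and only
#' candidate clusters larger than `min_cluster_voxels` voxels survive.
#'
#' @param u_threshold abnormality cut-off in (0, 1); default 0.5 (a voxel
#'   must be at least 50% likely to be abnormal).
#' @param min_cluster_voxels cluster-extent cut-off: clusters must have
#'   strictly more than this many voxels; default 100.
#' @param fwhm_mm Gaussian smoothing kernel full-width-half-maximum in mm;
#'   default 8.
#' @param connectivity neighbourhood for connected components: 6, 18 or 26.
#' @return A `lesion_config` list.
#' @export
lesion_config <- function(u_threshold = 0.5, min_cluster_voxels = 100,
                          fwhm_mm = 8, connectivity = 26) {
  stopifnot(u_threshold > 0, u_threshold < 1, min_cluster_voxels >= 1,
            fwhm_mm >= 0, connectivity %in% c(6, 18, 26))
  structure(list(u_threshold = u_threshold,
                 min_cluster_voxels = as.integer(min_cluster_voxels),
                 fwhm_mm = fwhm_mm, connectivity = as.integer(connectivity)),
            class = "lesion_config")
}

fwhm_to_sigma <- function(fwhm) fwhm / sqrt(8 * log(2))

reflect_index <- function(j, d) {
  # half-sample symmetric reflection: ... 3 2 1 | 1 2 3 ... d | d d-1 ...
  repeat {
    below <- j < 1L
    above <- j > d
    if (!any(below) && !any(above)) return(j)
    j[below] <- 1L - j[below]
    j[above] <- 2L * d + 1L - j[above]
  }
}

axis_conv_matrix <- function(d, sigma_vox) {
  r <- max(1L, ceiling(6 * sigma_vox))
  k <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, d, d)
  for (o in seq_along(k)) {
    off <- o - r - 1L
    src <- reflect_index(seq_len(d) + off, d)
    K[cbind(seq_len(d), src)] <- K[cbind(seq_len(d), src)] + k[o]
  }
  K
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter specified by its full-width-half-maximum in mm.
#' The per-axis sigma in voxels is `(fwhm_mm / sqrt(8 log 2)) / voxel_size`,
#' so anisotropic voxel grids are honoured through the affine. Boundaries are
#' handled by reflection, which preserves the total sum of the volume.
#'
#' @param vol a [volume()].
#' @param fwhm_mm kernel full-width-half-maximum in mm (>= 0; 0 is identity).
#' @return Smoothed [volume()] with tag `"stat"` unless the input tag is
#'   `"abnormality"` or `"intensity"`, which are preserved.
#' @export
gaussian_smooth <- function(vol, fwhm_mm) {
  stopifnot(is_volume(vol))
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  vdim <- voxel_dims(vol$affine)
  sig <- fwhm_to_sigma(fwhm_mm) / vdim
  a <- vol$data
  dims <- dim(a)
  for (ax in 1:3) {
    if (sig[ax] < 1e-8) next
    K <- axis_conv_matrix(dims[ax], sig[ax])
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), nrow = dims[ax])
    m <- K %*% m
    a <- aperm(array(m, dims[perm]), order(perm))
  }
  out_tag <- if (vol$tag %in% c("abnormality", "intensity")) vol$tag else "stat"
  if (out_tag == "abnormality") a <- pmin(pmax(a, 0), 1)
  volume(a, vol$affine, tag = out_tag)
}

#' Abnormality likelihood map from a control cohort
#'
#' Scores each patient voxel by how far its intensity lies from the control
#' distribution at the same voxel: with control mean `mu` and SD `sigma`,
#' abnormality = `2 * pnorm(|x - mu| / max(sigma, floor)) - 1`, a value in
#' \[0, 1\] that is monotone in the absolute deviation. The SD floor guards
#' voxels where the controls are (near-)constant; it is a small fraction of
#' the overall control intensity range.
#'
#' @param patient_volume patient [volume()].
#' @param control_volumes list of at least 3 control [volume()]s on the same
#'   grid.
#' @param sigma_floor_rel SD floor as a fraction of the control intensity
#'   range; default 1e-6.
#' @return An abnormality-tagged [volume()].
#' @export
abnormality_from_controls <- function(patient_volume, control_volumes,
                                      sigma_floor_rel = 1e-6) {
  stopifnot(is_volume(patient_volume))
  if (length(control_volumes) < 3)
    stop("at least 3 control volumes are required, got ", length(control_volumes))
  d <- dim(patient_volume$data)
  for (cv in control_volumes) {
    stopifnot(is_volume(cv))
    if (!all(dim(cv$data) == d))
      stop("control volume grid mismatch: ", paste(dim(cv$data), collapse = "x"),
           " vs patient ", paste(d, collapse = "x"))
  }
  ctrl <- vapply(control_volumes, function(v) v$data, patient_volume$data)
  mu <- apply(ctrl, 1:3, mean)
  sd_c <- apply(ctrl, 1:3, stats::sd)
  rng <- max(ctrl) - min(ctrl)
  floor_sd <- max(sigma_floor_rel * rng, .Machine$double.xmin)
  z <- abs(patient_volume$data - mu) / pmax(sd_c, floor_sd)
  volume(2 * stats::pnorm(z) - 1, patient_volume$affine, tag = "abnormality")
}

#' Binarize an abnormality map into a lesion mask
#'
#' Voxels whose abnormality exceeds the U-threshold are candidate lesion
#' voxels; connected components (under the configured neighbourhood) with
#' `min_cluster_voxels` or fewer voxels are then discarded, so a surviving
#' cluster has strictly more than `min_cluster_voxels` voxels.
#'
#' @param abnormality abnormality-tagged [volume()].
#' @param config a [lesion_config()].
#' @return A binary [volume()].
#' @export
binarize_lesion <- function(abnormality, config = lesion_config()) {
  stopifnot(is_volume(abnormality))
  if (abnormality$tag != "abnormality")
    stop("binarize_lesion expects an abnormality-tagged volume, got '",
         abnormality$tag, "'")
  cand <- abnormality$data > config$u_threshold
  lab <- label_components(cand, connectivity = config$connectivity)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes > config$min_cluster_voxels)
    cand <- array(lab %in% keep, dim(cand))
  }
  volume(array(as.numeric(cand), dim(cand)), abnormality$affine, tag = "binary")
}

#' Lesion overlap map across a patient group
#'
#' Voxel-wise sum of binary lesion masks, giving the number of patients
#' lesioned at each voxel (the group lesion profile).
#'
#' @param binary_volumes non-empty list of binary [volume()]s on one grid.
#' @return A count-tagged [volume()].
#' @export
overlap_map <- function(binary_volumes) {
  if (length(binary_volumes) < 1) stop("need at least one binary volume")
  d <- dim(binary_volumes[[1]]$data)
  acc <- array(0, d)
  for (v in binary_volumes) {
    stopifnot(is_volume(v))
    if (!all(dim(v$data) == d)) stop("grid mismatch in overlap_map")
    acc <- acc + v$data
  }
  volume(acc, binary_volumes[[1]]$affine, tag = "count")
}

#' Threshold a statistic volume and tabulate its clusters
#'
#' Applies `value > threshold` (or `|value| > threshold` when
#' `two_sided = TRUE`), labels connected components, removes clusters smaller
#' than `min_cluster_voxels` voxels, and tabulates the survivors sorted by
#' size. Peak and centre-of-mass coordinates are reported in mm through the
#' affine; the centre of mass weights every suprathreshold voxel equally.
#'
#' @param vol scalar [volume()].
#' @param threshold scalar threshold.
#' @param min_cluster_voxels smallest cluster size kept (>=); default 1.
#' @param connectivity 6, 18 or 26; default 26.
#' @param two_sided threshold on |value| instead of value.
#' @return List with `mask` (binary [volume()] of surviving voxels) and
#'   `clusters`, a data frame with columns `id`, `n_voxels`, `volume_mm3`,
#'   `peak`, `peak_x_mm`, `peak_y_mm`, `peak_z_mm`, `com_x_mm`, `com_y_mm`,
#'   `com_z_mm`.
#' @export
extract_clusters <- function(vol, threshold, min_cluster_voxels = 1,
                             connectivity = 26, two_sided = FALSE) {
  stopifnot(is_volume(vol))
  val <- if (two_sided) abs(vol$data) else vol$data
  supra <- val > threshold
  lab <- label_components(supra, connectivity = connectivity)
  nlab <- max(lab)
  rows <- list()
  keep_mask <- array(FALSE, dim(vol$data))
  if (nlab > 0) {
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    keep <- which(sizes >= min_cluster_voxels)
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    vv <- voxel_volume(vol$affine)
    for (i in seq_along(keep)) {
      lin <- which(lab == keep[i])
      keep_mask[lin] <- TRUE
      ijk <- arrayInd(lin, dim(vol$data)) - 1L
      mm <- voxel_to_mm(vol$affine, ijk)
      pk <- which.max(val[lin])
      rows[[i]] <- data.frame(
        id = i, n_voxels = length(lin), volume_mm3 = length(lin) * vv,
        peak = vol$data[lin[pk]],
        peak_x_mm = mm[pk, 1], peak_y_mm = mm[pk, 2], peak_z_mm = mm[pk, 3],
        com_x_mm = mean(mm[, 1]), com_y_mm = mean(mm[, 2]),
        com_z_mm = mean(mm[, 3]))
    }
  }
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(), n_voxels = integer(), volume_mm3 = numeric(),
               peak = numeric(), peak_x_mm = numeric(), peak_y_mm = numeric(),
               peak_z_mm = numeric(), com_x_mm = numeric(), com_y_mm = numeric(),
               com_z_mm = numeric())
  list(mask = volume(array(as.numeric(keep_mask), dim(vol$data)), vol$affine,
                     tag = "binary"),
       clusters = clusters)
}

#' Centre of mass of a voxel set in mm
#'
#' Unweighted mean of the mm coordinates of the selected voxels. With
#' `largest_cluster_only = TRUE` the voxel set is first reduced to its
#' largest connected component.
#'
#' @param mask binary [volume()].
#' @param largest_cluster_only reduce to the largest connected cluster first.
#' @param connectivity neighbourhood used when `largest_cluster_only`.
#' @return Length-3 mm coordinate vector, or `NULL` for an empty mask.
#' @export
mask_centre_of_mass <- function(mask, largest_cluster_only = FALSE,
                                connectivity = 26) {
  stopifnot(is_volume(mask))
  sel <- mask$data > 0
  if (!any(sel)) return(NULL)
  if (largest_cluster_only) {
    lab <- label_components(sel, connectivity = connectivity)
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    sel <- lab == which.max(sizes)
  }
  ijk <- arrayInd(which(sel), dim(mask$data)) - 1L
  colMeans(voxel_to_mm(mask$affine, ijk))
}

#' Euclidean displacement between two mm points
#'
#' @param point_a_mm,point_b_mm length-3 coordinate vectors in mm.
#' @return Distance in mm.
#' @export
euclidean_displacement <- function(point_a_mm, point_b_mm) {
  stopifnot(length(point_a_mm) == 3, length(point_b_mm) == 3)
  sqrt(sum((as.numeric(point_a_mm) - as.numeric(point_b_mm))^2))
}

#' Write a cluster table as tab-delimited text
#'
#' @param clusters cluster data frame from [extract_clusters()].
#' @param path output path.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
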