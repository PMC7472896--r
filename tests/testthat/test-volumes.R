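test_that("NIfTI round trip preserves data, shape and affine", {
  set.seed(1)
  aff <- diag(c(2, 2.5, 3, 1)); aff[1:3, 4] <- c(-10, -20, -5)
  # dyadic fractions are exactly float32-representable, so the cast is lossless
  a <- array(sample(0:4096, 512, replace = TRUE) / 4096, c(8, 8, 8))
  v <- volume(a, aff, tag = "intensity")
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f, datatype = "float")
  r <- read_volume(f)
  expect_identical(dim(r$data), c(8L, 8L, 8L))
  expect_identical(r$data, a)
  expect_equal(r$affine, aff, ignore_attr = TRUE)
  b <- array(as.numeric(a > 0.5), c(8, 8, 8))
  write_volume(volume(b, aff, tag = "binary"), f, datatype = "uint8")
  expect_identical(read_volume(f, tag = "binary")$data, b)
  unlink(f)
})

test_that("reading a 4-D image fails naming the dimensionality", {
  f <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), "4-D")
  unlink(f)
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  expect_error(volume(array(0, c(3, 3, 3)), matrix(0, 4, 4)), "invertible")
})

test_that("volume tags enforce their value ranges", {
  expect_error(volume(array(2, c(2, 2, 2)), tag = "abnormality"), "\\[0, 1\\]")
  expect_error(volume(array(0.5, c(2, 2, 2)), tag = "binary"), "\\{0, 1\\}")
  expect_error(volume(array(-1, c(2, 2, 2)), tag = "label"), "non-negative")
  expect_silent(volume(array(0.5, c(2, 2, 2)), tag = "abnormality"))
})

test_that("gaussian smoothing: identity, constancy, closed-form impulse", {
  set.seed(2)
  v <- volume(array(runif(1000), c(10, 10, 10)), default_affine(c(10, 10, 10), 2))
  expect_identical(gaussian_smooth(v, 0)$data, v$data)
  const <- volume(array(3.5, c(10, 10, 10)), v$affine, tag = "stat")
  expect_lt(max(abs(gaussian_smooth(const, 8)$data - 3.5)), 1e-9)
  expect_error(gaussian_smooth(v, -1), "non-negative")
  # unit impulse on 1-mm voxels, fwhm 8: response equals the 3-D normal density
  g <- array(0, c(41, 41, 41)); g[21, 21, 21] <- 1
  s <- gaussian_smooth(volume(g, default_affine(c(41, 41, 41), 1), tag = "stat"), 8)
  sg <- 8 / sqrt(8 * log(2))
  for (d in list(c(0, 0, 0), c(3, 0, 0), c(2, 2, 1), c(0, 4, 3))) {
    expct <- (2 * pi * sg^2)^(-1.5) * exp(-sum(d^2) / (2 * sg^2))
    obs <- s$data[21 + d[1], 21 + d[2], 21 + d[3]]
    expect_lt(abs(obs - expct) / expct, 1e-6)
  }
  # total mass preserved under the reflective boundary
  expect_lt(abs(sum(gaussian_smooth(v, 8)$data) - sum(v$data)) / sum(v$data),
            1e-6)
})

test_that("gaussian smoothing commutes with translation in the interior", {
  set.seed(3)
  a <- array(0, c(20, 20, 20))
  a[8:12, 8:12, 8:12] <- runif(125)
  aff <- default_affine(c(20, 20, 20), 1)
  s1 <- gaussian_smooth(volume(a, aff, tag = "stat"), 4)$data
  b <- array(0, c(20, 20, 20)); b[9:13, 8:12, 8:12] <- a[8:12, 8:12, 8:12]
  s2 <- gaussian_smooth(volume(b, aff, tag = "stat"), 4)$data
  interior <- 6:14
  expect_lt(max(abs(s1[interior, interior, interior] -
                      s2[interior + 1, interior, interior])), 1e-9)
})

test_that("abnormality map follows the control-referenced normal CDF rule", {
  gs <- c(6, 6, 6)
  aff <- default_affine(gs, 2)
  set.seed(4)
  ctrl <- lapply(1:8, function(i)
    volume(array(rnorm(prod(gs), 10, 1), gs), aff))
  mu <- apply(vapply(ctrl, function(v) v$data, ctrl[[1]]$data), 1:3, mean)
  pat0 <- volume(mu, aff)
  expect_lt(max(abnormality_from_controls(pat0, ctrl)$data), 1e-12)
  # deviations of 1 and 2 control SDs give 2*pnorm(z) - 1
  sdv <- apply(vapply(ctrl, function(v) v$data, ctrl[[1]]$data), 1:3, sd)
  pat <- mu; pat[1, 1, 1] <- mu[1, 1, 1] + sdv[1, 1, 1]
  pat[2, 1, 1] <- mu[2, 1, 1] + 2 * sdv[2, 1, 1]
  pat[3, 1, 1] <- mu[3, 1, 1] - 10 * sdv[3, 1, 1]
  ab <- abnormality_from_controls(volume(pat, aff), ctrl)$data
  expect_equal(ab[1, 1, 1], 2 * pnorm(1) - 1, tolerance = 1e-10)
  expect_equal(ab[2, 1, 1], 2 * pnorm(2) - 1, tolerance = 1e-10)
  expect_gt(ab[2, 1, 1], ab[1, 1, 1])
  expect_gt(ab[3, 1, 1], 0.999)
  # invariant to adding a constant to patient and all controls
  ctrl_c <- lapply(ctrl, function(v) volume(v$data + 7, aff))
  ab2 <- abnormality_from_controls(volume(pat + 7, aff), ctrl_c)$data
  expect_equal(ab, ab2, tolerance = 1e-12)
  expect_error(abnormality_from_controls(pat0, ctrl[1:2]), "3 control")
  expect_error(abnormality_from_controls(
    volume(array(0, c(5, 5, 5)), aff), ctrl), "mismatch")
})

test_that("binarization applies the U-threshold and strict cluster extent", {
  gs <- c(30, 30, 30)
  aff <- default_affine(gs, 2)
  cfg <- lesion_config()
  empty <- binarize_lesion(volume(array(0, gs), aff, tag = "abnormality"), cfg)
  expect_equal(sum(empty$data), 0)
  # a 26-connected blob of exactly 100 voxels at 0.6 is removed; 101 retained
  a <- array(0, gs)
  a[as.matrix(expand.grid(1:4, 1:5, 1:5))] <- 0.6  # 100 voxels
  expect_equal(sum(binarize_lesion(volume(a, aff, tag = "abnormality"), cfg)$data), 0)
  a[5, 1, 1] <- 0.6                                 # 101st, 26-connected
  expect_equal(sum(binarize_lesion(volume(a, aff, tag = "abnormality"), cfg)$data), 101)
  # idempotent on its own output
  b1 <- binarize_lesion(volume(a, aff, tag = "abnormality"), cfg)
  b2 <- binarize_lesion(volume(b1$data, aff, tag = "abnormality"), cfg)
  expect_identical(b1$data, b2$data)
})

test_that("connected-component labelling matches a flood-fill oracle", {
  set.seed(5)
  for (conn in c(6, 18, 26)) {
    m <- array(runif(12^3) < 0.25, c(12, 12, 12))
    lab <- label_components(m, conn)
    ref <- flood_fill_labels(m, conn)
    expect_equal(max(lab), max(ref))
    # same partition up to label renaming
    key <- paste(lab[m], ref[m])
    expect_equal(length(unique(key)), max(ref))
  }
})

test_that("overlap map equals an explicit per-voxel summation", {
  set.seed(6)
  gs <- c(7, 7, 7)
  aff <- default_affine(gs, 2)
  vols <- lapply(1:5, function(i)
    volume(array(as.numeric(runif(prod(gs)) < 0.3), gs), aff, tag = "binary"))
  om <- overlap_map(vols)
  ref <- Reduce(`+`, lapply(vols, function(v) v$data))
  expect_identical(om$data, ref)
  expect_lte(max(om$data), 5)
  expect_identical(overlap_map(vols[c(1, 1)])$data, 2 * vols[[1]]$data)
  disj <- list(volume(array(c(1, rep(0, 7)), c(2, 2, 2)), diag(4), tag = "binary"),
               volume(array(c(0, 1, rep(0, 6)), c(2, 2, 2)), diag(4), tag = "binary"))
  expect_equal(max(overlap_map(disj)$data), 1)
})

test_that("cluster extraction: geometry, extent rule and partition property", {
  gs <- c(20, 20, 20)
  aff <- default_affine(gs, 2)
  a <- array(0, gs); a[4, 5, 6] <- 2
  ec <- extract_clusters(volume(a, aff, tag = "stat"), 1, min_cluster_voxels = 1)
  expect_equal(nrow(ec$clusters), 1)
  expect_equal(as.numeric(ec$clusters[1, c("com_x_mm", "com_y_mm", "com_z_mm")]),
               voxel_to_mm(aff, c(3, 4, 5)))
  expect_equal(ec$clusters$volume_mm3, 8)
  # 600-voxel and 150-voxel blobs, extent 500: only the large one survives
  b <- array(0, gs)
  b[as.matrix(expand.grid(1:10, 1:10, 1:6))] <- 5     # 600
  b[as.matrix(expand.grid(15:19, 15:19, 12:17))] <- 9 # 150, disjoint
  tab <- extract_clusters(volume(b, aff, tag = "stat"), 1,
                          min_cluster_voxels = 500)$clusters
  expect_equal(tab$n_voxels, 600)
  # symmetric two-voxel cluster: centre of mass at the midpoint
  cc <- array(0, gs); cc[10, 10, 10] <- 1; cc[11, 10, 10] <- 1
  com <- extract_clusters(volume(cc, aff, tag = "stat"), 0.5)$clusters
  expect_equal(as.numeric(com[1, c("com_x_mm", "com_y_mm", "com_z_mm")]),
               (voxel_to_mm(aff, c(9, 9, 9)) + voxel_to_mm(aff, c(10, 9, 9))) / 2)
  # partition: union of clusters = suprathreshold set; disjoint by construction
  set.seed(7)
  r <- array(rnorm(8000), gs)
  ecr <- extract_clusters(volume(r, aff, tag = "stat"), 1.5)
  expect_identical(ecr$mask$data > 0, r > 1.5)
  expect_equal(sum(ecr$clusters$n_voxels), sum(r > 1.5))
})

test_that("euclidean displacement is the mm L2 norm", {
  expect_equal(euclidean_displacement(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(euclidean_displacement(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(8)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(euclidean_displacement(a, b), sqrt(sum((a - b)^2)))
  expect_equal(euclidean_displacement(a, b), euclidean_displacement(b, a))
})

test_that("dice similarity counts overlap correctly", {
  gs <- c(10, 10, 2)
  aff <- diag(4)
  mk <- function(idx) {
    a <- array(0, gs); a[idx] <- 1
    volume(a, aff, tag = "binary")
  }
  expect_equal(dice(mk(1:50), mk(1:50)), 1)
  expect_equal(dice(mk(1:50), mk(51:100)), 0)
  expect_equal(dice(mk(1:100), mk(51:150)), 0.5)
  expect_warning(d0 <- dice(mk(integer(0)), mk(integer(0))), "empty")
  expect_equal(d0, 0)
})
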