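#' Optimal one-to-one assignment (Hungarian algorithm)
#'
#' Minimum-cost perfect matching of rows to columns of a square cost
#' matrix, by the shortest-augmenting-path (Jonker-Volgenant) formulation.
#' Used to match recovered lesion components to generating territories.
#'
#' @param cost square numeric cost matrix.
#' @return Integer vector: `result[i]` is the column assigned to row i.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) ans[p[j + 1]] <- j
  ans
}

#' Match lesion components to atlas territories by Dice overlap
#'
#' Thresholds each component's z map (two-sided, with the extent rule
#' expressed in mm^3), computes its Dice overlap with every territory, and
#' finds the one-to-one component-territory assignment maximizing total
#' Dice.
#'
#' @param solution a `component_solution` with as many components as
#'   territories.
#' @param lesion_matrix the `lesion_matrix` behind the solution.
#' @param atlas label [volume()] of territories.
#' @param z_cut two-sided z threshold (default 3.29).
#' @param min_cluster_mm3 extent rule in mm^3 (default 4000, i.e. the
#'   4 cm^3 component-map convention).
#' @return Data frame (territory, component, dice) with attribute
#'   `dice_matrix`.
#' @export
match_components_to_territories <- function(solution, lesion_matrix, atlas,
                                            z_cut = 3.29,
                                            min_cluster_mm3 = 4000) {
  labs <- sort(unique(atlas$data[atlas$data > 0]))
  stopifnot(solution$k == length(labs))
  minvox <- max(1L, round(min_cluster_mm3 / voxel_volume(lesion_matrix$affine)))
  maps <- component_maps(solution, lesion_matrix, z_cut = z_cut,
                         min_cluster_voxels = minvox)
  D <- matrix(0, length(labs), solution$k,
              dimnames = list(paste0("territory_", labs),
                              paste0("comp_", seq_len(solution$k))))
  for (t in seq_along(labs)) {
    tm <- volume(array(as.numeric(atlas$data == labs[t]), dim(atlas$data)),
                 atlas$affine, tag = "binary")
    for (j in seq_len(solution$k))
      D[t, j] <- suppressWarnings(dice(tm, maps[[j]]$mask))
  }
  assign <- hungarian_assignment(-D)
  out <- data.frame(territory = labs, component = assign,
                    dice = D[cbind(seq_along(labs), assign)])
  attr(out, "dice_matrix") <- D
  out
}
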