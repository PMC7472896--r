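#' Label connected components of a 3-D logical array
#'
#' Voxels are adjacent under a 6 (faces), 18 (faces + edges) or 26 (faces +
#' edges + corners) neighbourhood. Component labels start at 1; background
#' voxels get 0. Label order is arbitrary.
#'
#' @param mask logical or 0/1 numeric 3-D array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the same shape.
#' @export
label_components <- function(mask, connectivity = 26) {
  if (is_volume(mask)) mask <- mask$data
  stopifnot(length(dim(mask)) == 3, connectivity %in% c(6, 18, 26))
  d <- dim(mask)
  sel <- which(mask > 0)
  out <- array(0L, d)
  n <- length(sel)
  if (n == 0L) return(out)
  offs <- connectivity_offsets(connectivity)
  pos <- integer(prod(d))           # linear index -> rank among selected
  pos[sel] <- seq_len(n)
  ijk <- arrayInd(sel, d)
  edges <- vector("list", nrow(offs))
  for (r in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[r, ], "+")
    ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
          nb[, 2] >= 1L & nb[, 2] <= d[2] &
          nb[, 3] >= 1L & nb[, 3] <= d[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1L) * d[1] * d[2] + (nb[ok, 2] - 1L) * d[1] + nb[ok, 1]
    hit <- pos[lin] > 0L
    if (!any(hit)) next
    edges[[r]] <- cbind(which(ok)[hit], pos[lin[hit]])
  }
  el <- do.call(rbind, edges)
  if (is.null(el) || nrow(el) == 0L) {
    out[sel] <- seq_len(n)
    return(out)
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out[sel] <- as.integer(memb)
  out
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6)  g <- g[rowSums(abs(g)) == 1, , drop = FALSE]
  if (connectivity == 18) g <- g[rowSums(abs(g)) <= 2, , drop = FALSE]
  # keep one of each +/- pair: edges are undirected
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

#' Brain mask helper
#'
#' Wraps a binary volume as the analysis mask and records its voxel count;
#' all matrix-based analyses restrict to in-mask voxels.
#'
#' @param mask binary [volume()].
#' @return A `brain_mask` list with fields `mask`, `n_voxels`, `index`
#'   (linear indices of in-mask voxels, fixed column order for lesion
#'   matrices).
#' @export
brain_mask <- function(mask) {
  stopifnot(is_volume(mask))
  idx <- which(mask$data > 0)
  if (length(idx) == 0L) stop("brain mask is empty")
  structure(list(mask = mask, n_voxels = length(idx), index = idx),
            class = "brain_mask")
}

#' Dice similarity between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks give 0 with a warning (the
#' score is undefined there).
#'
#' @param mask_a,mask_b binary [volume()]s on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(is_volume(mask_a), is_volume(mask_b))
  if (!all(dim(mask_a$data) == dim(mask_b$data)))
    stop("grid mismatch in dice()")
  a <- mask_a$data > 0; b <- mask_b$data > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    warning("both masks empty; Dice undefined, returning 0")
    return(0)
  }
  2 * sum(a & b) / denom
}
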