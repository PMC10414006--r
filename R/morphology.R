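# 3D binary morphology on logical arrays. Neuroimaging masks at the sizes used
# here fit comfortably in memory, so all operations are expressed as whole-array
# shifts rather than per-voxel loops. Out-of-bounds voxels are background.

neighbourhood_offsets <- function(connectivity = 26L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) {
    stop("`connectivity` must be 6 or 26", call. = FALSE)
  }
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# result[i,j,k] = x[i+d1, j+d2, k+d3], out-of-bounds filled with `fill`
shift_array <- function(x, d, fill = FALSE) {
  n <- dim(x)
  out <- array(fill, dim = n)
  rng <- function(nn, dd) {
    lo <- max(1L, 1L - dd); hi <- min(nn, nn - dd)
    if (lo > hi) integer(0) else lo:hi
  }
  r1 <- rng(n[1L], d[1L]); r2 <- rng(n[2L], d[2L]); r3 <- rng(n[3L], d[3L])
  if (!length(r1) || !length(r2) || !length(r3)) return(out)
  out[r1, r2, r3] <- x[r1 + d[1L], r2 + d[2L], r3 + d[3L]]
  out
}

check_mask3d <- function(mask) {
  if (!is.logical(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a logical 3D array", call. = FALSE)
  }
  invisible(mask)
}

#' Erode a binary mask by one voxel
#'
#' A voxel survives erosion iff its whole structuring-element neighbourhood is
#' inside the mask; voxels outside the volume count as background, so the mask
#' also retreats from the volume faces. The default structuring element is the
#' full 3x3x3 cube (26-neighbourhood); `"cross"` uses the 6-neighbourhood
#' face-adjacent cross instead.
#'
#' @param mask Logical 3D array.
#' @param kernel `"cube"` (3x3x3, default) or `"cross"` (face neighbours only).
#' @return Logical 3D array of the same dimensions.
#' @export
#' @examples
#' m <- array(TRUE, c(3, 3, 3))
#' which(erode_one_voxel(m))  # only the centre voxel survives
erode_one_voxel <- function(mask, kernel = c("cube", "cross")) {
  check_mask3d(mask)
  kernel <- match.arg(kernel)
  offs <- neighbourhood_offsets(if (kernel == "cube") 26L else 6L)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    out <- out & shift_array(mask, offs[r, ], fill = FALSE)
    if (!any(out)) break
  }
  out
}

#' Dilate a binary mask by one voxel
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 (default) or 6; which neighbours receive the dilation.
#' @return Logical 3D array of the same dimensions.
#' @export
dilate_one_voxel <- function(mask, connectivity = 26L) {
  check_mask3d(mask)
  offs <- neighbourhood_offsets(connectivity)
  out <- mask
  for (r in seq_len(nrow(offs))) {
    out <- out | shift_array(mask, offs[r, ], fill = FALSE)
  }
  out
}

#' One-voxel outer boundary band of a lesion mask
#'
#' The set of voxels in direct contact with the lesion but not part of it:
#' the 26-neighbourhood dilation minus the mask itself. `radius > 1` repeats
#' the dilation before subtracting, giving a thicker contact band.
#'
#' @param mask Logical 3D array (the lesion).
#' @param radius Band thickness in voxels (default 1).
#' @param connectivity 26 (default) or 6.
#' @return Logical 3D array, disjoint from `mask`.
#' @export
#' @examples
#' m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
#' sum(outer_band(m))  # the 26 neighbours of the centre voxel
outer_band <- function(mask, radius = 1L, connectivity = 26L) {
  check_mask3d(mask)
  stopifnot_scalar_number(radius, "radius", lower = 1)
  dil <- mask
  for (i in seq_len(radius)) dil <- dilate_one_voxel(dil, connectivity)
  dil & !mask
}

#' Label connected components of a binary 3D mask
#'
#' Maximal connected voxel sets under the requested neighbourhood. Component
#' labels are assigned deterministically in raster-scan order: the component
#' containing the smallest flat index gets label 1, and so on, making outputs
#' bit-reproducible.
#'
#' @param mask Logical 3D array.
#' @param connectivity 26 (corner-touching voxels connect, default) or 6
#'   (face-adjacent only).
#' @return Integer 3D array; 0 outside the mask, component labels 1..n inside.
#' @export
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE
#' max(label_components(m, connectivity = 26))  # corner contact: 1 component
#' max(label_components(m, connectivity = 6))   # 2 components
label_components <- function(mask, connectivity = 26L) {
  check_mask3d(mask)
  n <- dim(mask)
  sel <- which(mask)
  out <- array(0L, dim = n)
  if (length(sel) == 0L) return(out)

  # adjacency as an edge list between selected voxels, built from half the
  # neighbourhood (each unordered pair found once)
  offs <- neighbourhood_offsets(connectivity)
  offs <- offs[offs[, 3L] > 0L |
                 (offs[, 3L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L),
               , drop = FALSE]
  rank_of <- array(0L, dim = n)
  rank_of[sel] <- seq_along(sel)
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    d <- offs[r, ]
    both <- mask & shift_array(mask, d, fill = FALSE)
    i <- which(both)
    if (length(i)) {
      flat_off <- d[1L] + d[2L] * n[1L] + d[3L] * n[1L] * n[2L]
      edges_from <- c(edges_from, rank_of[i])
      edges_to <- c(edges_to, rank_of[i + flat_off])
    }
  }
  g <- igraph::make_empty_graph(n = length(sel), directed = FALSE)
  if (length(edges_from)) {
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  }
  comp <- igraph::components(g)$membership
  # relabel in raster-scan order of first occurrence (sel is already sorted)
  relabel <- integer(max(comp))
  first_seen <- !duplicated(comp)
  relabel[comp[first_seen]] <- seq_len(sum(first_seen))
  out[sel] <- relabel[comp]
  out
}
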