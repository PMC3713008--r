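#' Tissue of interest (TOI)
#'
#' A named region on the imaging grid, carrying the tissue class used by the
#' group statistics (enhancing lesion `EL`, non-enhancing lesion `NEL`,
#' normal-appearing white matter `NAWM`, or `OTHER`). Masks are stored as 3D
#' logical arrays `(slice, row, col)`; a 2D mask is accepted together with
#' `slice_index` and expanded internally.
#'
#' By convention the contours the classes are drawn on differ: `NEL` contours
#' are drawn during the baseline period, `EL` at the end of reperfusion and
#' `NAWM` during inflow (`definition_interval` records this; it does not
#' affect computation, the same mask is reused at every time point).
#'
#' @param label Region identifier (unique within a TOI set).
#' @param tissue_class One of `"NAWM"`, `"EL"`, `"NEL"`, `"OTHER"`.
#' @param mask Logical matrix `(row, col)` or 3D logical array
#'   `(slice, row, col)` with at least one `TRUE` voxel.
#' @param slice_index Slice the contour lives on (required for 2D masks).
#' @param definition_interval Interval the contour was drawn in
#'   (`"BLP"`, `"IFP"`, `"OFP"` or `"RPP"`).
#' @return An object of class `toi`.
#' @examples
#' m <- matrix(FALSE, 8, 8); m[3:5, 3:5] <- TRUE
#' toi("lesion1", "EL", m, slice_index = 1)
#' @export
toi <- function(label, tissue_class, mask, slice_index = NULL,
                definition_interval = NULL) {
  tissue_class <- match.arg(tissue_class, TISSUE_CLASSES)
  if (is.matrix(mask)) {
    if (is.null(slice_index))
      stop("2D TOI masks need `slice_index`")
    mask <- array(mask, dim = c(1L, dim(mask)))
    mask3 <- mask
  } else if (is.array(mask) && length(dim(mask)) == 3L) {
    mask3 <- mask
  } else {
    stop("`mask` must be a logical matrix or 3D array")
  }
  storage.mode(mask3) <- "logical"
  if (!any(mask3)) stop("TOI mask must contain at least one voxel")
  if (is.null(definition_interval))
    definition_interval <- switch(tissue_class,
                                  NEL = "BLP", EL = "RPP", NAWM = "IFP",
                                  OTHER = "IFP")
  structure(
    list(label = label, tissue_class = tissue_class, mask = mask3,
         slice_index = slice_index,
         definition_interval = match.arg(definition_interval, INTERVALS)),
    class = "toi")
}

#' @export
print.toi <- function(x, ...) {
  cat(sprintf("<toi> '%s' (%s), %d voxel(s)\n",
              x$label, x$tissue_class, sum(x$mask)))
  invisible(x)
}

# Expand a TOI mask to the spatial grid of a series (2D masks are placed on
# their slice). Errors if shapes are incompatible.
toi_mask_on_grid <- function(toi, spatial) {
  m <- toi$mask
  d <- dim(m)
  if (identical(unname(d), unname(as.integer(spatial)))) return(m)
  if (d[1] == 1L && !is.null(toi$slice_index) &&
      identical(unname(d[2:3]), unname(as.integer(spatial[2:3])))) {
    out <- array(FALSE, dim = spatial)
    out[toi$slice_index, , ] <- m[1L, , ]
    return(out)
  }
  stop(sprintf("TOI '%s' mask shape (%s) does not match the series grid (%s)",
               toi$label, paste(d, collapse = "x"),
               paste(spatial, collapse = "x")))
}

#' Test voxel centers against a closed polygon (even-odd rule)
#'
#' Vectorised point-in-polygon test used to rasterise contour TOIs. A voxel
#' belongs to the region when its center lies strictly inside the polygon
#' under the even-odd (ray crossing) rule, or exactly on a polygon edge
#' (boundary-inclusive convention, so integer-vertex rectangles keep their
#' corner voxels).
#'
#' @param pr,pc Numeric vectors of point (row, col) coordinates, 0-based voxel
#'   units at voxel centers.
#' @param vr,vc Numeric vectors of polygon vertex (row, col) coordinates
#'   (closed implicitly; at least 3 vertices).
#' @return Logical vector, one entry per point.
#' @export
point_in_polygon <- function(pr, pc, vr, vc) {
  n <- length(vr)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  if (length(vc) != n) stop("vertex coordinate vectors differ in length")
  inside <- rep(FALSE, length(pr))
  on_edge <- rep(FALSE, length(pr))
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    r1 <- vr[j]; c1 <- vc[j]; r2 <- vr[i]; c2 <- vc[i]
    # edge crossing for a ray in +col direction
    crosses <- ((r1 > pr) != (r2 > pr))
    if (any(crosses)) {
      cx <- c1 + (pr - r1) / (r2 - r1) * (c2 - c1)
      inside[crosses] <- xor(inside[crosses], pc[crosses] < cx[crosses])
    }
    # point exactly on the (closed) segment?
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr * dr + dc * dc
    if (len2 > 0) {
      t <- ((pr - r1) * dr + (pc - c1) * dc) / len2
      perp <- abs((pr - r1) * dc - (pc - c1) * dr) / sqrt(len2)
      on_edge <- on_edge | (perp < eps & t > -eps & t < 1 + eps)
    } else {
      on_edge <- on_edge | (abs(pr - r1) < eps & abs(pc - c1) < eps)
    }
    j <- i
  }
  inside | on_edge
}

#' Rasterise a polygon contour into a TOI mask
#'
#' @param vertices Two-column matrix of polygon vertices `(row, col)` in
#'   0-based voxel coordinates.
#' @param nrow,ncol Grid size of the slice.
#' @inheritParams toi
#' @return A [toi] with a 2D mask on `slice_index`.
#' @export
toi_from_polygon <- function(label, tissue_class, vertices, nrow, ncol,
                             slice_index = 1L, definition_interval = NULL) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L)
    stop(sprintf("TOI '%s': a polygon needs at least 3 vertices", label))
  centers <- expand.grid(r = seq_len(nrow) - 1L, c = seq_len(ncol) - 1L)
  inside <- point_in_polygon(centers$r, centers$c, vertices[, 1], vertices[, 2])
  mask <- matrix(FALSE, nrow, ncol)
  mask[cbind(centers$r + 1L, centers$c + 1L)] <- inside
  toi(label, tissue_class, mask, slice_index = slice_index,
      definition_interval = definition_interval)
}
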