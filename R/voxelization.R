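#' Construct a voxel grid from a logical occupancy array
#'
#' Low-level constructor shared by [build_grid()] and [generate_grid()].
#' Occupied voxels are classified by 6-connectivity (face adjacency):
#' a voxel is SURFACE when at least one of its six face neighbours is
#' exterior (out-of-bounds counts as exterior), INTERIOR otherwise.
#'
#' Voxel index `(i, j, k)` (1-based) maps to the Cartesian centre
#' `origin + spacing * (c(i, j, k) - 1)`; `origin` is the centre of voxel
#' `(1, 1, 1)`.
#'
#' @param occupancy Logical 3-d array, `TRUE` = occupied.
#' @param origin Numeric length-3, centre of voxel (1,1,1) in Angstrom.
#' @param spacing Voxel edge length in Angstrom (> 0).
#' @return Object of class `voxel_grid`: list with `origin`, `spacing`,
#'   `dims`, and `label` (integer array; see [voxel_labels()]).
#' @export
voxel_grid <- function(occupancy, origin = c(0, 0, 0), spacing = 1) {
  stopifnot(is.array(occupancy), length(dim(occupancy)) == 3L,
            is.logical(occupancy), length(origin) == 3L, spacing > 0)
  d <- dim(occupancy)
  ext_nb <- array(FALSE, d)
  # +x / -x / +y / -y / +z / -z face neighbours; boundary faces see exterior
  ext <- !occupancy
  f <- array(FALSE, d); f[d[1], , ] <- TRUE
  f[-d[1], , ] <- ext[-1, , ];            ext_nb <- ext_nb | f
  f <- array(FALSE, d); f[1, , ] <- TRUE
  f[-1, , ] <- ext[-d[1], , ];            ext_nb <- ext_nb | f
  f <- array(FALSE, d); f[, d[2], ] <- TRUE
  f[, -d[2], ] <- ext[, -1, ];            ext_nb <- ext_nb | f
  f <- array(FALSE, d); f[, 1, ] <- TRUE
  f[, -1, ] <- ext[, -d[2], ];            ext_nb <- ext_nb | f
  f <- array(FALSE, d); f[, , d[3]] <- TRUE
  f[, , -d[3]] <- ext[, , -1];            ext_nb <- ext_nb | f
  f <- array(FALSE, d); f[, , 1] <- TRUE
  f[, , -1] <- ext[, , -d[3]];            ext_nb <- ext_nb | f
  label <- array(VOX_EXTERIOR, d)
  label[occupancy & ext_nb] <- VOX_SURFACE
  label[occupancy & !ext_nb] <- VOX_INTERIOR
  structure(list(origin = as.numeric(origin), spacing = as.numeric(spacing),
                 dims = d, label = label),
            class = "voxel_grid")
}

#' Voxelize a structure onto a van der Waals occupancy grid
#'
#' A voxel is occupied iff its centre lies within the van der Waals sphere
#' of at least one atom (centre-inside convention).  The grid bounding box
#' covers every atom sphere plus `padding` on all sides, and the origin is
#' snapped to an integer multiple of `spacing` so that integer-translated
#' inputs produce index-translated grids.
#'
#' @param structure A `pdb_structure` with radii assigned.
#' @param spacing Grid resolution in Angstrom (default 1.0).
#' @param padding Clearance around the atom spheres, Angstrom.  Must be at
#'   least as large as the largest virtual-sphere radius used downstream
#'   (default 10, matching the cavity-volume probe radius).
#' @return A [voxel_grid()].
#' @export
build_grid <- function(structure, spacing = 1.0, padding = 10) {
  stopifnot(inherits(structure, "pdb_structure"))
  if (spacing <= 0) stop("spacing must be > 0")
  if (padding < 0) stop("padding must be >= 0")
  atoms <- structure$atoms
  if (nrow(atoms) == 0L) stop("structure has no atoms")
  if (any(is.na(atoms$radius))) stop("radii not assigned; see assign_radii()")
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$radius
  lo <- floor((apply(pos - r, 2, min) - padding) / spacing) * spacing
  hi <- ceiling((apply(pos + r, 2, max) + padding) / spacing) * spacing
  dims <- as.integer(round((hi - lo) / spacing)) + 1L
  occ <- array(FALSE, dims)
  ax_centers <- lapply(1:3, function(a) lo[a] + spacing * (seq_len(dims[a]) - 1))
  for (n in seq_len(nrow(pos))) {
    p <- pos[n, ]; ra <- r[n]
    idx <- lapply(1:3, function(a) {
      which(abs(ax_centers[[a]] - p[a]) <= ra)
    })
    if (any(lengths(idx) == 0L)) next
    dx2 <- (ax_centers[[1]][idx[[1]]] - p[1])^2
    dy2 <- (ax_centers[[2]][idx[[2]]] - p[2])^2
    dz2 <- (ax_centers[[3]][idx[[3]]] - p[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ra^2
    occ[idx[[1]], idx[[2]], idx[[3]]] <-
      occ[idx[[1]], idx[[2]], idx[[3]]] | inside
  }
  voxel_grid(occ, origin = lo, spacing = spacing)
}

#' Surface voxel indices of a grid
#'
#' @param grid A [voxel_grid()].
#' @return Integer matrix (n x 3) of 1-based voxel indices, in
#'   column-major order.
#' @export
classify_surface <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  which(grid$label == VOX_SURFACE, arr.ind = TRUE, useNames = FALSE)
}

#' Cartesian centres of voxels
#'
#' @param grid A [voxel_grid()].
#' @param idx Integer matrix (n x 3) of voxel indices.
#' @return Numeric matrix (n x 3) of centres in Angstrom.
#' @export
voxel_centers <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"))
  idx <- rbind(idx)
  sweep(sweep(idx, 2, 1) * grid$spacing, 2, grid$origin, "+")
}

# linear (column-major) index of voxel rows
lin_index <- function(dims, idx) {
  idx[, 1L] + (idx[, 2L] - 1L) * dims[1L] +
    (idx[, 3L] - 1L) * dims[1L] * dims[2L]
}

#' @export
print.voxel_grid <- function(x, ...) {
  tab <- tabulate(as.integer(x$label) + 1L, nbins = 3L)
  cat("<voxel_grid> ", paste(x$dims, collapse = " x "),
      " voxels @ ", x$spacing, " Angstrom\n",
      "  exterior ", tab[1], " | interior ", tab[2],
      " | surface ", tab[3], "\n", sep = "")
  invisible(x)
}

#' Dump a grid to a plain-text debug file
#'
#' Writes a JSON header (origin, spacing, dims, label codes) and the label
#' array flattened in column-major order, one value per line.
#'
#' @param grid A [voxel_grid()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  header <- jsonlite::toJSON(
    list(origin = grid$origin, spacing = grid$spacing, dims = grid$dims,
         labels = as.list(voxel_labels())),
    auto_unbox = TRUE, digits = NA)
  writeLines(c(as.character(header), as.character(as.integer(grid$label))),
             path)
  invisible(path)
}
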