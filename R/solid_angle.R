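#' Integer lattice offsets inside a sphere
#'
#' All integer voxel offsets whose centres lie within `radius` of the
#' origin voxel centre (inclusive, with a tiny tolerance so that exact
#' lattice distances such as 6.0 at spacing 1 are kept regardless of
#' floating-point representation).
#'
#' @param radius Sphere radius in Angstrom.
#' @param spacing Grid spacing in Angstrom.
#' @return Integer matrix (n x 3) of offsets; `(0, 0, 0)` is included.
#' @export
sphere_offsets <- function(radius, spacing = 1) {
  stopifnot(radius >= 0, spacing > 0)
  r <- floor(radius / spacing + 1e-9)
  s <- seq.int(-r, r)
  g <- as.matrix(expand.grid(i = s, j = s, k = s, KEEP.OUT.ATTRS = FALSE))
  keep <- (g[, 1]^2 + g[, 2]^2 + g[, 3]^2) * spacing^2 <= radius^2 + 1e-9
  g[keep, , drop = FALSE]
}

# shared final formula: counts -> steradians.  Kept as one function so the
# scalar and vectorized paths are bit-identical.
sa_from_counts <- function(n_interior, n_surface, n_total, surface_weight) {
  (n_interior + surface_weight * n_surface) / n_total * (4 * pi)
}

check_sphere_fits <- function(grid, idx, off) {
  rng_off <- apply(off, 2, range)
  rng_idx <- apply(rbind(idx), 2, range)
  if (any(rng_idx[1, ] + rng_off[1, ] < 1L) ||
      any(rng_idx[2, ] + rng_off[2, ] > grid$dims)) {
    stop("virtual sphere extends beyond the grid for at least one surface ",
         "voxel; rebuild the grid with padding >= sphere radius")
  }
}

#' Solid angle at one surface voxel
#'
#' Estimates the solid angle (steradians) subtended by the protein body at
#' a surface voxel as `4*pi` times the occupied fraction of a virtual
#' sphere centred on the voxel: buried (interior) voxels count fully and
#' surface voxels count with weight `surface_weight`.
#'
#' The default `surface_weight = 0.5` is a boundary correction: a surface
#' voxel's centre sits half a voxel below the true interface, and the
#' discrete boundary layer would otherwise be counted entirely as solid,
#' biasing a flat face from `2*pi` up to about `2.25*pi` at 1 Angstrom
#' spacing.  Half-weighting the boundary layer restores the flat-face value
#' `2*pi`, the convex cube corner `pi/2` and edge `pi`, and exact
#' complementarity (two shapes that fit together have solid angles summing
#' to `4*pi`).  Set `surface_weight = 1` for the raw occupied-voxel count.
#'
#' The virtual sphere must lie entirely inside the grid (guaranteed by
#' `build_grid(padding >= radius)`); otherwise an error is raised rather
#' than silently clipping the sphere.
#'
#' @param grid A [voxel_grid()].
#' @param voxel Integer length-3 voxel index; must be a SURFACE voxel.
#' @param radius Virtual sphere radius in Angstrom (default 6).
#' @param surface_weight Weight of surface voxels in the occupied count.
#' @return Solid angle in steradians, in `[0, 4*pi]`.
#' @export
solid_angle_at <- function(grid, voxel, radius = 6, surface_weight = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"), length(voxel) == 3L,
            radius > grid$spacing)
  voxel <- as.integer(voxel)
  if (grid$label[voxel[1], voxel[2], voxel[3]] != VOX_SURFACE) {
    stop("voxel (", paste(voxel, collapse = ","), ") is not a surface voxel")
  }
  off <- sphere_offsets(radius, grid$spacing)
  check_sphere_fits(grid, matrix(voxel, 1L), off)
  labs <- grid$label[sweep(off, 2, voxel, "+")]
  sa_from_counts(sum(labs == VOX_INTERIOR), sum(labs == VOX_SURFACE),
                 nrow(off), surface_weight)
}

#' Solid angles of all surface voxels
#'
#' Vectorized map over the surface voxel set; results are bit-identical to
#' calling [solid_angle_at()] on each voxel (the same integer counts feed
#' the same final expression) and independent of any batching.
#'
#' @inheritParams solid_angle_at
#' @return Object of class `solid_angle_map`: a data frame with columns
#'   `i`, `j`, `k` (voxel index), `x`, `y`, `z` (centre, Angstrom), and
#'   `sa` (steradians), one row per surface voxel, plus attributes
#'   `radius`, `surface_weight`, `spacing`, `origin`, `dims`.
#' @export
solid_angle_all <- function(grid, radius = 6, surface_weight = 0.5) {
  stopifnot(inherits(grid, "voxel_grid"), radius > grid$spacing)
  surf <- classify_surface(grid)
  off <- sphere_offsets(radius, grid$spacing)
  n_surf_vox <- nrow(surf)
  if (n_surf_vox == 0L) {
    sa <- numeric(0)
    out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      sa = sa)
  } else {
    check_sphere_fits(grid, surf, off)
    labv <- as.integer(grid$label)
    slin <- lin_index(grid$dims, surf)
    doff <- off[, 1L] + off[, 2L] * grid$dims[1L] +
      off[, 3L] * grid$dims[1L] * grid$dims[2L]
    n_int <- integer(n_surf_vox)
    n_sur <- integer(n_surf_vox)
    for (d in doff) {
      v <- labv[slin + d]
      n_int <- n_int + (v == VOX_INTERIOR)
      n_sur <- n_sur + (v == VOX_SURFACE)
    }
    sa <- sa_from_counts(n_int, n_sur, nrow(off), surface_weight)
    ctr <- voxel_centers(grid, surf)
    out <- data.frame(i = surf[, 1], j = surf[, 2], k = surf[, 3],
                      x = ctr[, 1], y = ctr[, 2], z = ctr[, 3], sa = sa)
  }
  structure(out,
            class = c("solid_angle_map", "data.frame"),
            radius = radius, surface_weight = surface_weight,
            spacing = grid$spacing, origin = grid$origin, dims = grid$dims)
}

#' Map surface solid angles onto atoms as B-factors
#'
#' Assigns each surface voxel to its nearest atom and writes the mean solid
#' angle of each atom's voxels into the B-factor column, for visual
#' inspection of convex (low) versus concave (high) surface regions in any
#' molecular viewer.  Atoms with no assigned surface voxel get 0.
#'
#' @param structure A `pdb_structure`.
#' @param sa_map A [solid_angle_all()] result for the structure's grid.
#' @param path Optional output PDB path.
#' @return Invisibly, the PDB lines (see [write_pdb()]).
#' @export
solid_angle_to_bfactor <- function(structure, sa_map, path = NULL) {
  stopifnot(inherits(structure, "pdb_structure"),
            inherits(sa_map, "solid_angle_map"))
  pos <- as.matrix(structure$atoms[, c("x", "y", "z")])
  vox <- as.matrix(sa_map[, c("x", "y", "z")])
  b <- rep(0, nrow(pos))
  if (nrow(vox) > 0L) {
    nearest <- integer(nrow(vox))
    for (m in seq_len(nrow(vox))) {
      d2 <- (pos[, 1] - vox[m, 1])^2 + (pos[, 2] - vox[m, 2])^2 +
        (pos[, 3] - vox[m, 3])^2
      nearest[m] <- which.min(d2)
    }
    means <- tapply(sa_map$sa, nearest, mean)
    b[as.integer(names(means))] <- as.numeric(means)
  }
  write_pdb(structure, path, bfactor = b)
}
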