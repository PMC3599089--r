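#' Discretized cavity-depth indicator of a solid angle
#'
#' Step transform from solid angle (steradians) to an integer depth bin:
#' 5 for `sa > 0.9 * 4pi`, then 4, 3, 2, 1 for each successive 10-percent
#' band down to `0.5 * 4pi`, and -1 otherwise (flat or convex).  Each band
#' boundary belongs to the lower bin (e.g. exactly `0.9 * 4pi` maps to 4).
#' Comparisons use a relative tolerance of 1e-12 so that a boundary value
#' computed by any algebraically equivalent expression lands in the lower
#' bin.
#'
#' @param sa Numeric vector of solid angles, each in `[0, 4pi]`.
#' @return Integer vector of depth values in `{5, 4, 3, 2, 1, -1}`.
#' @export
#' @examples
#' depth_of(0.95 * 4 * pi)  # 5
#' depth_of(0.9 * 4 * pi)   # 4 (boundary belongs to the lower bin)
depth_of <- function(sa) {
  tol <- 4 * pi * 1e-12
  if (any(sa < -tol | sa > 4 * pi + tol)) {
    stop("solid angle outside [0, 4*pi]")
  }
  d <- rep(-1L, length(sa))
  for (step in 1:5) {
    d[sa > (0.4 + 0.1 * step) * (4 * pi) + tol] <- step
  }
  d
}

#' Average depth indicator of a cluster
#'
#' Applies [depth_of()] to every member's solid angle and averages,
#' including any -1 values (a cluster dominated by flat or convex voxels
#' gets a negative average and will rank last).
#'
#' @param cluster A `pocket_cluster`.
#' @return Object of class `depth_indicator`: list with `per_voxel`
#'   (integer vector, one per member, in member order) and `average`.
#' @export
average_depth <- function(cluster) {
  stopifnot(inherits(cluster, "pocket_cluster"))
  per <- depth_of(cluster$members$sa)
  structure(list(per_voxel = per, average = mean(per)),
            class = "depth_indicator")
}

# the 7 bi-directional scan lines: 3 axes + 4 body diagonals
ray_directions <- function() {
  rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
        c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(-1L, 1L, 1L))
}

# does the ray from `voxel` in integer-step direction `d` hit an occupied
# voxel before leaving the grid?
ray_blocked <- function(label, dims, voxel, d) {
  steps <- Inf
  for (a in 1:3) {
    if (d[a] > 0L) steps <- min(steps, dims[a] - voxel[a])
    if (d[a] < 0L) steps <- min(steps, voxel[a] - 1L)
  }
  if (steps < 1) return(FALSE)
  t <- seq_len(steps)
  idx <- cbind(voxel[1] + t * d[1], voxel[2] + t * d[2], voxel[3] + t * d[3])
  any(label[idx] != VOX_EXTERIOR)
}

#' Number of interior directional lines through an empty voxel
#'
#' For each of the 7 bi-directional lines through the voxel (the 3 axis
#' directions and the 4 body diagonals, marched in unit index steps), the
#' line counts as interior iff stepping in BOTH of its directions hits an
#' occupied voxel before leaving the grid.  A ray that exits the (padded)
#' grid is open to solvent and does not count.
#'
#' @param grid A [voxel_grid()].
#' @param voxel Integer length-3 index of an EXTERIOR (empty) voxel.
#' @return Integer in `[0, 7]`.
#' @export
interior_direction_count <- function(grid, voxel) {
  stopifnot(inherits(grid, "voxel_grid"), length(voxel) == 3L)
  voxel <- as.integer(voxel)
  if (grid$label[voxel[1], voxel[2], voxel[3]] != VOX_EXTERIOR) {
    stop("voxel (", paste(voxel, collapse = ","),
         ") is occupied; interior directions are defined for empty voxels")
  }
  dirs <- ray_directions()
  n <- 0L
  for (r in seq_len(nrow(dirs))) {
    d <- dirs[r, ]
    if (ray_blocked(grid$label, grid$dims, voxel, d) &&
        ray_blocked(grid$label, grid$dims, voxel, -d)) {
      n <- n + 1L
    }
  }
  n
}

#' Cavity-volume indicator at an anchor voxel
#'
#' Counts the empty voxels whose centres lie within `probe_radius` of the
#' anchor centre and that have at least `min_directions` of their 7
#' bi-directional lines blocked by protein on both sides
#' ([interior_direction_count()]).  The count of such "enclosed" empty
#' voxels is the cavity-volume indicator (a voxel count, not Angstrom^3).
#'
#' @param grid A [voxel_grid()].
#' @param anchor Integer length-3 index of a SURFACE voxel.
#' @param probe_radius Virtual sphere radius in Angstrom (default 10).
#' @param min_directions Minimum interior lines for a voxel to count
#'   (default 4 of 7).
#' @return Object of class `volume_indicator`: list with `voxel_count`,
#'   `probe_radius`, `min_directions`, and `members` (n x 3 index matrix of
#'   the counted voxels).
#' @export
cavity_volume <- function(grid, anchor, probe_radius = 10,
                          min_directions = 4L) {
  stopifnot(inherits(grid, "voxel_grid"), length(anchor) == 3L,
            probe_radius >= 0, min_directions >= 0)
  anchor <- as.integer(anchor)
  if (grid$label[anchor[1], anchor[2], anchor[3]] != VOX_SURFACE) {
    stop("anchor (", paste(anchor, collapse = ","),
         ") is not a surface voxel")
  }
  off <- sphere_offsets(probe_radius, grid$spacing)
  cand <- sweep(off, 2, anchor, "+")
  inb <- cand[, 1] >= 1L & cand[, 1] <= grid$dims[1] &
    cand[, 2] >= 1L & cand[, 2] <= grid$dims[2] &
    cand[, 3] >= 1L & cand[, 3] <= grid$dims[3]
  cand <- cand[inb, , drop = FALSE]
  empty <- grid$label[cand] == VOX_EXTERIOR
  cand <- cand[empty, , drop = FALSE]
  ok <- logical(nrow(cand))
  for (r in seq_len(nrow(cand))) {
    ok[r] <- interior_direction_count(grid, cand[r, ]) >= min_directions
  }
  structure(list(voxel_count = sum(ok), probe_radius = probe_radius,
                 min_directions = as.integer(min_directions),
                 members = cand[ok, , drop = FALSE]),
            class = "volume_indicator")
}

#' Per-cluster feature table
#'
#' @param features List of lists with elements `cluster`, `depth`,
#'   `volume` (as assembled by [pocket_predict()]).
#' @param path Optional TSV output path.
#' @return Data frame with cluster id, size, average depth, volume count
#'   and probe parameters.
#' @export
feature_report <- function(features, path = NULL) {
  df <- do.call(rbind, lapply(features, function(f) {
    data.frame(cluster = f$cluster$id, size = nrow(f$cluster$members),
               avg_depth = f$depth$average,
               volume_voxels = f$volume$voxel_count,
               probe_radius = f$volume$probe_radius,
               min_directions = f$volume$min_directions)
  }))
  if (!is.null(path) && !is.null(df)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
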