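#' Ranking weights
#'
#' @param w1 Weight of the normalized average depth.
#' @param w2 Weight of the normalized cavity volume.  `w1 + w2` must be 1
#'   and both must be non-negative.
#' @return Object of class `pocket_weights`.
#' @export
pocket_weights <- function(w1 = 0.5, w2 = 0.5) {
  stopifnot(w1 >= 0, w2 >= 0)
  if (abs(w1 + w2 - 1) > 1e-8) stop("w1 + w2 must equal 1")
  structure(list(w1 = w1, w2 = w2), class = "pocket_weights")
}

#' Rank candidate pockets by combined depth and volume score
#'
#' Each region's ranked value is
#' `rv = (CD_avg / CD_max) * w1 + (CV / CV_max) * w2`, where `CD_max` and
#' `CV_max` are the maxima over the candidate list of this query protein.
#' Regions are sorted by `rv` descending; ties are broken by larger volume,
#' then smaller cluster id.  Negative average depths are not clamped: such
#' regions rank last.
#'
#' @param features List of lists, each with `cluster` (a `pocket_cluster`
#'   or any list with an `id`), `depth` (list with `average`), and
#'   `volume` (list with `voxel_count`).
#' @param weights A [pocket_weights()].
#' @return List of `ranked_region` objects (fields `rank`, `rv`, `cluster`,
#'   `depth`, `volume`), rank 1 first.  If the maximal average depth is
#'   not positive or the maximal volume is zero, a condition of class
#'   `voxpocket_no_region` is signalled: no concave cavity was found.
#' @export
rank_regions <- function(features, weights = pocket_weights()) {
  stopifnot(length(features) > 0, inherits(weights, "pocket_weights"))
  cd <- vapply(features, function(f) as.numeric(f$depth$average),
               numeric(1))
  cv <- vapply(features, function(f) as.numeric(f$volume$voxel_count),
               numeric(1))
  id <- vapply(features, function(f) as.integer(f$cluster$id), integer(1))
  cd_max <- max(cd)
  cv_max <- max(cv)
  if (cd_max <= 0 || cv_max <= 0) {
    stop(structure(
      class = c("voxpocket_no_region", "error", "condition"),
      list(message = paste0(
             "no rankable region: maximal average depth = ", cd_max,
             ", maximal volume = ", cv_max,
             " (no concave cavity found)"),
           call = sys.call(-1))))
  }
  rv <- cd / cd_max * weights$w1 + cv / cv_max * weights$w2
  ord <- order(-rv, -cv, id)
  out <- vector("list", length(ord))
  for (r in seq_along(ord)) {
    f <- features[[ord[r]]]
    out[[r]] <- structure(
      list(rank = r, rv = rv[ord[r]], cluster = f$cluster,
           depth = f$depth, volume = f$volume),
      class = "ranked_region")
  }
  out
}

#' First k ranked regions
#'
#' @param regions List of `ranked_region` (rank order).
#' @param k Positive integer.
#' @return The first `min(k, length(regions))` regions.
#' @export
top_k <- function(regions, k) {
  stopifnot(k >= 1)
  regions[seq_len(min(k, length(regions)))]
}

#' Prediction table for ranked regions
#'
#' @param regions List of `ranked_region`.
#' @param structure Optional `pdb_structure`; when given, the residues with
#'   an atom within `residue_distance` of any member voxel are listed per
#'   region.
#' @param residue_distance Contact distance in Angstrom for the residue
#'   annotation column.
#' @return Data frame: rank, rv, anchor coordinates, cluster size, average
#'   depth, volume count, and (optionally) nearest residues.
#' @export
region_report <- function(regions, structure = NULL,
                          residue_distance = 4.5) {
  rows <- lapply(regions, function(rg) {
    res <- NA_character_
    if (!is.null(structure)) {
      near <- residues_near(structure,
                            as.matrix(rg$cluster$members[, c("x", "y", "z")]),
                            residue_distance)
      res <- paste(paste0(near$chain, near$resseq, ":", near$resname),
                   collapse = ",")
    }
    data.frame(rank = rg$rank, rv = rg$rv, cluster = rg$cluster$id,
               size = nrow(rg$cluster$members),
               anchor_x = rg$cluster$anchor_xyz[1],
               anchor_y = rg$cluster$anchor_xyz[2],
               anchor_z = rg$cluster$anchor_xyz[3],
               anchor_sa = rg$cluster$anchor_sa,
               avg_depth = rg$depth$average,
               volume_voxels = rg$volume$voxel_count,
               residues = res,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(rank = integer(0), rv = numeric(0),
                      cluster = integer(0), size = integer(0),
                      anchor_x = numeric(0), anchor_y = numeric(0),
                      anchor_z = numeric(0), anchor_sa = numeric(0),
                      avg_depth = numeric(0), volume_voxels = numeric(0),
                      residues = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# residues of `structure` with at least one atom within `cutoff` of any of
# the given points (n x 3 matrix)
residues_near <- function(structure, points, cutoff) {
  atoms <- structure$atoms
  if (nrow(atoms) == 0L || nrow(points) == 0L) {
    return(data.frame(chain = character(0), resseq = integer(0),
                      resname = character(0)))
  }
  pos <- as.matrix(atoms[, c("x", "y", "z")])
  mind2 <- rep(Inf, nrow(pos))
  for (m in seq_len(nrow(points))) {
    d2 <- (pos[, 1] - points[m, 1])^2 + (pos[, 2] - points[m, 2])^2 +
      (pos[, 3] - points[m, 3])^2
    mind2 <- pmin(mind2, d2)
  }
  hit <- mind2 <= cutoff^2
  res <- unique(atoms[hit, c("chain", "resseq", "resname")])
  rownames(res) <- NULL
  res[order(res$chain, res$resseq), , drop = FALSE]
}
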