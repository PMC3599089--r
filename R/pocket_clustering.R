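#' Select the most concave surface voxels
#'
#' Returns the `ceiling(fraction * n)` surface voxels with the largest
#' solid angles; voxels tied with the cutoff value are all included.
#'
#' @param sa_map A [solid_angle_all()] result.
#' @param fraction Proportion of surface voxels to keep (default 0.20,
#'   the "highest 20 percent" rule).
#' @return The candidate subset of `sa_map` (same class and attributes,
#'   plus attribute `cutoff`).
#' @export
select_candidates <- function(sa_map, fraction = 0.20) {
  stopifnot(inherits(sa_map, "solid_angle_map"),
            fraction > 0, fraction <= 1)
  n <- nrow(sa_map)
  if (n == 0L) stop("empty solid-angle map")
  m <- ceiling(fraction * n)
  cutoff <- sort(sa_map$sa, decreasing = TRUE)[m]
  out <- sa_map[sa_map$sa >= cutoff, , drop = FALSE]
  attributes(out)[c("radius", "surface_weight", "spacing", "origin",
                    "dims")] <-
    attributes(sa_map)[c("radius", "surface_weight", "spacing", "origin",
                         "dims")]
  attr(out, "cutoff") <- cutoff
  class(out) <- class(sa_map)
  out
}

#' Cluster candidate voxels into pocket groups
#'
#' Single-linkage connected components: two candidate voxels are linked iff
#' their Euclidean centre distance is at most `distance_threshold` (20
#' Angstrom by default) and their solid angles differ by at most `sa_band`.
#' Each component becomes one cluster; its anchor is the member with the
#' largest solid angle (ties: lexicographically smallest voxel index).
#'
#' @param candidates A candidate set from [select_candidates()] (any
#'   `solid_angle_map` subset works).
#' @param distance_threshold Linkage distance in Angstrom.
#' @param sa_band Maximum solid-angle difference (steradians) for a link;
#'   default `0.1 * 4 * pi`, one depth-bin width.
#' @return List of `pocket_cluster` objects sorted by anchor solid angle,
#'   descending (ties: smaller anchor index first), each a list with
#'   `id`, `members` (data frame i, j, k, x, y, z, sa, sorted by index),
#'   `anchor` (length-3 index), `anchor_xyz`, `anchor_sa`, `mean_sa`.
#' @export
cluster_voxels <- function(candidates, distance_threshold = 20,
                           sa_band = 0.1 * 4 * pi) {
  stopifnot(inherits(candidates, "solid_angle_map"),
            distance_threshold > 0, sa_band >= 0)
  n <- nrow(candidates)
  if (n == 0L) return(list())
  xyz <- as.matrix(candidates[, c("x", "y", "z")])
  if (n == 1L) {
    memb <- 1L
  } else {
    dmat <- as.matrix(stats::dist(xyz))
    smat <- abs(outer(candidates$sa, candidates$sa, "-"))
    adj <- dmat <= distance_threshold & smat <= sa_band
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    memb <- igraph::components(g)$membership
  }
  groups <- split(seq_len(n), memb)
  clusters <- lapply(groups, function(rows) {
    mem <- as.data.frame(candidates[rows, c("i", "j", "k", "x", "y", "z",
                                            "sa")])
    mem <- mem[order(mem$i, mem$j, mem$k), , drop = FALSE]
    rownames(mem) <- NULL
    a <- pick_anchor(mem)
    list(id = NA_integer_, members = mem,
         anchor = as.integer(unlist(mem[a, c("i", "j", "k")])),
         anchor_xyz = as.numeric(unlist(mem[a, c("x", "y", "z")])),
         anchor_sa = mem$sa[a], mean_sa = mean(mem$sa))
  })
  ord <- order(-vapply(clusters, `[[`, numeric(1), "anchor_sa"),
               vapply(clusters, function(cl) cl$anchor[1], integer(1)),
               vapply(clusters, function(cl) cl$anchor[2], integer(1)),
               vapply(clusters, function(cl) cl$anchor[3], integer(1)))
  clusters <- clusters[ord]
  for (c_i in seq_along(clusters)) {
    clusters[[c_i]]$id <- c_i
    class(clusters[[c_i]]) <- "pocket_cluster"
  }
  unname(clusters)
}

#' Anchor (maximum solid angle) row of a member table
#'
#' @param members Data frame with columns `i`, `j`, `k`, `sa`.
#' @return Row index of the member with maximal solid angle; ties broken
#'   by lexicographically smallest `(i, j, k)`.
#' @export
pick_anchor <- function(members) {
  stopifnot(nrow(members) > 0L)
  order(-members$sa, members$i, members$j, members$k)[1L]
}

#' Tabular report of clusters
#'
#' @param clusters List of `pocket_cluster` objects.
#' @param path Optional TSV output path.
#' @return Data frame: cluster id, size, anchor grid index, anchor
#'   Cartesian coordinates, anchor and mean solid angle.
#' @export
cluster_report <- function(clusters, path = NULL) {
  df <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(cluster = cl$id, size = nrow(cl$members),
               anchor_i = cl$anchor[1], anchor_j = cl$anchor[2],
               anchor_k = cl$anchor[3],
               anchor_x = cl$anchor_xyz[1], anchor_y = cl$anchor_xyz[2],
               anchor_z = cl$anchor_xyz[3],
               anchor_sa = cl$anchor_sa, mean_sa = cl$mean_sa)
  }))
  if (is.null(df)) {
    df <- data.frame(cluster = integer(0), size = integer(0),
                     anchor_i = integer(0), anchor_j = integer(0),
                     anchor_k = integer(0), anchor_x = numeric(0),
                     anchor_y = numeric(0), anchor_z = numeric(0),
                     anchor_sa = numeric(0), mean_sa = numeric(0))
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}
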