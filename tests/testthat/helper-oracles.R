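# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the vectorized implementations they check.

# triple-loop solid angle: scan every voxel of the grid, count those within
# `radius` of the centre voxel by label class, apply the defining formula.
oracle_solid_angle <- function(grid, voxel, radius, surface_weight = 0.5) {
  d <- grid$dims
  s <- grid$spacing
  n_tot <- 0L; n_int <- 0L; n_sur <- 0L
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    dist2 <- ((i - voxel[1])^2 + (j - voxel[2])^2 + (k - voxel[3])^2) * s^2
    if (dist2 <= radius^2 + 1e-9) {
      n_tot <- n_tot + 1L
      lab <- grid$label[i, j, k]
      if (lab == 1L) n_int <- n_int + 1L
      if (lab == 2L) n_sur <- n_sur + 1L
    }
  }
  (n_int + surface_weight * n_sur) / n_tot * (4 * pi)
}

# step-by-step ray march for one signed direction
oracle_ray_blocked <- function(grid, voxel, dvec) {
  p <- voxel
  repeat {
    p <- p + dvec
    if (any(p < 1L) || any(p > grid$dims)) return(FALSE)
    if (grid$label[p[1], p[2], p[3]] != 0L) return(TRUE)
  }
}

oracle_interior_count <- function(grid, voxel) {
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
               c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1))
  n <- 0L
  for (dv in dirs) {
    if (oracle_ray_blocked(grid, voxel, dv) &&
        oracle_ray_blocked(grid, voxel, -dv)) n <- n + 1L
  }
  n
}

# O(N * 6) neighbour-scan surface classification oracle
oracle_surface_set <- function(occ) {
  d <- dim(occ)
  out <- matrix(integer(0), 0, 3)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (!occ[i, j, k]) next
    ext <- FALSE
    for (dv in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      p <- c(i, j, k) + dv
      if (any(p < 1) || any(p > d) || !occ[p[1], p[2], p[3]]) {
        ext <- TRUE
        break
      }
    }
    if (ext) out <- rbind(out, c(i, j, k))
  }
  out
}

# random blob grid whose occupancy stays `margin` voxels clear of the
# boundary, so downstream virtual spheres fit
random_blob_grid <- function(dims, margin, n_blobs = 3, seed = 1) {
  set.seed(seed)
  occ <- array(FALSE, dims)
  for (b in seq_len(n_blobs)) {
    r <- stats::runif(1, 1, max(1, floor(min(dims) / 2) - margin - 1))
    cr <- ceiling(r)
    ctr <- sapply(dims, function(d) {
      sample(seq(margin + 1 + cr, d - margin - cr), 1)
    })
    lo <- pmax(ctr - cr, 1); hi <- pmin(ctr + cr, dims)
    for (i in lo[1]:hi[1]) for (j in lo[2]:hi[2]) for (k in lo[3]:hi[3]) {
      if (sum((c(i, j, k) - ctr)^2) <= r^2) occ[i, j, k] <- TRUE
    }
  }
  voxel_grid(occ, spacing = 1)
}
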