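test_that("depth transform: all six branches, boundaries, monotonicity", {
  f4pi <- 4 * pi
  cases <- rbind(
    c(0.95, 5), c(0.90, 4), c(0.85, 4), c(0.80, 3), c(0.75, 3),
    c(0.70, 2), c(0.65, 2), c(0.60, 1), c(0.55, 1), c(0.50, -1),
    c(0.30, -1), c(0.00, -1), c(1.00, 5))
  expect_equal(depth_of(cases[, 1] * f4pi), as.integer(cases[, 2]))
  # boundary value computed through a different fp expression still lands
  # in the lower bin
  expect_equal(depth_of(0.9 * 4 * pi), 4L)
  expect_equal(depth_of(0.9 * (4 * pi)), 4L)
  # monotone non-decreasing step function
  grid_sa <- seq(0, f4pi, length.out = 400)
  expect_true(all(diff(depth_of(grid_sa)) >= 0))
  expect_error(depth_of(4 * pi + 0.1), "outside")
  expect_error(depth_of(-0.1), "outside")
})

test_that("average depth includes -1 values in the mean", {
  sa_for_depth <- function(d) {
    c(`5` = 0.95, `4` = 0.85, `3` = 0.75, `2` = 0.65, `1` = 0.55,
      `-1` = 0.3)[as.character(d)] * 4 * pi
  }
  mk <- function(depths) {
    structure(list(id = 1L,
                   members = data.frame(i = seq_along(depths), j = 1L,
                                        k = 1L, x = 0, y = 0, z = 0,
                                        sa = sa_for_depth(depths))),
              class = "pocket_cluster")
  }
  expect_equal(average_depth(mk(c(5, 5, 4, 3, 1, -1)))$average, 17 / 6)
  expect_equal(average_depth(mk(c(5, 5, 5)))$average, 5)
  expect_equal(average_depth(mk(-1))$average, -1)
})

test_that("interior direction count matches the ray-march oracle exactly", {
  # enclosed void: every line is blocked in both directions
  g <- generate_grid(shape_spec("enclosed_void", radius = 7,
                                void_radius = 2.5, padding = 3))
  centre <- round((c(0, 0, 0) - g$origin) / g$spacing) + 1
  expect_equal(interior_direction_count(g, centre), 7L)

  # far above a flat slab: at most the 3 in-plane-ish lines can block
  gs <- generate_grid(shape_spec("slab", lx = 20, ly = 20, lz = 6,
                                 padding = 8))
  above <- round((c(0, 0, 9) - gs$origin) / gs$spacing) + 1
  expect_equal(interior_direction_count(gs, above),
               oracle_interior_count(gs, above))
  expect_lte(interior_direction_count(gs, above), 3L)

  # occupied voxel is rejected
  inside <- round((c(0, 0, 0) - gs$origin) / gs$spacing) + 1
  expect_error(interior_direction_count(gs, inside), "occupied")

  # exhaustive oracle equivalence on a random small grid
  gr <- random_blob_grid(c(14, 14, 14), margin = 3, n_blobs = 3, seed = 7)
  empties <- which(gr$label == 0L, arr.ind = TRUE, useNames = FALSE)
  for (r in seq_len(nrow(empties))) {
    expect_identical(interior_direction_count(gr, empties[r, ]),
                     oracle_interior_count(gr, empties[r, ]))
  }
})

test_that("cavity volume counts enclosed empty voxels only", {
  # fully enclosed spherical void: every void voxel within the probe counts
  g <- generate_grid(shape_spec("enclosed_void", radius = 8,
                                void_radius = 3, padding = 3))
  # anchor: a surface voxel on the void wall (the void's own surface shell)
  surf <- classify_surface(g)
  ctr <- voxel_centers(g, surf)
  wall <- surf[which.min(rowSums(ctr^2)), ]
  cv <- cavity_volume(g, wall, probe_radius = 10)
  empt <- which(g$label == 0L, arr.ind = TRUE, useNames = FALSE)
  ec <- voxel_centers(g, empt)
  wc <- voxel_centers(g, matrix(wall, 1))
  in_void <- rowSums(ec^2) <= 3^2          # void empties (rest is outside)
  in_ball <- (ec[, 1] - wc[1])^2 + (ec[, 2] - wc[2])^2 +
    (ec[, 3] - wc[3])^2 <= 100
  expect_equal(cv$voxel_count, sum(in_void & in_ball))

  # convex sphere: no line through an exterior point can be blocked twice
  gs <- generate_grid(shape_spec("solid_sphere", radius = 6, padding = 10))
  ssurf <- classify_surface(gs)
  anchor <- ssurf[1, ]
  expect_equal(cavity_volume(gs, anchor, probe_radius = 6)$voxel_count, 0L)
  # degenerate probe
  expect_equal(cavity_volume(gs, anchor, probe_radius = 0)$voxel_count, 0L)
  # anchor must be on the surface
  expect_error(cavity_volume(gs, c(1, 1, 1), 10), "not a surface voxel")
})

test_that("deepening the carved pocket never shrinks its cavity volume", {
  counts <- vapply(c(7.5, 6.5, 5.5), function(d) {
    g <- generate_grid(shape_spec("sphere_with_cap_pocket", radius = 9,
                                  pocket_radius = 6,
                                  pocket_center_dist = d))
    sam <- solid_angle_all(g, 6)
    anchor <- as.integer(sam[which.max(sam$sa), c("i", "j", "k")])
    cavity_volume(g, anchor, probe_radius = 10)$voxel_count
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
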