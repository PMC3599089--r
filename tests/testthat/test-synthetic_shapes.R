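# 6-connected flood fill from the grid boundary through empty voxels
flood_exterior <- function(grid) {
  ext <- grid$label == 0L
  d <- grid$dims
  reach <- array(FALSE, d)
  reach[1, , ] <- ext[1, , ]; reach[d[1], , ] <- ext[d[1], , ]
  reach[, 1, ] <- reach[, 1, ] | ext[, 1, ]
  reach[, d[2], ] <- reach[, d[2], ] | ext[, d[2], ]
  reach[, , 1] <- reach[, , 1] | ext[, , 1]
  reach[, , d[3]] <- reach[, , d[3]] | ext[, , d[3]]
  repeat {
    grown <- reach
    grown[-1, , ] <- grown[-1, , ] | reach[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | reach[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | reach[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | reach[, -1, ]
    grown[, , -1] <- grown[, , -1] | reach[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | reach[, , -1]
    grown <- grown & ext
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

test_that("cube grid has the closed-form occupied count", {
  g <- generate_grid(shape_spec("cube", edge = 20))
  expect_equal(sum(g$label > 0L), 21L^3)
})

test_that("pocket mouth is open to the exterior; enclosed void is not", {
  spec <- shape_spec("sphere_with_cap_pocket")
  g <- generate_grid(spec)
  reach <- flood_exterior(g)
  # a voxel in the carved pocket, just above the bottom wall
  p <- spec$params
  void_idx <- round((c(0, 0, p$pocket_center_dist - p$pocket_radius + 1) -
                       g$origin) / g$spacing) + 1
  expect_equal(g$label[void_idx[1], void_idx[2], void_idx[3]], 0L)
  expect_true(reach[void_idx[1], void_idx[2], void_idx[3]])

  gv <- generate_grid(shape_spec("enclosed_void", radius = 7,
                                 void_radius = 2.5, padding = 2))
  rv <- flood_exterior(gv)
  ctr <- round((c(0, 0, 0) - gv$origin) / gv$spacing) + 1
  expect_equal(gv$label[ctr[1], ctr[2], ctr[3]], 0L)
  expect_false(rv[ctr[1], ctr[2], ctr[3]])
})

test_that("complementary pair partitions the box", {
  pair <- generate_grid(shape_spec("complementary_pair", edge = 16,
                                   padding = 2))
  occA <- pair$A$label > 0L
  occB <- pair$B$label > 0L
  expect_false(any(occA & occB))                       # disjoint
  # together they are exactly the box lattice
  box <- generate_grid(shape_spec("cube", edge = 16, padding = 2))
  expect_equal(occA | occB, box$label > 0L)
})

test_that("pseudo-atom PDB is deterministic and re-voxelizes faithfully", {
  spec <- shape_spec("solid_sphere", radius = 6, padding = 4)
  f1 <- generate_pdb(spec)
  f2 <- generate_pdb(spec)
  expect_identical(f1$lines, f2$lines)

  # jittered variant is deterministic given the seed, differs across seeds
  sj1 <- shape_spec("solid_sphere", radius = 6, padding = 4, jitter = 0.2,
                    seed = 5)
  sj2 <- shape_spec("solid_sphere", radius = 6, padding = 4, jitter = 0.2,
                    seed = 6)
  expect_identical(generate_pdb(sj1)$lines, generate_pdb(sj1)$lines)
  expect_false(identical(generate_pdb(sj1)$lines, generate_pdb(sj2)$lines))

  # re-voxelized occupancy tracks the analytic solid to within one atom
  # radius: every occupied centre is inside the sphere grown by 1.8
  # Angstrom, and every lattice point of the sphere shrunk by 1.8 Angstrom
  # is occupied
  g_pdb <- build_grid(f1$structure, spacing = spec$spacing,
                      padding = spec$padding)
  occ_idx <- which(g_pdb$label > 0L, arr.ind = TRUE, useNames = FALSE)
  occ_r <- sqrt(rowSums(voxel_centers(g_pdb, occ_idx)^2))
  expect_true(all(occ_r <= 6 + 1.8))
  all_idx <- which(array(TRUE, g_pdb$dims), arr.ind = TRUE,
                   useNames = FALSE)
  core <- sqrt(rowSums(voxel_centers(g_pdb, all_idx)^2)) <= 6 - 1.8
  expect_true(all(g_pdb$label[all_idx[core, , drop = FALSE]] > 0L))
})

test_that("pocket fixtures carry a machine-readable truth table", {
  fix <- pocket_fixture_cache()$fix
  expect_true(is.data.frame(fix$truth))
  expect_gt(nrow(fix$truth), 0L)
  expect_named(fix$truth, c("chain", "resseq"))
  expect_true(all(fix$truth$resseq %in% fix$structure$atoms$resseq))
  # written files round-trip through the evaluation reader
  out <- withr::local_tempfile(fileext = ".pdb")
  generate_pdb(fix$spec, path = out)
  expect_true(file.exists(out))
  expect_equal(read_truth(paste0(out, ".truth.tsv")), fix$truth,
               ignore_attr = TRUE)
  # invalid specs are rejected
  expect_error(shape_spec("sphere_with_cap_pocket", pocket_radius = 20),
               "smaller")
  expect_error(shape_spec("cube", edge = -1), "> 0")
  expect_error(shape_spec("cube", bogus = 2), "unknown parameter")
})
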