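# shared small fixtures, built in code at test time

# minimal hand-written PDB text with chains A and B plus one ligand HETATM
make_two_chain_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.500   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.200   1.300   0.000  1.00  0.00           C",
    "ATOM      4  N   GLY B   5      10.000   0.000   0.000  1.00  0.00           N",
    "ATOM      5  CA  GLY B   5      11.500   0.000   0.000  1.00  0.00           C",
    "HETATM    6  O   HOH A 101       3.000   3.000   3.000  1.00  0.00           O",
    "END"), path)
  path
}

# a lone carbon at an integer lattice position
make_single_atom_pdb <- function(path, x = 0, y = 0, z = 0, element = "C") {
  writeLines(c(
    sprintf("ATOM      1 %-4s UNK A   1    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            paste0(" ", element), x, y, z, element),
    "END"), path)
  path
}

# solid 3x3x3 cube in a padded grid
make_cube3_grid <- function(pad = 8) {
  d <- 3L + 2L * pad
  occ <- array(FALSE, rep(d, 3))
  idx <- pad + (1:3)
  occ[idx, idx, idx] <- TRUE
  voxel_grid(occ, spacing = 1)
}

# fabricate a solid_angle_map directly (for clustering unit tests)
make_sa_map <- function(i, j, k, sa, spacing = 1, origin = c(0, 0, 0)) {
  df <- data.frame(i = as.integer(i), j = as.integer(j), k = as.integer(k),
                   x = origin[1] + (i - 1) * spacing,
                   y = origin[2] + (j - 1) * spacing,
                   z = origin[3] + (k - 1) * spacing, sa = sa)
  structure(df, class = c("solid_angle_map", "data.frame"),
            radius = 6, surface_weight = 0.5, spacing = spacing,
            origin = origin, dims = c(100L, 100L, 100L))
}

# features list entry for ranking tests
make_feature <- function(id, avg_depth, volume) {
  cl <- structure(list(id = id,
                       members = data.frame(i = 1L, j = 1L, k = 1L,
                                            x = 0, y = 0, z = 0, sa = 2)),
                  class = "pocket_cluster")
  list(cluster = cl,
       depth = structure(list(per_voxel = avg_depth, average = avg_depth),
                         class = "depth_indicator"),
       volume = structure(list(voxel_count = volume, probe_radius = 10,
                               min_directions = 4L),
                          class = "volume_indicator"))
}

# memoized default pocket fixture + prediction (used by several files)
pocket_fixture_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$fix)) {
      env$fix <- generate_pdb(shape_spec("sphere_with_cap_pocket"))
      env$pred <- pocket_predict(env$fix)
    }
    list(fix = env$fix, pred = env$pred)
  }
})
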