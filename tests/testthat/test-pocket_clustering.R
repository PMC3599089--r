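test_that("candidate selection keeps the top fraction with tie inclusion", {
  sam <- make_sa_map(1:10, rep(1, 10), rep(1, 10), sa = (1:10) / 10 * 4)
  top2 <- select_candidates(sam, 0.2)
  expect_equal(sort(top2$sa), c(3.6, 4.0))

  ties <- make_sa_map(1:10, rep(1, 10), rep(1, 10), sa = rep(2, 10))
  expect_equal(nrow(select_candidates(ties, 0.2)), 10L)  # all tied

  expect_equal(nrow(select_candidates(sam, 1.0)), 10L)
  expect_error(select_candidates(sam, 0), "fraction")
})

test_that("single linkage with distance and solid-angle band", {
  # two candidates 25 Angstrom apart -> separate clusters at 20 threshold
  far <- make_sa_map(c(1, 26), c(1, 1), c(1, 1), sa = c(3, 3))
  expect_length(cluster_voxels(far), 2L)
  # 5 Angstrom apart, equal SA -> one cluster
  near <- make_sa_map(c(1, 6), c(1, 1), c(1, 1), sa = c(3, 3))
  expect_length(cluster_voxels(near), 1L)
  # chain A-B-C: A-C beyond threshold but linked through B
  chain <- make_sa_map(c(1, 16, 31), c(1, 1, 1), c(1, 1, 1),
                       sa = c(3, 3, 3))
  expect_length(cluster_voxels(chain), 1L)
  # same chain but B's SA outside the band: breaks the bridge
  broken <- make_sa_map(c(1, 16, 31), c(1, 1, 1), c(1, 1, 1),
                        sa = c(3, 3 + 2, 3))
  expect_length(cluster_voxels(broken, sa_band = 1), 3L)
})

test_that("anchors maximize SA with lexicographic tie-break", {
  m <- data.frame(i = c(5L, 2L, 9L), j = c(1L, 1L, 1L), k = c(1L, 1L, 1L),
                  sa = c(3, 5, 4))
  expect_equal(pick_anchor(m), 2L)
  tie <- data.frame(i = c(7L, 3L), j = c(2L, 9L), k = c(1L, 1L),
                    sa = c(5, 5))
  expect_equal(pick_anchor(tie), 2L)  # smaller i wins
  single <- data.frame(i = 4L, j = 4L, k = 4L, sa = 1)
  expect_equal(pick_anchor(single), 1L)
})

test_that("clusters partition candidates and are order-independent", {
  set.seed(42)
  n <- 40
  sam <- make_sa_map(sample(1:60, n, TRUE), sample(1:60, n, TRUE),
                     sample(1:60, n, TRUE),
                     sa = runif(n, 0, 4 * pi))
  sam <- sam[!duplicated(sam[, c("i", "j", "k")]), ]
  cl <- cluster_voxels(sam, distance_threshold = 12, sa_band = 2)
  all_members <- do.call(rbind, lapply(cl, function(c) c$members))
  expect_equal(nrow(all_members), nrow(sam))            # covering
  expect_false(any(duplicated(all_members[, c("i", "j", "k")])))  # disjoint
  expect_true(all(vapply(cl, function(c) {
    c$anchor_sa == max(c$members$sa)
  }, logical(1))))
  # permuted input gives identical clusters
  perm <- sam[sample(nrow(sam)), ]
  attributes(perm)[c("radius", "surface_weight", "spacing", "origin",
                     "dims")] <-
    attributes(sam)[c("radius", "surface_weight", "spacing", "origin",
                      "dims")]
  class(perm) <- class(sam)
  cl2 <- cluster_voxels(perm, distance_threshold = 12, sa_band = 2)
  expect_equal(lapply(cl2, function(c) c$members),
               lapply(cl, function(c) c$members))
  # empty candidate set
  expect_equal(cluster_voxels(sam[0, ]), list())
})

test_that("pocket fixture: one cluster anchored in the pocket's deep half", {
  p <- pocket_fixture_cache()
  spec <- p$fix$spec$params
  mouth_z <- (spec$radius^2 + spec$pocket_center_dist^2 -
                spec$pocket_radius^2) / (2 * spec$pocket_center_dist)
  bottom_z <- spec$pocket_center_dist - spec$pocket_radius
  mid_z <- (mouth_z + bottom_z) / 2
  in_deep_half <- vapply(p$pred$clusters, function(cl) {
    a <- cl$anchor_xyz
    dc <- sqrt(a[1]^2 + a[2]^2 + (a[3] - spec$pocket_center_dist)^2)
    dc <= spec$pocket_radius + 1 && a[3] < mid_z
  }, logical(1))
  expect_equal(sum(in_deep_half), 1L)
  expect_true(in_deep_half[1])  # and it is the top-SA cluster
})
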