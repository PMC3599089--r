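test_that("metrics match hand-evaluated formulas", {
  perfect <- compute_metrics(confusion_counts(10, 0, 90, 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "ppv", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1, ppv = 1,
                 mcc = 1))

  m <- compute_metrics(confusion_counts(5, 5, 85, 5))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 85 / 90)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$mcc, 400 / 900)

  degen <- compute_metrics(confusion_counts(0, 0, 100, 0))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$ppv, 0)
  expect_true(all(c("sensitivity", "ppv") %in% degen$flagged))
  expect_equal(degen$specificity, 1)
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("metrics agree with a textbook oracle on random counts; MCC symmetry", {
  set.seed(99)
  for (rep in 1:250) {
    cts <- sample(0:40, 4, replace = TRUE)
    if (sum(cts) == 0) cts[1] <- 1
    tp <- cts[1]; fp <- cts[2]; tn <- cts[3]; fn <- cts[4]
    m <- compute_metrics(confusion_counts(tp, fp, tn, fn))
    sd0 <- function(n, d) if (d == 0) 0 else n / d
    expect_equal(m$sensitivity, sd0(tp, tp + fn))
    expect_equal(m$specificity, sd0(tn, tn + fp))
    expect_equal(m$accuracy, (tp + tn) / sum(cts))
    expect_equal(m$ppv, sd0(tp, tp + fp))
    expect_equal(m$mcc,
                 sd0(tp * tn - fp * fn,
                     sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) *
                       sqrt(tn + fn)),
                 tolerance = 1e-12)
    # swapping classes leaves MCC unchanged
    m_swap <- compute_metrics(confusion_counts(tn, fn, tp, fp))
    expect_equal(m_swap$mcc, m$mcc, tolerance = 1e-12)
  }
})

test_that("region matching on the pocket fixture", {
  p <- pocket_fixture_cache()
  res <- match_regions(p$pred$regions, p$fix$truth, p$fix$structure, k = 1)
  expect_true(res$success)
  expect_equal(res$matched_ranks, 1L)
  # success is monotone in k
  res2 <- match_regions(p$pred$regions, p$fix$truth, p$fix$structure, k = 2)
  res3 <- match_regions(p$pred$regions, p$fix$truth, p$fix$structure, k = 3)
  expect_true(res2$success && res3$success)
  # counts cover every residue of the structure exactly once
  at <- p$fix$structure$atoms
  n_res <- length(unique(paste(at$chain, at$resseq)))
  cts <- res$counts
  expect_equal(cts$tp + cts$fp + cts$tn + cts$fn, n_res)

  # truth far from any prediction: no success, no true positives
  far <- data.frame(chain = "A", resseq = at$resseq[which.min(at$z)][1])
  at_far <- at[at$resseq == far$resseq, ]
  res_far <- match_regions(p$pred$regions[1], far, p$fix$structure, k = 1,
                           match_distance = 0.1)
  expect_false(res_far$success)
  expect_equal(res_far$counts$tp, 0)

  expect_error(match_regions(p$pred$regions, data.frame(chain = character(0),
                                                        resseq = integer(0)),
                             p$fix$structure), "empty truth")
})

test_that("ligand-derived truth and truth file round-trip", {
  pdb <- make_two_chain_pdb(withr::local_tempfile(fileext = ".pdb"))
  st <- parse_pdb(pdb)
  st$het$resname <- "LIG"  # make the water a ligand
  tr <- ligand_binding_residues(st, cutoff = 4.5)
  expect_equal(tr$resseq, 1L)  # only residue A1 is within 4.5 of (3,3,3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(tr, f)
  expect_equal(read_truth(f), tr, ignore_attr = TRUE)
  st$het <- st$het[0, ]
  expect_error(ligand_binding_residues(st), "no ligand")
})
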