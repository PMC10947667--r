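test_that("keep_fraction = 1 is the identity on the tip set", {
  tr <- prune_extinct(simulate_complete_tree(bd_params(1, 0.5, 30, seed = 2)))
  out <- subsample_taxa(tr, sampling_scheme(1))
  expect_setequal(out$tip.label, tr$tip.label)
})

test_that("1% of 1,000 extant taxa retains exactly 10 tips", {
  tr <- simulate_complete_tree(bd_params(1, 0, 1000, seed = 3))
  set.seed(4)
  out <- subsample_taxa(tr, sampling_scheme(0.01))
  expect_equal(ape::Ntip(out), 10)
})

test_that("retained counts use half-up rounding with a constraint floor", {
  expect_equal(ghostshift:::round_half_up(2.5), 3)
  expect_equal(ghostshift:::round_half_up(2.49), 2)
  tr <- prune_extinct(simulate_complete_tree(bd_params(1, 0.3, 40, seed = 6)))
  set.seed(7)
  rec <- tr$tip.label[1:4]
  # 0.01 * 40 rounds to 0; the 2-recipient + 1-donor floor applies
  out <- subsample_taxa(tr, sampling_scheme(0.01), recipient_taxa = rec)
  expect_equal(ape::Ntip(out), 3)
  expect_gte(sum(out$tip.label %in% rec), 2)
  expect_gte(sum(!out$tip.label %in% rec), 1)
})

test_that("subsampling preserves pairwise distances among retained tips", {
  tr <- prune_extinct(simulate_complete_tree(bd_params(1, 0.5, 60, seed = 10)))
  before <- ape::cophenetic.phylo(tr)
  set.seed(11)
  out <- subsample_taxa(tr, sampling_scheme(0.2))
  keep <- out$tip.label
  expect_equal(ape::cophenetic.phylo(out)[keep, keep], before[keep, keep],
               tolerance = 1e-10)
})

test_that("subsampling requires an extant-only tree", {
  tr <- simulate_complete_tree(bd_params(1, 0.7, 10, seed = 12))
  expect_error(subsample_taxa(tr, sampling_scheme(0.5)), "extant-only")
})

test_that("apparent donor: sampled donor descendants pin the divergence at tau", {
  gt <- worked_gene_tree()$gene_tree # transfer at tau = 1 onto the D1 branch
  obs <- as_chronotree(ape::keep.tip(gt, c("D1", "E1", "E2")))
  inf <- inferred_donor(obs, c("E1", "E2"))
  expect_equal(inf$divergence_age, 1)
  expect_identical(inf$sister_taxa, "D1")
})

test_that("apparent donor: pruning the donor clade pushes the divergence deeper", {
  gt <- worked_gene_tree()$gene_tree
  obs <- as_chronotree(ape::keep.tip(gt, c("D2", "E1", "E2")))
  inf <- inferred_donor(obs, c("E1", "E2"))
  expect_equal(inf$divergence_age, 2) # D1-D2 ancestor
  obs2 <- as_chronotree(ape::keep.tip(gt, c("O", "E1", "E2")))
  inf2 <- inferred_donor(obs2, c("E1", "E2"))
  expect_equal(inf2$divergence_age, 3) # the root: sister is the lone outgroup
  expect_identical(inf2$sister_taxa, "O")
})

test_that("observed-tree reading agrees with the complete-tree walk", {
  sp <- worked_species()
  # donor = D1 branch, tau = 1; apparent age for each retained donor-side set
  d1 <- which(sp$tip.label == "D1")
  expect_equal(apparent_divergence_age(sp, d1, 1, "D1"), 1)
  expect_equal(apparent_divergence_age(sp, d1, 1, "D2"), 2)
  expect_equal(apparent_divergence_age(sp, d1, 1, "O"), 3)
  expect_equal(apparent_divergence_age(sp, d1, 1, c("D2", "O")), 2)
})

test_that("fast and explicit gene-tree routes agree on random scenarios", {
  set.seed(31)
  sp <- simulate_complete_tree(bd_params(1, 0.5, 60))
  org <- origin_age(sp)
  rec <- simulate_recipient_clade(bd_params(1, 0.5, 6), crown_age = 0.25 * org)
  for (i in 1:15) {
    pr <- draw_transfer_pair(sp, c(0.75 * org, 0.25 * org))
    ret <- ghostshift:::pick_retained_taxa(
      c(extant_tips(sp), extant_tips(rec)), sampling_scheme(0.1),
      extant_tips(rec))
    a <- evaluate_event_pair(sp, rec, pr$tau_early, pr$tau_late,
                             pr$donor_early, pr$donor_late, ret, "fast")
    b <- evaluate_event_pair(sp, rec, pr$tau_early, pr$tau_late,
                             pr$donor_early, pr$donor_late, ret, "genetree")
    expect_equal(a$d_early, b$d_early, tolerance = 1e-8)
    expect_equal(a$d_late, b$d_late, tolerance = 1e-8)
    expect_equal(a$s_early, b$s_early, tolerance = 1e-8)
    expect_identical(a$result, b$result)
  }
})

test_that("apparent divergence age inflates monotonically on nested subsamples", {
  set.seed(41)
  for (i in 1:5) {
    sp <- simulate_complete_tree(bd_params(1, 0.6, 40))
    org <- origin_age(sp)
    tau <- runif(1, 0.3 * org, 0.7 * org)
    donor <- sample_donor(sp, tau)
    ext <- extant_tips(sp)
    s1 <- sample(ext, 20)
    s2 <- sample(s1, 8)
    s3 <- sample(s2, 2)
    d <- sapply(list(ext, s1, s2, s3), function(s)
      apparent_divergence_age(sp, donor, tau, s))
    expect_true(all(diff(d) >= -1e-12))
    expect_gte(d[1], tau)
  }
})

test_that("extinction alone already inflates the apparent divergence age", {
  # complete vs extant-restricted attachment, f = 1: whenever every sampled
  # descendant of the donor is extinct, the observed age must exceed tau
  set.seed(51)
  hits <- 0
  for (i in 1:20) {
    sp <- simulate_complete_tree(bd_params(1, 0.8, 15))
    org <- origin_age(sp)
    tau <- runif(1, 0.4 * org, 0.8 * org)
    donor <- sample_donor(sp, tau)
    d_complete <- apparent_divergence_age(sp, donor, tau, sp$tip.label)
    d_extant <- apparent_divergence_age(sp, donor, tau, extant_tips(sp))
    expect_equal(d_complete, tau, tolerance = 1e-9) # some lineage always spans
    expect_gte(d_extant, tau - 1e-9)
    if (d_extant > tau + 1e-9) hits <- hits + 1
  }
  expect_gt(hits, 0) # ghost donors do occur at this extinction fraction
})

test_that("non-monophyletic recipients are reported as corrupted input", {
  bad <- as_chronotree(ape::read.tree(text = "((E1:1,X:1):1,(E2:1.5,Y:1.5):0.5);"))
  expect_error(inferred_donor(bad, c("E1", "E2")), "monophyletic")
})
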