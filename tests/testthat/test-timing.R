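test_that("the worked six-taxon example yields s = 0.5 and r = 1", {
  gt <- worked_gene_tree()$gene_tree
  tc <- timing_call(gt, c("E1", "E2"))
  expect_equal(tc$s, 0.5)
  expect_equal(tc$r, 1) # recipient branches {0.5, 0.5}, median 0.5
  expect_true(tc$r_defined)
})

test_that("a two-tip recipient divides the stem by the tip length", {
  gt <- worked_gene_tree()$gene_tree
  obs <- as_chronotree(ape::keep.tip(gt, c("D2", "E1", "E2")))
  tc <- timing_call(obs, c("E1", "E2"))
  expect_equal(tc$s, 1.5) # divergence 2 (D1-D2 ancestor) minus crown 0.5
  # brute-force median over the 2-branch multiset {0.5, 0.5}
  expect_equal(tc$r, 1.5 / median(c(0.5, 0.5)))
})

test_that("relative order reads larger statistics as earlier", {
  a <- structure(list(s = 2, r = 4), class = "timing_call")
  b <- structure(list(s = 1, r = 2), class = "timing_call")
  expect_identical(relative_order(a, b), "A_earlier")
  expect_identical(relative_order(b, a), "B_earlier")
  expect_identical(relative_order(a, a), "tie")
  expect_identical(relative_order(a, b, criterion = "ratio"), "A_earlier")
})

test_that("shift classification counts reversals and ties as incorrect", {
  expect_identical(classify_shift("A_earlier", "A_earlier"), "correct")
  expect_identical(classify_shift("A_earlier", "B_earlier"), "incorrect")
  expect_identical(classify_shift("A_earlier", "tie"), "incorrect")
  expect_identical(classify_shift("A_earlier", "tie", tie_policy = "correct"),
                   "correct")
})

test_that("complete unpruned gene trees always recover the true order", {
  set.seed(61)
  for (i in 1:6) {
    sp <- simulate_complete_tree(bd_params(1, 0.5, 25))
    org <- origin_age(sp)
    rec <- simulate_recipient_clade(bd_params(1, 0.5, 4), crown_age = 0.25 * org)
    pr <- draw_transfer_pair(sp, c(0.75 * org, 0.25 * org))
    out <- evaluate_event_pair(sp, rec, pr$tau_early, pr$tau_late,
                               pr$donor_early, pr$donor_late,
                               retained = c(sp$tip.label, rec$tip.label),
                               method = "genetree")
    expect_identical(out$result, "correct")
    expect_equal(out$s_early - out$s_late, pr$tau_early - pr$tau_late,
                 tolerance = 1e-8)
  }
})

test_that("stem and ratio criteria agree for a shared observed recipient clade", {
  sp <- worked_species()
  rec <- worked_recipient()
  d1 <- which(sp$tip.label == "D1")
  gt_e <- build_gene_tree(sp, rec, transfer_event(d1, 1.8))$gene_tree
  gt_l <- build_gene_tree(sp, rec, transfer_event(d1, 0.9))$gene_tree
  keep <- c("D2", "O", "E1", "E2")
  tc_e <- timing_call(as_chronotree(ape::keep.tip(gt_e, keep)), c("E1", "E2"))
  tc_l <- timing_call(as_chronotree(ape::keep.tip(gt_l, keep)), c("E1", "E2"))
  expect_identical(relative_order(tc_e, tc_l, "stem"),
                   relative_order(tc_e, tc_l, "ratio"))
})

test_that("ghost scenarios validate their age structure", {
  expect_error(ghost_scenario(c(0, 1), c(0.5, 0.5), c(0.2, 0.2)), "period")
  expect_error(ghost_scenario(c(1, 0.1), c(0.5, 0.3), c(0.6, 0.2)),
               "must exist before")
})

test_that("the shift conditions hold on the canonical reversed scenario", {
  # ghost 1 transferred earlier (tau 0.4 > 0.3) but diverged later
  # (d 0.5 < 0.9): divergence order reverses transfer order, both in period
  sc <- ghost_scenario(c(1, 0.1), d = c(0.5, 0.9), tau = c(0.4, 0.3))
  expect_true(shift_possible(sc))

  # condition (a): a divergence outside the period forbids the shift
  sc_a <- ghost_scenario(c(1, 0.45), d = c(0.5, 1.3), tau = c(0.5, 0.46))
  out <- shift_possible(sc_a)
  expect_false(out)
  expect_true("a" %in% attr(out, "failed"))

  # conditions (b)-(c): divergence order matching transfer order forbids it
  sc_bc <- ghost_scenario(c(1, 0.1), d = c(0.9, 0.5), tau = c(0.4, 0.3))
  out2 <- shift_possible(sc_bc)
  expect_false(out2)
  expect_true("bc" %in% attr(out2, "failed"))

  expect_error(shift_possible(ghost_scenario(c(1, 0.1), c(0.5, 0.6), c(0.3, 0.3))),
               "distinct")
})

test_that("shift_possible agrees with the tiny-tree oracle on a coarse grid", {
  lv <- c(0.2, 0.45, 0.7, 0.95)
  combos <- expand.grid(d1 = lv, t1 = lv, d2 = lv, t2 = lv)
  combos <- combos[combos$d1 >= combos$t1 & combos$d2 >= combos$t2 &
                     combos$t1 != combos$t2, ]
  period <- c(1, 0.1)
  for (k in seq_len(nrow(combos))) {
    x <- combos[k, ]
    sc <- ghost_scenario(period, c(x$d1, x$d2), c(x$t1, x$t2))
    expect_identical(as.logical(shift_possible(sc)),
                     shift_oracle(x$d1, x$t1, x$d2, x$t2),
                     info = paste(unlist(x), collapse = ","))
  }
})
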