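id_roles <- c(`1` = "background", `2` = "leaf", `3` = "fruit")

test_that("segmentation accuracy counts role-matching pixels", {
  gt <- matrix(c(1L, 2L, 3L, 1L), 2, 2)
  expect_equal(acc_seg(gt, id_roles, gt, id_roles), 1)
  pred <- matrix(c(2L, 1L, 1L, 2L), 2, 2)  # disagrees everywhere
  expect_equal(acc_seg(pred, id_roles, gt, id_roles), 0)
  pred2 <- gt; pred2[2, 2] <- 3L           # 3 of 4 agree
  expect_equal(acc_seg(pred2, id_roles, gt, id_roles), 0.75)
  expect_error(acc_seg(matrix(1L, 2, 3), id_roles, gt, id_roles), "extents")
})

test_that("metrics compare roles, not raw cluster indices", {
  gt <- matrix(c(1L, 2L, 3L, 3L), 2, 2)
  # prediction uses permuted cluster indices but identical roles per pixel
  pred <- matrix(c(3L, 1L, 2L, 2L), 2, 2)
  perm_roles <- c(`3` = "background", `1` = "leaf", `2` = "fruit")
  expect_equal(acc_seg(pred, perm_roles, gt, id_roles), 1)
  rep1 <- evaluate_segmentation(pred, gt, perm_roles, id_roles)
  rep2 <- evaluate_segmentation(gt, gt, id_roles, id_roles)
  expect_equal(unclass(rep1), unclass(rep2))
})

test_that("fruit accuracy and rates reproduce their defining ratios", {
  gt <- matrix(FALSE, 4, 5); gt[1:2, 1:5] <- TRUE     # a = 10
  pred <- gt; pred[2, 4:5] <- FALSE; pred[4, 1] <- FALSE
  pred[2, 4] <- FALSE                                  # 7 of 10 matched
  pred_7 <- gt; pred_7[2, 3:5] <- FALSE                # l_fruit = 7
  expect_equal(acc_fruit(pred_7, gt), 0.7)
  expect_equal(acc_fruit(gt, gt), 1)
  expect_equal(acc_fruit(!gt, gt), 0)                  # disjoint masks
  superset <- gt; superset[3, 1] <- TRUE               # pred contains all gt fruit
  expect_equal(acc_fruit(superset, gt), 1)
  expect_error(acc_fruit(gt, matrix(FALSE, 4, 5)), "no fruit")

  # P_gt = 8, P_over = 2 -> Seg_over = 0.2
  gt8 <- matrix(FALSE, 4, 4); gt8[1:2, 1:4] <- TRUE
  p_over2 <- gt8; p_over2[3, 1:2] <- TRUE
  expect_equal(unname(seg_rates(p_over2, gt8)), c(0.2, 0))
  # P_gt = 10, P_under = 4 -> Seg_under = 0.4
  gt10 <- matrix(FALSE, 4, 5); gt10[1:2, 1:5] <- TRUE
  p_und <- gt10; p_und[2, 2:5] <- FALSE
  expect_equal(unname(seg_rates(p_und, gt10)), c(0, 0.4))
  expect_equal(unname(seg_rates(gt10, gt10)), c(0, 0))
  expect_error(seg_rates(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)), "no fruit")
})

test_that("randomized masks match the brute-force counting oracle", {
  set.seed(99)
  for (trial in 1:100) {
    pred <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    gt <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
    rep <- evaluate_segmentation(pred, gt, id_roles, id_roles)
    oracle <- brute_metrics(as.vector(pred), as.vector(gt))
    expect_equal(rep$acc_seg, oracle$acc_seg)
    expect_equal(rep$acc_fruit, oracle$acc_fruit)
    expect_equal(rep$seg_over, oracle$seg_over)
    expect_equal(rep$seg_under, oracle$seg_under)
    # structural identities
    expect_equal(rep$p_under, rep$a - rep$l_fruit)
    if (!is.na(rep$seg_over)) {
      expect_equal(rep$seg_over + rep$p_gt / (rep$p_gt + rep$p_over), 1)
    }
  }
})

test_that("degenerate predictions yield the forced metric values", {
  s <- tiny_scene(seed = 2)
  all_bg <- matrix(1L, nrow(s$labels), ncol(s$labels))
  rep <- evaluate_segmentation(all_bg, s, pred_roles = id_roles)
  expect_equal(rep$acc_fruit, 0)
  expect_equal(rep$seg_under, 1)   # P_over = 0, so Seg_under = P_under / P_gt
  expect_equal(rep$p_over, 0)
  perfect <- evaluate_segmentation(s$labels, s, pred_roles = s$roles)
  expect_equal(perfect$acc_seg, 1)
  expect_equal(perfect$acc_fruit, 1)
  expect_equal(perfect$seg_over, 0)
  expect_equal(perfect$seg_under, 0)
  expect_equal(perfect$k_matching, length(s$labels))
})
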