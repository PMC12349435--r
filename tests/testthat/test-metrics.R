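# Evaluation metrics: closed-form examples first, then behaviour on
# composed cases; the bulk oracle-equivalence sweeps live with the
# acceptance properties.

mk <- function(h, w, idx) { m <- matrix(0L, h, w); m[idx] <- 1L; m }

test_that("dice matches hand-computed overlaps and flags empty pairs", {
  a <- mk(10, 10, 1:30)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(mk(10, 10, 1:10), mk(10, 10, 51:60)), 0)
  # |A| = 100, |B| = 50, |A n B| = 25
  a2 <- mk(20, 20, 1:100); b2 <- mk(20, 20, 76:125)
  expect_equal(dice(a2, b2), 2 * 25 / 150)
  e <- dice(mk(5, 5, integer(0)), mk(5, 5, integer(0)))
  expect_equal(as.numeric(e), 1)
  expect_true(attr(e, "empty_pair"))
  expect_error(dice(mk(5, 5, 1), mk(6, 5, 1)), "shape mismatch")
  # symmetry
  expect_equal(dice(a2, b2), dice(b2, a2))
})

test_that("mean error keeps the sign of over/under-segmentation", {
  t <- mk(10, 10, 1:20)
  expect_equal(mean_error(t, t), 0)
  expect_equal(mean_error(mk(10, 10, integer(0)), mk(10, 10, 1:100)), 1)
  # truth = [1,1,0,0], pred = [1,0,1,0]
  expect_equal(mean_error(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2)), 0)
  expect_gt(mean_error(t, mk(10, 10, 1:40)), 0)  # pred superset -> positive
  expect_lt(mean_error(t, mk(10, 10, 1:10)), 0)  # pred subset -> negative
})

test_that("pixel precision/recall match set algebra", {
  t <- mk(20, 20, 1:100)
  pp <- pixel_precision_recall(t, t)
  expect_equal(c(pp$precision, pp$recall), c(1, 1))
  sup <- pixel_precision_recall(t, mk(20, 20, 1:200))
  expect_equal(c(sup$precision, sup$recall), c(0.5, 1))
  # truth 100 px, pred 80 px, 60 overlap
  mix <- pixel_precision_recall(t, mk(20, 20, 41:120))
  expect_equal(c(mix$precision, mix$recall), c(0.75, 0.6))
  empty <- pixel_precision_recall(t, mk(20, 20, integer(0)))
  expect_equal(empty$precision, 1)
  expect_false(empty$precision_defined)
})

test_that("instance matching reproduces the stated small cases", {
  tr <- matrix(0L, 30, 30)
  tr[2:10, 2:10] <- 1L; tr[2:10, 15:25] <- 2L; tr[20:28, 5:15] <- 3L
  mm <- match_instances(tr, tr)
  expect_identical(c(mm$TP, mm$FP, mm$FN), c(3L, 0L, 0L))
  expect_equal(mm$pairs$dice, rep(1, 3))
  # a pred overlapping nothing is a false positive
  pr <- tr; pr[12:14, 27:29] <- 4L
  mm2 <- match_instances(pr, tr)
  expect_identical(c(mm2$TP, mm2$FP, mm2$FN), c(3L, 1L, 0L))
  # a 2x2 dice matrix ~[[0.60, 0.20], [0.34, 0.51]] must match diagonally;
  # masks chosen so both preds and both truths are disjoint
  pm <- matrix(0L, 40, 40); tm <- matrix(0L, 40, 40)
  pm[1:100] <- 1L; pm[301:400] <- 2L
  tm[c(41:100, 301:320, 501:520)] <- 1L  # d(p1,t1)=0.6, d(p2,t1)=0.2
  tm[c(11:40, 341:385)] <- 2L            # d(p1,t2)=0.343, d(p2,t2)=0.514
  pd <- match_instances(pm, tm)
  expect_identical(pd$pairs$pred, c(1L, 2L))
  expect_identical(pd$pairs$truth, c(1L, 2L))
  orc <- oracle_match(oracle_dice_matrix(pm, tm)$d, 0.1)
  expect_identical(pd$TP, orc$count)
  expect_equal(sum(pd$pairs$dice), orc$total, tolerance = 1e-12)
})

test_that("average precision reproduces the hand-computed staircase", {
  tr <- matrix(0L, 20, 40)
  tr[2:10, 2:10] <- 1L; tr[2:10, 20:30] <- 2L
  # three detections scored [0.9, 0.8, 0.7] realizing [TP, FP, TP]
  d1 <- tr == 1L
  d2 <- matrix(FALSE, 20, 40); d2[15:18, 35:39] <- TRUE
  d3 <- tr == 2L
  ap <- average_precision(list(d1, d2, d3), tr, scores = c(0.9, 0.8, 0.7))
  expect_equal(as.numeric(ap), 5 / 6, tolerance = 1e-12)
  expect_equal(as.numeric(ap), oracle_ap(c(TRUE, FALSE, TRUE), 2),
               tolerance = 1e-12)
  # single matching pred
  expect_equal(as.numeric(average_precision(list(d1), tr * (tr == 1L))), 1)
  # nothing matches
  expect_equal(as.numeric(average_precision(list(d2), tr)), 0)
  # empty cases
  expect_equal(as.numeric(average_precision(list(), tr)), 0)
  ap0 <- average_precision(list(), matrix(0L, 4, 4))
  expect_true(is.na(ap0) && attr(ap0, "undefined"))
  expect_equal(as.numeric(average_precision(list(d2), matrix(0L, 20, 40))), 0)
})

test_that("AP is stable under permutations of tied scores on equivalent detections", {
  tr <- matrix(0L, 20, 20); tr[2:10, 2:10] <- 1L; tr[12:18, 12:18] <- 2L
  dets <- list(tr == 1L, tr == 2L)
  a1 <- as.numeric(average_precision(dets, tr, scores = c(1, 1)))
  a2 <- as.numeric(average_precision(rev(dets), tr, scores = c(1, 1)))
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("paired t test matches closed form, base t.test, and handles degeneracy", {
  d <- c(0.1, -0.2, 0.3, 0.0, 0.2)
  x <- runif(5); y <- x - d
  out <- paired_t_test(x, y)
  expect_equal(out$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-12)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(out$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(out$p_value, oracle_t_pvalue(out$t, 4), tolerance = 1e-9)
  # x = y
  same <- paired_t_test(1:4, 1:4)
  expect_equal(c(same$t, same$p_value), c(0, 1))
  # constant nonzero difference: flagged infinite t
  inf <- paired_t_test(c(2, 3, 4, 5), c(1, 2, 3, 4))
  expect_true(is.infinite(inf$t) && inf$p_value == 0 && inf$degenerate)
  expect_error(paired_t_test(1:3, 1:4), "paired")
  expect_error(paired_t_test(1, 1), "at least 2")
})

test_that("evaluate_run aggregates per tree, per image, and overall", {
  tr <- matrix(0L, 30, 30)
  tr[2:10, 2:10] <- 1L; tr[2:10, 15:25] <- 2L
  perfect <- evaluate_run(list(a = tr, b = tr), list(a = tr, b = tr))
  expect_equal(perfect$summary$mean_dice, 1)
  expect_equal(perfect$summary$mean_me, 0)
  expect_equal(perfect$summary$mean_ap, 1)
  # empty predictions: dice 0 over truths, FN = total trees
  none <- evaluate_run(list(a = matrix(0L, 30, 30)), list(a = tr))
  expect_equal(none$summary$mean_dice, 0)
  expect_identical(sum(none$per_image$fn), 2L)
  expect_equal(none$summary$instance_recall, 0)
  # unpaired images warn but do not fail
  expect_warning(evaluate_run(list(a = tr, z = tr), list(a = tr)), "unpaired")
})

test_that("reports round-trip to CSV and compare via the paired t test", {
  tr <- matrix(0L, 30, 30); tr[2:10, 2:10] <- 1L
  half <- tr; half[2:5, 2:10] <- 0L
  a <- evaluate_run(list(i1 = tr, i2 = tr), list(i1 = tr, i2 = tr))
  b <- evaluate_run(list(i1 = half, i2 = half), list(i1 = tr, i2 = tr))
  td <- withr::local_tempdir()
  write_eval_report(a, file.path(td, "rep"))
  expect_true(file.exists(file.path(td, "rep.csv")))
  got <- readr::read_csv(file.path(td, "rep_summary.csv"),
                         show_col_types = FALSE)
  expect_equal(got$mean_dice, 1)
  cmp <- compare_reports(a, b)
  expect_true(cmp$degenerate)  # identical differences on both images
  expect_gt(cmp$mean_diff, 0)
})
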