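# Count readout, peak localisation + matching, and the four counting
# metrics.

test_that("count readout integrates the density map", {
  expect_equal(count_from_density(matrix(0, 16, 16)), 0L)
  pts <- data.frame(x = c(10, 40, 44, 12, 25), y = c(10, 40, 8, 44, 25))
  target <- points_to_density(pts, c(56, 56))
  expect_equal(count_from_density(target), 5L)
  two <- points_to_density(data.frame(x = c(8, 24), y = c(8, 24)), c(32, 32))
  expect_equal(count_from_density(two), 2L)
  expect_error(count_from_density(matrix(-0.1, 4, 4)), "negative")
})

test_that("peaks at the truth give zero omissions and false detections", {
  pts <- data.frame(x = c(10, 40, 44, 12), y = c(10, 40, 8, 44))
  pred <- points_to_density(pts, c(56, 56))
  s <- localize_and_match(pred, pts, radius = 4)
  expect_equal(s$Nm, 0L)
  expect_equal(s$Nf, 0L)
  expect_equal(s$NE, 4L)

  empty <- matrix(0, 56, 56)
  gt5 <- data.frame(x = seq(5, 45, 10), y = seq(5, 45, 10))
  s2 <- localize_and_match(empty, gt5, radius = 4)
  expect_equal(s2$Nm, 5L)
  expect_equal(s2$NE, 0L)
  expect_equal(s2$Nf, 0L)
})

test_that("spurious far-away peaks count as commissions, not omissions", {
  gt <- data.frame(x = c(10, 20), y = c(10, 20))
  peaks <- data.frame(x = c(10, 20, 50), y = c(10, 20, 50))
  pred <- points_to_density(peaks, c(64, 64))
  s <- localize_and_match(pred, gt, radius = 4)
  expect_equal(s$Nm, 0L)
  expect_equal(s$Nf, 1L)
  # brute-force optimal matching agrees on this instance
  expect_equal(s$NA_ - s$Nm, oracle_max_matching(peaks, gt, 4))
})

test_that("greedy matching is optimal-size on small random instances", {
  set.seed(12)
  for (i in 1:60) {
    np <- sample(0:8, 1); ng <- sample(0:8, 1)
    pred <- data.frame(x = runif(np, 0, 30), y = runif(np, 0, 30))
    gt <- data.frame(x = runif(ng, 0, 30), y = runif(ng, 0, 30))
    r <- runif(1, 2, 8)
    greedy <- swincount:::greedy_match(pred, gt, r)
    best <- oracle_max_matching(pred, gt, r)
    expect_lte(greedy, best)
    # greedy-by-distance may in principle fall short of optimal, but never
    # by more than a factor of two (standard maximal-matching bound)
    expect_gte(2 * greedy, best)
  }
})

test_that("the four metrics reproduce the published worked examples", {
  # dataset-level counts: 230 images, 73286 actual, 72598 detected,
  # 912 omitted, 709 false
  expect_equal(round(estimation_error(72598, 73286), 2), 0.94)
  expect_equal(round(commission_error(709, 73286), 2), 0.97)
  expect_equal(round(omission_error(912, 73286), 1), 1.2)
  expect_equal(round(overall_accuracy(72598, 73286), 2), 99.06)
})

test_that("metric edge cases and error handling", {
  expect_equal(overall_accuracy(50, 50), 100)
  expect_equal(overall_accuracy(0, 10), 0)
  expect_equal(omission_error(0, 10), 0)
  expect_equal(omission_error(10, 10), 100)
  expect_equal(commission_error(0, 10), 0)
  expect_equal(commission_error(10, 10), 100)
  expect_equal(estimation_error(10, 10), 0)
  expect_equal(estimation_error(20, 10), 100)
  expect_error(overall_accuracy(5, 0), "undefined")
  expect_error(count_summary(NA_ = 3, NE = 4, Nm = 5, Nf = 0), "exceed")
})

test_that("estimation error is symmetric and zero only at equality", {
  set.seed(13)
  for (i in 1:50) {
    na <- sample(1:500, 1); delta <- sample(0:na, 1)
    expect_equal(estimation_error(na + delta, na),
                 estimation_error(na - delta, na))
    if (delta > 0) expect_gt(estimation_error(na + delta, na), 0)
  }
  # omissions and matches partition the actual trees
  for (i in 1:20) {
    na <- sample(1:100, 1); nm <- sample(0:na, 1)
    s <- count_summary(NA_ = na, NE = sample(0:150, 1), Nm = nm, Nf = 3)
    expect_equal(omission_error(s$Nm, s$NA_) + s$matched / s$NA_ * 100, 100)
  }
})

test_that("evaluation pools counts across images", {
  gt <- rbind(data.frame(image = "one.png",
                         x = seq(10, 100, 10), y = seq(10, 100, 10)),
              data.frame(image = "two.png",
                         x = rep(seq(10, 50, 10), 4),
                         y = rep(seq(10, 40, 10), each = 5)))
  # predictions: 9 of 10 for image one, 21 (20 + 1 spurious) for image two
  p1 <- points_to_density(gt[gt$image == "one.png", ][1:9, c("x", "y")],
                          c(112, 112))
  p2pts <- rbind(gt[gt$image == "two.png", c("x", "y")],
                 data.frame(x = 100, y = 100))
  p2 <- points_to_density(p2pts, c(112, 112))
  res <- evaluate(list(one.png = p1, two.png = p2), gt, radius = 4)
  expect_equal(res$pooled$ee, 0)               # 9 + 21 vs 10 + 20
  expect_equal(res$per_image$ee, c(10, 5))
  expect_equal(res$pooled$counts$NE, 30L)
  expect_equal(res$pooled$counts$Nm, 1L)
  expect_equal(res$pooled$counts$Nf, 1L)
  # single-image case reduces to the per-image operations
  solo <- evaluate(list(one.png = p1), gt[gt$image == "one.png", ],
                   radius = 4)
  expect_equal(solo$pooled$ee, solo$per_image$ee)

  expect_error(evaluate(list(one.png = p1), gt, radius = 4),
               "two.png")
})

test_that("pooled rates recompute the published table from its counts", {
  s <- count_summary(NA_ = 73286, NE = 72598, Nm = 912, Nf = 709)
  r <- metric_report(s)
  expect_equal(round(r$ee, 2), 0.94)
  expect_equal(round(r$cer, 2), 0.97)
  expect_equal(round(r$oer, 1), 1.2)
  expect_lt(r$ee_signed, 0)                    # under-count is signed
})
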