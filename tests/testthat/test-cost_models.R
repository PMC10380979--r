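# Cost formulas of both models and the pairwise equal-cost boundary line.

test_that("expected misclassification cost matches direct evaluation", {
  # perfect classifier incurs no cost
  expect_equal(misc_expected_cost(predictor_profile("perfect", 1, 1),
                                  rho = 0.3, c0 = 5, c1 = 2), 0)
  # frozen value: 0.5*0.08*1 + 0.5*0.06*1
  expect_equal(misc_expected_cost(predictor_profile("REVEL", 0.92, 0.94),
                                  rho = 0.5, c0 = 1, c1 = 1), 0.07)
  # always-wrong classifier under symmetric unit costs
  expect_equal(misc_expected_cost(predictor_profile("wrong", 0, 0),
                                  rho = 0.5, c0 = 1, c1 = 1), 1)
  # dividing by cT equals the normalized cost at rc1 = c1/cT
  p <- predictor_profile("X", 0.85, 0.75)
  c0 <- 3; c1 <- 2
  expect_equal(misc_expected_cost(p, 0.2, c0, c1) / (c0 + c1),
               misc_normalized_cost(p, 0.2, rc1 = c1 / (c0 + c1)))
  expect_error(misc_expected_cost(p, 0.2, -1, 1), "non-negative")
  expect_error(misc_expected_cost(p, 0.2, 0, 0), "positive")
})

test_that("normalized misclassification cost matches the line form", {
  p <- predictor_profile("REVEL", 0.92, 0.94)
  expect_equal(misc_normalized_cost(p, 0.5, 0.5), 0.035)
  # perfect classifier: zero everywhere
  expect_equal(misc_normalized_cost(predictor_profile("perfect", 1, 1),
                                    0.37, c(0, 0.2, 0.9, 1)), rep(0, 4))
  # intercept limit: rc -> rho * (1 - se) as rc1 -> 0
  expect_equal(misc_normalized_cost(p, 0.25, 0), 0.25 * (1 - 0.92))
  expect_error(misc_normalized_cost(p, 0.5, 1.2), "\\[0, 1\\]")
  # agrees with the two-term definition on random scenarios
  set.seed(11)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1); rho <- runif(1, 0.01, 0.99)
    rc1 <- runif(5)
    expect_equal(misc_normalized_cost(predictor_profile("p", se, sp), rho, rc1),
                 ref_misc_rc(se, sp, rho, rc1), tolerance = 1e-14)
  }
})

test_that("rejection-model normalized cost matches the plane form", {
  # alpha = 0: everything rejected, rc = rc2
  p0 <- predictor_profile("reject_all", 0.5, 0.5, alpha = 0)
  expect_equal(miscrej_normalized_cost(p0, 0.5, 0.2, 0.3), 0.5)
  expect_equal(miscrej_normalized_cost(p0, 0.9, 0, 0), 1)
  # alpha = 1 on the hypotenuse reduces to the misclassification model
  p <- predictor_profile("REVEL", 0.92, 0.94)
  expect_equal(miscrej_normalized_cost(p, 0.5, 0.7, 0.3),
               misc_normalized_cost(p, 0.5, 0.3))
  # frozen value
  expect_equal(miscrej_normalized_cost(p, 0.5, 0.3, 0.3), 0.021)
  expect_error(miscrej_normalized_cost(p, 0.5, 0.7, 0.7), "triangle")
  # agrees with the three-term definition on random scenarios
  set.seed(12)
  for (i in 1:20) {
    se <- runif(1); sp <- runif(1); al <- runif(1); rho <- runif(1, 0.01, 0.99)
    pt <- sample_triangle(5)
    expect_equal(
      miscrej_normalized_cost(predictor_profile("p", se, sp, al), rho,
                              pt[, 1], pt[, 2]),
      ref_miscrej_rc(se, sp, al, rho, pt[, 1], pt[, 2]),
      tolerance = 1e-14)
  }
})

test_that("normalized costs stay in [0, 1] and decrease in se and sp", {
  set.seed(13)
  for (i in 1:50) {
    se <- runif(1); sp <- runif(1); al <- runif(1); rho <- runif(1, 0.01, 0.99)
    p <- predictor_profile("p", se, sp, al)
    rc1 <- runif(3)
    v1 <- misc_normalized_cost(p, rho, rc1)
    expect_true(all(v1 >= 0 & v1 <= 1))
    pts <- sample_triangle(3)
    v2 <- miscrej_normalized_cost(p, rho, pts[, 1], pts[, 2])
    expect_true(all(v2 >= 0 & v2 <= 1))
    # monotone: improving se or sp never increases the cost
    d <- runif(1, 0, 1 - max(se, sp))
    expect_true(all(misc_normalized_cost(
      predictor_profile("q", min(se + d, 1), sp), rho, rc1) <= v1 + 1e-14))
    expect_true(all(miscrej_normalized_cost(
      predictor_profile("q", se, min(sp + d, 1), al), rho,
      pts[, 1], pts[, 2]) <= v2 + 1e-14))
  }
})

test_that("boundary line equalizes the two classifiers' costs", {
  a <- predictor_profile("A", 0.9, 0.7)
  b <- predictor_profile("B", 0.7, 0.9)
  l <- boundary_line(a, b, 0.5)
  expect_false(l$coincident)
  # derived coefficients: -0.1 rc0 + 0.1 rc1 = 0, i.e. the rc0 = rc1 line
  expect_equal(l$a, -0.1)
  expect_equal(l$b, 0.1)
  expect_equal(l$c, 0)
  # equal coverages: line passes through the origin
  expect_equal(boundary_line(predictor_profile("C", 0.8, 0.6, 0.7),
                             predictor_profile("D", 0.6, 0.9, 0.7), 0.3)$c, 0)
  # identical profiles under different names: coincident flag
  expect_true(boundary_line(predictor_profile("E", 0.8, 0.8, 0.9),
                            predictor_profile("F", 0.8, 0.8, 0.9), 0.5)$coincident)
  expect_error(boundary_line(a, a, 0.5), "distinct")
})

test_that("sampled points on a boundary line give equal costs", {
  set.seed(14)
  for (i in 1:25) {
    ps <- generate_profiles(2, seed = 300 + i)
    rho <- sample(c(0.001, 0.01, 0.1, 0.5), 1)
    l <- boundary_line(ps[1, ], ps[2, ], rho)
    if (l$coincident) next
    # parametrize 100 points on the line inside the unit box
    if (abs(l$b) > abs(l$a)) {
      x <- seq(0, 1, length.out = 100)
      y <- -(l$a * x + l$c) / l$b
    } else {
      y <- seq(0, 1, length.out = 100)
      x <- -(l$b * y + l$c) / l$a
    }
    keep <- x >= 0 & y >= 0 & x + y <= 1
    if (!any(keep)) next
    d <- abs(ref_miscrej_rc(ps$se[1], ps$sp[1], ps$alpha[1], rho, x[keep], y[keep]) -
             ref_miscrej_rc(ps$se[2], ps$sp[2], ps$alpha[2], rho, x[keep], y[keep]))
    expect_lt(max(d), 1e-10)
  }
})

test_that("rejection is the only cost at the rc2 corner", {
  set.seed(15)
  for (i in 1:10) {
    al <- runif(1)
    p <- predictor_profile("p", runif(1), runif(1), al)
    expect_equal(miscrej_normalized_cost(p, runif(1, 0.1, 0.9), 0, 0), 1 - al)
  }
})

test_that("profile validation rejects out-of-range and duplicate inputs", {
  expect_error(profile_set("A", 1.2, 0.5), "\\[0, 1\\]")
  expect_error(profile_set(c("A", "A"), c(0.5, 0.6), c(0.5, 0.6)), "duplicate")
  expect_error(predictor_profile("A", NA, 0.5), "finite")
  expect_error(misc_normalized_cost(predictor_profile("A", 0.9, 0.9), 1.5, 0.5),
               "rho")
})
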