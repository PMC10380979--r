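# Arrangement construction, face enumeration and the full 2-D partition.

test_that("arrangement of no lines is the bare triangle", {
  g <- build_arrangement(data.frame(a = numeric(0), b = numeric(0),
                                    c = numeric(0)))
  expect_equal(nrow(g$vertices), 3L)
  expect_equal(nrow(g$edges), 3L)
  faces <- enumerate_faces(g)
  expect_length(faces, 1L)
  expect_equal(attr(faces[[1]], "area"), 0.5, tolerance = 1e-14)
})

test_that("one interior line splits the triangle into two faces", {
  # vertical line rc0 = 0.4: crosses the bottom side and the hypotenuse
  g <- build_arrangement(data.frame(a = 1, b = 0, c = -0.4))
  expect_equal(nrow(g$vertices), 5L)
  expect_equal(nrow(g$edges), 6L)
  faces <- enumerate_faces(g)
  expect_length(faces, 2L)
  areas <- sort(vapply(faces, attr, numeric(1), "area"))
  # left trapezoid-free split: triangle piece 0.6^2/2 = 0.18, rest 0.32
  expect_equal(areas, c(0.18, 0.32), tolerance = 1e-12)
  # a line through the corner (rc0 = rc1) still yields a clean two-face split
  g2 <- build_arrangement(data.frame(a = 1, b = -1, c = 0))
  faces2 <- enumerate_faces(g2)
  expect_length(faces2, 2L)
  expect_equal(sum(vapply(faces2, attr, numeric(1), "area")), 0.5,
               tolerance = 1e-12)
})

test_that("concurrent lines share a single merged vertex", {
  # three lines through (0.4, 0.3)
  lines <- data.frame(a = c(1, 1, 1), b = c(-1, 1, 0),
                      c = c(-0.1, -0.7, -0.4))
  g <- build_arrangement(lines)
  hits <- which(abs(g$vertices[, 1] - 0.4) < 1e-9 &
                abs(g$vertices[, 2] - 0.3) < 1e-9)
  expect_length(hits, 1L)
  faces <- enumerate_faces(g)
  expect_equal(sum(vapply(faces, attr, numeric(1), "area")), 0.5,
               tolerance = 1e-10)
  expect_length(faces, 6L)  # 3 concurrent lines -> 6 wedges
})

test_that("two generically crossing lines give four faces", {
  lines <- data.frame(a = c(1, 0), b = c(0, 1), c = c(-0.4, -0.3))
  faces <- enumerate_faces(build_arrangement(lines))
  expect_length(faces, 4L)
  expect_equal(sum(vapply(faces, attr, numeric(1), "area")), 0.5,
               tolerance = 1e-12)
})

test_that("coincident duplicate lines and side-collinear lines are dropped", {
  lines <- data.frame(a = c(1, 2, 0, 1, 1), b = c(0, 0, 1, 1, 0),
                      c = c(-0.4, -0.8, 0, -1, -0.4))
  # line 2 duplicates line 1; line 3 is the rc0 axis; line 4 the hypotenuse
  g <- build_arrangement(lines)
  expect_equal(g$n_lines, 1L)
  expect_length(enumerate_faces(g), 2L)
})

test_that("faces are convex, disjoint and cover the triangle", {
  for (trial in 1:6) {
    n <- c(3, 5, 8, 11, 14, 17)[trial]
    rho <- c(0.5, 0.1, 0.01, 0.001, 0.5, 0.1)[trial]
    ps <- generate_profiles(n, seed = 700 + trial)
    part <- partition_triangle(ps, rho)
    areas <- vapply(part$faces, attr, numeric(1), "area")
    expect_equal(sum(areas), 0.5, tolerance = 1e-10)
    expect_true(all(vapply(part$faces, costspace:::is_convex_polygon, TRUE)))
    expect_equal(sum(part$summary$fraction), 1, tolerance = 1e-9)
    # random scenarios lie in exactly one face (strictly, away from edges)
    set.seed(800 + trial)
    pts <- sample_triangle(300)
    n_hits <- vapply(seq_len(300), function(k) {
      sum(vapply(part$faces, function(f) {
        point_in_convex(pts[k, ], f, tol = -1e-9)  # strict interior
      }, TRUE))
    }, integer(1))
    expect_true(all(n_hits <= 1L))
    on_edge <- vapply(seq_len(300), function(k) {
      any(vapply(part$faces, function(f) {
        point_in_convex(pts[k, ], f, tol = 1e-9) &&
          !point_in_convex(pts[k, ], f, tol = -1e-9)
      }, TRUE))
    }, TRUE)
    expect_true(all(n_hits == 1L | on_edge))
  }
})

test_that("face winners assigned at the vertex average hold across the face", {
  set.seed(25)
  for (trial in 1:5) {
    ps <- generate_profiles(6, seed = 900 + trial)
    rho <- c(0.001, 0.01, 0.1, 0.5, 0.5)[trial]
    part <- partition_triangle(ps, rho)
    # sample random faces; the assigned winner must be cost-minimal at
    # random interior points of that face
    for (f in sample(seq_along(part$faces), min(10, length(part$faces)))) {
      poly <- part$faces[[f]]
      for (r in 1:10) {
        pt <- random_interior_point(poly)
        cost <- vapply(seq_len(nrow(ps)), function(i) {
          ref_miscrej_rc(ps$se[i], ps$sp[i], ps$alpha[i], rho, pt[1], pt[2])
        }, numeric(1))
        best <- min(cost)
        winner_cost <- cost[ps$name == part$face_winners[f]]
        expect_lt(winner_cost - best, 1e-9)
      }
    }
  }
})

test_that("assignment handles trivial and degenerate classifier sets", {
  tri <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)
  # single profile wins any polygon
  expect_equal(assign_best_predictor(tri, predictor_profile("only", 0.6, 0.6, 0.5),
                                     0.5)$predictor, "only")
  # a perfect classifier beats an all-rejecting one everywhere
  ps <- profile_set(c("reject_all", "perfect"), se = c(0.5, 1), sp = c(0.5, 1),
                    alpha = c(0, 1))
  part <- partition_triangle(ps, 0.5)
  expect_equal(part$summary$predictor, "perfect")
  expect_equal(part$summary$fraction, 1)
  # identical predictors: single region, first-named wins, tie recorded
  ps2 <- profile_set(c("dup1", "dup2"), se = c(0.8, 0.8), sp = c(0.85, 0.85),
                     alpha = c(0.9, 0.9))
  part2 <- partition_triangle(ps2, 0.5)
  expect_equal(part2$summary$predictor, "dup1")
  expect_equal(part2$summary$fraction, 1)
  expect_true(any(vapply(part2$ties, identical, TRUE, c("dup1", "dup2"))))
})

test_that("merging regions checks tiling and aggregates areas", {
  g <- build_arrangement(data.frame(a = 1, b = 0, c = -0.4))
  faces <- enumerate_faces(g)
  # all faces to one winner: one region with fraction 1
  part <- merge_regions(faces, rep("W", length(faces)))
  expect_equal(part$summary$predictor, "W")
  expect_equal(part$summary$fraction, 1)
  expect_equal(part$summary$n_polygons, 2L)
  # dropping a face breaks the tiling contract
  expect_error(merge_regions(faces[1], "W"), "tile")
})

test_that("region fractions match the independent Monte-Carlo oracle", {
  for (trial in 1:8) {
    n <- c(2, 4, 6, 9, 11, 13, 15, 17)[trial]
    rho <- c(0.5, 0.001, 0.1, 0.01, 0.5, 0.001, 0.1, 0.5)[trial]
    ps <- generate_profiles(n, seed = 1100 + trial)
    part <- partition_triangle(ps, rho)
    mc <- ref_miscrej_mc_fractions(ps, rho, n = 2e5, seed = 1200 + trial)
    expect_equal(full_fractions(part, ps), mc, tolerance = 0.01)
  }
})

test_that("with full coverage the hypotenuse reduces to the 1-D partition", {
  for (trial in 1:4) {
    n <- c(3, 6, 10, 17)[trial]
    rho <- c(0.5, 0.1, 0.01, 0.5)[trial]
    ps <- generate_profiles(n, seed = 1300 + trial, alpha_range = c(1, 1))
    tri <- partition_triangle(ps, rho)
    iv <- partition_interval(ps, rho)
    # at each 1-D interval midpoint, the face just inside the hypotenuse
    # must be owned by the same classifier
    for (i in seq_len(nrow(iv))) {
      m <- (iv$lo[i] + iv$hi[i]) / 2
      pt <- c((1 - m), m) * (1 - 1e-7)
      f <- face_containing(tri, pt)
      expect_false(is.na(f))
      expect_equal(tri$face_winners[f], iv$predictor[i])
    }
  }
})

test_that("grouped partitioning reproduces the direct computation", {
  ps <- generate_profiles(17, seed = 41)
  direct <- partition_triangle(ps, 0.5)
  grouped <- partition_grouped(ps, 0.5, group_size = 6)
  d <- full_fractions(direct, ps)
  g <- full_fractions(grouped, ps)
  expect_equal(d, g, tolerance = 1e-3)
  # survivors identical
  expect_setequal(names(which(d > 1e-9)), names(which(g > 1e-9)))
  # N <= group_size: identical to the direct run
  small <- generate_profiles(5, seed = 42)
  expect_equal(partition_grouped(small, 0.2, group_size = 8)$summary,
               partition_triangle(small, 0.2)$summary)
  expect_error(partition_grouped(ps, 0.5, group_size = 1), "between 2 and 10")
})

test_that("fractions vary continuously along a prevalence sweep", {
  ps <- generate_profiles(8, seed = 43)
  rhos <- seq(0.05, 0.95, by = 0.05)
  sw <- sweep_rho(ps, rhos, model = "miscrej")
  frac <- sw$fractions
  expect_equal(unname(rowSums(frac)), rep(1, length(rhos)), tolerance = 1e-9)
  # neighbouring rho values never jump by more than a grid-consistent bound
  jumps <- abs(diff(frac))
  expect_lt(max(jumps), 0.25)
})
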