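test_that("cluster radius equals the mean member-to-centroid distance", {
  x <- matrix(c(0, 0, 2, 0), ncol = 2, byrow = TRUE)
  expect_equal(cluster_radius(x, 1:2, centroid = c(1, 0)), 1)
  expect_equal(cluster_radius(rbind(c(3, 3), c(3, 3)), 1:2), 0)

  set.seed(2)
  x20 <- matrix(rnorm(40), 20, 2)
  expect_equal(cluster_radius(x20, 1:20), brute_radius(x20, 1:20),
               tolerance = 1e-12)
  expect_error(cluster_radius(x20, integer()), "non-empty")
})

test_that("distinctiveness is centroid separation over summed radii", {
  # identical clusters overlap completely
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(distinctiveness(x, 1:10, 1:10), 0)

  # radii 1 and 1 with centroid distance 2: exactly at the overlap boundary
  xb <- rbind(c(-1, 0), c(1, 0), c(1, 0), c(3, 0))
  expect_equal(distinctiveness(xb, 1:2, 3:4), 1)

  # two point-clusters at distinct locations: undefined overlap
  xp <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_identical(distinctiveness(xp, 1:2, 3:4), Inf)

  # planted blobs: score tracks centroid distance / (r1 + r2) and grows
  # monotonically with the planted separation
  scores <- vapply(c(6, 10, 14), function(d) {
    g <- generate_geometry(2, d, 1, 150, seed = 5)
    distinctiveness(g$points, which(g$assignment == 1),
                    which(g$assignment == 2))
  }, numeric(1))
  expect_gt(scores[2], 4); expect_lt(scores[2], 6)
  expect_true(all(diff(scores) > 0))
})

test_that("distinctiveness is symmetric, translation- and scale-stable", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(60), 30, 2)
    a <- 1:12; b <- 13:30
    s_ab <- distinctiveness(x, a, b)
    expect_equal(s_ab, distinctiveness(x, b, a), tolerance = 1e-12)

    shift <- sweep(x, 2, c(100, -50), `+`)
    expect_equal(distinctiveness(shift, a, b), s_ab, tolerance = 1e-9)
    expect_equal(cluster_radius(shift, a), cluster_radius(x, a),
                 tolerance = 1e-9)

    scaled <- x * 3.7
    expect_equal(distinctiveness(scaled, a, b), s_ab, tolerance = 1e-9)
    expect_equal(cluster_radius(scaled, a), 3.7 * cluster_radius(x, a),
                 tolerance = 1e-9)
  }
})

test_that("prominent_vs_rest enumerates all ordered pairs", {
  g <- generate_geometry(20, 12, 1, 10, seed = 6)
  geom <- cluster_geometry(g$points, g$assignment)
  pv <- prominent_vs_rest(geom, 1:4, 5:20)
  expect_equal(nrow(pv$scores), 64)
  expect_equal(pv$mean, mean(pv$scores$score))

  single <- prominent_vs_rest(geom, 1, 2)
  expect_equal(single$scores$score,
               distinctiveness(g$points, which(g$assignment == 1),
                               which(g$assignment == 2)),
               tolerance = 1e-12)

  expect_error(prominent_vs_rest(geom, 1:4, 4:8), "disjoint")
  expect_error(prominent_vs_rest(geom, 1:4, integer()), "non-empty")
})

test_that("the pooled two-sample t matches its closed form", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # hand-computed: means 2 and 5, pooled variance 1, SE = sqrt(2/3)
  tt <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 4), tolerance = 1e-12)

  welch <- two_sample_t(c(1, 2, 3), c(4, 5, 6), variance = "unequal")
  expect_equal(welch$t, tt$t, tolerance = 1e-12)  # equal variances here
  one <- two_sample_t(c(4, 5, 6), c(1, 2, 3), tail = "one")
  expect_equal(one$p, pt(-abs(tt$t), 4), tolerance = 1e-12)

  expect_error(two_sample_t(1, c(1, 2)), "at least 2")
})

test_that("summary-statistic t reproduces the study-scale comparison", {
  # group summaries shaped like the published distance comparison:
  # means 1.33 vs 1.30, SDs 0.07 and 0.09, ~60 pairs per group
  st <- summary_t(1.33, 0.07, 60, 1.30, 0.09, 64)
  expect_gt(abs(st$t), 2)
  expect_lt(abs(st$t), 2.6)
  expect_equal(st$df, 122)
  expect_lt(st$p, 0.05)
})

test_that("the geometry figure renders deterministically", {
  g <- generate_geometry(4, 10, 1, 15, seed = 8)
  geom <- cluster_geometry(g$points, g$assignment, stance = "pro")
  f1 <- withr::local_tempfile(fileext = ".svg")
  f2 <- withr::local_tempfile(fileext = ".svg")
  res <- plot_geometry(geom, prominent = 1, rest = 2:3, path = f1)
  plot_geometry(geom, prominent = 1, rest = 2:3, path = f2)
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(f2))
  # 1 prominent + 2 rest circles and 2 edges
  expect_equal(nrow(attr(res, "layout")), 3)
  expect_equal(nrow(attr(res, "edges")), 2)
  expect_error(plot_geometry(geom, 1, 2, "figure.bmp"), "extension")

  # zero-radius cluster gets a minimum-size marker and an annotation flag
  pts <- rbind(matrix(0, 5, 2), matrix(rnorm(10, 5), 5, 2))
  geom0 <- cluster_geometry(pts, rep(1:2, each = 5))
  f3 <- withr::local_tempfile(fileext = ".svg")
  res0 <- plot_geometry(geom0, 1, 2, f3)
  lay <- attr(res0, "layout")
  expect_true(lay$zero[lay$id == 1])
  expect_gt(lay$r[lay$id == 1], 0)
})
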