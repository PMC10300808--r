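# Pairwise similarity alignment, Procrustes distance and the GPA mean.

test_that("centroid size has the closed form and scaling behaviour", {
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(centroid_size(two), sqrt(2))  # each point 1 from the centroid

  pts <- rand_landmarks(seed = 10)
  expect_equal(centroid_size(pts * 3), 3 * centroid_size(pts))
  expect_equal(centroid_size(sweep(pts, 2, c(5, -7, 11), `+`)),
               centroid_size(pts))
})

test_that("self-alignment returns the identity transform", {
  pts <- rand_landmarks(seed = 11)
  ap <- align_pair(pts, pts)
  expect_equal(ap$transform$rotation, diag(3), tolerance = 1e-10)
  expect_equal(ap$transform$scale, 1, tolerance = 1e-12)
  expect_equal(unname(ap$transform$translation), c(0, 0, 0), tolerance = 1e-9)
  expect_lt(ap$residual, 1e-10)
})

test_that("alignment recovers a constructed similarity transform", {
  set.seed(12)
  pts <- rand_landmarks()
  R0 <- random_rotation()
  t0 <- c(40, -25, 12)
  target <- sweep(1.7 * pts %*% R0, 2, t0, `+`)
  ap <- align_pair(pts, target)
  expect_equal(ap$transform$rotation, R0, tolerance = 1e-8)
  expect_equal(ap$transform$scale, 1.7, tolerance = 1e-8)
  expect_equal(unname(ap$transform$translation), t0, tolerance = 1e-6)
  expect_lt(ap$residual, 1e-8)
  expect_equal(apply_transform(ap$transform, pts), target, tolerance = 1e-8)
})

test_that("alignment residual matches independent oracles", {
  set.seed(13)
  for (i in 1:2) {
    X <- rand_landmarks()
    Y <- rand_landmarks()
    ap <- align_pair(X, Y)
    expect_equal(ap$residual, oracle_align_residual(X, Y), tolerance = 1e-6)
  }

  # vegan permits reflections, so cross-check it on noisy-similarity pairs
  # where the optimum is unambiguously a proper rotation
  skip_if_not_installed("vegan")
  for (i in 1:5) {
    X <- rand_landmarks()
    Y <- rand_similarity(X) + matrix(rnorm(54, sd = 3), 18, 3)
    ap <- align_pair(X, Y)
    vg <- vegan::procrustes(Y, X, scale = TRUE, symmetric = FALSE)
    expect_equal(ap$residual, sqrt(vg$ss / nrow(X)), tolerance = 1e-6)
  }
})

test_that("rigid alignment fixes scale at one and still optimizes rotation", {
  set.seed(14)
  X <- rand_landmarks()
  R0 <- random_rotation()
  Y <- sweep(X %*% R0, 2, c(3, 4, 5), `+`)
  ap <- align_pair(X, Y, allow_scale = FALSE)
  expect_identical(ap$transform$scale, 1)
  expect_lt(ap$residual, 1e-9)

  skip_if_not_installed("vegan")
  Y2 <- sweep(X %*% random_rotation(), 2, c(-8, 2, 6), `+`) +
    matrix(rnorm(54, sd = 3), 18, 3)
  rigid <- align_pair(X, Y2, allow_scale = FALSE)
  vg <- vegan::procrustes(Y2, X, scale = FALSE, symmetric = FALSE)
  expect_equal(rigid$residual, sqrt(vg$ss / nrow(X)), tolerance = 1e-6)
})

test_that("mirrored targets never elicit improper rotations", {
  set.seed(15)
  for (i in 1:20) {
    X <- rand_landmarks()
    Y <- X
    Y[, 1] <- -Y[, 1]           # reflected copy
    ap <- align_pair(X, Y)
    expect_equal(det(ap$transform$rotation), 1, tolerance = 1e-10)
    expect_gt(ap$residual, 1e-3)  # reflection cannot be reproduced
  }
})

test_that("degenerate and mismatched inputs are rejected", {
  line <- cbind(1:18, 2 * (1:18), 3 * (1:18))
  expect_error(align_pair(line, rand_landmarks(seed = 16)), "rank-deficient")
  expect_error(align_pair(rand_landmarks()[1:17, ], rand_landmarks()),
               "mismatched landmark counts")
  expect_error(gpa_mean(list(rand_landmarks())), "at least two shapes")
})

test_that("procrustes distance is a symmetric similarity-invariant metric", {
  set.seed(17)
  S <- rand_landmarks()
  expect_equal(procrustes_distance(S, S), 0, tolerance = 1e-12)
  expect_lt(procrustes_distance(S, rand_similarity(S)), 1e-8)
  for (i in 1:50) {
    a <- rand_landmarks()
    b <- rand_landmarks()
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-10)
  }
})

test_that("GPA recovers a common shape from congruent copies", {
  set.seed(18)
  base <- rand_landmarks()
  copies <- lapply(1:10, function(i) rand_similarity(base))
  ens <- gpa_mean(copies)
  expect_true(ens$converged)
  expect_lt(procrustes_distance(ens$mean_shape, base), 1e-8)
  expect_equal(centroid_size(ens$mean_shape), 1, tolerance = 1e-12)
})

test_that("the two-shape GPA mean is equidistant from both shapes", {
  set.seed(19)
  a <- rand_landmarks()
  b <- rand_landmarks()
  ens <- gpa_mean(list(a, b))
  d1 <- procrustes_distance(ens$mean_shape, ens$shapes[[1]])
  d2 <- procrustes_distance(ens$mean_shape, ens$shapes[[2]])
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("the GPA mean is invariant to the pose of its inputs", {
  set.seed(20)
  shapes <- lapply(1:12, function(i) {
    rand_landmarks() })
  ens0 <- gpa_mean(shapes)
  reposed <- lapply(shapes, rand_similarity)
  ens1 <- gpa_mean(reposed)
  expect_lt(procrustes_distance(ens0$mean_shape, ens1$mean_shape), 1e-6)
})

test_that("the GPA objective decreases monotonically and the mean stays unit size", {
  co <- generate_cohort(cohort_spec(list(
    cohort_group("g", 15, cal_table$male, sex = "male", noise_sd_mm = 2)),
    seed = 21))
  ens <- gpa_mean(co$specimens)
  expect_true(all(diff(ens$objective) <= 1e-9))
  expect_equal(centroid_size(ens$mean_shape), 1, tolerance = 1e-12)
  # the aligned shapes average to the mean (solver contract)
  avg <- Reduce(`+`, lapply(ens$shapes, function(s) s$points)) /
    length(ens$shapes)
  avg <- avg / centroid_size(avg)
  expect_lt(procrustes_distance(avg, ens$mean_shape), 1e-7)
})
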