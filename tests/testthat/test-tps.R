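# 3D thin-plate spline: interpolation contract, affine absorption,
# regularization, and mesh morphing.

test_that("the identity map has identity affine part and vanishing weights", {
  src <- rand_landmarks(seed = 50)
  tf <- tps_solve(src, src)
  expect_lt(max(abs(tf$weights)), 1e-10)
  expect_equal(unname(tf$affine[2:4, ]), diag(3), tolerance = 1e-9)
  probe <- rand_landmarks(seed = 51)
  expect_equal(tps_apply(tf, probe), probe, tolerance = 1e-10)
})

test_that("exact affine source-target maps are absorbed by the affine part", {
  set.seed(52)
  src <- rand_landmarks()
  shift <- c(12, -7, 30)
  tf <- tps_solve(src, sweep(src, 2, shift, `+`))
  expect_lt(max(abs(tf$weights)), 1e-10)
  probe <- matrix(rnorm(300, sd = 80), 100, 3)
  expect_equal(tps_apply(tf, probe), sweep(probe, 2, shift, `+`),
               tolerance = 1e-8)

  R <- random_rotation()
  tf_rot <- tps_solve(src, src %*% R)
  expect_lt(max(abs(tf_rot$weights)), 1e-10)
  tf_scale <- tps_solve(src, 1.3 * src)
  expect_lt(max(abs(tf_scale$weights)), 1e-10)
})

test_that("lambda = 0 interpolates the targets exactly", {
  set.seed(53)
  for (i in 1:5) {
    src <- rand_landmarks()
    tgt <- rand_landmarks()
    tf <- tps_solve(src, tgt)
    mapped <- tps_apply(tf, src)
    expect_lt(sqrt(mean((mapped - tgt)^2)), 1e-8)
    # side conditions: weights orthogonal to [1 | source]
    expect_lt(max(abs(crossprod(cbind(1, src), tf$weights))), 1e-8)
  }
})

test_that("evaluation agrees with a naive double-loop oracle", {
  set.seed(54)
  src <- rand_landmarks()
  tgt <- rand_landmarks()
  tf <- tps_solve(src, tgt)
  pts <- matrix(rnorm(60, sd = 60), 20, 3)
  fast <- tps_apply(tf, pts)
  slow <- matrix(NA_real_, 20, 3)
  for (i in 1:20) {
    acc <- drop(tf$affine[1, ] + pts[i, ] %*% tf$affine[2:4, ])
    for (j in 1:18) {
      r <- sqrt(sum((pts[i, ] - src[j, ])^2))
      acc <- acc + (-r) * tf$weights[j, ]
    }
    slow[i, ] <- acc
  }
  expect_equal(fast, slow, tolerance = 1e-10)
})

test_that("both kernel sign conventions define the same map", {
  set.seed(55)
  src <- rand_landmarks()
  tgt <- rand_landmarks()
  pts <- matrix(rnorm(30, sd = 50), 10, 3)
  a <- tps_apply(tps_solve(src, tgt, kernel = "minus_r"), pts)
  b <- tps_apply(tps_solve(src, tgt, kernel = "r"), pts)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("bending energy decreases monotonically with regularization", {
  set.seed(56)
  src <- rand_landmarks()
  tgt <- src + matrix(rnorm(54, sd = 5), 18, 3)
  energies <- vapply(c(0, 0.1, 1, 10), function(lam) {
    tps_bending_energy(tps_solve(src, tgt, lambda = lam))
  }, numeric(1))
  expect_true(all(energies >= -1e-10))
  expect_true(all(diff(energies) <= 1e-9))
})

test_that("degenerate control points are rejected with a named reason", {
  flat <- cbind(rnorm(18), rnorm(18), 0)
  expect_error(tps_solve(flat, rand_landmarks()), "coplanar")
  expect_error(tps_solve(rand_landmarks()[1:4, ], rand_landmarks()[1:4, ]),
               "at least 5")
  expect_error(tps_solve(rand_landmarks(), rand_landmarks()[1:17, ]),
               "same landmark count")
  expect_error(tps_solve(rand_landmarks(), rand_landmarks(), lambda = -1),
               "non-negative")
})

test_that("morphing to the template's own shape is the identity", {
  lm <- realize_proportions(cal_table$male_m1, sex = "male")
  mesh <- generate_toy_mesh(lm, subdivisions = 1)
  out <- morph_template(mesh, lm, as_shape(lm$points, normalize = TRUE))
  expect_equal(out$vertices, mesh$vertices, tolerance = 1e-8)
  expect_identical(out$faces, mesh$faces)

  # a uniformly rescaled target differs from the template only by a
  # similarity, which the alignment step absorbs entirely
  ctr <- colMeans(lm$points)
  scaled <- sweep(1.1 * sweep(lm$points, 2, ctr), 2, ctr, `+`)
  out2 <- morph_template(mesh, lm, scaled)
  expect_equal(out2$vertices, mesh$vertices, tolerance = 1e-6)
})

test_that("morphed meshes carry their landmarks onto the rescaled targets", {
  lm <- realize_proportions(cal_table$male_m1, sex = "male")
  mesh <- generate_toy_mesh(lm, subdivisions = 1)
  target <- gpa_mean(generate_cohort(cohort_spec(list(
    cohort_group("m2", 8, cal_table$male_m2, sex = "male",
                 noise_sd_mm = 0.5)), seed = 57))$specimens)$mean_shape

  out <- morph_template(mesh, lm, target)
  expect_identical(out$faces, mesh$faces)
  expect_identical(nrow(out$vertices), nrow(mesh$vertices))

  # independent recomputation of the rescaling contract
  ap <- align_pair(target$points, lm$points, allow_scale = TRUE)
  rescaled <- apply_transform(ap$transform, target$points)
  expect_lt(sqrt(mean((out$landmarks - rescaled)^2)), 1e-6)
  # the morph interpolates: template landmark positions map onto targets
  tf <- tps_solve(lm$points, rescaled)
  expect_lt(sqrt(mean((tps_apply(tf, lm$points) - rescaled)^2)), 1e-8)

  expect_error(morph_template(triangle_mesh(mesh$vertices, mesh$faces),
                              NULL, target), "no landmark annotations")
})
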