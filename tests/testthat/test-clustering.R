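# k-means sub-phenotype discovery, elbow diagnostics, phenotype labels.

test_that("well-separated planted clusters are recovered exactly", {
  set.seed(40)
  X <- rbind(matrix(rnorm(20 * 8, 0, 0.01), 20, 8),
             matrix(rnorm(20 * 8, 1, 0.01), 20, 8))
  colnames(X) <- sprintf("P%02d", 1:8)
  truth <- rep(1:2, each = 20)
  model <- kmeans_fit(X, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(model$assignments, truth), 1)
  expect_identical(model$sizes, c(20L, 20L))
})

test_that("k-means wss attains the brute-force optimum on tiny inputs", {
  set.seed(41)
  X <- matrix(rnorm(12), 6, 2)
  model <- kmeans_fit(X, k = 2, scaling = "none", seed = 1, n_init = 50)
  wss_of <- function(split) {
    sum(vapply(split(seq_len(6), split), function(idx) {
      sub <- X[idx, , drop = FALSE]
      sum(sweep(sub, 2, colMeans(sub))^2)
    }, numeric(1)))
  }
  # enumerate all 2-partitions with both parts non-empty
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    split <- as.integer(intToBits(mask))[1:6] + 1L
    if (length(unique(split)) == 2) best <- min(best, wss_of(split))
  }
  expect_equal(model$wss, best, tolerance = 1e-10)
})

test_that("k = 1 reduces to the feature mean and total variance", {
  set.seed(42)
  X <- matrix(rnorm(30 * 4), 30, 4)
  model <- kmeans_fit(X, k = 1, scaling = "none", seed = 1)
  expect_equal(unname(model$cluster_means[1, ]), unname(colMeans(X)),
               tolerance = 1e-12)
  expect_equal(model$wss, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-10)
})

test_that("fits are reproducible from the seed and are centroid fixed points", {
  set.seed(43)
  X <- matrix(rnorm(50 * 8), 50, 8)
  m1 <- kmeans_fit(X, k = 3, seed = 7)
  m2 <- kmeans_fit(X, k = 3, seed = 7)
  expect_identical(m1$assignments, m2$assignments)
  expect_identical(m1$centroids, m2$centroids)
  expect_identical(m1$wss, m2$wss)
  # reassigning points to the returned centroids reproduces the labels
  expect_equal(unname(assign_clusters(m1, X)), m1$assignments)
  # centroids are the means of their members in the clustering space
  sc <- sweep(sweep(X, 2, m1$scale_center), 2, m1$scale_scale, `/`)
  for (j in seq_len(3)) {
    expect_equal(unname(m1$centroids[j, ]),
                 unname(colMeans(sc[m1$assignments == j, , drop = FALSE])),
                 tolerance = 1e-9)
  }
})

test_that("degenerate and invalid inputs are handled per contract", {
  X <- matrix(1, 10, 8, dimnames = list(NULL, sprintf("P%02d", 1:8)))
  expect_warning(model <- kmeans_fit(X, k = 2, seed = 1),
                 "single effective centroid")
  expect_identical(model$assignments, rep(1L, 10))
  expect_equal(model$wss, 0)

  expect_error(kmeans_fit(matrix(rnorm(8), 2, 4), k = 5, seed = 1),
               "exceeds the number of specimens")
  expect_error(kmeans_fit(matrix(rnorm(8), 2, 4), k = 0, seed = 1),
               "k must be >= 1")
})

test_that("the elbow curve is non-increasing and finds planted structure", {
  set.seed(44)
  X <- rbind(matrix(rnorm(25 * 8, 0, 0.05), 25, 8),
             matrix(rnorm(25 * 8, 2, 0.05), 25, 8))
  colnames(X) <- sprintf("P%02d", 1:8)
  curve <- elbow_curve(X, k_max = 6, seed = 2)
  expect_identical(curve$suggested_k, 2L)
  expect_true(all(diff(curve$wss_values) <= 1e-9))

  blob <- matrix(rnorm(30 * 8, 0, 0.05), 30, 8)
  flat <- elbow_curve(blob, k_max = 5, seed = 3)
  expect_true(all(diff(flat$wss_values) <= 1e-9))
  expect_error(elbow_curve(X, k_max = 50), "smaller than the number")
})

test_that("phenotype labels follow the vertical/transverse ratio P01", {
  base <- matrix(1, 2, 8, dimnames = list(NULL, sprintf("P%02d", 1:8)))

  m <- base; m[, "P01"] <- c(1.178, 1.071)   # male cluster means
  model <- list(k = 2, cluster_means = m, phenotype_labels = rep("unlabelled", 2))
  class(model) <- "cluster_model"
  expect_identical(label_phenotypes(model)$phenotype_labels,
                   c("dolichofacial", "brachyfacial"))

  f <- base; f[, "P01"] <- c(1.034, 1.164)   # female cluster means, reversed
  model$cluster_means <- f
  expect_identical(label_phenotypes(model)$phenotype_labels,
                   c("brachyfacial", "dolichofacial"))

  tie <- base; tie[, "P02"] <- c(1.9, 2.1)   # P01 tied, P02 breaks it
  model$cluster_means <- tie
  expect_identical(label_phenotypes(model)$phenotype_labels,
                   c("brachyfacial", "dolichofacial"))

  model$k <- 3
  expect_warning(out <- label_phenotypes(model), "requires k = 2")
  expect_true(all(out$phenotype_labels == "unlabelled"))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(45)
  for (i in 1:20) {
    a <- sample(1:3, 40, replace = TRUE)
    b <- sample(1:4, 40, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("calibrated two-cluster cohorts are recovered with ARI 1", {
  co <- generate_cohort(cohort_spec(list(
    cohort_group("m1", 23, cal_table$male_m1, sex = "male", true_cluster = 1,
                 noise_sd_mm = 0.5),
    cohort_group("m2", 23, cal_table$male_m2, sex = "male", true_cluster = 2,
                 noise_sd_mm = 0.5)), seed = 46))
  props <- measure_proportions(co)
  truth <- cohort_metadata(co)$true_cluster
  model <- kmeans_fit(props, k = 2, seed = 5)
  expect_equal(adjusted_rand_index(model$assignments, truth), 1)
  model <- label_phenotypes(model)
  doli <- which(model$phenotype_labels == "dolichofacial")
  expect_gt(model$cluster_means[doli, "P01"],
            model$cluster_means[-doli, "P01"])
})
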