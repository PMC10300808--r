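# k-means sub-phenotype discovery on the proportion feature space,
# elbow diagnostics and dolichofacial/brachyfacial labelling.

features_matrix <- function(features) {
  X <- if (is.matrix(features)) features else do.call(rbind, features)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- sprintf("P%02d", seq_len(ncol(X)))
  X
}

scale_features <- function(X, scaling) {
  if (scaling == "none") {
    return(list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1  # constant columns carry no clustering information
  list(X = sweep(sweep(X, 2, ctr), 2, scl, `/`), center = ctr, scale = scl)
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, then
# each next center drawn with probability proportional to squared distance
# to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(X, 2, X[idx[1], ])^2)
    for (j in 2:k) {
      if (all(d2 == 0)) {
        idx[j] <- sample.int(n, 1)
      } else {
        idx[j] <- sample.int(n, 1, prob = d2)
      }
      d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx[j], ])^2))
    }
  }
  X[idx, , drop = FALSE]
}

nearest_center <- function(X, centers) {
  apply(X, 1, function(row) which.min(colSums((t(centers) - row)^2)))
}

run_lloyd <- function(X, centers, max_iter) {
  # stats::kmeans (Lloyd) errors on an empty cluster; repair by reseeding
  # each empty centroid at the point farthest from its current centroid.
  for (attempt in 1:10) {
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = centers, iter.max = max_iter,
                              algorithm = "Lloyd")),
      error = function(e) NULL
    )
    if (!is.null(km)) return(km)
    assign <- nearest_center(X, centers)
    empty <- setdiff(seq_len(nrow(centers)), unique(assign))
    if (length(empty) == 0) empty <- sample.int(nrow(centers), 1)
    for (e in empty) {
      d2 <- rowSums((X - centers[assign, , drop = FALSE])^2)
      centers[e, ] <- X[which.max(d2), ]
      assign <- nearest_center(X, centers)
    }
  }
  stop("k-means failed: persistent empty clusters")
}

#' k-means clustering of proportion vectors
#'
#' Lloyd iterations from k-means++ seedings, best of \code{n_init}
#' restarts by total within-cluster sum of squares; deterministic given
#' \code{seed}. Features are z-score standardized by default: the eight
#' proportions differ about five-fold in magnitude (P05 around 5 versus
#' P04 around 1), so unscaled Euclidean clustering would be dominated by
#' P05.
#'
#' @param features Specimens x proportions matrix or list of proportion
#'   vectors.
#' @param k Number of clusters (>= 1).
#' @param scaling \code{"zscore"} (default) or \code{"none"}.
#' @param seed Integer seed controlling the restarts.
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return A \code{cluster_model}: list with \code{k}, \code{centroids}
#'   (k x p, in the scaled feature space), \code{assignments},
#'   \code{wss}, \code{feature_scaling}, \code{seed},
#'   \code{cluster_means} (k x p, original feature space),
#'   \code{sizes} and \code{phenotype_labels}.
#' @export
#' @examples
#' X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 8), 20))
#' kmeans_fit(X, k = 2, seed = 1)$sizes
kmeans_fit <- function(features, k, scaling = c("zscore", "none"),
                       seed = 1, n_init = 20, max_iter = 100) {
  scaling <- match.arg(scaling)
  X <- features_matrix(features)
  n <- nrow(X)
  if (k < 1) stop("k must be >= 1")
  if (k > n) stop("k (", k, ") exceeds the number of specimens (", n, ")")
  sc <- scale_features(X, scaling)
  Xs <- sc$X

  if (k > 1 && all(apply(Xs, 2, function(col) diff(range(col)) == 0))) {
    warning("all feature vectors identical: single effective centroid")
    centroids <- Xs[rep(1, k), , drop = FALSE]
    model <- list(k = k, centroids = centroids,
                  assignments = rep(1L, n), wss = 0,
                  feature_scaling = scaling, seed = seed,
                  cluster_means = X[rep(1, k), , drop = FALSE],
                  sizes = c(n, rep(0L, k - 1)),
                  scale_center = sc$center, scale_scale = sc$scale,
                  phenotype_labels = rep("unlabelled", k))
    return(structure(model, class = "cluster_model"))
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)

  best <- NULL
  for (i in seq_len(max(1L, n_init))) {
    km <- run_lloyd(Xs, kmeanspp_init(Xs, k), max_iter)
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  # canonical cluster numbering: by order of first appearance in the data
  first_seen <- unique(best$cluster)
  relabel <- match(seq_len(k), first_seen)
  assignments <- relabel[best$cluster]
  centroids <- best$centers[first_seen, , drop = FALSE]
  rownames(centroids) <- NULL
  cluster_means <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(X[assignments == j, , drop = FALSE])
  }))
  structure(
    list(k = k, centroids = centroids, assignments = as.integer(assignments),
         wss = best$tot.withinss, feature_scaling = scaling, seed = seed,
         cluster_means = cluster_means,
         sizes = as.integer(table(factor(assignments, levels = seq_len(k)))),
         scale_center = sc$center, scale_scale = sc$scale,
         phenotype_labels = rep("unlabelled", k)),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", x$k, ", sizes ",
      paste(x$sizes, collapse = "/"), ", wss ", format(x$wss),
      ", scaling ", x$feature_scaling, "\n", sep = "")
  if (any(x$phenotype_labels != "unlabelled")) {
    cat("  phenotypes: ", paste(x$phenotype_labels, collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Assign feature vectors to the nearest model centroid
#'
#' @param model A \code{cluster_model}.
#' @param features Matrix or list of proportion vectors in the original
#'   (unscaled) feature space.
#' @return Integer vector of cluster indices (ties to the lowest index).
#' @export
assign_clusters <- function(model, features) {
  X <- features_matrix(features)
  Xs <- sweep(sweep(X, 2, model$scale_center), 2, model$scale_scale, `/`)
  apply(Xs, 1, function(row) {
    which.min(colSums((t(model$centroids) - row)^2))
  })
}

#' Within-cluster sum-of-squares elbow curve
#'
#' Fits \code{\link{kmeans_fit}} for k = 1..k_max and reports the total
#' within-cluster sum of squares per k, plus an automated elbow proposal:
#' the k maximizing the discrete second difference of the WSS curve. To
#' keep the curve non-increasing each k additionally tries an init seeded
#' from the previous best centroids plus the farthest point.
#'
#' @inheritParams kmeans_fit
#' @param k_max Largest k to fit (must be < number of specimens).
#' @return An \code{elbow_curve}: list with \code{k_values},
#'   \code{wss_values} and \code{suggested_k}.
#' @export
elbow_curve <- function(features, k_max = 6, scaling = c("zscore", "none"),
                        seed = 1, n_init = 20, max_iter = 100) {
  scaling <- match.arg(scaling)
  X <- features_matrix(features)
  if (k_max >= nrow(X)) stop("k_max must be smaller than the number of specimens")
  sc <- scale_features(X, scaling)
  wss <- numeric(k_max)
  prev_centers <- NULL
  for (k in seq_len(k_max)) {
    model <- kmeans_fit(X, k, scaling = scaling, seed = seed + k,
                        n_init = n_init, max_iter = max_iter)
    wss_k <- model$wss
    if (!is.null(prev_centers)) {
      d2 <- vapply(seq_len(nrow(sc$X)), function(i) {
        min(colSums((t(prev_centers) - sc$X[i, ])^2))
      }, numeric(1))
      seeded <- rbind(prev_centers, sc$X[which.max(d2), ])
      km <- tryCatch(
        suppressWarnings(kmeans(sc$X, centers = seeded, iter.max = max_iter,
                                algorithm = "Lloyd")),
        error = function(e) NULL
      )
      if (!is.null(km) && km$tot.withinss < wss_k) {
        wss_k <- km$tot.withinss
        model$centroids <- km$centers
      }
    }
    wss[k] <- wss_k
    prev_centers <- model$centroids
  }
  suggested <- if (k_max >= 3) {
    d2 <- wss[1:(k_max - 2)] - 2 * wss[2:(k_max - 1)] + wss[3:k_max]
    which.max(d2) + 1L
  } else {
    1L
  }
  structure(list(k_values = seq_len(k_max), wss_values = wss,
                 suggested_k = as.integer(suggested)),
            class = "elbow_curve")
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat("<elbow_curve> k = ", paste(x$k_values, collapse = ", "),
      "; suggested k = ", x$suggested_k, "\n", sep = "")
  invisible(x)
}

#' Label two clusters as dolichofacial / brachyfacial
#'
#' For a two-cluster model, the cluster with the larger mean P01 (the
#' vertical-to-transverse ratio V1/H1, i.e. the longer, narrower face) is
#' labelled dolichofacial and the other brachyfacial. A tie on P01 is
#' broken by mean P02. Models with k != 2 get \code{"unlabelled"} labels
#' with a warning.
#'
#' @param model A \code{cluster_model}.
#' @param cluster_mean_props Optional k x p matrix of per-cluster mean
#'   proportions in the original feature space (defaults to the model's
#'   own \code{cluster_means}).
#' @return The model with \code{phenotype_labels} filled in.
#' @export
label_phenotypes <- function(model, cluster_mean_props = model$cluster_means) {
  if (model$k != 2) {
    warning("phenotype labelling requires k = 2; labels set to 'unlabelled'")
    model$phenotype_labels <- rep("unlabelled", model$k)
    return(model)
  }
  p01 <- cluster_mean_props[, "P01"]
  if (p01[1] == p01[2]) p01 <- cluster_mean_props[, "P02"]
  labels <- rep("brachyfacial", 2)
  labels[which.max(p01)] <- "dolichofacial"
  model$phenotype_labels <- labels
  model
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the
#' same specimens; 1 for identical partitions, about 0 for independent
#' ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
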