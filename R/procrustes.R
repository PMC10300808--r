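# Ordinary (pairwise) and generalized Procrustes superimposition.
# Rotations act on row-vector points: y = scale * x %*% R + translation.

shape_points <- function(x) {
  if (inherits(x, "landmark_set")) return(x$points)
  if (inherits(x, "cm_shape")) return(x$points)
  if (is.matrix(x)) return(x)
  stop("cannot interpret object of class ", class(x)[1], " as a shape")
}

#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid; the standard size measure removed by Procrustes scaling.
#'
#' @param lm A \code{landmark_set}, shape, or n x 3 coordinate matrix.
#' @return Positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0, 0), c(2, 0, 0)))  # sqrt(2)
centroid_size <- function(lm) {
  pts <- shape_points(lm)
  ctr <- colMeans(pts)
  sqrt(sum(sweep(pts, 2, ctr)^2))
}

#' Construct a centered shape
#'
#' Centers a landmark configuration at the origin, recording its centroid
#' size, and optionally rescales it to unit centroid size.
#'
#' @param x A \code{landmark_set} or n x 3 matrix.
#' @param normalize If \code{TRUE}, scale the centered points to unit
#'   centroid size (coordinates become dimensionless).
#' @return A \code{cm_shape}: list with \code{points} (centered n x 3
#'   matrix) and \code{centroid_size} (the original size in input units).
#' @export
as_shape <- function(x, normalize = FALSE) {
  pts <- shape_points(x)
  cs <- centroid_size(pts)
  if (cs <= 0) stop("degenerate configuration: zero centroid size")
  pts <- sweep(pts, 2, colMeans(pts))
  if (normalize) pts <- pts / cs
  structure(list(points = pts, centroid_size = cs), class = "cm_shape")
}

#' @export
print.cm_shape <- function(x, ...) {
  cat("<shape> ", nrow(x$points), " landmarks, centroid size ",
      format(x$centroid_size), "\n", sep = "")
  invisible(x)
}

similarity_transform <- function(rotation, scale, translation) {
  structure(list(rotation = rotation, scale = scale, translation = translation),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param tf A \code{similarity_transform} (rotation, scale, translation).
#' @param points n x 3 matrix.
#' @return Transformed n x 3 matrix \code{scale * points \%*\% rotation +
#'   translation}.
#' @export
apply_transform <- function(tf, points) {
  sweep(tf$scale * points %*% tf$rotation, 2, tf$translation, `+`)
}

#' Random rotation matrix (Haar-uniform)
#'
#' Draws a proper rotation uniformly over SO(3) by normalizing a standard
#' Gaussian quaternion.
#'
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

check_rank <- function(ptsc, what = "configuration") {
  sv <- svd(ptsc, nu = 0, nv = 0)$d
  if (sv[2] < max(sv) * 1e-10 || !is.finite(sv[1]) || sv[1] == 0) {
    stop("rank-deficient (collinear) ", what)
  }
  invisible(sv)
}

#' Least-squares similarity alignment of one shape onto another
#'
#' Finds the similarity transform (rotation, optional uniform scale,
#' translation) minimizing the summed squared distance between the
#' transformed source landmarks and the target landmarks. The rotation is
#' obtained from the SVD of the cross-covariance matrix with the
#' determinant-correction step, so reflections are never returned: a
#' mirrored target yields a proper rotation with nonzero residual.
#'
#' @param source,target Landmark sets, shapes, or n x 3 matrices with
#'   identical landmark count and order.
#' @param allow_scale If \code{FALSE}, a rigid (Kabsch) fit with scale
#'   fixed at 1.
#' @return List with \code{transform} (a \code{similarity_transform}
#'   mapping source onto target in the original coordinates) and
#'   \code{residual}, the root-mean-square landmark misfit after
#'   transformation.
#' @export
#' @examples
#' src <- realize_proportions(rep(1, 8))$points
#' tgt <- 1.7 * src %*% diag(3) + 5
#' align_pair(src, tgt)$transform$scale  # 1.7
align_pair <- function(source, target, allow_scale = TRUE) {
  X <- shape_points(source)
  Y <- shape_points(target)
  if (!all(dim(X) == dim(Y))) {
    stop("mismatched landmark counts: ", nrow(X), " vs ", nrow(Y))
  }
  muX <- colMeans(X); muY <- colMeans(Y)
  Xc <- sweep(X, 2, muX); Yc <- sweep(Y, 2, muY)
  check_rank(Xc, "source configuration")
  A <- crossprod(Xc, Yc)
  sv <- svd(A)
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  S <- diag(c(1, 1, d))
  R <- sv$u %*% S %*% t(sv$v)
  trDS <- sum(sv$d * c(1, 1, d))
  s <- if (allow_scale) trDS / sum(Xc^2) else 1
  tr <- muY - s * drop(muX %*% R)
  resid <- sqrt(sum((s * Xc %*% R - Yc)^2) / nrow(X))
  list(transform = similarity_transform(R, s, tr), residual = resid)
}

#' Procrustes distance between two configurations
#'
#' Root-mean-square landmark misfit after both configurations are scaled
#' to unit centroid size and optimally rotated and scaled onto each other
#' (the full-Procrustes residual, symmetric in its arguments).
#'
#' @param a,b Landmark sets, shapes, or n x 3 matrices with identical
#'   landmark order.
#' @return Non-negative scalar; 0 iff the shapes are similar.
#' @export
procrustes_distance <- function(a, b) {
  X <- as_shape(a, normalize = TRUE)$points
  Y <- as_shape(b, normalize = TRUE)$points
  if (!all(dim(X) == dim(Y))) {
    stop("mismatched landmark counts: ", nrow(X), " vs ", nrow(Y))
  }
  sv <- svd(crossprod(X, Y))
  d <- sign(det(sv$u) * det(sv$v))
  if (d == 0) d <- 1
  trDS <- sum(sv$d * c(1, 1, d))
  # both unit size: optimal scale equals trDS, residual^2 = 1 - trDS^2
  sqrt(max(0, 1 - trDS^2) / nrow(X))
}

#' Generalized Procrustes analysis mean shape
#'
#' Iteratively superimposes a set of configurations: each shape is
#' centered and scaled to unit centroid size, rotated onto the current
#' mean, the mean is recomputed and renormalized to unit centroid size,
#' until it moves by less than \code{tol} in Procrustes distance. With
#' \code{scale_mode = "per_iteration"} the per-shape scale is instead
#' re-optimized at every alignment (full-Procrustes scaling).
#'
#' @param shapes List (length >= 2) of \code{landmark_set}s, shapes or
#'   n x 3 matrices with identical landmark order.
#' @param tol Convergence tolerance on the Procrustes distance moved by
#'   the mean between iterations.
#' @param max_iter Iteration cap.
#' @param scale_mode \code{"unit_size"} (default) or
#'   \code{"per_iteration"}.
#' @param group_label Label stored on the result.
#' @return A \code{shape_ensemble}: list with \code{shapes} (aligned
#'   unit-size \code{cm_shape}s), \code{mean_shape} (unit centroid size),
#'   \code{group_label}, \code{iterations}, \code{converged}, and
#'   \code{objective}, the per-iteration summed squared distance of the
#'   aligned shapes to the mean.
#' @export
#' @examples
#' lms <- generate_cohort(cohort_spec(list(cohort_group("g", 5,
#'   rep(1, 8), noise_sd_mm = 1)), seed = 7))$specimens
#' ens <- gpa_mean(lms)
#' centroid_size(ens$mean_shape)  # 1
gpa_mean <- function(shapes, tol = 1e-8, max_iter = 100,
                     scale_mode = c("unit_size", "per_iteration"),
                     group_label = "") {
  scale_mode <- match.arg(scale_mode)
  if (!is.list(shapes) || length(shapes) < 2) {
    stop("gpa_mean needs at least two shapes")
  }
  mats <- lapply(shapes, function(s) as_shape(s, normalize = TRUE)$points)
  nlm <- nrow(mats[[1]])
  for (m in mats) {
    if (!all(dim(m) == dim(mats[[1]]))) stop("shapes differ in landmark count")
  }
  sizes <- vapply(shapes, centroid_size, numeric(1))
  mean_pts <- mats[[1]]
  converged <- FALSE
  it <- 0
  objective <- numeric(0)
  while (it < max_iter) {
    it <- it + 1
    aligned <- lapply(mats, function(m) {
      ap <- align_pair(m, mean_pts, allow_scale = (scale_mode == "per_iteration"))
      apply_transform(ap$transform, m)
    })
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    new_mean <- new_mean / centroid_size(new_mean)
    objective <- c(objective,
                   sum(vapply(aligned, function(a) sum((a - new_mean)^2), numeric(1))))
    delta <- procrustes_distance(new_mean, mean_pts)
    mean_pts <- new_mean
    mats <- aligned
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  dimnames(mean_pts) <- dimnames(shape_points(shapes[[1]]))
  aligned_shapes <- lapply(seq_along(mats), function(i) {
    p <- mats[[i]]
    dimnames(p) <- dimnames(mean_pts)
    structure(list(points = p, centroid_size = sizes[i]), class = "cm_shape")
  })
  structure(
    list(shapes = aligned_shapes,
         mean_shape = structure(list(points = mean_pts, centroid_size = 1),
                                class = "cm_shape"),
         group_label = group_label, iterations = it, converged = converged,
         objective = objective, scale_mode = scale_mode),
    class = "shape_ensemble"
  )
}

#' @export
print.shape_ensemble <- function(x, ...) {
  cat("<shape_ensemble> ", length(x$shapes), " shapes",
      if (nzchar(x$group_label)) paste0(" [", x$group_label, "]"),
      ", GPA ", x$iterations, " iterations (",
      if (x$converged) "converged" else "not converged", ")\n", sep = "")
  invisible(x)
}
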