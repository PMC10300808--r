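# 3D thin-plate spline: exact landmark interpolation (affine part +
# radial kernel weights) and transport of full triangle meshes through
# the map. Kernel U(r) = -r by default, the biharmonic fundamental
# solution convention in 3D morphometrics; U(r) = r flips only the sign
# of the solved weights.

tps_kernel_matrix <- function(A, B, kernel) {
  # |A| x |B| matrix of U(|a_i - b_j|)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  r <- sqrt(pmax(d2, 0))
  if (kernel == "minus_r") -r else r
}

#' Solve a 3D thin-plate spline
#'
#' Solves the standard bordered linear system
#' \code{[K + lambda I, P; P', 0]} for the kernel weights and affine part
#' of the TPS mapping \code{source} landmarks onto \code{target}
#' landmarks, where \code{K[i, j] = U(|s_i - s_j|)} and
#' \code{P = [1 | source]}. With \code{lambda = 0} the map interpolates
#' the targets exactly; positive \code{lambda} trades exactness for lower
#' bending energy (useful for noisy landmark placements).
#'
#' @param source,target n x 3 matrices (n >= 5, source non-coplanar) in
#'   corresponding order.
#' @param lambda Non-negative regularization.
#' @param kernel \code{"minus_r"} (default, U(r) = -r) or \code{"r"}.
#' @return A \code{tps_transform}: list with \code{source_points},
#'   \code{weights} (n x 3 kernel weights), \code{affine} (4 x 3: first
#'   row offset, rows 2-4 the linear part), \code{kernel},
#'   \code{lambda}.
#' @export
#' @examples
#' src <- realize_proportions(rep(1, 8))$points
#' tf <- tps_solve(src, src + 5)   # pure translation
#' max(abs(tf$weights))            # ~0
tps_solve <- function(source, target, lambda = 0,
                      kernel = c("minus_r", "r")) {
  kernel <- match.arg(kernel)
  source <- as.matrix(source); target <- as.matrix(target)
  if (!all(dim(source) == dim(target))) {
    stop("source and target must have the same landmark count and order")
  }
  n <- nrow(source)
  if (n < 5) stop("thin-plate spline needs at least 5 control points")
  if (lambda < 0) stop("lambda must be non-negative")
  ctr <- sweep(source, 2, colMeans(source))
  sv <- svd(ctr, nu = 0, nv = 0)$d
  if (sv[3] < max(sv) * 1e-10) {
    stop("coplanar source landmarks: affine part is rank-deficient")
  }
  K <- tps_kernel_matrix(source, source, kernel)
  P <- cbind(1, source)
  L <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- solve(L, rhs)
  structure(
    list(source_points = source, weights = sol[seq_len(n), , drop = FALSE],
         affine = sol[n + 1:4, , drop = FALSE], kernel = kernel,
         lambda = lambda),
    class = "tps_transform"
  )
}

#' @export
print.tps_transform <- function(x, ...) {
  cat("<tps_transform> ", nrow(x$source_points), " control points, kernel ",
      x$kernel, ", lambda ", format(x$lambda), "\n", sep = "")
  invisible(x)
}

#' Evaluate a thin-plate spline at arbitrary points
#'
#' @param transform A \code{tps_transform}.
#' @param points m x 3 matrix.
#' @return m x 3 matrix of mapped points (affine part plus kernel sum);
#'   cost is linear in m times the number of control points.
#' @export
tps_apply <- function(transform, points) {
  points <- as.matrix(points)
  U <- tps_kernel_matrix(points, transform$source_points, transform$kernel)
  out <- cbind(1, points) %*% transform$affine + U %*% transform$weights
  dimnames(out) <- dimnames(points)
  out
}

#' Bending energy of a thin-plate spline
#'
#' The quadratic form \code{tr(W' K W)} evaluated with the U(r) = -r
#' kernel (under which it is non-negative on the side-condition
#' subspace); decreases monotonically as \code{lambda} grows.
#'
#' @param transform A \code{tps_transform}.
#' @return Non-negative scalar.
#' @export
tps_bending_energy <- function(transform) {
  K <- tps_kernel_matrix(transform$source_points, transform$source_points,
                         "minus_r")
  sum(diag(crossprod(transform$weights, K %*% transform$weights)))
}

#' Morph a template mesh onto a target mean shape
#'
#' Creates a normative template: the (unit-size, origin-centered) GPA
#' target mean shape is first similarity-aligned to the template's own
#' landmark configuration -- restoring millimetre scale and pose so that
#' the morph changes only shape, never gross size or position -- and a
#' thin-plate spline from the template landmarks to those rescaled
#' targets is then applied to every mesh vertex. Topology (face list,
#' vertex count) is preserved exactly.
#'
#' @param mesh A \code{triangle_mesh}. If \code{template_landmarks} is
#'   NULL the mesh must carry its own landmark annotations.
#' @param template_landmarks A \code{landmark_set} (or 18 x 3 matrix)
#'   digitized on the template mesh, in canonical order.
#' @param target_mean A \code{cm_shape} (typically
#'   \code{gpa_mean(...)$mean_shape}) or an 18 x 3 matrix.
#' @param lambda TPS regularization (default 0, exact interpolation).
#' @return The morphed \code{triangle_mesh} (same faces; landmark
#'   annotations updated to the rescaled targets).
#' @export
morph_template <- function(mesh, template_landmarks = NULL, target_mean,
                           lambda = 0) {
  if (is.null(template_landmarks)) {
    if (is.null(mesh$landmarks)) {
      stop("mesh carries no landmark annotations and none were supplied")
    }
    src <- mesh$landmarks
  } else {
    src <- shape_points(template_landmarks)
  }
  tgt <- shape_points(target_mean)
  if (!all(dim(src) == dim(tgt))) {
    stop("template and target landmark counts differ")
  }
  ap <- align_pair(tgt, src, allow_scale = TRUE)
  rescaled <- apply_transform(ap$transform, tgt)
  tf <- tps_solve(src, rescaled, lambda = lambda)
  out <- mesh
  out$vertices <- tps_apply(tf, mesh$vertices)
  if (!is.null(out$landmarks)) {
    rownames(rescaled) <- rownames(out$landmarks)
    out$landmarks <- rescaled
  }
  out
}
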