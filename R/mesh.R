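# Triangle mesh container, a small 3D convex hull, midpoint subdivision
# and the toy annotated-mesh generator used to exercise the morphing
# pipeline without anatomical surface data.

#' Construct a triangle mesh
#'
#' @param vertices m x 3 numeric matrix (mm).
#' @param faces f x 3 integer matrix of 1-based vertex indices.
#' @param landmarks Optional named n x 3 matrix of landmark positions
#'   (free points near the surface; not snapped to vertices).
#' @param comment Optional comment string carried into PLY output.
#' @return A \code{triangle_mesh}.
#' @export
triangle_mesh <- function(vertices, faces, landmarks = NULL, comment = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3) stop("vertices must be m x 3")
  if (ncol(faces) != 3) stop("faces must be f x 3 (triangles)")
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces, landmarks = landmarks,
                 comment = comment),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("<triangle_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$faces),
      " faces", if (!is.null(x$landmarks)) paste0(", ", nrow(x$landmarks),
                                                  " landmarks"), "\n",
      sep = "")
  invisible(x)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' 3D convex hull of a point cloud
#'
#' Enumerates supporting planes (triples whose plane has all points on
#' one side), merges coplanar facets, and triangulates each facet by a
#' fan over its 2D hull. Suitable for the small point sets this package
#' works with (landmark clouds); cost is cubic in the number of points.
#'
#' @param points m x 3 matrix (m >= 4, not all coplanar).
#' @return List with \code{vertices} (the hull points) and \code{faces}
#'   (triangles, outward-oriented, 1-based into \code{vertices}).
#' @export
convex_hull3 <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  if (n < 4) stop("convex hull needs at least 4 points")
  scale <- max(dist(pts))
  if (scale == 0) stop("degenerate point cloud")
  tol <- 1e-9 * scale
  facets <- list()
  seen <- character(0)
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      for (k in (j + 1):n) {
        nrm <- cross3(pts[j, ] - pts[i, ], pts[k, ] - pts[i, ])
        len <- sqrt(sum(nrm^2))
        if (len < tol * scale) next
        nrm <- nrm / len
        d <- drop(pts %*% nrm) - sum(nrm * pts[i, ])
        if (all(d <= tol)) {
          outward <- nrm
        } else if (all(d >= -tol)) {
          outward <- -nrm
        } else {
          next
        }
        on_plane <- which(abs(d) <= tol)
        key <- paste(on_plane, collapse = "-")
        if (key %in% seen) next
        seen <- c(seen, key)
        facets[[length(facets) + 1]] <- list(idx = on_plane, normal = outward)
      }
    }
  }
  if (length(facets) == 0) stop("all points coplanar: no 3D hull")
  tris <- list()
  for (fc in facets) {
    idx <- fc$idx
    nrm <- fc$normal
    # orthonormal in-plane basis for the 2D hull
    ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- cross3(nrm, ref); u <- u / sqrt(sum(u^2))
    v <- cross3(nrm, u)
    p2 <- cbind(pts[idx, , drop = FALSE] %*% u, pts[idx, , drop = FALSE] %*% v)
    h <- chull(p2)
    ring <- idx[h]
    for (t in seq_len(length(ring) - 2)) {
      tri <- c(ring[1], ring[t + 1], ring[t + 2])
      # orient outward
      tn <- cross3(pts[tri[2], ] - pts[tri[1], ], pts[tri[3], ] - pts[tri[1], ])
      if (sum(tn * nrm) < 0) tri <- tri[c(1, 3, 2)]
      tris[[length(tris) + 1]] <- tri
    }
  }
  faces <- do.call(rbind, tris)
  used <- sort(unique(as.vector(faces)))
  remap <- match(faces, used)
  list(vertices = pts[used, , drop = FALSE],
       faces = matrix(remap, ncol = 3))
}

#' Midpoint (1-to-4) triangle subdivision
#'
#' Splits every triangle into four at its welded edge midpoints,
#' \code{times} times. Vertex positions are not smoothed, so subdividing
#' a convex surface keeps all new vertices on it.
#'
#' @param mesh A \code{triangle_mesh}.
#' @param times Number of subdivision rounds.
#' @return The refined \code{triangle_mesh}.
#' @export
subdivide_mesh <- function(mesh, times = 1) {
  for (s in seq_len(times)) {
    V <- mesh$vertices
    F <- mesh$faces
    edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "_")
    mid_idx <- new.env(parent = emptyenv())
    newV <- list()
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      hit <- mid_idx[[key]]
      if (!is.null(hit)) return(hit)
      newV[[length(newV) + 1]] <<- (V[a, ] + V[b, ]) / 2
      idx <- nrow(V) + length(newV)
      mid_idx[[key]] <- idx
      idx
    }
    newF <- vector("list", nrow(F) * 4)
    for (f in seq_len(nrow(F))) {
      a <- F[f, 1]; b <- F[f, 2]; cc <- F[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newF[[4 * f - 3]] <- c(a, ab, ca)
      newF[[4 * f - 2]] <- c(ab, b, bc)
      newF[[4 * f - 1]] <- c(ca, bc, cc)
      newF[[4 * f]] <- c(ab, bc, ca)
    }
    mesh <- triangle_mesh(rbind(V, do.call(rbind, newV)),
                          do.call(rbind, newF),
                          landmarks = mesh$landmarks,
                          comment = mesh$comment)
  }
  mesh
}

#' Toy annotated mesh around a landmark cloud
#'
#' Builds a closed convex triangulated surface (the convex hull of the
#' landmarks, optionally midpoint-subdivided for density) and annotates
#' it with the landmark positions. This is a geometric stand-in for a
#' segmented skull surface: it carries the full 18-landmark annotation
#' needed by \code{\link{morph_template}} but no anatomical detail.
#'
#' @param lm A \code{landmark_set}.
#' @param subdivisions Rounds of midpoint subdivision (0 = raw hull).
#' @return A \code{triangle_mesh} whose \code{landmarks} matrix holds the
#'   landmark coordinates (free points on or inside the surface).
#' @export
generate_toy_mesh <- function(lm, subdivisions = 0) {
  pts <- lm_points(lm)
  hull <- convex_hull3(pts)
  mesh <- triangle_mesh(hull$vertices, hull$faces, landmarks = pts,
                        comment = if (inherits(lm, "landmark_set")) {
                          paste0("specimen_id ", lm$specimen_id)
                        })
  subdivide_mesh(mesh, subdivisions)
}
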