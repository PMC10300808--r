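# 18-landmark craniofacial scheme, inter-landmark distances and the
# eight dimensionless facial proportions derived from them.

#' Canonical landmark codes
#'
#' The fixed ordering of the 18 cephalometric landmarks used throughout the
#' package: Nasion (N), paired frontoorbital suture points (FOS r/l),
#' inferior orbital edges (IOE r/l), incisura frontalis points (IF r/l),
#' anterior nasal spine (SPA), upper/lower molar root bone levels
#' (UpMdbrbl r/l, LoMdbrbl r/l), lower incisor bone level (LIbl), condyles
#' (Co r/l), Pogonion (Po) and posterior inferior mandibular points
#' (Pom r/l). All downstream matrices use this row order.
#'
#' @return Character vector of length 18, in canonical order.
#' @export
#' @examples
#' landmark_codes()
landmark_codes <- function() {
  c("N", "FOS r", "FOS l", "IOE r", "IOE l", "IF r", "IF l", "SPA",
    "UpMdbrbl r", "UpMdbrbl l", "LIbl", "LoMdbrbl r", "LoMdbrbl l",
    "Co r", "Co l", "Po", "Pom r", "Pom l")
}

# landmark pairs defining each named distance; V* vertical, H* horizontal,
# Z1 oblique. All pairs are midline or right-sided except the H* pairs,
# which span the midline.
#' Inter-landmark distance definitions
#'
#' Named list mapping each distance code (V1..V4, H1..H3, Z1) to the pair
#' of landmark codes whose Euclidean separation defines it, e.g.
#' V1 = Nasion--Pogonion (anterior facial height) and H1 = FOS r--FOS l
#' (upper facial width).
#'
#' @return Named list of length-2 character vectors.
#' @export
distance_definitions <- function() {
  list(
    V1 = c("N", "Po"),
    V2 = c("N", "SPA"),
    V3 = c("SPA", "Po"),
    V4 = c("FOS r", "IOE r"),
    H1 = c("FOS r", "FOS l"),
    H2 = c("Co r", "Co l"),
    H3 = c("UpMdbrbl r", "UpMdbrbl l"),
    Z1 = c("IOE r", "Co r")
  )
}

proportion_codes <- function() sprintf("P%02d", 1:8)

#' Default facial proportion definitions
#'
#' The eight dimensionless proportions P01..P08 expressed as ratios of the
#' named distances. Two entries deviate from the published shorthand and
#' are flagged in the \code{"substitutions"} attribute: P05 is taken as
#' V1/V4 (the printed V6 is undefined among the distance codes, and V4 is
#' the only vertical distance of the required magnitude), and P07 is taken
#' as the ratio V3/H1 (a literal difference V3 - H1 would not be
#' scale-invariant, contradicting the dimensionless use of proportions).
#'
#' @return Named character vector mapping P01..P08 to expressions of the
#'   form \code{"A/B"} (or \code{"A-B"}) over distance codes, with a
#'   \code{"substitutions"} attribute documenting the two interpreted
#'   entries.
#' @export
#' @examples
#' default_proportion_spec()
default_proportion_spec <- function() {
  spec <- c(P01 = "V1/H1", P02 = "V1/H3", P03 = "V1/H2", P04 = "V1/V3",
            P05 = "V1/V4", P06 = "V1/Z1", P07 = "V3/H1", P08 = "H1/H3")
  attr(spec, "substitutions") <- c(
    P05 = "ratio denominator V4 substituted for the undefined code V6",
    P07 = "interpreted as the scale-invariant ratio V3/H1"
  )
  spec
}

normalize_landmark_name <- function(x) {
  codes <- landmark_codes()
  key <- function(s) tolower(gsub("[ _]+", " ", trimws(s)))
  idx <- match(key(x), key(codes))
  codes[idx]
}

#' Validate and canonicalize a landmark record
#'
#' Accepts a candidate landmark record -- a data frame with columns
#' \code{name}, \code{x}, \code{y}, \code{z} (or \code{x_mm} etc.), a
#' numeric 18 x 3 matrix with landmark-code rownames, or a named list of
#' 3-vectors -- and returns a \code{landmark_set} with points in the
#' canonical order of \code{\link{landmark_codes}}. Landmark names are
#' matched case-insensitively and may use underscores for spaces.
#'
#' @param raw Candidate record (see above).
#' @param specimen_id Specimen identifier (default \code{"specimen"}).
#' @param sex One of \code{"female"}, \code{"male"}, \code{"unknown"}.
#' @param age_years Optional non-negative age in years.
#' @return A \code{landmark_set}: list with \code{specimen_id}, \code{sex},
#'   \code{age_years} and \code{points}, an 18 x 3 matrix (mm) with
#'   canonical rownames.
#' @export
#' @examples
#' pts <- realize_proportions(rep(1, 8))$points
#' lm <- validate_landmark_set(pts, specimen_id = "s1", sex = "female")
validate_landmark_set <- function(raw, specimen_id = "specimen",
                                  sex = c("unknown", "female", "male"),
                                  age_years = NA_real_) {
  sex <- match.arg(sex)
  codes <- landmark_codes()
  if (inherits(raw, "landmark_set")) {
    nm <- rownames(raw$points)
    pts <- raw$points
    specimen_id <- raw$specimen_id
    sex <- raw$sex
    age_years <- raw$age_years
  } else if (is.data.frame(raw)) {
    nm <- as.character(raw$name)
    xc <- if ("x_mm" %in% names(raw)) "x_mm" else "x"
    yc <- if ("y_mm" %in% names(raw)) "y_mm" else "y"
    zc <- if ("z_mm" %in% names(raw)) "z_mm" else "z"
    pts <- as.matrix(raw[, c(xc, yc, zc)])
  } else if (is.matrix(raw)) {
    nm <- rownames(raw)
    pts <- raw
  } else if (is.list(raw)) {
    nm <- names(raw)
    pts <- do.call(rbind, lapply(raw, as.numeric))
  } else {
    stop("unsupported landmark record type: ", class(raw)[1])
  }
  if (is.null(nm)) stop("landmark record must name its points")
  canon <- normalize_landmark_name(nm)
  if (anyNA(canon)) {
    stop("unknown landmark name(s): ", paste(nm[is.na(canon)], collapse = ", "),
         "; valid codes are: ", paste(codes, collapse = ", "))
  }
  if (anyDuplicated(canon)) {
    stop("duplicate landmark: ", paste(unique(canon[duplicated(canon)]), collapse = ", "))
  }
  missing <- setdiff(codes, canon)
  if (length(missing) > 0) {
    stop("missing landmark: ", paste(missing, collapse = ", "))
  }
  pts <- pts[match(codes, canon), , drop = FALSE]
  storage.mode(pts) <- "double"
  rownames(pts) <- codes
  colnames(pts) <- c("x", "y", "z")
  if (!all(is.finite(pts))) {
    bad <- codes[!apply(is.finite(pts), 1, all)]
    stop("non-finite coordinate at landmark: ", paste(bad, collapse = ", "))
  }
  dd <- as.matrix(dist(pts))
  diag(dd) <- Inf
  if (any(dd == 0)) {
    pair <- which(dd == 0, arr.ind = TRUE)[1, ]
    stop("coincident landmarks: ", codes[pair[1]], " and ", codes[pair[2]])
  }
  structure(
    list(specimen_id = specimen_id, sex = sex,
         age_years = as.numeric(age_years), points = pts),
    class = "landmark_set"
  )
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> ", x$specimen_id, " (", x$sex, "), 18 landmarks [mm]\n",
      sep = "")
  invisible(x)
}

lm_points <- function(lm) {
  if (inherits(lm, "landmark_set")) lm$points else lm
}

#' Inter-landmark distances
#'
#' Computes the eight named Euclidean distances (V1..V4, H1..H3, Z1) of
#' \code{\link{distance_definitions}} from a landmark set, in the input's
#' units (mm).
#'
#' @param lm A \code{landmark_set} or an 18 x 3 matrix with canonical
#'   rownames.
#' @return Named numeric vector of 8 positive distances.
#' @export
#' @examples
#' lm <- realize_proportions(rep(1, 8), base_scale_mm = 100)
#' compute_distances(lm)
compute_distances <- function(lm) {
  pts <- lm_points(lm)
  defs <- distance_definitions()
  vapply(defs, function(pair) {
    sqrt(sum((pts[pair[1], ] - pts[pair[2], ])^2))
  }, numeric(1))
}

parse_proportion_expr <- function(expr, code) {
  m <- regmatches(expr, regexec("^\\s*([VHZ][0-9]+)\\s*([/-])\\s*([VHZ][0-9]+)\\s*$", expr))[[1]]
  if (length(m) != 4) {
    stop("cannot parse proportion definition for ", code, ": '", expr, "'")
  }
  list(a = m[2], op = m[3], b = m[4])
}

#' Facial proportions from distances
#'
#' Evaluates a proportion-definition table (default
#' \code{\link{default_proportion_spec}}) on a distance vector. Each
#' definition is a ratio (or difference) of two distance codes.
#'
#' @param d Named numeric distance vector as returned by
#'   \code{\link{compute_distances}}.
#' @param spec Named character vector of definitions, as
#'   \code{\link{default_proportion_spec}}.
#' @return Named numeric vector of proportions, carrying the
#'   \code{"definitions"} and \code{"substitutions"} attributes of the
#'   spec used.
#' @export
#' @examples
#' d <- compute_distances(realize_proportions(rep(1, 8)))
#' compute_proportions(d)
compute_proportions <- function(d, spec = default_proportion_spec()) {
  out <- vapply(names(spec), function(code) {
    p <- parse_proportion_expr(spec[[code]], code)
    for (side in c(p$a, p$b)) {
      if (!side %in% names(d)) {
        stop("proportion ", code, " references undefined distance '", side, "'")
      }
    }
    if (p$op == "/") d[[p$a]] / d[[p$b]] else d[[p$a]] - d[[p$b]]
  }, numeric(1))
  attr(out, "definitions") <- stats::setNames(as.character(spec), names(spec))
  attr(out, "substitutions") <- attr(spec, "substitutions")
  out
}

#' Measure proportions for every specimen in a collection
#'
#' Convenience wrapper running \code{\link{compute_distances}} and
#' \code{\link{compute_proportions}} over a list of landmark sets.
#'
#' @param sets List of \code{landmark_set} objects (or a
#'   \code{synthetic_cohort}).
#' @param spec Proportion-definition table.
#' @return Numeric matrix, one row per specimen (rownames = specimen ids),
#'   columns P01..P08.
#' @export
measure_proportions <- function(sets, spec = default_proportion_spec()) {
  if (inherits(sets, "synthetic_cohort")) sets <- sets$specimens
  rows <- lapply(sets, function(lm) compute_proportions(compute_distances(lm), spec))
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(sets, function(lm) lm$specimen_id, character(1))
  out
}
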