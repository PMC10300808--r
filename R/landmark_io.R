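# Landmark CSV/JSON dialect and mean-shape serialization.
# Long CSV: one row per landmark with columns specimen_id, sex, age,
# landmark_no, name, x_mm, y_mm, z_mm (optional true_cluster); wide JSON:
# one object per specimen.

landmark_set_to_df <- function(lm) {
  codes <- landmark_codes()
  df <- data.frame(
    specimen_id = lm$specimen_id,
    sex = lm$sex,
    age = lm$age_years,
    landmark_no = seq_len(18),
    name = codes,
    x_mm = lm$points[, 1],
    y_mm = lm$points[, 2],
    z_mm = lm$points[, 3],
    row.names = NULL
  )
  if (!is.null(lm$true_cluster)) df$true_cluster <- lm$true_cluster
  df
}

#' Write landmark sets
#'
#' @param sets List of \code{landmark_set}s (or a
#'   \code{synthetic_cohort}).
#' @param path Output path; \code{format} inferred from the extension
#'   (.csv long form, .json wide form) unless given.
#' @param format \code{"csv"}, \code{"json"} or NULL.
#' @return The path, invisibly.
#' @export
write_landmarks <- function(sets, path, format = NULL) {
  if (inherits(sets, "synthetic_cohort")) sets <- sets$specimens
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     json = "json",
                     stop("cannot infer landmark format from extension: ", path))
  }
  if (format == "csv") {
    df <- do.call(rbind, lapply(sets, landmark_set_to_df))
    write.csv(df, path, row.names = FALSE)
  } else {
    objs <- lapply(sets, function(lm) {
      pts <- lapply(seq_len(18), function(i) unname(lm$points[i, ]))
      names(pts) <- rownames(lm$points)
      obj <- list(specimen_id = lm$specimen_id, sex = lm$sex,
                  age = lm$age_years, landmarks = pts)
      if (!is.null(lm$true_cluster)) obj$true_cluster <- lm$true_cluster
      obj
    })
    jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read landmark sets
#'
#' Reads the long CSV or wide JSON landmark dialect, validating each
#' specimen against the canonical 18-landmark scheme (unknown landmark
#' codes are an error listing the valid codes).
#'
#' @param path Input path; format inferred from the extension unless
#'   given.
#' @param format \code{"csv"}, \code{"json"} or NULL.
#' @return List of \code{landmark_set}s; any \code{true_cluster} column
#'   is carried on each set.
#' @export
read_landmarks <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     json = "json",
                     stop("cannot infer landmark format from extension: ", path))
  }
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    sets <- lapply(split(df, factor(df$specimen_id,
                                    levels = unique(df$specimen_id))),
                   function(sub) {
      lm <- validate_landmark_set(
        sub, specimen_id = sub$specimen_id[1],
        sex = if ("sex" %in% names(sub)) sub$sex[1] else "unknown",
        age_years = if ("age" %in% names(sub)) sub$age[1] else NA_real_)
      if ("true_cluster" %in% names(sub)) lm$true_cluster <- sub$true_cluster[1]
      lm
    })
    unname(sets)
  } else {
    objs <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(objs, function(obj) {
      pts <- do.call(rbind, lapply(obj$landmarks, function(p) unlist(p)))
      lm <- validate_landmark_set(
        pts, specimen_id = obj$specimen_id,
        sex = if (!is.null(obj$sex)) obj$sex else "unknown",
        age_years = if (!is.null(obj$age)) as.numeric(obj$age) else NA_real_)
      if (!is.null(obj$true_cluster)) lm$true_cluster <- obj$true_cluster
      lm
    })
  }
}

#' Serialize a shape or mean shape to JSON
#'
#' Writes the landmark coordinates with a coordinate-frame tag:
#' \code{"raw_mm"} for millimetre configurations or \code{"gpa_unit"} for
#' unit-centroid-size Procrustes shapes.
#'
#' @param shape A \code{cm_shape}, \code{landmark_set} or 18 x 3 matrix.
#' @param path Output path.
#' @param frame Coordinate frame tag.
#' @param label Optional group label.
#' @export
write_shape_json <- function(shape, path, frame = c("gpa_unit", "raw_mm"),
                             label = "") {
  frame <- match.arg(frame)
  pts <- shape_points(shape)
  nm <- rownames(pts)
  if (is.null(nm)) nm <- landmark_codes()[seq_len(nrow(pts))]
  coords <- lapply(seq_len(nrow(pts)), function(i) unname(pts[i, ]))
  names(coords) <- nm
  jsonlite::write_json(
    list(coordinate_frame = frame, label = label, landmarks = coords),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a shape serialized by \code{\link{write_shape_json}}
#'
#' @param path Input path.
#' @return A \code{cm_shape} with a \code{"frame"} attribute.
#' @export
read_shape_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  pts <- do.call(rbind, lapply(obj$landmarks, unlist))
  colnames(pts) <- c("x", "y", "z")
  out <- as_shape(pts)
  attr(out, "frame") <- obj$coordinate_frame
  attr(out, "label") <- obj$label
  out
}
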