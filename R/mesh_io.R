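# Readers/writers for PLY (ascii, binary little-endian) and binary STL.
# Units are assumed millimetres throughout; STL carries no names, so
# landmark annotations always travel in a sidecar CSV/JSON.

ply_type_bytes <- c(char = 1, int8 = 1, uchar = 1, uint8 = 1,
                    short = 2, int16 = 2, ushort = 2, uint16 = 2,
                    int = 4, int32 = 4, uint = 4, uint32 = 4,
                    float = 4, float32 = 4, double = 8, float64 = 8)

ply_read_scalar <- function(raw, offset, type) {
  nbytes <- ply_type_bytes[[type]]
  bytes <- raw[offset + seq_len(nbytes)]
  val <- if (type %in% c("float", "float32", "double", "float64")) {
    readBin(bytes, "double", size = nbytes, endian = "little")
  } else {
    readBin(bytes, "integer", size = nbytes, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
  }
  list(value = val, offset = offset + nbytes)
}

parse_ply_header <- function(lines) {
  if (lines[1] != "ply") stop("malformed PLY header: missing 'ply' magic")
  fmt_line <- grep("^format ", lines, value = TRUE)
  if (length(fmt_line) != 1) stop("malformed PLY header: missing format line")
  fmt <- strsplit(fmt_line, "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  elements <- list()
  current <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2], count = as.integer(tok[3]),
                      properties = list())
    } else if (tok[1] == "property" && !is.null(current)) {
      if (tok[2] == "list") {
        current$properties[[length(current$properties) + 1]] <-
          list(name = tok[5], list = TRUE, count_type = tok[3],
               item_type = tok[4])
      } else {
        current$properties[[length(current$properties) + 1]] <-
          list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      break
    }
  }
  if (!is.null(current)) elements[[current$name]] <- current
  list(format = fmt, elements = elements)
}

read_ply <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  # header is ascii text terminated by "end_header\n"; locate it on the raw
  # bytes (the binary body may contain nul bytes)
  he <- grepRaw("end_header", raw, fixed = TRUE)
  if (length(he) == 0) stop("malformed PLY header: no end_header")
  newlines <- which(raw == as.raw(10L))
  body_offset <- newlines[newlines >= he][1]
  if (is.na(body_offset)) stop("malformed PLY header: no end_header line")
  hdr_txt <- rawToChar(raw[seq_len(he - 1)])
  hdr_lines <- strsplit(hdr_txt, "\r?\n")[[1]]
  header <- parse_ply_header(hdr_lines)
  velem <- header$elements[["vertex"]]
  felem <- header$elements[["face"]]
  if (is.null(velem)) stop("PLY file declares no vertex element")
  vprops <- vapply(velem$properties, function(p) p$name, character(1))
  if (!all(c("x", "y", "z") %in% vprops)) {
    stop("PLY vertex element lacks x/y/z properties")
  }
  comment <- sub("^comment ", "",
                 grep("^comment ", hdr_lines, value = TRUE)[1])
  if (is.na(comment)) comment <- NULL

  if (header$format == "ascii") {
    body <- rawToChar(raw[(body_offset + 1):length(raw)])
    tok <- scan(text = body, what = character(), quiet = TRUE)
    pos <- 0
    take <- function(k) {
      out <- tok[pos + seq_len(k)]
      pos <<- pos + k
      out
    }
    V <- matrix(NA_real_, velem$count, 3)
    for (i in seq_len(velem$count)) {
      row <- as.numeric(take(length(velem$properties)))
      V[i, ] <- row[match(c("x", "y", "z"), vprops)]
    }
    faces <- list()
    if (!is.null(felem)) {
      for (i in seq_len(felem$count)) {
        k <- as.integer(take(1))
        idx <- as.integer(take(k)) + 1L
        if (k < 3) stop("face with fewer than 3 vertices")
        for (t in seq_len(k - 2)) {     # fan-wise split of polygons
          faces[[length(faces) + 1]] <- idx[c(1, t + 1, t + 2)]
        }
      }
    }
  } else {
    offset <- body_offset
    V <- matrix(NA_real_, velem$count, 3)
    for (i in seq_len(velem$count)) {
      vals <- numeric(length(velem$properties))
      for (j in seq_along(velem$properties)) {
        p <- velem$properties[[j]]
        if (p$list) stop("list property on vertex element unsupported")
        r <- ply_read_scalar(raw, offset, p$type)
        vals[j] <- r$value
        offset <- r$offset
      }
      V[i, ] <- vals[match(c("x", "y", "z"), vprops)]
    }
    faces <- list()
    if (!is.null(felem)) {
      fp <- felem$properties[[1]]
      if (!fp$list) stop("face element must carry a list property")
      for (i in seq_len(felem$count)) {
        r <- ply_read_scalar(raw, offset, fp$count_type)
        k <- r$value; offset <- r$offset
        idx <- integer(k)
        for (j in seq_len(k)) {
          r <- ply_read_scalar(raw, offset, fp$item_type)
          idx[j] <- r$value; offset <- r$offset
        }
        idx <- idx + 1L
        if (k < 3) stop("face with fewer than 3 vertices")
        for (t in seq_len(k - 2)) {
          faces[[length(faces) + 1]] <- idx[c(1, t + 1, t + 2)]
        }
      }
    }
  }
  colnames(V) <- c("x", "y", "z")
  triangle_mesh(V, if (length(faces)) do.call(rbind, faces) else
                matrix(integer(0), 0, 3), comment = comment)
}

write_ply <- function(mesh, path, binary = FALSE) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii",
                 "1.0"),
           if (!is.null(mesh$comment)) paste("comment", mesh$comment),
           paste("element vertex", nrow(V)),
           if (binary) c("property float x", "property float y",
                         "property float z")
           else c("property double x", "property double y",
                  "property double z"),
           paste("element face", nrow(F)),
           "property list uchar int vertex_indices",
           "end_header")
  writeLines(hdr, con, sep = "\n")
  if (binary) {
    writeBin(as.vector(t(V)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(F))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(F[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    writeLines(apply(V, 1, function(r) paste(sprintf("%.17g", r),
                                             collapse = " ")), con)
    writeLines(apply(F, 1, function(r) paste(c(3, r - 1L), collapse = " ")),
               con)
  }
  invisible(path)
}

read_stl_binary <- function(path, weld_tol = 1e-6) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) >= 5 && identical(rawToChar(raw[1:5]), "solid") &&
      length(raw) < 84) {
    stop("ascii STL is not supported; export binary STL")
  }
  if (length(raw) < 84) stop("truncated STL file")
  ntri <- readBin(raw[81:84], "integer", size = 4, endian = "little")
  expect <- 84 + 50 * ntri
  if (!is.finite(ntri) || ntri < 0 || length(raw) < expect) {
    if (identical(rawToChar(raw[1:5]), "solid")) {
      stop("ascii STL is not supported; export binary STL")
    }
    stop("truncated STL body")
  }
  tri_pts <- matrix(NA_real_, ntri * 3, 3)
  for (i in seq_len(ntri)) {
    off <- 84 + 50 * (i - 1)
    vals <- readBin(raw[(off + 1):(off + 48)], "double", n = 12, size = 4,
                    endian = "little")
    tri_pts[3 * i - 2, ] <- vals[4:6]
    tri_pts[3 * i - 1, ] <- vals[7:9]
    tri_pts[3 * i, ] <- vals[10:12]
  }
  # weld duplicate vertices on a tolerance grid
  key <- apply(round(tri_pts / weld_tol), 1, paste, collapse = "_")
  uniq <- !duplicated(key)
  V <- tri_pts[uniq, , drop = FALSE]
  colnames(V) <- c("x", "y", "z")
  idx <- match(key, key[uniq])
  F <- matrix(idx, ncol = 3, byrow = TRUE)
  triangle_mesh(V, F)
}

write_stl_binary <- function(mesh, path) {
  V <- mesh$vertices
  F <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "cephalomorph binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(F)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(F))) {
    p <- V[F[i, ], , drop = FALSE]
    nrm <- cross3(p[2, ] - p[1, ], p[3, ] - p[1, ])
    len <- sqrt(sum(nrm^2))
    nrm <- if (len > 0) nrm / len else c(0, 0, 0)
    writeBin(c(nrm, t(p)), con, size = 4, endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
  invisible(path)
}

#' Read a triangle mesh
#'
#' Reads PLY (ascii or binary little-endian; polygon faces are split
#' fan-wise into triangles) or binary STL (with vertex welding at
#' \code{weld_tol}).
#'
#' @param path File path; format inferred from the extension unless
#'   \code{format} is given.
#' @param format One of \code{"ply"}, \code{"stl"} or NULL (infer).
#' @param weld_tol Vertex welding tolerance (mm) for STL import.
#' @return A \code{triangle_mesh} (vertices in file units, assumed mm).
#' @export
read_mesh <- function(path, format = NULL, weld_tol = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     ply = "ply", stl = "stl",
                     stop("cannot infer mesh format from extension: ", path))
  }
  switch(format,
         ply = read_ply(path),
         stl = read_stl_binary(path, weld_tol = weld_tol),
         stop("unknown mesh format: ", format))
}

#' Write a triangle mesh
#'
#' Output is deterministic for a fixed mesh and format (fixed property
#' ordering and float formatting).
#'
#' @param mesh A \code{triangle_mesh}.
#' @param path Output path.
#' @param format \code{"ply_ascii"}, \code{"ply_binary_le"} or
#'   \code{"stl_binary"}.
#' @return A \code{mesh_file_record}: list with \code{path},
#'   \code{format}, \code{vertex_count}, \code{face_count}.
#' @export
write_mesh <- function(mesh, path,
                       format = c("ply_ascii", "ply_binary_le", "stl_binary")) {
  format <- match.arg(format)
  if (nrow(mesh$faces) == 0) stop("refusing to write a mesh with no faces")
  switch(format,
         ply_ascii = write_ply(mesh, path, binary = FALSE),
         ply_binary_le = write_ply(mesh, path, binary = TRUE),
         stl_binary = write_stl_binary(mesh, path))
  structure(list(path = path, format = format,
                 vertex_count = nrow(mesh$vertices),
                 face_count = nrow(mesh$faces)),
            class = "mesh_file_record")
}
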