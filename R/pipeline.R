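# End-to-end analysis: validation -> distances/proportions -> per-sex
# normality screen -> sex comparison (BH) -> per-sex k-means ->
# per-cluster comparison (BH) -> GPA mean shape per sex x cluster ->
# optional TPS template morphing. BH correction is applied within each
# 8-test table separately, never across tables.

#' Analysis configuration
#'
#' @param landmarks Path to a landmark CSV/JSON file, a list of
#'   \code{landmark_set}s, or a \code{synthetic_cohort}.
#' @param out_dir Output directory (created if needed); NULL to skip
#'   writing files.
#' @param k Number of clusters per sex (the elbow curve is always
#'   computed as a diagnostic, but k is an explicit choice).
#' @param alpha Significance level.
#' @param scaling Feature scaling for k-means (\code{"zscore"} or
#'   \code{"none"}).
#' @param seed Integer seed for the clustering restarts.
#' @param n_init k-means++ restarts.
#' @param lambda TPS regularization for template morphing.
#' @param template_meshes Optional named list
#'   \code{list(female = , male = )} of \code{triangle_mesh} objects (or
#'   mesh file paths) carrying 18-landmark annotations.
#' @param proportion_spec Proportion-definition table.
#' @return An \code{analysis_config}.
#' @export
analysis_config <- function(landmarks, out_dir = NULL, k = 2, alpha = 0.05,
                            scaling = c("zscore", "none"), seed = 1,
                            n_init = 20, lambda = 0,
                            template_meshes = NULL,
                            proportion_spec = default_proportion_spec()) {
  scaling <- match.arg(scaling)
  if (k < 1) stop("k must be >= 1")
  if (is.character(landmarks) && !file.exists(landmarks)) {
    stop("landmark file not found: ", landmarks)
  }
  structure(list(landmarks = landmarks, out_dir = out_dir, k = as.integer(k),
                 alpha = alpha, scaling = scaling, seed = as.integer(seed),
                 n_init = n_init, lambda = lambda,
                 template_meshes = template_meshes,
                 proportion_spec = proportion_spec),
            class = "analysis_config")
}

resolve_landmarks <- function(landmarks) {
  if (is.character(landmarks)) return(read_landmarks(landmarks))
  if (inherits(landmarks, "synthetic_cohort")) return(landmarks$specimens)
  if (inherits(landmarks, "landmark_set")) return(list(landmarks))
  landmarks
}

#' Run the full cephalometric analysis
#'
#' Executes, in order: landmark validation (specimens failing validation
#' are dropped with a message, never imputed), distance and proportion
#' measurement, per-sex Kolmogorov-Smirnov normality screening, sex
#' comparison with Benjamini-Hochberg correction, per-sex k-means
#' sub-phenotype clustering (with the elbow curve as a diagnostic),
#' per-cluster comparison with BH correction, a generalized Procrustes
#' mean shape per sex x cluster group, and -- when template meshes are
#' supplied -- thin-plate-spline morphing into normative template skulls.
#' The result is a pure function of (input data, config, seed).
#'
#' @param config An \code{\link{analysis_config}}.
#' @return An \code{analysis_report}: list with \code{specimens},
#'   \code{proportions}, \code{normality}, \code{sex_comparison},
#'   \code{clusters} (per sex: \code{cluster_model}, \code{elbow},
#'   comparison table), \code{mean_shapes} (one \code{shape_ensemble} per
#'   sex x cluster), \code{templates} (morphed meshes or NULL) and
#'   \code{provenance}.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  raw_sets <- resolve_landmarks(config$landmarks)
  sets <- list()
  dropped <- character(0)
  for (s in raw_sets) {
    ok <- tryCatch({
      validate_landmark_set(s)
      TRUE
    }, error = function(e) {
      message("dropping specimen '",
              if (inherits(s, "landmark_set")) s$specimen_id else "?",
              "': ", conditionMessage(e))
      FALSE
    })
    if (ok) sets[[length(sets) + 1]] <- s else {
      dropped <- c(dropped, if (inherits(s, "landmark_set")) s$specimen_id
                            else "<invalid>")
    }
  }
  sexes <- vapply(sets, function(s) s$sex, character(1))
  groups <- intersect(c("female", "male"), unique(sexes))
  if (length(groups) == 0) stop("no specimens with a female/male sex label")
  for (g in groups) {
    if (sum(sexes == g) < 2) stop("group '", g, "' has fewer than 2 specimens")
  }

  props <- measure_proportions(sets, config$proportion_spec)
  meta <- cohort_metadata(sets)

  normality <- do.call(rbind, lapply(groups, function(g) {
    normality_screen(props[sexes == g, , drop = FALSE], group = g,
                     alpha = config$alpha)
  }))

  sex_comparison <- if (length(groups) == 2) {
    compare_groups(props[sexes == "female", , drop = FALSE],
                   props[sexes == "male", , drop = FALSE],
                   alpha = config$alpha, labels = c("female", "male"))
  }

  clusters <- list()
  mean_shapes <- list()
  for (g in groups) {
    idx <- which(sexes == g)
    gp <- props[idx, , drop = FALSE]
    elbow <- if (length(idx) > max(3, config$k)) {
      elbow_curve(gp, k_max = min(6, length(idx) - 1),
                  scaling = config$scaling, seed = config$seed,
                  n_init = config$n_init)
    }
    model <- kmeans_fit(gp, k = config$k, scaling = config$scaling,
                        seed = config$seed, n_init = config$n_init)
    if (config$k == 2) model <- label_phenotypes(model)
    comparison <- if (config$k == 2 && all(model$sizes >= 2)) {
      compare_groups(gp[model$assignments == 1, , drop = FALSE],
                     gp[model$assignments == 2, , drop = FALSE],
                     alpha = config$alpha,
                     labels = paste0(substr(g, 1, 1), 1:2))
    }
    clusters[[g]] <- list(model = model, elbow = elbow,
                          comparison = comparison,
                          specimen_ids = meta$specimen_id[idx])
    for (cl in seq_len(config$k)) {
      members <- idx[model$assignments == cl]
      label <- paste0(g, "_cluster", cl)
      if (length(members) >= 2) {
        mean_shapes[[label]] <- gpa_mean(sets[members], group_label = label)
      }
    }
  }

  report <- structure(
    list(specimens = sets, proportions = props, metadata = meta,
         normality = normality, sex_comparison = sex_comparison,
         clusters = clusters, mean_shapes = mean_shapes, templates = NULL,
         dropped = dropped,
         provenance = list(
           seed = config$seed, k = config$k, alpha = config$alpha,
           scaling = config$scaling, n_init = config$n_init,
           lambda = config$lambda,
           proportion_definitions = unclass(config$proportion_spec),
           proportion_substitutions = attr(config$proportion_spec,
                                           "substitutions"),
           package_version = as.character(utils::packageVersion("cephalomorph")))),
    class = "analysis_report")

  if (!is.null(config$template_meshes)) {
    meshes <- lapply(config$template_meshes, function(m) {
      if (is.character(m)) read_mesh(m) else m
    })
    report$templates <- make_templates(report,
                                       male_mesh = meshes$male,
                                       female_mesh = meshes$female,
                                       lambda = config$lambda)
  }
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Morph template meshes to the four cluster mean shapes
#'
#' The male template mesh is morphed onto each male cluster mean and the
#' female template onto each female cluster mean, via
#' \code{\link{morph_template}} (similarity rescaling of the unit-size
#' mean followed by exact TPS interpolation).
#'
#' @param report An \code{analysis_report} containing the cluster mean
#'   shapes.
#' @param male_mesh,female_mesh \code{triangle_mesh} objects carrying
#'   18-landmark annotations (may be NULL to skip a sex).
#' @param lambda TPS regularization.
#' @return Named list of morphed \code{triangle_mesh}es, one per
#'   available sex x cluster mean shape.
#' @export
make_templates <- function(report, male_mesh = NULL, female_mesh = NULL,
                           lambda = 0) {
  out <- list()
  for (label in names(report$mean_shapes)) {
    sex <- sub("_cluster[0-9]+$", "", label)
    mesh <- if (sex == "male") male_mesh else female_mesh
    if (is.null(mesh)) next
    if (is.null(mesh$landmarks)) {
      stop("template mesh for '", sex, "' carries no landmark annotations")
    }
    out[[label]] <- morph_template(
      mesh, template_landmarks = mesh$landmarks,
      target_mean = report$mean_shapes[[label]]$mean_shape,
      lambda = lambda)
  }
  out
}

#' Write all report artifacts to a directory
#'
#' Deterministic CSV/JSON serialization of every table the analysis
#' produced: proportions, normality screen, the sex comparison, the two
#' per-sex cluster comparisons, per-specimen cluster assignments, the
#' mean shapes (unit Procrustes frame) and a provenance block; morphed
#' templates are written as ascii PLY.
#'
#' @param report An \code{analysis_report}.
#' @param out_dir Output directory.
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write.csv(data.frame(specimen_id = rownames(report$proportions),
                       report$proportions, check.names = FALSE),
            fp("proportions.csv"), row.names = FALSE)
  write.csv(report$normality, fp("normality.csv"), row.names = FALSE)
  if (!is.null(report$sex_comparison)) {
    write_comparison_csv(report$sex_comparison, fp("sex_comparison.csv"))
  }
  assignments <- list()
  for (g in names(report$clusters)) {
    cl <- report$clusters[[g]]
    if (!is.null(cl$comparison)) {
      write_comparison_csv(cl$comparison,
                           fp(sprintf("cluster_comparison_%s.csv", g)))
    }
    assignments[[g]] <- data.frame(
      specimen_id = cl$specimen_ids, sex = g,
      cluster = cl$model$assignments,
      phenotype = cl$model$phenotype_labels[cl$model$assignments])
  }
  write.csv(do.call(rbind, assignments), fp("cluster_assignments.csv"),
            row.names = FALSE)
  for (label in names(report$mean_shapes)) {
    write_shape_json(report$mean_shapes[[label]]$mean_shape,
                     fp(sprintf("mean_shape_%s.json", label)),
                     frame = "gpa_unit", label = label)
  }
  for (label in names(report$templates)) {
    write_mesh(report$templates[[label]],
               fp(sprintf("template_%s.ply", label)), "ply_ascii")
  }
  jsonlite::write_json(report$provenance, fp("provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report> ", length(x$specimens), " specimens, ",
      length(x$mean_shapes), " group mean shapes\n", sep = "")
  if (!is.null(x$sex_comparison)) {
    cat("\nSex comparison:\n")
    print(x$sex_comparison)
  }
  for (g in names(x$clusters)) {
    cmp <- x$clusters[[g]]$comparison
    if (!is.null(cmp)) {
      cat("\nCluster comparison (", g, "):\n", sep = "")
      print(cmp)
    }
  }
  invisible(x)
}
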