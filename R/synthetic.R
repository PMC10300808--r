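# Synthetic landmark cohorts: an inverse-geometry realizer that builds a
# bilaterally symmetric 18-landmark scaffold attaining prescribed
# proportions exactly, plus a cohort generator adding per-landmark
# Gaussian digitization noise and arbitrary similarity poses.

#' Published normative proportion means
#'
#' Mean values of the eight facial proportions reported for an adult
#' Eurasian cohort (46 male / 44 female), by sex and by the two k-means
#' sub-phenotype clusters within each sex. These columns are the default
#' calibration targets for \code{\link{realize_proportions}} and
#' \code{\link{generate_cohort}}.
#'
#' @return Data frame with rownames P01..P08 and columns \code{female},
#'   \code{male} (sex means), \code{male_m1}, \code{male_m2},
#'   \code{female_f1}, \code{female_f2} (cluster means; m1/f1 are the
#'   dolichofacial clusters).
#' @export
#' @examples
#' normative_proportion_targets()
normative_proportion_targets <- function() {
  data.frame(
    female    = c(1.080, 1.877, 1.040, 0.962, 4.851, 1.806, 1.816, 1.738),
    male      = c(1.115, 2.008, 1.082, 0.986, 5.293, 1.874, 1.785, 1.802),
    male_m1   = c(1.178, 2.146, 1.136, 0.940, 5.535, 1.977, 1.643, 1.823),
    male_m2   = c(1.071, 1.912, 1.043, 1.019, 5.123, 1.802, 1.884, 1.786),
    female_f1 = c(1.164, 2.001, 1.092, 0.921, 4.979, 1.900, 1.670, 1.746),
    female_f2 = c(1.034, 1.791, 1.003, 0.989, 4.763, 1.742, 1.917, 1.733),
    row.names = sprintf("P%02d", 1:8)
  )
}

# scaffold positions (relative to V1) of the landmarks not pinned by the
# eight defining distances; arbitrary but frozen, since GPA mean shapes
# depend on all 18 points. v1 of the scaffold: do not move.
scaffold_free <- list(
  `IF r`  = c(0.12, 0.12, 0.02),
  LIbl    = c(0.00, 0.25, -0.85),
  `LoMdbrbl r` = c(0.28, 0.15, -0.80),
  `Pom r` = c(0.40, -0.45, -0.95),
  UpM_yz  = c(0.30, -0.60),   # y, z of the upper molar pair (x = +-H3/2)
  FOS_yz  = c(0.10, 0.00),    # y, z of the frontoorbital pair (x = +-H1/2)
  V2_rel  = 0.55              # Nasion--SPA distance as a fraction of V1
)

#' Realize a landmark configuration with prescribed proportions
#'
#' Inverse construction for the proportion definitions: fixes the upper
#' facial width H1 at \code{base_scale_mm} and derives the remaining
#' defining distances from the targets (V1 = P01 H1, H3 = V1/P02,
#' H2 = V1/P03, V3 = V1/P04, V4 = V1/P05, Z1 = V1/P06), then places the
#' 18 landmarks on a fixed bilaterally symmetric scaffold (midline points
#' on the x = 0 plane, paired points mirrored in x) so that exactly the
#' defining pairs attain those distances. P07 and P08 share distances
#' already fixed by P01-P06 and cannot be set independently; the realized
#' values (P07 = P01/P04, P08 = P02/P01) are reported in the
#' \code{"realized_proportions"} attribute.
#'
#' @param targets Numeric vector with names P01..P08 (P07/P08 optional
#'   and ignored), or a column of
#'   \code{\link{normative_proportion_targets}}; an unnamed length-8
#'   vector is taken in P01..P08 order.
#' @param base_scale_mm The realized H1 (frontoorbital width) in mm.
#' @param specimen_id,sex Passed to the resulting \code{landmark_set}.
#' @return A \code{landmark_set} whose measured default proportions
#'   P01..P06 equal the targets exactly, with attribute
#'   \code{"realized_proportions"}.
#' @export
#' @examples
#' lm <- realize_proportions(normative_proportion_targets()$male_m1)
#' compute_proportions(compute_distances(lm))[["P05"]]  # 5.535
realize_proportions <- function(targets, base_scale_mm = 100,
                                specimen_id = "synthetic",
                                sex = c("unknown", "female", "male")) {
  sex <- match.arg(sex)
  targets <- unlist(targets)
  if (is.null(names(targets))) {
    if (length(targets) < 6) stop("need at least P01..P06 targets")
    names(targets) <- sprintf("P%02d", seq_along(targets))
  }
  need <- sprintf("P%02d", 1:6)
  if (!all(need %in% names(targets))) {
    stop("missing proportion targets: ",
         paste(setdiff(need, names(targets)), collapse = ", "))
  }
  if (any(targets[need] <= 0) || base_scale_mm <= 0) {
    stop("proportion targets and base scale must be strictly positive")
  }
  H1 <- base_scale_mm
  V1 <- targets[["P01"]] * H1
  H3 <- V1 / targets[["P02"]]
  H2 <- V1 / targets[["P03"]]
  V3 <- V1 / targets[["P04"]]
  V4 <- V1 / targets[["P05"]]
  Z1 <- V1 / targets[["P06"]]
  V2 <- scaffold_free$V2_rel * V1

  # midline: Nasion at the origin, Pogonion straight below
  N <- c(0, 0, 0)
  Po <- c(0, 0, -V1)
  zs <- (V3^2 - V2^2 - V1^2) / (2 * V1)
  ys2 <- V2^2 - zs^2
  if (ys2 <= 0) {
    stop("unrealizable geometry: V1/V2/V3 violate the triangle inequality ",
         "(P04 = ", format(targets[["P04"]]), ")")
  }
  SPA <- c(0, sqrt(ys2), zs)

  FOSr <- c(H1 / 2, scaffold_free$FOS_yz[1] * V1, scaffold_free$FOS_yz[2] * V1)
  IOEr <- FOSr + c(0, 0, -V4)
  dx <- (H1 - H2) / 2
  back2 <- Z1^2 - dx^2
  if (back2 <= 0) {
    stop("unrealizable geometry: Z1 shorter than the half-width gap ",
         "between the orbital and condylar pairs")
  }
  Cor <- c(H2 / 2, IOEr[2] - sqrt(back2), IOEr[3])
  UpMr <- c(H3 / 2, scaffold_free$UpM_yz[1] * V1, scaffold_free$UpM_yz[2] * V1)

  mirror <- function(p) c(-p[1], p[2], p[3])
  IFr <- scaffold_free$`IF r` * V1
  LoMr <- scaffold_free$`LoMdbrbl r` * V1
  Pomr <- scaffold_free$`Pom r` * V1
  LIbl <- scaffold_free$LIbl * V1

  pts <- rbind(
    N, FOSr, mirror(FOSr), IOEr, mirror(IOEr), IFr, mirror(IFr), SPA,
    UpMr, mirror(UpMr), LIbl, LoMr, mirror(LoMr), Cor, mirror(Cor), Po,
    Pomr, mirror(Pomr)
  )
  rownames(pts) <- landmark_codes()
  lm <- validate_landmark_set(pts, specimen_id = specimen_id, sex = sex)
  attr(lm, "realized_proportions") <-
    compute_proportions(compute_distances(lm))
  attr(lm, "requested_targets") <- targets
  lm
}

#' Describe one synthetic cohort group
#'
#' @param label Group label (also the specimen id prefix).
#' @param n Number of specimens (>= 1).
#' @param proportion_targets Targets passed to
#'   \code{\link{realize_proportions}}.
#' @param base_scale_mm Realized H1 in mm.
#' @param noise_sd_mm Isotropic per-coordinate Gaussian digitization
#'   noise, mm. The default 0.5 mm is of the order of the voxel spacing
#'   of clinical CBCT.
#' @param pose \code{"canonical"} (scaffold frame) or
#'   \code{"random_similarity"} (random rotation, translation within
#'   +-500 mm, scale in [0.8, 1.25] per specimen).
#' @param sex Sex label stored on each specimen.
#' @param true_cluster Ground-truth cluster id stored on each specimen.
#' @return A list consumed by \code{\link{cohort_spec}}.
#' @export
cohort_group <- function(label, n, proportion_targets, base_scale_mm = 100,
                         noise_sd_mm = 0.5,
                         pose = c("random_similarity", "canonical"),
                         sex = "unknown", true_cluster = NA_integer_) {
  pose <- match.arg(pose)
  if (n < 1) stop("each group needs n >= 1")
  if (noise_sd_mm < 0) stop("noise_sd_mm must be non-negative")
  list(label = label, n = as.integer(n),
       proportion_targets = proportion_targets,
       base_scale_mm = base_scale_mm, noise_sd_mm = noise_sd_mm,
       pose = pose, sex = sex, true_cluster = true_cluster)
}

#' Cohort specification
#'
#' @param groups List of \code{\link{cohort_group}} descriptions.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A \code{cohort_spec}.
#' @export
cohort_spec <- function(groups, seed = 1) {
  if (length(groups) < 1) stop("cohort needs at least one group")
  structure(list(groups = groups, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic landmark cohort
#'
#' For each group: the canonical realization of its proportion targets,
#' plus i.i.d. Gaussian displacement of every coordinate
#' (\code{noise_sd_mm}), plus -- under \code{pose =
#' "random_similarity"} -- a Haar-uniform random rotation, a translation
#' drawn within +-500 mm per axis and a uniform scale in [0.8, 1.25].
#' Deterministic given the spec's seed.
#'
#' @param spec A \code{cohort_spec} (or list of \code{cohort_group}s,
#'   with \code{seed}).
#' @param seed Overrides the spec's seed if given.
#' @return A \code{synthetic_cohort}: list with \code{specimens} (each a
#'   \code{landmark_set} carrying \code{group}, \code{true_cluster}) and
#'   \code{spec}.
#' @export
#' @examples
#' tab <- normative_proportion_targets()
#' spec <- cohort_spec(list(
#'   cohort_group("m1", 10, tab$male_m1, sex = "male", true_cluster = 1),
#'   cohort_group("m2", 10, tab$male_m2, sex = "male", true_cluster = 2)),
#'   seed = 42)
#' cohort <- generate_cohort(spec)
#' length(cohort$specimens)
generate_cohort <- function(spec, seed = NULL) {
  if (!inherits(spec, "cohort_spec")) spec <- cohort_spec(spec)
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(spec$seed)
  specimens <- list()
  for (g in spec$groups) {
    sex <- if (g$sex %in% c("female", "male")) g$sex else "unknown"
    canonical <- realize_proportions(g$proportion_targets,
                                     base_scale_mm = g$base_scale_mm,
                                     sex = sex)
    for (i in seq_len(g$n)) {
      pts <- canonical$points +
        matrix(rnorm(54, sd = g$noise_sd_mm), 18, 3)
      if (g$pose == "random_similarity") {
        R <- random_rotation()
        s <- runif(1, 0.8, 1.25)
        tr <- runif(3, -500, 500)
        pts <- sweep(s * pts %*% R, 2, tr, `+`)
      }
      rownames(pts) <- landmark_codes()
      lm <- validate_landmark_set(pts,
                                  specimen_id = sprintf("%s_%03d", g$label, i),
                                  sex = sex)
      lm$group <- g$label
      lm$true_cluster <- g$true_cluster
      specimens[[length(specimens) + 1]] <- lm
    }
  }
  structure(list(specimens = specimens, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  labels <- vapply(x$specimens, function(s) s$group, character(1))
  cat("<synthetic_cohort> ", length(x$specimens), " specimens (",
      paste(sprintf("%s: %d", names(table(labels)), table(labels)),
            collapse = ", "), "), seed ", x$spec$seed, "\n", sep = "")
  invisible(x)
}

#' Per-specimen metadata of a cohort
#'
#' @param cohort A \code{synthetic_cohort} or list of
#'   \code{landmark_set}s.
#' @return Data frame with \code{specimen_id}, \code{sex}, \code{group},
#'   \code{true_cluster}.
#' @export
cohort_metadata <- function(cohort) {
  sets <- if (inherits(cohort, "synthetic_cohort")) cohort$specimens else cohort
  do.call(rbind, lapply(sets, function(s) {
    data.frame(specimen_id = s$specimen_id, sex = s$sex,
               group = if (!is.null(s$group)) s$group else NA_character_,
               true_cluster = if (!is.null(s$true_cluster)) s$true_cluster
                              else NA_integer_)
  }))
}
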