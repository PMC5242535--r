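## Synthetic labelled brain phantoms.
##
## The anatomy is deliberately schematic: an ellipsoidal brain envelope
## containing a cortical shell and ellipsoidal striatum, hippocampus, corpus
## callosum and ventricles, plus a cheek-muscle block outside the brain that
## serves as the internal control tissue. Regional volumes follow
## genotype/sex/age trajectories with known ground truth, so every downstream
## estimator can be validated against the generating model.

REGION_LABELS <- c(
  background = 0L, brain = 1L, cortex = 2L, striatum = 3L,
  hippocampus = 4L, corpus_callosum = 5L, ventricles = 6L, muscle = 7L
)

#' Phantom geometry specification
#'
#' Defines the voxel grid and the analytic (ellipsoid / ellipsoidal-shell)
#' region set of the synthetic brain. Sizes are in mm; the default grid is
#' 64 x 96 x 64 voxels at 0.15625 x 0.15625 x 0.5 mm, matching a typical
#' in vivo mouse protocol (156 um in plane, 0.5 mm slices).
#'
#' Each region entry holds the ellipsoid centre (mm, relative to the grid
#' centre), semi-axes (mm) at reference volume, and for the cortex the
#' inner/outer shell ratio. Regions are rasterised by voxel centre; scaling to
#' a target volume multiplies all semi-axes by `(V_target / V_ref)^(1/3)`.
#'
#' @param dim integer 3-vector of grid dimensions.
#' @param spacing numeric 3-vector of voxel spacing in mm.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64L, 96L, 64L),
                         spacing = c(0.15625, 0.15625, 0.5)) {
  stopifnot(length(dim) == 3, length(spacing) == 3, all(spacing > 0),
            all(dim >= 4))
  regions <- list(
    brain           = list(center = c(0, 0, 0), semi = c(3.90, 5.40, 4.90)),
    ## cortical shell: outer surface co-scales with the brain envelope, inner
    ## surface is derived from the target shell volume (atrophy thins the
    ## shell rather than shrinking the whole annulus)
    cortex          = list(center = c(0, 0, 0), semi = c(3.70, 5.10, 4.60),
                           shell = TRUE),
    striatum        = list(center = c(0, 0.50, -0.60), semi = c(1.45, 1.95, 1.15)),
    hippocampus     = list(center = c(0, -0.90, 1.90), semi = c(1.45, 1.85, 1.05)),
    corpus_callosum = list(center = c(0, 2.60, 1.20),  semi = c(1.70, 0.60, 1.20)),
    ventricles      = list(center = c(0, -0.30, -2.70), semi = c(1.20, 1.30, 0.70)),
    muscle          = list(center = c(-3.70, -5.40, 0), semi = c(0.90, 0.90, 3.20))
  )
  structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                 regions = regions),
            class = "phantom_spec")
}

#' Analytic reference volume of a region spec (mm^3)
#'
#' `4/3 * pi * a * b * c` for ellipsoids; outer minus inner for the cortical
#' shell.
#'
#' @param spec a [phantom_spec()].
#' @param region region name.
#' @return volume in mm^3 at reference (unit) scale.
#' @export
region_reference_volume <- function(spec, region) {
  r <- spec$regions[[region]]
  if (is.null(r)) stop("unknown region: ", region)
  4 / 3 * pi * prod(r$semi)
}

ellipsoid_mask <- function(coords_mm, center, semi) {
  q <- ((coords_mm[, 1] - center[1]) / semi[1])^2 +
       ((coords_mm[, 2] - center[2]) / semi[2])^2 +
       ((coords_mm[, 3] - center[3]) / semi[3])^2
  q <= 1
}

#' Generate a labelled phantom volume
#'
#' Rasterises the phantom anatomy at a given age for a given genotype and sex,
#' with regional target volumes taken from the trajectory model. The result is
#' deterministic in its arguments; cohort-level randomness (per-subject size
#' factors, sub-voxel positioning jitter) enters through `size_factor` and
#' `offset_mm`, which the cohort generator draws once per subject/scan.
#'
#' @param spec a [phantom_spec()].
#' @param age_weeks age in weeks, within [8, 94].
#' @param trajectory a [trajectory_config()].
#' @param genotype `"WT"` or `"HD"`.
#' @param sex `"male"` or `"female"`.
#' @param size_factor multiplicative subject size factor applied to all brain
#'   region volumes (default 1).
#' @param offset_mm rigid sub-voxel positioning offset in mm (default 0).
#' @return a `label_volume`: list with integer array `labels`, `spacing`,
#'   named label `codes`, and the generating `truth` table of target volumes.
#' @export
generate_phantom <- function(spec, age_weeks, trajectory, genotype, sex,
                             size_factor = 1, offset_mm = c(0, 0, 0)) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(trajectory, "trajectory_config"))
  if (age_weeks < 8 || age_weeks > 94) {
    stop("age_weeks must lie within [8, 94]")
  }
  genotype <- match.arg(genotype, c("WT", "HD"))
  sex <- match.arg(sex, c("male", "female"))

  d <- spec$dim
  centre_mm <- (d - 1) / 2 * spec$spacing
  g <- index_grid(d)
  coords <- sweep(sweep(g - 1, 2, spec$spacing, `*`), 2,
                  centre_mm + offset_mm, `-`)

  voxvol <- prod(spec$spacing)
  labels <- integer(nrow(g))
  truth <- data.frame(region = character(0), target_mm3 = numeric(0),
                      scale = numeric(0))

  scale_for <- function(region, target) {
    vref <- region_reference_volume(spec, region)
    if (target < voxvol) {
      stop("degenerate region '", region, "': target volume ", target,
           " mm^3 is below one voxel")
    }
    (target / vref)^(1 / 3)
  }

  ## brain envelope first
  v_brain <- region_volume_at(trajectory, "brain", genotype, sex, age_weeks) *
    size_factor
  rb <- spec$regions$brain
  sb <- scale_for("brain", v_brain)
  brain_mask <- ellipsoid_mask(coords, rb$center, rb$semi * sb)
  labels[brain_mask] <- REGION_LABELS[["brain"]]
  truth <- rbind(truth, data.frame(region = "brain", target_mm3 = v_brain,
                                   scale = sb))

  interior <- c("cortex", "striatum", "hippocampus", "corpus_callosum",
                "ventricles")
  for (region in interior) {
    r <- spec$regions[[region]]
    v <- region_volume_at(trajectory, region, genotype, sex, age_weeks) *
      size_factor
    if (isTRUE(r$shell)) {
      ## outer surface follows the brain envelope; inner surface set by the
      ## target shell volume
      outer_semi <- r$semi * sb
      v_outer <- 4 / 3 * pi * prod(outer_semi)
      if (v >= v_outer) {
        stop("configuration error: cortex target volume exceeds its outer ",
             "ellipsoid")
      }
      if (v < voxvol) {
        stop("degenerate region 'cortex': target volume below one voxel")
      }
      eta <- (1 - v / v_outer)^(1 / 3)
      m <- ellipsoid_mask(coords, r$center, outer_semi) &
        !ellipsoid_mask(coords, r$center, outer_semi * eta)
      s <- sb
    } else {
      s <- scale_for(region, v)
      m <- ellipsoid_mask(coords, r$center, r$semi * s)
    }
    if (any(!brain_mask[m])) {
      stop("configuration error: region '", region,
           "' extends outside the brain envelope")
    }
    if (any(labels[m] > REGION_LABELS[["brain"]])) {
      stop("configuration error: region '", region,
           "' overlaps a previously placed region")
    }
    labels[m] <- REGION_LABELS[[region]]
    truth <- rbind(truth, data.frame(region = region, target_mm3 = v, scale = s))
  }

  ## muscle control block, outside the brain
  rm_ <- spec$regions$muscle
  v_m <- region_volume_at(trajectory, "muscle", genotype, sex, age_weeks)
  sm <- scale_for("muscle", v_m)
  mm <- ellipsoid_mask(coords, rm_$center, rm_$semi * sm)
  if (any(brain_mask[mm])) {
    stop("configuration error: muscle block overlaps the brain envelope")
  }
  labels[mm] <- REGION_LABELS[["muscle"]]
  truth <- rbind(truth, data.frame(region = "muscle", target_mm3 = v_m,
                                   scale = sm))

  structure(list(labels = array(labels, d), spacing = spec$spacing,
                 codes = REGION_LABELS, truth = truth,
                 meta = list(age_weeks = age_weeks, genotype = genotype,
                             sex = sex, size_factor = size_factor)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels at ", paste(signif(x$spacing, 4), collapse = " x "), " mm\n",
      sep = "")
  tab <- table(factor(x$labels, levels = x$codes,
                      labels = names(x$codes)))
  print(tab)
  invisible(x)
}
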