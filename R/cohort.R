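## Seeded longitudinal cohort generation: behavioural tables plus per-scan
## phantom parameters. All randomness is drawn once at cohort creation, so
## materialising any phantom afterwards is a pure (deterministic) function.

#' Generate a synthetic longitudinal cohort
#'
#' Emulates the study design: 2 genotypes x 2 sexes, `n_per_cell` animals per
#' cell, behavioural measures at `behaviour_ages` and imaging at
#' `imaging_ages`. Behavioural values carry a per-subject size factor, residual
#' noise, configurable missingness and occasional large (+/- `outlier_sd` SD)
#' outliers. Imaging randomness (subject size factor, per-scan noise,
#' sub-voxel positioning) is stored per scan; label volumes are materialised
#' lazily with [cohort_phantom()].
#'
#' @param trajectory a [trajectory_config()].
#' @param n_per_cell animals per genotype x sex cell (>= 2).
#' @param behaviour_ages ages (weeks) at which behaviour is measured.
#' @param imaging_ages ages (weeks) at which imaging takes place; the default
#'   is the seven-scan longitudinal schedule (8-94 weeks).
#' @param seed integer seed.
#' @return object of class `hd_cohort` with elements `subjects`, `behaviour`
#'   (long-format data.frame: subject, genotype, sex, age_weeks, measure,
#'   value, missing), `scans` (per subject x imaging age phantom parameters)
#'   and the generating `trajectory`.
#' @export
generate_cohort <- function(trajectory, n_per_cell = 10,
                            behaviour_ages = c(9, 16, 26, 38, 53, 79, 94),
                            imaging_ages = c(8, 15, 23, 36, 52, 81, 94),
                            seed = 1L) {
  stopifnot(inherits(trajectory, "trajectory_config"))
  if (n_per_cell < 2) stop("n_per_cell must be >= 2")
  if (length(behaviour_ages) == 0 && length(imaging_ages) == 0) {
    stop("configuration error: no measurement ages given")
  }
  set.seed(as.integer(seed))
  nz <- trajectory$noise

  cells <- expand.grid(genotype = c("WT", "HD"), sex = c("male", "female"),
                       stringsAsFactors = FALSE)
  subjects <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    data.frame(
      subject = sprintf("%s_%s_%02d", cells$genotype[i],
                        substr(cells$sex[i], 1, 1), seq_len(n_per_cell)),
      genotype = cells$genotype[i], sex = cells$sex[i],
      stringsAsFactors = FALSE
    )
  }))
  ns <- nrow(subjects)
  subjects$beh_factor <- exp(stats::rnorm(ns, 0, nz$subject_cv))
  subjects$vol_factor <- exp(stats::rnorm(ns, 0, nz$volume_subject_cv))

  measures <- names(trajectory$behaviour)
  beh <- expand.grid(subject = subjects$subject, age_weeks = behaviour_ages,
                     measure = measures, stringsAsFactors = FALSE)
  beh <- merge(beh, subjects[, c("subject", "genotype", "sex", "beh_factor")],
               by = "subject", sort = FALSE)
  beh <- beh[order(beh$measure, beh$age_weeks, beh$subject), ]
  mu <- mapply(function(m, g, s, a) behaviour_mean_at(trajectory, m, g, s, a),
               beh$measure, beh$genotype, beh$sex, beh$age_weeks)
  nb <- nrow(beh)
  value <- mu * beh$beh_factor * (1 + stats::rnorm(nb, 0, nz$residual_cv))
  ## inject outliers: +/- outlier_sd group SDs
  tot_cv <- sqrt(nz$subject_cv^2 + nz$residual_cv^2)
  is_out <- stats::runif(nb) < trajectory$outlier_rate
  value[is_out] <- value[is_out] +
    sample(c(-1, 1), sum(is_out), replace = TRUE) *
    trajectory$outlier_sd * tot_cv * mu[is_out]
  missing <- stats::runif(nb) < trajectory$missingness
  value[missing] <- NA_real_
  beh <- data.frame(subject = beh$subject, genotype = beh$genotype,
                    sex = beh$sex, age_weeks = beh$age_weeks,
                    measure = beh$measure, value = value, missing = missing,
                    outlier = is_out, stringsAsFactors = FALSE)

  scans <- expand.grid(subject = subjects$subject, age_weeks = imaging_ages,
                       stringsAsFactors = FALSE)
  scans <- merge(scans, subjects[, c("subject", "genotype", "sex",
                                     "vol_factor")],
                 by = "subject", sort = FALSE)
  nsc <- nrow(scans)
  scans$scan_factor <- exp(stats::rnorm(nsc, 0, nz$volume_residual_cv))
  scans$off_x <- stats::runif(nsc)
  scans$off_y <- stats::runif(nsc)
  scans$off_z <- stats::runif(nsc)
  scans$noise_seed <- sample.int(2^30, nsc)

  structure(list(subjects = subjects, behaviour = beh, scans = scans,
                 trajectory = trajectory, seed = as.integer(seed)),
            class = "hd_cohort")
}

#' Materialise the label phantom for one scan of a cohort
#'
#' Deterministic given the cohort object: all per-scan randomness was drawn at
#' cohort creation.
#'
#' @param cohort an `hd_cohort`.
#' @param subject subject id.
#' @param age_weeks one of the cohort's imaging ages.
#' @param spec a [phantom_spec()].
#' @return a `label_volume`.
#' @export
cohort_phantom <- function(cohort, subject, age_weeks, spec = phantom_spec()) {
  stopifnot(inherits(cohort, "hd_cohort"))
  row <- cohort$scans[cohort$scans$subject == subject &
                      cohort$scans$age_weeks == age_weeks, ]
  if (nrow(row) != 1) stop("no scan for ", subject, " at ", age_weeks,
                           " weeks")
  off <- c(row$off_x, row$off_y, row$off_z) * spec$spacing
  generate_phantom(spec, age_weeks, cohort$trajectory, row$genotype, row$sex,
                   size_factor = row$vol_factor * row$scan_factor,
                   offset_mm = off)
}

#' Materialise the multi-echo stack for one scan
#'
#' @inheritParams cohort_phantom
#' @param model a [tissue_model()].
#' @param echo_times echo times in ms.
#' @return a `multiecho_image`.
#' @export
cohort_multiecho <- function(cohort, subject, age_weeks,
                             spec = phantom_spec(), model = tissue_model(),
                             echo_times = echo_train()) {
  row <- cohort$scans[cohort$scans$subject == subject &
                      cohort$scans$age_weeks == age_weeks, ]
  if (nrow(row) != 1) stop("no scan for ", subject, " at ", age_weeks,
                           " weeks")
  lv <- cohort_phantom(cohort, subject, age_weeks, spec)
  render_multiecho(lv, model, echo_times, seed = row$noise_seed)
}

#' Zero-effect variant of the default trajectory configuration
#'
#' Both genotypes share the wild-type growth curves and behavioural means;
#' useful for null calibrations.
#'
#' @param ... passed through to [trajectory_config()].
#' @return a `trajectory_config`.
#' @export
null_trajectory_config <- function(...) {
  tc <- trajectory_config(...)
  for (rn in names(tc$regions)) tc$regions[[rn]]$HD <- tc$regions[[rn]]$WT
  for (mn in names(tc$behaviour)) {
    tc$behaviour[[mn]]$deficit[] <- 0
  }
  tc
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat("<hd_cohort> ", nrow(x$subjects), " subjects (",
      paste(table(x$subjects$genotype, x$subjects$sex), collapse = "/"),
      " per cell), ", length(unique(x$behaviour$age_weeks)),
      " behavioural ages, ", length(unique(x$scans$age_weeks)),
      " imaging ages, seed ", x$seed, "\n", sep = "")
  invisible(x)
}
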