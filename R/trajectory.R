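## Growth-then-atrophy trajectory model.
##
## Every brain region follows a logistic rise toward a genotype-specific peak
## volume, reached at `peak_age`; after the peak the volume declines linearly
## so that the total peak-to-final loss at 94 weeks equals the configured
## `decline` fraction. Wild-type regions plateau (decline 0) by default; the
## disease genotype combines a lower peak (lost growth) with post-peak
## atrophy, so the genotype gap at the final age compounds both effects.
## Behavioural measures follow a wild-type age curve with a genotype deficit
## that ramps linearly from a per-sex onset age to the configured final-age
## deficit fraction.

#' Trajectory configuration for the synthetic cohort
#'
#' The defaults are calibrated so that the disease group's peak-to-final
#' declines are 27% (striatum), 12% (cortex) and 21% (hippocampus), and the
#' final-age locomotor deficits are 34% (males) and 39% (females) - the
#' headline effect sizes of the HdhQ150 phenotype this package emulates.
#'
#' @param regions per-region, per-genotype growth parameters; see Details.
#' @param behaviour per-measure behavioural parameters.
#' @param sex_factor named multiplicative volume factors for `male`/`female`.
#' @param noise list: `volume_subject_cv` (per-subject size factor, shared
#'   across ages), `volume_residual_cv` (per-scan), `subject_cv` and
#'   `residual_cv` (behavioural analogues). Coefficients of variation.
#' @param missingness probability a behavioural observation is missing.
#' @param outlier_rate probability a behavioural observation is replaced by an
#'   outlier shifted `outlier_sd` group standard deviations.
#' @param outlier_sd outlier magnitude in group SDs (default 4, large enough
#'   for a Grubbs screen to have true positives).
#' @param final_age study end in weeks (decline is anchored at this age).
#'
#' @details Region parameters: `peak` (WT peak volume, mm^3), `peak_factor`
#' (HD peak relative to WT), `peak_age` (weeks), `decline` (fraction of peak
#' lost by `final_age`; in `[0, 1)`), `mid`/`tau` (logistic growth midpoint and
#' scale, weeks), `baseline` (fraction of peak-level signal at the lower
#' asymptote). Behavioural parameters: `base` (WT young-adult mean),
#' `age_slope` (fractional change per week of age in WT), `onset` and
#' `deficit` (per-sex onset age and final-age HD deficit fraction; negative
#' deficits model measures where impairment raises the value).
#'
#' @return object of class `trajectory_config`.
#' @export
trajectory_config <- function(regions = NULL, behaviour = NULL,
                              sex_factor = c(male = 1, female = 0.94),
                              noise = list(volume_subject_cv = 0.04,
                                           volume_residual_cv = 0.01,
                                           subject_cv = 0.05,
                                           residual_cv = 0.05),
                              missingness = 0.03,
                              outlier_rate = 0.01,
                              outlier_sd = 4,
                              final_age = 94) {
  if (is.null(regions)) regions <- default_region_trajectories()
  if (is.null(behaviour)) behaviour <- default_behaviour_trajectories()
  for (rn in names(regions)) {
    for (gt in c("WT", "HD")) {
      p <- regions[[rn]][[gt]]
      if (p$decline < 0 || p$decline >= 1) {
        stop("decline fraction for ", rn, "/", gt, " must lie in [0, 1)")
      }
      if (p$peak <= 0) stop("peak volume for ", rn, "/", gt, " must be > 0")
    }
  }
  structure(list(regions = regions, behaviour = behaviour,
                 sex_factor = sex_factor, noise = noise,
                 missingness = missingness, outlier_rate = outlier_rate,
                 outlier_sd = outlier_sd, final_age = final_age),
            class = "trajectory_config")
}

region_par <- function(peak, peak_factor, decline, peak_age = 36,
                       mid = 15, tau = 5, baseline = 0.8,
                       mid_hd = 18, tau_hd = 6) {
  list(
    WT = list(peak = peak, peak_age = peak_age, decline = 0,
              mid = mid, tau = tau, baseline = baseline),
    HD = list(peak = peak * peak_factor, peak_age = peak_age,
              decline = decline, mid = mid_hd, tau = tau_hd,
              baseline = baseline)
  )
}

default_region_trajectories <- function() {
  tr <- list(
    brain           = region_par(peak = 460, peak_factor = 0.96, decline = 0.05),
    cortex          = region_par(peak = 120, peak_factor = 0.875, decline = 0.12),
    striatum        = region_par(peak = 16,  peak_factor = 0.88, decline = 0.27),
    hippocampus     = region_par(peak = 14,  peak_factor = 0.92, decline = 0.21),
    corpus_callosum = region_par(peak = 5,   peak_factor = 0.95, decline = 0.10),
    ventricles      = region_par(peak = 4,   peak_factor = 1.30, decline = 0),
    muscle          = list(WT = list(peak = 12, peak_age = 8, decline = 0,
                                     mid = 0, tau = 1, baseline = 1),
                           HD = list(peak = 12, peak_age = 8, decline = 0,
                                     mid = 0, tau = 1, baseline = 1))
  )
  ## ventricles enlarge with disease; modelled as a higher HD plateau
  tr
}

default_behaviour_trajectories <- function() {
  list(
    locomotor_activity = list(base = 6000, age_slope = -0.004,
                              onset = c(male = 38, female = 16),
                              deficit = c(male = 0.34, female = 0.39)),
    grip_fore          = list(base = 100, age_slope = -0.001,
                              onset = c(male = 9, female = 38),
                              deficit = c(male = 0.25, female = 0.18)),
    grip_all           = list(base = 180, age_slope = -0.001,
                              onset = c(male = 38, female = 38),
                              deficit = c(male = 0.20, female = 0.20)),
    tmaze_trials       = list(base = 30, age_slope = 0.002,
                              onset = c(male = 13, female = 34),
                              deficit = c(male = -0.10, female = -0.05)),
    odor_preference    = list(base = 70, age_slope = -0.0005,
                              onset = c(male = 9, female = 9),
                              deficit = c(male = 0, female = 0)),
    social_preference  = list(base = 60, age_slope = -0.0005,
                              onset = c(male = 9, female = 9),
                              deficit = c(male = 0, female = 0))
  )
}

#' Target regional volume at an age (mm^3)
#'
#' The generating ground truth: logistic growth normalised to reach the
#' genotype peak at `peak_age`, then linear decline losing `decline` of the
#' peak by the final age. Multiplied by the per-sex size factor.
#'
#' @param trajectory a [trajectory_config()].
#' @param region region name.
#' @param genotype `"WT"` or `"HD"`.
#' @param sex `"male"` or `"female"`.
#' @param age_weeks age in weeks.
#' @return volume in mm^3.
#' @export
region_volume_at <- function(trajectory, region, genotype, sex, age_weeks) {
  p <- trajectory$regions[[region]][[genotype]]
  if (is.null(p)) stop("unknown region/genotype: ", region, "/", genotype)
  sf <- trajectory$sex_factor[[sex]]
  peak <- p$peak * sf
  growth <- function(a) {
    p$baseline + (1 - p$baseline) * stats::plogis((a - p$mid) / p$tau)
  }
  if (age_weeks <= p$peak_age) {
    peak * growth(age_weeks) / growth(p$peak_age)
  } else {
    fin <- trajectory$final_age
    peak * (1 - p$decline * (age_weeks - p$peak_age) / (fin - p$peak_age))
  }
}

#' Expected behavioural value at an age (group mean, no noise)
#'
#' @inheritParams region_volume_at
#' @param measure behavioural measure name.
#' @return expected group mean at that age.
#' @export
behaviour_mean_at <- function(trajectory, measure, genotype, sex, age_weeks) {
  p <- trajectory$behaviour[[measure]]
  if (is.null(p)) stop("unknown behavioural measure: ", measure)
  wt <- p$base * (1 + p$age_slope * (age_weeks - 9))
  if (genotype == "WT") return(wt)
  fin <- trajectory$final_age
  onset <- p$onset[[sex]]
  ramp <- if (age_weeks <= onset) 0 else (age_weeks - onset) / (fin - onset)
  wt * (1 - p$deficit[[sex]] * ramp)
}
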