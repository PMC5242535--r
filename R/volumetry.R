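## ROI volumetry: regional volumes from label volumes, longitudinal
## trajectories, percent-change and genotype-gap summaries.

#' Volume of a labelled region (mm^3)
#'
#' Voxel count times voxel volume. `"whole_brain"` is the union of all brain
#' labels (parenchyma, cortex, striatum, hippocampus, corpus callosum,
#' ventricles); muscle and background are never part of it.
#'
#' @param labels a `label_volume`.
#' @param region region name, or `"whole_brain"`.
#' @return volume in mm^3 (0 for an empty but known region).
#' @export
roi_volume <- function(labels, region) {
  stopifnot(inherits(labels, "label_volume"))
  voxvol <- prod(labels$spacing)
  if (region == "whole_brain") {
    codes <- labels$codes[setdiff(names(labels$codes),
                                  c("background", "muscle"))]
    return(sum(labels$labels %in% codes) * voxvol)
  }
  if (!region %in% names(labels$codes)) stop("unknown region: ", region)
  sum(labels$labels == labels$codes[[region]]) * voxvol
}

#' Longitudinal volume table for a cohort
#'
#' Materialises every scan of the cohort and measures all regional volumes,
#' returning a tidy table (subject, genotype, sex, age_weeks, region,
#' volume_mm3). This is the volumetry stage of the pipeline: volumes are
#' measured from the rasterised label volumes, not read from the generating
#' trajectory.
#'
#' @param cohort an `hd_cohort`.
#' @param spec a [phantom_spec()].
#' @param regions regions to measure.
#' @param ages subset of imaging ages (default: all).
#' @param genotypes subset of genotypes to materialise (default: both).
#' @return data.frame in long format.
#' @export
cohort_volumes <- function(cohort, spec = phantom_spec(),
                           regions = c("whole_brain", "cortex", "striatum",
                                       "hippocampus", "corpus_callosum"),
                           ages = NULL, genotypes = NULL) {
  stopifnot(inherits(cohort, "hd_cohort"))
  sc <- cohort$scans
  if (!is.null(ages)) sc <- sc[sc$age_weeks %in% ages, ]
  if (!is.null(genotypes)) sc <- sc[sc$genotype %in% genotypes, ]
  out <- vector("list", nrow(sc))
  for (i in seq_len(nrow(sc))) {
    lv <- cohort_phantom(cohort, sc$subject[i], sc$age_weeks[i], spec)
    out[[i]] <- data.frame(
      subject = sc$subject[i], genotype = sc$genotype[i], sex = sc$sex[i],
      age_weeks = sc$age_weeks[i], region = regions,
      volume_mm3 = vapply(regions, function(r) roi_volume(lv, r), numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Percent change in volume between two ages
#'
#' `100 * (V_to - V_from) / V_from`; negative values are losses (a -27%
#' change is a 27% decrease).
#'
#' @param series data.frame with columns `age_weeks` and `volume_mm3` (one
#'   row per age; e.g. a group mean trajectory), or a named numeric vector of
#'   volumes keyed by age.
#' @param from_age,to_age ages (weeks); both must be present.
#' @return percent change.
#' @export
percent_change <- function(series, from_age, to_age) {
  if (is.data.frame(series)) {
    v <- stats::setNames(series$volume_mm3, series$age_weeks)
  } else {
    v <- series
  }
  fa <- as.character(from_age); ta <- as.character(to_age)
  if (!fa %in% names(v) || !ta %in% names(v)) {
    stop("missing-data error: both ages must be present in the series")
  }
  100 * (v[[ta]] - v[[fa]]) / v[[fa]]
}

#' Peak-to-final percent decline of a group mean trajectory
#'
#' The peak age is the argmax of the mean trajectory over the available ages
#' (regional peaks differ between regions and genotypes, so no fixed age is
#' assumed). Returned as a positive percent decline.
#'
#' @param volumes long-format volume table (as from [cohort_volumes()]).
#' @param region region name.
#' @param genotype genotype to summarise.
#' @param final_age final age (default: latest age present).
#' @param pool_sexes average over sexes (default TRUE).
#' @return list: `decline_pct` (positive = loss), `peak_age`, `mean_curve`.
#' @export
peak_to_final_decline <- function(volumes, region, genotype = "HD",
                                  final_age = NULL, pool_sexes = TRUE) {
  v <- volumes[volumes$region == region & volumes$genotype == genotype, ]
  if (!nrow(v)) stop("no data for region ", region, " / ", genotype)
  if (!pool_sexes) v <- split(v, v$sex)[[1]]
  mc <- stats::aggregate(volume_mm3 ~ age_weeks, data = v, FUN = mean)
  mc <- mc[order(mc$age_weeks), ]
  if (is.null(final_age)) final_age <- max(mc$age_weeks)
  peak_age <- mc$age_weeks[which.max(mc$volume_mm3)]
  dec <- -percent_change(mc, peak_age, final_age)
  list(decline_pct = dec, peak_age = peak_age, mean_curve = mc)
}

#' Genotype gap in group means at one age
#'
#' `100 * (mean_WT - mean_HD) / mean_WT`: the percent by which the disease
#' group falls short of wild type. Applies to volumes or behavioural values.
#'
#' @param table data.frame with columns `genotype`, `value` (or `volume_mm3`),
#'   and optionally `age_weeks`, `sex`, `region`, `measure` for filtering.
#' @param age age to evaluate (filter applied if column present).
#' @param region,measure,sex optional filters.
#' @return percent gap (positive when the HD mean is lower).
#' @export
genotype_gap <- function(table, age = NULL, region = NULL, measure = NULL,
                         sex = NULL) {
  t <- table
  if (!is.null(age) && "age_weeks" %in% names(t)) t <- t[t$age_weeks == age, ]
  if (!is.null(region) && "region" %in% names(t)) t <- t[t$region == region, ]
  if (!is.null(measure) && "measure" %in% names(t)) {
    t <- t[t$measure == measure, ]
  }
  if (!is.null(sex) && "sex" %in% names(t)) t <- t[t$sex == sex, ]
  val <- if ("value" %in% names(t)) t$value else t$volume_mm3
  wt <- val[t$genotype == "WT"]
  hd <- val[t$genotype == "HD"]
  wt <- wt[!is.na(wt)]; hd <- hd[!is.na(hd)]
  if (!length(wt) || !length(hd)) {
    stop("insufficient-data error: empty genotype group after filtering")
  }
  100 * (mean(wt) - mean(hd)) / mean(wt)
}
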