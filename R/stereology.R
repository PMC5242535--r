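## Design-based stereology: Cavalieri point-counting volumes, the optical
## fractionator, sampling-fraction bookkeeping and the Gundersen-Jensen
## coefficient of error.

#' Cavalieri point-counting design
#'
#' @param area_per_point area associated with each grid point, a/p (um^2).
#' @param section_period_um distance between sampled section planes d (um);
#'   for sections of thickness t separated by gap g this is t + g.
#' @param counts integer vector of point counts per section (sum P_i).
#' @return object of class `cavalieri_design`.
#' @export
cavalieri_design <- function(area_per_point, section_period_um, counts) {
  if (area_per_point <= 0 || section_period_um <= 0) {
    stop("design error: a/p and section period must be positive")
  }
  if (any(counts < 0)) stop("design error: counts must be >= 0")
  structure(list(area_per_point = area_per_point,
                 section_period_um = section_period_um,
                 counts = as.numeric(counts)),
            class = "cavalieri_design")
}

#' Cavalieri volume estimate (mm^3)
#'
#' `V = sum(P) * (a/p) * d`, converted from um^3 to mm^3. An unbiased
#' estimator of the reference volume under systematic uniform random
#' sectioning.
#'
#' @param design a [cavalieri_design()].
#' @return volume in mm^3; zero total points gives 0 with a warning.
#' @export
cavalieri_volume <- function(design) {
  stopifnot(inherits(design, "cavalieri_design"))
  total <- sum(design$counts)
  if (total == 0) {
    warning("zero points counted: volume estimate 0 with no precision")
    return(0)
  }
  total * design$area_per_point * design$section_period_um * 1e-9
}

#' Optical fractionator sampling design
#'
#' Sampling fractions: `ssf` (sections), `asf` = frame area / grid-step area,
#' `tsf` = dissector height / section thickness. The dissector height is the
#' section thickness minus both guard zones.
#'
#' @param ssf section sampling fraction, in (0, 1].
#' @param frame_um counting frame c(width, height) (um).
#' @param grid_um sampling grid step c(x, y) (um).
#' @param thickness_um measured section thickness (um).
#' @param guard_um guard zone applied at top and bottom (um).
#' @param counts per-site (or per-section) counts of objects counted in the
#'   dissectors, sum Q-.
#' @return object of class `fractionator_design` with derived `asf`, `tsf`,
#'   `dissector_um`.
#' @export
fractionator_design <- function(ssf, frame_um = c(65, 35),
                                grid_um = c(400, 400), thickness_um = 18,
                                guard_um = 0.5, counts = numeric(0)) {
  h <- dissector_height(thickness_um, guard_um)
  asf <- prod(frame_um) / prod(grid_um)
  tsf <- h / thickness_um
  for (f in c(ssf = ssf, asf = asf, tsf = tsf)) {
    if (f <= 0 || f > 1) {
      stop("design error: sampling fractions must lie in (0, 1]")
    }
  }
  if (any(counts < 0)) stop("design error: counts must be >= 0")
  structure(list(ssf = ssf, asf = asf, tsf = tsf, frame_um = frame_um,
                 grid_um = grid_um, thickness_um = thickness_um,
                 guard_um = guard_um, dissector_um = h,
                 counts = as.numeric(counts)),
            class = "fractionator_design")
}

#' Optical dissector height
#'
#' Section thickness minus the top and bottom guard zones.
#'
#' @param thickness_um section thickness (um).
#' @param guard_um guard zone at each surface (um).
#' @return dissector height (um).
#' @export
dissector_height <- function(thickness_um, guard_um) {
  if (thickness_um <= 2 * guard_um) {
    stop("design error: thickness must exceed twice the guard zone")
  }
  thickness_um - 2 * guard_um
}

#' Optical fractionator estimate of total object number
#'
#' `N = sum(Q-) * (1/ssf) * (1/asf) * (1/tsf)`.
#'
#' @param design a [fractionator_design()].
#' @param counts optionally override the design's counts.
#' @return estimated total number.
#' @export
optical_fractionator <- function(design, counts = NULL) {
  stopifnot(inherits(design, "fractionator_design"))
  if (is.null(counts)) counts <- design$counts
  sum(counts) / (design$ssf * design$asf * design$tsf)
}

#' Gundersen-Jensen coefficient of error
#'
#' CE of a systematic-random point/particle count sequence, smoothness class
#' m = 1: noise variance = `sum(P)` (Poisson counting noise) and systematic
#' variance `max(0, (3(A - sum(P)) - 4B + C) / 240)` with
#' `A = sum(P_i^2)`, `B = sum(P_i P_(i+1))`, `C = sum(P_i P_(i+2))`;
#' `CE = sqrt(noise + systematic) / sum(P)`.
#'
#' @param counts per-section counts, length >= 3.
#' @return list: `ce`, `noise_var`, `systematic_var`.
#' @export
gundersen_ce <- function(counts) {
  if (length(counts) < 3) {
    stop("insufficient sections: Gundersen CE needs >= 3")
  }
  p <- as.numeric(counts)
  tot <- sum(p)
  n <- length(p)
  A <- sum(p^2)
  B <- sum(p[-n] * p[-1])
  C <- sum(p[seq_len(n - 2)] * p[-(1:2)])
  sys_var <- max(0, (3 * (A - tot) - 4 * B + C) / 240)
  list(ce = sqrt(tot + sys_var) / tot, noise_var = tot,
       systematic_var = sys_var)
}

## --- synthetic sampling helpers (validation of unbiasedness) ---------------

#' Sample a Cavalieri point count from an analytic ellipsoid
#'
#' Simulates systematic uniform random sectioning plus a square point grid on
#' each section, counting grid points falling inside the ellipse cross
#' section; the independent route to validating [cavalieri_volume()] against
#' the analytic `4/3 pi a b c`.
#'
#' @param semi_um ellipsoid semi-axes (um), z last.
#' @param grid_step_um point-grid spacing (um); a/p = grid_step^2.
#' @param section_period_um section period (um).
#' @param offset_frac 3-vector of grid/section phase offsets in \[0, 1).
#' @return a [cavalieri_design()] with one count per section.
#' @export
cavalieri_sample_ellipsoid <- function(semi_um, grid_step_um,
                                       section_period_um,
                                       offset_frac = c(0, 0, 0)) {
  a <- semi_um[1]; b <- semi_um[2]; c_ <- semi_um[3]
  z0 <- (offset_frac[3] - 0.5) * section_period_um
  zs <- seq(z0 - ceiling(2 * c_ / section_period_um) * section_period_um,
            c_ + section_period_um, by = section_period_um)
  zs <- zs[abs(zs) < c_]
  counts <- vapply(zs, function(z) {
    sc <- sqrt(1 - (z / c_)^2)
    ae <- a * sc; be <- b * sc
    xs <- grid_points(ae, grid_step_um, offset_frac[1])
    ys <- grid_points(be, grid_step_um, offset_frac[2])
    if (!length(xs) || !length(ys)) return(0)
    sum(outer((xs / ae)^2, (ys / be)^2, `+`) <= 1)
  }, numeric(1))
  cavalieri_design(grid_step_um^2, section_period_um, counts)
}

grid_points <- function(half_extent, step, frac) {
  x0 <- (frac - 0.5) * step
  k <- ceiling((half_extent + step) / step)
  xs <- x0 + step * seq(-k, k)
  xs[abs(xs) <= half_extent]
}

#' Sample fractionator counts from planted particles
#'
#' Applies the fractionator design to a set of particle positions in a slab:
#' systematic section sampling, a systematic x-y grid of counting frames per
#' sampled section, and an optical dissector excluding the guard zones. Each
#' particle is counted by its unique point using half-open frame intervals
#' (the unbiased counting-frame rule for point-like particles).
#'
#' @param xyz_um matrix of particle coordinates (x, y, z in um), z within the
#'   tissue slab.
#' @param slab_um c(x, y, z) extents of the tissue block (um).
#' @param design a [fractionator_design()]; `ssf` is interpreted as 1/k with
#'   integer k sections period.
#' @param offset_frac 3-vector of sampling phase offsets in \[0, 1).
#' @return the design with `counts` filled in (one entry per sampled
#'   section).
#' @export
fractionator_sample <- function(xyz_um, slab_um, design,
                                offset_frac = c(0, 0, 0)) {
  stopifnot(inherits(design, "fractionator_design"))
  period <- design$thickness_um / design$ssf
  n_sections <- floor(slab_um[3] / design$thickness_um)
  first <- 1 + floor(offset_frac[3] * round(1 / design$ssf))
  sampled <- seq(first, n_sections, by = round(1 / design$ssf))
  counts <- vapply(sampled, function(si) {
    z_lo <- (si - 1) * design$thickness_um + design$guard_um
    z_hi <- si * design$thickness_um - design$guard_um
    inz <- xyz_um[, 3] >= z_lo & xyz_um[, 3] < z_hi
    if (!any(inz)) return(0)
    x <- xyz_um[inz, 1]; y <- xyz_um[inz, 2]
    ## frame occupies [off, off + frame) within each grid cell
    fx <- (x - offset_frac[1] * design$grid_um[1]) %% design$grid_um[1]
    fy <- (y - offset_frac[2] * design$grid_um[2]) %% design$grid_um[2]
    sum(fx < design$frame_um[1] & fy < design$frame_um[2])
  }, numeric(1))
  fractionator_design(design$ssf, design$frame_um, design$grid_um,
                      design$thickness_um, design$guard_um, counts)
}
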