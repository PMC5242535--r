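## Threshold-based immunoreactivity quantification (two darkness levels:
## dense nuclear inclusions vs total aggregated staining) and cortical
## thickness measurement on section images.
##
## Scale convention: images are on a 0-255 transmitted-light scale where
## stain-dark pixels have LOW values (0 = no transmission / darkest stain,
## 255 = full transmission / unstained). Under this reading the standard
## two-level thresholds - nuclear 90, total 130 - are nested as required:
## dense nuclear pixels (darkest, lowest values) satisfy value <= 90, all
## aggregated staining satisfies value <= 130, and the nuclear mask is a
## subset of the total mask. The `orientation` flag preserves the opposite
## (darkness-value) reading, under which these particular thresholds break
## the containment and raise an error.

#' Threshold pair for two-level inclusion quantification
#'
#' @param nuclear threshold for dense nuclear inclusions (default 90 on the
#'   0-255 scale).
#' @param total threshold for total aggregated staining (default 130).
#' @param orientation `"dark-low"` (default; stained pixels have low values:
#'   stained = value <= threshold) or `"dark-high"` (darkness-value reading:
#'   stained = value >= threshold).
#' @return object of class `threshold_pair`.
#' @details [two_level_quantification()] verifies on every image that the
#' nuclear mask is contained in the total mask and raises an orientation
#' error otherwise.
#' @export
threshold_pair <- function(nuclear = 90, total = 130,
                           orientation = c("dark-low", "dark-high")) {
  orientation <- match.arg(orientation)
  stopifnot(nuclear >= 0, nuclear <= 255, total >= 0, total <= 255)
  structure(list(nuclear = nuclear, total = total,
                 orientation = orientation),
            class = "threshold_pair")
}

section_pixels <- function(img) {
  px <- if (inherits(img, "section_image")) img$pixels else img
  if (length(px) == 0) stop("validation error: empty image")
  if (min(px) < 0 || max(px) > 255) {
    stop("image must be on the 0-255 darkness scale")
  }
  px
}

#' Immunoreactive area fraction of a field of view
#'
#' Percentage of pixels passing the stain threshold on the stain-dark side.
#'
#' @param img a `section_image` or numeric matrix on the 0-255 scale.
#' @param threshold stain threshold.
#' @param orientation see [threshold_pair()].
#' @return percent of the field of view (0-100).
#' @export
immunoreactive_area <- function(img, threshold,
                                orientation = c("dark-low", "dark-high")) {
  orientation <- match.arg(orientation)
  px <- section_pixels(img)
  hit <- if (orientation == "dark-low") px <= threshold else px >= threshold
  100 * sum(hit) / length(px)
}

#' Two-level inclusion quantification
#'
#' Nuclear (dense) and total (nuclear + diffuse) immunoreactive area
#' percentages per field of view. The nuclear mask must be contained in the
#' total mask; an orientation that breaks this containment on the given image
#' raises an error.
#'
#' @param img a `section_image` or matrix.
#' @param pair a [threshold_pair()].
#' @return list: `nuclear_pct`, `total_pct`.
#' @export
two_level_quantification <- function(img, pair = threshold_pair()) {
  stopifnot(inherits(pair, "threshold_pair"))
  px <- section_pixels(img)
  if (pair$orientation == "dark-low") {
    nuc <- px <= pair$nuclear
    tot <- px <= pair$total
  } else {
    nuc <- px >= pair$nuclear
    tot <- px >= pair$total
  }
  if (any(nuc & !tot)) {
    stop("orientation error: nuclear mask not contained in total mask")
  }
  list(nuclear_pct = 100 * sum(nuc) / length(px),
       total_pct = 100 * sum(tot) / length(px))
}

#' Tile-wise immunoreactive area
#'
#' Splits the section into equal non-overlapping tiles (fields of view) and
#' reports the per-tile percentage; the mean over equal tiles equals the
#' whole-image percentage.
#'
#' @param img matrix or `section_image`.
#' @param tiles c(nx, ny) tile counts; image dimensions must be divisible.
#' @param threshold stain threshold.
#' @param orientation see [threshold_pair()].
#' @return numeric matrix of per-tile percentages.
#' @export
immunoreactive_area_tiled <- function(img, tiles, threshold,
                                      orientation = c("dark-low",
                                                      "dark-high")) {
  orientation <- match.arg(orientation)
  px <- section_pixels(img)
  d <- dim(px)
  if (any(d %% tiles != 0)) stop("image not divisible into equal tiles")
  step <- d %/% tiles
  out <- matrix(NA_real_, tiles[1], tiles[2])
  for (i in seq_len(tiles[1])) {
    for (j in seq_len(tiles[2])) {
      blk <- px[(i - 1) * step[1] + seq_len(step[1]),
                (j - 1) * step[2] + seq_len(step[2])]
      out[i, j] <- immunoreactive_area(blk, threshold, orientation)
    }
  }
  out
}

#' Ruler for cortical thickness measurement
#'
#' Thickness is measured along vertical lines between an inner boundary (the
#' dorsal horn of the corpus callosum) and an outer (pial) boundary, both
#' given as polylines, and averaged over consecutive sections.
#'
#' @param n_lines number of vertical lines (default 10).
#' @param n_sections sections to average (default 3).
#' @return object of class `thickness_ruler`.
#' @export
thickness_ruler <- function(n_lines = 10, n_sections = 3) {
  stopifnot(n_lines >= 1, n_sections >= 1)
  structure(list(n_lines = n_lines, n_sections = n_sections),
            class = "thickness_ruler")
}

polyline_y_at <- function(boundary, x) {
  stats::approx(boundary$x_um, boundary$y_um, xout = x, rule = 1)$y
}

#' Cortical thickness from boundary polylines
#'
#' Drops `n_lines` equally spaced vertical lines across the outer (pial)
#' boundary's x-range and measures the vertical segment length to the inner
#' boundary; lines that fail to intersect both boundaries (e.g. beyond a
#' truncated inner polyline) are excluded with a warning. With a list of
#' per-section boundary pairs, the mean over sections is returned.
#'
#' @param sections either a list with elements `inner` and `outer` (each a
#'   data.frame with `x_um`, `y_um`), or a list of such per-section lists.
#' @param ruler a [thickness_ruler()].
#' @return list: `thickness_um` (grand mean), `per_line_um` (matrix sections
#'   x lines), `n_excluded`.
#' @export
cortical_thickness <- function(sections, ruler = thickness_ruler()) {
  stopifnot(inherits(ruler, "thickness_ruler"))
  if (!is.null(sections$inner)) sections <- list(sections)
  per <- matrix(NA_real_, length(sections), ruler$n_lines)
  excluded <- 0L
  for (si in seq_along(sections)) {
    sec <- sections[[si]]
    x_lo <- min(sec$outer$x_um)
    x_hi <- max(sec$outer$x_um)
    if (x_hi <= x_lo) stop("outer boundary has no x-extent")
    xs <- seq(x_lo, x_hi, length.out = ruler$n_lines)
    yi <- polyline_y_at(sec$inner, xs)
    yo <- polyline_y_at(sec$outer, xs)
    len <- abs(yo - yi)
    bad <- !is.finite(len)
    if (any(bad)) {
      warning(sum(bad), " line(s) failed to intersect both boundaries; ",
              "excluded")
      excluded <- excluded + sum(bad)
    }
    per[si, ] <- ifelse(bad, NA_real_, len)
  }
  list(thickness_um = mean(per, na.rm = TRUE), per_line_um = per,
       n_excluded = excluded)
}
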