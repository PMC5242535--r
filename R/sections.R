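## Synthetic histology sections: NeuN-like neuron staining and two-class
## (dense nuclear vs diffuse) inclusion staining with exact ground truth.
##
## Ground truth stores stain DARKNESS per class (0 = unstained, 255 =
## darkest; the nuclear class is strictly darker than the diffuse class).
## Rendered images are on the transmitted-light value scale used by the
## quantification layer: pixel value = 255 - darkness, so stained objects
## are LOW values on a bright (high-value) background.

#' Ground truth for a stack of synthetic histology sections
#'
#' Places neurons (3-D: in-plane position plus depth within the section) and
#' inclusion blobs of two darkness classes on each section. Placement is
#' uniform within the field; `non_overlapping` enforces disjoint neuron discs
#' by rejection sampling.
#'
#' @param n_sections number of sections.
#' @param thickness_um section thickness (um).
#' @param field_um field (section) size, c(width, height), um.
#' @param neurons_per_section expected neurons per section (integer) or a
#'   vector of length `n_sections`.
#' @param nuclear_per_section,diffuse_per_section inclusion blob counts per
#'   section for the dense-nuclear and diffuse classes.
#' @param neuron_radius_um,inclusion_radius_um object radii (um).
#' @param neuron_darkness,nuclear_darkness,diffuse_darkness,background stain
#'   darkness levels on the 0-255 scale; nuclear must exceed diffuse. The
#'   defaults place rendered values (255 - darkness) so that the standard
#'   two-level thresholds (90 nuclear / 130 total) separate the classes.
#' @param non_overlapping logical; enforce non-overlapping neuron discs.
#' @param seed integer seed for placement.
#' @return object of class `histo_truth` with per-section data frames
#'   `neurons` (x_um, y_um, z_um) and `inclusions` (x_um, y_um, class).
#' @export
histo_ground_truth <- function(n_sections = 4, thickness_um = 18,
                               field_um = c(400, 400),
                               neurons_per_section = 100,
                               nuclear_per_section = 30,
                               diffuse_per_section = 30,
                               neuron_radius_um = 5,
                               inclusion_radius_um = 3,
                               neuron_darkness = 100,
                               nuclear_darkness = 215,
                               diffuse_darkness = 145,
                               background = 15,
                               non_overlapping = TRUE,
                               seed = 1L) {
  if (nuclear_darkness <= diffuse_darkness) {
    stop("nuclear-class darkness must strictly exceed diffuse-class darkness")
  }
  if (any(c(neurons_per_section, nuclear_per_section,
            diffuse_per_section) < 0)) {
    stop("object counts must be >= 0")
  }
  neurons_per_section <- rep(neurons_per_section, length.out = n_sections)
  set.seed(as.integer(seed))
  place <- function(n, radius, avoid = NULL) {
    if (n == 0) {
      return(data.frame(x_um = numeric(0), y_um = numeric(0)))
    }
    pts <- matrix(NA_real_, n, 2)
    k <- 0; tries <- 0
    while (k < n) {
      tries <- tries + 1
      if (tries > 200 * n) stop("placement error: field too crowded")
      p <- c(stats::runif(1, radius, field_um[1] - radius),
             stats::runif(1, radius, field_um[2] - radius))
      if (non_overlapping && k > 0) {
        dd <- sqrt((pts[seq_len(k), 1] - p[1])^2 +
                   (pts[seq_len(k), 2] - p[2])^2)
        if (any(dd < 2 * radius + 4)) next
      }
      k <- k + 1
      pts[k, ] <- p
    }
    data.frame(x_um = pts[, 1], y_um = pts[, 2])
  }
  sections <- lapply(seq_len(n_sections), function(si) {
    nn <- neurons_per_section[si]
    neu <- place(nn, neuron_radius_um)
    neu$z_um <- if (nn > 0) stats::runif(nn, 0, thickness_um) else numeric(0)
    nuc <- place(nuclear_per_section, inclusion_radius_um)
    dif <- place(diffuse_per_section, inclusion_radius_um)
    inc <- rbind(
      if (nrow(nuc)) cbind(nuc, class = "nuclear"),
      if (nrow(dif)) cbind(dif, class = "diffuse")
    )
    if (is.null(inc)) {
      inc <- data.frame(x_um = numeric(0), y_um = numeric(0),
                        class = character(0))
    }
    list(neurons = neu, inclusions = inc)
  })
  structure(list(n_sections = n_sections, thickness_um = thickness_um,
                 field_um = field_um, sections = sections,
                 neuron_radius_um = neuron_radius_um,
                 inclusion_radius_um = inclusion_radius_um,
                 levels = c(neuron = neuron_darkness,
                            nuclear = nuclear_darkness,
                            diffuse = diffuse_darkness,
                            background = background)),
            class = "histo_truth")
}

render_discs <- function(img, px, py, xs, ys, radius_px, level) {
  if (length(xs) == 0) return(img)
  for (i in seq_along(xs)) {
    xr <- which(abs(px - xs[i]) <= radius_px)
    yr <- which(abs(py - ys[i]) <= radius_px)
    if (!length(xr) || !length(yr)) next
    sub <- outer((px[xr] - xs[i])^2, (py[yr] - ys[i])^2, `+`) <= radius_px^2
    blk <- img[xr, yr, drop = FALSE]
    blk[sub] <- pmax(blk[sub], level)
    img[xr, yr] <- blk
  }
  img
}

#' Render section images from ground truth
#'
#' Each object is drawn as a filled disc at its configured darkness level
#' (taking the maximum darkness where classes touch); the composited darkness
#' image is then converted to the transmitted-light value scale
#' (`255 - darkness`). The returned images carry their generating
#' annotations, which exactly equal the rendered objects.
#'
#' @param truth a [histo_ground_truth()].
#' @param pixel_size_um pixel size (um); object radii must be >= 1 pixel.
#' @param noise_sd darkness noise added to the background (Gaussian, clipped
#'   to the 0-255 range); 0 for noiseless sections.
#' @param seed integer seed for the background noise.
#' @return list of `section_image` objects: `pixels` (matrix, 0-255
#'   transmitted-light values, stain = low), `pixel_size_um`, `truth` (the
#'   section's annotations), `levels` (the generating darkness levels).
#' @export
generate_sections <- function(truth, pixel_size_um = 2, noise_sd = 0,
                              seed = 1L) {
  stopifnot(inherits(truth, "histo_truth"))
  if (truth$neuron_radius_um < pixel_size_um ||
      truth$inclusion_radius_um < pixel_size_um) {
    stop("object radii must be at least one pixel")
  }
  nx <- ceiling(truth$field_um[1] / pixel_size_um)
  ny <- ceiling(truth$field_um[2] / pixel_size_um)
  px <- (seq_len(nx) - 0.5) * pixel_size_um
  py <- (seq_len(ny) - 0.5) * pixel_size_um
  lv <- truth$levels
  set.seed(as.integer(seed))
  lapply(seq_len(truth$n_sections), function(si) {
    sec <- truth$sections[[si]]
    if (nrow(sec$neurons) &&
        (any(sec$neurons$x_um < 0) || any(sec$neurons$x_um > truth$field_um[1]) ||
         any(sec$neurons$y_um < 0) || any(sec$neurons$y_um > truth$field_um[2]))) {
      stop("placement error: object outside image bounds")
    }
    img <- matrix(lv[["background"]], nx, ny)
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(nx * ny, 0, noise_sd), nx, ny)
    }
    img <- render_discs(img, px, py, sec$neurons$x_um, sec$neurons$y_um,
                        truth$neuron_radius_um, lv[["neuron"]])
    inc <- sec$inclusions
    dif <- inc[inc$class == "diffuse", ]
    nuc <- inc[inc$class == "nuclear", ]
    img <- render_discs(img, px, py, dif$x_um, dif$y_um,
                        truth$inclusion_radius_um, lv[["diffuse"]])
    img <- render_discs(img, px, py, nuc$x_um, nuc$y_um,
                        truth$inclusion_radius_um, lv[["nuclear"]])
    img <- 255 - pmin(pmax(img, 0), 255)  # to transmitted-light values
    structure(list(pixels = img, pixel_size_um = pixel_size_um, truth = sec,
                   levels = lv),
              class = "section_image")
  })
}
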