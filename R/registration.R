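## Linear and viscous-fluid image registration with Jacobian-determinant
## maps. All operators are dimension-generic: 2-D matrices are first-class
## (fast tests, methodological checks), 3-D arrays are the production case.
##
## Conventions: voxel coordinates are 1-based; transforms act about the image
## centre; displacement fields are stored in voxel units on the fixed-image
## grid, mapping fixed coordinates x to moving coordinates x + u(x)
## (pull-back / resampling convention).

#' Rigid or rigid-plus-scale linear transform
#'
#' `dof = 6` is rigid (rotation + translation; in 2-D this collapses to 3
#' parameters), `dof = 9` adds per-axis scales (2-D: 5 parameters). With
#' `uniform_scale = TRUE` the scale block collapses to a single factor
#' (7 dof in 3-D).
#'
#' @param angles rotation angles in radians (3-D: about x, y, z; 2-D: one).
#' @param translation translation in voxels.
#' @param scales per-axis scale factors (all 1 for rigid).
#' @param dof 6 or 9.
#' @return object of class `linear_transform`.
#' @export
linear_transform <- function(angles, translation, scales = NULL, dof = 6) {
  nd <- length(translation)
  if (is.null(scales)) scales <- rep(1, nd)
  stopifnot(all(scales > 0), nd %in% 2:3,
            length(angles) == if (nd == 3) 3 else 1)
  structure(list(angles = angles, translation = translation,
                 scales = scales, dof = dof, nd = nd),
            class = "linear_transform")
}

rotation_matrix <- function(angles, nd) {
  if (nd == 2) {
    a <- angles[1]
    matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  } else {
    cx <- cos(angles[1]); sx <- sin(angles[1])
    cy <- cos(angles[2]); sy <- sin(angles[2])
    cz <- cos(angles[3]); sz <- sin(angles[3])
    rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    rz %*% ry %*% rx
  }
}

#' Linear part (matrix) of a transform
#' @param tf a `linear_transform`.
#' @return the `nd x nd` matrix `R %*% diag(scales)`.
#' @export
transform_matrix <- function(tf) {
  rotation_matrix(tf$angles, tf$nd) %*% diag(tf$scales, tf$nd)
}

## map fixed-grid coordinates (rows) through the transform, about centre
transform_coords <- function(tf, coords, dims) {
  ctr <- (dims + 1) / 2
  a <- transform_matrix(tf)
  xc <- sweep(coords, 2, ctr, `-`)
  sweep(xc %*% t(a), 2, ctr + tf$translation, `+`)
}

#' Resample an image through a linear transform
#'
#' Samples the moving image at the transformed fixed-grid coordinates
#' (multilinear interpolation, edge clamped).
#'
#' @param img numeric array (2-D or 3-D).
#' @param tf a `linear_transform`.
#' @return resampled array, same shape.
#' @export
apply_linear <- function(img, tf) {
  d <- dim(img)
  g <- index_grid(d)
  array(interp_linear(img, transform_coords(tf, g, d)), d)
}

#' Invert a linear transform
#' @param tf a `linear_transform`.
#' @return the inverse `linear_transform` (same dof family).
#' @export
invert_linear <- function(tf) {
  ## y = A (x - c) + c + t  =>  x = A^-1 (y - c - t) + c
  ## inverse in the same parameterisation: angles negated in reverse order is
  ## only exact for single-axis rotations, so recover parameters from A^-1
  a_inv <- solve(transform_matrix(tf))
  s <- apply(a_inv, 2, function(col) sqrt(sum(col^2)))
  r <- a_inv %*% diag(1 / s, tf$nd)
  angles <- matrix_to_angles(r, tf$nd)
  t_new <- as.vector(-a_inv %*% tf$translation)
  linear_transform(angles, t_new, s, dof = tf$dof)
}

matrix_to_angles <- function(r, nd) {
  if (nd == 2) {
    atan2(r[2, 1], r[1, 1])
  } else {
    ## inverse of rz %*% ry %*% rx
    ry <- asin(-r[3, 1])
    rx <- atan2(r[3, 2], r[3, 3])
    rz <- atan2(r[2, 1], r[1, 1])
    c(rx, ry, rz)
  }
}

pack_par <- function(tf, with_scales, uniform_scale) {
  p <- c(tf$angles, tf$translation)
  if (with_scales) {
    p <- c(p, if (uniform_scale) log(tf$scales[1]) else log(tf$scales))
  }
  p
}

unpack_par <- function(p, nd, with_scales, uniform_scale, dof) {
  na <- if (nd == 3) 3 else 1
  angles <- p[seq_len(na)]
  trans <- p[na + seq_len(nd)]
  scales <- rep(1, nd)
  if (with_scales) {
    rest <- p[-(seq_len(na + nd))]
    scales <- if (uniform_scale) rep(exp(rest[1]), nd) else exp(rest)
  }
  linear_transform(angles, trans, scales, dof = dof)
}

#' Linear (6 or 9 dof) intensity-based registration
#'
#' Minimises the mean squared intensity difference between the fixed image
#' and the resampled moving image over the rigid (`dof = 6`) or
#' rigid-plus-scales (`dof = 9`) family, with a multi-resolution pyramid and
#' Nelder-Mead refinement. Images are z-score normalised before matching.
#'
#' @param moving,fixed numeric arrays of equal dimensionality.
#' @param dof 6 (rigid) or 9 (rigid + per-axis scales).
#' @param uniform_scale collapse the scale block to a single factor.
#' @param init optional initial `linear_transform`.
#' @param maxit optimiser iteration budget per pyramid level.
#' @return list: `transform` (a `linear_transform`), `resampled` (moving image
#'   resampled into the fixed frame), `ssd` (final mean squared difference),
#'   `converged`.
#' @export
register_linear <- function(moving, fixed, dof = 6, uniform_scale = FALSE,
                            init = NULL, maxit = 400) {
  stopifnot(identical(dim(moving) > 0, dim(fixed) > 0))
  nd <- length(dim(fixed))
  stopifnot(nd %in% 2:3, dof %in% c(6, 9))
  with_scales <- dof == 9
  mv <- scale_intensity(moving, "quantile")
  fx <- scale_intensity(fixed, "quantile")

  ## pyramid (coarse to fine)
  pyr_m <- list(mv); pyr_f <- list(fx)
  while (min(dim(pyr_m[[1]])) >= 32 && length(pyr_m) < 3) {
    pyr_m <- c(list(downsample2(gaussian_smooth(pyr_m[[1]], 1))), pyr_m)
    pyr_f <- c(list(downsample2(gaussian_smooth(pyr_f[[1]], 1))), pyr_f)
  }

  na <- if (nd == 3) 3 else 1
  tf <- if (is.null(init)) {
    linear_transform(rep(0, na), rep(0, nd), rep(1, nd), dof = dof)
  } else init
  conv <- TRUE
  for (li in seq_along(pyr_m)) {
    m_l <- pyr_m[[li]]; f_l <- pyr_f[[li]]
    d_l <- dim(f_l)
    g <- index_grid(d_l)
    fvec <- as.vector(f_l)
    obj <- function(p) {
      tfp <- unpack_par(p, nd, with_scales, uniform_scale, dof)
      smp <- interp_linear(m_l, transform_coords(tfp, g, d_l))
      mean((smp - fvec)^2)
    }
    p0 <- pack_par(tf, with_scales, uniform_scale)
    psc <- c(rep(0.05, na), rep(max(d_l) / 20, nd),
             if (with_scales) rep(0.05, if (uniform_scale) 1 else nd))
    fit <- stats::optim(p0, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10,
                                       parscale = psc))
    ## polish: restart once from the optimum (Nelder-Mead simplex renewal)
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12,
                                       parscale = psc / 10))
    conv <- conv && fit$convergence == 0
    tf <- unpack_par(fit$par, nd, with_scales, uniform_scale, dof)
    if (li < length(pyr_m)) {
      tf$translation <- tf$translation * dim(pyr_f[[li + 1]]) / d_l
    }
  }
  list(transform = tf, resampled = apply_linear(moving, tf),
       ssd = fit$value, converged = conv)
}

#' Iterated register-and-average population template
#'
#' Registers every image to the current template, averages the resampled
#' images, and re-centres the template by the inverse of the mean transform
#' parameters so the template does not drift toward any input.
#'
#' @param images list of >= 2 numeric arrays of identical shape.
#' @param dof 6 or 9, passed to [register_linear()].
#' @param iterations register-average cycles.
#' @return list: `template` (numeric array), `transforms` (final per-image
#'   transforms).
#' @export
build_population_mean <- function(images, dof = 6, iterations = 2) {
  if (length(images) < 2) {
    stop("configuration error: need at least 2 images for a population mean")
  }
  d <- dim(images[[1]])
  nd <- length(d)
  template <- Reduce(`+`, images) / length(images)
  tfs <- NULL
  for (it in seq_len(iterations)) {
    regs <- lapply(images, register_linear, fixed = template, dof = dof)
    template <- Reduce(`+`, lapply(regs, `[[`, "resampled")) / length(images)
    tfs <- lapply(regs, `[[`, "transform")
    ## drift control: undo the average transform
    mean_angles <- Reduce(`+`, lapply(tfs, `[[`, "angles")) / length(tfs)
    mean_trans <- Reduce(`+`, lapply(tfs, `[[`, "translation")) / length(tfs)
    mean_logsc <- Reduce(`+`, lapply(tfs, function(t) log(t$scales))) /
      length(tfs)
    mean_tf <- linear_transform(mean_angles, mean_trans, exp(mean_logsc),
                                dof = dof)
    template <- apply_linear(template, mean_tf)
  }
  list(template = template, transforms = tfs)
}

#' Solver parameters for viscous-fluid registration
#'
#' @param sigma_fluid Gaussian width (voxels) regularising the velocity
#'   field - the fluid constant. Larger values give smoother, stiffer flows.
#' @param max_step largest displacement update per iteration (voxels).
#' @param regrid_jmin regrid (re-compose and reset the field) when the
#'   minimum Jacobian of the current increment falls below this; in (0, 1).
#' @param max_iter iteration budget per pyramid level.
#' @param tol convergence tolerance on the relative SSD improvement.
#' @param n_levels pyramid levels (1 = single resolution).
#' @return object of class `fluid_params`.
#' @export
fluid_params <- function(sigma_fluid = 2.5, max_step = 0.4,
                         regrid_jmin = 0.5, max_iter = 300, tol = 1e-5,
                         n_levels = 2) {
  stopifnot(regrid_jmin > 0, regrid_jmin < 1, max_step > 0, sigma_fluid > 0)
  structure(list(sigma_fluid = sigma_fluid, max_step = max_step,
                 regrid_jmin = regrid_jmin, max_iter = max_iter, tol = tol,
                 n_levels = n_levels),
            class = "fluid_params")
}

## displacement-field helpers -------------------------------------------------

field_array <- function(d, nd) array(0, c(d, nd))

field_component <- function(u, k) {
  d <- dim(u)
  nd <- length(d) - 1
  if (nd == 2) u[, , k] else u[, , , k]
}

`field_component<-` <- function(u, k, value) {
  d <- dim(u)
  nd <- length(d) - 1
  if (nd == 2) u[, , k] <- value else u[, , , k] <- value
  u
}

#' Warp an image through a displacement field
#'
#' Samples the image at `x + u(x)` with multilinear interpolation.
#'
#' @param img numeric array.
#' @param field a `displacement_field` or raw field array (dims x nd).
#' @return warped array.
#' @export
warp_image <- function(img, field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  d <- dim(img)
  nd <- length(d)
  g <- index_grid(d)
  coords <- g + matrix(u, ncol = nd)
  array(interp_linear(img, coords), d)
}

## compose two fields: result(x) = b(x) + a(x + b(x))
## (warping by the result equals warping by a, then by b)
compose_fields <- function(a, b) {
  d <- dim(a)
  nd <- length(d) - 1
  dims <- d[seq_len(nd)]
  g <- index_grid(dims)
  coords <- g + matrix(b, ncol = nd)
  out <- b
  for (k in seq_len(nd)) {
    ak <- interp_linear(field_component(a, k), coords)
    field_component(out, k) <- field_component(b, k) + array(ak, dims)
  }
  out
}

upsample_field <- function(u, new_dims) {
  d <- dim(u)
  nd <- length(d) - 1
  old_dims <- d[seq_len(nd)]
  g <- index_grid(new_dims)
  ## fine index -> coarse index mapping for a factor-2 pyramid
  coords <- sweep(g + 1, 2, rep(2, nd), `/`)
  ratio <- new_dims / old_dims
  out <- field_array(new_dims, nd)
  for (k in seq_len(nd)) {
    v <- interp_linear(field_component(u, k), coords) * ratio[k]
    field_component(out, k) <- array(v, new_dims)
  }
  out
}

#' Jacobian determinant map of a displacement field
#'
#' `det(I + grad(u))` with central differences (one-sided at the boundary).
#' Identity fields give exactly 1 everywhere; values > 1 are local expansion,
#' < 1 contraction.
#'
#' @param field a `displacement_field` or raw field array.
#' @return numeric array of determinants.
#' @export
jacobian_determinant <- function(field) {
  u <- if (inherits(field, "displacement_field")) field$u else field
  if (!all(is.finite(u))) stop("validation error: field contains non-finite values")
  d <- dim(u)
  nd <- length(d) - 1
  dims <- d[seq_len(nd)]
  gr <- vector("list", nd)  # gr[[i]][[j]] = d u_i / d x_j
  for (i in seq_len(nd)) gr[[i]] <- array_gradient(field_component(u, i))
  if (nd == 2) {
    (1 + gr[[1]][[1]]) * (1 + gr[[2]][[2]]) - gr[[1]][[2]] * gr[[2]][[1]]
  } else {
    a11 <- 1 + gr[[1]][[1]]; a12 <- gr[[1]][[2]]; a13 <- gr[[1]][[3]]
    a21 <- gr[[2]][[1]]; a22 <- 1 + gr[[2]][[2]]; a23 <- gr[[2]][[3]]
    a31 <- gr[[3]][[1]]; a32 <- gr[[3]][[2]]; a33 <- 1 + gr[[3]][[3]]
    a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
      a13 * (a21 * a32 - a22 * a31)
  }
}

#' Viscous-fluid non-rigid registration
#'
#' Greedy compositional flow approximating fluid registration. At each
#' iteration the gradient-normalised force
#' `(fixed - warped) * grad(warped) / (|grad|^2 + diff^2)` (gated to zero
#' below a noise floor) is Gaussian-regularised - the fluid constant acts on
#' the velocity, not the displacement, permitting large diffeomorphic
#' deformations - scaled so the largest update is `max_step` voxels, and
#' composed into the running field. The warped image is always resampled from
#' the original moving image through the composed total field, so repeated
#' regridding never blurs it. When the active increment's minimum Jacobian
#' drops below `regrid_jmin` the increment is folded into the base field and
#' reset (regridding), preserving invertibility under large deformations.
#' SSD decreases monotonically over accepted steps (rejected steps are
#' backtracked); iteration stops when the relative improvement stays below
#' `tol` for several consecutive accepted steps.
#'
#' @param moving,fixed numeric arrays (2-D or 3-D), pre-aligned linearly.
#' @param params a [fluid_params()].
#' @param normalise intensity scaling before matching: `"quantile"` (default;
#'   maps the 1st/99th percentiles to 0/1 so tissue-class levels correspond
#'   even when class proportions differ between the images), `"zscore"`, or
#'   `"none"`.
#' @return a `displacement_field`: list with field array `u` (voxel units, on
#'   the fixed grid; warping samples the moving image at `x + u(x)`),
#'   `jacobian` (of the total field), and a convergence `report`
#'   (iterations, SSD trace, regrid count, status).
#' @export
register_fluid <- function(moving, fixed, params = fluid_params(),
                           normalise = "quantile") {
  stopifnot(identical(length(dim(moving)), length(dim(fixed))))
  nd <- length(dim(fixed))
  mv <- scale_intensity(moving, normalise)
  fx <- scale_intensity(fixed, normalise)

  pyr_m <- list(mv); pyr_f <- list(fx)
  while (length(pyr_m) < params$n_levels && min(dim(pyr_m[[1]])) >= 24) {
    pyr_m <- c(list(downsample2(gaussian_smooth(pyr_m[[1]], 1))), pyr_m)
    pyr_f <- c(list(downsample2(gaussian_smooth(pyr_f[[1]], 1))), pyr_f)
  }

  patience <- 5L
  noise_floor <- 0.02 * max(abs(fx))
  u_base <- NULL
  total_regrids <- 0L
  trace <- numeric(0)
  status <- "converged"
  for (li in seq_along(pyr_m)) {
    m_l <- pyr_m[[li]]; f_l <- pyr_f[[li]]
    d_l <- dim(f_l)
    u_base <- if (is.null(u_base)) field_array(d_l, nd) else
      upsample_field(u_base, d_l)
    u <- field_array(d_l, nd)
    total_field <- function(base, inc) {
      if (all(base == 0)) inc else compose_fields(base, inc)
    }
    warped <- warp_image(m_l, total_field(u_base, u))
    ssd <- mean((warped - f_l)^2)
    step_fac <- 1
    it <- 0
    stall <- 0L
    while (it < params$max_iter) {
      it <- it + 1
      g <- array_gradient(warped)
      diffimg <- f_l - warped
      gmag2 <- Reduce(`+`, lapply(g, function(x) x^2))
      denom <- gmag2 + diffimg^2
      live <- abs(diffimg) > noise_floor & gmag2 > 1e-4
      v <- field_array(d_l, nd)
      for (k in seq_len(nd)) {
        field_component(v, k) <- gaussian_smooth(
          ifelse(live, diffimg * g[[k]] / denom, 0), params$sigma_fluid)
      }
      vmax <- max(abs(v))
      if (vmax < 1e-12) break
      accepted <- FALSE
      for (bt in seq_len(6)) {
        alpha <- params$max_step * step_fac / vmax
        u_try <- compose_fields(u, alpha * v)
        warped_try <- warp_image(m_l, total_field(u_base, u_try))
        ssd_try <- mean((warped_try - f_l)^2)
        if (ssd_try < ssd) {
          accepted <- TRUE
          rel <- (ssd - ssd_try) / ssd
          u <- u_try; warped <- warped_try; ssd <- ssd_try
          step_fac <- min(step_fac * 1.2, 1)
          trace <- c(trace, ssd)
          if (min(jacobian_determinant(u)) < params$regrid_jmin) {
            u_base <- total_field(u_base, u)
            u <- field_array(d_l, nd)
            total_regrids <- total_regrids + 1L
          }
          stall <- if (rel < params$tol) stall + 1L else 0L
          break
        }
        step_fac <- step_fac / 2
      }
      if (!accepted) { status <- "stalled"; break }
      if (stall >= patience) break
    }
    u_base <- total_field(u_base, u)
  }
  structure(list(u = u_base, jacobian = jacobian_determinant(u_base),
                 report = list(iterations = length(trace), ssd_trace = trace,
                               regrids = total_regrids, status = status)),
            class = "displacement_field")
}
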