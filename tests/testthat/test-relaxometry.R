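test_that("echo summation is the voxel-wise sum and is linear", {
  a <- array(1, c(3, 3, 2, 8))
  expect_equal(sum_echoes(a), array(8, c(3, 3, 2)))

  set.seed(1)
  x <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  y <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  expect_equal(sum_echoes(x + y), sum_echoes(x) + sum_echoes(y))

  ## noiseless decay: summed signal equals the 8-term analytic sum
  lab <- uniform_label_volume()
  tm <- tissue_model(s0 = c(brain = 1000), t2 = c(brain = 40), noise_sd = 0)
  img <- render_multiecho(lab, tm, echo_train(), seed = 1)
  expected <- sum(1000 * exp(-echo_train() / 40))
  expect_equal(as.vector(sum_echoes(img))[1], expected)
})

test_that("mono-exponential fit is exact on noiseless data", {
  lab <- uniform_label_volume()
  for (t2_true in c(25, 40, 80, 300)) {
    tm <- tissue_model(s0 = c(brain = 500), t2 = c(brain = t2_true),
                       noise_sd = 0)
    img <- render_multiecho(lab, tm, echo_train(), seed = 1)
    fit <- fit_t2_map(img)
    expect_equal(as.vector(fit$t2), rep(t2_true, length(fit$t2)),
                 tolerance = 1e-10)
    expect_true(all(fit$valid))
  }
})

test_that("two-region phantom fits region-exact bimodal T2", {
  codes <- c(background = 0L, brain = 1L, cortex = 2L)
  labels <- array(1L, c(6, 6, 2)); labels[4:6, , ] <- 2L
  lab <- structure(list(labels = labels, spacing = c(1, 1, 1),
                        codes = codes), class = "label_volume")
  tm <- tissue_model(s0 = c(brain = 800, cortex = 800),
                     t2 = c(brain = 30, cortex = 80), noise_sd = 0)
  fit <- fit_t2_map(render_multiecho(lab, tm, echo_train(), 1))
  expect_equal(unique(round(fit$t2[labels == 1L], 8)), 30)
  expect_equal(unique(round(fit$t2[labels == 2L], 8)), 80)
})

test_that("noisy fits agree with a dense grid-search oracle", {
  set.seed(9)
  te <- echo_train()
  s0 <- 1000; t2 <- 45; sigma <- 10  # 1% of S0
  n_vox <- 200
  sig <- outer(rep(1, n_vox), s0 * exp(-te / t2)) +
    matrix(rnorm(n_vox * length(te), 0, sigma), n_vox)
  img <- array(NA_real_, c(n_vox, 1, 1, length(te)))
  img[, 1, 1, ] <- sig
  fit <- fit_t2_map(img, te, refine = TRUE)
  expect_lt(abs(median(fit$t2[fit$valid]) - t2), 1)

  ## grid-search oracle on the first few voxels: the refined solution must
  ## sit within half a grid step of the brute-force SSE minimiser
  grid_t2 <- seq(30, 60, by = 0.25)
  grid_s0 <- seq(800, 1200, by = 5)
  for (v in 1:5) {
    sse <- outer(grid_s0, grid_t2, function(s, t) {
      vapply(seq_along(s), function(i) {
        sum((sig[v, ] - s[i] * exp(-te / t[i]))^2)
      }, numeric(1))
    })
    best <- arrayInd(which.min(sse), dim(sse))
    t2_oracle <- grid_t2[best[2]]
    expect_lt(abs(fit$t2[v] - t2_oracle), 0.5)
  }
})

test_that("invalid voxels are flagged, never silently zeroed", {
  img <- array(1000, c(2, 2, 1, 8))
  img[1, 1, 1, ] <- c(-5, rep(1000, 7))        # non-positive first echo
  img[2, 1, 1, ] <- rep(1000, 8)               # zero decay -> T2 out of range
  img[, 2, 1, ] <- rep(1000 * exp(-echo_train() / 50), each = 2)
  fit <- fit_t2_map(img, echo_train())
  expect_false(fit$valid[1, 1, 1])
  expect_false(fit$valid[2, 1, 1])
  expect_warning(fit_t2_map(array(-1, c(1, 1, 1, 8)), echo_train()),
                 "empty fit")
})

test_that("ROI mean T2 averages valid voxels and reports exclusions", {
  lab <- uniform_label_volume(dims = c(4, 4, 2))
  mk_map <- function(t2_vals, valid) {
    structure(list(t2 = array(t2_vals, c(4, 4, 2)),
                   s0 = array(1, c(4, 4, 2)),
                   valid = array(valid, c(4, 4, 2))),
              class = "t2_map")
  }
  expect_equal(roi_mean_t2(mk_map(45, TRUE), lab, "brain")$mean_t2_ms, 45)

  half <- rep(c(30, 50), each = 16)
  expect_equal(roi_mean_t2(mk_map(half, TRUE), lab, "brain")$mean_t2_ms, 40)

  some_invalid <- mk_map(45, rep(c(TRUE, FALSE), 16))
  res <- roi_mean_t2(some_invalid, lab, "brain")
  expect_equal(res$n_excluded, 16)
  expect_error(roi_mean_t2(mk_map(45, TRUE), lab, "thalamus"), "not present")
})

test_that("muscle control T2 is recovered from a rendered phantom", {
  spec <- small_phantom_spec()
  lv <- generate_phantom(spec, 36, trajectory_config(), "WT", "male")
  tm <- tissue_model()  # default noise at SNR 5.4
  img <- render_multiecho(lv, tm, echo_train(), seed = 21)
  fit <- fit_t2_map(img, refine = TRUE)
  res <- roi_mean_t2(fit, lv, "muscle")
  expect_lt(abs(res$mean_t2_ms - tm$t2[["muscle"]]), 2.5)
})

test_that("ROI T2 is invariant under relabelling of other regions", {
  lab <- uniform_label_volume(dims = c(4, 4, 2))
  lab$labels[1:2, 1, 1] <- 7L  # carve out some muscle voxels
  map <- structure(list(t2 = array(seq_len(32), c(4, 4, 2)),
                        s0 = array(1, c(4, 4, 2)),
                        valid = array(TRUE, c(4, 4, 2))),
                   class = "t2_map")
  before <- roi_mean_t2(map, lab, "brain")$mean_t2_ms
  lab2 <- lab
  lab2$labels[lab2$labels == 7L] <- 2L  # rename muscle voxels to cortex
  expect_equal(roi_mean_t2(map, lab2, "brain")$mean_t2_ms, before)
})

test_that("planned geometry reproduces the printed protocol numbers", {
  invivo <- acquisition_protocol()
  g <- planned_geometry(invivo)
  expect_equal(g$resolution_um, c(156, 156))
  expect_equal(g$scan_time_min, 21)
  expect_equal(g$echo_times_ms, seq(10, 80, 10))

  exvivo <- acquisition_protocol(tr_ms = 3000, averages = 22,
                                 matrix_size = c(192, 192),
                                 fov_mm = c(19.2, 19.2), n_slices = 35)
  ge <- planned_geometry(exvivo)
  expect_equal(ge$resolution_um, c(100, 100))
  expect_equal(round(ge$scan_time_s / 3600, 1), 3.5)

  expect_error(acquisition_protocol(tr_ms = -1), "positive")
})
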