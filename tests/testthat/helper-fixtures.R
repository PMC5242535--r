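## Shared in-code fixtures for the test suite. Everything is generated
## programmatically; no binary data on disk.

## soft-edged disk image (2-D), value ~1 inside radius r
soft_disk <- function(r, n = 48, soft = 1.5, cx = 0, cy = 0) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  d <- sqrt((g$x - (n + 1) / 2 - cx)^2 + (g$y - (n + 1) / 2 - cy)^2)
  array(stats::plogis((r - d) / soft), c(n, n))
}

## smooth two-blob image with internal intensity structure (identifiable
## deformations for registration tests)
textured_blob <- function(n = 48) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  c1 <- (n + 1) / 2
  a <- exp(-(((g$x - c1) / 9)^2 + ((g$y - c1) / 13)^2)) *
    (1 + 0.35 * sin(g$x / 4) * cos(g$y / 5)) +
    0.5 * exp(-(((g$x - 18) / 5)^2 + ((g$y - 30) / 6)^2))
  array(a, c(n, n))
}

## smooth radial displacement field, amplitude amp voxels at radius sig
radial_field <- function(n, amp = 2.5, sig = 8) {
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  dx <- g$x - (n + 1) / 2
  dy <- g$y - (n + 1) / 2
  r <- sqrt(dx^2 + dy^2)
  f <- amp * exp(-r^2 / (2 * sig^2))
  u <- array(0, c(n, n, 2))
  u[, , 1] <- array(f * dx / pmax(r, 1e-9), c(n, n))
  u[, , 2] <- array(f * dy / pmax(r, 1e-9), c(n, n))
  u
}

## single-region label volume for relaxometry tests
uniform_label_volume <- function(dims = c(6, 6, 4), region = "brain",
                                 spacing = c(1, 1, 1)) {
  codes <- c(background = 0L, brain = 1L, cortex = 2L, muscle = 7L)
  structure(list(labels = array(codes[[region]], dims), spacing = spacing,
                 codes = codes),
            class = "label_volume")
}

## small phantom spec for fast 3-D tests (coarser grid, same anatomy)
small_phantom_spec <- function() {
  phantom_spec(dim = c(40L, 56L, 40L), spacing = c(0.26, 0.28, 0.8))
}

## quick cohort with no missingness/outliers for deterministic checks
clean_trajectory <- function(...) {
  trajectory_config(missingness = 0, outlier_rate = 0, ...)
}
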