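test_that("identical images register to the identity transform", {
  img <- textured_blob()
  r <- register_linear(img, img, dof = 6)
  expect_lt(max(abs(r$transform$angles)), 1e-3)
  expect_lt(max(abs(r$transform$translation)), 1e-3)
  r9 <- register_linear(img, img, dof = 9)
  expect_lt(max(abs(r9$transform$scales - 1)), 1e-3)
})

test_that("known rigid transforms are recovered within 0.5 deg / 0.1 voxel", {
  fx <- textured_blob()
  tf_true <- linear_transform(10 * pi / 180, c(0.5, 0.3))
  mv <- apply_linear(fx, tf_true)  # moving sampled through tf_true
  r <- register_linear(mv, fx, dof = 6)
  ## registering back recovers the inverse of the generating transform
  tf_inv <- invert_linear(tf_true)
  expect_lt(abs(r$transform$angles - tf_inv$angles) * 180 / pi, 0.5)
  expect_lt(max(abs(r$transform$translation - tf_inv$translation)), 0.1)
})

test_that("9 dof recovers a uniform scale that 6 dof cannot", {
  fx <- textured_blob()
  tf_scale <- linear_transform(0, c(0, 0), scales = c(1.1, 1.1), dof = 9)
  mv <- apply_linear(fx, tf_scale)
  r9 <- register_linear(mv, fx, dof = 9)
  expect_lt(max(abs(r9$transform$scales - 1 / 1.1)), 0.01 / 1.1)
  r6 <- register_linear(mv, fx, dof = 6)
  expect_gt(r6$ssd, 5 * r9$ssd)  # rigid family leaves residual misfit
})

test_that("rigid (6 dof) transforms never change volume", {
  tf <- linear_transform(c(0.2, -0.1, 0.35), c(1.2, -0.7, 0.4), dof = 6)
  expect_equal(det(transform_matrix(tf)), 1, tolerance = 1e-12)
  ## and composition with the inverse is the identity
  comp <- transform_matrix(tf) %*% transform_matrix(invert_linear(tf))
  expect_equal(comp, diag(3), tolerance = 1e-10)
})

test_that("population mean template behaves like a Frechet mean", {
  img <- textured_blob()
  ## identical inputs: template equals the input
  pm <- build_population_mean(list(img, img, img), dof = 6, iterations = 1)
  expect_lt(max(abs(pm$template - img)), 0.05)

  ## two copies translated +/- d: template centred at the midpoint
  tf_p <- linear_transform(0, c(3, 0)); tf_m <- linear_transform(0, c(-3, 0))
  a <- apply_linear(img, tf_p); b <- apply_linear(img, tf_m)
  pm2 <- build_population_mean(list(a, b), dof = 6, iterations = 2)
  centroid <- function(x) {
    w <- pmax(x, 0); g <- expand.grid(i = seq_len(nrow(x)), j = seq_len(ncol(x)))
    c(sum(g$i * w) / sum(w), sum(g$j * w) / sum(w))
  }
  mid <- (centroid(a) + centroid(b)) / 2
  expect_lt(max(abs(centroid(pm2$template) - mid)), 0.5)

  ## order invariance
  pm3 <- build_population_mean(list(b, a), dof = 6, iterations = 2)
  expect_lt(mean(abs(pm2$template - pm3$template)), 0.02)

  expect_error(build_population_mean(list(img)), "at least 2")
})

test_that("fluid registration of identical images is the zero field", {
  img <- soft_disk(10)
  fld <- register_fluid(img, img)
  expect_equal(max(abs(fld$u)), 0)
  expect_equal(unique(as.vector(fld$jacobian)), 1)
})

test_that("disk expansion recovers the analytic area ratio", {
  ## template disk radius 10, subject radius 12: mean Jacobian inside the
  ## template disk approximates (12/10)^2 = 1.44
  fld <- register_fluid(soft_disk(12), soft_disk(10))
  n <- 48
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((g$x - (n + 1) / 2)^2 + (g$y - (n + 1) / 2)^2)
  inside <- array(r <= 10, c(n, n))
  expect_lt(abs(mean(fld$jacobian[inside]) - 1.44), 0.144)
  ## SSD decreased monotonically over accepted steps
  expect_true(all(diff(fld$report$ssd_trace) < 0))
})

test_that("a known smooth deformation is recovered inside the object", {
  ## pattern with gradients everywhere, so the field is identifiable (in
  ## flat regions any intensity-driven method is blind to displacement)
  set.seed(1)
  n <- 48
  pattern <- gaussian_smooth(array(rnorm(n * n), c(n, n)), 2)
  pattern <- (pattern - min(pattern)) / diff(range(pattern))
  utrue <- radial_field(n, amp = 2.5, sig = 8)
  subject <- warp_image(pattern, utrue)
  fld <- register_fluid(pattern, subject)  # expect u ~ utrue
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((g$x - (n + 1) / 2)^2 + (g$y - (n + 1) / 2)^2)
  obj <- array(r <= 16, c(n, n))
  err <- sqrt((fld$u[, , 1] - utrue[, , 1])^2 +
              (fld$u[, , 2] - utrue[, , 2])^2)
  expect_lt(median(err[obj]), 0.5)
  ## at least 80% of the displacement magnitude is recovered
  mag_rec <- sqrt(fld$u[, , 1]^2 + fld$u[, , 2]^2)
  mag_true <- sqrt(utrue[, , 1]^2 + utrue[, , 2]^2)
  expect_gt(sum(mag_rec[obj]) / sum(mag_true[obj]), 0.8)
})

test_that("forward and backward fluid fields compose to near identity", {
  a <- textured_blob()
  b <- warp_image(a, radial_field(48, amp = 2, sig = 9))
  fab <- register_fluid(a, b)
  fba <- register_fluid(b, a)
  comp <- hdpheno:::compose_fields(fba$u, fab$u)
  mag <- sqrt(comp[, , 1]^2 + comp[, , 2]^2)
  obj <- array(a > 0.15, c(48, 48))
  expect_lt(median(mag[obj]), 0.5)
})

test_that("Jacobian determinants match closed forms", {
  ## zero field
  u0 <- array(0, c(12, 12, 2))
  expect_equal(jacobian_determinant(u0), array(1, c(12, 12)))

  ## uniform scale x -> s x gives det = s^nd in the interior
  n <- 20; s <- 1.1
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  u <- array(0, c(n, n, n, 3))
  ctr <- (n + 1) / 2
  u[, , , 1] <- array((g$x - ctr) * (s - 1), c(n, n, n))
  u[, , , 2] <- array((g$y - ctr) * (s - 1), c(n, n, n))
  u[, , , 3] <- array((g$z - ctr) * (s - 1), c(n, n, n))
  J <- jacobian_determinant(u)
  expect_equal(J[10, 10, 10], s^3, tolerance = 1e-10)
  expect_equal(J[5, 14, 8], s^3, tolerance = 1e-10)

  ## polynomial field with hand-computed determinant:
  ## u1 = a x^2, u2 = b x y  =>  J = (1 + 2ax)(1 + bx) exactly for
  ## second-order-accurate central differences (quadratic in x, bilinear)
  n2 <- 16; a_c <- 0.002; b_c <- 0.003
  g2 <- expand.grid(x = seq_len(n2), y = seq_len(n2))
  u2 <- array(0, c(n2, n2, 2))
  u2[, , 1] <- array(a_c * g2$x^2, c(n2, n2))
  u2[, , 2] <- array(b_c * g2$x * g2$y, c(n2, n2))
  J2 <- jacobian_determinant(u2)
  interior <- as.matrix(expand.grid(4:12, 4:12))
  expected <- (1 + 2 * a_c * interior[, 1]) * (1 + b_c * interior[, 1])
  expect_equal(J2[interior], expected, tolerance = 1e-8)

  u_bad <- u0; u_bad[1, 1, 1] <- NA
  expect_error(jacobian_determinant(u_bad), "validation error")
})

test_that("mean Jacobian over the template mask conserves object area", {
  ## integral check: mean J over the template object x its area approximates
  ## the subject object area
  fld <- register_fluid(soft_disk(12), soft_disk(10))
  n <- 48
  g <- expand.grid(x = seq_len(n), y = seq_len(n))
  r <- sqrt((g$x - (n + 1) / 2)^2 + (g$y - (n + 1) / 2)^2)
  tmpl_mask <- array(r <= 10.5, c(n, n))
  est_area <- mean(fld$jacobian[tmpl_mask]) * sum(tmpl_mask)
  expect_lt(abs(est_area - pi * 12^2) / (pi * 12^2), 0.05)
})
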