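spec <- small_phantom_spec()
traj <- trajectory_config()

test_that("phantom generation is deterministic and respects trajectories", {
  a <- generate_phantom(spec, 36, traj, "HD", "male", 1.02, c(0.1, 0.2, 0.3))
  b <- generate_phantom(spec, 36, traj, "HD", "male", 1.02, c(0.1, 0.2, 0.3))
  expect_identical(a$labels, b$labels)

  ## flat trajectory: WT striatum has zero decline, so equal target volumes
  ## (and equal voxel counts at identical offsets) at 36 vs 94 weeks
  w36 <- generate_phantom(spec, 36, traj, "WT", "male")
  w94 <- generate_phantom(spec, 94, traj, "WT", "male")
  expect_equal(sum(w36$labels == w36$codes[["striatum"]]),
               sum(w94$labels == w94$codes[["striatum"]]))
})

test_that("phantom voxel volumes track the analytic ellipsoid targets", {
  ## voxel-count volume within a surface-shell bound of 4/3 pi a b c
  lv <- generate_phantom(spec, 36, traj, "WT", "male")
  voxvol <- prod(spec$spacing)
  for (region in c("striatum", "hippocampus", "cortex")) {
    target <- lv$truth$target_mm3[lv$truth$region == region]
    meas <- sum(lv$labels == lv$codes[[region]]) * voxvol
    ## surface-shell bound: area of sphere of equal volume x voxel diagonal
    r_eq <- (3 * target / (4 * pi))^(1 / 3)
    bound <- 4 * pi * r_eq^2 * sqrt(sum(spec$spacing^2))
    expect_lt(abs(meas - target), bound)
  }
})

test_that("HD striatal decline at 94 weeks matches the configured fraction", {
  ## voxel-count ratio vs the trajectory peak, fine grid, jitter averaged out
  fine <- phantom_spec()
  offs <- matrix(stats::runif(30), 10, 3)
  ratio <- mean(vapply(seq_len(10), function(i) {
    peak <- generate_phantom(fine, 36, traj, "HD", "male",
                             offset_mm = offs[i, ] * fine$spacing)
    fin <- generate_phantom(fine, 94, traj, "HD", "male",
                            offset_mm = offs[i, ] * fine$spacing)
    sum(fin$labels == fin$codes[["striatum"]]) /
      sum(peak$labels == peak$codes[["striatum"]])
  }, numeric(1)))
  decline <- traj$regions$striatum$HD$decline
  expect_lt(abs(ratio - (1 - decline)), 0.03)
})

test_that("degenerate and invalid phantom configurations error", {
  expect_error(generate_phantom(spec, 5, traj, "WT", "male"), "age")
  tiny <- traj
  tiny$regions$ventricles$WT$peak <- 1e-4
  expect_error(generate_phantom(spec, 36, tiny, "WT", "male"), "degenerate")
  crowd <- traj
  crowd$regions$striatum$WT$peak <- 120   # blows the striatum up into the shell
  expect_error(generate_phantom(spec, 36, crowd, "WT", "male"),
               "configuration error")
})

test_that("multi-echo rendering follows the mono-exponential closed form", {
  lab <- uniform_label_volume()
  tm <- tissue_model(s0 = c(brain = 1000), t2 = c(brain = 40), noise_sd = 0)
  img <- render_multiecho(lab, tm, echo_times = c(10), seed = 1)
  expect_equal(as.vector(img$data), rep(1000 * exp(-0.25), prod(dim(lab$labels))))

  ## protocol echo train: 8 echoes at 10..80 ms
  expect_equal(echo_train(10, 8), seq(10, 80, by = 10))

  ## seeding contract
  tm_n <- tissue_model(s0 = c(brain = 1000), t2 = c(brain = 40), noise_sd = 5)
  r1 <- render_multiecho(lab, tm_n, echo_train(), seed = 11)
  r2 <- render_multiecho(lab, tm_n, echo_train(), seed = 11)
  r3 <- render_multiecho(lab, tm_n, echo_train(), seed = 12)
  expect_identical(r1$data, r2$data)
  expect_false(identical(r1$data, r3$data))

  ## unknown label -> mapping error
  expect_error(render_multiecho(lab, tissue_model(s0 = c(cortex = 1),
                                                  t2 = c(cortex = 40)),
                                echo_train(), 1),
               "no entry")
  expect_error(render_multiecho(lab, tm, echo_times = c(20, 10), seed = 1),
               "increasing")
})

test_that("rendered white:grey contrast matches the configured ratio", {
  tm <- tissue_model(noise_sd = 0)
  wg <- (tm$s0[["corpus_callosum"]] * exp(-10 / tm$t2[["corpus_callosum"]])) /
    (tm$s0[["cortex"]] * exp(-10 / tm$t2[["cortex"]]))
  expect_equal(wg, 1.25, tolerance = 0.01)
})

test_that("zero-effect cohorts show only sampling noise between genotypes", {
  co <- generate_cohort(null_trajectory_config(missingness = 0,
                                               outlier_rate = 0),
                        n_per_cell = 10, seed = 5)
  beh <- co$behaviour
  final <- max(beh$age_weeks)
  tstats <- vapply(unique(beh$measure), function(m) {
    d <- beh[beh$measure == m & beh$age_weeks == final, ]
    unname(stats::t.test(value ~ genotype, data = d)$statistic)
  }, numeric(1))
  ## all |t| below the 99.9th-percentile bound for ~38 df
  expect_true(all(abs(tstats) < stats::qt(0.999, 38)))
})

test_that("behavioural missingness matches the configured rate", {
  tc <- trajectory_config(missingness = 0.1, outlier_rate = 0)
  co <- generate_cohort(tc, n_per_cell = 10, seed = 2)
  n <- nrow(co$behaviour)
  phat <- mean(co$behaviour$missing)
  se <- sqrt(0.1 * 0.9 / n)
  expect_lt(abs(phat - 0.1), 4 * se)
})

test_that("large-n cohorts close the calibration loop within 2 points", {
  ## pipeline-recovered effect sizes converge to the configured values
  co <- generate_cohort(clean_trajectory(), n_per_cell = 40, seed = 3)
  gap_m <- genotype_gap(co$behaviour, age = 94,
                        measure = "locomotor_activity", sex = "male")
  expect_lt(abs(gap_m - 34), 2)
  gap_f <- genotype_gap(co$behaviour, age = 94,
                        measure = "locomotor_activity", sex = "female")
  expect_lt(abs(gap_f - 39), 2)

  vols <- cohort_volumes(co, spec, regions = c("striatum", "hippocampus"),
                         genotypes = "HD")
  expect_lt(abs(peak_to_final_decline(vols, "striatum")$decline_pct - 27), 2)
  expect_lt(abs(peak_to_final_decline(vols, "hippocampus")$decline_pct - 21),
            2)
})

test_that("section generation renders exact ground truth", {
  ## blank sections for zero objects
  t0 <- histo_ground_truth(n_sections = 2, neurons_per_section = 0,
                           nuclear_per_section = 0, diffuse_per_section = 0)
  secs <- generate_sections(t0, pixel_size_um = 2)
  expect_true(all(secs[[1]]$pixels == 255 - t0$levels[["background"]]))

  ## darkness classes appear at their configured levels
  t1 <- histo_ground_truth(n_sections = 1, neurons_per_section = 0,
                           nuclear_per_section = 20, diffuse_per_section = 20,
                           seed = 4)
  s1 <- generate_sections(t1, pixel_size_um = 2)[[1]]
  vals <- sort(unique(as.vector(s1$pixels)))
  expect_setequal(vals, 255 - c(t1$levels[["background"]],
                                t1$levels[["diffuse"]],
                                t1$levels[["nuclear"]]))

  ## invariant: nuclear darkness must exceed diffuse darkness
  expect_error(histo_ground_truth(nuclear_darkness = 100,
                                  diffuse_darkness = 150),
               "strictly exceed")
})

test_that("non-overlapping neuron discs match a component-labelling oracle", {
  tr <- histo_ground_truth(n_sections = 1, field_um = c(1200, 1200),
                           neurons_per_section = 500,
                           nuclear_per_section = 0, diffuse_per_section = 0,
                           seed = 7)
  sec <- generate_sections(tr, pixel_size_um = 2)[[1]]
  mask <- sec$pixels <= 255 - tr$levels[["neuron"]]
  n_comp <- max(EBImage::bwlabel(mask))
  expect_equal(n_comp, 500)
})
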