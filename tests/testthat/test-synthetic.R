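test_that("generate_phantom is deterministic and analysis-complete", {
  s1 <- generate_phantom()
  s2 <- generate_phantom()
  expect_identical(s1$landmarks, s2$landmarks)
  expect_equal(nrow(s1$landmarks), 13L)
  expect_true(analysis_complete(s1))
  expect_true(all(s1$truth == 0))

  custom <- phantom_spec(
    target_layout = matrix(c(0, -20, 80), 1, 3,
                           dimnames = list("P1", NULL)),
    target_depth = c(P1 = 120)
  )
  expect_equal(nrow(generate_phantom(custom)$landmarks), 7L)

  line <- matrix(cbind(0:5, 0, 0), 6, 3,
                 dimnames = list(paste0("R", 1:6), NULL))
  expect_error(phantom_spec(reference_layout = line), "collinear")
  expect_error(phantom_spec(target_depth = c(P1 = -1)), "> 0")
})

test_that("insufflation follows the depth-attenuated linear pressure law", {
  s <- generate_phantom()
  expect_identical(apply_insufflation(s, 0)$landmarks, s$landmarks)
  expect_error(apply_insufflation(s, 10), "allowed")

  # closed form: alpha 0.8 mm/mmHg, lambda 30 mm, depth 120 mm, 15 mmHg
  spec <- phantom_spec(
    target_layout = matrix(c(0, -20, 80), 1, 3,
                           dimnames = list("P1", NULL)),
    target_depth = c(P1 = 120)
  )
  pars <- deformation_params(alpha = 0.8, lambda_depth = 30)
  out <- apply_insufflation(generate_phantom(spec), 15, pars)
  shift <- out$landmarks["P1", ] - generate_phantom(spec)$landmarks["P1", ]
  expect_equal(sqrt(sum(shift^2)), 0.8 * 15 * exp(-4), tolerance = 1e-12)
  expect_equal(unname(shift), c(0, 0.8 * 15 * exp(-4), 0))  # anterior push
  # references unmoved
  expect_identical(active_references(out),
                   active_references(generate_phantom(spec)))

  # shift magnitude strictly increasing in pressure
  mags <- vapply(scan_pressures(), function(p) {
    o <- apply_insufflation(generate_phantom(spec), p, pars)
    sqrt(sum((o$landmarks["P1", ] -
                generate_phantom(spec)$landmarks["P1", ])^2))
  }, 0)
  expect_true(all(diff(mags) > 0))
})

test_that("position changes are rigid for bone, gravity-chord for tissue", {
  s <- generate_phantom()
  expect_identical(apply_position(s, "supine")$landmarks, s$landmarks)
  expect_error(apply_position(s, "prone"), "allowed")

  # zero compliance: pure rigid motion, so the surrogate vanishes
  p0 <- deformation_params(sag_compliance = stats::setNames(rep(0, 7),
                                                            paste0("P", 1:7)))
  rot <- apply_position(s, "left_lateral_decubitus_45", p0)
  for (tg in paste0("P", 1:7)) {
    expect_lt(displacement(s, rot, tg)$mean_abs_diff_mm, 1e-9)
  }
  # bony constellation congruent with baseline in every position
  for (pos in scan_positions()) {
    moved <- apply_position(s, pos)
    expect_lt(fit_rigid(active_references(moved),
                        active_references(s))$fre, 1e-9)
  }

  # 45 degree roll with 5 mm compliance: chord 2*sin(22.5deg)
  p5 <- deformation_params(sag_compliance = c(P5 = 5))
  m <- apply_position(s, "left_lateral_decubitus_45", p5)
  expect_equal(sqrt(sum(m$truth["P5", ]^2)), 5 * 2 * sin(pi / 8),
               tolerance = 1e-12)
  expect_equal(true_displacement(s, m, "P5"), 5 * 2 * sin(pi / 8),
               tolerance = 1e-9)
})

test_that("placement noise is seed-reproducible and sigma-0 is identity", {
  s <- generate_phantom()
  expect_identical(add_placement_noise(s, 0, seed = 1)$landmarks,
                   s$landmarks)
  a <- add_placement_noise(s, 1.5, seed = 42)
  b <- add_placement_noise(s, 1.5, seed = 42)
  expect_identical(a$landmarks, b$landmarks)
  expect_false(identical(a$landmarks, s$landmarks))
})

test_that("simulate_study builds the 20-condition factorial with truth", {
  study <- simulate_study(params = deformation_params(seed = 41))
  expect_s3_class(study, "synthetic_study")
  expect_equal(length(study$sets), 20L)
  expect_setequal(names(study$sets),
                  sprintf("%s|%g", study_conditions()$position,
                          study_conditions()$pressure))
  expect_true(all(study$ground_truth[["supine|0"]] == 0))

  # identical seed -> bit-identical studies
  study2 <- simulate_study(params = deformation_params(seed = 41))
  expect_identical(lapply(study$sets, `[[`, "landmarks"),
                   lapply(study2$sets, `[[`, "landmarks"))

  # all gains zero, sigma zero: static study
  pz <- deformation_params(alpha = 0, noise_sigma = 0,
                           sag_compliance = stats::setNames(rep(0, 7),
                                                            paste0("P", 1:7)))
  stz <- simulate_study(params = pz)
  expect_true(all(vapply(stz$ground_truth, function(m) all(m == 0), TRUE)))

  gt <- ground_truth_table(study)
  expect_equal(nrow(gt), 140L)  # 20 conditions x 7 targets
  expect_true(all(gt$magnitude_mm >= 0))
})

test_that("recorded ground truth matches registration-based truth", {
  set.seed(43)
  study <- simulate_study(params = random_deformation_params(noise_sigma = 0))
  base <- study$sets[["supine|0"]]
  for (key in names(study$sets)) {
    for (tg in c("P1", "P4", "P7")) {
      expect_equal(true_displacement(base, study$sets[[key]], tg),
                   sqrt(sum(study$ground_truth[[key]][tg, ]^2)),
                   tolerance = 1e-9)
    }
  }
})

test_that("noiseless ground truth recovers the insufflation gain exactly", {
  pars <- deformation_params(alpha = 1.3, lambda_depth = 55, noise_sigma = 0)
  study <- simulate_study(params = pars)
  depths <- study$spec$target_depth
  for (tg in paste0("P", 1:7)) {
    shifts <- vapply(scan_pressures(), function(p) {
      study$ground_truth[[sprintf("supine|%g", p)]][tg, 2]
    }, 0)
    slope <- sum(shifts * scan_pressures()) / sum(scan_pressures()^2)
    expect_equal(slope, pars$alpha * exp(-depths[[tg]] / pars$lambda_depth),
                 tolerance = 1e-9)
  }
})

test_that("default simulation: pressure effects smaller than position effects", {
  study <- simulate_study(params = deformation_params(seed = 44))
  pres <- pressure_effect_table(study$sets)
  post <- position_effect_table(study$sets)
  expect_lt(mean(pres$mean_abs_diff_mm), mean(post$mean_abs_diff_mm))
})
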