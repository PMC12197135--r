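test_that("distance_matrix gives Euclidean mm distances for active pairs", {
  s <- scan_landmark_set(
    scan_condition("supine", 0),
    rbind(R1 = c(0, 0, 0), R2 = c(1, 1, 1), P1 = c(3, 4, 0))
  )
  d <- distance_matrix(s)
  expect_equal(d["R1", "P1"], 5)  # 3-4-5 triangle
  s2 <- scan_landmark_set(scan_condition("supine", 0),
                          rbind(R1 = c(2, -1, 7), P1 = c(2, -1, 7)))
  expect_equal(distance_matrix(s2)["R1", "P1"], 0)

  set.seed(21)
  full <- random_landmark_set()
  expect_equal(dim(distance_matrix(full)), c(6L, 7L))  # 42 entries

  refs_only <- scan_landmark_set(scan_condition("supine", 0),
                                 rbind(R1 = c(0, 0, 0), R2 = c(1, 0, 0)))
  expect_error(distance_matrix(refs_only), "target")
  tgt_only <- scan_landmark_set(scan_condition("supine", 0),
                                rbind(P1 = c(0, 0, 0)))
  expect_error(distance_matrix(tgt_only), "reference")
})

test_that("distance_matrix matches a brute-force double loop", {
  set.seed(22)
  for (i in 1:25) {
    s <- random_landmark_set(scale = stats::runif(1, 1, 300))
    d <- distance_matrix(s)
    refs <- active_references(s); tgts <- active_targets(s)
    for (r in rownames(refs)) for (tg in rownames(tgts)) {
      expect_equal(d[r, tg], sqrt(sum((refs[r, ] - tgts[tg, ])^2)),
                   tolerance = 1e-12)
    }
  }
})

test_that("displacement reproduces the hand-derived octahedral example", {
  p <- octahedron_pair(c(1, 0, 0))
  d <- displacement(p$baseline, p$comparison, "P1")
  expect_equal(d$mean_abs_diff_mm, octahedron_expected_mean,
               tolerance = 1e-9)
  expect_equal(d$mean_abs_diff_mm, 0.3665837, tolerance = 1e-6)
  expect_equal(d$n_references, 6L)
  # the surrogate under-reports the true 1 mm shift
  expect_lt(d$mean_abs_diff_mm, 1)
})

test_that("displacement is zero for identical or rigidly moved scans", {
  set.seed(23)
  b <- random_landmark_set()
  same <- displacement(b, b, "P3")
  expect_equal(same$mean_abs_diff_mm, 0)
  expect_equal(same$sd_abs_diff_mm, 0)
  for (i in 1:10) {
    moved <- transform_set(b, random_rotation(), stats::rnorm(3, 0, 200))
    moved$condition <- scan_condition("trendelenburg_15", 15)
    for (tg in paste0("P", 1:7)) {
      expect_lt(displacement(b, moved, tg)$mean_abs_diff_mm, 1e-9)
    }
  }
})

test_that("displacement is symmetric in its two scans", {
  set.seed(24)
  for (i in 1:10) {
    a <- random_landmark_set()
    b <- random_landmark_set(scan_condition("supine", 15))
    ab <- displacement(a, b, "P2")
    ba <- displacement(b, a, "P2")
    expect_equal(ab$mean_abs_diff_mm, ba$mean_abs_diff_mm)
    expect_equal(ab$sd_abs_diff_mm, ba$sd_abs_diff_mm)
  }
})

test_that("SD convention and missing-landmark policy are honoured", {
  p <- octahedron_pair(c(1, 0, 0))
  d_s <- displacement(p$baseline, p$comparison, "P1", sd_mode = "sample")
  d_p <- displacement(p$baseline, p$comparison, "P1",
                      sd_mode = "population")
  expect_equal(d_p$sd_abs_diff_mm, d_s$sd_abs_diff_mm * sqrt(5 / 6))

  # strict mode refuses an incomplete reference matrix
  b2 <- p$baseline
  b2$landmarks <- b2$landmarks[c("R1", "R2", "R3", "P1"), ]
  b2$excluded <- b2$excluded[c("R1", "R2", "R3", "P1")]
  expect_error(displacement(b2, p$comparison, "P1"), "R4")
  d3 <- displacement(b2, p$comparison, "P1", strict = FALSE)
  expect_equal(d3$n_references, 3L)
  expect_error(displacement(p$baseline, p$comparison, "P9"), "missing")
})

test_that("comparison tables have the factorial cell structure", {
  study <- simulate_study(params = deformation_params(seed = 25))
  pres <- pressure_effect_table(study$sets)
  post <- position_effect_table(study$sets)
  expect_equal(nrow(pres), 105L)  # 7 targets x 3 pressures x 5 positions
  expect_equal(nrow(post), 112L)  # 7 targets x 4 positions x 4 pressures
  expect_false(anyNA(pres$mean_abs_diff_mm))
  expect_false(anyNA(post$mean_abs_diff_mm))
  expect_true(all(pres$n_references == 6L))
  expect_identical(attr(pres, "layout"), "pressure_effect")

  # single-stratum study
  supine_only <- study$sets[grepl("^supine", names(study$sets))]
  expect_equal(nrow(pressure_effect_table(supine_only)), 21L)  # 7 x 3 x 1

  # a position absent from the whole study is dropped and flagged
  no_rt <- study$sets[!grepl("^reverse_trendelenburg", names(study$sets))]
  post3 <- position_effect_table(no_rt)
  expect_equal(nrow(post3), 84L)  # 7 x 3 x 4
  expect_identical(attr(post3, "missing_levels"),
                   "reverse_trendelenburg_15")

  # a missing baseline is an error naming the stratum
  no_base <- study$sets[names(study$sets) != "supine|0"]
  expect_error(pressure_effect_table(no_base), "supine")
  expect_error(position_effect_table(no_base), "0 mmHg")

  # a single absent non-baseline condition leaves NA cells, not zeros
  partial <- study$sets[names(study$sets) != "trendelenburg_15|25"]
  pres_p <- pressure_effect_table(partial)
  expect_equal(nrow(pres_p), 105L)
  na_cells <- pres_p[is.na(pres_p$mean_abs_diff_mm), ]
  expect_equal(nrow(na_cells), 7L)
  expect_true(all(na_cells$stratum == "trendelenburg_15" &
                    na_cells$level == "25"))
})

test_that("identical scans everywhere give all-zero tables", {
  base <- generate_phantom()
  sets <- lapply(seq_len(nrow(study_conditions())), function(i) {
    s <- base
    s$condition <- scan_condition(study_conditions()$position[i],
                                  study_conditions()$pressure[i])
    s
  })
  pres <- pressure_effect_table(sets)
  expect_true(all(pres$mean_abs_diff_mm == 0))
  expect_true(all(pres$sd_abs_diff_mm == 0))
})

test_that("repeatability reproduces hand-computed pairwise statistics", {
  mk <- function(xyz) {
    scan_landmark_set(scan_condition("supine", 0),
                      matrix(xyz, 1, 3, dimnames = list("P1", NULL)))
  }
  # identical replicates
  r0 <- repeatability(list(mk(c(1, 2, 3)), mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(r0$mean_mm, 0)
  expect_equal(r0$sd_mm, 0)
  # pairwise distances {3, 4, 5} -> mean 4
  r1 <- repeatability(list(mk(c(0, 0, 0)), mk(c(3, 0, 0)), mk(c(0, 4, 0))))
  expect_equal(r1$mean_mm, 4)
  expect_equal(r1$n_replicates, 3L)
  # centroid alternative: centroid (1, 4/3, 0); hand distances
  r2 <- repeatability(list(mk(c(0, 0, 0)), mk(c(3, 0, 0)), mk(c(0, 4, 0))),
                      statistic = "centroid")
  ctr <- c(1, 4 / 3, 0)
  expected <- mean(c(sqrt(sum(ctr^2)), sqrt(sum((c(3, 0, 0) - ctr)^2)),
                     sqrt(sum((c(0, 4, 0) - ctr)^2))))
  expect_equal(r2$mean_mm, expected)
})

test_that("repeatability pools by role and warns on lone placements", {
  set.seed(26)
  base <- generate_phantom()
  reps <- replicate(3, add_placement_noise(base, 1.0), simplify = FALSE)
  res <- repeatability(reps, pool = TRUE)
  expect_setequal(setdiff(res$landmark, c(paste0("R", 1:6), paste0("P", 1:7))),
                  c("pooled_reference", "pooled_target"))
  pooled <- res[res$landmark == "pooled_reference", ]
  expect_gt(pooled$mean_mm, 0)

  # landmark present in only one replicate is dropped with a warning
  reps[[2]]$landmarks <- reps[[2]]$landmarks[-13, ]
  reps[[2]]$excluded <- reps[[2]]$excluded[-13]
  reps[[3]]$landmarks <- reps[[3]]$landmarks[-13, ]
  reps[[3]]$excluded <- reps[[3]]$excluded[-13]
  expect_warning(res2 <- repeatability(reps), "P7")
  expect_false("P7" %in% res2$landmark)
  expect_error(repeatability(reps[1]), "length")
})

test_that("pooled pairwise repeatability follows the chi-3 closed form", {
  # Two placements with iid N(0, sigma^2 I3) errors are sqrt(2)*sigma*chi_3
  # apart, so the mean pairwise distance is sigma * 4/sqrt(pi) = 2.2568*sigma.
  # Monte-Carlo oracle at modest n, matched within 3 standard errors.
  set.seed(27)
  sigma <- 2.0
  base <- generate_phantom()
  dists <- replicate(400, {
    reps <- replicate(3, add_placement_noise(base, sigma), simplify = FALSE)
    r <- repeatability(reps, pool = TRUE)
    r$mean_mm[r$landmark == "pooled_reference"]
  })
  se <- stats::sd(dists) / sqrt(length(dists))
  expect_lt(abs(mean(dists) - 4 / sqrt(pi) * sigma), 3 * se)
})
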