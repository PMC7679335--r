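test_that("composition percentages are computed per replicate and averaged", {
  m <- matrix(c(50, 50), 2, 1, dimnames = list(c("A", "B"), "r1"))
  prof <- composition_from_lanes(m)
  expect_equal(prof$mean_percent, c(50, 50))
  expect_equal(prof$sd_percent, c(0, 0))
  # background row is equivalent to manual pre-subtraction
  m2 <- rbind(m + 5, background = c(5))
  prof2 <- composition_from_lanes(m2)
  expect_equal(prof2$mean_percent, prof$mean_percent)
  # negatives after subtraction clip with a warning
  m3 <- rbind(matrix(c(1, 50), 2, 1, dimnames = list(c("A", "B"), "r1")),
              background = 5)
  expect_warning(composition_from_lanes(m3), "clipped")
  # an empty replicate is an error naming the lane
  m4 <- matrix(c(1, 1, 0, 0), 2, 2, dimnames = list(c("A", "B"), c("r1", "r2")))
  expect_error(composition_from_lanes(m4), "r2")
})

test_that("percentages sum to 100 for replicates and means", {
  lanes <- simulate_profile_experiment(synthetic_config(seed = 3))
  for (g in names(lanes)) {
    prof <- composition_from_lanes(lanes[[g]])
    expect_equal(sum(prof$mean_percent), 100, tolerance = 0.01 / 100)
    reps <- attr(prof, "replicates")
    expect_equal(unname(colSums(reps)), rep(100, ncol(reps)),
                 tolerance = 0.01 / 100)
  }
})

test_that("the podocyte composition is recovered from synthetic lanes", {
  cfg <- synthetic_config(seed = 11)
  lanes <- simulate_profile_experiment(cfg)
  prof <- composition_from_lanes(lanes$Mock)
  base <- 100 * cfg$base / sum(cfg$base)
  rel_dev <- abs(prof$mean_percent - base[prof$species]) / base[prof$species]
  # judged against the configured noise (an SD estimated from 3 replicates
  # has only 2 df and is too unstable to divide by): means of 3 draws at
  # CV 5% should sit within ~3 CV of truth, with typical errors below 1 CV
  expect_true(all(rel_dev <= 3 * cfg$lane_cv))
  expect_lte(stats::median(rel_dev), cfg$lane_cv)
})

test_that("percent_change implements the Mock-reference semantics", {
  expect_equal(percent_change(c(LacCer = 58), c(LacCer = 100))$percent_change, -42)
  expect_equal(percent_change(c(A = 7), c(A = 7))$percent_change, 0)
  expect_warning(fc <- percent_change(c(A = 1), c(A = 0)), "mock value 0")
  expect_true(is.na(fc$percent_change))
  # scale invariance
  x <- c(A = 3.2, B = 1.1); y <- c(A = 4.0, B = 0.9)
  f1 <- percent_change(x, y)
  f2 <- percent_change(17.3 * x, 17.3 * y)
  expect_equal(f1$percent_change, f2$percent_change, tolerance = 1e-12)
  expect_error(percent_change(c(A = 1), c(B = 1)), "same species")
  # first-order SD propagation from both inputs
  s <- data.frame(species = "A", mean = 58, sd = 6)
  m <- data.frame(species = "A", mean = 100, sd = 0)
  expect_equal(percent_change(s, m)$sd, 6)
})

test_that("drm_species_change matches the raft comparisons", {
  expect_equal(drm_species_change(c(Cer = 0.2), c(Cer = 1.0))$percent_change, -80)
  expect_equal(drm_species_change(c(DSGb5Cer = 1.81), c(DSGb5Cer = 1.0))$percent_change,
               81, tolerance = 1e-12)
  expect_equal(drm_species_change(c(SM = 2), c(SM = 2))$percent_change, 0)
})

test_that("gradient_analysis pools DRM/HD fractions and reports recovery", {
  uni <- gradient_analysis(gradient_profile(rep(1, 11)))
  expect_equal(uni$percent, rep(100 / 11, 11), tolerance = 1e-12)
  expect_equal(uni$drm_share, 0.5)
  expect_equal(sum(uni$percent), 100, tolerance = 0.01 / 100)
  expect_error(gradient_profile(rep(1, 10)), "11 fractions")
  only_drm <- c(0, 0, 0, 0, 3, 2, 0, 0, 0, 0, 0)
  expect_equal(gradient_analysis(gradient_profile(only_drm))$drm_share, 1.0)
  prof <- simulate_gradient(synthetic_config(seed = 2))$Mock
  ana <- gradient_analysis(prof)
  expect_equal(ana$recovered_nCi, 225, tolerance = 1e-9)
  expect_equal(ana$recovery, 1, tolerance = 1e-9)
})

test_that("group_compare runs Welch t for 2 groups and ANOVA beyond", {
  same <- group_compare(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  sep <- group_compare(list(a = c(0, 0.01, -0.01), b = c(10, 10.01, 9.99)))
  expect_lt(sep$p_value, 0.001)
  # Welch statistic against the explicit formula
  x <- c(19.8, 20.4, 19.6, 17.8, 18.5, 18.9, 18.3, 18.9, 19.5, 22.0)
  y <- c(28.2, 26.6, 20.1, 23.3, 25.2, 22.1, 17.7, 27.6, 20.6, 13.7)
  got <- group_compare(list(x = x, y = y))
  t_hand <- (mean(x) - mean(y)) / sqrt(var(x) / 10 + var(y) / 10)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$method, "welch_t")
  three <- group_compare(list(a = rnorm(5), b = rnorm(5), c = rnorm(5)))
  expect_equal(three$method, "anova")
  expect_error(group_compare(list(a = 1, b = c(1, 2))), "replicates")
})

test_that("lane and gradient CSV readers parse documented layouts", {
  lane_csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,rep1,rep2", "SM,26,27", "Cer,6,5"), lane_csv)
  m <- read_lane_csv(lane_csv)
  expect_equal(rownames(m), c("SM", "Cer"))
  expect_equal(dim(m), c(2L, 2L))
  grad_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(fraction = 1:11, nCi = rep(2, 11)), grad_csv,
                   row.names = FALSE)
  prof <- read_gradient_csv(grad_csv, loaded_nCi = 25)
  expect_equal(gradient_analysis(prof)$recovery, 22 / 25, tolerance = 1e-12)
})
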