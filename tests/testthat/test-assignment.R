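test_that("derive_diagnostics recovers the published discriminating ions", {
  gm1 <- lapply(c("GM1a", "GM1b"), build_structure, ceramide = "d18:1/24:1")
  d <- derive_diagnostics(gm1)
  gm1a_only <- d[d$owners == "GM1a", ]
  expect_true(any(abs(gm1a_only$mz - 1261.815) <= 1e-3))

  gd1 <- lapply(c("GD1a", "GD1b", "GD1alpha"), build_structure,
                ceramide = "d18:1/22:0")
  d2 <- derive_diagnostics(gd1)
  expect_true(any(abs(d2$mz[d2$owners == "GD1b"] - 581.183) <= 1e-3))
  near_1235 <- d2[abs(d2$mz - 1235.800) <= 1e-3, ]
  expect_true(nrow(near_1235) == 1 && grepl("GD1a", near_1235$owners))

  expect_error(derive_diagnostics(gm1[1]), "not an isomer set")
  mixed <- list(build_structure("GM1a", "d18:1/24:1"),
                build_structure("GM3", "d18:1/24:1"))
  expect_error(derive_diagnostics(mixed), "not an isomer set")
})

test_that("sialidase digestion spares only inner sialic acids", {
  expect_equal(sialidase_digest(build_structure("GM1b"))[[1]]$name, "GA1")
  expect_equal(sialidase_digest(build_structure("GM1a"))[[1]]$name, "GM1a")
  expect_equal(sialidase_digest(build_structure("GD1a"))[[1]]$name, "GM1a")
  expect_equal(sialidase_digest(build_structure("GD1b"))[[1]]$name, "GM1a")
  expect_equal(sialidase_digest(build_structure("GD1alpha"))[[1]]$name, "GA1")
  singles <- vapply(sialidase_digest(build_structure("GD1alpha"), "single_step"),
                    `[[`, "", "name")
  expect_length(singles, 2)
  expect_true("GM1b" %in% singles)
  # globo backbones keep their own asialo core, not a ganglio one
  expect_equal(sialidase_digest(build_structure("MSGb5Cer"))[[1]]$name, "Gb5Cer")
  expect_equal(sialidase_digest(build_structure("DSGb5Cer"))[[1]]$name, "Gb5Cer")
})

test_that("digestion conserves mass and is idempotent", {
  for (nm in fragmentable_names()) {
    s <- build_structure(nm, "d18:1/24:1")
    prod <- sialidase_digest(s)[[1]]
    k <- sum(s$composition["Neu5Ac"], na.rm = TRUE) -
      sum(prod$composition["Neu5Ac"], na.rm = TRUE)
    expect_equal(gsl_neutral_mass(prod),
                 gsl_neutral_mass(s) - k * 291.0954165,
                 tolerance = 1e-6 / 1600, info = nm)
    again <- sialidase_digest(prod)[[1]]
    expect_equal(gslms:::canonical_topology_string(again$topology),
                 gslms:::canonical_topology_string(prod$topology), info = nm)
  }
})

test_that("the GM1 series with sialidase evidence is called GM1b", {
  res <- assign_structure(
    gm1_peaklist(), c("GM1a", "GM1b"), "d18:1/24:1",
    digestion = digestion_observation("GM1", "GA1", "exhaustive")
  )
  expect_equal(res$assigned, "GM1b")
  expect_equal(unname(res$status["GM1a"]), "excluded")
  expect_false(res$digestion_consistent[["GM1a"]])
  expect_true(res$digestion_consistent[["GM1b"]])
  # the exclusion also stands on the spectrum alone (no 1261.78 ion)
  res2 <- assign_structure(gm1_peaklist(), c("GM1a", "GM1b"), "d18:1/24:1")
  expect_equal(res2$assigned, "GM1b")
})

test_that("the GD1 series is called GD1alpha against both competitors", {
  res <- assign_structure(
    gd1_peaklist(), c("GD1a", "GD1b", "GD1alpha"), "d18:1/22:0",
    digestion = digestion_observation("GD1", c("GM1", "GA1"), "partial")
  )
  expect_equal(res$assigned, "GD1alpha")
  expect_equal(unname(res$status[c("GD1a", "GD1b")]), rep("excluded", 2))
  expect_false(res$digestion_consistent[["GD1a"]])
  expect_false(res$digestion_consistent[["GD1b"]])
  expect_true(res$digestion_consistent[["GD1alpha"]])
})

test_that("assignment is stable under peak permutation and far noise", {
  base <- gd1_peaklist()
  res0 <- assign_structure(base, c("GD1a", "GD1b", "GD1alpha"), "d18:1/22:0")
  perm <- spectrum(rev(base$peaks$mz), rev(base$peaks$intensity),
                   precursor_mz = base$precursor_mz,
                   precursor_charge = base$precursor_charge)
  res1 <- assign_structure(perm, c("GD1a", "GD1b", "GD1alpha"), "d18:1/22:0")
  expect_equal(res1$assigned, res0$assigned)
  expect_equal(res1$status, res0$status)
  # noise peaks > tol away from every theoretical ion of every candidate
  cands <- lapply(c("GD1a", "GD1b", "GD1alpha"), build_structure,
                  ceramide = "d18:1/22:0")
  theo <- unlist(lapply(cands, function(s) enumerate_fragments(s, 2)$mz))
  set.seed(9)
  noise <- runif(200, 200, 2000)
  noise <- noise[vapply(noise, function(m) all(abs(theo - m) > 0.25), TRUE)][1:20]
  noisy <- spectrum(c(base$peaks$mz, noise),
                    c(base$peaks$intensity, rep(1, length(noise))),
                    precursor_mz = base$precursor_mz,
                    precursor_charge = base$precursor_charge)
  res2 <- assign_structure(noisy, c("GD1a", "GD1b", "GD1alpha"), "d18:1/22:0")
  expect_equal(res2$assigned, res0$assigned)
  expect_equal(res2$status, res0$status)
})

test_that("simulated spectra are assigned to their generating structure", {
  sp <- simulate_ms2(build_structure("GM1a", "d18:1/24:1"),
                     synthetic_config(seed = 7))
  res <- assign_structure(sp, c("GM1a", "GM1b"), "d18:1/24:1")
  expect_equal(res$assigned, "GM1a")
  # a noise-only spectrum cannot support any verdict
  blank <- simulate_ms2(build_structure("GM1a", "d18:1/24:1"),
                        synthetic_config(seed = 7, detection_prob = 0))
  res2 <- assign_structure(blank, c("GM1a", "GM1b"), "d18:1/24:1")
  expect_true(is.na(res2$assigned))
})

test_that("precursor mismatches are recorded and inputs validated", {
  off <- spectrum(c(290.11), precursor_mz = 900.0, precursor_charge = 2)
  res <- assign_structure(off, c("GD1a", "GD1b", "GD1alpha"), "d18:1/22:0")
  expect_true(any(grepl("precursor", res$warnings)))
  expect_error(assign_structure(gm1_peaklist(), list()), "empty candidate")
})

test_that("assignment reports serialize to JSON", {
  res <- assign_structure(gm1_peaklist(), c("GM1a", "GM1b"), "d18:1/24:1")
  path <- withr::local_tempfile(fileext = ".json")
  write_assignment_json(res, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$assigned, "GM1b")
  expect_length(parsed$candidates, 2)
})
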