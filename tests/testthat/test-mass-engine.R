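test_that("neutral masses match independent elemental sums", {
  # frozen values from a hand calculation over atomic monoisotopic masses
  expect_equal(gsl_neutral_mass(build_structure("LacCer", "d18:1/16:0")),
               861.6177, tolerance = 1e-3 / 861)
  expect_equal(gsl_neutral_mass(build_structure("Cer", "d18:1/24:1")),
               647.6216, tolerance = 1e-3 / 647)
  expect_equal(gsl_neutral_mass(build_structure("GM1b", "d18:1/24:1")),
               1627.9549, tolerance = 2e-3 / 1627)
  expect_error(gsl_neutral_mass(build_structure("GM1b")), "ceramide required")
})

test_that("precursor m/z reproduces the printed ion-trap values", {
  expect_equal(precursor_mz(build_structure("GM1b", "d18:1/24:1"), 1),
               1626.90, tolerance = 0.10 / 1626)
  expect_equal(precursor_mz(build_structure("GD1alpha", "d18:1/22:0"), 2),
               945.51, tolerance = 0.10 / 945)
  expect_equal(precursor_mz(build_structure("Neu5AcGb5Cer", "d18:1/24:0"), 2),
               895.00, tolerance = 0.10 / 895)
  expect_error(precursor_mz(build_structure("GM3", "d18:1/16:0"), 3),
               "unsupported charge")
})

test_that("fragment m/z follows the negative-mode B/C/Y/Z conventions", {
  expect_equal(fragment_mz("B", c(Neu5Ac = 1)), 290.088, tolerance = 1e-3 / 290)
  expect_equal(fragment_mz("C", c(Neu5Ac = 1, Hex = 1)), 470.151,
               tolerance = 1e-3 / 470)
  gm1b_y <- fragment_mz("Y", c(Hex = 3, HexNAc = 1), "d18:1/24:1")
  expect_equal(gm1b_y, 1335.852, tolerance = 1e-3 / 1335)
  expect_equal(gm1b_y, 1335.79, tolerance = 0.10 / 1335) # printed value
  expect_error(fragment_mz("A", c(Hex = 1)), "invalid cleavage")
  expect_error(fragment_mz("Y", c(Hex = 1)), "requires a ceramide")
})

test_that("complementary single-cleavage pairs reconstruct the precursor", {
  for (nm in setdiff(fragmentable_names(), c("Cer", "SM"))) {
    s <- build_structure(nm, "d18:1/24:1")
    ions <- enumerate_fragments(s, 1)
    prec <- ions$mz[ions$ion_type == "precursor"]
    singles <- ions[ions$n_cleavages == 1, ]
    # pair fragments through complementary residue multisets
    full <- s$composition
    for (i in which(singles$ion_type == "B")) {
      bkey <- singles$residues[i]
      b_comp <- gslms:::parse_composition_key(bkey)
      ykey <- gslms:::composition_key(gslms:::subtract_composition(full, b_comp))
      y <- singles$mz[singles$ion_type == "Y" & singles$residues == ykey]
      c_ <- singles$mz[singles$ion_type == "C" & singles$residues == bkey]
      z <- singles$mz[singles$ion_type == "Z" & singles$residues == ykey]
      expect_equal(singles$mz[i] + y[1], prec - 1.007276, tolerance = 1e-6 / 1600)
      expect_equal(c_[1] + z[1], prec - 1.007276, tolerance = 1e-6 / 1600)
      expect_equal(c_[1] - singles$mz[i], 18.010565, tolerance = 1e-9)
      expect_equal(y[1] - z[1], 18.010565, tolerance = 1e-9)
    }
  }
})

test_that("doubly charged ions obey mz2 = (mz1 - proton)/2", {
  for (nm in c("GM1b", "GD1alpha", "DSGb5Cer")) {
    s <- build_structure(nm, "d18:1/24:1")
    expect_equal(precursor_mz(s, 2), (precursor_mz(s, 1) - 1.007276) / 2,
                 tolerance = 1e-9)
    expect_equal(fragment_mz("B", s$composition, charge = 2),
                 (fragment_mz("B", s$composition) - 1.007276) / 2,
                 tolerance = 1e-9)
  }
})

test_that("one extra hexose shifts precursor and Y ions by exactly its residue mass", {
  hex <- 162.0528234
  ladder <- c("GlcCer", "LacCer", "Gb3Cer")
  prec <- vapply(ladder, function(nm) {
    precursor_mz(build_structure(nm, "d18:1/16:0"), 1)
  }, 0)
  expect_equal(unname(diff(prec)), rep(hex, 2), tolerance = 1e-9)
  # the shared Y ions (ceramide side) are untouched, the new ones shifted
  y_lac <- fragment_mz("Y", c(Hex = 2), "d18:1/16:0")
  y_gb3 <- fragment_mz("Y", c(Hex = 3), "d18:1/16:0")
  expect_equal(y_gb3 - y_lac, hex, tolerance = 1e-9)
})

test_that("enumerate_fragments equals the brute-force cut enumerator", {
  reg <- default_registry()
  for (nm in names(reg)) {
    s <- build_structure(nm, "d18:1/24:1", registry = reg)
    expect_oracle_equal(ion_table_as_oracle(enumerate_fragments(s, 2)),
                        oracle_fragments(s, 2), info = nm)
  }
  # ceramide-only and sphingomyelin entries yield precursors only
  expect_equal(enumerate_fragments(build_structure("Cer", "d18:1/24:1"))$ion_type,
               "precursor")
  expect_equal(enumerate_fragments(build_structure("SM", "d18:1/24:1"))$ion_type,
               "precursor")
})

test_that("infer_ceramide picks the unique species within tolerance", {
  gd1 <- c(Hex = 3, HexNAc = 1, Neu5Ac = 2)
  expect_equal(infer_ceramide(945.51, 2, gd1, tol = 0.15)$fatty_acid, "C22:0")
  ds <- c(Hex = 4, HexNAc = 1, Neu5Ac = 2)
  expect_equal(infer_ceramide(1039.56, 2, ds, tol = 0.15)$fatty_acid, "C24:1")
  gm3 <- c(Hex = 2, Neu5Ac = 1)
  expect_error(infer_ceramide(500.0, 1, gm3, tol = 0.15), "no ceramide assignment")
  # two candidates inside an absurdly wide tolerance -> ambiguous
  expect_error(infer_ceramide(958.9, 2, gd1, tol = 5), "ambiguous ceramide")
})
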