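#' Default podocyte sphingolipid composition
#'
#' The shipped steady-state composition (percent of total sphingolipid
#' signal) used as the base of the profile simulator. Editable copy at
#' `system.file("extdata", "base_composition.csv", package = "gslms")`.
#'
#' @return Named numeric vector of percentages (sums to ~100).
#' @export
default_composition <- function() {
  tab <- utils::read.csv(system.file("extdata", "base_composition.csv",
                                     package = "gslms"))
  stats::setNames(tab$percent, tab$species)
}

#' Default genotype effect table
#'
#' Percent change of each species relative to Mock for the APOL1 wild-type
#' (WT) and the G1/G2 risk-variant overexpression conditions. Editable copy
#' at `system.file("extdata", "genotype_effects.csv", package = "gslms")`.
#'
#' @return data.frame, species in rows (rownames), one column per genotype.
#' @export
default_effects <- function() {
  tab <- utils::read.csv(system.file("extdata", "genotype_effects.csv",
                                     package = "gslms"))
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$species
  m
}

#' Configuration for the synthetic-data generators
#'
#' One root seed fans out to fixed per-stage substreams (spectra, lanes,
#' gradients, kinetics) so each stage regenerates independently and
#' identically for the same seed.
#'
#' @param seed integer root seed.
#' @param ms_sigma calibration offset SD applied to every theoretical m/z
#'   (Da), default 0.03 (unit-resolution ion trap).
#' @param noise_peaks number of uniform noise peaks per spectrum.
#' @param noise_range m/z range of the noise peaks.
#' @param detection_prob probability that a theoretical fragment is detected.
#' @param lane_cv multiplicative coefficient of variation of lane signals.
#' @param n_replicates replicates per genotype.
#' @param base base composition (percent, ~100 total).
#' @param effects genotype effect matrix (percent change per species).
#' @param drm_share DRM/(DRM+HD) share per genotype; the risk variants get a
#'   reduced share (raft sphingolipid radioactivity is depleted there).
#' @param bulk_share fraction of the loaded radioactivity recovered in the
#'   pooled DRM+HD fractions (the rest spreads over fractions 1-4 and 7-9).
#' @param gradient_cv per-fraction multiplicative noise (scintillation-level,
#'   small).
#' @param loaded_nCi radioactivity loaded per gradient, default 225.
#' @param kinetics_sigma Gaussian fluorescence noise SD on time courses and
#'   calibration standards.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             ms_sigma = 0.03, noise_peaks = 10,
                             noise_range = c(200, 2000), detection_prob = 1,
                             lane_cv = 0.05, n_replicates = 3,
                             base = default_composition(),
                             effects = default_effects(),
                             drm_share = c(Mock = 0.5, WT = 0.5, G1 = 0.35, G2 = 0.35),
                             bulk_share = 0.8, gradient_cv = 0.02,
                             loaded_nCi = 225,
                             kinetics_sigma = 0.5) {
  stopifnot(ms_sigma >= 0, detection_prob >= 0, detection_prob <= 1,
            lane_cv >= 0, gradient_cv >= 0, kinetics_sigma >= 0,
            all(drm_share >= 0 & drm_share <= 1))
  structure(
    list(seed = as.integer(seed), ms_sigma = ms_sigma,
         noise_peaks = noise_peaks, noise_range = noise_range,
         detection_prob = detection_prob, lane_cv = lane_cv,
         n_replicates = n_replicates, base = base, effects = effects,
         drm_share = drm_share, bulk_share = bulk_share,
         gradient_cv = gradient_cv, loaded_nCi = loaded_nCi,
         kinetics_sigma = kinetics_sigma),
    class = "synthetic_config"
  )
}

# per-stage substream (kept well below 2^31)
stage_seed <- function(config, stage) {
  offs <- c(ms2 = 101L, profile = 202L, gradient = 303L, kinetics = 404L)
  (config$seed %% 1000000L) * 1000L + offs[[stage]]
}

#' Simulate an ion-trap MS2 spectrum of a known structure
#'
#' The inverse of the assignment engine: peaks at every theoretical ion up to
#' two cleavages (each retained with `detection_prob`), shifted by a
#' Normal(0, `ms_sigma`) calibration offset, with `noise_peaks` uniform
#' contaminant peaks. Real fragment intensities follow a decreasing ladder;
#' noise stays low.
#'
#' @param structure `gsl_structure` with ceramide.
#' @param config a `synthetic_config`.
#' @param precursor_charge charge recorded on the spectrum (1 or 2).
#' @return A `spectrum`.
#' @export
simulate_ms2 <- function(structure, config = synthetic_config(),
                         precursor_charge = 1) {
  set.seed(stage_seed(config, "ms2"))
  theo <- enumerate_fragments(structure, 2, charges = 1)
  keep <- stats::runif(nrow(theo)) <= config$detection_prob
  mz <- theo$mz[keep] + stats::rnorm(sum(keep), 0, config$ms_sigma)
  n <- length(mz)
  # decreasing intensity ladder: lowest-m/z fragment most intense
  intensity <- if (n) {
    100 * (n - rank(mz, ties.method = "first") + 1) / n
  } else numeric()
  if (config$noise_peaks > 0) {
    nm <- stats::runif(config$noise_peaks, config$noise_range[1], config$noise_range[2])
    ni <- stats::runif(config$noise_peaks, 0.5, 5)
    mz <- c(mz, nm); intensity <- c(intensity, ni)
  }
  spectrum(mz, intensity,
           precursor_mz = precursor_mz(structure, precursor_charge),
           precursor_charge = precursor_charge,
           metadata = list(TITLE = paste0("synthetic ", structure$name)))
}

#' Simulate a metabolic-labelling profile experiment
#'
#' Lane tables for Mock plus each genotype in the effect table: per replicate
#' each species signal is `base * (1 + effect/100) * LogNormal(0, cv)`.
#' Compositions within 0.5 of 100 are renormalized to exactly 100.
#'
#' @param config a `synthetic_config`.
#' @return Named list of lane matrices (species x replicates), one per
#'   condition (`Mock` first).
#' @export
simulate_profile_experiment <- function(config = synthetic_config()) {
  base <- config$base
  if (abs(sum(base) - 100) > 0.5) {
    stop("base composition must sum to 100 (got ", sum(base), ")")
  }
  base <- 100 * base / sum(base)
  effects <- config$effects
  if (!all(rownames(effects) %in% names(base))) {
    stop("effect table species missing from base composition")
  }
  set.seed(stage_seed(config, "profile"))
  conditions <- c("Mock", colnames(effects))
  out <- lapply(conditions, function(cond) {
    eff <- if (cond == "Mock") stats::setNames(rep(0, length(base)), names(base))
           else stats::setNames(effects[names(base), cond], names(base))
    m <- sapply(seq_len(config$n_replicates), function(r) {
      base * (1 + eff / 100) *
        stats::rlnorm(length(base), 0, config$lane_cv)
    })
    rownames(m) <- names(base)
    colnames(m) <- paste0("rep", seq_len(config$n_replicates))
    m
  })
  names(out) <- conditions
  out
}

#' Simulate sucrose-gradient radioactivity profiles
#'
#' The loaded radioactivity is split into a DRM bump (fractions 5-6), an HD
#' bump (fractions 10-11) and a low-level remainder over the other fractions;
#' the DRM/(DRM+HD) share is genotype-specific. Small multiplicative noise is
#' applied per fraction and the profile rescaled so the fractions sum exactly
#' to the loaded amount.
#'
#' @param config a `synthetic_config`.
#' @return Named list of `gradient_profile`, one per genotype in
#'   `config$drm_share`.
#' @export
simulate_gradient <- function(config = synthetic_config()) {
  set.seed(stage_seed(config, "gradient"))
  L <- config$loaded_nCi
  b <- config$bulk_share
  rest_fracs <- c(1:4, 7:9)
  out <- lapply(names(config$drm_share), function(g) {
    s <- config$drm_share[[g]]
    f <- numeric(11)
    f[c(5, 6)] <- b * s * c(0.55, 0.45)
    f[c(10, 11)] <- b * (1 - s) * c(0.5, 0.5)
    f[rest_fracs] <- (1 - b) / length(rest_fracs)
    f <- f * stats::rlnorm(11, 0, config$gradient_cv)
    f <- L * f / sum(f)
    gradient_profile(f, loaded_nCi = L)
  })
  names(out) <- names(config$drm_share)
  out
}

#' Simulate a fluorogenic enzyme time course with matched standards
#'
#' Linear product accumulation at `true_activity` (pmol/h per normalizer
#' unit) read out as fluorescence through a known calibration line, with
#' Gaussian noise on both the time course and the standards.
#'
#' @param true_activity pmol product per hour per normalizer unit (>= 0).
#' @param config a `synthetic_config`.
#' @param time_h sampling times (h).
#' @param normalizer mg protein (or 10^6 cells) in the assay.
#' @param cal_slope,cal_intercept true fluorescence-per-pmol calibration.
#' @return A list with `record` (an `assay_record`) and `standards`
#'   (data.frame for [fit_calibration()]).
#' @export
simulate_kinetics <- function(true_activity, config = synthetic_config(),
                              time_h = c(0, 1, 2, 4), normalizer = 1,
                              cal_slope = 2, cal_intercept = 5) {
  stopifnot(true_activity >= 0)
  set.seed(stage_seed(config, "kinetics"))
  std_pmol <- c(0, 5, 10, 20, 40)
  standards <- data.frame(
    pmol = std_pmol,
    fluorescence = cal_intercept + cal_slope * std_pmol +
      stats::rnorm(length(std_pmol), 0, config$kinetics_sigma)
  )
  pmol <- true_activity * normalizer * time_h
  fl <- cal_intercept + cal_slope * pmol +
    stats::rnorm(length(time_h), 0, config$kinetics_sigma)
  list(
    record = assay_record(time_h, fl, normalizer = normalizer),
    standards = standards
  )
}
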