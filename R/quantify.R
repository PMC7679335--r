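#' Sphingolipid composition profile from HPTLC lane intensities
#'
#' Converts a lane table (rows = sphingolipid species, columns = replicates;
#' densitometry or radioactivity units) into percent-of-total composition:
#' per replicate each species is expressed as 100 x signal / total lane
#' signal, then averaged across replicates. An optional row named
#' `background` is subtracted from every species row first; negatives after
#' subtraction are clipped to zero with a warning.
#'
#' @param lanes numeric matrix or data.frame, species in rows (rownames),
#'   replicates in columns.
#' @return An object of class `sl_profile`: data.frame with `species`,
#'   `mean_percent`, `sd_percent`, `n`; per-replicate percentages in
#'   attribute `"replicates"`.
#' @examples
#' composition_from_lanes(matrix(c(50, 50), 2, 1,
#'   dimnames = list(c("A", "B"), "r1")))
#' @export
composition_from_lanes <- function(lanes) {
  m <- as.matrix(lanes)
  if (is.null(rownames(m))) stop("lane table needs species rownames")
  storage.mode(m) <- "numeric"
  bg_row <- tolower(rownames(m)) == "background"
  if (any(bg_row)) {
    bg <- m[which(bg_row)[1], , drop = TRUE]
    m <- m[!bg_row, , drop = FALSE]
    m <- sweep(m, 2, bg, "-")
    if (any(m < 0)) {
      warning("negative signals after background subtraction clipped to 0")
      m[m < 0] <- 0
    }
  }
  if (ncol(m) < 1) stop("need at least one replicate")
  totals <- colSums(m)
  if (any(totals <= 0)) {
    bad <- colnames(m)[totals <= 0]
    if (is.null(bad)) bad <- which(totals <= 0)
    stop("replicate(s) with no signal: ", paste(bad, collapse = ", "))
  }
  pct <- sweep(m, 2, totals, "/") * 100
  out <- data.frame(
    species = rownames(m),
    mean_percent = rowMeans(pct),
    sd_percent = apply(pct, 1, stats::sd),
    n = ncol(pct),
    row.names = NULL
  )
  if (ncol(pct) == 1) out$sd_percent <- 0
  attr(out, "replicates") <- pct
  class(out) <- c("sl_profile", "data.frame")
  out
}

#' Percent change of each species relative to a reference (Mock) condition
#'
#' Fold-change semantics of the genotype comparisons: per species,
#' `100 * (sample - mock) / mock`. Inputs may be `sl_profile` objects or
#' plain per-species vectors/data.frames of totals (the preferred input is
#' the absolute per-species signal at matched loading). When both inputs
#' carry SDs, the SD of the change is propagated to first order:
#' `|100/m| * sqrt(ss^2 + (s/m)^2 sm^2)`. A zero mock value yields `NA` with
#' a warning.
#'
#' @param sample,mock `sl_profile`, or named numeric vector, or data.frame
#'   with columns `species` and `mean` (optionally `sd`).
#' @return An object of class `fold_change`: data.frame with `species`,
#'   `percent_change`, `sd`.
#' @examples
#' percent_change(c(LacCer = 58), c(LacCer = 100))$percent_change # -42
#' @export
percent_change <- function(sample, mock) {
  s <- as_species_stats(sample)
  m <- as_species_stats(mock)
  if (!setequal(s$species, m$species)) {
    stop("sample and mock must cover the same species")
  }
  m <- m[match(s$species, m$species), , drop = FALSE]
  zero <- m$mean == 0
  if (any(zero)) {
    warning("mock value 0 for: ", paste(s$species[zero], collapse = ", "),
            "; change undefined, reported as NA")
  }
  change <- ifelse(zero, NA_real_, 100 * (s$mean - m$mean) / m$mean)
  sd_out <- ifelse(
    zero, NA_real_,
    (100 / abs(m$mean)) * sqrt(s$sd^2 + (s$mean / m$mean)^2 * m$sd^2)
  )
  out <- data.frame(species = s$species, percent_change = change, sd = sd_out,
                    row.names = NULL)
  class(out) <- c("fold_change", "data.frame")
  out
}

as_species_stats <- function(x) {
  if (inherits(x, "sl_profile")) {
    return(data.frame(species = x$species, mean = x$mean_percent,
                      sd = x$sd_percent))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.frame(species = names(x), mean = as.numeric(x), sd = 0))
  }
  if (is.data.frame(x)) {
    mean_col <- intersect(c("mean", "mean_percent", "value", "nCi"), names(x))[1]
    if (is.na(mean_col) || !"species" %in% names(x)) {
      stop("data.frame input needs 'species' and a mean/value column")
    }
    sd_col <- intersect(c("sd", "sd_percent"), names(x))[1]
    return(data.frame(species = x$species, mean = x[[mean_col]],
                      sd = if (is.na(sd_col)) 0 else x[[sd_col]]))
  }
  stop("unsupported input type for species statistics")
}

#' Sucrose-gradient profile with DRM/HD pooling
#'
#' @param nCi numeric vector of 11 fraction radioactivities, fraction 1 = top
#'   of the tube.
#' @param loaded_nCi total radioactivity loaded on the gradient (optional;
#'   enables recovery computation).
#' @param drm_fractions,hd_fractions fraction indices pooled as
#'   detergent-resistant membranes and as the high-density (soluble)
#'   fraction. The defaults (5-6 and 10-11) follow the caveolin-1 / calnexin
#'   marker distribution; other gradients can pool differently.
#' @return An object of class `gradient_profile`.
#' @export
gradient_profile <- function(nCi, loaded_nCi = NA_real_,
                             drm_fractions = c(5, 6), hd_fractions = c(10, 11)) {
  if (length(nCi) != 11) stop("expected 11 fractions, got ", length(nCi))
  if (any(nCi < 0)) stop("fraction radioactivities must be non-negative")
  structure(
    list(nCi = as.numeric(nCi), loaded_nCi = loaded_nCi,
         drm_fractions = drm_fractions, hd_fractions = hd_fractions),
    class = "gradient_profile"
  )
}

#' Summarize a gradient profile
#'
#' Per-fraction percent of the recovered total, pooled DRM and HD
#' radioactivity, the DRM share `DRM / (DRM + HD)`, and — when the loaded
#' amount is known — the recovery `sum(fractions) / loaded`.
#'
#' @param profile a `gradient_profile` (or a bare numeric vector of 11
#'   fractions).
#' @param loaded_nCi overrides the profile's loaded amount.
#' @return A list with `percent` (length 11), `drm_nCi`, `hd_nCi`,
#'   `drm_share`, `recovered_nCi`, `recovery`.
#' @examples
#' gradient_analysis(gradient_profile(rep(1, 11)))$drm_share # 0.5
#' @export
gradient_analysis <- function(profile, loaded_nCi = NULL) {
  if (!inherits(profile, "gradient_profile")) profile <- gradient_profile(profile)
  if (!is.null(loaded_nCi)) profile$loaded_nCi <- loaded_nCi
  total <- sum(profile$nCi)
  drm <- sum(profile$nCi[profile$drm_fractions])
  hd <- sum(profile$nCi[profile$hd_fractions])
  list(
    percent = if (total > 0) 100 * profile$nCi / total else rep(NA_real_, 11),
    drm_nCi = drm,
    hd_nCi = hd,
    drm_share = if (drm + hd > 0) drm / (drm + hd) else NA_real_,
    recovered_nCi = total,
    recovery = if (is.na(profile$loaded_nCi)) NA_real_ else total / profile$loaded_nCi
  )
}

#' Per-species change in the pooled DRM fraction
#'
#' [percent_change()] applied to per-species radioactivity pooled over the
#' DRM fractions, the comparison behind the lipid-raft genotype figures.
#'
#' @param drm_sample,drm_mock per-species nCi in the pooled DRM fractions
#'   (named vectors, data.frames, or `sl_profile`s).
#' @return A `fold_change` table.
#' @examples
#' drm_species_change(c(Cer = 0.2), c(Cer = 1.0))$percent_change # -80
#' @export
drm_species_change <- function(drm_sample, drm_mock) {
  percent_change(drm_sample, drm_mock)
}

#' Compare replicate groups (Welch t or one-way ANOVA)
#'
#' Two groups are compared with Welch's unequal-variance t test; three or
#' more with one-way ANOVA.
#'
#' @param groups named list of numeric replicate vectors (>= 2 groups, each
#'   with >= 2 replicates).
#' @return A list: `method` (`"welch_t"` or `"anova"`), `statistic`, `p_value`,
#'   `df`.
#' @export
group_compare <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes < 2)) stop("each group needs >= 2 replicates")
  if (length(groups) == 2) {
    constant <- vapply(groups, function(g) stats::sd(g) == 0, TRUE)
    if (all(constant) && groups[[1]][1] == groups[[2]][1]) {
      return(list(method = "welch_t", statistic = 0, p_value = 1,
                  df = sum(sizes) - 2))
    }
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
    list(method = "welch_t", statistic = unname(tt$statistic),
         p_value = tt$p.value, df = unname(tt$parameter))
  } else {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(seq_along(groups), sizes))
    fit <- stats::aov(values ~ fac)
    s <- summary(fit)[[1]]
    list(method = "anova", statistic = s[["F value"]][1],
         p_value = s[["Pr(>F)"]][1], df = s[["Df"]])
  }
}

#' Read a lane table / gradient CSV
#'
#' Lane CSV: first column `species`, remaining columns one per replicate.
#' Gradient CSV: columns `fraction` (1-11) and `nCi`.
#'
#' @param path CSV file.
#' @return `read_lane_csv`: numeric matrix with species rownames;
#'   `read_gradient_csv`: a `gradient_profile`.
#' @export
read_lane_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- tab[[1]]
  m
}

#' @rdname read_lane_csv
#' @param loaded_nCi loaded radioactivity annotation.
#' @export
read_gradient_csv <- function(path, loaded_nCi = NA_real_) {
  tab <- utils::read.csv(path)
  if (!all(c("fraction", "nCi") %in% names(tab))) {
    stop("gradient CSV needs columns 'fraction' and 'nCi'")
  }
  tab <- tab[order(tab$fraction), ]
  gradient_profile(tab$nCi, loaded_nCi = loaded_nCi)
}
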