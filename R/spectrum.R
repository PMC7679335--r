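#' Construct an MS2 spectrum (centroided peak list)
#'
#' @param mz,intensity numeric vectors of equal length; intensities must be
#'   non-negative. Peaks are stored sorted by m/z.
#' @param precursor_mz,precursor_charge optional precursor annotation; for
#'   negative mode, `precursor_charge` is the absolute charge (1 or 2).
#' @param metadata free-form named list.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(mz, intensity = rep(1, length(mz)),
                     precursor_mz = NA_real_, precursor_charge = NA_integer_,
                     metadata = list()) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative")
  o <- order(mz)
  structure(
    list(
      peaks = data.frame(mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o])),
      precursor_mz = precursor_mz,
      precursor_charge = as.integer(precursor_charge),
      metadata = metadata
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d peaks, precursor %.4f (z=%s)>\n",
              nrow(x$peaks), x$precursor_mz,
              ifelse(is.na(x$precursor_charge), "?", x$precursor_charge)))
  invisible(x)
}

#' Match theoretical ions to observed peaks
#'
#' Each theoretical ion is matched to the nearest observed peak within `tol`
#' (ties broken by smaller |delta|, then higher intensity). One observed peak
#' may serve several isobaric theoretical ions. Intensities never influence
#' identity, only the optional relative-intensity floor.
#'
#' @param theoretical an `ion_table` (or any data.frame with an `mz` column).
#' @param spec a `spectrum`.
#' @param tol match tolerance in Da (default 0.10, unit-resolution ion trap).
#' @param min_rel_intensity fraction of the base peak an observed peak must
#'   reach to count as present (default 0: any detected ion counts).
#' @return A data.frame of class `match_report`: the theoretical columns plus
#'   `matched`, `observed_mz`, `delta` (observed - theoretical),
#'   `observed_intensity`; attribute `tol`.
#' @export
match_peaks <- function(theoretical, spec, tol = 0.10, min_rel_intensity = 0) {
  stopifnot(tol > 0, min_rel_intensity >= 0, min_rel_intensity <= 1)
  theoretical <- as.data.frame(theoretical)
  pk <- spec$peaks
  if (nrow(pk) && min_rel_intensity > 0) {
    pk <- pk[pk$intensity >= min_rel_intensity * max(pk$intensity), , drop = FALSE]
  }
  n <- nrow(theoretical)
  matched <- logical(n)
  obs_mz <- obs_int <- delta <- rep(NA_real_, n)
  if (nrow(pk)) {
    for (i in seq_len(n)) {
      d <- pk$mz - theoretical$mz[i]
      ok <- which(abs(d) <= tol)
      if (length(ok)) {
        best <- ok[order(abs(d[ok]), -pk$intensity[ok])][1]
        matched[i] <- TRUE
        obs_mz[i] <- pk$mz[best]
        obs_int[i] <- pk$intensity[best]
        delta[i] <- d[best]
      }
    }
  }
  out <- cbind(theoretical,
               data.frame(matched = matched, observed_mz = obs_mz,
                          delta = delta, observed_intensity = obs_int))
  attr(out, "tol") <- tol
  class(out) <- c("match_report", "data.frame")
  out
}

#' Is an ion present in a spectrum?
#'
#' @param spec a `spectrum`.
#' @param target_mz m/z to look for.
#' @param tol tolerance in Da.
#' @param min_rel_intensity relative-intensity floor (fraction of base peak).
#' @return `TRUE` iff a peak within `tol` exists at or above the floor.
#' @export
is_present <- function(spec, target_mz, tol = 0.10, min_rel_intensity = 0) {
  stopifnot(min_rel_intensity >= 0, min_rel_intensity <= 1)
  pk <- spec$peaks
  if (!nrow(pk)) return(FALSE)
  floorv <- min_rel_intensity * max(pk$intensity)
  any(abs(pk$mz - target_mz) <= tol & pk$intensity >= floorv)
}

# ---------------------------------------------------------------------------
# peak-list IO: two-column CSV and a minimal MGF dialect

#' Read / write peak lists
#'
#' `read_peaklist_csv` accepts a two-column (mz, intensity) CSV, header
#' optional; a single-column file is read as m/z with unit intensities.
#' `read_mgf` reads the first `BEGIN IONS` block of a minimal MGF dialect
#' (`PEPMASS`, `CHARGE` accepting both `2-` and `-2`). The writers mirror the
#' readers.
#'
#' @param path file path.
#' @param precursor_mz,precursor_charge annotation attached to CSV-read
#'   spectra (CSV carries none).
#' @return A `spectrum`.
#' @export
read_peaklist_csv <- function(path, precursor_mz = NA_real_,
                              precursor_charge = NA_integer_) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*-?[0-9.]+\\s*(,|$)", first)
  tab <- utils::read.csv(path, header = has_header)
  if (ncol(tab) == 1) tab$intensity <- 1
  spectrum(tab[[1]], tab[[2]],
           precursor_mz = precursor_mz, precursor_charge = precursor_charge)
}

#' @rdname read_peaklist_csv
#' @param spec a `spectrum`.
#' @export
write_peaklist_csv <- function(spec, path) {
  utils::write.csv(spec$peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_peaklist_csv
#' @export
read_mgf <- function(path) {
  lines <- trimws(readLines(path))
  beg <- which(lines == "BEGIN IONS")[1]
  end <- which(lines == "END IONS")[1]
  if (is.na(beg) || is.na(end) || end < beg) stop("no BEGIN IONS/END IONS block in ", path)
  block <- lines[(beg + 1):(end - 1)]
  is_kv <- grepl("=", block, fixed = TRUE)
  kv <- strsplit(block[is_kv], "=", fixed = TRUE)
  keys <- toupper(vapply(kv, `[`, "", 1))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
  pm <- NA_real_; ch <- NA_integer_
  if ("PEPMASS" %in% keys) {
    pm <- as.numeric(strsplit(trimws(vals[keys == "PEPMASS"][1]), "\\s+")[[1]][1])
  }
  if ("CHARGE" %in% keys) {
    raw <- trimws(vals[keys == "CHARGE"][1])
    ch <- as.integer(gsub("[^0-9]", "", raw)) # "2-" and "-2" both -> 2
  }
  meta <- as.list(vals[!keys %in% c("PEPMASS", "CHARGE")])
  names(meta) <- keys[!keys %in% c("PEPMASS", "CHARGE")]
  pk <- block[!is_kv & nzchar(block)]
  if (length(pk)) {
    parts <- strsplit(pk, "[ \t]+")
    mz <- as.numeric(vapply(parts, `[`, "", 1))
    it <- vapply(parts, function(x) if (length(x) > 1) as.numeric(x[2]) else 1, 0)
  } else {
    mz <- numeric(); it <- numeric()
  }
  spectrum(mz, it, precursor_mz = pm, precursor_charge = ch, metadata = meta)
}

#' @rdname read_peaklist_csv
#' @export
write_mgf <- function(spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("BEGIN IONS", con)
  for (k in names(spec$metadata)) {
    writeLines(paste0(k, "=", spec$metadata[[k]]), con)
  }
  if (!is.na(spec$precursor_mz)) {
    writeLines(sprintf("PEPMASS=%.6f", spec$precursor_mz), con)
  }
  if (!is.na(spec$precursor_charge)) {
    writeLines(sprintf("CHARGE=%d-", spec$precursor_charge), con)
  }
  if (nrow(spec$peaks)) {
    writeLines(sprintf("%.6f %.6f", spec$peaks$mz, spec$peaks$intensity), con)
  }
  writeLines("END IONS", con)
  invisible(path)
}
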