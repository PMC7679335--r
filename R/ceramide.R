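#' Ceramide species from lipid shorthand
#'
#' Builds a ceramide from the usual sphingolipid shorthand: a dihydroxy
#' long-chain base such as `"d18:1"` N-acylated with a fatty acid such as
#' `"C24:1"` (the `C` is optional). The neutral monoisotopic mass is the free
#' base plus the free fatty acid minus one water (amide condensation); for a
#' dCn:m base the free-base formula is CnH(2n+3-2m)NO2 and for a Cn:m acid
#' CnH(2n-2m)O2.
#'
#' @param long_chain_base shorthand like `"d18:1"` (only dihydroxy `d` bases
#'   are supported).
#' @param fatty_acid shorthand like `"C24:1"` or `"24:1"`.
#' @return An object of class `ceramide_species` with fields
#'   `long_chain_base`, `fatty_acid`, `neutral_mass` (Da).
#' @examples
#' ceramide("d18:1", "C24:1")$neutral_mass # 647.6216
#' @export
ceramide <- function(long_chain_base = "d18:1", fatty_acid = "C24:1") {
  lcb <- parse_chain(long_chain_base, prefix = "d")
  fa <- parse_chain(fatty_acid, prefix = "C", optional_prefix = TRUE)
  lcb_mass <- elemental_mass(c(C = lcb$n, H = 2 * lcb$n + 3 - 2 * lcb$db, N = 1, O = 2))
  fa_mass <- elemental_mass(c(C = fa$n, H = 2 * fa$n - 2 * fa$db, O = 2))
  structure(
    list(
      long_chain_base = paste0("d", lcb$n, ":", lcb$db),
      fatty_acid = paste0("C", fa$n, ":", fa$db),
      neutral_mass = lcb_mass + fa_mass - mass_constants[["water"]]
    ),
    class = "ceramide_species"
  )
}

#' Parse a combined ceramide shorthand like "d18:1/24:1"
#'
#' @param x shorthand string `"<lcb>/<fa>"`.
#' @return A `ceramide_species`.
#' @export
parse_ceramide <- function(x) {
  if (inherits(x, "ceramide_species")) return(x)
  parts <- strsplit(x, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2) {
    stop("ceramide shorthand must look like 'd18:1/24:1', got: ", x)
  }
  ceramide(parts[1], parts[2])
}

parse_chain <- function(x, prefix, optional_prefix = FALSE) {
  pat <- if (optional_prefix) {
    paste0("^(", prefix, ")?([0-9]+):([0-9]+)$")
  } else {
    paste0("^", prefix, "([0-9]+):([0-9]+)$")
  }
  m <- regmatches(x, regexec(pat, x))[[1]]
  if (!length(m)) stop("cannot parse chain shorthand: ", x)
  n <- as.integer(m[length(m) - 1])
  db <- as.integer(m[length(m)])
  if (db >= n) stop("more double bonds than plausible for ", x)
  list(n = n, db = db)
}

#' The fatty-acyl species observed in human podocyte sphingolipids
#'
#' The chain lengths and unsaturation reported as most abundant (C16:0,
#' C22:0, C24:1, C24:0), each on a d18:1 base. Used as the default candidate
#' set for [infer_ceramide()].
#'
#' @return A named list of `ceramide_species`.
#' @export
default_ceramides <- function() {
  fas <- c("C16:0", "C22:0", "C24:1", "C24:0")
  out <- lapply(fas, function(fa) ceramide("d18:1", fa))
  names(out) <- paste0("d18:1/", sub("^C", "", fas))
  out
}

#' @export
print.ceramide_species <- function(x, ...) {
  cat(sprintf("<ceramide %s/%s  M = %.4f Da>\n",
              x$long_chain_base, sub("^C", "", x$fatty_acid), x$neutral_mass))
  invisible(x)
}

#' @export
format.ceramide_species <- function(x, ...) {
  paste0(x$long_chain_base, "/", sub("^C", "", x$fatty_acid))
}
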