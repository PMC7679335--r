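#' Monoisotopic mass constants
#'
#' Atomic and derived monoisotopic masses used throughout the package. All
#' ion chemistry is negative mode, deprotonated (\eqn{[M-zH]^{z-}}): no
#' adducts, no isotope envelopes.
#'
#' @format A named numeric vector with elements `H`, `C`, `N`, `O`, `P`,
#'   `proton`, `water`, `hydroxide`.
#' @export
mass_constants <- local({
  H <- 1.0078250319
  C <- 12
  N <- 14.0030740052
  O <- 15.9949146221
  P <- 30.97376151
  c(
    H = H, C = C, N = N, O = O, P = P,
    proton = 1.007276,
    # conventional rounded water mass used in the fragment-type arithmetic
    # (within 1e-6 of 2H + O)
    water = 18.010565,
    # neutral cap gained by C-type (and internal C/Y) fragments relative to B
    hydroxide = 18.010565 - 1.007276
  )
})

# monoisotopic mass of an element->count vector, e.g. c(C = 6, H = 10, O = 5)
elemental_mass <- function(composition) {
  stopifnot(all(names(composition) %in% c("H", "C", "N", "O", "P")))
  sum(mass_constants[names(composition)] * composition)
}

#' Monosaccharide residue table
#'
#' Dehydrated (glycosidically linked) residue masses for the four symbols the
#' annotation engine resolves. Glc/Gal are isobaric and both carried as
#' `Hex`; GlcNAc/GalNAc as `HexNAc`. Named structures keep their conventional
#' sugar identities as labels only; masses never distinguish them.
#'
#' @format A data.frame with columns `symbol`, `formula` (text), `mass` (Da).
#' @export
residue_table <- local({
  comps <- list(
    Hex    = c(C = 6, H = 10, O = 5),
    HexNAc = c(C = 8, H = 13, N = 1, O = 5),
    Neu5Ac = c(C = 11, H = 17, N = 1, O = 8),
    dHex   = c(C = 6, H = 10, O = 4)
  )
  data.frame(
    symbol  = names(comps),
    formula = vapply(comps, function(x) paste0(names(x), x, collapse = ""), ""),
    mass    = vapply(comps, elemental_mass, 0),
    row.names = NULL
  )
})

#' Residue mass lookup
#'
#' @param symbol character vector of residue symbols (`Hex`, `HexNAc`,
#'   `Neu5Ac`, `dHex`).
#' @return numeric vector of dehydrated monoisotopic residue masses (Da).
#' @examples
#' residue_mass("Neu5Ac") # 291.0954
#' @export
residue_mass <- function(symbol) {
  i <- match(symbol, residue_table$symbol)
  if (anyNA(i)) {
    stop("unknown residue symbol(s): ",
         paste(unique(symbol[is.na(i)]), collapse = ", "))
  }
  residue_table$mass[i]
}

# mass of a composition given as a named count vector, e.g. c(Hex = 3, Neu5Ac = 1)
composition_mass <- function(composition) {
  composition <- composition[composition > 0]
  if (!length(composition)) return(0)
  sum(residue_mass(names(composition)) * as.numeric(composition))
}

# net mass added to a ceramide by the sphingomyelin phosphocholine headgroup:
# phosphocholine (C5H14NO4P) minus the water of condensation
sm_headgroup_mass <- function() {
  elemental_mass(c(C = 5, H = 14, N = 1, O = 4, P = 1)) - mass_constants[["water"]]
}
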