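#' Neutral monoisotopic mass of a glycosphingolipid
#'
#' Additivity convention: the free ceramide mass plus the sum of dehydrated
#' residue masses over the glycan tree (plus the fixed phosphocholine
#' headgroup for sphingomyelin).
#'
#' @param structure a `gsl_structure` with a specified ceramide.
#' @return Neutral mass in Da.
#' @examples
#' gsl_neutral_mass(build_structure("LacCer", "d18:1/16:0")) # 861.618
#' @export
gsl_neutral_mass <- function(structure) {
  stopifnot(inherits(structure, "gsl_structure"))
  if (is.null(structure$ceramide)) stop("ceramide required")
  structure$ceramide$neutral_mass +
    composition_mass(structure$composition) +
    structure$headgroup_mass
}

#' Deprotonated precursor m/z
#'
#' \eqn{[M-zH]^{z-}} for z = 1 or 2, the only precursor species observed for
#' these lipids in negative-mode ion-trap ESI.
#'
#' @param structure a `gsl_structure` with ceramide.
#' @param charge 1 or 2.
#' @return m/z (Da per charge).
#' @examples
#' precursor_mz(build_structure("GM1b", "d18:1/24:1"), 1) # 1626.95
#' @export
precursor_mz <- function(structure, charge = 1) {
  if (!charge %in% c(1, 2)) stop("unsupported charge: ", charge)
  (gsl_neutral_mass(structure) - charge * mass_constants[["proton"]]) / charge
}

#' m/z of a glycosidic fragment ion from its retained residues
#'
#' Singly charged negative-mode conventions (Domon-Costello glycosidic
#' types): B is the anhydro non-reducing fragment (sum of dehydrated residue
#' masses minus a proton), C = B + water; Y retains the ceramide and the
#' glycosidic oxygen (ceramide + residue sum minus a proton), Z = Y - water.
#' Internal (double-cleavage) fragments follow the same pattern: `CY`
#' carries the C-type cap (+ water), `BY` the B-type cap. Doubly charged
#' fragments: mz2 = (mz1 - proton)/2.
#'
#' @param ion_type one of `"B"`, `"C"`, `"Y"`, `"Z"`, `"BY"`, `"CY"`.
#' @param residues named count vector of retained residues, e.g.
#'   `c(Neu5Ac = 1)`.
#' @param ceramide required for Y/Z ions (a `ceramide_species` or shorthand).
#' @param charge 1 (default) or 2.
#' @return m/z (Da per charge).
#' @examples
#' fragment_mz("B", c(Neu5Ac = 1))            # 290.088
#' fragment_mz("C", c(Neu5Ac = 1, Hex = 1))   # 470.151
#' @export
fragment_mz <- function(ion_type, residues, ceramide = NULL, charge = 1) {
  if (!ion_type %in% c("B", "C", "Y", "Z", "BY", "CY")) {
    stop("invalid cleavage: unknown ion type '", ion_type, "'")
  }
  if (!charge %in% c(1, 2)) stop("unsupported charge: ", charge)
  res_sum <- composition_mass(residues)
  p <- mass_constants[["proton"]]
  w <- mass_constants[["water"]]
  mz1 <- switch(ion_type,
    B  = res_sum - p,
    BY = res_sum - p,
    C  = res_sum + w - p,
    CY = res_sum + w - p,
    Y  = {
      if (is.null(ceramide)) stop("invalid cleavage: Y ion requires a ceramide")
      parse_ceramide(ceramide)$neutral_mass + res_sum - p
    },
    Z  = {
      if (is.null(ceramide)) stop("invalid cleavage: Z ion requires a ceramide")
      parse_ceramide(ceramide)$neutral_mass + res_sum - p - w
    }
  )
  if (charge == 1) mz1 else (mz1 - p) / 2
}

# descendant node ids (including `node`) in a topology, from the parent vector
subtree_nodes <- function(topology, node) {
  out <- node
  frontier <- node
  while (length(frontier)) {
    frontier <- topology$node[topology$parent %in% frontier]
    out <- c(out, frontier)
  }
  out
}

res_key <- function(residues) composition_key(residues)

count_residues <- function(topology, nodes) {
  composition_of(topology[topology$node %in% nodes, , drop = FALSE])
}

#' Enumerate theoretical fragment ions
#'
#' Cuts every combination of up to `max_cleavages` glycosidic bonds of the
#' structure (each node's bond to its parent; the root's bond is the
#' glycan-ceramide bond) and emits the resulting ions, deduplicated by
#' (ion type, retained residue multiset, charge) and sorted by m/z. A single
#' cut yields B/C (non-reducing side) and Y/Z (ceramide side); two nested
#' cuts yield an internal fragment (`BY`/`CY` types); two cuts on disjoint
#' branches yield a double-loss Y (and Z). The uncut precursor is included
#' when `"precursor"` is among `ion_types`. Sphingomyelin and ceramide-only
#' entries produce precursors only.
#'
#' @param structure `gsl_structure` with ceramide.
#' @param max_cleavages 1 or 2.
#' @param ion_types subset of `c("precursor","B","C","Y","Z","BY","CY")`.
#' @param charges fragment charges to emit (precursors are emitted at each
#'   charge too), default 1.
#' @return A data.frame of class `ion_table` with columns `ion_type`,
#'   `residues` (composition key), `n_cleavages`, `charge`, `mz`.
#' @export
enumerate_fragments <- function(structure,
                                max_cleavages = 2,
                                ion_types = c("precursor", "B", "C", "Y", "Z", "BY", "CY"),
                                charges = 1) {
  stopifnot(inherits(structure, "gsl_structure"), max_cleavages %in% 1:2)
  topo <- structure$topology
  cer <- structure$ceramide
  if (is.null(cer)) stop("ceramide required")
  rows <- list()
  add <- function(type, residues, ncl) {
    if (!type %in% ion_types) return()
    for (z in charges) {
      rows[[length(rows) + 1L]] <<- list(
        ion_type = type, residues = res_key(residues),
        n_cleavages = ncl, charge = z,
        mz = fragment_mz(type, residues, cer, z)
      )
    }
  }
  if ("precursor" %in% ion_types) {
    for (z in unique(c(charges))) {
      rows[[length(rows) + 1L]] <- list(
        ion_type = "precursor", residues = res_key(structure$composition),
        n_cleavages = 0L, charge = z, mz = precursor_mz(structure, z)
      )
    }
  }
  if (structure$fragmentable && nrow(topo) > 0) {
    subs <- lapply(topo$node, function(nd) subtree_nodes(topo, nd))
    all_nodes <- topo$node
    for (e in topo$node) {
      nr <- subs[[e]]
      add("B", count_residues(topo, nr), 1L)
      add("C", count_residues(topo, nr), 1L)
      red <- setdiff(all_nodes, nr)
      add("Y", count_residues(topo, red), 1L)
      add("Z", count_residues(topo, red), 1L)
    }
    if (max_cleavages >= 2 && nrow(topo) >= 2) {
      for (i in seq_len(nrow(topo) - 1L)) {
        for (j in (i + 1L):nrow(topo)) {
          e1 <- topo$node[i]; e2 <- topo$node[j]
          s1 <- subs[[e1]]; s2 <- subs[[e2]]
          if (e2 %in% s1) {
            mid <- setdiff(s1, s2)
            add("BY", count_residues(topo, mid), 2L)
            add("CY", count_residues(topo, mid), 2L)
          } else if (e1 %in% s2) {
            mid <- setdiff(s2, s1)
            add("BY", count_residues(topo, mid), 2L)
            add("CY", count_residues(topo, mid), 2L)
          } else {
            red <- setdiff(topo$node, union(s1, s2))
            add("Y", count_residues(topo, red), 2L)
            add("Z", count_residues(topo, red), 2L)
          }
        }
      }
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(ion_type = r$ion_type, residues = r$residues,
               n_cleavages = r$n_cleavages, charge = r$charge, mz = r$mz,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(ion_type = character(), residues = character(),
                      n_cleavages = integer(), charge = integer(),
                      mz = numeric(), stringsAsFactors = FALSE)
  }
  key <- paste(out$ion_type, out$residues, out$charge)
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ion_table", "data.frame")
  out
}

#' Infer the ceramide species from an observed precursor m/z
#'
#' Given a glycan composition and the observed (de)protonation state, picks
#' the allowed ceramide whose theoretical precursor lies nearest the
#' observation and within `tol`. Errors on no match and on ambiguity (two
#' candidates both within `tol`).
#'
#' @param observed_mz observed precursor m/z.
#' @param charge 1 or 2.
#' @param composition glycan residue counts.
#' @param allowed list of `ceramide_species` (default: the podocyte fatty
#'   acyl set, [default_ceramides()]).
#' @param tol tolerance in Da (on the m/z axis).
#' @param registry used only to pick up headgroup conventions via
#'   `build_structure`; composition-based structures carry none.
#' @return The matching `ceramide_species`.
#' @examples
#' infer_ceramide(945.51, 2, c(Hex = 3, HexNAc = 1, Neu5Ac = 2))$fatty_acid
#' @export
infer_ceramide <- function(observed_mz, charge, composition,
                           allowed = default_ceramides(), tol = 0.15) {
  stopifnot(length(allowed) > 0, tol > 0)
  p <- mass_constants[["proton"]]
  glycan <- composition_mass(composition)
  theo <- vapply(allowed, function(cer) {
    (cer$neutral_mass + glycan - charge * p) / charge
  }, 0)
  delta <- abs(theo - observed_mz)
  within <- which(delta <= tol)
  if (!length(within)) {
    stop("no ceramide assignment: nearest candidate is ",
         sprintf("%.3f", min(delta)), " Da/charge away (tol ", tol, ")")
  }
  if (length(within) > 1) {
    stop("ambiguous ceramide: ",
         paste(vapply(allowed[within], format, ""), collapse = ", "),
         " all within tol ", tol)
  }
  allowed[[within]]
}

#' Write a theoretical ion table as CSV
#'
#' @param ions an `ion_table` from [enumerate_fragments()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ion_table <- function(ions, path) {
  utils::write.csv(as.data.frame(ions), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
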