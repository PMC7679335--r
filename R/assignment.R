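#' In-silico Vibrio cholerae sialidase digestion
#'
#' Removes sialic acids according to the lability rule calibrated on the
#' observed conversions (GM1b to GA1; GD1alpha to GM1 plus GA1; GM1a
#' untouched): a Neu5Ac is RESISTANT iff it sits on a backbone hexose that is
#' extended toward the non-reducing end (a chain-internal Hex, as in
#' GM1a/GM1c-type sialylation); every other Neu5Ac — on a terminal residue,
#' on a HexNAc, or the outer unit of a disialyl element — is labile.
#'
#' In `exhaustive` mode labile residues are removed iteratively to a fixed
#' point (the enzyme is given unlimited time); in `single_step` mode each
#' labile Neu5Ac is removed once in turn, giving the set of one-cut
#' intermediates. Products are renamed by topology lookup in the registry;
#' unnamed topologies get a descriptive composition placeholder.
#'
#' Note on the sialylated globopentaosylceramides: the asialo backbone
#' product predicted here is Gb5Cer (the same globo backbone), even where
#' comigration shorthand would call the product band "GA1".
#'
#' @param structure a `gsl_structure`.
#' @param mode `"exhaustive"` (default) or `"single_step"`.
#' @param registry registry used to rename products.
#' @return A list of `gsl_structure` products (deduplicated; for exhaustive
#'   mode a single structure).
#' @examples
#' sialidase_digest(build_structure("GM1b"))[[1]]$name # "GA1"
#' @export
sialidase_digest <- function(structure, mode = c("exhaustive", "single_step"),
                             registry = default_registry()) {
  mode <- match.arg(mode)
  topo <- structure$topology
  if (mode == "exhaustive") {
    repeat {
      lab <- labile_neu5ac(topo)
      if (!length(lab)) break
      topo <- drop_nodes(topo, lab)
    }
    return(list(rename_product(structure, topo, registry)))
  }
  lab <- labile_neu5ac(topo)
  products <- lapply(lab, function(nd) {
    rename_product(structure, drop_nodes(topo, nd), registry)
  })
  keys <- vapply(products, function(p) canonical_topology_string(p$topology), "")
  products[!duplicated(keys)]
}

# node ids of labile Neu5Ac residues
labile_neu5ac <- function(topo) {
  if (!nrow(topo)) return(integer())
  neu <- topo$node[topo$residue == "Neu5Ac"]
  Filter(function(nd) {
    par <- topo$parent[topo$node == nd]
    if (par == 0) return(TRUE) # directly on ceramide: nothing protects it
    par_row <- topo[topo$node == par, ]
    if (par_row$residue != "Hex" || par_row$role != "backbone") return(TRUE)
    kids <- topo[topo$parent == par, , drop = FALSE]
    !any(kids$role == "backbone") # internal Hex (extended chain) protects
  }, neu)
}

# remove nodes (must be leaves or whole subtrees are removed) and renumber
drop_nodes <- function(topo, nodes) {
  gone <- unique(unlist(lapply(nodes, function(nd) subtree_nodes(topo, nd))))
  keep <- topo[!topo$node %in% gone, , drop = FALSE]
  remap <- stats::setNames(seq_len(nrow(keep)), keep$node)
  glycan_topology(
    keep$residue,
    ifelse(keep$parent == 0, 0L, as.integer(remap[as.character(keep$parent)])),
    keep$role, keep$label
  )
}

rename_product <- function(substrate, topo, registry) {
  key <- canonical_topology_string(topo)
  hit <- names(registry)[vapply(
    registry, function(e) canonical_topology_string(e$topology) == key, TRUE
  )]
  name <- if (length(hit)) {
    hit[1]
  } else {
    comp <- composition_of(topo)
    paste0("[", paste(names(comp), comp, sep = "", collapse = " "), " isomer]")
  }
  new_gsl_structure(name, topo, substrate$ceramide,
                    fragmentable = substrate$fragmentable,
                    headgroup_mass = substrate$headgroup_mass)
}

#' Record an exoglycosidase digestion observation
#'
#' What comigration on the thin-layer plate showed after sialidase
#' treatment: product names may be generic migration classes (`"GM1"`,
#' `"GD1"`) that cannot distinguish sialylation-site isomers.
#'
#' @param substrate substrate name (informational).
#' @param products character vector of observed product names.
#' @param completeness `"exhaustive"` if the digestion ran to completion (all
#'   products are end points), `"partial"` if intermediates were seen too.
#' @return An object of class `digestion_observation`.
#' @export
digestion_observation <- function(substrate, products,
                                  completeness = c("exhaustive", "partial")) {
  structure(list(substrate = substrate, products = products,
                 completeness = match.arg(completeness)),
            class = "digestion_observation")
}

# composition for an observed product name: registry names/aliases plus the
# generic migration classes used in comigration calls
name_composition <- function(name, registry) {
  generic <- list(
    GM1 = c(Hex = 3, HexNAc = 1, Neu5Ac = 1),
    GD1 = c(Hex = 3, HexNAc = 1, Neu5Ac = 2),
    GT1 = c(Hex = 3, HexNAc = 1, Neu5Ac = 3)
  )
  if (name %in% names(generic)) return(generic[[name]])
  key <- tryCatch(resolve_name(name, registry), error = function(e) NULL)
  if (is.null(key)) stop("cannot interpret product name '", name, "'")
  composition_of(registry[[key]]$topology)
}

# does a candidate's predicted digestion behaviour agree with what was seen?
digestion_consistent <- function(candidate, obs, registry) {
  exhaust <- sialidase_digest(candidate, "exhaustive", registry)
  singles <- sialidase_digest(candidate, "single_step", registry)
  predicted <- if (obs$completeness == "exhaustive") {
    exhaust
  } else {
    c(list(candidate), singles, exhaust)
  }
  pred_keys <- unique(vapply(predicted, function(p) composition_key(p$composition), ""))
  obs_keys <- vapply(obs$products,
                     function(nm) composition_key(name_composition(nm, registry)), "")
  if (!all(obs_keys %in% pred_keys)) return(FALSE)
  if (obs$completeness == "exhaustive") {
    # end points must be fully accounted for in both directions
    return(all(pred_keys %in% obs_keys))
  }
  TRUE
}

#' Derive diagnostic ions for an isomer candidate set
#'
#' Enumerates every glycosidic fragment (up to two cleavages, singly charged)
#' of each candidate, merges the pooled m/z values at `tol`, and keeps the
#' clusters produced by a proper, non-empty subset of candidates: those are
#' the ions whose presence or absence can discriminate. Precursors are never
#' diagnostic (the candidates are isobaric by construction).
#'
#' @param candidates list of `gsl_structure` sharing glycan composition; a
#'   common ceramide must be attached (pass `ceramide` to attach one).
#' @param ceramide optional ceramide applied to all candidates.
#' @param tol m/z merge tolerance (Da), default 0.10.
#' @param max_cleavages cleavage depth used for ownership (default 2).
#' @return A data.frame of class `diagnostic_table`: `mz` (mean theoretical
#'   m/z of the cluster), `owners` (comma-separated candidate names),
#'   `n_owners`, `description` (ion type and residues of one representative).
#' @export
derive_diagnostics <- function(candidates, ceramide = NULL, tol = 0.10,
                               max_cleavages = 2) {
  if (length(candidates) < 2) stop("not an isomer set: need >= 2 candidates")
  if (!is.null(ceramide)) {
    candidates <- lapply(candidates, function(s) {
      s$ceramide <- parse_ceramide(ceramide); s
    })
  }
  comps <- vapply(candidates, function(s) composition_key(s$composition), "")
  if (length(unique(comps)) != 1) stop("not an isomer set: compositions differ")
  if (any(vapply(candidates, function(s) is.null(s$ceramide), TRUE))) {
    stop("ceramide required")
  }
  nms <- vapply(candidates, `[[`, "", "name")
  tabs <- lapply(seq_along(candidates), function(i) {
    t <- enumerate_fragments(candidates[[i]], max_cleavages,
                             ion_types = c("B", "C", "Y", "Z", "BY", "CY"),
                             charges = 1)
    t$candidate <- nms[i]
    t
  })
  pool <- do.call(rbind, tabs)
  pool <- pool[order(pool$mz), , drop = FALSE]
  cl <- cumsum(c(TRUE, diff(pool$mz) > tol))
  rows <- lapply(split(pool, cl), function(g) {
    owners <- sort(unique(g$candidate))
    data.frame(
      mz = mean(unique(g$mz)),
      owners = paste(owners, collapse = ","),
      n_owners = length(owners),
      n_cleavages = min(g$n_cleavages),
      description = paste0(g$ion_type[1], " [", g$residues[1], "]"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[out$n_owners < length(candidates), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("diagnostic_table", "data.frame")
  out
}

#' Assign a structure to an MS2 spectrum among isomer candidates
#'
#' Implements the discrimination procedure used for the podocyte
#' gangliosides: candidates sharing the precursor composition are scored
#' against the spectrum with automatically derived diagnostic ions
#' ([derive_diagnostics()]) and, optionally, against a sialidase digestion
#' observation. A candidate is EXCLUDED when
#' \itemize{
#'   \item at least `presence_votes` (default 2) distinct diagnostic ions it
#'     cannot produce are present in the spectrum, or
#'   \item it solely owns single-cleavage diagnostic ions, none of them is
#'     present, and at least one of its shared (non-diagnostic) sequence ions
#'     is matched (structure-specific evidence collectively missing while
#'     backbone evidence is there; internal double-cleavage diagnostics are
#'     too low-abundance for their absence to count), or
#'   \item its predicted sialidase products contradict the digestion
#'     observation.
#' }
#' The survivor is ASSIGNED when it is the only non-excluded candidate and
#' carries positive evidence: at least `y_threshold` of its single-cleavage
#' Y-series is matched, or it explains at least `coverage_threshold` of the
#' assignable peaks (peaks explained by at least one candidate; contaminant
#' peaks foreign to the whole family are ignored). Curated peak lists often
#' contain only non-reducing-end ions, so either route counts. Anything else
#' is AMBIGUOUS.
#'
#' @param spec a `spectrum`.
#' @param candidates list of `gsl_structure`, or character names resolved
#'   against `registry`.
#' @param ceramide ceramide attached to all candidates (shorthand ok).
#' @param tol match tolerance in Da (default 0.10).
#' @param digestion optional `digestion_observation`.
#' @param y_threshold fraction of the single-cleavage Y-series required
#'   (default 0.5).
#' @param coverage_threshold fraction of observed peaks that must be
#'   explained for the coverage route (default 0.8).
#' @param presence_votes distinct present diagnostics required to exclude a
#'   non-owner (default 2; robust to a single stray noise peak).
#' @param registry structure registry.
#' @return An object of class `assignment_result`: `assigned` (name or `NA`),
#'   `status` per candidate (`assigned`/`compatible`/`excluded`), `evidence`
#'   (per-diagnostic table), `digestion_consistent` flags, `y_fraction`,
#'   `coverage`, `warnings`.
#' @export
assign_structure <- function(spec, candidates, ceramide = NULL, tol = 0.10,
                             digestion = NULL, y_threshold = 0.5,
                             coverage_threshold = 0.8, presence_votes = 2,
                             registry = default_registry()) {
  if (is.character(candidates)) {
    candidates <- lapply(candidates, build_structure,
                         ceramide = ceramide, registry = registry)
  } else if (!is.null(ceramide)) {
    candidates <- lapply(candidates, function(s) {
      s$ceramide <- parse_ceramide(ceramide); s
    })
  }
  if (!length(candidates)) stop("empty candidate list")
  nms <- vapply(candidates, `[[`, "", "name")
  warnings <- character()

  # precursor sanity (single candidate suffices: all are isobaric)
  if (!is.na(spec$precursor_mz)) {
    z <- if (is.na(spec$precursor_charge)) 1L else spec$precursor_charge
    theo_prec <- precursor_mz(candidates[[1]], z)
    if (abs(theo_prec - spec$precursor_mz) > tol) {
      warnings <- c(warnings, sprintf(
        "precursor %.4f (z=%d) is %.3f Da from theoretical %.4f",
        spec$precursor_mz, z, spec$precursor_mz - theo_prec, theo_prec))
    }
  }

  single_candidate <- length(candidates) == 1
  diags <- if (single_candidate) NULL else derive_diagnostics(candidates, tol = tol)

  theo <- lapply(candidates, function(s) {
    enumerate_fragments(s, 2, charges = 1)
  })
  reports <- lapply(theo, match_peaks, spec = spec, tol = tol)

  excluded <- stats::setNames(rep(FALSE, length(nms)), nms)
  reason <- stats::setNames(rep("", length(nms)), nms)
  evidence <- NULL
  if (!single_candidate) {
    present <- vapply(diags$mz, function(m) is_present(spec, m, tol), TRUE)
    owner_list <- strsplit(diags$owners, ",", fixed = TRUE)
    evidence <- cbind(as.data.frame(diags), observed = present)
    for (i in seq_along(nms)) {
      nm <- nms[i]
      owns <- vapply(owner_list, function(o) nm %in% o, TRUE)
      # (a) presence of ions this candidate cannot make
      votes <- sum(present & !owns)
      if (votes >= presence_votes) {
        excluded[nm] <- TRUE
        reason[nm] <- sprintf("%d foreign diagnostic ion(s) present", votes)
        next
      }
      # (b) all solely-owned single-cleavage diagnostics missing while shared
      # ions match; internal (double-cleavage) ions are too low-abundance for
      # their absence to count against a candidate
      sole <- owns & diags$n_owners == 1 & diags$n_cleavages == 1
      if (any(sole) && !any(present[sole])) {
        shared_matched <- any(reports[[i]]$matched &
                                !vapply(reports[[i]]$mz, function(m) {
                                  any(abs(diags$mz - m) <= tol)
                                }, TRUE))
        if (shared_matched) {
          excluded[nm] <- TRUE
          reason[nm] <- sprintf(
            "all %d candidate-specific diagnostic ion(s) absent", sum(sole))
        }
      }
    }
  }

  digestion_ok <- stats::setNames(rep(NA, length(nms)), nms)
  if (!is.null(digestion)) {
    for (i in seq_along(nms)) {
      ok <- digestion_consistent(candidates[[i]], digestion, registry)
      digestion_ok[nms[i]] <- ok
      if (!ok && !excluded[nms[i]]) {
        excluded[nms[i]] <- TRUE
        reason[nms[i]] <- "sialidase products contradict observation"
      } else if (!ok) {
        reason[nms[i]] <- paste0(reason[nms[i]], " + digestion contradiction")
      }
    }
  }

  # positive evidence per candidate; "coverage" is the share of assignable
  # peaks (those explained by at least one candidate) this candidate
  # explains, so contaminant peaks foreign to the whole isomer family do not
  # dilute it
  y_fraction <- coverage <- stats::setNames(rep(NA_real_, length(nms)), nms)
  explained_by <- vapply(seq_along(nms), function(i) {
    vapply(spec$peaks$mz, function(m) any(abs(reports[[i]]$mz - m) <= tol), TRUE)
  }, logical(nrow(spec$peaks)))
  explained_by <- matrix(explained_by, nrow = nrow(spec$peaks))
  assignable <- rowSums(explained_by) > 0
  n_obs <- sum(assignable)
  for (i in seq_along(nms)) {
    rep_i <- reports[[i]]
    ys <- rep_i[rep_i$ion_type == "Y" & rep_i$n_cleavages == 1, , drop = FALSE]
    y_fraction[nms[i]] <- if (nrow(ys)) mean(ys$matched) else 0
    coverage[nms[i]] <- if (n_obs) mean(explained_by[assignable, i]) else 0
  }

  survivors <- nms[!excluded]
  assigned <- NA_character_
  status <- stats::setNames(ifelse(excluded, "excluded", "compatible"), nms)
  if (length(survivors) == 1) {
    nm <- survivors
    # the coverage route needs a minimally informative spectrum
    if (y_fraction[nm] >= y_threshold ||
        (n_obs >= 3 && coverage[nm] >= coverage_threshold)) {
      assigned <- nm
      status[nm] <- "assigned"
    }
  }
  structure(
    list(
      assigned = assigned, status = status, reason = reason,
      evidence = evidence, digestion_consistent = digestion_ok,
      y_fraction = y_fraction, coverage = coverage,
      tol = tol, warnings = warnings, reports = reports
    ),
    class = "assignment_result"
  )
}

#' @export
print.assignment_result <- function(x, ...) {
  cat("Structure assignment\n")
  for (nm in names(x$status)) {
    cat(sprintf("  %-10s %-10s Y-series %4.0f%%  coverage %4.0f%%  %s\n",
                nm, x$status[nm], 100 * x$y_fraction[nm], 100 * x$coverage[nm],
                x$reason[nm]))
  }
  cat(if (is.na(x$assigned)) "  verdict: ambiguous\n"
      else sprintf("  verdict: %s\n", x$assigned))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Write an assignment result as JSON
#'
#' @param result an `assignment_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_assignment_json <- function(result, path) {
  out <- list(
    assigned = if (is.na(result$assigned)) NULL else result$assigned,
    tolerance = result$tol,
    candidates = lapply(names(result$status), function(nm) {
      list(name = nm, status = unname(result$status[nm]),
           reason = unname(result$reason[nm]),
           y_fraction = unname(result$y_fraction[nm]),
           coverage = unname(result$coverage[nm]),
           digestion_consistent = unname(result$digestion_consistent[nm]))
    }),
    evidence = result$evidence,
    warnings = result$warnings
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}
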