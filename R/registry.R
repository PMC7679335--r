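#' Glycan topologies and the glycosphingolipid structure registry
#'
#' A glycan topology is a rooted tree of monosaccharide residues; the root
#' attaches to the ceramide. Nodes carry a mass-level residue symbol (`Hex`,
#' `HexNAc`, `Neu5Ac`, `dHex`), a conventional sugar label (`Glc`, `Gal`,
#' `GalNAc`, ...; labels are documentation only and never enter any mass),
#' and an attachment role: `backbone` for the neutral core chain, `branch`
#' for substituents (all sialic acids are branches). Glycosidic linkage
#' positions (alpha-2,3 vs alpha-2,6 and so on) are deliberately not modeled:
#' which residue attaches to which is the resolution level that low-energy
#' CID fragmentation and exoglycosidase treatment can actually test.
#'
#' @name glycan-topology
NULL

#' Construct a glycan topology
#'
#' @param residue character vector of residue symbols, one per node; node ids
#'   are `seq_along(residue)`.
#' @param parent integer vector of parent node ids; `0` means the node
#'   attaches to the ceramide (exactly one node must, unless the glycan is
#'   empty).
#' @param role attachment role per node, `"backbone"` or `"branch"`.
#' @param label optional conventional sugar names (documentation only).
#' @return A data.frame of class `glycan_topology` with columns `node`,
#'   `residue`, `parent`, `role`, `label`.
#' @export
glycan_topology <- function(residue = character(), parent = integer(),
                            role = character(), label = residue) {
  n <- length(residue)
  stopifnot(length(parent) == n, length(role) == n, length(label) == n)
  topo <- data.frame(
    node = seq_len(n), residue = as.character(residue),
    parent = as.integer(parent), role = as.character(role),
    label = as.character(label), stringsAsFactors = FALSE
  )
  if (n > 0) {
    residue_mass(topo$residue) # validates symbols
    if (!all(topo$role %in% c("backbone", "branch"))) {
      stop("role must be 'backbone' or 'branch'")
    }
    if (sum(topo$parent == 0) != 1) {
      stop("exactly one node must attach to the ceramide (parent 0)")
    }
    if (any(topo$parent < 0 | topo$parent > n)) stop("parent out of range")
    # every node reachable from the root exactly once (rooted tree)
    reached <- 0L
    frontier <- topo$node[topo$parent == 0]
    while (length(frontier)) {
      reached <- reached + length(frontier)
      frontier <- topo$node[topo$parent %in% frontier]
    }
    if (reached != n) stop("topology is not a connected rooted tree")
  }
  class(topo) <- c("glycan_topology", "data.frame")
  topo
}

# residue -> count named integer vector, fixed symbol order
composition_of <- function(topology) {
  syms <- residue_table$symbol
  counts <- vapply(syms, function(s) sum(topology$residue == s), 0L)
  counts[counts > 0]
}

# inverse of composition_key
parse_composition_key <- function(key) {
  if (!nzchar(key)) return(integer())
  parts <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) as.integer(p[2]), 0L),
                  vapply(parts, `[`, "", 1))
}

subtract_composition <- function(full, part) {
  for (nm in names(part)) {
    full[nm] <- full[nm] - part[nm]
  }
  if (any(full < 0)) stop("composition subtraction went negative")
  full[full > 0]
}

composition_key <- function(composition) {
  composition <- composition[composition > 0]
  if (!length(composition)) return("")
  composition <- composition[order(names(composition))]
  paste(names(composition), composition, sep = ":", collapse = ",")
}

# canonical serialization of a topology (children sorted recursively), used
# for isomer comparison and for renaming digestion products
canonical_topology_string <- function(topology) {
  if (nrow(topology) == 0) return("()")
  kids <- split(topology$node, factor(topology$parent, levels = 0:nrow(topology)))
  render <- function(node) {
    subs <- sort(vapply(kids[[as.character(node)]], render, ""))
    paste0(topology$residue[node], "[", topology$role[node], "]",
           "(", paste(subs, collapse = ","), ")")
  }
  root <- topology$node[topology$parent == 0]
  render(root)
}

new_gsl_structure <- function(name, topology, ceramide = NULL,
                              fragmentable = TRUE, headgroup_mass = 0) {
  structure(
    list(
      name = name, topology = topology, ceramide = ceramide,
      composition = composition_of(topology),
      fragmentable = fragmentable, headgroup_mass = headgroup_mass
    ),
    class = "gsl_structure"
  )
}

#' @export
print.gsl_structure <- function(x, ...) {
  comp <- x$composition
  comp_str <- if (length(comp)) paste(names(comp), comp, sep = ":", collapse = " ") else "none"
  cer <- if (is.null(x$ceramide)) "unspecified" else format(x$ceramide)
  cat(sprintf("<gsl_structure %s | glycan %s | ceramide %s>\n", x$name, comp_str, cer))
  invisible(x)
}

# ---------------------------------------------------------------------------
# default registry

# helper: linear backbone chain from a label string like "Glc-Gal-GalNAc-Gal",
# plus optional branches as list(node = <attach to>, label = <sugar>)
chain_entry <- function(labels, branches = list()) {
  sym <- c(Glc = "Hex", Gal = "Hex", GalNAc = "HexNAc", GlcNAc = "HexNAc",
           Neu5Ac = "Neu5Ac", Fuc = "dHex")
  labs <- strsplit(labels, "-", fixed = TRUE)[[1]]
  residue <- unname(sym[labs]); parent <- c(0L, seq_len(length(labs) - 1L))
  role <- rep("backbone", length(labs)); label <- labs
  for (b in branches) {
    residue <- c(residue, unname(sym[[b$label]]))
    parent <- c(parent, as.integer(b$node))
    role <- c(role, "branch")
    label <- c(label, b$label)
  }
  glycan_topology(residue, parent, role, label)
}

#' The default glycosphingolipid registry
#'
#' Named glycan topologies for the sphingolipid species identified in human
#' podocytes: the ganglio-series (0-, a-, b- and alpha-branch isomers), the
#' globo-series up to the mono- and disialylated globopentaosylceramides,
#' plus ceramide and sphingomyelin. Registry insertion order is fixed so that
#' candidate enumeration ([isomer_set()]) is reproducible. Aliases:
#' `GD1α -> GD1alpha`, `Neu5AcGb5Cer -> MSGb5Cer`,
#' `(Neu5Ac)2Gb5Cer -> DSGb5Cer`.
#'
#' Isomer families encoded here: GM1a carries its sialic acid on the inner
#' galactose, GM1b on the terminal galactose; GD1a on inner + terminal Gal,
#' GD1b as a disialyl unit on the inner Gal, GD1alpha on the GalNAc and the
#' terminal Gal. MSGb5Cer is sialylated on the terminal Gal of the globo
#' backbone; DSGb5Cer on the terminal Gal and the adjacent GalNAc.
#'
#' @return A named list of registry entries of class `gsl_registry`.
#' @export
default_registry <- function() {
  entries <- list(
    Cer      = list(topology = glycan_topology()),
    SM       = list(topology = glycan_topology(), fragmentable = FALSE,
                    headgroup_mass = sm_headgroup_mass()),
    GlcCer   = list(topology = chain_entry("Glc")),
    LacCer   = list(topology = chain_entry("Glc-Gal")),
    Gb3Cer   = list(topology = chain_entry("Glc-Gal-Gal")),
    Gb4Cer   = list(topology = chain_entry("Glc-Gal-Gal-GalNAc")),
    Gb5Cer   = list(topology = chain_entry("Glc-Gal-Gal-GalNAc-Gal")),
    MSGb5Cer = list(topology = chain_entry("Glc-Gal-Gal-GalNAc-Gal",
                      list(list(node = 5, label = "Neu5Ac")))),
    DSGb5Cer = list(topology = chain_entry("Glc-Gal-Gal-GalNAc-Gal",
                      list(list(node = 5, label = "Neu5Ac"),
                           list(node = 4, label = "Neu5Ac")))),
    GA1      = list(topology = chain_entry("Glc-Gal-GalNAc-Gal")),
    GM3      = list(topology = chain_entry("Glc-Gal",
                      list(list(node = 2, label = "Neu5Ac")))),
    GM2      = list(topology = chain_entry("Glc-Gal-GalNAc",
                      list(list(node = 2, label = "Neu5Ac")))),
    GM1a     = list(topology = chain_entry("Glc-Gal-GalNAc-Gal",
                      list(list(node = 2, label = "Neu5Ac")))),
    GM1b     = list(topology = chain_entry("Glc-Gal-GalNAc-Gal",
                      list(list(node = 4, label = "Neu5Ac")))),
    GD3      = list(topology = glycan_topology(
                      residue = c("Hex", "Hex", "Neu5Ac", "Neu5Ac"),
                      parent = c(0L, 1L, 2L, 3L),
                      role = c("backbone", "backbone", "branch", "branch"),
                      label = c("Glc", "Gal", "Neu5Ac", "Neu5Ac"))),
    GD1a     = list(topology = chain_entry("Glc-Gal-GalNAc-Gal",
                      list(list(node = 2, label = "Neu5Ac"),
                           list(node = 4, label = "Neu5Ac")))),
    GD1b     = list(topology = glycan_topology(
                      residue = c("Hex", "Hex", "HexNAc", "Hex", "Neu5Ac", "Neu5Ac"),
                      parent = c(0L, 1L, 2L, 3L, 2L, 5L),
                      role = c(rep("backbone", 4), "branch", "branch"),
                      label = c("Glc", "Gal", "GalNAc", "Gal", "Neu5Ac", "Neu5Ac"))),
    GD1alpha = list(topology = chain_entry("Glc-Gal-GalNAc-Gal",
                      list(list(node = 3, label = "Neu5Ac"),
                           list(node = 4, label = "Neu5Ac"))))
  )
  entries <- lapply(entries, function(e) {
    e$fragmentable <- isTRUE(e$fragmentable) || is.null(e$fragmentable)
    e$headgroup_mass <- if (is.null(e$headgroup_mass)) 0 else e$headgroup_mass
    e
  })
  structure(entries,
            aliases = stats::setNames(
              c("GD1alpha", "MSGb5Cer", "DSGb5Cer"),
              c("GD1\u03b1", "Neu5AcGb5Cer", "(Neu5Ac)2Gb5Cer")),
            class = "gsl_registry")
}

resolve_name <- function(name, registry) {
  aliases <- attr(registry, "aliases")
  if (!is.null(aliases) && name %in% names(aliases)) name <- aliases[[name]]
  if (!name %in% names(registry)) {
    stop("unknown structure '", name, "'; registry contains: ",
         paste(names(registry), collapse = ", "))
  }
  name
}

#' Build a named structure from the registry
#'
#' @param name a registry key (or alias such as `"(Neu5Ac)2Gb5Cer"`).
#' @param ceramide a `ceramide_species`, a shorthand string like
#'   `"d18:1/24:1"`, or `NULL` for an unspecified ceramide.
#' @param registry a registry from [default_registry()] or [read_registry()].
#' @return A `gsl_structure` (deep copy; composition recomputed from the
#'   topology).
#' @examples
#' build_structure("GM1b", "d18:1/24:1")$composition
#' @export
build_structure <- function(name, ceramide = NULL, registry = default_registry()) {
  key <- resolve_name(name, registry)
  e <- registry[[key]]
  if (!is.null(ceramide)) ceramide <- parse_ceramide(ceramide)
  new_gsl_structure(key, e$topology, ceramide,
                    fragmentable = e$fragmentable,
                    headgroup_mass = e$headgroup_mass)
}

#' All registry structures with a given glycan composition
#'
#' Enumerates isomer candidates: every registry entry whose residue multiset
#' equals `composition`, in registry insertion order. Structures that share a
#' composition (GM1a/GM1b; GD1a/GD1b/GD1alpha; GA1/Gb4Cer) are exactly the
#' isobaric candidates an MS1 measurement cannot distinguish.
#'
#' @param composition named count vector, e.g. `c(Hex = 3, HexNAc = 1, Neu5Ac = 1)`.
#' @param ceramide optional ceramide attached to every returned structure.
#' @param registry structure registry.
#' @return A list of `gsl_structure` (possibly empty).
#' @examples
#' names0 <- vapply(isomer_set(c(Hex = 3, HexNAc = 1, Neu5Ac = 1)), `[[`, "", "name")
#' names0 # GM1a, GM1b
#' @export
isomer_set <- function(composition, ceramide = NULL, registry = default_registry()) {
  if (!length(composition) || all(composition == 0)) {
    stop("composition must be non-empty")
  }
  key <- composition_key(composition)
  hits <- names(registry)[vapply(
    registry, function(e) composition_key(composition_of(e$topology)) == key, TRUE
  )]
  lapply(hits, build_structure, ceramide = ceramide, registry = registry)
}

# ---------------------------------------------------------------------------
# plain-text registry serialization (edge-list table) so users can add
# structures without code changes

#' Write / read a registry as a plain-text edge-list table
#'
#' One row per glycan node (`name, node, residue, parent, role, label`);
#' glycan-free entries (Cer, SM) appear with `node = 0`. The `headgroup`
#' column carries the fixed sphingomyelin phosphocholine mass; `fragmentable`
#' marks entries excluded from glycosidic fragmentation.
#'
#' @param registry a `gsl_registry`.
#' @param path file path for the tab-separated table.
#' @return `write_registry` returns `path` invisibly; `read_registry` returns
#'   a `gsl_registry` preserving row order as insertion order.
#' @export
write_registry <- function(registry, path) {
  rows <- lapply(names(registry), function(nm) {
    e <- registry[[nm]]
    t <- e$topology
    if (nrow(t) == 0) {
      data.frame(name = nm, node = 0L, residue = "-", parent = NA_integer_,
                 role = "-", label = "-", fragmentable = e$fragmentable,
                 headgroup = e$headgroup_mass)
    } else {
      data.frame(name = nm, node = t$node, residue = t$residue,
                 parent = t$parent, role = t$role, label = t$label,
                 fragmentable = e$fragmentable, headgroup = e$headgroup_mass)
    }
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "node", "residue", "parent", "role", "label")
  if (!all(need %in% names(tab))) {
    stop("registry table must have columns: ", paste(need, collapse = ", "))
  }
  entries <- list()
  for (nm in unique(tab$name)) {
    rows <- tab[tab$name == nm, , drop = FALSE]
    if (nrow(rows) == 1 && rows$node[1] == 0) {
      topo <- glycan_topology()
    } else {
      rows <- rows[order(rows$node), , drop = FALSE]
      topo <- glycan_topology(rows$residue, rows$parent, rows$role, rows$label)
    }
    entries[[nm]] <- list(
      topology = topo,
      fragmentable = if ("fragmentable" %in% names(rows)) isTRUE(rows$fragmentable[1]) else TRUE,
      headgroup_mass = if ("headgroup" %in% names(rows)) rows$headgroup[1] else 0
    )
  }
  structure(entries, aliases = attr(default_registry(), "aliases"),
            class = "gsl_registry")
}
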