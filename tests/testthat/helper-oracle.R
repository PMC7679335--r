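# Independent brute-force fragment enumerator used as the oracle for
# enumerate_fragments(). Deliberately written from scratch: its own mass
# constants, an explicit ancestor matrix instead of subtree recursion, and
# direct iteration over edge subsets via combn().

ORACLE_P <- 1.007276
ORACLE_W <- 18.010565
ORACLE_RES <- c(Hex = 162.0528234, HexNAc = 203.0793725,
                Neu5Ac = 291.0954165, dHex = 146.0579089)

oracle_multiset_key <- function(residues) {
  residues <- sort(residues)
  tab <- table(residues)
  paste(names(tab), as.integer(tab), sep = ":", collapse = ",")
}

oracle_fragments <- function(structure, max_cleavages = 2) {
  topo <- structure$topology
  cer_mass <- structure$ceramide$neutral_mass
  total <- cer_mass + sum(ORACLE_RES[topo$residue]) + structure$headgroup_mass
  out <- list()
  emit <- function(type, key, mz) {
    out[[length(out) + 1L]] <<- list(type = type, key = key, mz = mz)
  }
  emit("precursor", oracle_multiset_key(topo$residue), total - ORACLE_P)
  if (structure$fragmentable && nrow(topo) > 0) {
    n <- nrow(topo)
    # anc[i, j] TRUE iff node i is on the root path of node j (i ancestor-or-self)
    anc <- diag(n) > 0
    for (j in seq_len(n)) {
      p <- topo$parent[j]
      while (p != 0) { anc[p, j] <- TRUE; p <- topo$parent[p] }
    }
    below <- function(e) which(anc[e, ]) # e and everything beyond it
    res_of <- function(nodes) topo$residue[nodes]
    msum <- function(nodes) sum(ORACLE_RES[res_of(nodes)])
    for (e in seq_len(n)) {
      nonred <- below(e)
      red <- setdiff(seq_len(n), nonred)
      emit("B", oracle_multiset_key(res_of(nonred)), msum(nonred) - ORACLE_P)
      emit("C", oracle_multiset_key(res_of(nonred)), msum(nonred) + ORACLE_W - ORACLE_P)
      emit("Y", oracle_multiset_key(res_of(red)), cer_mass + msum(red) - ORACLE_P)
      emit("Z", oracle_multiset_key(res_of(red)), cer_mass + msum(red) - ORACLE_P - ORACLE_W)
    }
    if (max_cleavages >= 2 && n >= 2) {
      for (pair in utils::combn(n, 2, simplify = FALSE)) {
        e1 <- pair[1]; e2 <- pair[2]
        if (anc[e1, e2]) {
          mid <- setdiff(below(e1), below(e2))
          emit("BY", oracle_multiset_key(res_of(mid)), msum(mid) - ORACLE_P)
          emit("CY", oracle_multiset_key(res_of(mid)), msum(mid) + ORACLE_W - ORACLE_P)
        } else if (anc[e2, e1]) {
          mid <- setdiff(below(e2), below(e1))
          emit("BY", oracle_multiset_key(res_of(mid)), msum(mid) - ORACLE_P)
          emit("CY", oracle_multiset_key(res_of(mid)), msum(mid) + ORACLE_W - ORACLE_P)
        } else {
          red <- setdiff(seq_len(n), c(below(e1), below(e2)))
          emit("Y", oracle_multiset_key(res_of(red)), cer_mass + msum(red) - ORACLE_P)
          emit("Z", oracle_multiset_key(res_of(red)), cer_mass + msum(red) - ORACLE_P - ORACLE_W)
        }
      }
    }
  }
  keys <- vapply(out, function(r) paste(r$type, r$key), "")
  out <- out[!duplicated(keys)]
  df <- data.frame(
    id = vapply(out, function(r) paste(r$type, r$key), ""),
    mz = vapply(out, function(r) r$mz, 0)
  )
  df[order(df$id), , drop = FALSE]
}

# package ion table rendered in the oracle's comparison format
ion_table_as_oracle <- function(ions) {
  ions <- ions[ions$charge == 1, , drop = FALSE]
  df <- data.frame(id = paste(ions$ion_type, ions$residues), mz = ions$mz)
  df[order(df$id), , drop = FALSE]
}

# set equality of ion identities plus numeric agreement of every m/z
expect_oracle_equal <- function(got, want, info = NULL, mz_tol = 1e-5) {
  testthat::expect_equal(got$id, want$id, info = info)
  testthat::expect_lt(max(abs(got$mz - want$mz)), mz_tol)
}
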