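# Printed negative-mode peak lists used as regression fixtures.

# GM1 MS2 series (precursor and complete Y ladder; note: no ion at 1261.78)
gm1_peaklist <- function() {
  spectrum(c(1626.90, 1335.79, 1173.75, 970.67, 808.62, 646.56),
           precursor_mz = 1626.90, precursor_charge = 1)
}

# GD1 MS2 series from the doubly charged precursor at 945.51
# (sialyl-arm B/C/internal ions; 1235.81 and 581.22 absent)
gd1_peaklist <- function() {
  spectrum(c(290.11, 493.19, 835.29, 964.35),
           precursor_mz = 945.51, precursor_charge = 2)
}

# registry entries that carry a fragmentable glycan
fragmentable_names <- function(registry = default_registry()) {
  names(registry)[vapply(registry, function(e) {
    nrow(e$topology) > 0 && (is.null(e$fragmentable) || isTRUE(e$fragmentable))
  }, TRUE)]
}
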