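# Small reusable simulation fixtures.

tiny_library <- function(n = 3, lengths = c(300, 1000), seed = 11) {
  make_fixture_library(n, length_range = lengths, seed = seed)
}

tiny_config <- function(seed = 5, copies = 8, base_length = 30000,
                        target_divergence = 0.1, fragment_fraction = 0,
                        nesting_fraction = 0, n_families = 3) {
  lib <- tiny_library(n_families)
  fams <- dplyr::bind_rows(lapply(names(lib), function(nm) {
    family_spec(nm, lib[[nm]], copies = copies,
                target_divergence = target_divergence,
                fragment_fraction = fragment_fraction,
                nesting_fraction = nesting_fraction)
  }))
  simulation_config(fams, base_length = base_length, seed = seed)
}
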