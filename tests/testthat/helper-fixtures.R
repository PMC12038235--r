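# Shared fixtures, built once per test run. Everything derives from one
# seeded locus configuration so tests are deterministic.

.fixtures <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

fx_config <- function() fx("config", function() default_locus_config(1L))

fx_hap <- function(name) {
  fx(name, function() build_haplotype(name, fx_config()))
}

fx_panel <- function() fx("panel", function() hapf_marker_panel(fx_config()))

fx_ase <- function() fx("ase", function() ase_reference_set(fx_config()))
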