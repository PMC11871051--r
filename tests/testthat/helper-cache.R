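# Heavyweight shared computation for the acceptance checks: the thermally
# smeared ground-state ensemble (n = 2000, default sigma_oop, all charges +1,
# from rest), exploded once and reused across test blocks.
.ceisim_test_cache <- new.env(parent = emptyenv())

s0_reference_run <- function(n = 2000, seed = 20251) {
  key <- paste0("s0_", n, "_", seed)
  if (is.null(.ceisim_test_cache[[key]])) {
    ens <- thermal_ensemble(build_s0(), 0.05, n, seed = seed)
    .ceisim_test_cache[[key]] <- explode_ensemble_events(ens)
  }
  .ceisim_test_cache[[key]]
}
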