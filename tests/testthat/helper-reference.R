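# The reference synthetic configuration run through the full pipeline:
# computed once per test session (it is the costly fixture behind the
# crescent-map checks) and memoised.

.reference_cache <- new.env(parent = emptyenv())

reference_run <- function() {
  if (!is.null(.reference_cache$run)) return(.reference_cache$run)
  cfg <- pipeline_config(
    seed = 1L,
    simulate = list(geometry = "grid12x12", duration_s = 60, fs = 3052),
    montage = list(scheme = "euclidean", max_skip = 5, bin_width = 2,
                   range_mm = c(2, 60), max_pairs_per_bin = 250))
  out <- file.path(tempfile("refrun"), "run")
  .reference_cache$run <- run_pipeline(cfg, out)
  .reference_cache$run
}
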