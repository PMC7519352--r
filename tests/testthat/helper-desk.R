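# Desk-scale phantom experiment shared by the acceptance checks: the
# full recipe (300 stage positions, 25-um voxels, 2.4-mm offsets) at a
# one-million-photon Monte Carlo budget, one seed pair. Memoized: several
# acceptance blocks read different quantities from the same run.
desk_run <- function() {
  if (!is.null(.flot_test_cache$desk)) return(.flot_test_cache$desk)
  cfg <- pipeline_config(data_seed = 401, w_seed = 402)
  run <- run_pipeline(cfg)
  .flot_test_cache$desk <- run
  run
}
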