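# Shared eight-condition panel, computed once per test run and memoized.
# panel_run(noise_sd) returns, per light class: the rendered scene, the
# fitted per-class mapping, the pipeline comparison table and the
# spectral-truth table.

.panel_cache <- new.env(parent = emptyenv())

panel_run <- function(noise_sd = 0, seed = 11) {
  key <- sprintf("noise%g_seed%d", noise_sd, seed)
  if (!is.null(.panel_cache[[key]])) return(.panel_cache[[key]])
  camera <- default_camera(noise_sd = noise_sd)
  system <- horse_visual_system()
  scenes <- generate_condition_panel(seed = seed, noise_sd = noise_sd,
                                     camera = camera)
  out <- lapply(names(scenes), function(cond) {
    mapping <- fit_mapping(generate_training_spectra(500, seed = 7),
                           camera, system, make_illuminant(cond))
    list(scene = scenes[[cond]], mapping = mapping,
         pipeline = analyze_scene(scenes[[cond]], camera, mapping, system),
         truth = scenes[[cond]]$truth$jnd)
  })
  names(out) <- names(scenes)
  .panel_cache[[key]] <- out
  out
}
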