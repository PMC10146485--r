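# shared fixtures: figure-caption parameter sets and generic m3-m6 sets
# (built in code; the m3-m6 values are package choices, no printed analogue)

fig_presets <- function() {
  list(m1 = motif_preset("fig4"), m2 = motif_preset("fig8"),
       m7 = motif_preset("fig6"), m8 = motif_preset("fig11"))
}

generic_motifs <- function() {
  list(
    m3 = build_motif("m3", c(k1 = 0, k2 = 1, k3 = 1, k4 = 0, k5 = 31,
                             k6 = 1, k7 = 1e-6, k8 = 0.1)),
    m4 = build_motif("m4", c(k1 = 0, k2 = 1, k3 = 1e4, k4 = 0, k5 = 1,
                             k6 = 31, k7 = 1e-6, k8 = 0.1, k9 = 0.1)),
    m5 = build_motif("m5", c(k1 = 1, k2 = 0, k3 = 0, k4 = 0.03, k5 = 1,
                             k6 = 3, k7 = 1e-6)),
    m6 = build_motif("m6", c(k1 = 1, k2 = 0, k3 = 0, k4 = 1e4, k5 = 3,
                             k6 = 1, k7 = 1e-6, k9 = 0.1))
  )
}

all_motifs <- function() c(fig_presets(), generic_motifs())

# step protocol in the motif's perturbation parameter, from its baseline
motif_step_protocol <- function(model, height, onset = 10, total_time = 60,
                                background = NULL, step = 0.005) {
  baseline <- list()
  if (!is.null(background)) baseline[[model$background_name]] <- background
  ov <- stats::setNames(list(height), model$perturbation_name)
  step_protocol(onset, ov, total_time, baseline = baseline,
                dense_output_step = step)
}
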