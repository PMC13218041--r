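# Small conveniences shared by the kinetics tests.

fit_fusion_decay_wrap <- function(ev) fit_fusion_decay(ev$t, ev$AR)

# Mean normalized (Rg, SASA) for a trajectory against a pooled
# normalization; used by the compact-vs-extended contrast tests.
pooled_norm_means <- function(x_a, x_b) {
  ns <- normalize_series(c(x_a, x_b))
  list(a = mean(ns$X_norm[seq_along(x_a)]),
       b = mean(ns$X_norm[length(x_a) + seq_along(x_b)]))
}
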