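# shared helper: one recovery trial; returns TRUE when the recovered
# ranking never strictly contradicts the ground truth (ties from the
# extent-analysis zero-truncation are allowed)
recovery_concordant <- function(seed, n_criteria, noise, n_experts = 10) {
  spec <- synthetic_spec(seed = seed, n_experts = n_experts,
                         n_criteria = n_criteria, opinion_noise = noise)
  mats <- gen_matrices(spec)
  w <- ahp_weights(mats)
  truth <- spec$true_weights
  for (i in seq_len(n_criteria - 1)) {
    for (j in seq.int(i + 1, n_criteria)) {
      if (sign(truth[i] - truth[j]) * sign(w[i] - w[j]) < 0) return(FALSE)
    }
  }
  TRUE
}

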