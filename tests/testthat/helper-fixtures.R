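# Shared fixtures built in code at test time.

paper_intensities <- c(8.6e12, 5.3e13, 3e14, 8.7e14, 1.6e15, 2.3e15)

# Small protocol for fast count-tier tests: full intensity ladder, few reps.
small_protocol <- function(reps = 5) make_protocol(reps = reps)

# One-intensity protocol for trace-tier tests (keeps traces short).
trace_protocol <- function(reps = 4, dark_gap = 2) {
  make_protocol(intensities = 3e14, reps = reps, dark_gap = dark_gap)
}

# Gaussian log2-expression matrix with a spiked differential block:
# the canonical benchmark world for the permutation-FDR test.
sim_log2_matrix <- function(n_genes, n_per_group = 3, frac_de = 0.1,
                            effect_log2 = 2, sd = 0.25, seed = 1) {
  withr::with_seed(seed, {
    base <- stats::rnorm(n_genes, 7, 2)
    n_de <- round(frac_de * n_genes)
    x <- matrix(stats::rnorm(n_genes * 2 * n_per_group, base, sd),
                nrow = n_genes)
    if (n_de > 0) {
      x[seq_len(n_de), n_per_group + seq_len(n_per_group)] <-
        x[seq_len(n_de), n_per_group + seq_len(n_per_group)] + effect_log2
    }
    rownames(x) <- sprintf("g%04d", seq_len(n_genes))
    list(x = x, group = factor(rep(c("control", "treated"),
                                   each = n_per_group)),
         true_de = seq_len(n_genes) <= n_de)
  })
}

# Greedy matching of detected spike times to ground truth within a tolerance;
# returns sensitivity and precision.
match_spikes <- function(truth, detected, tol = 5e-4) {
  tp <- 0L
  used <- rep(FALSE, nrow(detected))
  for (i in seq_len(nrow(truth))) {
    j <- which(!used & detected$channel == truth$channel[i] &
                 abs(detected$t_s - truth$t_s[i]) <= tol)
    if (length(j)) {
      used[j[1]] <- TRUE
      tp <- tp + 1L
    }
  }
  c(sensitivity = tp / nrow(truth), precision = tp / nrow(detected))
}

spike_train_df <- function(spikes) {
  data.frame(channel = rep(seq_along(spikes),
                           vapply(spikes, length, integer(1))),
             t_s = unlist(spikes, use.names = FALSE))
}
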