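# Independent oracles, kept free of the package's own code paths.

# Generic n-receptor receptor-noise-limited distance: the noise-weighted
# distance between two stimuli in log receptor-contrast space, minimised
# over the intensity (common-shift) direction:
#   dS^2 = min_c sum_i (df_i - c)^2 / e_i^2,  df_i = ln(qa_i / qb_i).
# Solved numerically so it shares no algebra with the closed form.
rnl_oracle <- function(qa, qb, e) {
  df <- log(qa / qb)
  obj <- function(c0) sum((df - c0)^2 / e^2)
  span <- max(abs(df)) + 1
  opt <- stats::optimize(obj, interval = c(-span, span), tol = 1e-14)
  sqrt(opt$objective)
}

# random strictly positive catch triples on assorted scales
random_catches <- function(n) {
  matrix(exp(stats::rnorm(3 * n, 0, 1)), ncol = 3,
         dimnames = list(NULL, c("SW", "MW", "LW")))
}
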