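# Generators for synthetic test series (all positive-valued, as cumulative
# PCI-like statistics are).

# i.i.d. noise before the change stride, constant afterwards
noisy_then_constant <- function(change_stride, n = 49, level = 5,
                                rel_noise = 0.2) {
  m <- change_stride - 1L  # stride -> series position
  c(level * (1 + stats::rnorm(m - 1, 0, rel_noise)), rep(level, n - m + 1L))
}

# heterogeneous random series for oracle-equivalence sweeps
random_test_series <- function(n) {
  kind <- sample(3, 1)
  if (kind == 1) {
    as.numeric(cumulative_pci_series(180 + stats::rnorm(n + 1, 0,
                                                        stats::runif(1, 1, 12))))
  } else if (kind == 2) {
    noisy_then_constant(sample(3:(n - 2), 1), n = n,
                        rel_noise = stats::runif(1, 0.05, 0.4))
  } else {
    exp(stats::rnorm(n, log(5), stats::runif(1, 0.01, 0.3)))
  }
}
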