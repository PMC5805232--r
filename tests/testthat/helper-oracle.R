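# Independent brute-force re-implementation of the two-stage POS procedure,
# written as a literal transliteration of the published flowchart (explicit
# loops, own CV arithmetic). Used only as an oracle; shares no code with the
# package implementation.

oracle_cv <- function(v) {
  n <- length(v)
  m <- sum(v) / n
  s <- sqrt(sum((v - m)^2) / (n - 1))
  s / m
}

oracle_dispersed <- function(S, N, K) {
  real <- S + (0:(K - 1)) * (N - S) / (K - 1)
  ii <- floor(real + 0.5)
  for (j in 2:K) if (ii[j] <= ii[j - 1]) ii[j] <- ii[j - 1] + 1
  as.integer(ii)
}

oracle_detect_pos <- function(x, K = 15, thr = 0.05) {
  N <- length(x)
  pos_opt <- c(consecutive = NA_real_, dispersed = NA_real_)
  for (opt in 1:2) {
    roi <- NULL
    for (S in seq(N - K + 1, 1)) {
      idx <- if (opt == 1) seq(S, S + K - 1) else oracle_dispersed(S, N, K)
      cv <- oracle_cv(x[idx])
      if (!(is.finite(cv) && cv <= thr)) { roi <- idx; break }
    }
    if (is.null(roi)) {
      pos_opt[opt] <- 2
    } else {
      idx <- roi
      while (length(idx) > 2) {
        sub <- idx[-1]
        cv <- oracle_cv(x[sub])
        idx <- if (is.finite(cv) && cv <= thr) idx[-length(idx)] else sub
      }
      pos_opt[opt] <- idx[2] + 1  # series position -> stride count
    }
  }
  list(pos = max(pos_opt), pos_by_option = pos_opt)
}
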