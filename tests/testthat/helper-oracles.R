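# Independent statistical oracle: exhaustive null distribution of
# U = min(U1, U2) over all rank assignments (tiny samples only).
enumerate_mwu_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U_obs <- min(sum(r[1:n1]) - n1 * (n1 + 1) / 2,
               sum(r[(n1 + 1):N]) - n2 * (n2 + 1) / 2)
  vals <- combn(N, n1, function(idx) {
    U1 <- sum(seq_len(N)[idx]) - n1 * (n1 + 1) / 2
    min(U1, n1 * n2 - U1)
  })
  mean(vals <= U_obs + 1e-12)
}
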