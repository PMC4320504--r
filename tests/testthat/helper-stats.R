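# Brute-force oracle for the exact rank-sum p value: enumerate every
# assignment of the pooled (midrank) ranks to the first group and count
# deviations at least as extreme as the observed one. Independent of the
# package's dynamic-programming implementation.
enum_ranksum_p <- function(x, y) {
  n1 <- length(x)
  rk <- rank(c(x, y))
  n <- length(rk)
  w_obs <- sum(rk[seq_len(n1)])
  e_w <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(rk[combos], nrow = n1))
  mean(abs(w_all - e_w) >= abs(w_obs - e_w) - 1e-9)
}
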