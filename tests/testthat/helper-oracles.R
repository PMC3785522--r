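# Independent brute-force oracles used to freeze expected values.

# Two-sided Fisher p by direct enumeration of every margin-preserving 2x2
# table, with point probabilities from choose() ratios (no log-space trick).
fisher_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  k <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- choose(c1, k) * choose(n - c1, r1 - k) / choose(n, r1)
  p_obs <- prob[k == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Arm-call tibble shorthand: states named by arm, e.g. arm_calls(`1p` = "loss")
toy_arm_calls <- function(..., median_log2 = -0.7) {
  states <- c(...)
  tibble::tibble(
    arm = names(states),
    n_probes = 100L,
    median_log2 = ifelse(states == "loss", median_log2,
                         ifelse(states == "gain", 0.4, 0)),
    state = factor(states, levels = c("loss", "neutral", "gain"))
  )
}

# Uniform-log2 probe tibble on one arm
toy_probes <- function(arm = "19q", n = 10, log2_ratio = -0.9,
                       chrom = sub("[pq]$", "", arm), start0 = 1e6,
                       spacing = 1e4) {
  start <- start0 + (seq_len(n) - 1) * spacing
  tibble::tibble(
    chrom = chrom, start = start, end = start + 59,
    probe_id = sprintf("%s_%03d", arm, seq_len(n)),
    arm = arm, log2_ratio = rep_len(log2_ratio, n)
  )
}
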