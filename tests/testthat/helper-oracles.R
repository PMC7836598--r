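# Independent oracles used only by the tests; deliberately naive
# re-implementations, never shared with the package code paths they check.

# Benjamini-Hochberg by direct definition: sort ascending, q_i = p_i * m / i,
# running minimum from the largest rank down, cap at 1, unsort.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- (m / seq_len(m)) * p[o]
  adj <- pmin(1, rev(cummin(rev(q))))
  adj[order(o)]
}

# Two-group log-rank chi-square by explicit observed-minus-expected sums
# over the distinct event times (hypergeometric variance).
logrank_oracle <- function(time, event, in_group1) {
  stopifnot(length(time) == length(event), length(time) == length(in_group1))
  event_times <- sort(unique(time[event == 1]))
  omE <- 0
  V <- 0
  for (t in event_times) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & in_group1)
    dj <- sum(time == t & event == 1)
    d1j <- sum(time == t & event == 1 & in_group1)
    omE <- omE + (d1j - dj * n1j / nj)
    if (nj > 1)
      V <- V + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  omE^2 / V
}

# Partial correlation from the inverse of the full correlation matrix of
# (x, y, controls): -Omega_xy / sqrt(Omega_xx * Omega_yy).
partial_oracle <- function(x, y, Z) {
  M <- cbind(x, y, Z)
  Om <- solve(stats::cor(M))
  -Om[1, 2] / sqrt(Om[1, 1] * Om[2, 2])
}

# Small expression matrix with labelled genes/samples.
toy_matrix <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}

# Compact generator configuration for fast tests.
tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(seed = 42, n_genes = 200, hallmark_size = 30,
                   emt_size = 30, n_planted = 10, n_tumor = 10,
                   n_normal = 10, cohort_size = 60)
  do.call(synthetic_config, utils::modifyList(defaults, args))
}

# Minimal valid clinical table for IO/association tests.
toy_clinical <- function(n = 8, seed = 7) {
  set.seed(seed)
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    os_time = round(rexp(n, 0.05), 3), os_event = rbinom(n, 1, 0.7),
    pfs_time = round(rexp(n, 0.08), 3), pfs_event = rbinom(n, 1, 0.7),
    stage = sample(c("I", "II", "III/IV"), n, replace = TRUE),
    grade = sample(c("G1", "G2", "G3/G4"), n, replace = TRUE),
    residual = rbinom(n, 1, 0.4), gender = rbinom(n, 1, 0.5),
    stringsAsFactors = FALSE)
}
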