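# Independent oracles used across the suite. Each one recomputes a
# statistic from first principles (enumeration, brute force, or the
# textbook definition) so the package implementation has something to be
# checked against that shares no code with it.

# Benjamini-Hochberg by the brute-force step-up definition:
# fdr_(i) = min_{j >= i} p_(j) * m / j, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  p_sorted <- p[ord]
  fdr_sorted <- vapply(seq_len(m), function(i) {
    min(pmin(p_sorted[i:m] * m / (i:m), 1))
  }, numeric(1))
  fdr <- numeric(m)
  fdr[ord] <- fdr_sorted
  fdr
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of all
# choose(n+m, n) group assignments of the pooled sample.
wilcoxon_enumeration <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)])
  mu <- n * (length(pooled) + 1) / 2
  sets <- utils::combn(length(pooled), n)
  w_all <- colSums(matrix(ranks[sets], nrow = n))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Log-rank chi-square from hypergeometric expectations and variances
# summed over distinct event times (textbook two-group formula).
logrank_oracle <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2L)
  event_times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in event_times) {
    at_risk <- time >= t
    n_tot <- sum(at_risk)
    n_1 <- sum(at_risk & group == groups[1L])
    d_tot <- sum(time == t & event == 1)
    d_1 <- sum(time == t & event == 1 & group == groups[1L])
    o_minus_e <- o_minus_e + d_1 - d_tot * n_1 / n_tot
    if (n_tot > 1) {
      v <- v + d_tot * (n_1 / n_tot) * (1 - n_1 / n_tot) *
        (n_tot - d_tot) / (n_tot - 1)
    }
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Noise-free 4PL responses for a dilution series.
pl4_curve <- function(conc, bottom, top, hill, ec50) {
  bottom + (top - bottom) / (1 + (conc / ec50)^hill)
}

# A single simulated dose-response curve with multiplicative log-normal
# noise of relative SD cv (unit mean), as a tibble ready for fit_4pl().
make_curve <- function(ec50, cv = 0, hill = 1, top_dose = 10,
                       n_replicates = 1L) {
  conc <- rep(top_dose / 3.3^(0:9), n_replicates)
  v <- pl4_curve(conc, 0, 1, hill, ec50)
  if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    v <- v * stats::rlnorm(length(v), -sdlog^2 / 2, sdlog)
  }
  tibble::tibble(concentration = conc, viability = v)
}

# One fully-passing variant candidate; fields can be overridden to break
# exactly one criterion at a time.
passing_variant <- function(...) {
  base <- tibble::tibble(
    chrom = "chr1", pos = 1000L, ref = "C", alt = "T",
    tumor_depth = 200L, tumor_alt_reads = 20L, tumor_vaf = 0.10,
    normal_vaf = 0.00, strand_bias = 0.60, population_freq = 0.001,
    effect_class = "missense", near_repeat = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}
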