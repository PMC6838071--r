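#' Per-event recurrence counts and cohort fractions
#'
#' Counts altered samples per (gene, kind) event and reports the fraction of
#' the cohort carrying each. `min_fraction` applies the display filter used
#' for recurrence heatmaps (events with recurrence strictly greater than the
#' threshold are kept); the default 0 keeps every event with at least one
#' carrier.
#'
#' @param alterations Long tibble with an identifier column (`sample` or
#'   `line`) plus `gene`, `kind`, `altered`.
#' @param min_fraction Strict lower bound on the reported fraction.
#' @return Tibble `gene`, `kind`, `count`, `fraction`, `n_samples`, sorted
#'   by descending fraction.
#' @export
recurrence <- function(alterations, min_fraction = 0) {
  check_columns(alterations, c("gene", "kind", "altered"), "`alterations`")
  check_fraction(min_fraction, "min_fraction")
  id <- id_column(alterations)
  n_samples <- n_distinct(alterations[[id]])
  alterations |>
    group_by(.data$gene, .data$kind) |>
    summarise(count = sum(.data$altered), .groups = "drop") |>
    mutate(fraction = .data$count / n_samples, n_samples = n_samples) |>
    filter(.data$fraction > min_fraction) |>
    arrange(desc(.data$fraction), .data$gene)
}

#' Inclusion-exclusion arithmetic for two co-occurring alterations
#'
#' @param count_a,count_b Samples carrying event A / event B.
#' @param count_both Samples carrying both.
#' @param n_total Cohort size.
#' @return One-row tibble `n_union`, `fraction_union`, `fraction_a`,
#'   `fraction_b`, `fraction_both`, `jaccard`.
#' @export
cooccurrence <- function(count_a, count_b, count_both, n_total) {
  count_a <- check_count(count_a, "count_a", min = 0L)
  count_b <- check_count(count_b, "count_b", min = 0L)
  count_both <- check_count(count_both, "count_both", min = 0L)
  n_total <- check_count(n_total, "n_total", min = 1L)
  if (count_both > min(count_a, count_b)) {
    abort("`count_both` cannot exceed either marginal count.")
  }
  if (max(count_a, count_b) > n_total) {
    abort("Marginal counts cannot exceed `n_total`.")
  }
  n_union <- count_a + count_b - count_both
  tibble(n_union = n_union,
         fraction_union = n_union / n_total,
         fraction_a = count_a / n_total,
         fraction_b = count_b / n_total,
         fraction_both = count_both / n_total,
         jaccard = if (n_union == 0L) NA_real_ else count_both / n_union)
}

surv_formula <- function(data, group) {
  check_columns(data, c("time", "event"), "Survival table")
  if (any(data$time < 0)) abort("Survival times must be >= 0.")
  if (group && !"group" %in% names(data)) {
    abort("Survival table needs a `group` column for group comparisons.")
  }
}

#' Kaplan-Meier product-limit estimate
#'
#' @param data Tibble `time`, `event` (1 = event, 0 = censored), optional
#'   `group`.
#' @return Tidy step-function tibble `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, including the `time = 0, survival = 1` anchor
#'   per group.
#' @export
km_estimate <- function(data) {
  surv_formula(data, group = FALSE)
  grp <- if ("group" %in% names(data)) data$group else rep("all", nrow(data))
  fit <- survival::survfit(
    survival::Surv(data$time, data$event) ~ grp)
  strata <- if (is.null(fit$strata)) {
    rep(unique(grp)[1L], length(fit$time))
  } else {
    rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  }
  steps <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, n_censor = fit$n.censor,
                  survival = fit$surv)
  anchors <- distinct(steps, .data$group) |>
    mutate(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
           survival = 1)
  bind_rows(anchors, steps) |>
    arrange(.data$group, .data$time)
}

#' Log-rank test between two survival groups
#'
#' Standard log-rank statistic from hypergeometric expectations and
#' variances summed over event times, referred to a 1-df chi-square.
#'
#' @param data Tibble `time`, `event`, `group` (exactly two groups).
#' @return One-row tibble `statistic`, `df`, `p`.
#' @export
logrank_test <- function(data) {
  surv_formula(data, group = TRUE)
  if (n_distinct(data$group) != 2L) {
    abort("`logrank_test()` compares exactly two groups.")
  }
  if (sum(data$event) == 0L) {
    return(tibble(statistic = 0, df = 1L, p = 1))
  }
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group, data = data)
  tibble(statistic = sd_fit$chisq, df = 1L,
         p = stats::pchisq(sd_fit$chisq, df = 1L, lower.tail = FALSE))
}

#' Plot Kaplan-Meier curves
#'
#' @param km Output of [km_estimate()].
#' @return A ggplot step plot of survival against time by group.
#' @export
plot_km <- function(km) {
  check_columns(km, c("group", "time", "survival"), "`km`")
  ggplot(km, aes(.data$time, .data$survival, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "Time (months)", y = "Survival probability", colour = NULL) +
    theme_minimal()
}

#' Two-sided Wilcoxon rank-sum test with exact enumeration
#'
#' Exact mode enumerates all `choose(n + m, n)` assignments of the pooled
#' values to the two groups and reports the two-sided tail probability of
#' the rank-sum statistic; it is the default (`mode = "auto"`) whenever
#' `n + m <= 12` and there are no ties. Otherwise a normal approximation
#' with continuity and tie correction is used (with a warning if exact mode
#' was requested in the presence of ties).
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"normal"`.
#' @return One-row tibble `statistic` (rank sum of `x`), `p`, `method`.
#' @export
wilcoxon_ranksum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be nonempty.")
  }
  pooled <- c(x, y)
  n <- length(x)
  m <- length(y)
  ties <- anyDuplicated(pooled) > 0L
  use_exact <- switch(mode,
                      exact = TRUE,
                      normal = FALSE,
                      auto = (n + m) <= 12L && !ties)
  if (use_exact && ties) {
    warn("Ties present: falling back to the normal approximation.")
    use_exact <- FALSE
  }
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)])
  mu <- n * (n + m + 1) / 2

  if (use_exact) {
    assignments <- combn(n + m, n)
    w_all <- colSums(matrix(ranks[assignments], nrow = n))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(tibble(statistic = w_obs, p = p, method = "exact"))
  }
  tie_counts <- table(pooled)
  sigma2 <- n * m / 12 *
    ((n + m + 1) - sum(tie_counts^3 - tie_counts) / ((n + m) * (n + m - 1)))
  z <- (abs(w_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  tibble(statistic = w_obs, p = min(1, 2 * pnorm(-z)),
         method = "normal_approx")
}

#' Per-gene Z-score normalization of an expression matrix
#'
#' Centers and scales each gene's expression across samples using the
#' sample standard deviation (n - 1). Constant genes are returned as
#' all-zero rows and flagged.
#'
#' @param expr Tibble with a `gene` column and one numeric column per
#'   sample (>= 2 samples).
#' @return Tibble of the same shape with Z-scores, plus a logical
#'   `constant` column.
#' @export
zscore_normalize <- function(expr) {
  check_columns(expr, "gene", "`expr`")
  sample_cols <- setdiff(names(expr), "gene")
  if (length(sample_cols) < 2L) {
    abort("Z-score normalization needs >= 2 samples per gene.")
  }
  mat <- as.matrix(expr[sample_cols])
  mu <- rowMeans(mat)
  sds <- apply(mat, 1L, sd)
  constant <- sds == 0
  z <- (mat - mu) / if_else(constant, 1, sds)
  z[constant, ] <- 0
  bind_cols(tibble(gene = expr$gene), as_tibble(z),
            tibble(constant = constant))
}
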