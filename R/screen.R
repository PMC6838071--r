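#' Two-sided unpaired t test for one drug-gene group comparison
#'
#' Pooled-variance Student's t by default (Welch by `var_equal = FALSE`),
#' on the raw or log10 IC50 scale. Degenerate inputs (zero variance in both
#' groups) are handled explicitly: equal means give t = 0, p = 1; unequal
#' means give p = 0 with a degenerate flag.
#'
#' @param x,y Numeric IC50s of the mutated and wild-type groups (both of
#'   length >= 2).
#' @param scale `"raw"` or `"log10"`.
#' @param var_equal Pooled variance (Student) if TRUE, Welch otherwise.
#' @return One-row tibble `t`, `p`, `degenerate`.
#' @export
test_association <- function(x, y, scale = c("raw", "log10"),
                             var_equal = TRUE) {
  scale <- match.arg(scale)
  if (length(x) < 2L || length(y) < 2L) {
    abort("Both groups need >= 2 values for a t test.")
  }
  if (scale == "log10") {
    if (any(c(x, y) <= 0)) abort("log10 scale requires positive IC50s.")
    x <- log10(x)
    y <- log10(y)
  }
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble(t = 0, p = 1, degenerate = TRUE))
    }
    return(tibble(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                  degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = var_equal)
  tibble(t = unname(ht$statistic), p = ht$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment with monotonicity enforcement; output lies in (0, 1]
#' and is elementwise >= the input p-values.
#'
#' @param p P-values in (0, 1].
#' @return Adjusted FDR values.
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Drug-by-genotype association screen on an IC50 table
#'
#' Every (drug, gene-alteration) pair is compared between carrier and
#' non-carrier lines. Pairs with both groups of size >= 2 are tested
#' (two-sided unpaired t) and enter the Benjamini-Hochberg family; pairs
#' where either group has exactly one line are kept in the output with the
#' p-value recorded as missing and the FDR forced to 1; pairs with an empty
#' group are untested and excluded entirely.
#'
#' @param ic50 Tibble `line`, `drug`, `ic50` (e.g. from [fit_ic50()] or
#'   [simulate_ic50()]).
#' @param alterations Long tibble `line`, `gene`, `kind`, `altered`.
#' @param scale Test scale, `"raw"` (default) or `"log10"`.
#' @param var_equal Pooled-variance Student's t (default) or Welch.
#' @return Tibble with one row per tested or singleton pair: `drug`,
#'   `gene`, `kind`, `event`, `n_mut`, `n_wt`, `mean_ic50_mut`,
#'   `mean_ic50_wt`, `effect_ratio`, `t`, `p`, `fdr`, `direction`
#'   (`"sensitive"` if carriers have the lower mean IC50, else
#'   `"resistant"`).
#' @export
screen_associations <- function(ic50, alterations,
                                scale = c("raw", "log10"),
                                var_equal = TRUE) {
  scale <- match.arg(scale)
  check_columns(ic50, c("line", "drug", "ic50"), "`ic50`")
  check_columns(alterations, c("line", "gene", "kind", "altered"),
                "`alterations`")
  if (!setequal(unique(ic50$line), unique(alterations$line))) {
    abort("`ic50` and `alterations` must cover the same cell lines.")
  }

  events <- alterations |>
    unite("event", "gene", "kind", sep = ":", remove = FALSE)

  records <- crossing(drug = unique(ic50$drug),
                      distinct(events, .data$event, .data$gene, .data$kind)) |>
    pmap(function(drug, event, gene, kind) {
      carriers <- events$line[events$event == event & events$altered == 1L]
      drug_ic50 <- ic50[ic50$drug == drug, ]
      x <- drug_ic50$ic50[drug_ic50$line %in% carriers]
      y <- drug_ic50$ic50[!(drug_ic50$line %in% carriers)]
      n_mut <- length(x)
      n_wt <- length(y)
      if (n_mut == 0L || n_wt == 0L) return(NULL)
      rec <- tibble(
        drug = drug, gene = gene, kind = kind, event = event,
        n_mut = n_mut, n_wt = n_wt,
        mean_ic50_mut = mean(x), mean_ic50_wt = mean(y),
        effect_ratio = mean(x) / mean(y),
        t = NA_real_, p = NA_real_, fdr = NA_real_
      )
      if (n_mut >= 2L && n_wt >= 2L) {
        ht <- test_association(x, y, scale = scale, var_equal = var_equal)
        rec$t <- ht$t
        rec$p <- ht$p
      }
      rec
    }) |>
    list_rbind()

  if (is.null(records) || nrow(records) == 0L) {
    return(tibble(drug = character(), gene = character(), kind = character(),
                  event = character(), n_mut = integer(), n_wt = integer(),
                  mean_ic50_mut = double(), mean_ic50_wt = double(),
                  effect_ratio = double(), t = double(), p = double(),
                  fdr = double(), direction = character()))
  }
  tested <- !is.na(records$p)
  records$fdr[tested] <- adjust_bh(records$p[tested])
  records$fdr[!tested] <- 1  # singleton-group pairs: FDR forced to 1
  records |>
    mutate(direction = if_else(.data$effect_ratio < 1,
                               "sensitive", "resistant"))
}

#' Rank associations by FDR and select candidates at the largest FDR gap
#'
#' Records are sorted by ascending FDR (ties broken by descending
#' `|log10 effect_ratio|`, then by drug and event name). The gap index is
#' the rank `i < k_max` maximizing `fdr[i+1] / fdr[i]` (zero FDRs are
#' floored at 1e-300); candidates are the records above the gap. When every
#' FDR is equal there is no gap and no candidates, with a warning.
#'
#' @param records Output of [screen_associations()] (>= 2 rows).
#' @param k_max Largest candidate-set size considered.
#' @return The ranked tibble with `rank` and `candidate` columns; the chosen
#'   gap index is attached as attribute `"gap_index"`.
#' @export
rank_associations <- function(records, k_max = 10L) {
  check_columns(records, c("drug", "event", "effect_ratio", "fdr"),
                "`records`")
  if (nrow(records) < 2L) abort("Need >= 2 records to rank.")
  k_max <- check_count(k_max, "k_max")
  ranked <- records |>
    arrange(.data$fdr, desc(abs(log10(.data$effect_ratio))),
            .data$drug, .data$event) |>
    mutate(rank = row_number())
  f <- pmax(ranked$fdr, 1e-300)
  upto <- min(k_max, nrow(ranked) - 1L)
  ratios <- f[seq_len(upto) + 1L] / f[seq_len(upto)]
  if (all(ratios == 1)) {
    warn("All FDRs equal: no FDR gap, no candidates selected.")
    gap_index <- 0L
  } else {
    gap_index <- which.max(ratios)
  }
  ranked <- mutate(ranked, candidate = .data$rank <= gap_index)
  attr(ranked, "gap_index") <- gap_index
  ranked
}

#' Volcano-style plot of a ranked association screen
#'
#' @param records Output of [rank_associations()] (or
#'   [screen_associations()]).
#' @return A ggplot of log10 effect ratio against -log10 FDR; point size is
#'   the carrier-group size and candidates are highlighted.
#' @export
plot_volcano <- function(records) {
  check_columns(records, c("effect_ratio", "fdr", "n_mut"), "`records`")
  if (!"candidate" %in% names(records)) records$candidate <- FALSE
  ggplot(records,
         aes(log10(.data$effect_ratio), -log10(pmax(.data$fdr, 1e-300)),
             size = .data$n_mut, colour = .data$candidate)) +
    geom_point(alpha = 0.7) +
    scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "#b2182b"),
                        guide = "none") +
    labs(x = "log10 (mean IC50 carrier / non-carrier)",
         y = "-log10 FDR", size = "carrier lines") +
    theme_minimal()
}
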