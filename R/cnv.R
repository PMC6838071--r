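#' Normalize tumor coverage to the matched normal with GC correction
#'
#' Per-bin tumor/normal count ratios are median-centered (absorbing global
#' depth differences) and then divided by a GC-stratified median (deciles of
#' observed GC by default; strata with fewer than `min_stratum_bins` bins
#' borrow the global median). The output is the log2 of the corrected
#' ratio. Bins with zero normal count are masked, never divided.
#'
#' @param bins Tibble with `chrom`, `start`, `end`, `gc`, `normal_count`,
#'   `tumor_count`.
#' @param n_gc_strata Number of GC strata (quantile bins).
#' @param min_stratum_bins Minimum bins for a stratum to use its own median.
#' @return `bins` with `log2_ratio` (NA when masked) and `masked` appended.
#' @export
normalize_coverage <- function(bins, n_gc_strata = 10L,
                               min_stratum_bins = 20L) {
  check_columns(bins, c("chrom", "start", "end", "gc", "normal_count",
                        "tumor_count"), "`bins`")
  if (any(bins$normal_count < 0 | bins$tumor_count < 0)) {
    abort("Counts must be non-negative.")
  }
  n_gc_strata <- check_count(n_gc_strata, "n_gc_strata")
  masked <- bins$normal_count == 0
  ratio <- rep(NA_real_, nrow(bins))
  ratio[!masked] <- bins$tumor_count[!masked] / bins$normal_count[!masked]
  ratio <- ratio / median(ratio, na.rm = TRUE)

  breaks <- unique(quantile(bins$gc[!masked],
                            probs = seq(0, 1, length.out = n_gc_strata + 1L),
                            na.rm = TRUE))
  if (length(breaks) > 2L) {
    stratum <- cut(bins$gc, breaks = breaks, include.lowest = TRUE)
    global_med <- median(ratio, na.rm = TRUE)
    med <- tapply(ratio, stratum, median, na.rm = TRUE)
    n_in <- tapply(!masked, stratum, sum)
    med[is.na(med) | n_in < min_stratum_bins] <- global_med
    ratio <- ratio / unname(med[stratum])
  }
  bins |>
    mutate(log2_ratio = log2(ratio), masked = masked)
}

# Greedy bottom-up merging of adjacent bins into piecewise-constant
# segments. Each merge is scored by its residual-sum-of-squares increase in
# units of the bin-level noise variance (estimated from successive
# differences); merging proceeds while the cheapest merge costs less than
# the BIC penalty `penalty * log(n)` for the removed segment parameter.
merge_segments_1d <- function(x, penalty) {
  n <- length(x)
  if (n == 1L) return(tibble(first = 1L, last = 1L, mean = x))
  d <- diff(x)
  sigma2 <- (median(abs(d)) / 0.6745)^2 / 2
  sigma2 <- max(sigma2, 1e-12)
  threshold <- penalty * log(n) * sigma2

  cnt <- rep(1, n)
  sm <- x
  active <- rep(TRUE, n)
  right <- c(seq_len(n)[-1L], NA_integer_)
  left <- c(NA_integer_, seq_len(n)[-n])
  # cost[i]: RSS increase from merging segment i with its right neighbor
  merge_cost <- function(i, j) {
    (sm[i] / cnt[i] - sm[j] / cnt[j])^2 * cnt[i] * cnt[j] / (cnt[i] + cnt[j])
  }
  cost <- rep(Inf, n)
  for (i in seq_len(n - 1L)) cost[i] <- merge_cost(i, i + 1L)

  repeat {
    b <- which.min(cost)
    if (!is.finite(cost[b]) || cost[b] >= threshold) break
    j <- right[b]
    cnt[b] <- cnt[b] + cnt[j]
    sm[b] <- sm[b] + sm[j]
    active[j] <- FALSE
    right[b] <- right[j]
    if (!is.na(right[j])) left[right[j]] <- b
    cost[j] <- Inf
    cost[b] <- if (is.na(right[b])) Inf else merge_cost(b, right[b])
    if (!is.na(left[b])) cost[left[b]] <- merge_cost(left[b], b)
  }

  idx <- which(active)
  starts <- idx
  ends <- c(idx[-1L] - 1L, n)

  # local breakpoint refinement: each boundary may shift within a small
  # window to the exact RSS-minimizing split of its two flanking segments
  if (length(starts) > 1L) {
    window <- 10L
    for (k in seq_len(length(starts) - 1L)) {
      a <- starts[k]
      c_end <- ends[k + 1L]
      lo <- max(a, ends[k] - window)
      hi <- min(c_end - 1L, ends[k] + window)
      cand <- lo:hi
      rss_split <- vapply(cand, function(t) {
        left <- x[a:t]
        right <- x[(t + 1L):c_end]
        sum((left - mean(left))^2) + sum((right - mean(right))^2)
      }, numeric(1))
      t_best <- cand[which.min(rss_split)]
      ends[k] <- t_best
      starts[k + 1L] <- t_best + 1L
    }
  }
  means <- vapply(seq_along(starts),
                  function(k) mean(x[starts[k]:ends[k]]), numeric(1))
  tibble(first = starts, last = ends, mean = means)
}

#' Segment per-bin log2 ratios into piecewise-constant intervals
#'
#' Per-chromosome greedy bottom-up merging under a Bayesian information
#' criterion penalty. Segments partition the (unmasked) bins exactly and
#' each segment's `log2_ratio` is the mean of its member bins.
#'
#' @param bins Output of [normalize_coverage()]: tibble with `chrom`,
#'   `start`, `end`, `log2_ratio` (and optionally `masked`).
#' @param penalty BIC penalty multiplier (lambda >= 0); larger values give
#'   fewer segments.
#' @return Tibble `chrom`, `start`, `end`, `n_bins`, `log2_ratio`.
#' @export
segment_log_ratios <- function(bins, penalty = 2) {
  check_columns(bins, c("chrom", "start", "end", "log2_ratio"), "`bins`")
  check_scalar_number(penalty, "penalty", 0, Inf)
  if ("masked" %in% names(bins)) bins <- filter(bins, !.data$masked)
  bins <- filter(bins, is.finite(.data$log2_ratio))
  if (nrow(bins) == 0L) {
    abort("No usable bins to segment (all masked or non-finite).")
  }
  bins |>
    group_by(.data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    group_split() |>
    map(function(chr_bins) {
      segs <- merge_segments_1d(chr_bins$log2_ratio, penalty)
      tibble(chrom = chr_bins$chrom[1L],
             start = chr_bins$start[segs$first],
             end = chr_bins$end[segs$last],
             n_bins = segs$last - segs$first + 1L,
             log2_ratio = segs$mean)
    }) |>
    list_rbind()
}

#' Call segment-level copy-number status
#'
#' A segment is a gain when its log2 ratio is strictly greater than
#' `gain_threshold`, a loss when strictly less than `loss_threshold`,
#' otherwise neutral.
#'
#' @param segments Tibble from [segment_log_ratios()].
#' @param gain_threshold Log2-ratio threshold for gains (> 0).
#' @param loss_threshold Log2-ratio threshold for losses (< 0).
#' @return `segments` with a `call` column (`gain`/`loss`/`neutral`).
#' @export
call_segments <- function(segments, gain_threshold = 0.7,
                          loss_threshold = -0.7) {
  check_columns(segments, "log2_ratio", "`segments`")
  if (!(gain_threshold > 0 && loss_threshold < 0)) {
    abort("Thresholds must satisfy gain_threshold > 0 > loss_threshold.")
  }
  segments |>
    mutate(call = case_when(
      .data$log2_ratio > gain_threshold ~ "gain",
      .data$log2_ratio < loss_threshold ~ "loss",
      TRUE ~ "neutral"
    ))
}

#' Call gene-level copy-number status from called segments
#'
#' An exon overlaps a called segment when at least 1 bp intersects it. Per
#' gene the overlapping-exon fraction is computed separately for gain and
#' for loss segments; the gene's status is the direction whose fraction is
#' strictly greater than `min_exon_fraction` (larger fraction wins if both
#' qualify; an exact tie gives neutral with a warning).
#'
#' @param genes Exon table: tibble with `gene`, `chrom`, `start`, `end`
#'   (0-based half-open), one row per exon. Genes spanning multiple
#'   chromosomes are rejected with a warning.
#' @param segments Called segments from [call_segments()].
#' @param min_exon_fraction Strict lower bound on the overlapping-exon
#'   fraction (default 0.75, i.e. ">75% of exons").
#' @return Tibble `gene`, `status`, `fraction_exons`, `fraction_gain`,
#'   `fraction_loss`, `n_exons`.
#' @export
call_gene_cnv <- function(genes, segments, min_exon_fraction = 0.75) {
  check_columns(genes, c("gene", "chrom", "start", "end"), "`genes`")
  check_columns(segments, c("chrom", "start", "end", "call"), "`segments`")
  check_fraction(min_exon_fraction, "min_exon_fraction")

  multi <- genes |>
    group_by(.data$gene) |>
    summarise(n_chrom = n_distinct(.data$chrom), .groups = "drop") |>
    filter(.data$n_chrom > 1L)
  if (nrow(multi) > 0L) {
    warn(sprintf("Dropping gene(s) with exons on multiple chromosomes: %s.",
                 paste(multi$gene, collapse = ", ")))
    genes <- filter(genes, !(.data$gene %in% multi$gene))
  }

  overlap_frac <- function(exons, segs) {
    if (nrow(segs) == 0L) return(0)
    hit <- map_lgl(seq_len(nrow(exons)), function(i) {
      any(segs$chrom == exons$chrom[i] &
            segs$start < exons$end[i] & segs$end > exons$start[i])
    })
    mean(hit)
  }

  gain_segs <- filter(segments, .data$call == "gain")
  loss_segs <- filter(segments, .data$call == "loss")

  genes |>
    group_by(.data$gene) |>
    group_split() |>
    map(function(ex) {
      fg <- overlap_frac(ex, gain_segs)
      fl <- overlap_frac(ex, loss_segs)
      status <- "neutral"
      if (fg > min_exon_fraction || fl > min_exon_fraction) {
        if (fg == fl) {
          warn(sprintf(
            "Gene %s: gain and loss exon fractions tie at %.3f; calling neutral.",
            ex$gene[1L], fg))
        } else {
          status <- if (fg > fl) "gain" else "loss"
        }
      }
      tibble(gene = ex$gene[1L], status = status,
             fraction_exons = max(fg, fl),
             fraction_gain = fg, fraction_loss = fl,
             n_exons = nrow(ex))
    }) |>
    list_rbind() |>
    arrange(.data$gene)
}
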