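#' Somatic filter configuration
#'
#' Thresholds of the post-calling tumor/normal somatic filter chain. All
#' "minimum/maximum is X" thresholds are inclusive; the population-frequency
#' filter removes strictly greater than `max_population_freq`.
#'
#' @param min_tumor_depth Minimum total coverage at the site in the tumor.
#' @param max_normal_vaf Maximum variant allele fraction in the matched
#'   normal.
#' @param min_vaf_diff Minimum (tumor - normal) VAF difference, signed.
#' @param max_strand_bias Maximum fraction of alt reads on the majority
#'   strand.
#' @param min_alt_reads Minimum alt-supporting reads in the tumor.
#' @param max_population_freq Variants with population frequency strictly
#'   above this are removed.
#' @param retained_effect_classes Effect classes advanced to analysis;
#'   everything else (including `"other"`) is dropped.
#' @param drop_near_repeat Drop candidates flagged as lying near a tandem
#'   repeat.
#' @return A `filter_config` object.
#' @export
filter_config <- function(min_tumor_depth = 30,
                          max_normal_vaf = 0.03,
                          min_vaf_diff = 0.05,
                          max_strand_bias = 0.9,
                          min_alt_reads = 5,
                          max_population_freq = 0.015,
                          retained_effect_classes = c(
                            "missense", "stopgain", "stoploss", "splice",
                            "frameshift_ins", "frameshift_del",
                            "nonframeshift_ins", "nonframeshift_del",
                            "synonymous"),
                          drop_near_repeat = TRUE) {
  check_scalar_number(min_tumor_depth, "min_tumor_depth", 0, Inf)
  check_fraction(max_normal_vaf, "max_normal_vaf")
  check_fraction(min_vaf_diff, "min_vaf_diff")
  check_fraction(max_strand_bias, "max_strand_bias")
  check_scalar_number(min_alt_reads, "min_alt_reads", 0, Inf)
  check_fraction(max_population_freq, "max_population_freq")
  stopifnot(is.character(retained_effect_classes),
            length(retained_effect_classes) >= 1L,
            is.logical(drop_near_repeat), length(drop_near_repeat) == 1L)
  structure(list(min_tumor_depth = min_tumor_depth,
                 max_normal_vaf = max_normal_vaf,
                 min_vaf_diff = min_vaf_diff,
                 max_strand_bias = max_strand_bias,
                 min_alt_reads = min_alt_reads,
                 max_population_freq = max_population_freq,
                 retained_effect_classes = retained_effect_classes,
                 drop_near_repeat = drop_near_repeat),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat("  tumor depth >=", x$min_tumor_depth,
      "| normal VAF <=", x$max_normal_vaf,
      "| VAF diff >=", x$min_vaf_diff, "\n")
  cat("  strand bias <=", x$max_strand_bias,
      "| alt reads >=", x$min_alt_reads,
      "| population freq <=", x$max_population_freq, "\n")
  invisible(x)
}

variant_required_columns <- function() {
  c("tumor_depth", "tumor_alt_reads", "tumor_vaf", "normal_vaf",
    "strand_bias", "population_freq", "effect_class", "near_repeat")
}

validate_variants <- function(candidates) {
  check_columns(candidates, variant_required_columns(), "Variant table")
  frac_cols <- c("tumor_vaf", "normal_vaf", "strand_bias", "population_freq")
  for (col in frac_cols) {
    bad <- which(!is.finite(candidates[[col]]) |
                   candidates[[col]] < 0 | candidates[[col]] > 1)
    if (length(bad) > 0L) {
      abort(sprintf("Malformed variant record: `%s` outside [0, 1] at row %d.",
                    col, bad[1L]))
    }
  }
  bad <- which(candidates$tumor_alt_reads > candidates$tumor_depth)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Malformed variant record: tumor_alt_reads > tumor_depth at row %d.",
      bad[1L]))
  }
  invisible(candidates)
}

#' Apply the somatic variant filter chain
#'
#' A candidate is retained iff it clears every criterion: tumor depth,
#' normal VAF, tumor-normal VAF difference, strand bias, alt-read support,
#' population frequency, retained effect class, and (optionally) distance
#' from tandem repeats. Every failing candidate lists all criteria it
#' violates.
#'
#' @param candidates Tibble of variant candidates with at least the columns
#'   `tumor_depth`, `tumor_alt_reads`, `tumor_vaf`, `normal_vaf`,
#'   `strand_bias`, `population_freq`, `effect_class`, `near_repeat`.
#' @param config A [filter_config()].
#' @return The input tibble with two columns appended: `pass` (logical) and
#'   `failed_criteria` (list-column of criterion names, empty when `pass`).
#' @seealso [retained_variants()] for the retained subset only.
#' @export
apply_filters <- function(candidates, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  candidates <- as_tibble(candidates)
  validate_variants(candidates)
  fails <- list(
    min_tumor_depth = candidates$tumor_depth < config$min_tumor_depth,
    max_normal_vaf = candidates$normal_vaf > config$max_normal_vaf,
    min_vaf_diff = (candidates$tumor_vaf - candidates$normal_vaf) <
      config$min_vaf_diff,
    max_strand_bias = candidates$strand_bias > config$max_strand_bias,
    min_alt_reads = candidates$tumor_alt_reads < config$min_alt_reads,
    max_population_freq = candidates$population_freq >
      config$max_population_freq,
    effect_class = !(candidates$effect_class %in%
                       config$retained_effect_classes),
    near_repeat = if (config$drop_near_repeat) candidates$near_repeat else
      rep(FALSE, nrow(candidates))
  )
  fail_mat <- do.call(cbind, fails)
  failed_criteria <- apply(fail_mat, 1L, function(row) names(fails)[row],
                           simplify = FALSE)
  candidates |>
    mutate(pass = rowSums(fail_mat) == 0L,
           failed_criteria = failed_criteria)
}

#' Retained variants after filtering
#'
#' @param candidates Variant tibble; filtered with `config` first unless it
#'   already carries a `pass` column.
#' @param config A [filter_config()].
#' @return The retained rows, without the decision columns.
#' @export
retained_variants <- function(candidates, config = filter_config()) {
  if (!"pass" %in% names(candidates)) {
    candidates <- apply_filters(candidates, config)
  }
  candidates |>
    filter(.data$pass) |>
    select(-"pass", -"failed_criteria")
}

#' Flag variants near tandem-repeat regions
#'
#' Marks `near_repeat = TRUE` for variants lying within `margin` bp of any
#' interval in a repeat track (BED-style, 0-based half-open).
#'
#' @param variants Tibble with `chrom` and `pos` (1-based).
#' @param repeats Tibble with `chrom`, `start`, `end` (0-based half-open).
#' @param margin Proximity in bp.
#' @return `variants` with `near_repeat` set.
#' @export
flag_near_repeat <- function(variants, repeats, margin = 5L) {
  check_columns(variants, c("chrom", "pos"), "`variants`")
  check_columns(repeats, c("chrom", "start", "end"), "`repeats`")
  margin <- check_count(margin, "margin", min = 0L)
  pos0 <- variants$pos - 1L
  near <- map_lgl(seq_len(nrow(variants)), function(i) {
    r <- repeats[repeats$chrom == variants$chrom[i], ]
    any(pos0[i] >= r$start - margin & pos0[i] < r$end + margin)
  })
  mutate(variants, near_repeat = near)
}

#' Classify a base substitution in the pyrimidine-reference convention
#'
#' Single-base substitutions are collapsed onto the six classes with a
#' pyrimidine (C or T) reference by complementing purine-reference pairs;
#' multi-base or length-changing alleles are `"not_snv"`.
#'
#' @param ref,alt Allele strings (A/C/G/T characters).
#' @return Character vector over
#'   `{C>A, C>G, C>T, T>A, T>C, T>G, not_snv}`.
#' @export
classify_substitution <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  if (any(grepl("[^ACGT]", c(ref, alt)))) {
    abort("Alleles must contain only A/C/G/T characters.")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- rep("not_snv", length(ref))
  snv <- nchar(ref) == 1L & nchar(alt) == 1L & ref != alt
  r <- ref[snv]
  a <- alt[snv]
  flip <- r %in% c("A", "G")
  r[flip] <- comp[r[flip]]
  a[flip] <- comp[a[flip]]
  out[snv] <- paste0(r, ">", a)
  out
}

#' Summarize the retained mutation spectrum
#'
#' Proportions of retained variants by effect class, and of retained SNVs by
#' pyrimidine-reference substitution class.
#'
#' @param retained Tibble of retained variants with `effect_class`, `ref`,
#'   `alt`.
#' @return Tibble `metric` (`"effect_class"` or `"substitution"`), `class`,
#'   `n`, `proportion`; each metric's proportions sum to 1. Empty input
#'   yields an empty summary.
#' @export
summarize_spectrum <- function(retained) {
  empty <- tibble(metric = character(), class = character(),
                  n = integer(), proportion = double())
  if (nrow(retained) == 0L) return(empty)
  check_columns(retained, c("effect_class", "ref", "alt"), "`retained`")
  by_class <- retained |>
    count(class = .data$effect_class, name = "n") |>
    mutate(metric = "effect_class", proportion = .data$n / sum(.data$n))
  subs <- classify_substitution(retained$ref, retained$alt)
  subs <- subs[subs != "not_snv"]
  by_sub <- if (length(subs) > 0L) {
    tibble(class = subs) |>
      count(.data$class, name = "n") |>
      mutate(metric = "substitution", proportion = .data$n / sum(.data$n))
  } else empty
  bind_rows(by_class, by_sub) |>
    select("metric", "class", "n", "proportion") |>
    arrange(.data$metric, desc(.data$proportion))
}
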