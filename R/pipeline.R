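#' Pipeline configuration
#'
#' Nested configuration for a full synthetic-cohort run. Defaults equal the
#' thresholds and study geometry the package documents: filter thresholds
#' (30x / 0.03 / 0.05 / 0.9 / 5 reads / 0.015), CNV thresholds (log2 +-0.7,
#' exon fraction 0.75, penalty 2), 10-dose 3.3-fold viability curves in
#' quadruplicate, raw-scale pooled-variance screen. Unknown keys are
#' rejected.
#'
#' @param filter Arguments for [filter_config()].
#' @param cnv List: `gain_threshold`, `loss_threshold`,
#'   `min_exon_fraction`, `penalty`, `n_gc_strata`.
#' @param dose_response List: `level`, `pooled`.
#' @param screen List: `scale`, `var_equal`, `k_max`.
#' @param simulate List: `n_samples`, `n_somatic`, `artifact_rate`,
#'   `n_bins`, `depth_mean`, `survival_n`, `survival_hazards`,
#'   `censor_rate`.
#' @param panel A [panel_spec()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(filter = list(), cnv = list(),
                            dose_response = list(), screen = list(),
                            simulate = list(), panel = panel_spec()) {
  defaults <- list(
    filter = list(),
    cnv = list(gain_threshold = 0.7, loss_threshold = -0.7,
               min_exon_fraction = 0.75, penalty = 2, n_gc_strata = 10L),
    dose_response = list(level = 0.5, pooled = FALSE),
    screen = list(scale = "raw", var_equal = TRUE, k_max = 10L),
    simulate = list(n_samples = 161L, n_somatic = 300L, artifact_rate = 0.2,
                    n_bins = 1500L, depth_mean = 100,
                    survival_n = 60L,
                    survival_hazards = c(alt = 0.06, wt = 0.02),
                    censor_rate = 0.2)
  )
  supplied <- list(filter = filter, cnv = cnv, dose_response = dose_response,
                   screen = screen, simulate = simulate)
  merged <- imap(defaults, function(def, section) {
    sup <- supplied[[section]]
    if (section == "filter") return(sup)  # validated by filter_config()
    unknown <- setdiff(names(sup), names(def))
    if (length(unknown) > 0L) {
      abort(sprintf("Unknown key(s) in config section `%s`: %s.",
                    section, paste(unknown, collapse = ", ")))
    }
    modifyList(def, sup)
  })
  merged$filter <- do.call(filter_config, merged$filter)
  stopifnot(inherits(panel, "panel_spec"))
  merged$panel <- panel
  structure(merged, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> sections:",
      paste(names(unclass(x)), collapse = ", "), "\n")
  invisible(x)
}

config_hash <- function(config) {
  rlang::hash(unclass(config)[setdiff(names(unclass(config)), "panel")])
}

# stage-table writer: plain TSV with a provenance comment header
write_stage_table <- function(tbl, path, hash) {
  header <- sprintf("# pdcscreen %s config=%s",
                    as.character(packageVersion("pdcscreen")), hash)
  writeLines(header, path)
  # list-columns (e.g. failed_criteria) are flattened for the text artifact
  tbl <- mutate(tbl, dplyr::across(
    dplyr::where(is.list), ~ map_chr(.x, paste, collapse = ",")))
  readr::write_tsv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates every input from the configuration and seed, then executes the
#' stages in order: somatic variant filtering, coverage normalization /
#' segmentation / gene-level CNV calls, per-curve IC50 fitting, the
#' drug-by-genotype association screen with FDR-gap candidate selection,
#' and cohort statistics (recurrence, survival). Reruns with the same
#' config and seed are identical. When `out_dir` is given every stage table
#' is written as TSV with a provenance header, plus a JSON run report.
#'
#' @param config A [pipeline_config()].
#' @param seed Integer seed driving every stage's randomness.
#' @param out_dir Optional output directory.
#' @return Named list of stage results: `variants`, `spectrum`, `coverage`,
#'   `segments`, `gene_cnv`, `cohort`, `recurrence`, `ic50`,
#'   `associations`, `candidates`, `survival`, `logrank`, `report`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- check_count(seed, "seed", min = 0L)
  sim <- config$simulate
  hash <- config_hash(config)
  warnings_log <- character()

  # 1. cohort + variant filtering
  cohort <- simulate_cohort(cohort_spec(n_samples = sim$n_samples),
                            seed = derive_seed(seed, 1L))
  variants <- simulate_variants(n_somatic = sim$n_somatic,
                                artifact_rate = sim$artifact_rate,
                                config = config$filter,
                                seed = derive_seed(seed, 2L))
  decisions <- apply_filters(variants, config$filter)
  retained <- retained_variants(decisions)
  if (nrow(retained) == 0L) {
    warnings_log <- c(warnings_log, "variant stage: no variants retained")
  }
  spectrum <- summarize_spectrum(retained)

  # 2. copy number: planted segments -> bins -> segments -> gene calls
  # (segment positions scale with the configured bin count)
  nb <- sim$n_bins
  planted <- tibble(start_bin = as.integer(round(nb * c(0.15, 0.60))),
                    end_bin = as.integer(round(nb * c(0.28, 0.68))),
                    log2_ratio = c(1, -1.2))
  cov_spec <- coverage_spec(n_bins = nb, depth_mean = sim$depth_mean,
                            segments = planted)
  coverage <- simulate_coverage(cov_spec, seed = derive_seed(seed, 3L))
  normalized <- normalize_coverage(coverage,
                                   n_gc_strata = config$cnv$n_gc_strata)
  segments <- segment_log_ratios(normalized, penalty = config$cnv$penalty) |>
    call_segments(gain_threshold = config$cnv$gain_threshold,
                  loss_threshold = config$cnv$loss_threshold)
  bw <- cov_spec$bin_width
  exon_track <- function(gene, from_bin, to_bin) {
    starts <- as.integer(round(seq(from_bin, to_bin, length.out = 5L))) * bw
    tibble(gene = gene, chrom = "chr1", start = starts, end = starts + 200L)
  }
  genes <- bind_rows(
    exon_track("GENE_GAIN", nb * 0.16, nb * 0.27),
    exon_track("GENE_LOSS", nb * 0.61, nb * 0.67),
    exon_track("GENE_FLAT", nb * 0.40, nb * 0.50))
  gene_cnv <- call_gene_cnv(genes, segments,
                            min_exon_fraction = config$cnv$min_exon_fraction)

  # 3. drug screen: viability -> IC50 -> associations -> candidates
  alterations <- simulate_panel_alterations(config$panel,
                                            seed = derive_seed(seed, 4L))
  viability <- simulate_viability(config$panel, alterations,
                                  seed = derive_seed(seed, 5L))
  ic50 <- fit_ic50(viability, pooled = config$dose_response$pooled,
                   level = config$dose_response$level)
  associations <- screen_associations(ic50, alterations,
                                      scale = config$screen$scale,
                                      var_equal = config$screen$var_equal)
  ranked <- rank_associations(associations, k_max = config$screen$k_max)
  candidates <- filter(ranked, .data$candidate)

  # 4. cohort statistics
  recurrence_tbl <- recurrence(cohort)
  clinical <- simulate_survival(n_per_group = sim$survival_n,
                                hazards = sim$survival_hazards,
                                censor_rate = sim$censor_rate,
                                seed = derive_seed(seed, 6L))
  km <- km_estimate(clinical)
  logrank <- logrank_test(clinical)

  report <- list(
    package = "pdcscreen",
    version = as.character(packageVersion("pdcscreen")),
    config_hash = hash,
    seed = seed,
    counts = list(
      variants_in = nrow(variants),
      variants_retained = nrow(retained),
      variants_failed_by_criterion = as.list(
        table(unlist(decisions$failed_criteria))),
      segments = nrow(segments),
      genes_called = sum(gene_cnv$status != "neutral"),
      pairs_tested = sum(!is.na(associations$p)),
      candidates = nrow(candidates)
    ),
    candidates = candidates$event |> paste(candidates$drug, sep = " ~ "),
    logrank_p = logrank$p,
    warnings = warnings_log
  )

  results <- list(variants = decisions, spectrum = spectrum,
                  coverage = normalized, segments = segments,
                  gene_cnv = gene_cnv, cohort = cohort,
                  recurrence = recurrence_tbl, alterations = alterations,
                  ic50 = ic50, associations = ranked,
                  candidates = candidates, survival = km,
                  logrank = logrank, report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tables <- results[c("variants", "spectrum", "segments", "gene_cnv",
                        "recurrence", "ic50", "associations", "candidates",
                        "survival")]
    for (nm in names(tables)) {
      write_stage_table(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                        hash)
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  results
}
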