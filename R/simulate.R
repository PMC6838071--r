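#' Default per-gene alteration frequencies for a simulated ESCC cohort
#'
#' Recurrence frequencies of the most common somatic copy-number events in
#' esophageal squamous cell carcinoma cohorts: *CCND1*-amplicon genes
#' (CCND1/FGF3/FGF4/FGF19 on 11q13), *SOX2*, *MCL1*, *CDKN1B* gains, and
#' *MST1R*, *CDKN2A*, *CDKN2B* (9p21) losses, plus a handful of recurrently
#' mutated genes (TP53, KMT2D, NOTCH1, PIK3CA, EP300) carried as SNV/indel
#' events.
#'
#' @return A tibble with columns `gene`, `kind` (one of `"gain"`, `"loss"`,
#'   `"snv_indel"`) and `freq` (per-sample alteration probability).
#' @export
default_alteration_freqs <- function() {
  tibble(
    gene = c("CCND1", "MCL1", "FGF4", "FGF3", "SOX2", "FGF19", "CDKN1B",
             "MST1R", "CDKN2A", "CDKN2B",
             "TP53", "KMT2D", "NOTCH1", "PIK3CA", "EP300"),
    kind = c(rep("gain", 7L), rep("loss", 3L), rep("snv_indel", 5L)),
    freq = c(0.42, 0.38, 0.35, 0.35, 0.34, 0.34, 0.30,
             0.30, 0.26, 0.13,
             0.60, 0.30, 0.25, 0.15, 0.15)
  )
}

#' Specify a simulated patient cohort
#'
#' @param n_samples Number of tumor/normal pairs in the cohort.
#' @param alteration_freqs Tibble with columns `gene`, `kind`, `freq`; each
#'   row is an independent per-sample Bernoulli alteration event.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_samples = 161L,
                        alteration_freqs = default_alteration_freqs()) {
  n_samples <- check_count(n_samples, "n_samples")
  check_columns(alteration_freqs, c("gene", "kind", "freq"),
                "`alteration_freqs`")
  if (any(alteration_freqs$freq < 0 | alteration_freqs$freq > 1)) {
    abort("All alteration frequencies must lie in [0, 1].")
  }
  if (anyDuplicated(paste(alteration_freqs$gene, alteration_freqs$kind))) {
    abort("Duplicated (gene, kind) rows in `alteration_freqs`.")
  }
  structure(
    list(n_samples = n_samples,
         alteration_freqs = as_tibble(alteration_freqs)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_samples, "samples,",
      nrow(x$alteration_freqs), "alteration events\n")
  invisible(x)
}

#' Simulate a binary sample-by-alteration cohort
#'
#' Draws each (sample, gene, kind) alteration as an independent Bernoulli
#' event at the frequency given in the spec.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @return Long tibble with columns `sample`, `gene`, `kind`, `altered`
#'   (0/1).
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  samples <- sprintf("S%03d", seq_len(spec$n_samples))
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    crossing(sample = samples, spec$alteration_freqs) |>
      mutate(altered = rbinom(n(), 1L, .data$freq)) |>
      select("sample", "gene", "kind", "altered")
  })
}

# Effect-class and substitution weights used for simulated true somatic
# variants: the mutation spectrum typical of ESCC panels (C>T transitions
# dominate; missense > synonymous > stop-gain > splice).
variant_class_weights <- function() {
  c(missense = 0.57, synonymous = 0.30, stopgain = 0.07, splice = 0.03,
    frameshift_del = 0.01, frameshift_ins = 0.005, stoploss = 0.005,
    nonframeshift_del = 0.005, nonframeshift_ins = 0.005)
}

filter_criterion_names <- function() {
  c("min_tumor_depth", "max_normal_vaf", "min_vaf_diff", "max_strand_bias",
    "min_alt_reads", "max_population_freq", "effect_class", "near_repeat")
}

# one simulated SNV substitution with C>T transition excess
sample_substitutions <- function(n) {
  classes <- c("C>T", "C>A", "C>G", "T>A", "T>C", "T>G")
  weights <- c(0.45, 0.12, 0.10, 0.08, 0.15, 0.10)
  pick <- sample(classes, n, replace = TRUE, prob = weights)
  strand_flip <- runif(n) < 0.5
  ref <- substr(pick, 1L, 1L)
  alt <- substr(pick, 3L, 3L)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref <- if_else(strand_flip, unname(comp[ref]), ref)
  alt <- if_else(strand_flip, unname(comp[alt]), alt)
  tibble(ref = ref, alt = alt)
}

#' Simulate caller-emitted somatic variant candidates with planted artifacts
#'
#' Emits `n_somatic` true somatic variants constructed to satisfy every
#' criterion of the somatic filter chain, plus artifacts (at rate
#' `artifact_rate` of the final table) that each violate exactly one named
#' criterion, with truth labels attached.
#'
#' @param n_somatic Number of true somatic variants.
#' @param artifact_rate Fraction of the emitted table that is artifactual,
#'   in \[0, 1\].
#' @param config A [filter_config()] whose thresholds the true variants must
#'   clear (with margin) and the artifacts must individually break.
#' @param seed Integer seed.
#' @return Tibble of variant candidates with the columns required by
#'   [apply_filters()], plus `truth` (`"somatic"`/`"artifact"`) and
#'   `violated` (criterion name or `NA`).
#' @export
simulate_variants <- function(n_somatic = 200L, artifact_rate = 0.2,
                              config = filter_config(), seed = 1L) {
  n_somatic <- check_count(n_somatic, "n_somatic", min = 0L)
  check_fraction(artifact_rate, "artifact_rate")
  stopifnot(inherits(config, "filter_config"))

  n_artifact <- if (artifact_rate >= 1) {
    abort("`artifact_rate` must be < 1 so at least one true variant remains.")
  } else {
    as.integer(round(n_somatic * artifact_rate / (1 - artifact_rate)))
  }

  withr::with_seed(check_count(seed, "seed", min = 0L), {
    somatic <- simulate_true_variants(n_somatic, config)
    out <- somatic
    if (n_artifact > 0L) {
      criteria <- sample(filter_criterion_names(), n_artifact, replace = TRUE)
      artifacts <- map(criteria, function(cr) {
        base <- simulate_true_variants(1L, config)
        break_criterion(base, cr, config)
      }) |> list_rbind()
      out <- bind_rows(somatic, artifacts)
    }
    out |>
      mutate(chrom = sample(paste0("chr", 1:22), n(), replace = TRUE),
             pos = sample.int(2e8, n(), replace = TRUE)) |>
      select("chrom", "pos", "ref", "alt", "tumor_depth", "tumor_alt_reads",
             "tumor_vaf", "normal_vaf", "strand_bias", "population_freq",
             "effect_class", "near_repeat", "truth", "violated")
  })
}

# true somatic candidates clearing every threshold with margin
simulate_true_variants <- function(n, cfg) {
  depth <- sample(seq(cfg$min_tumor_depth + 20L, 500L), n, replace = TRUE)
  vaf <- runif(n, cfg$min_vaf_diff + 0.10, 0.60)
  normal_vaf <- runif(n, 0, min(cfg$max_normal_vaf, 0.02))
  alt_reads <- pmax(ceiling(depth * vaf), cfg$min_alt_reads)
  weights <- variant_class_weights()
  classes <- sample(names(weights), n, replace = TRUE, prob = weights)
  subs <- sample_substitutions(n)
  snv <- !grepl("frameshift", classes)
  # indels carry length-changing alleles
  subs$ref[!snv] <- paste0(subs$ref[!snv], "A")
  tibble(
    ref = subs$ref, alt = subs$alt,
    tumor_depth = depth, tumor_alt_reads = as.integer(alt_reads),
    tumor_vaf = pmin(vaf + normal_vaf, 0.95), normal_vaf = normal_vaf,
    strand_bias = runif(n, 0.5, cfg$max_strand_bias - 0.05),
    population_freq = runif(n, 0, cfg$max_population_freq * 0.6),
    effect_class = classes,
    near_repeat = FALSE,
    truth = "somatic", violated = NA_character_
  )
}

# mutate one passing candidate so it violates exactly `criterion`
break_criterion <- function(v, criterion, cfg) {
  switch(
    criterion,
    min_tumor_depth = {
      v$tumor_depth <- sample(seq(20L, cfg$min_tumor_depth - 1L), 1L)
      v$tumor_vaf <- 0.5
      v$normal_vaf <- 0
      v$tumor_alt_reads <- as.integer(ceiling(v$tumor_depth * 0.5))
    },
    max_normal_vaf = {
      v$normal_vaf <- runif(1L, cfg$max_normal_vaf + 0.01, 0.30)
      v$tumor_vaf <- min(v$normal_vaf + cfg$min_vaf_diff + 0.10, 0.95)
      v$tumor_alt_reads <-
        as.integer(max(ceiling(v$tumor_depth * v$tumor_vaf),
                       cfg$min_alt_reads))
    },
    min_vaf_diff = {
      v$tumor_depth <- 600L
      v$normal_vaf <- runif(1L, 0.01, cfg$max_normal_vaf)
      v$tumor_vaf <- v$normal_vaf + runif(1L, 0.005, cfg$min_vaf_diff - 0.005)
      v$tumor_alt_reads <-
        as.integer(max(ceiling(v$tumor_depth * v$tumor_vaf),
                       cfg$min_alt_reads))
    },
    max_strand_bias = {
      v$strand_bias <- runif(1L, cfg$max_strand_bias + 0.01, 1)
    },
    min_alt_reads = {
      # keep the implied VAF above min_vaf_diff so only support fails
      v$tumor_alt_reads <- sample(seq(2L, cfg$min_alt_reads - 1L), 1L)
      v$tumor_depth <- as.integer(cfg$min_tumor_depth)
      v$tumor_vaf <- v$tumor_alt_reads / v$tumor_depth
      v$normal_vaf <- 0
    },
    max_population_freq = {
      v$population_freq <- runif(1L, cfg$max_population_freq + 0.001, 0.5)
    },
    effect_class = {
      v$effect_class <- "other"
      v$ref <- substr(v$ref, 1L, 1L)
    },
    near_repeat = {
      v$near_repeat <- TRUE
    },
    abort(sprintf("Unknown criterion `%s`.", criterion))
  )
  v$truth <- "artifact"
  v$violated <- criterion
  v
}

#' Specify a simulated coverage track with planted copy-number segments
#'
#' @param n_bins Number of genomic bins (single chromosome).
#' @param bin_width Bin width in bp.
#' @param depth_mean Expected normal-sample read count per bin.
#' @param segments Tibble with columns `start_bin`, `end_bin` (0-based
#'   half-open bin indices) and `log2_ratio`, non-overlapping.
#' @param gc Optional per-bin GC fraction (length `n_bins`); default is a
#'   smooth wave in \[0.35, 0.55\].
#' @param gc_bias Function mapping GC fraction to a multiplicative coverage
#'   factor, applied identically to tumor and normal.
#' @return A `coverage_spec` object.
#' @export
coverage_spec <- function(n_bins = 2000L, bin_width = 1000L,
                          depth_mean = 100, segments = NULL,
                          gc = NULL, gc_bias = function(gc) rep(1, length(gc))) {
  n_bins <- check_count(n_bins, "n_bins")
  bin_width <- check_count(bin_width, "bin_width")
  check_scalar_number(depth_mean, "depth_mean", 0, Inf, strict_lower = TRUE)
  segments <- segments %||% tibble(start_bin = integer(), end_bin = integer(),
                                   log2_ratio = double())
  check_columns(segments, c("start_bin", "end_bin", "log2_ratio"),
                "`segments`")
  if (nrow(segments) > 0L) {
    segments <- arrange(segments, .data$start_bin)
    if (any(segments$start_bin < 0) || any(segments$end_bin > n_bins) ||
        any(segments$end_bin <= segments$start_bin)) {
      abort("Planted segments must satisfy 0 <= start_bin < end_bin <= n_bins.")
    }
    if (nrow(segments) > 1L &&
        any(segments$start_bin[-1L] < segments$end_bin[-nrow(segments)])) {
      abort("Planted segments must not overlap.")
    }
  }
  # default GC track: a slow wave plus golden-ratio scatter, so GC strata
  # sample bins genome-wide rather than one contiguous region
  gc <- gc %||% (0.45 + 0.06 * sin(seq_len(n_bins) / 150) +
                   0.20 * ((seq_len(n_bins) * 0.6180339887) %% 1 - 0.5))
  if (length(gc) != n_bins || any(gc < 0 | gc > 1)) {
    abort("`gc` must give one fraction in [0, 1] per bin.")
  }
  structure(list(n_bins = n_bins, bin_width = bin_width,
                 depth_mean = depth_mean, segments = as_tibble(segments),
                 gc = gc, gc_bias = gc_bias),
            class = "coverage_spec")
}

#' Simulate a paired tumor/normal binned coverage table
#'
#' Normal counts are Poisson around `depth_mean` times the GC-bias factor;
#' tumor counts are additionally scaled by `2^log2_ratio` inside planted
#' segments. The same GC bias is applied to both members of the pair. With
#' `noise = "none"` the expected (real-valued) counts are emitted, so ratios
#' are exact.
#'
#' @param spec A [coverage_spec()].
#' @param seed Integer seed.
#' @param noise `"poisson"` (default) or `"none"`.
#' @return Tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `gc`, `normal_count`, `tumor_count`, `true_log2_ratio`.
#' @export
simulate_coverage <- function(spec = coverage_spec(), seed = 1L,
                              noise = c("poisson", "none")) {
  stopifnot(inherits(spec, "coverage_spec"))
  noise <- match.arg(noise)
  n <- spec$n_bins
  true_lr <- rep(0, n)
  if (nrow(spec$segments) > 0L) {
    for (i in seq_len(nrow(spec$segments))) {
      idx <- seq(spec$segments$start_bin[i] + 1L, spec$segments$end_bin[i])
      true_lr[idx] <- spec$segments$log2_ratio[i]
    }
  }
  bias <- spec$gc_bias(spec$gc)
  lambda_n <- spec$depth_mean * bias
  lambda_t <- lambda_n * 2^true_lr
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    if (noise == "poisson") {
      normal_count <- rpois(n, lambda_n)
      tumor_count <- rpois(n, lambda_t)
    } else {
      normal_count <- lambda_n
      tumor_count <- lambda_t
    }
    tibble(chrom = "chr1",
           start = (seq_len(n) - 1L) * spec$bin_width,
           end = seq_len(n) * spec$bin_width,
           gc = spec$gc,
           normal_count = normal_count,
           tumor_count = tumor_count,
           true_log2_ratio = true_lr)
  })
}

#' Default 46-compound targeted-therapy panel
#'
#' Compound names for a simulated screen of targeted agents against genes
#' recurrently altered in ESCC (CDK4/6, MEK, EGFR-family, PI3K/mTOR, PARP,
#' kinase and epigenetic inhibitors).
#'
#' @return Character vector of 46 drug names.
#' @export
default_drug_panel <- function() {
  c("palbociclib", "ribociclib", "abemaciclib", "trametinib", "selumetinib",
    "imatinib", "dasatinib", "nilotinib", "azathioprine", "MM-102",
    "KU-55933", "momelotinib", "ruxolitinib", "gefitinib", "erlotinib",
    "afatinib", "lapatinib", "sunitinib", "sorafenib", "vemurafenib",
    "dabrafenib", "everolimus", "temsirolimus", "buparlisib", "alpelisib",
    "idelalisib", "olaparib", "rucaparib", "niraparib", "veliparib",
    "crizotinib", "ceritinib", "alectinib", "cabozantinib", "vandetanib",
    "tofacitinib", "ibrutinib", "vorinostat", "panobinostat", "entinostat",
    "azacitidine", "decitabine", "bortezomib", "carfilzomib", "volasertib",
    "nutlin-3")
}

#' Specify a simulated drug-screening panel
#'
#' The default mirrors a screen of 8 patient-derived lines against 46
#' targeted compounds, with CDK4/6 inhibitors planted as sensitive in
#' *CDKN2A*-loss carriers (5 carriers / 3 non-carriers).
#'
#' @param n_lines Number of cell lines (>= 2).
#' @param drugs Character vector of drug names.
#' @param planted_effects Tibble with columns `drug`, `gene`, `kind`,
#'   `fold_change` (> 0): carrier lines have IC50 = base x fold_change.
#' @param base_ic50 Baseline IC50 in uM, either one value or one per drug.
#' @param top_dose Top concentration of the dilution series, uM.
#' @param dilution Fold dilution between consecutive doses.
#' @param n_concentrations Number of doses per curve.
#' @param n_replicates Wells per dose (independent experiments).
#' @param cv_noise Relative SD of the multiplicative viability noise.
#' @param hill Hill slope of the generating curves.
#' @param carrier_count Carriers per planted-effect event when simulating
#'   panel alterations (default 5 of 8).
#' @return A `panel_spec` object.
#' @export
panel_spec <- function(n_lines = 8L,
                       drugs = default_drug_panel(),
                       planted_effects = tibble(
                         drug = c("palbociclib", "ribociclib"),
                         gene = "CDKN2A", kind = "loss",
                         fold_change = 0.05),
                       base_ic50 = 1, top_dose = 10, dilution = 3.3,
                       n_concentrations = 10L, n_replicates = 4L,
                       cv_noise = 0.1, hill = 1, carrier_count = 5L) {
  n_lines <- check_count(n_lines, "n_lines", min = 2L)
  stopifnot(is.character(drugs), length(drugs) >= 1L, !anyDuplicated(drugs))
  check_columns(planted_effects, c("drug", "gene", "kind", "fold_change"),
                "`planted_effects`")
  if (nrow(planted_effects) > 0L) {
    if (any(planted_effects$fold_change <= 0)) {
      abort("Planted fold changes must be > 0.")
    }
    bad <- setdiff(planted_effects$drug, drugs)
    if (length(bad) > 0L) {
      abort(sprintf("Planted effect refers to unknown drug(s): %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  if (length(base_ic50) == 1L) base_ic50 <- rep(base_ic50, length(drugs))
  if (length(base_ic50) != length(drugs) || any(base_ic50 <= 0)) {
    abort("`base_ic50` must be positive, one value or one per drug.")
  }
  check_scalar_number(top_dose, "top_dose", 0, Inf, strict_lower = TRUE)
  check_scalar_number(dilution, "dilution", 1, Inf, strict_lower = TRUE)
  n_concentrations <- check_count(n_concentrations, "n_concentrations", 2L)
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  check_scalar_number(cv_noise, "cv_noise", 0, Inf)
  carrier_count <- check_count(carrier_count, "carrier_count", 0L)
  if (carrier_count > n_lines) abort("`carrier_count` exceeds `n_lines`.")
  structure(
    list(n_lines = n_lines, lines = sprintf("PDC_%d", seq_len(n_lines)),
         drugs = drugs, planted_effects = as_tibble(planted_effects),
         base_ic50 = setNames(base_ic50, drugs),
         top_dose = top_dose, dilution = dilution,
         n_concentrations = n_concentrations, n_replicates = n_replicates,
         cv_noise = cv_noise, hill = hill, carrier_count = carrier_count),
    class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat("<panel_spec>", x$n_lines, "lines x", length(x$drugs), "drugs,",
      nrow(x$planted_effects), "planted effect(s)\n")
  invisible(x)
}

#' Simulate the alteration profile of a screening panel
#'
#' Every (gene, kind) event named in the panel's planted effects is carried
#' by exactly `carrier_count` lines (sampled); the remaining events from
#' `extra_events` are independent Bernoulli draws.
#'
#' @param spec A [panel_spec()].
#' @param seed Integer seed.
#' @param extra_events Tibble with `gene`, `kind`, `freq` for background
#'   (non-planted) events; defaults to [default_alteration_freqs()].
#' @return Long tibble `line`, `gene`, `kind`, `altered`.
#' @export
simulate_panel_alterations <- function(spec = panel_spec(), seed = 1L,
                                       extra_events = default_alteration_freqs()) {
  stopifnot(inherits(spec, "panel_spec"))
  planted <- distinct(spec$planted_effects, .data$gene, .data$kind)
  extra <- extra_events |>
    dplyr::anti_join(planted, by = c("gene", "kind"))
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    fixed <- crossing(line = spec$lines, planted) |>
      group_by(.data$gene, .data$kind) |>
      mutate(altered = as.integer(
        .data$line %in% sample(spec$lines, spec$carrier_count))) |>
      ungroup()
    random <- crossing(line = spec$lines, extra) |>
      mutate(altered = rbinom(n(), 1L, .data$freq)) |>
      select(-"freq")
    bind_rows(fixed, random) |>
      arrange(.data$line, .data$gene, .data$kind)
  })
}

# per-line true IC50 under the planted multiplicative model
true_ic50_table <- function(spec, alterations) {
  base <- tibble(drug = spec$drugs, base_ic50 = unname(spec$base_ic50))
  grid <- crossing(line = spec$lines, base)
  if (nrow(spec$planted_effects) == 0L) {
    return(mutate(grid, true_ic50 = .data$base_ic50))
  }
  carriers <- spec$planted_effects |>
    inner_join(alterations, by = c("gene", "kind"),
               relationship = "many-to-many") |>
    filter(.data$altered == 1L) |>
    group_by(.data$line, .data$drug) |>
    summarise(fold = prod(.data$fold_change), .groups = "drop")
  grid |>
    left_join(carriers, by = c("line", "drug")) |>
    mutate(true_ic50 = .data$base_ic50 * dplyr::coalesce(.data$fold, 1))
}

#' The dilution series of a panel
#'
#' @param spec A [panel_spec()].
#' @return Concentrations in uM, descending from `top_dose` in exact
#'   `dilution`-fold steps.
#' @export
dose_series <- function(spec = panel_spec()) {
  spec$top_dose / spec$dilution^(seq_len(spec$n_concentrations) - 1L)
}

#' Simulate per-well viability measurements for a drug screen
#'
#' Each (line, drug) pair is measured at `n_concentrations` doses in an
#' exact `dilution`-fold series from `top_dose`, in `n_replicates`
#' independent experiments. True response follows a four-parameter logistic
#' with bottom 0, top 1 and line-specific IC50 equal to the drug's base IC50
#' times the planted fold change for carrier lines. Noise is multiplicative
#' log-normal with unit mean and relative SD `cv_noise`.
#'
#' @param spec A [panel_spec()].
#' @param alterations Long alteration tibble from
#'   [simulate_panel_alterations()].
#' @param seed Integer seed.
#' @return Tibble `line`, `drug`, `concentration`, `replicate`, `viability`,
#'   `true_ic50`.
#' @export
simulate_viability <- function(spec = panel_spec(),
                               alterations = simulate_panel_alterations(spec),
                               seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"))
  check_columns(alterations, c("line", "gene", "kind", "altered"),
                "`alterations`")
  conc <- dose_series(spec)
  truth <- true_ic50_table(spec, alterations)
  grid <- crossing(truth, concentration = conc,
                   replicate = seq_len(spec$n_replicates))
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    clean <- 1 / (1 + (grid$concentration / grid$true_ic50)^spec$hill)
    noise <- if (spec$cv_noise > 0) {
      sdlog <- sqrt(log(1 + spec$cv_noise^2))
      rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    grid |>
      mutate(viability = clean * noise) |>
      select("line", "drug", "concentration", "replicate", "viability",
             "true_ic50")
  })
}

#' Simulate a per-(line, drug) IC50 table directly
#'
#' Skips the viability-curve level: observed IC50s are the planted true
#' IC50s under multiplicative log-normal noise with relative SD `cv`. This
#' is the distribution that replicate-averaged curve fits produce, and is
#' the fast input for large screen-calibration simulations.
#'
#' @inheritParams simulate_viability
#' @param cv Relative SD of the log-normal IC50 noise.
#' @return Tibble `line`, `drug`, `ic50`, `true_ic50`.
#' @export
simulate_ic50 <- function(spec = panel_spec(),
                          alterations = simulate_panel_alterations(spec),
                          cv = 0.1, seed = 1L) {
  stopifnot(inherits(spec, "panel_spec"))
  check_scalar_number(cv, "cv", 0, Inf)
  truth <- true_ic50_table(spec, alterations)
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    noise <- if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      rlnorm(nrow(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    truth |>
      mutate(ic50 = .data$true_ic50 * noise) |>
      select("line", "drug", "ic50", "true_ic50")
  })
}

#' Simulate a clinical survival table
#'
#' Event times are exponential with the given per-group hazards; censoring
#' times are independent Uniform(0, b) with b solved per group so that the
#' expected censored fraction equals `censor_rate`.
#'
#' @param n_per_group Subjects per group (recycled across groups).
#' @param hazards Named vector of per-month hazards, one per group.
#' @param censor_rate Expected fraction censored, in \[0, 1).
#' @param seed Integer seed.
#' @return Tibble `sample`, `group`, `time`, `event` (1 = event observed).
#' @export
simulate_survival <- function(n_per_group = 50L,
                              hazards = c(alt = 0.06, wt = 0.02),
                              censor_rate = 0.2, seed = 1L) {
  if (is.null(names(hazards)) || any(!nzchar(names(hazards)))) {
    abort("`hazards` must be a named vector (one hazard per group).")
  }
  if (any(hazards <= 0)) abort("All hazards must be > 0.")
  check_scalar_number(censor_rate, "censor_rate", 0, 1)
  if (censor_rate >= 1) abort("`censor_rate` must be < 1.")
  n_per_group <- rep_len(check_count(n_per_group, "n_per_group"),
                         length(hazards))
  withr::with_seed(check_count(seed, "seed", min = 0L), {
    imap(setNames(seq_along(hazards), names(hazards)), function(gi, gname) {
      lambda <- hazards[[gi]]
      n <- n_per_group[gi]
      t_event <- rexp(n, lambda)
      if (censor_rate > 0) {
        # P(censored) = P(C < T) = (1 - e^{-lambda b}) / (lambda b)
        # for C ~ U(0, b), T ~ Exp(lambda); solve b for the target rate
        b <- uniroot(function(b) {
          (1 - exp(-lambda * b)) / (lambda * b) - censor_rate
        }, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
        t_cens <- runif(n, 0, b)
      } else {
        t_cens <- rep(Inf, n)
      }
      tibble(group = gname,
             time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
    }) |>
      list_rbind() |>
      mutate(sample = sprintf("P%03d", row_number()), .before = 1L)
  })
}
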