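test_that("every generator is deterministic under a fixed seed", {
  spec <- cohort_spec(n_samples = 30L)
  expect_identical(simulate_cohort(spec, seed = 5),
                   simulate_cohort(spec, seed = 5))
  expect_false(identical(simulate_cohort(spec, seed = 5),
                         simulate_cohort(spec, seed = 6)))

  expect_identical(simulate_variants(50, 0.2, seed = 5),
                   simulate_variants(50, 0.2, seed = 5))

  cs <- coverage_spec(n_bins = 200L)
  expect_identical(simulate_coverage(cs, seed = 5),
                   simulate_coverage(cs, seed = 5))

  ps <- panel_spec(drugs = c("palbociclib", "ribociclib", "trametinib"),
                   planted_effects = tibble::tibble(
                     drug = "palbociclib", gene = "CDKN2A", kind = "loss",
                     fold_change = 0.05))
  alt <- simulate_panel_alterations(ps, seed = 5)
  expect_identical(alt, simulate_panel_alterations(ps, seed = 5))
  expect_identical(simulate_viability(ps, alt, seed = 5),
                   simulate_viability(ps, alt, seed = 5))
  expect_identical(simulate_ic50(ps, alt, seed = 5),
                   simulate_ic50(ps, alt, seed = 5))
  expect_identical(simulate_survival(seed = 5), simulate_survival(seed = 5))
})

test_that("cohort spec validates probabilities and emits binary calls", {
  expect_error(cohort_spec(alteration_freqs = tibble::tibble(
    gene = "A", kind = "gain", freq = 1.2)), "\\[0, 1\\]")
  expect_error(cohort_spec(n_samples = 0), ">= 1")
  cohort <- simulate_cohort(cohort_spec(n_samples = 40L), seed = 2)
  expect_true(all(cohort$altered %in% c(0L, 1L)))
  expect_equal(dplyr::n_distinct(cohort$sample), 40L)
})

test_that("variant generator: truths pass, artifacts break their named criterion", {
  clean <- apply_filters(simulate_variants(80, artifact_rate = 0, seed = 1))
  expect_true(all(clean$pass))

  for (s in 1:5) {
    d <- apply_filters(simulate_variants(60, artifact_rate = 0.3, seed = s))
    som <- dplyr::filter(d, truth == "somatic")
    art <- dplyr::filter(d, truth == "artifact")
    expect_true(all(som$pass))
    expect_true(all(!art$pass))
    # each artifact fails exactly the criterion it was planted to violate
    expect_true(all(mapply(function(f, viol) identical(f, viol),
                           art$failed_criteria, art$violated)))
  }
  d <- apply_filters(simulate_variants(60, artifact_rate = 0.4, seed = 9))
  nv <- dplyr::filter(d, violated == "max_normal_vaf")
  expect_true(all(nv$normal_vaf > 0.03))
  expect_error(simulate_variants(10, artifact_rate = 1.5), "\\[0, 1\\]")
})

test_that("coverage generator obeys planted ratios exactly without noise", {
  flat <- simulate_coverage(coverage_spec(n_bins = 100L), noise = "none")
  expect_equal(flat$tumor_count / flat$normal_count, rep(1, 100))

  cs <- coverage_spec(n_bins = 100L, segments = tibble::tibble(
    start_bin = 40L, end_bin = 60L, log2_ratio = 1))
  cov <- simulate_coverage(cs, noise = "none")
  ratio <- cov$tumor_count / cov$normal_count
  inside <- seq(41L, 60L)
  expect_equal(ratio[inside], rep(2, 20))
  expect_equal(ratio[-inside], rep(1, 80))
  expect_error(coverage_spec(segments = tibble::tibble(
    start_bin = c(0L, 5L), end_bin = c(10L, 15L), log2_ratio = c(1, 1))),
    "overlap")
})

test_that("noisy in-segment log2 ratio is within 3 SE of the planted value", {
  n_seg <- 400L
  depth <- 100
  cs <- coverage_spec(n_bins = 1000L, depth_mean = depth,
                      segments = tibble::tibble(
                        start_bin = 300L, end_bin = 700L, log2_ratio = 1))
  cov <- simulate_coverage(cs, seed = 11)
  lr <- log2(cov$tumor_count / cov$normal_count)[301:700]
  # per-bin variance of log2(T/N), T ~ Pois(2 * depth), N ~ Pois(depth)
  se <- sqrt((1 / (2 * depth) + 1 / depth) / log(2)^2 / n_seg)
  expect_lt(abs(mean(lr) - 1), 3 * se)
})

test_that("viability generator uses an exact 3.3-fold 10-dose series", {
  ps <- panel_spec(drugs = "palbociclib", planted_effects = tibble::tibble(
    drug = character(), gene = character(), kind = character(),
    fold_change = double()))
  conc <- dose_series(ps)
  expect_length(conc, 10L)
  expect_equal(conc[1], 10)
  expect_equal(conc[-10] / conc[-1], rep(3.3, 9))
  expect_equal(conc[2], 10 / 3.3)
})

test_that("noise-free viability refits recover the planted IC50 model", {
  ps <- panel_spec(n_lines = 4L, drugs = c("palbociclib", "trametinib"),
                   planted_effects = tibble::tibble(
                     drug = "palbociclib", gene = "CDKN2A", kind = "loss",
                     fold_change = 0.05),
                   cv_noise = 0, n_replicates = 1L, carrier_count = 2L)
  alt <- simulate_panel_alterations(
    ps, seed = 3, extra_events = tibble::tibble(
      gene = character(), kind = character(), freq = double()))
  viab <- simulate_viability(ps, alt, seed = 3)
  fits <- fit_ic50(viab)
  truth <- dplyr::distinct(viab, line, drug, true_ic50)
  merged <- dplyr::inner_join(fits, truth, by = c("line", "drug"))
  expect_equal(merged$ic50, merged$true_ic50, tolerance = 1e-5)
  carriers <- alt$line[alt$gene == "CDKN2A" & alt$altered == 1L]
  expect_length(carriers, 2L)
  planted <- merged[merged$drug == "palbociclib" &
                      merged$line %in% carriers, ]
  expect_equal(planted$ic50, rep(0.05, 2), tolerance = 1e-5)
  wild <- merged[merged$drug == "palbociclib" &
                   !(merged$line %in% carriers), ]
  expect_equal(wild$ic50, rep(1, 2), tolerance = 1e-5)
})

test_that("survival generator: censor rate zero gives all events, target rate holds", {
  surv <- simulate_survival(100L, c(a = 0.05, b = 0.05), censor_rate = 0,
                            seed = 4)
  expect_true(all(surv$event == 1L))
  pooled <- purrr::map(1:20, function(s) {
    simulate_survival(100L, c(a = 0.05, b = 0.05), censor_rate = 0.3,
                      seed = s)
  }) |> purrr::list_rbind()
  # 20 x 200 subjects: binomial 3-SE band around the target rate
  expect_lt(abs(mean(pooled$event == 0L) - 0.3),
            3 * sqrt(0.3 * 0.7 / nrow(pooled)))
})

test_that("log-rank over generated survival is calibrated under the null and powered under HR 3", {
  p_null <- vapply(1:1000, function(s) {
    d <- simulate_survival(30L, c(a = 0.05, b = 0.05), censor_rate = 0.2,
                           seed = s)
    logrank_test(d)$p
  }, numeric(1))
  # rejection rate ~ alpha; binomial 99.7% band around 0.05 at n = 1000
  expect_lt(abs(mean(p_null < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  p_alt <- vapply(1:20, function(s) {
    d <- simulate_survival(100L, c(a = 0.09, b = 0.03), censor_rate = 0.2,
                           seed = s)
    logrank_test(d)$p
  }, numeric(1))
  expect_lt(median(p_alt), 0.05)
})
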