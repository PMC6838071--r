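flat_bins <- function(n, tumor, normal, gc = NULL) {
  tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1L) * 1000L,
                 end = seq_len(n) * 1000L,
                 gc = if (is.null(gc)) rep(0.45, n) else gc,
                 normal_count = normal, tumor_count = tumor)
}

test_that("median centering absorbs global depth differences", {
  bins <- flat_bins(500L, tumor = 200, normal = 100)
  out <- normalize_coverage(bins)
  expect_equal(out$log2_ratio, rep(0, 500))
})

test_that("a focal doubling stands out at log2 ~ 1 over a diploid background", {
  n <- 2000L
  tumor <- rep(100, n)
  tumor[1001:1100] <- 200
  out <- normalize_coverage(flat_bins(n, tumor = tumor, normal = 100))
  expect_equal(out$log2_ratio[1001:1100], rep(1, 100), tolerance = 1e-9)
  expect_equal(out$log2_ratio[1:1000], rep(0, 1000), tolerance = 1e-9)
})

test_that("GC bias shared by tumor and normal cancels in the ratio", {
  cs_args <- list(n_bins = 600L, depth_mean = 120,
                  segments = tibble::tibble(start_bin = 200L, end_bin = 300L,
                                            log2_ratio = 1))
  no_bias <- do.call(coverage_spec, cs_args)
  biased <- do.call(coverage_spec,
                    c(cs_args, list(gc_bias = function(gc) 0.5 + gc)))
  a <- normalize_coverage(simulate_coverage(no_bias, noise = "none"))
  b <- normalize_coverage(simulate_coverage(biased, noise = "none"))
  expect_equal(a$log2_ratio, b$log2_ratio, tolerance = 1e-9)
})

test_that("zero-coverage normal bins are masked, never divided", {
  bins <- flat_bins(50L, tumor = 100, normal = c(0, rep(100, 49)))
  out <- normalize_coverage(bins)
  expect_true(out$masked[1])
  expect_true(is.na(out$log2_ratio[1]))
  expect_false(any(out$masked[-1]))
})

test_that("segmentation partitions bins and reproduces bin means", {
  n <- 300L
  lr <- c(rep(0, 150), rep(1, 150)) + 0  # noise-free two-level input
  bins <- tibble::tibble(chrom = "chr1", start = (seq_len(n) - 1L) * 1000L,
                         end = seq_len(n) * 1000L, log2_ratio = lr)
  segs <- segment_log_ratios(bins)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$end[1], 150L * 1000L)  # exact breakpoint
  expect_equal(segs$log2_ratio, c(0, 1))
  expect_identical(sum(segs$n_bins), n)
  expect_identical(segs$start[-1], segs$end[-nrow(segs)])

  const <- segment_log_ratios(dplyr::mutate(bins, log2_ratio = 0.3))
  expect_identical(nrow(const), 1L)
  expect_equal(const$log2_ratio, 0.3)
})

test_that("segment means equal member-bin means on noisy input", {
  cov <- simulate_coverage(coverage_spec(
    n_bins = 800L, segments = tibble::tibble(
      start_bin = 300L, end_bin = 500L, log2_ratio = 1)), seed = 2)
  nb <- normalize_coverage(cov)
  segs <- segment_log_ratios(nb)
  expect_identical(sum(segs$n_bins), 800L)
  for (i in seq_len(nrow(segs))) {
    members <- nb$log2_ratio[nb$start >= segs$start[i] & nb$end <= segs$end[i]]
    expect_equal(segs$log2_ratio[i], mean(members))
  }
})

test_that("segment calls use strict thresholds", {
  segs <- tibble::tibble(log2_ratio = c(0.71, 0.70, -0.8, -0.7, 0))
  called <- call_segments(segs)
  expect_identical(called$call,
                   c("gain", "neutral", "loss", "neutral", "neutral"))
  expect_error(call_segments(segs, gain_threshold = -1), "gain_threshold")
})

test_that("scaling both samples by a constant leaves all calls unchanged", {
  cov <- simulate_coverage(coverage_spec(
    n_bins = 500L, segments = tibble::tibble(
      start_bin = 100L, end_bin = 200L, log2_ratio = 1)), noise = "none")
  run <- function(x) {
    call_segments(segment_log_ratios(normalize_coverage(x)))
  }
  scaled <- dplyr::mutate(cov, tumor_count = tumor_count * 7,
                          normal_count = normal_count * 7)
  expect_equal(run(cov)$call, run(scaled)$call)
  expect_equal(run(cov)$log2_ratio, run(scaled)$log2_ratio, tolerance = 1e-9)
})

gene_exons <- function(gene, starts, width = 200L) {
  tibble::tibble(gene = gene, chrom = "chr1", start = starts,
                 end = starts + width)
}

test_that("gene-level calls require strictly more than 75% of exons", {
  segs <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                         call = "loss")
  all_in <- call_gene_cnv(gene_exons("G1", c(100L, 2000L, 4000L, 9000L)),
                          segs)
  expect_identical(all_in$status, "loss")
  expect_equal(all_in$fraction_exons, 1.0)

  three_quarters <- call_gene_cnv(
    gene_exons("G2", c(100L, 2000L, 4000L, 20000L)), segs)
  expect_identical(three_quarters$status, "neutral")  # 0.75 is not > 0.75
  expect_equal(three_quarters$fraction_loss, 0.75)

  none <- call_gene_cnv(gene_exons("G3", c(20000L, 30000L)), segs)
  expect_identical(none$status, "neutral")
  expect_equal(none$fraction_exons, 0)
})

test_that("gene calls are invariant to exon order and segment splitting", {
  exons <- gene_exons("G", c(100L, 2000L, 4000L, 9000L))
  one_seg <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                            call = "gain")
  split_seg <- tibble::tibble(chrom = "chr1", start = c(0L, 5000L),
                              end = c(5000L, 10000L), call = "gain")
  shuffled <- exons[c(3, 1, 4, 2), ]
  expect_identical(call_gene_cnv(exons, one_seg),
                   call_gene_cnv(shuffled, one_seg))
  expect_identical(call_gene_cnv(exons, one_seg),
                   call_gene_cnv(exons, split_seg))
})

test_that("genes spanning chromosomes are dropped with a warning", {
  exons <- dplyr::bind_rows(
    gene_exons("OK", c(100L, 2000L)),
    tibble::tibble(gene = "BAD", chrom = c("chr1", "chr2"),
                   start = c(0L, 0L), end = c(100L, 100L)))
  segs <- tibble::tibble(chrom = "chr1", start = 0L, end = 10000L,
                         call = "gain")
  expect_warning(res <- call_gene_cnv(exons, segs), "BAD")
  expect_identical(res$gene, "OK")
})

test_that("cohort-level gene frequencies match the generating spec", {
  spec <- cohort_spec(n_samples = 161L)
  cohort <- simulate_cohort(spec, seed = 21)
  rec <- recurrence(cohort)
  freqs <- spec$alteration_freqs
  joined <- dplyr::inner_join(rec, freqs, by = c("gene", "kind"))
  # all 15 events checked simultaneously, so use a 3-SE band per event
  # (keeps the joint check at ~99% rather than 0.95^15)
  half_width <- 3 * sqrt(joined$freq * (1 - joined$freq) / 161)
  expect_true(all(abs(joined$fraction - joined$freq) <= half_width + 1e-12))
})
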