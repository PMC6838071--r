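test_that("recurrence counts and fractions are exact", {
  # 153 of 161 samples carry the event
  tbl <- tibble::tibble(sample = sprintf("S%03d", 1:161), gene = "ANY_CNV",
                        kind = "gain",
                        altered = c(rep(1L, 153), rep(0L, 8)))
  rec <- recurrence(tbl)
  expect_identical(rec$count, 153L)
  expect_equal(rec$fraction, 153 / 161)
  expect_equal(round(100 * rec$fraction), 95)

  empty <- recurrence(tibble::tibble(sample = character(), gene = character(),
                                     kind = character(), altered = integer()))
  expect_identical(nrow(empty), 0L)

  # display filter is strict
  two <- dplyr::bind_rows(tbl, dplyr::mutate(tbl, gene = "RARE",
                                             altered = c(rep(1L, 16),
                                                         rep(0L, 145))))
  expect_identical(recurrence(two, min_fraction = 0.10)$gene,
                   c("ANY_CNV"))
})

test_that("co-occurrence arithmetic obeys inclusion-exclusion", {
  cc <- cooccurrence(41, 21, 18, 161)
  expect_identical(cc$n_union, 44L)
  expect_equal(cc$fraction_union, 44 / 161)
  expect_equal(cc$jaccard, 18 / 44)

  no_both <- cooccurrence(10, 5, 0, 100)
  expect_identical(no_both$n_union, 15L)

  nested <- cooccurrence(7, 7, 7, 50)
  expect_identical(nested$n_union, 7L)
  expect_equal(nested$jaccard, 1)

  expect_error(cooccurrence(5, 5, 6, 100), "marginal")
  expect_error(cooccurrence(50, 5, 5, 40), "n_total")

  for (s in 1:25) {
    withr::with_seed(s, {
      n <- sample(50:500, 1)
      a <- sample(0:n, 1)
      b <- sample(0:n, 1)
      both <- sample(0:min(a, b), 1)
    })
    cc <- cooccurrence(a, b, both, n)
    expect_identical(cc$n_union, a + b - both)
    expect_gte(cc$n_union, max(a, b))
    expect_lte(cc$fraction_both, min(cc$fraction_a, cc$fraction_b))
  }
})

test_that("Kaplan-Meier steps match hand-computed products", {
  # 6 records, interleaved censoring: S = 5/6, 5/8, 5/12, then 0
  d <- tibble::tibble(time = 1:6, event = c(1L, 0L, 1L, 1L, 0L, 1L))
  km <- km_estimate(d)
  steps <- km[km$n_event > 0, ]
  expect_equal(steps$survival, c(5 / 6, 5 / 8, 5 / 12, 0))

  all_cens <- km_estimate(tibble::tibble(time = 1:5, event = 0L))
  expect_true(all(all_cens$survival == 1))

  no_cens <- km_estimate(tibble::tibble(time = c(2, 4, 6, 8), event = 1L))
  expect_equal(no_cens$survival[no_cens$n_event > 0],
               c(0.75, 0.5, 0.25, 0))
  expect_error(km_estimate(tibble::tibble(time = -1, event = 1L)), ">= 0")
})

test_that("log-rank equals the hypergeometric-sum oracle on a toy table", {
  d <- tibble::tibble(
    time = c(1, 3, 5, 7, 2, 4, 6, 8),
    event = c(1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L),
    group = rep(c("A", "B"), each = 4L))
  got <- logrank_test(d)
  want <- logrank_oracle(d$time, d$event, d$group)
  expect_equal(got$statistic, want$chisq, tolerance = 1e-9)
  expect_equal(got$p, want$p, tolerance = 1e-9)

  # label swap leaves the statistic unchanged
  swapped <- dplyr::mutate(d, group = ifelse(group == "A", "B", "A"))
  expect_equal(logrank_test(swapped)$statistic, got$statistic,
               tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  dup <- tibble::tibble(time = rep(c(1, 2, 3), 2),
                        event = rep(c(1L, 1L, 0L), 2),
                        group = rep(c("A", "B"), each = 3L))
  same <- logrank_test(dup)
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  none <- logrank_test(tibble::tibble(time = 1:4, event = 0L,
                                      group = rep(c("A", "B"), 2)))
  expect_equal(none$p, 1)
})

test_that("exact Wilcoxon matches enumeration and the reference implementation", {
  # complete separation, 5 vs 3: the extreme arrangement has p = 2/56
  x <- c(10, 11, 12, 13, 14)
  y <- c(1, 2, 3)
  got <- wilcoxon_ranksum(x, y)
  expect_identical(got$method, "exact")
  expect_equal(got$p, 2 / 56)
  expect_equal(round(got$p, 4), 0.0357)

  # symmetry in the two samples
  expect_equal(wilcoxon_ranksum(y, x)$p, got$p)

  for (s in 1:20) {
    withr::with_seed(s, {
      n <- sample(2:6, 1)
      m <- sample(2:6, 1)
      while (n + m > 10) m <- m - 1
      xx <- round(rnorm(n), 6)
      yy <- round(rnorm(m, 0.5), 6)
    })
    mine <- wilcoxon_ranksum(xx, yy, mode = "exact")$p
    expect_equal(mine, wilcoxon_enumeration(xx, yy), tolerance = 1e-12)
    ref <- stats::wilcox.test(xx, yy, exact = TRUE)$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }

  # near-identical samples are nowhere near significance
  withr::with_seed(3, {
    base <- rnorm(4)
    jit <- base + rnorm(4, 0, 1e-6)
  })
  expect_gt(wilcoxon_ranksum(base, jit)$p, 0.5)

  # ties force the normal approximation with a warning
  expect_warning(tied <- wilcoxon_ranksum(c(1, 2, 2), c(2, 3, 4),
                                          mode = "exact"), "Ties")
  expect_identical(tied$method, "normal_approx")
})

test_that("normal-approximation Wilcoxon tracks the reference implementation", {
  withr::with_seed(9, {
    x <- rnorm(30)
    y <- rnorm(25, 0.4)
  })
  mine <- wilcoxon_ranksum(x, y, mode = "normal")$p
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("Z-score normalization centers and scales per gene", {
  expr <- tibble::tibble(gene = c("A", "B"),
                         s1 = c(1, 5), s2 = c(2, 5), s3 = c(3, 5))
  z <- zscore_normalize(expr)
  # sample-SD convention: (1,2,3) -> -0.816, 0, 0.816
  expect_equal(unname(unlist(z[z$gene == "A", c("s1", "s2", "s3")])),
               c(-1, 0, 1) / sd(1:3), tolerance = 1e-12)
  expect_equal(unname(unlist(z[z$gene == "B", c("s1", "s2", "s3")])),
               c(0, 0, 0))
  expect_identical(z$constant, c(FALSE, TRUE))

  withr::with_seed(2, {
    wide <- tibble::tibble(gene = paste0("g", 1:10))
    for (s in paste0("s", 1:6)) wide[[s]] <- rnorm(10)
  })
  zz <- zscore_normalize(wide)
  mat <- as.matrix(zz[paste0("s", 1:6)])
  expect_equal(rowMeans(mat), rep(0, 10), tolerance = 1e-12)
  expect_equal(apply(mat, 1, sd), rep(1, 10), tolerance = 1e-12)

  expect_error(zscore_normalize(tibble::tibble(gene = "A", s1 = 1)),
               ">= 2 samples")
})
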