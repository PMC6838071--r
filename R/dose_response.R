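#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill)` with the
#' midpoint parameterized on the log-concentration scale. Initialization is
#' multi-start (a data-driven start plus a grid of midpoints and both hill
#' signs); the best residual sum of squares wins. The fit is canonicalized
#' so that `top >= bottom` (flipping the hill sign leaves the curve
#' unchanged). Constant-response data give a degenerate, non-converged fit.
#'
#' @param data Tibble of measurements for one (line, drug) curve.
#' @param conc,viability Column names (tidy-eval) holding concentration
#'   (strictly positive, same unit throughout) and viability fraction.
#' @return A `pl4_fit` object: list with `params` (bottom, top, hill, ec50),
#'   `rss`, `converged`, `degenerate`, `n`, `conc_range`, `data`.
#' @examples
#' d <- tibble::tibble(conc = 10 / 3.3^(0:9),
#'                     v = 1 / (1 + conc / 0.5))
#' fit <- fit_4pl(d, conc, v)
#' tidy(fit)
#' @export
fit_4pl <- function(data, conc = concentration, viability = viability) {
  conc <- dplyr::pull(data, {{ conc }})
  v <- dplyr::pull(data, {{ viability }})
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    abort("Concentrations must be strictly positive and finite.")
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    abort("Viabilities must be finite and >= 0.")
  }
  n_conc <- length(unique(conc))
  if (n_conc < 4L) {
    abort(sprintf(
      "Need >= 4 distinct concentrations to fit a 4PL (got %d).", n_conc))
  }
  out <- list(n = length(v), conc_range = range(conc),
              data = tibble(concentration = conc, viability = v))

  if (sd(v) == 0) {
    out$params <- c(bottom = v[1L], top = v[1L], hill = NA_real_,
                    ec50 = NA_real_)
    out$rss <- 0
    out$converged <- FALSE
    out$degenerate <- TRUE
    class(out) <- "pl4_fit"
    return(out)
  }

  lc <- log(conc)
  # residuals of v(c) = bottom + (top - bottom) / (1 + (c / ec50)^hill),
  # with the midpoint carried as log(ec50)
  resid_fn <- function(par) {
    v - (par[1L] + (par[2L] - par[1L]) /
           (1 + exp(par[3L] * (lc - par[4L]))))
  }

  # data-driven midpoint start: concentration whose mean response is
  # closest to halfway between the extremes
  mean_by_c <- tapply(v, lc, mean)
  halfway <- (max(mean_by_c) + min(mean_by_c)) / 2
  lec50_data <- as.numeric(names(mean_by_c))[
    which.min(abs(mean_by_c - halfway))]
  starts <- crossing(
    lec50 = unique(c(lec50_data, median(lc))),
    hill = c(1, -1)
  )
  # an RSS this small relative to the response spread is a solved fit;
  # remaining starts cannot improve it meaningfully
  good_enough <- 1e-12 * sum((v - mean(v))^2)

  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = c(min(v), max(v), starts$hill[i], starts$lec50[i]),
        fn = resid_fn,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-14) {
      best <- list(fit = fit, rss = rss)
    }
    if (best$rss <= good_enough) break
  }

  if (is.null(best)) {
    out$params <- c(bottom = min(v), top = max(v), hill = NA_real_,
                    ec50 = NA_real_)
    out$rss <- Inf
    out$converged <- FALSE
    out$degenerate <- TRUE
    class(out) <- "pl4_fit"
    return(out)
  }

  cf <- best$fit$par
  bottom <- cf[1L]
  top <- cf[2L]
  hill <- cf[3L]
  ec50 <- exp(cf[4L])
  if (bottom > top) {  # canonical form: top >= bottom
    tmp <- bottom; bottom <- top; top <- tmp
    hill <- -hill
  }
  out$params <- c(bottom = bottom, top = top, hill = hill, ec50 = ec50)
  out$rss <- best$rss
  # nls.lm info codes 1-3 are proper convergence criteria
  out$converged <- best$fit$info %in% 1:3
  out$degenerate <- FALSE
  class(out) <- "pl4_fit"
  out
}

#' @export
print.pl4_fit <- function(x, ...) {
  cat("<pl4_fit>", x$n, "points; ")
  if (x$degenerate) {
    cat("degenerate (constant response", format(x$params[["bottom"]]), ")\n")
  } else {
    cat(sprintf("bottom %.4g, top %.4g, hill %.4g, ec50 %.4g; RSS %.4g%s\n",
                x$params[["bottom"]], x$params[["top"]], x$params[["hill"]],
                x$params[["ec50"]], x$rss,
                if (x$converged) "" else " (not converged)"))
  }
  invisible(x)
}

#' Predicted viability from a fitted 4PL
#'
#' @param object A `pl4_fit`.
#' @param newdata Optional tibble with a `concentration` column.
#' @param ... Unused.
#' @export
predict.pl4_fit <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$concentration else
    newdata$concentration
  p <- object$params
  if (object$degenerate) return(rep(p[["bottom"]], length(conc)))
  p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
    (1 + (conc / p[["ec50"]])^p[["hill"]])
}

#' @method tidy pl4_fit
#' @export
tidy.pl4_fit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @method glance pl4_fit
#' @export
glance.pl4_fit <- function(x, ...) {
  tibble(rss = x$rss, n = x$n, converged = x$converged,
         degenerate = x$degenerate)
}

#' Derive an absolute IC50 from a fitted 4PL
#'
#' The IC50 is the concentration at which the fitted curve crosses `level`
#' (0.5 on the normalized viability-fraction scale, i.e. 50% inhibition of
#' the untreated control). The result is censored `above_max` /
#' `below_min` when the crossing lies outside the tested range or does not
#' exist.
#'
#' @param fit A `pl4_fit`.
#' @param range Tested concentration range `c(min, max)`; defaults to the
#'   fitted data's range.
#' @param level Absolute viability level defining the IC50.
#' @return Tibble `ic50`, `censored` (`"none"`, `"above_max"`,
#'   `"below_min"`), `rss`, `converged`.
#' @export
derive_ic50 <- function(fit, range = NULL, level = 0.5) {
  stopifnot(inherits(fit, "pl4_fit"))
  range <- range %||% fit$conc_range
  stopifnot(length(range) == 2L, range[1L] <= range[2L])
  p <- fit$params
  res <- function(ic50, censored) {
    tibble(ic50 = ic50, censored = censored, rss = fit$rss,
           converged = fit$converged)
  }
  if (fit$degenerate) {
    flat <- p[["bottom"]]
    return(res(NA_real_, if (flat >= level) "above_max" else "below_min"))
  }
  bottom <- p[["bottom"]]; top <- p[["top"]]
  hill <- p[["hill"]]; ec50 <- p[["ec50"]]
  r <- (top - level) / (level - bottom)
  if (!is.finite(r) || r <= 0) {
    # curve never crosses `level`: censor by which side it sits on
    v_hi <- predict(fit, tibble(concentration = range[2L]))
    return(res(NA_real_, if (v_hi >= level) "above_max" else "below_min"))
  }
  crossing_conc <- ec50 * r^(1 / hill)
  if (crossing_conc > range[2L]) return(res(crossing_conc, "above_max"))
  if (crossing_conc < range[1L]) return(res(crossing_conc, "below_min"))
  res(crossing_conc, "none")
}

#' Aggregate IC50s over independent experiments
#'
#' Arithmetic mean and sample SD over uncensored IC50s; censored results are
#' excluded from the moments and surfaced as a count.
#'
#' @param ic50 Numeric IC50s.
#' @param censored Matching censoring labels (`"none"` / `"above_max"` /
#'   `"below_min"`).
#' @return One-row tibble `ic50_mean`, `ic50_sd`, `n_uncensored`,
#'   `n_censored`, `censored` (aggregate label: `"none"` unless every
#'   experiment was censored, in which case the majority bound).
#' @export
aggregate_ic50 <- function(ic50, censored = rep("none", length(ic50))) {
  stopifnot(length(ic50) == length(censored))
  ok <- censored == "none"
  if (!any(ok)) {
    lab <- names(sort(table(censored), decreasing = TRUE))[1L]
    return(tibble(ic50_mean = NA_real_, ic50_sd = NA_real_,
                  n_uncensored = 0L, n_censored = sum(!ok), censored = lab))
  }
  tibble(ic50_mean = mean(ic50[ok]),
         ic50_sd = if (sum(ok) > 1L) sd(ic50[ok]) else NA_real_,
         n_uncensored = sum(ok), n_censored = sum(!ok), censored = "none")
}

#' Fit IC50s for every (line, drug) curve in a viability table
#'
#' Default mode fits one 4PL per independent experiment (`replicate`) and
#' averages the uncensored IC50s; `pooled = TRUE` fits a single curve on all
#' replicates jointly. When every experiment of a pair is censored the
#' reported `ic50` is substituted by the censoring bound (max or min tested
#' concentration) and flagged, so downstream group comparisons keep the
#' pair.
#'
#' @param viability Tibble `line`, `drug`, `concentration`, `replicate`,
#'   `viability`.
#' @param pooled Fit pooled replicates instead of per-experiment fits.
#' @param level Viability level defining the IC50.
#' @return Tibble `line`, `drug`, `ic50`, `ic50_sd`, `n_experiments`,
#'   `n_censored`, `censored`.
#' @export
fit_ic50 <- function(viability, pooled = FALSE, level = 0.5) {
  check_columns(viability, c("line", "drug", "concentration", "replicate",
                             "viability"), "`viability`")
  viability |>
    group_by(.data$line, .data$drug) |>
    group_split() |>
    map(function(cur) {
      rng <- range(cur$concentration)
      per_exp <- if (pooled) list(cur) else
        group_split(group_by(cur, .data$replicate))
      ics <- map(per_exp, function(e) {
        derive_ic50(fit_4pl(e), range = rng, level = level)
      }) |> list_rbind()
      agg <- aggregate_ic50(ics$ic50, ics$censored)
      ic50 <- agg$ic50_mean
      if (agg$censored != "none") {
        ic50 <- if (agg$censored == "above_max") rng[2L] else rng[1L]
      }
      tibble(line = cur$line[1L], drug = cur$drug[1L],
             ic50 = ic50, ic50_sd = agg$ic50_sd,
             n_experiments = nrow(ics), n_censored = agg$n_censored,
             censored = agg$censored)
    }) |>
    list_rbind()
}

#' Plot a fitted dose-response curve
#'
#' @param object A `pl4_fit`.
#' @param ... Unused.
#' @return A ggplot: points are measurements, line is the fitted curve on a
#'   log10 concentration axis.
#' @method autoplot pl4_fit
#' @export
autoplot.pl4_fit <- function(object, ...) {
  rng <- object$conc_range
  grid <- tibble(concentration = exp(seq(log(rng[1L]), log(rng[2L]),
                                         length.out = 200L)))
  grid$viability <- predict(object, grid)
  ggplot(object$data, aes(.data$concentration, .data$viability)) +
    geom_point(alpha = 0.7) +
    geom_line(data = grid, colour = "#2166ac") +
    scale_x_log10() +
    labs(x = "Concentration (uM)", y = "Viability (fraction of control)") +
    theme_minimal()
}
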