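# Quasi-Poisson fitting of the segmented model and the rate-ratio surface.

#' Fit the segmented quasi-Poisson model
#'
#' Fits a log-link Poisson-mean model with variance `phi * mean` to the
#' non-gap weeks of a design built by [build_design()], by iteratively
#' reweighted least squares (relative deviance tolerance 1e-8, at most 100
#' iterations). Weeks inside the shutdown gap carry counts that are exactly
#' zero, so the gap coefficient's maximum-likelihood estimate diverges to
#' minus infinity; estimation therefore drops gap rows, which leaves every
#' remaining coefficient unchanged (see the gap-equivalence property in the
#' package tests), and the gap effect is reported as not estimable.
#' Dispersion is the Pearson estimate `phi = sum(r_pearson^2) / (n - p)` and
#' the returned covariance is scaled by it, so Wald intervals are
#' quasi-likelihood intervals.
#'
#' @param design a design tibble from [build_design()].
#' @param counts optional vector of weekly counts overriding
#'   `design$count`.
#' @param terms character vector of model terms; the default is the full
#'   segmented model. Use a subset (e.g. `c("t")`) for reduced models.
#' @return an object of class `its_fit`: list with `coefficients`, `vcov`
#'   (dispersion-scaled), `dispersion`, `n_obs` (non-gap weeks), `df_residual`,
#'   `converged`, the underlying `glm`, and the `design`.
#' @export
fit_quasipoisson <- function(design, counts = NULL,
                             terms = c("t", "t_sq", "season", "sig",
                                       "tpost", "tpost_sq")) {
  if (!is.null(counts)) design$count <- counts
  if (any(design$count < 0)) stop("counts must be non-negative", call. = FALSE)
  est <- design[design$lam == 0, , drop = FALSE]
  est$season <- droplevels(est$season)
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  fml <- stats::as.formula(paste("count ~", rhs, "+ offset(offset_log)"))
  fit <- stats::glm(fml, family = stats::quasipoisson(link = "log"),
                    data = est,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) {
    warning("IRLS did not converge within 100 iterations; ",
            "partial result returned", call. = FALSE)
  }
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  # Pearson dispersion computed from the definition so the identity
  # sum(r_pearson^2) / (n - p) == phi holds exactly
  phi <- sum(stats::residuals(fit, type = "pearson")^2) / fit$df.residual
  structure(
    list(
      coefficients = stats::coef(fit),
      vcov = sm$cov.unscaled * phi,
      dispersion = phi,
      n_obs = nrow(est),
      df_residual = fit$df.residual,
      converged = fit$converged,
      glm = fit,
      design = design,
      interruption = attr(design, "interruption")
    ),
    class = "its_fit"
  )
}

#' @export
coef.its_fit <- function(object, ...) object$coefficients

#' @export
vcov.its_fit <- function(object, ...) object$vcov

#' @export
print.its_fit <- function(x, ...) {
  cat("Segmented quasi-Poisson ITS fit\n")
  cat("  weeks used:", x$n_obs,
      " dispersion (Pearson):", signif(x$dispersion, 4),
      " converged:", x$converged, "\n")
  cat("  gap coefficient: not estimable (all-zero gap weeks excluded)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

# Map from report labels to design-matrix coefficient names.
rr_terms <- c(
  pre_linear = "t",
  pre_quadratic = "t_sq",
  step = "sig",
  post_linear = "tpost",
  post_quadratic = "tpost_sq"
)

#' Per-year rate ratios with 95% Wald intervals
#'
#' Exponentiates the trend, step and trend-change coefficients of one or more
#' fits. Time enters the model in years, so `exp(beta)` is directly a
#' per-year rate ratio; intervals are `exp(beta +/- 1.96 se)` with
#' dispersion-scaled standard errors.
#'
#' @param fits a single `its_fit` or a named list of them (names become the
#'   `stratum` column).
#' @return a tibble with columns `stratum`, `term` (`pre_linear`,
#'   `pre_quadratic`, `step`, `post_linear`, `post_quadratic`), `rr`,
#'   `ci_low`, `ci_high`.
#' @export
rate_ratio_table <- function(fits) {
  if (inherits(fits, "its_fit")) fits <- list(total = fits)
  dplyr::bind_rows(lapply(names(fits), function(nm) {
    fit <- fits[[nm]]
    beta <- fit$coefficients[rr_terms]
    se <- sqrt(diag(fit$vcov)[rr_terms])
    tibble::tibble(
      stratum = nm,
      term = names(rr_terms),
      rr = exp(unname(beta)),
      ci_low = exp(unname(beta - 1.96 * se)),
      ci_high = exp(unname(beta + 1.96 * se))
    )
  }))
}

#' Format a rate-ratio table for display
#'
#' Pivots [rate_ratio_table()] output to one row per stratum with
#' `"RR (low-high)"` strings rounded to 2 decimal places.
#'
#' @param rr_tbl output of [rate_ratio_table()].
#' @return a wide tibble, one row per stratum, one column per term.
#' @export
format_rr_table <- function(rr_tbl) {
  rr_tbl |>
    dplyr::mutate(cell = sprintf("%.2f (%.2f-%.2f)", .data$rr,
                                 .data$ci_low, .data$ci_high)) |>
    dplyr::select("stratum", "term", "cell") |>
    tidyr::pivot_wider(names_from = "term", values_from = "cell")
}

#' Residual diagnostics for a segmented fit
#'
#' Deviance and Pearson residuals per non-gap week, an optional residual
#' plot, and a small summary (mean Pearson residual, lag-1 autocorrelation,
#' dispersion).
#'
#' @param fit an `its_fit`.
#' @param plot_file optional path; when given, a residuals-vs-date plot is
#'   written there (PNG).
#' @return a list with `residuals` (tibble: `week_index`, `date`, `pearson`,
#'   `deviance`) and `summary` (list: `mean_pearson`, `lag1_autocorrelation`,
#'   `dispersion`).
#' @export
residual_diagnostics <- function(fit, plot_file = NULL) {
  stopifnot(inherits(fit, "its_fit"))
  est <- fit$design[fit$design$lam == 0, , drop = FALSE]
  res <- tibble::tibble(
    week_index = est$week_index,
    date = est$date,
    pearson = unname(stats::residuals(fit$glm, type = "pearson")),
    deviance = unname(stats::residuals(fit$glm, type = "deviance"))
  )
  r <- res$pearson
  lag1 <- if (stats::sd(r) == 0) 0 else
    stats::cor(r[-length(r)], r[-1])
  out <- list(
    residuals = res,
    summary = list(
      mean_pearson = mean(r),
      lag1_autocorrelation = lag1,
      dispersion = fit$dispersion
    )
  )
  if (!is.null(plot_file)) {
    p <- ggplot2::ggplot(res, ggplot2::aes(x = date, y = pearson)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.6) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = NULL, y = "Pearson residual",
                    title = "Residuals, segmented quasi-Poisson fit") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(plot_file, p, width = 8, height = 4, dpi = 150)
  }
  out
}
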