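# Shared test helpers: small weekly series builders and an independent
# Poisson maximum-likelihood oracle (generic quasi-Newton optimisation of
# the log-likelihood, no IRLS).

# A one-stratum weekly series of consecutive Saturdays.
make_series <- function(counts, population = 1000,
                        start = as.Date("2015-01-03")) {
  n <- length(counts)
  tibble::tibble(
    stratum = "total",
    week_index = 0:(n - 1),
    date = start + 7 * (0:(n - 1)),
    count = counts,
    population = population,
    rate_per_1000 = counts / population * 1000
  )
}

# An interruption far beyond any short test window, so lam = sig = 0
# everywhere and the series carries no gap.
far_interruption <- function() {
  interruption_config(gap_start = as.Date("2400-01-04"),
                      reopen_date = as.Date("2400-06-06"))
}

# Maximise the Poisson log-likelihood sum(y * eta - exp(eta)) with
# eta = X beta + offset, by BFGS with analytic gradient. Independent of the
# package's fitting route.
oracle_poisson_fit <- function(X, y, offset = 0) {
  offset <- rep_len(offset, length(y))
  negll <- function(beta) {
    eta <- drop(X %*% beta) + offset
    -sum(y * eta - exp(eta))
  }
  grad <- function(beta) {
    eta <- drop(X %*% beta) + offset
    -drop(crossprod(X, y - exp(eta)))
  }
  start <- qr.solve(X, log(pmax(y, 0.5)) - offset)
  opt <- stats::optim(start, negll, grad, method = "L-BFGS-B",
                      control = list(factr = 10, maxit = 5000))
  opt$par
}

# Model matrix for a design tibble restricted to non-gap rows, matching the
# term set used by fit_quasipoisson().
design_model_matrix <- function(design, terms) {
  est <- design[design$lam == 0, , drop = FALSE]
  est$season <- droplevels(est$season)
  rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = est)
  list(X = X, y = est$count, offset = est$offset_log)
}
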