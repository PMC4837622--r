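#' Heritability per posterior draw
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)` by default; with
#' `include_maternal = TRUE` the common maternal-environment variance is
#' added to the denominator (the phenotypic variance is then the sum of the
#' genetic, maternal-environmental and residual variances, as appropriate
#' for body weight).
#'
#' @param draws data.frame of draws with columns `sigma2_g<t>`,
#'   `sigma2_e<t>` and `sigma2_c` (a `chain_store` row set works directly).
#' @param trait 1 or 2: which trait of the pair.
#' @param include_maternal add `sigma2_c` to the denominator.
#' @return numeric vector of per-draw heritabilities.
#' @examples
#' h2_per_draw(data.frame(sigma2_g1 = 3, sigma2_e1 = 6, sigma2_c = 1),
#'             trait = 1, include_maternal = TRUE) # 0.3
#' @export
h2_per_draw <- function(draws, trait = 1, include_maternal = FALSE) {
  g <- draws[[paste0("sigma2_g", trait)]]
  e <- draws[[paste0("sigma2_e", trait)]]
  cc <- if (include_maternal) {
    if (is.null(draws$sigma2_c)) stop("no sigma2_c column in draws")
    ifelse(is.na(draws$sigma2_c), 0, draws$sigma2_c)
  } else 0
  g / (g + cc + e)
}

#' Genetic correlation per posterior draw
#'
#' `rg = sigma_g12 / sqrt(sigma2_g1 sigma2_g2)`. Draws with a genetic
#' variance at or below `tol` are returned as `NA` and counted in the
#' `"n_degenerate"` attribute.
#'
#' @param draws data.frame with columns `sigma_g12`, `sigma2_g1`,
#'   `sigma2_g2`.
#' @param tol degeneracy tolerance for the genetic variances.
#' @return numeric vector in `[-1, 1]` (PSD draws), attribute
#'   `n_degenerate`.
#' @export
rg_per_draw <- function(draws, tol = 1e-12) {
  g1 <- draws$sigma2_g1; g2 <- draws$sigma2_g2
  bad <- !is.na(g1) & !is.na(g2) & (g1 <= tol | g2 <= tol)
  r <- draws$sigma_g12 / sqrt(g1 * g2)
  r[bad] <- NA_real_
  attr(r, "n_degenerate") <- sum(bad)
  r
}

#' Posterior summary of a chain
#'
#' Per parameter: posterior mean, posterior SD (reported, following common
#' practice in the field, as the standard error of the estimate), a 95%
#' interval (equal-tail by default, highest-density on request), and a
#' significance flag marking parameters whose interval excludes 0.
#'
#' @param chain a `chain_store` or data.frame of draws.
#' @param params columns to summarize (default: all numeric).
#' @param level interval probability (default 0.95).
#' @param hdi use the highest-density interval instead of equal-tail
#'   quantiles.
#' @return data.frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`, `n_draws`, `significant`.
#' @export
summarize_chain <- function(chain, params = NULL, level = 0.95,
                            hdi = FALSE) {
  df <- as.data.frame(chain)
  if (is.null(params))
    params <- names(df)[vapply(df, is.numeric, TRUE)]
  rows <- lapply(params, function(p) {
    x <- df[[p]]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(parameter = p, mean = NA_real_, sd = NA_real_,
                        lower = NA_real_, upper = NA_real_, n_draws = 0L,
                        significant = NA))
    ci <- if (hdi) .hdi(x, level) else
      stats::quantile(x, c((1 - level) / 2, 1 - (1 - level) / 2),
                      names = FALSE)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               lower = ci[1], upper = ci[2], n_draws = length(x),
               significant = ci[1] > 0 | ci[2] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.hdi <- function(x, level) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, floor(level * n))
  if (m >= n) return(range(x))
  w <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(w)
  c(x[i], x[i + m])
}

#' Dempster-Lerner transformation of heritability to the observed scale
#'
#' Converts a liability-scale heritability to the observed (all-or-none)
#' scale for a binary classification with incidence `p`:
#' `h2_obs = h2_lia * z^2 / (p (1 - p))`, where `z` is the standard normal
#' density at the threshold `qnorm(1 - p)`. The factor is symmetric in
#' `p <-> 1 - p` and maximal at `p = 0.5`, where it equals `2 / pi`.
#'
#' @param h2_liability heritability on the liability scale, in `[0, 1]`.
#' @param incidence incidence of the affected class, in `(0, 1)`.
#' @return heritability on the observed scale.
#' @examples
#' dempster_lerner(0.65, 0.50) # ~0.41
#' @export
dempster_lerner <- function(h2_liability, incidence) {
  if (any(h2_liability < 0 | h2_liability > 1))
    stop("h2_liability must be in [0, 1]")
  if (any(incidence <= 0 | incidence >= 1))
    stop("incidence must be strictly inside (0, 1)")
  z <- stats::dnorm(stats::qnorm(1 - incidence))
  h2_liability * z^2 / (incidence * (1 - incidence))
}

#' Heidelberger-Welch convergence diagnostic
#'
#' Stationarity: a Cramer-von Mises test on the Brownian-bridge transform
#' of the cumulative sums, applied to the full chain and then, while it
#' fails, after discarding successive 10% increments up to half the chain.
#' Halfwidth: the asymptotic 95% interval halfwidth of the mean, from the
#' spectral density at frequency zero estimated by an autoregressive fit,
#' must be at most `eps` times the mean in absolute value.
#'
#' @param chain numeric vector, or data.frame of draws (each numeric column
#'   tested).
#' @param alpha stationarity test level (default 0.05).
#' @param eps halfwidth relative tolerance (default 0.1).
#' @return data.frame with one row per parameter: `parameter`,
#'   `stationarity` (pass?), `start` (first retained index), `cvm_pvalue`,
#'   `mean`, `halfwidth`, `halfwidth_pass`.
#' @export
heidelberger_welch <- function(chain, alpha = 0.05, eps = 0.1) {
  df <- if (is.numeric(chain)) data.frame(chain = chain) else
    as.data.frame(chain)
  df <- df[vapply(df, is.numeric, TRUE)]
  out <- lapply(names(df), function(p) {
    x <- df[[p]][!is.na(df[[p]])]
    n <- length(x)
    if (n < 100) stop("chain too short for the diagnostic (need >= 100)")
    if (stats::sd(x) == 0) # constant chain: trivially stationary & precise
      return(data.frame(parameter = p, stationarity = TRUE, start = 1L,
                        cvm_pvalue = 1, mean = mean(x), halfwidth = 0,
                        halfwidth_pass = TRUE))
    S0 <- .spectrum0_ar(x[seq(floor(n / 2), n)])
    converged <- FALSE; pval <- NA_real_; start <- 1L
    for (frac in seq(0, 0.5, by = 0.1)) {
      start <- floor(frac * n) + 1L
      y <- x[start:n]
      m <- length(y)
      B <- cumsum(y) - mean(y) * seq_len(m)
      I <- sum(B * B / (m * S0)) / m
      pval <- 1 - .pcramer(I)
      if (is.finite(pval) && pval > alpha) { converged <- TRUE; break }
    }
    y <- x[start:n]
    hw <- 1.96 * sqrt(.spectrum0_ar(y) / length(y))
    data.frame(parameter = p, stationarity = converged, start = start,
               cvm_pvalue = pval, mean = mean(y), halfwidth = hw,
               halfwidth_pass = converged && is.finite(hw) &&
                 abs(hw / mean(y)) <= eps)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

## spectral density at frequency zero via an AIC-selected AR fit
.spectrum0_ar <- function(x) {
  n <- length(x)
  if (stats::sd(x) == 0) return(0)
  fit <- try(stats::ar(x, aic = TRUE,
                       order.max = min(floor(10 * log10(n)), n - 1)),
             silent = TRUE)
  if (inherits(fit, "try-error")) return(stats::var(x))
  if (fit$order == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

## asymptotic CDF of the Cramer-von Mises statistic (series expansion)
.pcramer <- function(q, eps = 1e-5) {
  if (q <= 0) return(0)
  total <- 0
  for (k in 0:3) {
    z <- gamma(k + 0.5) * sqrt(4 * k + 1) / (gamma(k + 1) * pi^1.5 * sqrt(q))
    u <- (4 * k + 1)^2 / (16 * q)
    if (u <= -log(eps))
      total <- total + z * exp(-u) * besselK(u, 0.25)
  }
  min(max(total, 0), 1)
}

#' Trace and running-mean series for one parameter
#'
#' Plot-ready series for visual convergence checks.
#'
#' @param chain a `chain_store` or data.frame of draws.
#' @param param parameter (column) name.
#' @return data.frame with columns `iteration`, `value`, `running_mean`.
#' @export
trace_and_running_mean <- function(chain, param) {
  df <- as.data.frame(chain)
  if (!param %in% names(df))
    stop("unknown parameter '", param, "'; available: ",
         paste(names(df), collapse = ", "))
  x <- df[[param]]
  data.frame(iteration = seq_along(x), value = x,
             running_mean = cumsum(x) / seq_along(x))
}
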