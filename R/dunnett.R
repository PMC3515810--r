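# Dunnett many-to-one comparison: distribution of max |T_i| (or max T_i)
# over k treatment-vs-control t statistics sharing the control mean and a
# pooled variance estimate.
#
# With lambda_i = sqrt(n_i / (n_i + n_0)), the comparison statistics are
# equicorrelated multivariate t with corr(T_i, T_j) = lambda_i * lambda_j
# and nu degrees of freedom. Probabilities are computed by double
# Gauss-Legendre quadrature over the shared control variate Z_0 and the
# studentizing scale S = sqrt(chi^2_nu / nu); this factorizes the joint
# probability into a product of independent normal probabilities.

#' Specification of a many-to-one comparison family
#'
#' @param k Number of treatment groups compared against the control.
#' @param n_control Control group size (>= 2).
#' @param n_treat Treatment group sizes; scalar (balanced) or length-k.
#' @param alpha Familywise error rate.
#' @param sided `"two_sided"` (default) or `"upper"` (activity = increase
#'   over vehicle only).
#' @param nu Residual degrees of freedom; defaults to the one-way layout
#'   value `sum(n_i) - (k + 1)`.
#' @return A `dunnett_spec` list with the comparison correlations
#'   `lambda`.
#' @export
dunnett_spec <- function(k, n_control, n_treat = n_control, alpha = 0.05,
                         sided = c("two_sided", "upper"), nu = NULL) {
  sided <- match.arg(sided)
  if (k < 1) stop_ts("k must be >= 1")
  n_treat <- rep_len(n_treat, k)
  if (n_control < 2 || any(n_treat < 2)) stop_ts("all group sizes must be >= 2")
  nu <- nu %||% (sum(n_treat) + n_control - (k + 1))
  if (nu < 2) stop_ts("residual degrees of freedom must be >= 2")
  structure(list(k = as.integer(k), n_control = n_control,
                 n_treat = n_treat, alpha = alpha, sided = sided, nu = nu,
                 lambda = sqrt(n_treat / (n_treat + n_control))),
            class = "dunnett_spec")
}

# P(max_i |T_i| <= d) (two_sided) or P(max_i T_i <= d) (upper), vectorized
# over d. n_z/n_s quadrature orders give ~1e-7 absolute accuracy.
dunnett_prob <- function(d, spec, n_z = 128L, n_s = 96L) {
  lambda <- spec$lambda; nu <- spec$nu
  two_sided <- spec$sided == "two_sided"
  gz <- gauss_legendre_ab(n_z, -9, 9)
  s_hi <- sqrt(stats::qchisq(1 - 1e-14, nu) / nu)
  s_lo <- sqrt(stats::qchisq(1e-14, nu) / nu)
  gs <- gauss_legendre_ab(n_s, s_lo, s_hi)
  # density of S = sqrt(chi^2_nu / nu)
  log_gs_dens <- log(2) + (nu / 2) * log(nu / 2) - lgamma(nu / 2) +
    (nu - 1) * log(gs$nodes) - nu * gs$nodes^2 / 2
  ws <- gs$weights * exp(log_gs_dens)
  wz <- gz$weights * stats::dnorm(gz$nodes)
  equal_lambda <- length(unique(round(lambda, 15))) == 1L

  vapply(d, function(dd) {
    if (dd <= 0 && two_sided) return(0)
    # grid: rows = z nodes, cols = s nodes
    ds <- rep(dd * gs$nodes, each = n_z)              # d * s
    z <- rep(gz$nodes, times = n_s)
    if (equal_lambda) {
      lam <- lambda[1]; den <- sqrt(1 - lam^2)
      up <- stats::pnorm((ds - lam * z) / den)
      lo <- if (two_sided) stats::pnorm((-ds - lam * z) / den) else 0
      prodterm <- pmax(up - lo, 0)^spec$k
    } else {
      logp <- 0
      for (lam in lambda) {
        den <- sqrt(1 - lam^2)
        up <- stats::pnorm((ds - lam * z) / den)
        lo <- if (two_sided) stats::pnorm((-ds - lam * z) / den) else 0
        logp <- logp + log(pmax(up - lo, 1e-300))
      }
      prodterm <- exp(logp)
    }
    m <- matrix(prodterm, n_z, n_s)
    as.numeric(crossprod(wz, m) %*% ws)
  }, numeric(1))
}

#' Dunnett critical value
#'
#' Solves `P(max_i |T_i| <= d) = 1 - alpha` (two-sided; `max T_i` for
#' one-sided) for the equicorrelated multivariate t of the many-to-one
#' comparisons. For `k = 1` this reduces to the Student-t quantile.
#'
#' @param spec A [dunnett_spec()].
#' @param tol Absolute tolerance on the critical value.
#' @return The critical value `d`.
#' @export
dunnett_critical <- function(spec, tol = 1e-6) {
  target <- 1 - spec$alpha
  f <- function(d) dunnett_prob(d, spec) - target
  hi <- 2
  while (f(hi) < 0 && hi < 64) hi <- hi * 2
  if (f(hi) < 0) stop_ts("failed to bracket the Dunnett critical value")
  stats::uniroot(f, c(1e-8, hi), tol = tol)$root
}

#' Dunnett-adjusted p-values
#'
#' For observed comparison statistics `t`, returns
#' `P(max_j |T_j| >= |t_i|)` under the joint null (or the one-sided
#' analogue), i.e. single-step familywise-adjusted p-values.
#'
#' @param t Numeric vector of observed t statistics.
#' @param spec A [dunnett_spec()].
#' @return Adjusted p-values in (0, 1], same length as `t`.
#' @export
dunnett_pvalues <- function(t, spec) {
  tt <- if (spec$sided == "two_sided") abs(t) else t
  p <- 1 - dunnett_prob(tt, spec)
  pmin(pmax(p, 0), 1)
}

#' Monte-Carlo oracle for the max-|T| distribution
#'
#' Independent simulation of the many-to-one comparison statistics used to
#' cross-check the quadrature: draws `(Z_0, Z_1..Z_k, S)` and forms
#' `T_i = (lambda_i Z_0 + sqrt(1 - lambda_i^2) Z_i) / S`.
#'
#' @param spec A [dunnett_spec()].
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed RNG seed.
#' @return List with the simulated `1 - alpha` quantile of max statistic
#'   (`quantile`), its MC standard error (`se`), and a function
#'   `prob(d)` returning the simulated `P(max <= d)`.
#' @export
dunnett_mc_oracle <- function(spec, n_draws = 1e6, seed = 1) {
  with_seed(seed, {
    k <- spec$k; lambda <- spec$lambda
    z0 <- stats::rnorm(n_draws)
    s <- sqrt(stats::rchisq(n_draws, spec$nu) / spec$nu)
    mx <- rep(-Inf, n_draws)
    for (i in seq_len(k)) {
      ti <- (lambda[i] * z0 + sqrt(1 - lambda[i]^2) * stats::rnorm(n_draws)) / s
      if (spec$sided == "two_sided") ti <- abs(ti)
      mx <- pmax(mx, ti)
    }
    q <- stats::quantile(mx, 1 - spec$alpha, names = FALSE, type = 8)
    dens <- stats::density(mx, from = q, to = q, n = 1)$y
    se <- sqrt(spec$alpha * (1 - spec$alpha) / n_draws) / max(dens, 1e-12)
    list(quantile = q, se = se,
         prob = function(d) vapply(d, function(x) mean(mx <= x), numeric(1)))
  })
}
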