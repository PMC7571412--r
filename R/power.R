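#' Power for detecting a fitness difference with a t-test
#'
#' Exact power from the noncentral t distribution, matching the standard
#' t-test power conventions: the noncentrality parameter is d * sqrt(n)
#' for one-sample/paired designs and d * sqrt(n/2) for two-sample designs
#' (n per group), where d = effect / sd is the standardized effect. At
#' effect 0 the power equals alpha exactly.
#'
#' @param n observations per group (>= 2)
#' @param effect fitness difference to detect (same units as `sd`, e.g.
#'   Wrightian fitness proportion)
#' @param sd noise standard deviation (typically the replicate rMSE)
#' @param type "two.sample", "one.sample", or "paired"
#' @param alternative "two.sided", "greater", or "less"
#' @param alpha significance level
#' @return power (vectorized over n / effect)
#' @export
power_t <- function(n, effect, sd,
                    type = c("two.sample", "one.sample", "paired"),
                    alternative = c("two.sided", "greater", "less"),
                    alpha = 0.05) {
  type <- match.arg(type)
  alternative <- match.arg(alternative)
  stopifnot(all(n >= 2), sd > 0, alpha > 0, alpha < 1)
  d <- effect / sd
  ncp <- switch(type,
                two.sample = d * sqrt(n / 2),
                one.sample = , paired = d * sqrt(n))
  dfree <- switch(type,
                  two.sample = 2 * (n - 1),
                  one.sample = , paired = n - 1)
  switch(alternative,
         two.sided = {
           tc <- stats::qt(1 - alpha / 2, dfree)
           stats::pt(tc, dfree, ncp = ncp, lower.tail = FALSE) +
             stats::pt(-tc, dfree, ncp = ncp)
         },
         greater = {
           tc <- stats::qt(1 - alpha, dfree)
           stats::pt(tc, dfree, ncp = ncp, lower.tail = FALSE)
         },
         less = {
           tc <- stats::qt(alpha, dfree)
           stats::pt(tc, dfree, ncp = ncp)
         })
}

#' Power for a general-linear-model effect (Cohen's f2)
#'
#' Power from the noncentral F distribution with noncentrality
#' lambda = f2 * (u + v + 1), where u and v are the numerator and
#' denominator degrees of freedom — the convention used for
#' treatment-level contrasts in regression designs. At f2 = 0 the power
#' equals alpha exactly.
#'
#' @param u numerator degrees of freedom (>= 1)
#' @param v denominator degrees of freedom (>= 1)
#' @param f2 effect size (Cohen's f-squared, >= 0)
#' @param alpha significance level
#' @return power (vectorized over v / f2)
#' @export
power_f2 <- function(u, v, f2, alpha = 0.05) {
  stopifnot(all(u >= 1), all(v >= 1), all(f2 >= 0), alpha > 0, alpha < 1)
  lambda <- f2 * (u + v + 1)
  fc <- stats::qf(1 - alpha, u, v)
  stats::pf(fc, u, v, ncp = lambda, lower.tail = FALSE)
}

#' Power surface over effect size and replication
#'
#' Tabulates [power_t()] over a grid of fitness effects and replicate
#' numbers at a fixed noise sd — the usual way to visualize what a design
#' can detect (e.g. at the proof-of-concept rMSE of 1.76e-2 or the
#' end-point-assay rMSE of 4.31e-2). Power is monotone increasing in both
#' axes.
#'
#' @param effects vector of fitness differences
#' @param ns vector of replicate numbers
#' @param sd noise sd (replicate rMSE)
#' @inheritParams power_t
#' @return data.frame (fitchange, psd, n, power, sig.level)
#' @export
power_surface_t <- function(effects, ns, sd,
                            type = "two.sample",
                            alternative = "two.sided", alpha = 0.05) {
  if (!length(effects) || !length(ns)) stop("empty grid")
  grid <- expand.grid(fitchange = effects, n = ns)
  grid$psd <- sd
  grid$power <- power_t(grid$n, grid$fitchange, sd, type = type,
                        alternative = alternative, alpha = alpha)
  grid$sig.level <- alpha
  grid[, c("fitchange", "psd", "n", "power", "sig.level")]
}

#' @rdname power_surface_t
#' @param f2s vector of f2 effect sizes
#' @param vs vector of denominator degrees of freedom
#' @export
power_surface_f2 <- function(u, vs, f2s, alpha = 0.05) {
  if (!length(vs) || !length(f2s)) stop("empty grid")
  grid <- expand.grid(v = vs, f2 = f2s)
  grid$u <- u
  grid$power <- power_f2(u, grid$v, grid$f2, alpha = alpha)
  grid$sig.level <- alpha
  grid[, c("u", "v", "power", "f2", "sig.level")]
}
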