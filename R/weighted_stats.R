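#' Weighted t-test
#'
#' One-sample, paired, or two-sample (Welch-style) t-test with
#' observation weights. Weights are normalized within each sample to sum
#' to the sample size (count-weight semantics), so equal weights reduce
#' the two-sample test exactly to Welch's t-test and the one-sample test
#' to the classical t-test. Degrees of freedom are n - 1 for one-sample
#' and paired tests and Welch-Satterthwaite for two-sample tests.
#'
#' @param x numeric sample (or first member of pairs)
#' @param y optional second sample (paired when `paired = TRUE`)
#' @param weights weights for `x` (and for the pairs when paired)
#' @param weights_y weights for `y` in the two-sample case (default:
#'   `weights` if lengths match, else equal)
#' @param alternative "two.sided", "less", or "greater" (mean of x - y,
#'   or of x - mu)
#' @param paired treat x, y as paired observations
#' @param mu null value for the one-sample mean (default 0)
#' @return list: estimate, t, df, p_value, alternative
#' @export
weighted_t_test <- function(x, y = NULL, weights = NULL, weights_y = NULL,
                            alternative = c("two.sided", "less", "greater"),
                            paired = FALSE, mu = 0) {
  alternative <- match.arg(alternative)
  wmv <- function(v, w) {
    n <- length(v)
    w <- w * n / sum(w)
    m <- sum(w * v) / n
    s2 <- if (n > 1) sum(w * (v - m)^2) / (n - 1) else NA_real_
    list(n = n, mean = m, var = s2)
  }
  if (paired) {
    if (is.null(y) || length(x) != length(y))
      stop("paired test needs equal-length x and y")
    x <- x - y; y <- NULL
  }
  if (is.null(weights)) weights <- rep(1, length(x))
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  if (is.null(y)) {
    if (length(x) < 2L) stop("need >= 2 observations")
    a <- wmv(x, weights)
    est <- a$mean - mu
    se <- sqrt(a$var / a$n)
    dfree <- a$n - 1
  } else {
    if (is.null(weights_y))
      weights_y <- if (length(y) == length(weights)) weights else
        rep(1, length(y))
    if (length(x) < 2L || length(y) < 2L)
      stop("need >= 2 observations per group")
    a <- wmv(x, weights); b <- wmv(y, weights_y)
    est <- a$mean - b$mean - mu
    va <- a$var / a$n; vb <- b$var / b$n
    se <- sqrt(va + vb)
    dfree <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  if (se == 0) {
    tstat <- 0
    p <- switch(alternative, two.sided = 1, less = 0.5, greater = 0.5)
  } else {
    tstat <- est / se
    p <- switch(alternative,
                two.sided = 2 * stats::pt(abs(tstat), dfree,
                                          lower.tail = FALSE),
                less = stats::pt(tstat, dfree),
                greater = stats::pt(tstat, dfree, lower.tail = FALSE))
  }
  list(estimate = est, t = tstat, df = dfree, p_value = p,
       alternative = alternative)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values via `stats::p.adjust(method = "BH")`. The
#' output is invariant to the input order and monotone non-decreasing in
#' p. Re-applying the adjustment to already-adjusted values is not a
#' no-op and is not claimed to be.
#'
#' @param p p-values in [0, 1]
#' @return q-values, same length and order as `p`
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Weighted least-squares fit
#'
#' Thin wrapper over `lm()` with precision weights that returns a uniform
#' coefficient table. Treatment factors are releveled so the stated
#' reference level (by default the standard-condition control,
#' CM diploid at a 1:1000 transfer) anchors the contrasts.
#'
#' @param formula model formula
#' @param data data.frame; a `weight` column (or `weights` argument) is
#'   used as precision weights
#' @param weights optional numeric weights (overrides a `weight` column)
#' @param reference named character vector, factor column -> reference
#'   level, e.g. `c(treatment_id = "CM_diploid_1to1000")`
#' @return list of class `bse_fit`: coefficients (term, estimate, se,
#'   stat, df, p_value), sigma, n, reference, model ("wls"), fit object
#' @export
wls_fit <- function(formula, data, weights = NULL, reference = NULL) {
  data <- .apply_reference(data, reference)
  w <- if (!is.null(weights)) weights
       else if ("weight" %in% names(data)) data$weight
       else rep(1, nrow(data))
  if (any(w < 0)) stop("weights must be non-negative")
  data$.w <- w
  fit <- stats::lm(formula, data = data, weights = .w)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  out <- list(coefficients = data.frame(
                term = rownames(sm),
                estimate = unname(sm[, 1]), se = unname(sm[, 2]),
                stat = unname(sm[, 3]), df = fit$df.residual,
                p_value = unname(sm[, 4]), stringsAsFactors = FALSE),
              sigma = summary(fit)$sigma,
              ranef_variance = NA_real_,
              n = nrow(data), reference = reference,
              model = "wls", fit = fit)
  class(out) <- "bse_fit"
  out
}

#' Weighted linear mixed model with a random intercept
#'
#' REML fit via `lmerTest::lmer()` with precision weights and
#' Satterthwaite degrees of freedom for the fixed-effect tests. When the
#' estimated random-intercept variance is zero (a singular fit), the
#' fixed-effect estimates coincide with [wls_fit()] on the same fixed
#' part.
#'
#' @inheritParams wls_fit
#' @param formula model formula including one `(1 | group)` term
#' @return list of class `bse_fit` with `ranef_variance` filled in
#' @export
wlmm_fit <- function(formula, data, weights = NULL, reference = NULL) {
  data <- .apply_reference(data, reference)
  w <- if (!is.null(weights)) weights
       else if ("weight" %in% names(data)) data$weight
       else rep(1, nrow(data))
  if (any(w <= 0)) stop("mixed-model weights must be positive")
  data$.w <- w
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(formula, data = data, weights = .w, REML = TRUE)))
  sm <- stats::coef(summary(fit))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rint <- vc$vcov[vc$grp != "Residual"][1]
  out <- list(coefficients = data.frame(
                term = rownames(sm),
                estimate = unname(sm[, "Estimate"]),
                se = unname(sm[, "Std. Error"]),
                stat = unname(sm[, "t value"]),
                df = unname(sm[, "df"]),
                p_value = unname(sm[, "Pr(>|t|)"]),
                stringsAsFactors = FALSE),
              sigma = stats::sigma(fit),
              ranef_variance = rint,
              n = nrow(data), reference = reference,
              model = "wlmm", fit = fit)
  class(out) <- "bse_fit"
  out
}

.apply_reference <- function(data, reference) {
  if (is.null(reference)) return(data)
  for (col in names(reference)) {
    if (!col %in% names(data)) stop("no column '", col, "' to relevel")
    data[[col]] <- stats::relevel(factor(data[[col]]), ref = reference[col])
  }
  data
}

#' @export
print.bse_fit <- function(x, ...) {
  cat("Weighted ", if (x$model == "wlmm") "mixed model" else
    "linear model", " (n = ", x$n, ")\n", sep = "")
  if (!is.na(x$ranef_variance))
    cat("Random-intercept variance:", format(x$ranef_variance), "\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Default reference level for treatment contrasts: the standard-condition
# control (diploid, complete medium, 1:1000 transfer).
TREATMENT_REFERENCE <- c(treatment_id = "CM_diploid_1to1000")

#' Treatment-recipe model set
#'
#' The study's five weighted model families, as ready-made recipes over
#' pipeline outputs:
#' \describe{
#'   \item{initial_fitness}{mean-corrected fitness ~ 0 + strain, weighted;
#'     two-sided per-strain tests with BH adjustment
#'     ([fit_initial_fitness_model()]).}
#'   \item{fitness_change_strain}{delta_w ~ 0 + strain, weighted;
#'     one-tailed (greater) tests with BH adjustment
#'     ([fit_change_strain_model()]).}
#'   \item{fitness_change_treatment}{delta_w ~ treatment +
#'     cross-contamination + (1 | strain), weighted mixed model; the
#'     contamination covariate is dropped when non-significant
#'     (p > 0.05) ([fit_treatment_model()]).}
#'   \item{error_sources}{SE(delta_w) ~ treatment + contamination +
#'     delta_w + median count + median proportion, weighted
#'     ([fit_error_model()]).}
#'   \item{dynamics}{each of the seven dynamics metrics ~ treatment +
#'     initial abundance, weighted, with the initial-abundance covariate
#'     dropped when non-significant ([fit_dynamics_models()]).}
#' }
#' @name paper_models
NULL

#' @rdname paper_models
#' @param data data.frame with columns strain, fitness (Wrightian), weight
#' @export
fit_initial_fitness_model <- function(data) {
  data$value <- data$fitness - stats::weighted.mean(data$fitness,
                                                    data$weight)
  strain_significance(data[, c("strain", "value", "weight")],
                      tail = "two.sided")
}

#' @rdname paper_models
#' @param data data.frame with columns strain, delta_w, weight
#' @export
fit_change_strain_model <- function(data) {
  data$value <- data$delta_w
  strain_significance(data[, c("strain", "value", "weight")],
                      tail = "greater")
}

#' @rdname paper_models
#' @param data data.frame with columns delta_w, treatment_id,
#'   contamination, strain, weight
#' @param drop_threshold covariate retained only if p <= this (default
#'   0.05)
#' @export
fit_treatment_model <- function(data, drop_threshold = 0.05) {
  needed <- c("delta_w", "treatment_id", "contamination", "strain",
              "weight")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  full <- wlmm_fit(delta_w ~ treatment_id + contamination + (1 | strain),
                   data, reference = TREATMENT_REFERENCE)
  pcov <- full$coefficients$p_value[full$coefficients$term ==
                                      "contamination"]
  if (length(pcov) && !is.na(pcov) && pcov > drop_threshold) {
    fit <- wlmm_fit(delta_w ~ treatment_id + (1 | strain), data,
                    reference = TREATMENT_REFERENCE)
    fit$dropped <- "contamination"
    fit
  } else full
}

#' @rdname paper_models
#' @param data data.frame with columns se_delta_w, treatment_id,
#'   contamination, delta_w, median_count, median_proportion, weight
#' @export
fit_error_model <- function(data) {
  wls_fit(se_delta_w ~ treatment_id + contamination + delta_w +
            median_count + median_proportion,
          data, reference = TREATMENT_REFERENCE)
}

#' @rdname paper_models
#' @param dynamics output of [batch_dynamics()]
#' @export
fit_dynamics_models <- function(dynamics, drop_threshold = 0.05) {
  metrics <- c("t_max", "m_max", "t_max_rate", "m_max_rate", "t_max_diff",
               "m_max_diff", "total_change")
  fits <- list()
  for (metric in metrics) {
    dat <- dynamics
    dat$.y <- dat[[metric]]
    full <- wls_fit(.y ~ treatment_id + initial_abundance, dat,
                    reference = TREATMENT_REFERENCE)
    pcov <- full$coefficients$p_value[full$coefficients$term ==
                                        "initial_abundance"]
    if (length(pcov) && !is.na(pcov) && pcov > drop_threshold) {
      fit <- wls_fit(.y ~ treatment_id, dat,
                     reference = TREATMENT_REFERENCE)
      fit$dropped <- "initial_abundance"
      fits[[metric]] <- fit
    } else fits[[metric]] <- full
  }
  fits
}

#' Tabulate a fit the way treatment-contrast tables are reported
#'
#' @param fit a `bse_fit`
#' @return data.frame (term, estimate, se, p_value, signif) with
#'   significance stars (*** < 0.001, ** < 0.01, * < 0.05)
#' @export
tidy_fit <- function(fit) {
  co <- fit$coefficients
  stars <- cut(co$p_value, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", ""))
  data.frame(term = co$term, estimate = co$estimate, se = co$se,
             p_value = co$p_value, signif = as.character(stars),
             stringsAsFactors = FALSE)
}
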