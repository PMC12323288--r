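#' Orthogonal polynomial time basis
#'
#' Orthonormal polynomial contrasts of orders 1..k over the bin indices:
#' every column has zero mean and unit norm and the columns are mutually
#' orthogonal (equivalent to Gram-Schmidt orthogonalization of the raw
#' powers against the intercept and each other).
#'
#' @param n_bins Number of time bins.
#' @param k Highest polynomial order; must be smaller than `n_bins`.
#' @return Tibble with `bin` (0-based) and columns `ot1`..`otk`.
#' @export
orthogonal_time_basis <- function(n_bins, k) {
  if (k >= n_bins) stop("polynomial order k must be < n_bins")
  b <- stats::poly(seq_len(n_bins), degree = k, simple = TRUE)
  out <- tibble::as_tibble(as.data.frame(b))
  names(out) <- paste0("ot", seq_len(k))
  dplyr::bind_cols(tibble::tibble(bin = 0:(n_bins - 1)), out)
}

#' Fit the growth-curve model of the log-ratio time course
#'
#' Linear mixed-effects model of the log-gaze proportion ratio on
#' orthogonal time polynomials, group, and their interactions, with random
#' intercepts for participants and trials (trial intercepts only when the
#' series is at trial level):
#' `value ~ (ot1 + ... + otk) * group [+ covariates] +
#'  (1 | participant) [+ (1 | trial)]`.
#' Estimated by REML. Wald t statistics are reported with, by default,
#' residual-degrees-of-freedom p-values (`df_method = "residual"`,
#' effectively a z-test at these sample sizes); `df_method =
#' "satterthwaite"` uses lmerTest instead. A singular random-effects fit
#' is retried without the trial intercept and flagged.
#'
#' @param series Log-ratio series from [log_ratio_series()].
#' @param k Polynomial order (default 4, quartic).
#' @param ref_group Reference group level (the second, neurotypical-like
#'   group by convention).
#' @param covariates Optional participant-level covariate tibble
#'   (`participant_id` plus numeric columns) entered as fixed effects.
#' @param df_method `"residual"` or `"satterthwaite"`.
#' @param reml Fit by REML (default) or ML (used for model comparison).
#' @return A `vwp_growth_fit` list: `coefficients` (term, estimate, se, t,
#'   df, p), `varcor`, `k`, `ref_group`, `df_method`, `logLik`, `n_obs`,
#'   `singular`, `dropped_re`, and the fitted `model`.
#' @export
fit_growth_model <- function(series, k = 4, ref_group = NULL,
                             covariates = NULL,
                             df_method = c("residual", "satterthwaite"),
                             reml = TRUE) {
  df_method <- match.arg(df_method)
  n_bins <- length(unique(series$bin))
  basis <- orthogonal_time_basis(n_bins, k)
  dat <- dplyr::left_join(series, basis, by = "bin")
  groups <- unique(dat$group)
  if (is.null(ref_group)) ref_group <- sort(groups)[length(groups)]
  dat$group <- stats::relevel(factor(dat$group), ref = ref_group)
  if (!is.null(covariates)) {
    dat <- dplyr::left_join(dat, covariates, by = "participant_id")
  }
  ots <- paste0("ot", seq_len(k))
  fixed <- paste0("(", paste(ots, collapse = " + "), ") * group")
  if (!is.null(covariates)) {
    cov_terms <- setdiff(names(covariates), "participant_id")
    fixed <- paste(fixed, "+", paste(cov_terms, collapse = " + "))
  }
  has_trial <- "trial_id" %in% names(dat)
  re <- if (has_trial) {
    "(1 | participant_id) + (1 | trial_id)"
  } else {
    "(1 | participant_id)"
  }
  form <- stats::as.formula(paste("value ~", fixed, "+", re))
  fit <- lme4::lmer(form, data = dat, REML = reml,
                    control = lme4::lmerControl(calc.derivs = FALSE))
  dropped <- character()
  if (lme4::isSingular(fit) && has_trial) {
    form2 <- stats::as.formula(paste("value ~", fixed,
                                     "+ (1 | participant_id)"))
    fit2 <- lme4::lmer(form2, data = dat, REML = reml,
                       control = lme4::lmerControl(calc.derivs = FALSE))
    if (!lme4::isSingular(fit2)) {
      fit <- fit2
      dropped <- "trial_id"
    }
  }
  co <- as.data.frame(summary(fit)$coefficients)
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]; tv <- co[, "t value"]
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      stop("df_method = 'satterthwaite' requires the lmerTest package")
    }
    fit_t <- lmerTest::as_lmerModLmerTest(fit)
    cot <- as.data.frame(summary(fit_t)$coefficients)
    dfv <- cot[, "df"]; pv <- cot[, "Pr(>|t|)"]
  } else {
    dfv <- rep(stats::nobs(fit) - length(est), length(est))
    pv <- 2 * stats::pt(abs(tv), dfv, lower.tail = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = est, se = se, t = tv, df = dfv, p = pv
    ),
    varcor = tibble::tibble(component = vc$grp, variance = vc$vcov,
                            sd = vc$sdcor),
    k = k, ref_group = ref_group, df_method = df_method,
    logLik = as.numeric(stats::logLik(fit)), n_obs = stats::nobs(fit),
    singular = lme4::isSingular(fit), dropped_re = dropped,
    model = fit
  ), class = "vwp_growth_fit")
}

#' @export
print.vwp_growth_fit <- function(x, ...) {
  cat("Growth-curve fit (k =", x$k, ", reference group =", x$ref_group,
      ", df:", x$df_method, ")\n")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Select the polynomial order by forward likelihood-ratio tests
#'
#' Fits maximum-likelihood models of increasing polynomial order (each
#' order enters together with its group interaction) and compares
#' consecutive orders with likelihood-ratio tests, stopping at the first
#' order whose addition does not improve fit at `alpha`. The full
#' comparison table is returned alongside the selected order.
#'
#' @param series Log-ratio series.
#' @param k_max Highest order considered (at most 5, quintic).
#' @param alpha LRT significance level.
#' @param ... Passed to [fit_growth_model()].
#' @return List with `k` (selected order) and `table` (tibble `k`,
#'   `logLik`, `df`, `chisq`, `chisq_df`, `p`, `selected`).
#' @export
select_order <- function(series, k_max = 5, alpha = 0.05, ...) {
  if (k_max > 5) stop("k_max must be <= 5 (quintic)")
  fits <- lapply(seq_len(k_max), function(k) {
    fit_growth_model(series, k = k, reml = FALSE, ...)
  })
  ll <- vapply(fits, function(f) f$logLik, 0)
  npar <- vapply(fits, function(f) nrow(f$coefficients), 0)
  chisq <- c(NA, 2 * diff(ll))
  chisq_df <- c(NA, diff(npar))
  p <- stats::pchisq(chisq, chisq_df, lower.tail = FALSE)
  selected <- 1L
  if (k_max > 1) {
    for (k in 2:k_max) {
      if (!is.na(p[k]) && chisq[k] >= 0 && p[k] < alpha) selected <- k
      else break
    }
  }
  list(k = selected,
       table = tibble::tibble(k = seq_len(k_max), logLik = ll,
                              n_par = npar, chisq = chisq,
                              chisq_df = chisq_df, p = p,
                              selected = seq_len(k_max) == selected))
}
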