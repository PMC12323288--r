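#' Correlations between prediction indices and autism-related measures
#'
#' Pearson correlations (two-sided, with Fisher-z 95% CIs) between each
#' prediction-efficiency index (log-ratio index, individual divergence
#' point) and: CARS total in the group that has CARS scores; AQ total per
#' group; and the five AQ subscales per group, Benjamini-Hochberg adjusted
#' within each family of five subscales (one family per group x index).
#' Participants with a missing index (e.g. undefined divergence point) are
#' removed pairwise.
#'
#' @param indices Tibble from [participant_indices()].
#' @param scores Score table (`participant_id`, `group`, `cars_total`,
#'   `aq_total`, `aq_*` subscales).
#' @return Tibble with one row per test: `group`, `index`, `measure`, `n`,
#'   `r`, `p`, `ci_lo`, `ci_hi`, `fdr_p` (`NA` outside FDR families),
#'   `family`, `note`.
#' @export
correlation_suite <- function(indices, scores) {
  dat <- dplyr::inner_join(indices, scores,
                           by = c("participant_id", "group"))
  subscales <- c("aq_social_skills", "aq_attention_switching",
                 "aq_attention_to_detail", "aq_communication",
                 "aq_imagination")
  idx_cols <- c(log_ratio_index = "log_ratio_index",
                divergence_point = "individual_dp_ms")
  rows <- list()
  one <- function(x, y, group, index, measure, family = NA_character_) {
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 3) {
      return(tibble::tibble(group = group, index = index,
                            measure = measure, n = n, r = NA_real_,
                            p = NA_real_, ci_lo = NA_real_,
                            ci_hi = NA_real_, fdr_p = NA_real_,
                            family = family,
                            note = "fewer than 3 complete pairs"))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    z <- atanh(ct$estimate)
    zse <- 1 / sqrt(n - 3)
    tibble::tibble(group = group, index = index, measure = measure,
                   n = n, r = unname(ct$estimate), p = ct$p.value,
                   ci_lo = tanh(z - 1.96 * zse),
                   ci_hi = tanh(z + 1.96 * zse),
                   fdr_p = NA_real_, family = family, note = NA_character_)
  }
  # CARS: only where present (typically the clinically assessed group).
  cars_groups <- unique(dat$group[!is.na(dat$cars_total)])
  for (g in cars_groups) {
    sub <- dat[dat$group == g, ]
    for (ix in names(idx_cols)) {
      rows[[length(rows) + 1]] <-
        one(sub[[idx_cols[[ix]]]], sub$cars_total, g, ix, "cars_total")
    }
  }
  for (g in unique(dat$group)) {
    sub <- dat[dat$group == g, ]
    for (ix in names(idx_cols)) {
      rows[[length(rows) + 1]] <-
        one(sub[[idx_cols[[ix]]]], sub$aq_total, g, ix, "aq_total")
      fam <- paste(g, ix, "aq_subscales", sep = ":")
      fam_rows <- lapply(subscales, function(s) {
        one(sub[[idx_cols[[ix]]]], sub[[s]], g, ix, s, family = fam)
      })
      fam_tbl <- dplyr::bind_rows(fam_rows)
      fam_tbl$fdr_p <- stats::p.adjust(fam_tbl$p, method = "BH")
      rows[[length(rows) + 1]] <- fam_tbl
    }
  }
  dplyr::bind_rows(rows)
}

#' Behavioral accuracy mixed model
#'
#' Logistic mixed model of per-trial correctness on group, with random
#' intercepts for participants and (by default) trials:
#' `correct ~ group + (1 | participant_id) [+ (1 | trial_id)]`.
#' Complete separation (a group with all-identical responses) is flagged
#' and no estimate is reported for it.
#'
#' @param responses Tibble `participant_id`, `group`, `trial_id`,
#'   `correct` (0/1).
#' @param ref_group Reference group level (default: second sorted level).
#' @param trial_re Include the trial random intercept.
#' @return A `vwp_accuracy_fit` list: `coefficients` (term, estimate, se,
#'   z, p), `separation`, `ref_group` and the fitted `model` (NULL under
#'   separation).
#' @export
accuracy_model <- function(responses, ref_group = NULL, trial_re = TRUE) {
  groups <- sort(unique(responses$group))
  if (is.null(ref_group)) ref_group <- groups[length(groups)]
  responses$group <- stats::relevel(factor(responses$group),
                                    ref = ref_group)
  rates <- tapply(responses$correct, responses$group, mean)
  if (any(rates %in% c(0, 1))) {
    return(structure(list(coefficients = NULL, separation = TRUE,
                          ref_group = ref_group, model = NULL),
                     class = "vwp_accuracy_fit"))
  }
  re <- if (trial_re) {
    "(1 | participant_id) + (1 | trial_id)"
  } else {
    "(1 | participant_id)"
  }
  form <- stats::as.formula(paste("correct ~ group +", re))
  fit <- lme4::glmer(form, data = responses, family = stats::binomial())
  co <- as.data.frame(summary(fit)$coefficients)
  structure(list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = co[, "Estimate"],
      se = co[, "Std. Error"], z = co[, "z value"],
      p = co[, "Pr(>|z|)"]
    ),
    separation = FALSE, ref_group = ref_group, model = fit
  ), class = "vwp_accuracy_fit")
}

#' @export
print.vwp_accuracy_fit <- function(x, ...) {
  if (x$separation) {
    cat("Accuracy model: complete separation; no estimate.\n")
  } else {
    cat("Accuracy GLMM (reference group =", x$ref_group, ")\n")
    print(as.data.frame(x$coefficients), digits = 3)
  }
  invisible(x)
}
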