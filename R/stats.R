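# Condition-level inference on per-session behavioral summaries: a
# random-intercept mixed model (condition fixed, animal random) with an
# F-test of the condition factor, a likelihood-ratio test of the
# between-animal variance, and Bonferroni-adjusted pairwise contrasts.

CONDITIONS <- c("probe_only", "balloon_weight", "weight")

#' Assemble a condition dataset
#'
#' Validates one response column of a session-summary table for mixed-model
#' analysis: at least two animals, all three conditions present, and (unless
#' flagged) one observation per animal x condition.
#'
#' @param records Session-summary tibble (see [session_summary()]) or any
#'   data frame with `animal_id`, `condition` and the response column.
#' @param response Name of the response column, one of `distance_m`,
#'   `turning_rad`, `mean_walk_v`, `mean_walk_w` (other numeric columns are
#'   accepted).
#' @return A tibble `animal_id`, `condition` (factor with the three levels),
#'   `value`, with attributes `response` and `balanced`.
#' @export
condition_dataset <- function(records, response = "distance_m") {
  stopifnot(is.data.frame(records),
            all(c("animal_id", "condition", response) %in% names(records)))
  bad <- setdiff(unique(records$condition), CONDITIONS)
  if (length(bad) > 0) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!all(CONDITIONS %in% records$condition)) {
    stop("all three conditions must be present", call. = FALSE)
  }
  if (length(unique(records$animal_id)) < 2) {
    stop("need at least 2 animals", call. = FALSE)
  }
  out <- tibble::tibble(
    animal_id = factor(records$animal_id),
    condition = factor(records$condition, levels = CONDITIONS),
    value = as.numeric(records[[response]])
  )
  out <- out[is.finite(out$value), , drop = FALSE]
  counts <- table(out$animal_id, out$condition)
  balanced <- all(counts == 1)
  if (!balanced) {
    warning("design is not one observation per animal x condition; ",
            "flagged unbalanced", call. = FALSE)
  }
  attr(out, "response") <- response
  attr(out, "balanced") <- balanced
  out
}

#' Fit the condition mixed model
#'
#' Linear mixed model `value ~ condition + (1 | animal_id)` fitted by REML.
#' The fixed-effect p-value is the Satterthwaite F-test of the condition
#' factor (in the balanced randomized-block design used here its denominator
#' df equals the between-within value `(k-1)(n-1)`). The random-effect
#' p-value is a likelihood-ratio test of the animal intercept variance
#' against zero (chi-squared, 1 df, ML). A singular fit (zero between-animal
#' variance) reports `random_effect_p = 1` with a flag.
#'
#' @param data Output of [condition_dataset()].
#' @param alpha Significance level recorded in the result, default 0.05.
#' @param include_pairwise Compute marginal means and pairwise contrasts
#'   (default `TRUE`); set `FALSE` in simulation loops that only need the
#'   omnibus p-value.
#' @return An object of class `condition_fit`: a list with `model` (the
#'   `lmerModLmerTest` fit), `fixed_effect_p`, `random_effect_p`,
#'   `f_statistic`, `df`, `condition_means` (tibble of estimated marginal
#'   means), `pairwise` (see [bonferroni_pairwise()]), `singular`, `alpha`,
#'   `response`.
#' @export
fit_condition_model <- function(data, alpha = 0.05,
                                include_pairwise = TRUE) {
  stopifnot(is.data.frame(data),
            all(c("animal_id", "condition", "value") %in% names(data)))
  fit <- lmerTest::lmer(value ~ condition + (1 | animal_id), data = data,
                        REML = TRUE,
                        control = lme4::lmerControl(
                          check.conv.singular = "ignore"))
  an <- stats::anova(fit, ddf = "Satterthwaite")
  fixed_p <- an[["Pr(>F)"]][1]
  if (!is.finite(fixed_p)) {
    # degenerate case (e.g. zero residual variance): no evidence scale
    fixed_p <- if (an[["F value"]][1] == 0 || !is.finite(an[["F value"]][1]))
      1 else 0
  }
  singular <- lme4::isSingular(fit)

  # LRT of the intercept variance: ML fits with and without the random term
  random_p <- if (singular) {
    1
  } else {
    m1 <- stats::logLik(lme4::refitML(fit))
    m0 <- stats::logLik(stats::lm(value ~ condition, data = data))
    lrt <- max(0, 2 * (as.numeric(m1) - as.numeric(m0)))
    stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  }

  condition_means <- NULL
  pairwise <- NULL
  if (include_pairwise) {
    emm <- emmeans::emmeans(fit, ~condition)
    means <- as.data.frame(emm)
    condition_means <- tibble::tibble(
      condition = as.character(means$condition),
      mean = means$emmean, se = means$SE)
    pairwise <- bonferroni_pairwise(emm)
  }
  structure(list(
    model = fit,
    fixed_effect_p = unname(fixed_p),
    random_effect_p = unname(random_p),
    f_statistic = an[["F value"]][1],
    df = c(num = an[["NumDF"]][1], den = an[["DenDF"]][1]),
    condition_means = condition_means,
    pairwise = pairwise,
    singular = singular,
    alpha = alpha,
    response = attr(data, "response")
  ), class = "condition_fit")
}

#' Bonferroni-adjusted pairwise contrasts
#'
#' The three pairwise contrasts of the estimated marginal condition means
#' (probe-only vs balloon+weight, probe-only vs weight, balloon+weight vs
#' weight), each raw p-value multiplied by 3 and capped at 1.
#'
#' @param fit A `condition_fit` from [fit_condition_model()], or an
#'   `emmGrid` of the condition means.
#' @return A tibble: `contrast`, `estimate`, `p_raw`, `p_adjusted`.
#' @export
bonferroni_pairwise <- function(fit) {
  emm <- if (inherits(fit, "condition_fit")) {
    emmeans::emmeans(fit$model, ~condition)
  } else fit
  raw <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  tibble::tibble(
    contrast = as.character(raw$contrast),
    estimate = raw$estimate,
    p_raw = raw$p.value,
    p_adjusted = pmin(1, 3 * raw$p.value)
  )
}

#' Per-condition descriptive statistics
#'
#' Mean, standard deviation and n of each numeric response by condition.
#'
#' @param records Session-summary tibble.
#' @param responses Response columns to summarise; defaults to the four
#'   behavioral summaries present in `records`.
#' @return A tibble: `condition`, `response`, `mean`, `sd`, `n`.
#' @export
describe_conditions <- function(records,
                                responses = intersect(
                                  c("distance_m", "turning_rad",
                                    "mean_walk_v", "mean_walk_w"),
                                  names(records))) {
  stopifnot(is.data.frame(records), length(responses) > 0,
            "condition" %in% names(records))
  rows <- list()
  for (resp in responses) {
    for (cond in unique(records$condition)) {
      v <- records[[resp]][records$condition == cond]
      v <- v[is.finite(v)]
      if (length(v) == 0) {
        stop("no finite observations for ", resp, " under ", cond,
             call. = FALSE)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, response = resp,
        mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  do.call(rbind, rows)
}

#' @export
print.condition_fit <- function(x, ...) {
  cat("Condition mixed model (", x$response, ")\n", sep = "")
  cat(sprintf("  fixed effect (condition): F(%g, %.2f) = %.3f, p = %.4g\n",
              x$df["num"], x$df["den"], x$f_statistic, x$fixed_effect_p))
  cat(sprintf("  random effect (animal):   LRT p = %.4g%s\n",
              x$random_effect_p,
              if (x$singular) " (singular fit: zero variance)" else ""))
  if (is.null(x$pairwise)) return(invisible(x))
  cat("  Bonferroni pairwise contrasts:\n")
  for (i in seq_len(nrow(x$pairwise))) {
    cat(sprintf("    %-35s p_adj = %.4g\n", x$pairwise$contrast[i],
                x$pairwise$p_adjusted[i]))
  }
  invisible(x)
}
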