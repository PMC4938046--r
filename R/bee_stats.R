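#' Proportion of first landings on cued flowers within a treatment group
#'
#' Counts, among the bees of one cell of the two-by-two design (cue type x
#' reward distribution), how many landed first on a flower carrying the
#' added cue.
#'
#' @param records A `bee_choices` data frame (see
#'   [generate_choice_dataset()] / [read_choice_csv()]).
#' @param cue_type `"social"` or `"nonsocial"`.
#' @param distribution `"high_variance"` or `"no_variance"`.
#' @return A list with `k` (first landings on a cued flower), `n` (bees in
#'   the group) and `proportion = k/n`.
#' @export
group_proportion <- function(records, cue_type, distribution) {
  cue_type <- match.arg(cue_type, c("social", "nonsocial"))
  distribution <- match.arg(distribution, c("high_variance", "no_variance"))
  sel <- records$cue_type == cue_type & records$distribution == distribution
  if (!any(sel))
    stop(sprintf("no records in group (%s, %s)", cue_type, distribution))
  k <- sum(records$first_choice_cued[sel])
  n <- sum(sel)
  list(k = as.integer(k), n = as.integer(n), proportion = k / n)
}

#' Exact binomial test against a chance landing level
#'
#' Tests whether `k` successes in `n` trials are compatible with success
#' probability `p0` (default 1/3, the chance of landing on one of 4 cued
#' flowers out of 12) using exact binomial tail probabilities — no normal
#' approximation. The two-sided p-value follows the point-probability
#' method: it sums `P(X = x)` over every outcome whose probability does not
#' exceed that of the observed `k` (up to a relative tolerance of 1e-7),
#' as implemented by [stats::binom.test()].
#'
#' @param k Number of successes (first landings on a cued flower).
#' @param n Number of trials (bees).
#' @param p0 Null success probability, strictly between 0 and 1.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`.
#' @return A `binom_test_result` list: `k`, `n`, `p0`, `p_value`,
#'   `alternative`.
#' @examples
#' exact_binomial_test(12, 16)          # well above chance
#' exact_binomial_test(4, 12)           # exactly at chance
#' @export
exact_binomial_test <- function(k, n, p0 = 1 / 3,
                                alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(k) != 1 || length(n) != 1 || k < 0 || n < 1 || k > n ||
      k != round(k) || n != round(n))
    stop("k and n must be integers with 0 <= k <= n, n >= 1")
  if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
    stop("p0 must lie strictly between 0 and 1")
  alt <- switch(alternative, two_sided = "two.sided", greater = "greater",
                less = "less")
  pv <- stats::binom.test(k, n, p = p0, alternative = alt)$p.value
  structure(list(k = as.integer(k), n = as.integer(n), p0 = p0,
                 p_value = as.numeric(pv), alternative = alternative),
            class = "binom_test_result")
}

#' @export
print.binom_test_result <- function(x, ...) {
  cat(sprintf(
    "Exact binomial test: k = %d, n = %d, p0 = %.4f, %s p = %.4g\n",
    x$k, x$n, x$p0, sub("_", "-", x$alternative), x$p_value))
  invisible(x)
}

#' Adjusted-Wald (Agresti-Coull) confidence interval for a proportion
#'
#' Adds `z^2 / 2` pseudo-successes and `z^2` pseudo-trials before applying
#' the Wald formula: with `z` the standard-normal quantile at
#' `1 - (1 - confidence)/2`, the adjusted point estimate is
#' `p~ = (k + z^2/2) / (n + z^2)` and the half-width is
#' `z * sqrt(p~ (1 - p~) / (n + z^2))`. Bounds are clamped to \[0, 1\].
#' The default level is 90%, the level used to display group proportions
#' of cued first landings.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, at least 1.
#' @param confidence Confidence level in (0, 1); default 0.90.
#' @return An `interval_result` list: `point` (the adjusted proportion),
#'   `lower`, `upper`, `confidence`.
#' @examples
#' adjusted_wald_interval(12, 16)
#' @export
adjusted_wald_interval <- function(k, n, confidence = 0.90) {
  if (length(k) != 1 || length(n) != 1 || n < 1 || k < 0 || k > n)
    stop("require 0 <= k <= n with n >= 1")
  if (!is.finite(confidence) || confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n_adj <- n + z^2
  p_adj <- (k + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  structure(list(point = p_adj,
                 lower = max(0, p_adj - half),
                 upper = min(1, p_adj + half),
                 confidence = confidence),
            class = "interval_result")
}

#' @export
print.interval_result <- function(x, ...) {
  cat(sprintf("Adjusted-Wald %.0f%% interval: %.3f [%.3f, %.3f]\n",
              100 * x$confidence, x$point, x$lower, x$upper))
  invisible(x)
}

# Numeric coding used throughout the regression models: positive
# coefficients mean greater cue use for social cues / after high-variance
# experience. See the methods vignette for why this orientation is used.
code_model_frame <- function(records) {
  data.frame(
    y = as.integer(records$first_choice_cued),
    cue_type = as.integer(records$cue_type == "social"),
    distribution = as.integer(records$distribution == "high_variance"),
    colony = factor(records$colony)
  )
}

#' Random-intercept logistic regression on first flower choices
#'
#' Fits a logistic regression of the binary first-choice outcome (1 =
#' landed on a cued flower) with a normally distributed random intercept
#' per colony, by marginal maximum likelihood with adaptive Gauss-Hermite
#' quadrature ([lme4::glmer()]; `nAGQ` quadrature points, default 25).
#' Fixed-effect indicators are coded social cue = 1 and high-variance
#' experience = 1, so positive coefficients mean more cue use.
#'
#' Two model forms are available: `"full_interaction"` uses cue type,
#' reward distribution and their interaction (the full 57-bee analysis);
#' `"distribution_only"` uses reward distribution alone and is meant for
#' data already split by cue type (see [split_by_cue()]).
#'
#' With a single colony a random intercept is not identifiable: the fit
#' falls back to plain fixed-effects logistic regression with
#' `random_intercept_sd = 0` and a warning. Complete separation is flagged
#' via `separation_suspected` (divergent coefficients or standard errors)
#' rather than penalised, keeping estimates comparable to standard
#' mixed-logit output.
#'
#' @param records A `bee_choices` data frame.
#' @param model `"full_interaction"` or `"distribution_only"`.
#' @param nAGQ Number of adaptive Gauss-Hermite quadrature points.
#' @return A `glmm_fit` list: named `coefficients`, `standard_errors`,
#'   `z_values`, `p_values` (two-sided normal), `random_intercept_sd`,
#'   `loglik`, `converged`, `separation_suspected`, `n`, `model`, `nAGQ`,
#'   and the underlying `fit` object.
#' @export
fit_choice_glmm <- function(records,
                            model = c("full_interaction", "distribution_only"),
                            nAGQ = 25L) {
  model <- match.arg(model)
  df <- code_model_frame(records)
  form_fixed <- if (model == "full_interaction")
    y ~ cue_type * distribution else y ~ distribution
  if (nlevels(df$colony) < 2L) {
    warning("single colony: fitting plain logistic regression, random_intercept_sd = 0")
    fit <- stats::glm(form_fixed, family = stats::binomial(), data = df)
    beta <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
    sd_colony <- 0
    converged <- fit$converged
    ll <- as.numeric(stats::logLik(fit))
  } else {
    form <- stats::update(form_fixed, . ~ . + (1 | colony))
    fit <- lme4::glmer(form, data = df, family = stats::binomial(),
                       nAGQ = as.integer(nAGQ),
                       control = lme4::glmerControl(optimizer = "bobyqa"))
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    sd_colony <- as.numeric(attr(lme4::VarCorr(fit)$colony, "stddev"))
    conv <- fit@optinfo$conv
    converged <- conv$opt == 0 && length(conv$lme4$messages) == 0L
    ll <- as.numeric(stats::logLik(fit))
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(
    coefficients = beta, standard_errors = se, z_values = z, p_values = p,
    random_intercept_sd = sd_colony, loglik = ll, converged = converged,
    separation_suspected = any(abs(beta) > 10 | se > 10),
    n = nrow(df), model = model, nAGQ = as.integer(nAGQ), fit = fit
  ), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic regression (%s, n = %d bees)\n",
              x$model, x$n))
  tab <- data.frame(estimate = round(x$coefficients, 3),
                    se = round(x$standard_errors, 3),
                    z = round(x$z_values, 3),
                    p = signif(x$p_values, 3))
  print(tab)
  cat(sprintf("colony random-intercept SD = %.3f; converged: %s\n",
              x$random_intercept_sd, x$converged))
  if (x$separation_suspected)
    cat("warning: complete or quasi-complete separation suspected\n")
  invisible(x)
}

#' Split choice records by cue type
#'
#' @param records A `bee_choices` data frame.
#' @return A named list with elements `social` and `nonsocial`.
#' @export
split_by_cue <- function(records) {
  list(social = records[records$cue_type == "social", , drop = FALSE],
       nonsocial = records[records$cue_type == "nonsocial", , drop = FALSE])
}

#' Mean proportion of cued landings among each bee's first k landings
#'
#' For every bee, the proportion of landings on cued flowers among its
#' first `min(k, available)` landings; bees with fewer than `k` landings
#' contribute the proportion over the landings they have rather than being
#' excluded. Group means are reported for every cell of the two-by-two
#' design. `k = 1` reduces exactly to the first-choice proportion of
#' [group_proportion()].
#'
#' @param records A `bee_choices` data frame with a `landings` list column.
#' @param k Vector of landing-window sizes (typically `c(4, 10)`).
#' @return A data frame with columns `k`, `cue_type`, `distribution`,
#'   `n_bees`, `mean_proportion`.
#' @export
first_k_summary <- function(records, k = c(4L, 10L)) {
  if (any(k < 1)) stop("k must be >= 1")
  cells <- expand.grid(cue_type = c("social", "nonsocial"),
                       distribution = c("high_variance", "no_variance"),
                       stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(as.integer(k), function(kk) {
    per_bee <- vapply(records$landings, function(l) {
      mean(l[seq_len(min(kk, length(l)))])
    }, numeric(1))
    cbind(k = kk, cells, do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      sel <- records$cue_type == cells$cue_type[i] &
        records$distribution == cells$distribution[i]
      data.frame(n_bees = sum(sel),
                 mean_proportion = if (any(sel)) mean(per_bee[sel]) else NA_real_)
    })))
  }))
  rownames(out) <- NULL
  out
}

#' Full choice analysis pipeline
#'
#' Runs, for a complete two-by-two choice dataset: per-group first-choice
#' proportions with exact binomial tests against chance and adjusted-Wald
#' intervals; the full-interaction random-intercept logistic regression;
#' the two split models (one per cue type) with reward distribution as the
#' fixed effect; and first-k landing summaries.
#'
#' @param records A `bee_choices` data frame.
#' @param p0 Chance landing probability (default [chance_level()] = 1/3).
#' @param confidence Interval level (default 0.90).
#' @param first_k Landing windows for [first_k_summary()].
#' @param nAGQ Quadrature points for the mixed-model fits.
#' @return A `choice_analysis` list: `groups` (data frame with counts,
#'   proportions, p-values and interval bounds), `glmm_full`,
#'   `glmm_social`, `glmm_nonsocial`, `first_k`.
#' @export
analyze_choices <- function(records, p0 = chance_level(), confidence = 0.90,
                            first_k = c(4L, 10L), nAGQ = 25L) {
  cells <- expand.grid(cue_type = c("social", "nonsocial"),
                       distribution = c("high_variance", "no_variance"),
                       stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    gp <- group_proportion(records, cells$cue_type[i], cells$distribution[i])
    bt <- exact_binomial_test(gp$k, gp$n, p0 = p0)
    ci <- adjusted_wald_interval(gp$k, gp$n, confidence = confidence)
    data.frame(cue_type = cells$cue_type[i],
               distribution = cells$distribution[i],
               k = gp$k, n = gp$n, proportion = gp$proportion,
               p_value = bt$p_value, point_adj = ci$point,
               lower = ci$lower, upper = ci$upper)
  }))
  halves <- split_by_cue(records)
  structure(list(
    groups = groups,
    glmm_full = fit_choice_glmm(records, "full_interaction", nAGQ = nAGQ),
    glmm_social = fit_choice_glmm(halves$social, "distribution_only", nAGQ = nAGQ),
    glmm_nonsocial = fit_choice_glmm(halves$nonsocial, "distribution_only", nAGQ = nAGQ),
    first_k = first_k_summary(records, k = first_k),
    p0 = p0, confidence = confidence
  ), class = "choice_analysis")
}

#' @export
print.choice_analysis <- function(x, ...) {
  cat(sprintf("Bee choice analysis: chance level %.3f, %d%% adjusted-Wald intervals\n\n",
              x$p0, round(100 * x$confidence)))
  g <- x$groups
  g$proportion <- round(g$proportion, 3)
  g$p_value <- signif(g$p_value, 3)
  g$point_adj <- round(g$point_adj, 3)
  g$lower <- round(g$lower, 3)
  g$upper <- round(g$upper, 3)
  print(g, row.names = FALSE)
  cat("\nFull model (cue type x reward distribution):\n")
  print(x$glmm_full)
  cat("\nSplit model, social cue:\n")
  print(x$glmm_social)
  cat("\nSplit model, non-social cue:\n")
  print(x$glmm_nonsocial)
  invisible(x)
}

#' Write a choice analysis to JSON
#'
#' @param analysis A `choice_analysis` from [analyze_choices()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_analysis_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "choice_analysis"))
  strip <- function(g) g[setdiff(names(g), "fit")]
  out <- list(
    chance_level = analysis$p0,
    confidence = analysis$confidence,
    groups = analysis$groups,
    glmm_full = strip(unclass(analysis$glmm_full)),
    glmm_social = strip(unclass(analysis$glmm_social)),
    glmm_nonsocial = strip(unclass(analysis$glmm_nonsocial)),
    first_k = analysis$first_k
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
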