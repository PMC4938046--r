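test_that("group proportions count first landings on cued flowers", {
  bees <- make_bee_choices(
    bee_id = sprintf("b%02d", 1:20),
    colony = rep(c("c1", "c2"), 10),
    cue_type = rep(c("social", "nonsocial"), each = 10),
    distribution = rep(c("high_variance", "no_variance"), 10),
    landings = lapply(c(rep(1L, 8), rep(0L, 12)), function(v) v)
  )
  gp <- group_proportion(bees, "social", "high_variance")
  expect_equal(gp$n, 5L)
  expect_equal(gp$k, sum(bees$first_choice_cued[
    bees$cue_type == "social" & bees$distribution == "high_variance"]))
  expect_equal(gp$proportion, gp$k / gp$n)

  none <- bees[bees$cue_type == "social", , drop = FALSE]
  none$first_choice_cued <- 0L
  expect_equal(group_proportion(none, "social", "no_variance")$proportion, 0)
  expect_error(group_proportion(bees[0, ], "social", "no_variance"),
               "no records")
})

test_that("exact binomial p-values match closed forms and full enumeration", {
  # all successes, one-sided: p = p0^n
  expect_equal(exact_binomial_test(16, 16, alternative = "greater")$p_value,
               (1 / 3)^16)
  expect_equal((1 / 3)^16, 2.3230573125418753e-08)

  # observing exactly the null proportion is as probable as it gets
  expect_gte(exact_binomial_test(4, 12)$p_value, 0.99)

  # point-probability two-sided rule vs enumeration, frozen external value
  expect_equal(exact_binomial_test(12, 16)$p_value, 0.0007924645410274116,
               tolerance = 1e-12)
  expect_equal(exact_binomial_test(12, 16)$p_value, enum_binom_p(12, 16, 1 / 3))

  # one-sided p is non-increasing in k
  p_seq <- vapply(0:20, function(k)
    exact_binomial_test(k, 20, alternative = "greater")$p_value, numeric(1))
  expect_true(all(diff(p_seq) <= 1e-12))

  expect_error(exact_binomial_test(5, 4), "k and n")
  expect_error(exact_binomial_test(1, 4, p0 = 0), "strictly between")
})

test_that("adjusted-Wald intervals follow the Agresti-Coull formula", {
  # symmetry around 1/2
  ci <- adjusted_wald_interval(8, 16)
  expect_equal(ci$point, 0.5)
  expect_equal(ci$upper - 0.5, 0.5 - ci$lower)

  # clamping at the parameter boundary
  ci0 <- adjusted_wald_interval(0, 10)
  expect_equal(ci0$lower, 0)
  expect_gt(ci0$point, 0)

  # frozen external evaluation of the formula (90%, k = 12, n = 16)
  ci <- adjusted_wald_interval(12, 16, confidence = 0.90)
  expect_equal(ci$point, 0.7138403521830976, tolerance = 1e-12)
  expect_equal(ci$lower, 0.5419518468854213, tolerance = 1e-12)
  expect_equal(ci$upper, 0.8857288574807739, tolerance = 1e-12)

  # width shrinks with n at fixed k/n; bounds always inside [0, 1]
  widths <- vapply(c(8, 16, 64, 256), function(n) {
    ci <- adjusted_wald_interval(n / 2, n)
    expect_gte(ci$lower, 0); expect_lte(ci$upper, 1)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(adjusted_wald_interval(3, 0), "n >= 1")
})

test_that("the mixed logit recovers a null design and flags separation", {
  cfg <- generator_config(group_sizes = c(social_high = 1000, social_none = 1000,
                                          nonsocial_high = 1000, nonsocial_none = 1000),
                          colony_sd = 0, parameterization = "split",
                          dist_effect_social = 0, dist_effect_nonsocial = 0,
                          n_landings_per_bee = 1)
  bees <- generate_choice_dataset(cfg, seed = 77)
  fit <- suppressWarnings(fit_choice_glmm(bees))  # sd ~ 0: singular-fit note
  slopes <- fit$coefficients[-1]
  expect_true(all(abs(slopes) < 3 * fit$standard_errors[-1]))
  expect_false(fit$separation_suspected)

  # perfectly separated split data is flagged, not silently reported
  sep <- make_bee_choices(
    bee_id = sprintf("s%02d", 1:20),
    colony = rep(c("c1", "c2"), 10),
    cue_type = "social",
    distribution = rep(c("high_variance", "no_variance"), each = 10),
    landings = lapply(rep(c(1L, 0L), each = 10), function(v) v)
  )
  fit_sep <- suppressWarnings(fit_choice_glmm(sep, model = "distribution_only"))
  expect_true(fit_sep$separation_suspected)
})

test_that("a single colony falls back to plain logistic regression", {
  cfg <- generator_config(n_colonies = 1, colony_sd = 0)
  bees <- generate_choice_dataset(cfg, seed = 5)
  expect_warning(fit <- fit_choice_glmm(bees), "single colony")
  expect_equal(fit$random_intercept_sd, 0)

  ref <- stats::glm(first_choice_cued ~ cue * dist,
                    family = stats::binomial(),
                    data = data.frame(first_choice_cued = bees$first_choice_cued,
                                      cue = as.integer(bees$cue_type == "social"),
                                      dist = as.integer(bees$distribution == "high_variance")))
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$z_values),
               unname(fit$coefficients / fit$standard_errors))
})

test_that("the mixed logit matches a Gauss-Hermite + direct-optimisation oracle", {
  cfg <- generator_config(group_sizes = c(social_high = 10, social_none = 10,
                                          nonsocial_high = 10, nonsocial_none = 10))
  bees <- generate_choice_dataset(cfg, seed = 1)
  expect_equal(nrow(bees), 40)

  fit <- fit_choice_glmm(bees, model = "full_interaction", nAGQ = 25)
  oracle <- gh_glmm_oracle(bees, n_nodes = 64)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-3)
  expect_equal(unname(fit$coefficients), unname(oracle$coefficients),
               tolerance = 1e-3)
})

test_that("first-k summaries average per-bee landing proportions", {
  bees <- make_bee_choices(
    bee_id = c("b1", "b2", "b3", "b4"),
    colony = c("c1", "c2", "c1", "c2"),
    cue_type = c("social", "social", "nonsocial", "nonsocial"),
    distribution = c("high_variance", "high_variance",
                     "no_variance", "no_variance"),
    landings = list(c(1L, 0L, 1L, 0L), c(1L, 1L), c(0L, 0L, 0L, 0L, 1L),
                    c(1L))
  )
  s4 <- first_k_summary(bees, k = 4)
  expect_equal(s4$mean_proportion[s4$cue_type == "social" &
                                    s4$distribution == "high_variance"],
               mean(c(0.5, 1)))  # short sequences keep their own length
  expect_equal(s4$mean_proportion[s4$cue_type == "nonsocial" &
                                    s4$distribution == "no_variance"],
               mean(c(0, 1)))
  expect_error(first_k_summary(bees, k = 0), ">= 1")

  # k = 1 reduces exactly to the first-choice group proportion
  gen <- generate_choice_dataset(generator_config(), seed = 8)
  s1 <- first_k_summary(gen, k = 1)
  for (i in seq_len(nrow(s1))) {
    gp <- group_proportion(gen, s1$cue_type[i], s1$distribution[i])
    expect_equal(s1$mean_proportion[i], gp$proportion)
  }
})

test_that("the full pipeline orders groups as designed and exports JSON", {
  bees <- generate_choice_dataset(generator_config(), seed = 42)
  an <- analyze_choices(bees, nAGQ = 10)
  g <- an$groups
  top <- g[g$cue_type == "social" & g$distribution == "high_variance", ]
  expect_equal(top$n, 16)
  expect_true(all(top$proportion >= g$proportion))
  expect_true(top$lower <= top$point_adj & top$point_adj <= top$upper)

  # high-variance ordering is preserved when averaging the first 4 landings
  fk <- an$first_k[an$first_k$k == 4, ]
  expect_gt(fk$mean_proportion[fk$cue_type == "social" &
                                 fk$distribution == "high_variance"],
            max(fk$mean_proportion[!(fk$cue_type == "social" &
                                       fk$distribution == "high_variance")]))

  path <- withr::local_tempfile(fileext = ".json")
  write_analysis_json(an, path)
  parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(parsed$chance_level, 1 / 3)
  expect_equal(nrow(parsed$groups), 4)
})

test_that("arena worked examples: chance level and cue reward advantage", {
  expect_identical(chance_level(), 1 / 3)
  expect_identical(chance_level(4L, 12L), 4 / 12)
  expect_identical(cue_reward_advantage(), 3)
  expect_identical(cue_reward_advantage(2, 4, 2, 12), (2 / 4) / (2 / 12))
})
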