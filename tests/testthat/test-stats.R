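# Mixed models, pairwise contrasts, Fisher Omnibus, Cohen's kappa, and
# backward elimination.

sim_grouped <- function(seed, n = 200, n_ind = 20, effect = 2,
                        re_sd = 0.7, noise_sd = 1) {
  withr::with_seed(seed, {
    ind <- sample(sprintf("i%02d", seq_len(n_ind)), n, replace = TRUE)
    age <- factor(sample(c("adult", "pup"), n, replace = TRUE))
    b <- rnorm(n_ind, 0, re_sd)
    tibble::tibble(
      individual = ind, age_group = age,
      y = 1 + effect * (age == "pup") + b[match(ind, sprintf("i%02d",
                                                             seq_len(n_ind)))] +
        rnorm(n, 0, noise_sd))
  })
}

test_that("the mixed model recovers a simulated fixed effect", {
  d <- sim_grouped(1, effect = 2)
  fit <- fit_lme(y ~ age_group + (1 | individual), d)
  est <- lme4::fixef(fit$model)[["age_grouppup"]]
  se <- sqrt(diag(as.matrix(vcov(fit$model))))[2]
  expect_lt(abs(est - 2), 3 * se)
  expect_lt(fit$effects$p_value[fit$effects$term == "age_group"], 0.001)

  # constant response: no effect, p ~ 1
  dc <- d
  dc$y <- 5
  fc <- suppressWarnings(fit_lme(y ~ age_group + (1 | individual), dc))
  expect_lt(abs(lme4::fixef(fc$model)[["age_grouppup"]]), 1e-8)
  expect_gt(fc$effects$p_value[1], 0.99)

  # zero random-effect variance: estimates equal ordinary least squares
  dz <- sim_grouped(2, re_sd = 0)
  fz <- suppressWarnings(fit_lme(y ~ age_group + (1 | individual), dz))
  ols <- coef(lm(y ~ age_group, dz))
  expect_lt(max(abs(lme4::fixef(fz$model) - ols)), 1e-3)
  expect_true(fz$singular)
  expect_warning(fit_lme(y ~ age_group + (1 | individual), dz), "singular")
})

test_that("pairwise least-squares means use Tukey adjustment", {
  d <- withr::with_seed(3, tibble::tibble(
    g = factor(sample(c("a", "b", "c"), 150, replace = TRUE)),
    ind = sample(sprintf("i%d", 1:15), 150, replace = TRUE)))
  d$y <- withr::with_seed(4, rnorm(150) + 2 * (d$g == "c"))
  fit <- fit_lme(y ~ g + (1 | ind), d)
  cmp <- pairwise_lsmeans(fit, "g")
  expect_equal(nrow(cmp), 3)                    # C(3, 2)
  un <- summary(pairs(emmeans::emmeans(fit$model, "g", data = d,
                                       lmer.df = "satterthwaite"),
                      adjust = "none"))
  expect_true(all(cmp$p_value >= un$p.value - 1e-12))
  expect_error(pairwise_lsmeans(fit, "missing_factor"), "not in model")

  # type-I control: equal group means rarely yield significant contrasts
  hits <- vapply(1:30, function(s) {
    dn <- withr::with_seed(100 + s, {
      d <- tibble::tibble(
        g = factor(rep(c("a", "b", "c"), length.out = 120)),
        ind = sample(rep(sprintf("i%d", 1:10), length.out = 120)))
      b <- rnorm(10, 0, 0.5)
      d$y <- b[match(d$ind, sprintf("i%d", 1:10))] + rnorm(120)
      d
    })
    fitn <- suppressWarnings(fit_lme(y ~ g + (1 | ind), dn))
    any(pairwise_lsmeans(fitn, "g")$p_value < 0.05)
  }, TRUE)
  expect_gte(mean(!hits), 0.9)
})

test_that("Fisher Omnibus combines p-values as -2 sum log p on 2k df", {
  expect_equal(fisher_omnibus(rep(1, 4))$chisq, 0)
  one <- fisher_omnibus(0.05)
  expect_equal(one$chisq, -2 * log(0.05), tolerance = 1e-9)
  expect_equal(one$chisq, 5.991, tolerance = 1e-3)
  expect_equal(one$df, 2)
  expect_error(fisher_omnibus(c(0.5, 0)), "infinite")
  expect_error(fisher_omnibus(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Cohen's kappa matches the closed form and its limits", {
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a")), 1)
  # confusion counts [[40, 10], [10, 40]] -> kappa 0.6
  a <- rep(c("x", "x", "y", "y"), c(40, 10, 10, 40))
  b <- rep(c("x", "y", "x", "y"), c(40, 10, 10, 40))
  expect_equal(cohens_kappa(a, b), 0.6, tolerance = 1e-9)
  expect_error(cohens_kappa(c("a", "b"), c("a")), "length")
})

test_that("backward elimination retains a strong simulated interaction", {
  retained <- vapply(1:10, function(s) {
    d <- withr::with_seed(s, {
      d <- expand.grid(sex_composition = c("MM", "FF", "MF"),
                       housing_type = c("pair", "group"),
                       familiarity = c("fam", "unfam"),
                       rep = 1:8, stringsAsFactors = TRUE)
      d$individual_1 <- sample(rep(sprintf("A%02d", 1:12),
                                   length.out = nrow(d)))
      d$individual_2 <- sample(rep(sprintf("B%02d", 1:12),
                                   length.out = nrow(d)))
      d$rate_per_min <- 1 + 2.5 * (d$housing_type == "pair") *
        (d$familiarity == "fam") + rnorm(nrow(d))
      tibble::as_tibble(d)
    })
    be <- suppressWarnings(backward_eliminate(
      rate_per_min ~ sex_composition * housing_type +
        familiarity * housing_type + (1 | individual_1) +
        (1 | individual_2), d))
    labs <- attr(stats::terms(lme4::nobars(be$final$formula)), "term.labels")
    any(grepl("housing_type:familiarity|familiarity:housing_type", labs))
  }, TRUE)
  expect_gte(mean(retained), 0.9)
})

test_that("the elimination log never exceeds the interaction count", {
  d <- sim_grouped(9, n = 120, n_ind = 12)
  d$housing_type <- factor(rep(c("pair", "group"), 60))
  d$familiarity <- factor(rep(c("fam", "unfam"), each = 60))
  be <- suppressWarnings(backward_eliminate(
    y ~ age_group * housing_type + familiarity * housing_type +
      (1 | individual), d))
  expect_lte(nrow(be$log), 2)
  expect_true(be$stopped_because %in%
                c("only main terms remain",
                  "remaining interaction terms are significant",
                  "model comparison significant; drop reverted"))
})
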