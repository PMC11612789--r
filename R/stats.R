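# Statistical layer: linear mixed models (ML), Tukey-adjusted least-squares
# means, Fisher Omnibus combination, Cohen's kappa, and backward stepwise
# elimination of interaction terms.

#' Fit a linear mixed-effects model by maximum likelihood
#'
#' Thin wrapper around \pkg{lme4} used throughout the analysis: models are
#' fitted by ML (not REML, matching the model-comparison workflow), random
#' intercepts are written lme4-style in the formula (e.g.
#' `(1 | individual)`, or two crossed intercepts
#' `(1 | individual_1) + (1 | individual_2)` for dyads), and per-term
#' chi-square Wald tests (Type II) are attached.
#'
#' @param formula lmer formula with fixed terms and random intercepts.
#' @param data model data.
#' @return list of class `lme_fit`: `model`, `effects` (tibble with `term`,
#'   `statistic`, `df`, `den_df`, `p_value`, `test`), `singular` (logical).
#'   Per-term tests are Type II F-tests with Satterthwaite denominator
#'   degrees of freedom; when those cannot be computed the Wald chi-square
#'   table is reported instead (`test` says which).
#' @export
fit_lme <- function(formula, data) {
  model <- tryCatch(
    suppressMessages(
      lmerTest::lmer(formula, data = data, REML = FALSE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) suppressMessages(
      # degenerate fits (e.g. zero residual variance) can break the
      # Satterthwaite machinery; plain lme4 still fits them
      lme4::lmer(formula, data = data, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))))
  singular <- lme4::isSingular(model)
  if (singular) {
    warning("singular random-effect fit (a variance component is zero)",
            call. = FALSE)
  }
  effects <- tryCatch({
    if (!inherits(model, "lmerModLmerTest")) stop("no Satterthwaite table")
    aov <- suppressWarnings(stats::anova(model, type = 2))
    if (!"Pr(>F)" %in% colnames(aov)) stop("no Satterthwaite table")
    tibble::tibble(term = rownames(aov), statistic = aov$`F value`,
                   df = aov$NumDF, den_df = aov$DenDF,
                   p_value = aov$`Pr(>F)`, test = "F")
  }, error = function(e) tryCatch({
    aov <- suppressWarnings(car::Anova(model, type = "II"))
    tibble::tibble(term = rownames(aov), statistic = aov$Chisq,
                   df = aov$Df, den_df = NA_real_,
                   p_value = aov$`Pr(>Chisq)`, test = "Chisq")
  }, error = function(e2) {
    labs <- attr(stats::terms(lme4::nobars(formula)), "term.labels")
    tibble::tibble(term = labs, statistic = NA_real_, df = NA_real_,
                   den_df = NA_real_, p_value = NA_real_, test = "none")
  }))
  # a constant response carries no evidence for any effect: F = 0, p = 1
  if (stats::var(stats::model.frame(model)[[1]]) < 1e-300) {
    effects$statistic <- 0
    effects$p_value <- 1
  }
  structure(list(model = model, effects = effects, singular = singular,
                 formula = formula, data = data), class = "lme_fit")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat("Linear mixed model (ML):",
      deparse(x$formula), "\n")
  if (x$singular) cat("  note: singular random-effect fit\n")
  print(as.data.frame(x$effects), row.names = FALSE)
  invisible(x)
}

#' Tukey-adjusted pairwise least-squares means comparisons
#'
#' All pairwise contrasts between the levels of `factor` on the model's
#' least-squares (estimated marginal) means, with Tukey-family adjustment.
#'
#' @param fit an [fit_lme()] result or an lmerMod.
#' @param factor name of a fixed factor with at least two levels.
#' @return tibble with `contrast`, `estimate`, `se`, `df`, `t_ratio`,
#'   `p_value`.
#' @export
pairwise_lsmeans <- function(fit, factor) {
  model <- if (inherits(fit, "lme_fit")) fit$model else fit
  mf <- stats::model.frame(model)
  if (!factor %in% names(mf)) stop("factor not in model: ", factor)
  if (length(unique(mf[[factor]])) < 2) {
    stop("factor ", factor, " has fewer than 2 levels")
  }
  dat <- if (inherits(fit, "lme_fit")) fit$data else mf
  em <- emmeans::emmeans(model, specs = factor, data = dat,
                         lmer.df = "satterthwaite")
  cmp <- summary(graphics::pairs(em, adjust = "tukey"))
  tibble::tibble(contrast = as.character(cmp$contrast),
                 estimate = cmp$estimate, se = cmp$SE, df = cmp$df,
                 t_ratio = cmp$t.ratio, p_value = cmp$p.value)
}

#' Fisher Omnibus combination of p-values
#'
#' Combines k independent p-values into chi-square = -2 * sum(ln p) on
#' 2k degrees of freedom; used to control for multiple testing across the
#' per-parameter age comparisons of one call type.
#'
#' @param p_values numeric vector of p-values in (0, 1\].
#' @return list with `chisq`, `df`, `p_value`.
#' @export
fisher_omnibus <- function(p_values) {
  if (length(p_values) == 0) stop("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]; p = 0 gives an infinite statistic")
  }
  chisq <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(chisq = chisq, df = df,
       p_value = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Cohen's kappa agreement between two classifications
#'
#' kappa = (p_o - p_e) / (1 - p_e), with observed agreement p_o and chance
#' agreement p_e from the marginal products; used to compare the manual and
#' the statistical call-type classification.
#'
#' @param labels_a,labels_b equal-length label vectors over a common
#'   category set.
#' @return numeric kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label sequences differ in length (", length(labels_a), " vs ",
         length(labels_b), ")")
  }
  lev <- union(unique(as.character(labels_a)), unique(as.character(labels_b)))
  a <- factor(as.character(labels_a), levels = lev)
  b <- factor(as.character(labels_b), levels = lev)
  tab <- table(a, b)
  n <- length(a)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) return(as.numeric(po > 1 - 1e-12))
  (po - pe) / (1 - pe)
}

#' Backward stepwise elimination of interaction terms
#'
#' Starting from the full model, repeatedly removes the highest-level
#' interaction term with the highest non-significant p-value, refitting
#' after each drop and comparing the reduced model to the previous one by a
#' likelihood-based test of the nested ML fits. Elimination stops when (1)
#' only main terms remain, (2) all remaining interaction terms are
#' significant, or (3) the model comparison reveals a significant
#' difference, in which case the drop is reverted. When the final model
#' retains a significant interaction, the data are split along the levels of
#' one interacting factor to dissolve the term, and the per-level re-fits
#' are returned alongside.
#'
#' @param formula full lmer formula including the interaction terms.
#' @param data model data.
#' @param alpha significance level (default 0.05).
#' @param split_data whether to perform the data-splitting step when a
#'   significant interaction is retained.
#' @return list of class `backward_elimination`: `final` (an `lme_fit`),
#'   `log` (tibble of elimination steps), `stopped_because`, and optionally
#'   `split_models`.
#' @export
backward_eliminate <- function(formula, data, alpha = 0.05,
                               split_data = TRUE) {
  current <- fit_lme(formula, data)
  log <- tibble::tibble(step = integer(), dropped = character(),
                        term_p = numeric(), comparison_p = numeric())
  step <- 0
  reason <- NULL
  repeat {
    eff <- current$effects
    tt <- stats::terms(lme4::nobars(current$formula))
    ord <- attr(tt, "order")
    labs <- attr(tt, "term.labels")
    inter <- labs[ord == max(ord) & ord > 1]
    if (length(inter) == 0) { reason <- "only main terms remain"; break }
    p_int <- eff$p_value[match(inter, eff$term)]
    nonsig <- which(!is.na(p_int) & p_int >= alpha)
    if (length(nonsig) == 0) {
      reason <- "remaining interaction terms are significant"
      break
    }
    drop_term <- inter[nonsig[which.max(p_int[nonsig])]]
    reduced_formula <- stats::update(current$formula,
                                     paste(". ~ . -", drop_term))
    reduced <- fit_lme(reduced_formula, data)
    # previous vs reduced model differ exactly by drop_term's coefficients:
    # the Wald comparison is the joint Wald test of those coefficients
    cmp_p <- wald_term_test(current$model, drop_term)
    step <- step + 1
    log <- dplyr::bind_rows(log, tibble::tibble(
      step = step, dropped = drop_term,
      term_p = p_int[nonsig[which.max(p_int[nonsig])]],
      comparison_p = cmp_p))
    if (!is.na(cmp_p) && cmp_p < alpha) {
      log$dropped[step] <- paste0(drop_term, " (reverted)")
      reason <- "model comparison significant; drop reverted"
      break
    }
    current <- reduced
  }
  out <- list(final = current, log = log, stopped_because = reason)
  if (split_data && reason == "remaining interaction terms are significant") {
    out$split_models <- split_interaction(current, data, alpha)
  }
  class(out) <- "backward_elimination"
  out
}

# Joint Wald chi-square test that all fixed-effect coefficients belonging to
# `term` are zero, from the fitted model's coefficient covariance.
wald_term_test <- function(model, term) {
  asg <- attr(stats::model.matrix(model), "assign")
  labs <- attr(stats::terms(model), "term.labels")
  idx <- which(asg == match(term, labs))
  if (length(idx) == 0) return(NA_real_)
  b <- lme4::fixef(model)[idx]
  V <- as.matrix(stats::vcov(model))[idx, idx, drop = FALSE]
  w <- tryCatch(drop(t(b) %*% solve(V, b)), error = function(e) NA_real_)
  if (!is.finite(w)) return(NA_real_)
  stats::pchisq(w, df = length(b), lower.tail = FALSE)
}

# Dissolve a retained significant interaction by splitting the data along
# the interacting factor with the fewest levels and refitting without the
# interaction in each subset.
split_interaction <- function(fit, data, alpha) {
  tt <- stats::terms(lme4::nobars(fit$formula))
  labs <- attr(tt, "term.labels")
  ord <- attr(tt, "order")
  inter <- labs[ord > 1]
  p <- fit$effects$p_value[match(inter, fit$effects$term)]
  sig <- inter[!is.na(p) & p < alpha]
  if (length(sig) == 0) return(NULL)
  vars <- strsplit(sig[1], ":")[[1]]
  nlev <- vapply(vars, function(v) length(unique(data[[v]])), 0)
  split_var <- vars[which.min(nlev)]
  other <- setdiff(vars, split_var)
  models <- lapply(split(data, data[[split_var]]), function(d) {
    f <- stats::update(fit$formula, paste(". ~ . -", sig[1], "-", split_var))
    tryCatch(fit_lme(f, d), error = function(e) NULL)
  })
  list(interaction = sig[1], split_by = split_var, models = models)
}

#' @export
print.backward_elimination <- function(x, ...) {
  cat("Backward elimination:", x$stopped_because, "\n")
  if (nrow(x$log) > 0) print(as.data.frame(x$log), row.names = FALSE)
  cat("Final model terms:\n")
  print(as.data.frame(x$final$effects), row.names = FALSE)
  invisible(x)
}
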