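#' @importFrom lme4 glmer lmer glmerControl lmerControl fixef VarCorr
NULL

wald_tidy <- function(fit) {
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - 1.96 * se),
             ci_hi = unname(est + 1.96 * se),
             p_value = unname(2 * stats::pnorm(-abs(z))))
}

# Nakagawa-style variance-decomposition pseudo-R2 for mixed models.
# Marginal R2 = fixed-effect variance over total; conditional adds the
# random-effect variance. Distribution-specific residual variance: sigma^2
# (gaussian), pi^2/3 (binomial logit, latent scale), lognormal
# approximation log(1 + 1/lambda) (poisson log link).
r2_mixed <- function(fit) {
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  vc <- lme4::VarCorr(fit)
  var_r <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  fam <- stats::family(fit)
  var_e <- if (fam$family == "gaussian") {
    stats::sigma(fit)^2
  } else if (fam$family == "binomial") {
    pi^2 / 3
  } else if (fam$family == "poisson") {
    lambda <- exp(var_f / 2 + mean(as.numeric(X %*% lme4::fixef(fit))) +
                    var_r / 2)
    log1p(1 / lambda)
  } else NA_real_
  tot <- var_f + var_r + var_e
  c(r2_marginal = var_f / tot, r2_conditional = (var_f + var_r) / tot)
}

model_result <- function(coefficients, fit_stats, model, note = NULL) {
  structure(list(coefficients = coefficients, fit_stats = fit_stats,
                 model = model, note = note), class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  print(x$coefficients, digits = 3)
  if (length(x$fit_stats)) {
    cat("\n")
    print(round(unlist(x$fit_stats), 3))
  }
  invisible(x)
}

#' Poisson mixed model of agents on the profitable option
#'
#' Fits a Poisson mixed regression of the per-run, per-iteration count of
#' agents choosing the profitable option on bonus scheme and iteration,
#' with a run-level random intercept. The bonus scheme enters with
#' sum-to-zero (deviation) contrasts, so each scheme's coefficient reads
#' "this scheme versus the average of all schemes"; the deviation
#' coefficient of the level dropped by the coding is reconstructed (with a
#' delta-method standard error) so all three schemes are reported. The key
#' outputs are the `iteration` main effect (the pooled learning rate on the
#' log scale) and the scheme-by-iteration interactions (how each bonus
#' scheme speeds or slows learning).
#'
#' @param counts data frame with columns `run`, `iteration`, `bonus`
#'   (character or factor) and `count` (non-negative integers). Runs are
#'   treated as distinct between bonus schemes.
#' @return A `model_result`; coefficient terms are named
#'   `bonus_<kind>` and `bonus_<kind>:iteration`.
#' @export
fit_profitable_count_model <- function(counts) {
  need <- c("run", "iteration", "bonus", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("fit_profitable_count_model: missing columns: ",
         paste(miss, collapse = ", "))
  if (any(counts$count != round(counts$count)) || any(counts$count < 0))
    stop("fit_profitable_count_model: counts must be non-negative integers")
  lv <- intersect(c("none", "additive", "multiplicative"),
                  unique(as.character(counts$bonus)))
  if (length(lv) < 2L) lv <- unique(as.character(counts$bonus))
  d <- data.frame(count = as.integer(counts$count),
                  iteration = as.numeric(counts$iteration),
                  bonus = factor(as.character(counts$bonus), levels = lv),
                  run = interaction(counts$bonus, counts$run, drop = TRUE))
  if (length(lv) > 1L) {
    stats::contrasts(d$bonus) <- stats::contr.sum(length(lv))
    fit <- lme4::glmer(count ~ bonus * iteration + (1 | run),
                       data = d, family = stats::poisson,
                       control = lme4::glmerControl(optimizer = "bobyqa"))
  } else {
    # single scheme: no contrast terms to estimate
    fit <- lme4::glmer(count ~ iteration + (1 | run),
                       data = d, family = stats::poisson,
                       control = lme4::glmerControl(optimizer = "bobyqa"))
    return(model_result(wald_tidy(fit), as.list(r2_mixed(fit)), fit))
  }
  tidy <- wald_tidy(fit)
  # rename bonus1.. to the level names and reconstruct the dropped level
  nlev <- length(lv)
  for (j in seq_len(nlev - 1L)) {
    tidy$term <- sub(paste0("^bonus", j, ":iteration$"),
                     paste0("bonus_", lv[j], ":iteration"), tidy$term)
    tidy$term <- sub(paste0("^bonus", j, "$"),
                     paste0("bonus_", lv[j]), tidy$term)
  }
  V <- as.matrix(stats::vcov(fit))
  est <- lme4::fixef(fit)
  for (suffix in c("", ":iteration")) {
    nm <- paste0("bonus", seq_len(nlev - 1L), suffix)
    if (!all(nm %in% names(est))) next
    cvec <- stats::setNames(numeric(length(est)), names(est))
    cvec[nm] <- -1
    e <- sum(cvec * est)
    s <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tidy <- rbind(tidy, data.frame(
      term = paste0("bonus_", lv[nlev], suffix), estimate = e, se = s,
      ci_lo = e - 1.96 * s, ci_hi = e + 1.96 * s,
      p_value = 2 * stats::pnorm(-abs(e / s))))
  }
  model_result(tidy, as.list(r2_mixed(fit)), fit)
}

#' Logistic mixed model of the learning curve
#'
#' Fits the probability of choosing the profitable option as a function of
#' round via a logistic mixed model. Without a condition the formula is
#' `profitable ~ -1 + round` with random effects for round (slope at the
#' player level), player and group; with a condition, fixed effects for
#' condition, round and their interaction are estimated.
#'
#' If the outcome is constant the logistic likelihood has no interior
#' maximum (complete separation); the function then short-circuits and
#' returns the degenerate fitted probability with a note instead of
#' divergent coefficients.
#'
#' @param choices data frame with columns `player`, `group`, `round` and
#'   `profitable` (0/1); optionally `condition`.
#' @param condition optional name of the condition column to include.
#' @param random `"slope"` (random round slope at player level plus player
#'   and group intercepts) or `"intercepts"` only.
#' @return A `model_result` with an additional `fitted_by_round` data frame.
#' @export
fit_learning_curve <- function(choices, condition = NULL,
                               random = c("slope", "intercepts")) {
  random <- match.arg(random)
  if (!all(choices$profitable %in% c(0, 1)))
    stop("fit_learning_curve: 'profitable' must be binary 0/1")
  if (length(unique(choices$profitable)) == 1L) {
    p <- choices$profitable[1]
    fbr <- data.frame(round = sort(unique(choices$round)), fitted = p)
    return(model_result(
      data.frame(term = "round", estimate = NA_real_, se = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p_value = NA_real_),
      list(), NULL, note = paste0("constant outcome (", p,
                                  "): separation guard, no model fitted")) |>
        (\(m) {m$fitted_by_round <- fbr; m})())
  }
  re <- if (random == "slope")
    "(1 + round || player) + (1 | group)" else
      "(1 | player) + (1 | group)"
  fx <- if (is.null(condition)) "-1 + round" else
    paste0(condition, " * round")
  form <- stats::as.formula(paste("profitable ~", fx, "+", re))
  fit <- tryCatch(
    lme4::glmer(form, data = choices, family = stats::binomial,
                control = lme4::glmerControl(optimizer = "bobyqa")),
    error = function(e) {
      form2 <- stats::as.formula(paste("profitable ~", fx,
                                       "+ (1 | player) + (1 | group)"))
      lme4::glmer(form2, data = choices, family = stats::binomial,
                  control = lme4::glmerControl(optimizer = "bobyqa"))
    })
  out <- model_result(wald_tidy(fit), as.list(r2_mixed(fit)), fit)
  out$fitted_by_round <- stats::aggregate(
    list(fitted = stats::fitted(fit)), by = list(round = choices$round), mean)
  out
}

#' Exploration length versus decision quality
#'
#' Fits the quadratic model `choice_score ~ half_change_round +
#' half_change_round^2` with a group random intercept, the linear-only
#' companion model, and compares them with a likelihood-ratio test (both
#' fitted by maximum likelihood). An inverted-U relation between
#' exploration length and decision quality shows up as a negative quadratic
#' coefficient; a U-shape as a positive one.
#'
#' @param scores data frame with columns `player`, `group`, `choice_score`
#'   and `half_change_round`.
#' @return A list of class `exploration_quality` with `quadratic` and
#'   `linear` `model_result`s and `lrt_chisq` / `lrt_p`.
#' @export
fit_exploration_quality <- function(scores) {
  need <- c("group", "choice_score", "half_change_round")
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stop("fit_exploration_quality: missing columns: ",
         paste(miss, collapse = ", "))
  use_lm <- length(unique(scores$group)) < 2L
  if (use_lm)
    warning("fit_exploration_quality: fewer than 2 groups; ",
            "dropping the group random effect")
  fit_one <- function(form_mixed, form_lm) {
    if (use_lm) return(stats::lm(form_lm, data = scores))
    tryCatch(
      lme4::lmer(form_mixed, data = scores, REML = FALSE,
                 control = lme4::lmerControl(optimizer = "bobyqa",
                                             calc.derivs = FALSE)),
      error = function(e) stats::lm(form_lm, data = scores))
  }
  quad <- fit_one(
    choice_score ~ half_change_round + I(half_change_round^2) + (1 | group),
    choice_score ~ half_change_round + I(half_change_round^2))
  lin <- fit_one(choice_score ~ half_change_round + (1 | group),
                 choice_score ~ half_change_round)
  tidy_any <- function(fit) {
    if (inherits(fit, "merMod")) return(wald_tidy(fit))
    sm <- summary(fit)$coefficients
    est <- sm[, 1]; se <- sm[, 2]
    data.frame(term = rownames(sm), estimate = unname(est), se = unname(se),
               ci_lo = unname(est - 1.96 * se),
               ci_hi = unname(est + 1.96 * se), p_value = unname(sm[, 4]))
  }
  stats_any <- function(fit)
    if (inherits(fit, "merMod")) as.list(r2_mixed(fit)) else
      list(r2 = summary(fit)$r.squared)
  chisq <- max(0, 2 * (as.numeric(stats::logLik(quad)) -
                         as.numeric(stats::logLik(lin))))
  structure(list(quadratic = model_result(tidy_any(quad), stats_any(quad), quad),
                 linear = model_result(tidy_any(lin), stats_any(lin), lin),
                 lrt_chisq = chisq,
                 lrt_p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE)),
            class = "exploration_quality")
}

#' Mediation analysis by product of coefficients
#'
#' Decomposes the effect of a condition `x` on an outcome `y` into the
#' direct effect and the indirect effect through mediator `m`, using the
#' product-of-coefficients method on linear models: the a-path regresses
#' `m` on `x`, the b-path and direct effect come from regressing `y` on `x`
#' and `m`, and the indirect effect is `a * b` (for continuous outcomes
#' total = direct + indirect exactly). Binary outcomes are handled on the
#' linear-probability scale, an approximation adequate for effect
#' decomposition. Confidence intervals are percentile bootstrap over
#' cases. Following common reporting practice, the proportion mediated is
#' set to 0 when the indirect effect's bootstrap CI spans zero.
#'
#' @param x condition indicator (numeric, logical or 2-level factor).
#' @param m mediator (e.g. half-change round).
#' @param y outcome (e.g. choice score, or a 0/1 profitable-choice rate).
#' @param n_boot bootstrap resamples (>= 100; default 1000).
#' @param seed integer seed for the bootstrap.
#' @param conf confidence level.
#' @return A list of class `mediation_result` with `total`, `direct`,
#'   `indirect` (each estimate + CI) and `proportion_mediated`.
#' @export
mediate <- function(x, m, y, n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (n_boot < 100L)
    stop("mediate: n_boot must be at least 100")
  if (is.factor(x)) x <- as.numeric(x) - 1
  x <- as.numeric(x); m <- as.numeric(m); y <- as.numeric(y)
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  paths <- function(idx) {
    xi <- x[idx]; mi <- m[idx]; yi <- y[idx]
    Xa <- cbind(1, xi)
    a <- stats::.lm.fit(Xa, mi)$coefficients[2L]
    Xb <- cbind(1, xi, mi)
    cb <- stats::.lm.fit(Xb, yi)$coefficients
    tot <- stats::.lm.fit(Xa, yi)$coefficients[2L]
    c(total = tot, direct = cb[2L], indirect = a * cb[3L])
  }
  est <- paths(seq_len(n))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boot <- t(vapply(seq_len(n_boot),
                   function(b) paths(sample.int(n, n, replace = TRUE)),
                   numeric(3)))
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE)
  effect <- function(k) list(estimate = unname(est[k]),
                             ci = unname(ci[, k]))
  ind <- effect("indirect")
  significant <- ind$ci[1] > 0 || ind$ci[2] < 0
  prop <- if (!significant || est["total"] == 0) 0 else
    unname(est["indirect"] / est["total"])
  structure(list(total = effect("total"), direct = effect("direct"),
                 indirect = ind, proportion_mediated = prop,
                 n_boot = n_boot), class = "mediation_result")
}

#' Two-group and contingency comparisons
#'
#' Thin wrappers around the standard tests used to compare behavioral
#' metrics between conditions, returning the statistic, p-value and an
#' effect size in one row: Welch's t-test with Cohen's d, the Wilcoxon
#' rank-sum test with continuity correction (rank-biserial effect size), or
#' a chi-squared test on a contingency table (Cramer's V).
#'
#' @param x numeric vector (first group), or a contingency table/matrix for
#'   `test = "chi_square"`.
#' @param y numeric vector (second group); ignored for `chi_square`.
#' @param test which test to run.
#' @param ... passed to the underlying test (e.g. `alternative`).
#' @return One-row data frame: `test`, `statistic`, `p_value`,
#'   `effect_size`.
#' @export
compare_groups <- function(x, y = NULL,
                           test = c("welch_t", "wilcoxon", "chi_square"),
                           ...) {
  test <- match.arg(test)
  if (test == "chi_square") {
    ht <- stats::chisq.test(x, ...)
    n <- sum(x)
    v <- sqrt(unname(ht$statistic) / (n * (min(dim(as.matrix(x))) - 1)))
    return(data.frame(test = test, statistic = unname(ht$statistic),
                      p_value = ht$p.value, effect_size = v))
  }
  if (length(x) < 2L || length(y) < 2L)
    stop("compare_groups: need at least 2 observations per group")
  if (test == "welch_t") {
    ht <- stats::t.test(x, y, ...)
    sp <- sqrt((stats::var(x) * (length(x) - 1) +
                  stats::var(y) * (length(y) - 1)) /
                 (length(x) + length(y) - 2))
    d <- if (sp == 0) 0 else (mean(x) - mean(y)) / sp
    data.frame(test = test, statistic = unname(ht$statistic),
               p_value = ht$p.value, effect_size = d)
  } else {
    ht <- stats::wilcox.test(x, y, correct = TRUE, exact = FALSE, ...)
    rb <- 2 * unname(ht$statistic) / (length(x) * length(y)) - 1
    data.frame(test = test, statistic = unname(ht$statistic),
               p_value = ht$p.value, effect_size = rb)
  }
}
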