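#' Specification of a nested linear mixed-effect model
#'
#' Encodes the repeated-measures design of a chewing study: random
#' intercepts nested as gape-cycle order within food type and food type
#' within subject, fixed terms as requested, fit by maximum likelihood.
#'
#' @param response response column name.
#' @param fixed character vector of fixed-term column names (may be empty
#'   for an intercept-only model).
#' @param subject,food,cycle column names holding the nesting identifiers.
#' @return object of class `lme_spec`.
#' @export
lme_spec <- function(response, fixed = character(0),
                     subject = "subject", food = "food", cycle = "cycle") {
  stopifnot(is.character(response), length(response) == 1L)
  structure(list(response = response, fixed = as.character(fixed),
                 subject = subject, food = food, cycle = cycle),
            class = "lme_spec")
}

#' Fit a nested linear mixed-effect model
#'
#' Fits `response ~ fixed + (1 | subject) + (1 | subject:food) +
#' (1 | subject:food:cycle)` by maximum likelihood with [lme4::lmer()].
#' Term significance is assessed with Type-II Wald chi-square tests;
#' marginal and conditional R-squared are computed from the variance of the
#' fixed-effect predictor, the summed random-intercept variances and the
#' residual variance (see [r2_marginal_conditional()]). Singular fits (a
#' variance component estimated at 0) raise a warning and keep the pinned
#' zero component.
#'
#' @param data data.frame with the response, fixed covariates and nesting
#'   identifier columns.
#' @param spec an [lme_spec()].
#' @return object of class `lme_result`: list with `fixed` (term, estimate,
#'   se, ci_lo, ci_hi), `anova` (chi-square term tests with p-values),
#'   `varcomp` (named variance components incl. `residual`), `r2m`, `r2c`,
#'   and the underlying `model`.
#' @export
fit_lme <- function(data, spec) {
  stopifnot(inherits(spec, "lme_spec"))
  need <- c(spec$response, spec$fixed, spec$subject, spec$food, spec$cycle)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0)
    stop("columns not found in data: ", paste(missing_cols, collapse = ", "))
  for (f in spec$fixed) {
    if (is.character(data[[f]]) || is.factor(data[[f]])) {
      data[[f]] <- droplevels(as.factor(data[[f]]))
      tab <- table(data[[f]])
      if (length(tab) < 2L)
        stop("fixed factor '", f, "' needs at least 2 observed groups")
      if (any(tab == 0L))
        stop("empty cell in fixed factor '", f, "': level '",
             names(tab)[tab == 0L][1], "'")
    }
  }
  data$.subj <- as.factor(data[[spec$subject]])
  data$.food <- interaction(data$.subj, as.factor(data[[spec$food]]),
                            drop = TRUE)
  data$.cyc <- interaction(data$.food, as.factor(data[[spec$cycle]]),
                           drop = TRUE)
  rhs <- if (length(spec$fixed) > 0) paste(spec$fixed, collapse = " + ")
         else "1"
  # with one row per cycle the cycle-level intercept is inseparable from the
  # residual; drop it (its variance is then absorbed by the residual)
  has_cyc <- nlevels(data$.cyc) < nrow(data)
  fml <- stats::as.formula(paste(
    spec$response, "~", rhs, "+ (1 | .subj) + (1 | .food)",
    if (has_cyc) "+ (1 | .cyc)" else ""))
  mod <- suppressMessages(
    lme4::lmer(fml, data = data, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)))
  if (lme4::isSingular(mod, tol = 1e-5))
    warning("singular fit: one or more variance components pinned at 0")
  vc <- lme4::VarCorr(mod)
  varcomp <- c(subject = as.numeric(vc$.subj),
               food_in_subject = as.numeric(vc$.food),
               cycle_in_food = if (has_cyc) as.numeric(vc$.cyc) else 0,
               residual = attr(vc, "sc")^2)
  beta <- lme4::fixef(mod)
  se <- sqrt(diag(as.matrix(stats::vcov(mod))))
  fixed_df <- data.frame(term = names(beta), estimate = as.numeric(beta),
                         se = as.numeric(se),
                         ci_lo = as.numeric(beta) - 1.96 * as.numeric(se),
                         ci_hi = as.numeric(beta) + 1.96 * as.numeric(se),
                         row.names = NULL)
  an <- NULL
  if (length(spec$fixed) > 0) {
    a <- car::Anova(mod, type = 2)
    an <- data.frame(term = rownames(a), chisq = a[["Chisq"]],
                     df = a[["Df"]], p = a[["Pr(>Chisq)"]],
                     row.names = NULL)
  }
  X <- stats::model.matrix(mod)
  var_fixed <- stats::var(as.numeric(X %*% beta))
  r2 <- r2_marginal_conditional(var_fixed, varcomp[1:3],
                                varcomp[["residual"]])
  structure(list(fixed = fixed_df, anova = an, varcomp = varcomp,
                 r2m = r2[["r2m"]], r2c = r2[["r2c"]], model = mod),
            class = "lme_result")
}

#' @export
print.lme_result <- function(x, ...) {
  cat("<lme_result> ML nested mixed model\n")
  cat(sprintf("  R2m = %.3f, R2c = %.3f\n", x$r2m, x$r2c))
  cat("  variance components:\n")
  for (nm in names(x$varcomp))
    cat(sprintf("    %-16s %.4g\n", nm, x$varcomp[[nm]]))
  if (!is.null(x$anova)) {
    cat("  term tests (Type-II Wald chi-square):\n")
    for (i in seq_len(nrow(x$anova)))
      cat(sprintf("    %-16s chisq=%.3f df=%d p=%.4g\n", x$anova$term[i],
                  x$anova$chisq[i], x$anova$df[i], x$anova$p[i]))
  }
  invisible(x)
}

#' Marginal and conditional R-squared for mixed models
#'
#' Variance-partition coefficients of determination: the marginal R2 is the
#' fixed-effect variance over the total (fixed + random + residual)
#' variance; the conditional R2 adds the random components to the
#' numerator. `r2m <= r2c <= 1` always, with equality of the two iff all
#' random components are zero.
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param var_random_components vector of random-intercept variances.
#' @param var_residual residual variance.
#' @return named numeric vector `c(r2m = , r2c = )`.
#' @export
r2_marginal_conditional <- function(var_fixed, var_random_components,
                                    var_residual) {
  v <- c(var_fixed, var_random_components, var_residual)
  if (any(!is.finite(v)) || any(v < 0))
    stop("all variance inputs must be finite and non-negative")
  denom <- var_fixed + sum(var_random_components) + var_residual
  if (denom == 0) stop("total variance is zero")
  c(r2m = var_fixed / denom,
    r2c = (var_fixed + sum(var_random_components)) / denom)
}

#' Reduced major axis (standardized major axis) regression
#'
#' The RMA line used for scaling relationships: slope
#' `sign(r) * sd(y) / sd(x)`, intercept through the means. Symmetric in x
#' and y up to inversion of the slope.
#'
#' @param x,y numeric vectors, n >= 3, each with positive SD.
#' @return object of class `rma_fit` with `slope`, `intercept`, `r`, `n`.
#' @export
rma_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance in x or y")
  r <- stats::cor(x, y)
  s <- if (r < 0) -sy / sx else sy / sx
  structure(list(slope = s, intercept = mean(y) - s * mean(x), r = r,
                 n = length(x)), class = "rma_fit")
}

#' @export
print.rma_fit <- function(x, ...) {
  cat(sprintf("<rma_fit> slope %.4g, intercept %.4g, r %.3f (n=%d)\n",
              x$slope, x$intercept, x$r, x$n))
  invisible(x)
}

#' Sequential Bonferroni (Holm step-down) adjustment
#'
#' Holm's step-down procedure — the standard referent of "sequential
#' Bonferroni": sort the p-values ascending, multiply the i-th smallest by
#' (m - i + 1), enforce monotonicity by running maxima, cap at 1, and
#' return in the input order.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same order.
#' @export
holm_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Timing offset between per-cycle events and phase transitions
#'
#' For paired per-cycle event and transition frames, computes the offset as
#' a percentage of cycle duration, its mean and standard error, and a
#' two-sided one-sample t-test against zero offset (descriptives only when
#' n < 3 or the offsets are constant).
#'
#' @param event_frames,transition_frames,cycle_lengths equal-length numeric
#'   vectors (frames).
#' @return list with `offsets_pct`, `mean_pct`, `sem_pct`, `p`, `n`.
#' @export
event_timing_offset <- function(event_frames, transition_frames,
                                cycle_lengths) {
  if (length(event_frames) != length(transition_frames) ||
      length(event_frames) != length(cycle_lengths))
    stop("event, transition and cycle-length vectors must be paired")
  off <- 100 * (event_frames - transition_frames) / cycle_lengths
  n <- sum(is.finite(off))
  off <- off[is.finite(off)]
  m <- mean(off)
  sem <- if (n > 1) stats::sd(off) / sqrt(n) else NA_real_
  p <- NA_real_
  if (n >= 3 && stats::sd(off) > 0)
    p <- stats::t.test(off, mu = 0)$p.value
  list(offsets_pct = off, mean_pct = m, sem_pct = sem, p = p, n = n)
}
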