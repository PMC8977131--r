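# Association statistics: robust bisquare regression with standardized
# effect sizes, the t-to-r conversion, fitted-line visualization values,
# Steiger's test for two dependent correlations, paired t tests and the
# mixed 2x2 ANOVA.

#' Robust least-squares regression (IRLS, bisquare)
#'
#' Iteratively reweighted least squares with the bisquare weight
#' function (tuning constant 4.685), following the conventions of the
#' classic robustfit implementation: scale from the median absolute
#' residual (excluding the p smallest) divided by 0.6745, residuals
#' adjusted for leverage before weighting. On exactly linear data the
#' estimate equals ordinary least squares and all weights are 1.
#' Coefficient t statistics use the weighted covariance with df = n - p;
#' standardized effect sizes come from [t_to_r()].
#'
#' @param y response vector.
#' @param X predictor matrix or data.frame (at most 2 predictors; the
#'   intercept is added internally).
#' @param tune bisquare tuning constant.
#' @param max_iter,tol IRLS iteration cap and coefficient tolerance.
#' @param cor_max predictors with absolute intercorrelation above this
#'   are refused as collinear.
#' @return object of class `robust_fit`: `coefficients`, `t`, `df`, `r`,
#'   `p`, `weights`, `sigma`, `converged`.
#' @export
robust_fit <- function(y, X, tune = 4.685, max_iter = 50, tol = 1e-8,
                       cor_max = 0.999) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  p <- ncol(X) + 1
  if (n <= p) stop("need more observations than coefficients")
  if (ncol(X) >= 2) {
    cc <- cor(X)
    if (any(abs(cc[upper.tri(cc)]) > cor_max))
      stop("predictors are collinear (|r| > ", cor_max, ")")
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  h <- pmin(diag(Xd %*% solve(crossprod(Xd)) %*% t(Xd)), 1 - 1e-8)
  b <- qr.coef(qr(Xd), y)
  w <- rep(1, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    r <- y - Xd %*% b
    s <- median(sort(abs(r))[-seq_len(p - 1)]) / 0.6745
    if (s < 1e-10 * max(abs(y), 1)) { w <- rep(1, n); converged <- TRUE; break }
    u <- r / (tune * s * sqrt(1 - h))
    w <- as.numeric((1 - u^2)^2 * (abs(u) < 1))
    b_new <- qr.coef(qr(Xd * sqrt(w)), y * sqrt(w))
    if (max(abs(b_new - b)) < tol * max(abs(b), 1)) {
      b <- b_new; converged <- TRUE; break
    }
    b <- b_new
  }
  r <- as.numeric(y - Xd %*% b)
  df <- n - p
  # Street-Carroll-Ruppert robust scale with the DuMouchel-O'Brien
  # small-sample correction (the robustfit convention); covariance is
  # sigma_r^2 (X'X)^-1
  s_mad <- median(sort(abs(r))[-seq_len(p - 1)]) / 0.6745
  if (s_mad > 1e-10 * max(abs(y), 1)) {
    u <- r / (s_mad * sqrt(1 - h))
    psi <- ifelse(abs(u) < tune, u * (1 - (u / tune)^2)^2, 0)
    dpsi <- ifelse(abs(u) < tune,
                   (1 - (u / tune)^2) * (1 - 5 * (u / tune)^2), 0)
    m1 <- mean(dpsi)
    K <- 1 + (p / n) * var(dpsi) / m1^2
    sigma_r <- K * s_mad * sqrt(sum(psi^2) / df) / abs(m1)
  } else {
    sigma_r <- sqrt(sum(r^2) / df)   # (near-)exact fit: classical scale
  }
  se <- sigma_r * sqrt(diag(solve(crossprod(Xd))))
  tval <- as.numeric(b) / ifelse(se > 0, se, Inf)
  sigma2 <- sigma_r^2
  structure(list(coefficients = setNames(as.numeric(b), colnames(Xd)),
                 t = setNames(tval, colnames(Xd)), df = df,
                 r = setNames(t_to_r(tval, df), colnames(Xd)),
                 p = setNames(2 * pt(-abs(tval), df), colnames(Xd)),
                 weights = w, sigma = sqrt(sigma2), converged = converged),
            class = "robust_fit")
}

#' @export
print.robust_fit <- function(x, ...) {
  tab <- data.frame(b = x$coefficients, t = x$t, df = x$df,
                    r = round(x$r, 2), p = signif(x$p, 3))
  print(tab)
  invisible(x)
}

#' Standardized effect size from a t statistic
#'
#' \deqn{r = sign(t) \sqrt{t^2 / (t^2 + df)}}
#' Strictly increasing in t for fixed df; approaches sign(t) as |t| grows
#' and 0 as df grows. Conventionally reported rounded to 2 decimals.
#'
#' @param t t statistic(s).
#' @param df residual degrees of freedom, >= 1.
#' @export
t_to_r <- function(t, df) {
  if (any(df < 1)) stop("df must be >= 1")
  sign(t) * sqrt(t^2 / (t^2 + df))
}

#' Fitted line for one predictor of a two-predictor regression
#'
#' Visualization values `y = b0 + b[i] * x + b[other] * mean(x_other)`:
#' the fitted response along predictor `i` with the other predictor held
#' at its mean.
#'
#' @param b0 intercept.
#' @param b length-2 coefficient vector.
#' @param i predictor index (1 or 2).
#' @param x values of predictor `i` at which to evaluate.
#' @param other_mean mean of the other predictor.
#' @export
fitted_line <- function(b0, b, i, x, other_mean) {
  stopifnot(length(b) == 2, i %in% 1:2)
  b0 + b[i] * x + b[3 - i] * other_mean
}

#' Compare two dependent correlations sharing a variable
#'
#' Steiger's Z1* for correlations r12 and r13 that share variable 1:
#' the difference of Fisher z values scaled by the covariance term
#' evaluated at the pooled correlation. Antisymmetric under swapping r12
#' and r13; zero when they are equal.
#'
#' @param r12,r13 the two dependent correlations (shared variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size, >= 4.
#' @return list with `z`, `p` (two-sided) and `method`.
#' @export
compare_dependent_corrs <- function(r12, r13, r23, n) {
  if (any(abs(c(r12, r13, r23)) >= 1)) stop("correlations must be in (-1, 1)")
  if (n < 4) stop("n must be >= 4")
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  s <- psi / (1 - rbar^2)^2
  z <- (atanh(r12) - atanh(r13)) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * pnorm(-abs(z)), method = "Steiger Z1* (pooled r)")
}

#' Paired t test
#'
#' Standard paired t on the differences (df = n - 1); zero-variance
#' differences are rejected as degenerate.
#'
#' @param x,y paired measurements.
#' @return list with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need n >= 2")
  d <- x - y
  if (sd(d) <= 1e-12 * (mean(abs(d)) + 1)) {
    if (all(d == 0)) return(list(t = 0, df = length(x) - 1, p = 1))
    stop("differences have zero variance")
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Mixed 2x2 ANOVA (one between-group, one repeated factor)
#'
#' F tests for Group, Block (pre vs post) and their interaction, from
#' the closed-form sums of squares of the two-level mixed design with
#' unweighted (Type III) main effects, as in common commercial ANOVA
#' implementations. The interaction F equals the squared two-sample t on
#' the within-subject differences; the Group F equals the squared
#' two-sample t on the subject means. All F tests have df = (1, N - 2).
#'
#' @param group factor/character with exactly 2 levels.
#' @param pre,post within-subject measurements (complete cases).
#' @return data.frame with columns `effect`, `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(group, pre, post) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("need exactly 2 groups")
  if (anyNA(pre) || anyNA(post)) stop("complete cases required")
  n <- table(group)
  if (any(n < 2)) stop("each group needs at least 2 subjects")
  d <- post - pre
  m <- (post + pre) / 2
  N <- length(d)
  pool_var <- function(v) {
    sum(tapply(v, group, function(x) (length(x) - 1) * var(x))) / (N - 2)
  }
  two_t2 <- function(v) {
    mu <- tapply(v, group, mean)
    num <- (mu[1] - mu[2])^2
    den <- pool_var(v) * sum(1 / n)
    if (den == 0) return(if (num == 0) 0 else Inf)
    num / den
  }
  F_group <- as.numeric(two_t2(m))
  F_int <- as.numeric(two_t2(d))
  mu_d <- tapply(d, group, mean)
  blk_num <- mean(mu_d)^2
  blk_den <- pool_var(d) / 4 * sum(1 / n)
  F_block <- if (blk_den == 0) { if (blk_num == 0) 0 else Inf } else
    as.numeric(blk_num / blk_den)
  Fs <- c(Group = F_group, Block = F_block, `Group:Block` = F_int)
  data.frame(effect = names(Fs), F = unname(Fs), df1 = 1, df2 = N - 2,
             p = unname(pf(Fs, 1, N - 2, lower.tail = FALSE)),
             stringsAsFactors = FALSE)
}

#' Association battery
#'
#' The regression battery linking brain measures to behavioral change:
#' for each outcome, a robust two-predictor regression on the given
#' predictors, reported tidily (one row per outcome-predictor pair).
#' Post hoc pairwise gates can be applied at the Bonferroni-corrected
#' alpha of 0.025 for two tests.
#'
#' @param data per-subject data.frame.
#' @param outcomes names of outcome columns.
#' @param predictors names of the (two) predictor columns.
#' @param alpha significance threshold recorded in the output.
#' @return data.frame: outcome, predictor, b, t, df, r, p, significant.
#' @export
association_battery <- function(data, outcomes, predictors = c("d_dr", "d_th"),
                                alpha = 0.05) {
  do.call(rbind, lapply(outcomes, function(oc) {
    fit <- robust_fit(data[[oc]], as.matrix(data[predictors]))
    ix <- seq_along(predictors) + 1
    data.frame(outcome = oc, predictor = predictors,
               b = unname(fit$coefficients[ix]), t = unname(fit$t[ix]),
               df = fit$df, r = unname(fit$r[ix]), p = unname(fit$p[ix]),
               significant = unname(fit$p[ix]) < alpha,
               stringsAsFactors = FALSE)
  }))
}
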