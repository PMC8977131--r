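# Quantile-based multinomial fitting of block-constrained diffusion models,
# BIC model selection across the five-member family, and QP diagnostics.
#
# The objective follows the classic quantile-bin method: per block and
# response, observed RT quantiles at {.1,.3,.5,.7,.9} bound bins whose
# expected probabilities come from the model's defective CDF; the
# log-likelihood is multinomial over the bin counts.

PARAM_NAMES <- c("DR", "s", "TH", "zr", "szr", "Ter", "st")
BLOCK_LEVELS <- c("pre", "tr1", "tr2", "tr3", "tr4", "tr5")
MODEL_NAMES <- c("null", "DR", "DR-TH", "DR-TH-Ter", "full")

# box bounds for the internal parameterization (sigma = 0.1 scale; start
# point and its range are fractions of threshold so the parameter-space
# invariants reduce to box constraints)
param_bounds <- function(sigma = 0.1) {
  sc <- sigma / 0.1
  list(lower = c(DR = -0.5 * sc, s = 0, TH = 0.04 * sc, zr = 0.3, szr = 0,
                 Ter = 0.1, st = 0),
       upper = c(DR = 1.0 * sc, s = 0.35 * sc, TH = 0.40 * sc, zr = 0.7,
                 szr = 0.55, Ter = 1.0, st = 0.18))
}

#' Constrained model specification
#'
#' The five-member family of block-constrained diffusion models. A
#' parameter is either free per block (6 values) or shared across the 6
#' blocks: the `null` model shares everything; `DR` frees drift rate;
#' `DR-TH` frees drift rate and threshold; `DR-TH-Ter` frees drift rate,
#' threshold and nondecision time; `full` frees all seven parameters.
#' Shared parameters count once toward the free-parameter total `k`, free
#' ones six times (k = 7, 12, 17, 22, 42).
#'
#' @param name one of `"null"`, `"DR"`, `"DR-TH"`, `"DR-TH-Ter"`, `"full"`.
#' @param n_blocks number of blocks (6).
#' @return An object of class `ddm_model_spec`.
#' @export
model_spec <- function(name = MODEL_NAMES, n_blocks = 6) {
  name <- match.arg(name)
  free <- switch(name,
                 "null" = character(0),
                 "DR" = "DR",
                 "DR-TH" = c("DR", "TH"),
                 "DR-TH-Ter" = c("DR", "TH", "Ter"),
                 "full" = PARAM_NAMES)
  shared <- setdiff(PARAM_NAMES, free)
  structure(list(name = name, free_per_block = free, shared = shared,
                 n_blocks = n_blocks,
                 k = n_blocks * length(free) + length(shared)),
            class = "ddm_model_spec")
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  cat("model", x$name, "- free per block:",
      if (length(x$free_per_block)) paste(x$free_per_block, collapse = ", ")
      else "(none)", "| k =", x$k, "\n")
  invisible(x)
}

#' Empirical RT quantiles
#'
#' Quantiles by linear interpolation between order statistics
#' (`stats::quantile` type 7); returned nondecreasing.
#'
#' @param rts nonempty numeric vector of RTs.
#' @param probs strictly increasing probabilities in (0, 1).
#' @export
rt_quantiles <- function(rts, probs = c(.1, .3, .5, .7, .9)) {
  if (length(rts) == 0) stop("rts must be nonempty")
  if (any(diff(probs) <= 0) || any(probs <= 0) || any(probs >= 1))
    stop("probs must be strictly increasing in (0,1)")
  q <- unname(quantile(rts, probs, type = 7, names = FALSE))
  cummax(q)
}

# per-block observed quantile edges and bin counts; a response with fewer
# than min_bin_n observations collapses to a single count cell
prepare_blocks <- function(trials, probs = c(.1, .3, .5, .7, .9),
                           min_bin_n = 5) {
  stopifnot(all(c("block", "correct", "rt") %in% names(trials)))
  blocks <- intersect(BLOCK_LEVELS, unique(as.character(trials$block)))
  lapply(blocks, function(b) {
    tb <- trials[trials$block == b, ]
    prep_resp <- function(rts) {
      if (length(rts) == 0)
        return(list(edges = numeric(0), counts = integer(0), collapsed = TRUE))
      if (length(rts) < min_bin_n)
        return(list(edges = numeric(0), counts = length(rts), collapsed = TRUE))
      e <- rt_quantiles(rts, probs)
      cnt <- as.integer(diff(c(0, vapply(e, function(x) sum(rts <= x),
                                         numeric(1)), length(rts))))
      list(edges = e, counts = cnt, collapsed = FALSE)
    }
    corr <- prep_resp(tb$rt[tb$correct == 1])
    err <- prep_resp(tb$rt[tb$correct == 0])
    list(block = b, n = nrow(tb), corr = corr, err = err)
  })
}

# expected bin probabilities for one block under one parameter set
# (internal-scale parameter vector: DR s TH zr szr Ter st)
block_bin_probs <- function(p, blk, sigma, quad = c(5, 5, 5)) {
  a <- p[["TH"]]; z <- p[["zr"]] * a; sz <- p[["szr"]] * a
  pu <- choice_prob_cpp(p[["DR"]], p[["s"]], a, z, sz, sigma, TRUE, 16, 6)
  one <- function(resp, upper, pb) {
    if (length(resp$edges) == 0) return(pb)
    Fv <- wfpt_cdf_cpp(resp$edges, p[["DR"]], p[["s"]], a, z, sz,
                       p[["Ter"]], p[["st"]], sigma, upper,
                       quad[3], quad[1], quad[2])
    pmax(diff(c(0, Fv, max(pb, Fv[length(Fv)]))), 0)
  }
  list(p_upper = pu,
       corr = one(blk$corr, TRUE, pu),
       err = one(blk$err, FALSE, 1 - pu))
}

theta_map <- function(spec) {
  idx <- list(); pos <- 0L
  nb <- as.integer(spec$n_blocks)
  for (nm in PARAM_NAMES) {
    if (nm %in% spec$free_per_block) {
      idx[[nm]] <- pos + seq_len(nb); pos <- pos + nb
    } else {
      idx[[nm]] <- pos + 1L; pos <- pos + 1L
    }
  }
  attr(idx, "length") <- pos
  idx
}

theta_to_matrix <- function(theta, map, n_blocks) {
  out <- matrix(NA_real_, n_blocks, length(PARAM_NAMES),
                dimnames = list(NULL, PARAM_NAMES))
  for (nm in PARAM_NAMES) {
    v <- theta[map[[nm]]]
    out[, nm] <- if (length(v) == 1) rep(v, n_blocks) else v
  }
  out
}

neg_loglik_blocks <- function(P, blocks, sigma, quad, floor_p = 1e-10,
                              which_blocks = seq_along(blocks)) {
  nll <- 0
  for (b in which_blocks) {
    p <- P[b, ]
    blk <- blocks[[b]]
    a <- p[["TH"]]
    nll <- nll + block_negll_cpp(blk$corr$edges, blk$corr$counts,
                                 blk$err$edges, blk$err$counts,
                                 p[["DR"]], p[["s"]], a, p[["zr"]] * a,
                                 p[["szr"]] * a, p[["Ter"]], p[["st"]],
                                 sigma, quad[3], quad[1], quad[2], floor_p)
  }
  if (!is.finite(nll)) nll <- 1e10
  nll
}

#' Multinomial log-likelihood of a block-constrained model
#'
#' Log-likelihood of the observed quantile-bin counts given per-block
#' parameters. Bins are bounded by the observed \{.1,.3,.5,.7,.9\}
#' quantiles per response per block; expected probabilities come from the
#' defective CDF, floored at `1e-10`. Responses with fewer than
#' `min_bin_n` observations collapse to a single count cell.
#'
#' @param params_by_block list of [ddm_params()], one per block present in
#'   `trials` (in block order pre, tr1..tr5).
#' @param trials data.frame with columns `block`, `correct`, `rt`.
#' @param quad integration orders (start, nondecision, segment).
#' @param min_bin_n minimum responses for quantile binning.
#' @return scalar log-likelihood (larger is better).
#' @export
multinomial_loglik <- function(params_by_block, trials, quad = c(10, 10, 8),
                               min_bin_n = 5) {
  blocks <- prepare_blocks(trials, min_bin_n = min_bin_n)
  if (length(blocks) != length(params_by_block))
    stop("need one parameter set per block present in the data")
  sigma <- params_by_block[[1]]$sigma
  P <- do.call(rbind, lapply(params_by_block, function(p) {
    validate_ddm_params(p)
    c(DR = p$DR, s = p$s, TH = p$TH, zr = p$z / p$TH, szr = p$sz / p$TH,
      Ter = p$Ter, st = p$st)
  }))
  -neg_loglik_blocks(P, blocks, sigma, quad)
}

# EZ-style method-of-moments initial values from per-block summary stats
ez_init <- function(tb, sigma, bounds) {
  n <- nrow(tb)
  acc <- mean(tb$correct == 1)
  acc <- min(max(acc, 0.5 + 1 / (2 * n)), 1 - 1 / (2 * n))
  crt <- tb$rt[tb$correct == 1]
  if (length(crt) < 3) crt <- tb$rt
  vrt <- max(var(crt), 1e-4)
  mrt <- mean(crt)
  L <- qlogis(acc)
  x <- L * (L * acc^2 - L * acc + acc - 0.5) / vrt
  v <- sigma * max(x, 1e-6)^0.25
  a <- sigma^2 * L / v
  mdt <- (a / (2 * v)) * (1 - exp(-v * a / sigma^2)) / (1 + exp(-v * a / sigma^2))
  ter <- mrt - mdt
  clamp <- function(val, nm)
    min(max(val, bounds$lower[[nm]] + 1e-3), bounds$upper[[nm]] - 1e-3)
  c(DR = clamp(v, "DR"), TH = clamp(a, "TH"), Ter = clamp(ter, "Ter"))
}

#' Fitting control settings
#'
#' @param multistart number of optimization starts (first from
#'   method-of-moments initials, the rest jittered).
#' @param maxit iteration cap for the bounded quasi-Newton optimizer.
#' @param factr L-BFGS-B convergence setting (objective tolerance is
#'   roughly `factr` times machine precision times the objective scale;
#'   the default corresponds to about 1e-6 on these likelihoods).
#' @param quad integration orders used during fitting (start-point,
#'   nondecision, CDF segment).
#' @param min_bin_n minimum responses per block/response for quantile bins.
#' @param fd_h relative step (fraction of each parameter's box range) for
#'   the structured finite-difference gradient.
#' @param restarts maximum quasi-Newton restarts from the incumbent
#'   solution (each restarts the Hessian approximation).
#' @export
fit_control <- function(multistart = 3, maxit = 150, factr = 1e7,
                        quad = c(4, 4, 5), min_bin_n = 5, fd_h = 1e-5,
                        restarts = 2) {
  list(multistart = multistart, maxit = maxit, factr = factr,
       quad = quad, min_bin_n = min_bin_n, fd_h = fd_h, restarts = restarts)
}

# One bounded quasi-Newton run. The gradient is forward-difference but
# structured: perturbing a block-free parameter re-evaluates only that
# block's likelihood; shared parameters re-evaluate all blocks.
fit_one_start <- function(theta0, spec, blocks, sigma, control, bounds) {
  map <- theta_map(spec)
  nb <- length(blocks)
  npar <- attr(map, "length")
  lo <- up <- numeric(npar)
  block_of <- rep(NA_integer_, npar)   # NA = shared
  for (nm in PARAM_NAMES) {
    ix <- map[[nm]]
    lo[ix] <- bounds$lower[[nm]]
    up[ix] <- bounds$upper[[nm]]
    if (length(ix) > 1) block_of[ix] <- seq_len(nb)
  }
  # optimize on the unit box (parameters rescaled by their ranges) so the
  # quasi-Newton curvature estimates are well conditioned
  rng <- up - lo
  to_theta <- function(u) lo + u * rng
  h <- control$fd_h
  block_eval <- function(theta, b)
    neg_loglik_blocks(theta_to_matrix(theta, map, nb), blocks, sigma,
                      control$quad, which_blocks = b)
  fn <- function(u) {
    v <- neg_loglik_blocks(theta_to_matrix(to_theta(u), map, nb), blocks,
                           sigma, control$quad)
    if (!is.finite(v)) 1e10 else v
  }
  gr <- function(u) {
    theta <- to_theta(u)
    base_b <- vapply(seq_len(nb), function(b) block_eval(theta, b), numeric(1))
    base <- sum(base_b)
    g <- numeric(npar)
    for (j in seq_len(npar)) {
      hj <- if (u[j] + h <= 1) h else -h
      th <- theta; th[j] <- theta[j] + hj * rng[j]
      b <- block_of[j]
      g[j] <- if (is.na(b)) (fn((th - lo) / rng) - base) / hj
              else (block_eval(th, b) - base_b[b]) / hj
    }
    g
  }
  u0 <- pmin(pmax((theta0 - lo) / rng, 1e-8), 1 - 1e-8)
  run <- function(u) tryCatch(
    optim(u, fn, gr, method = "L-BFGS-B", lower = 0, upper = 1,
          control = list(maxit = control$maxit, factr = control$factr)),
    error = function(e)
      optim(u, function(x) fn(pmin(pmax(x, 0), 1)),
            method = "Nelder-Mead", control = list(maxit = 5000)))
  res <- run(u0)
  # a restart with a fresh Hessian approximation often recovers the last
  # couple of nats the line search leaves behind; a restart gain below
  # 0.2 nat counts as converged
  settled <- res$convergence == 0
  for (r in seq_len(control$restarts)) {
    res2 <- run(pmin(pmax(res$par, 1e-8), 1 - 1e-8))
    gain <- res$value - res2$value
    if (res2$value < res$value) res <- res2
    if (gain < 0.2) { settled <- TRUE; break }
    settled <- res$convergence == 0
  }
  list(theta = to_theta(pmin(pmax(res$par, 0), 1)), value = res$value,
       converged = settled)
}

#' Fit one subject's trial data under a constrained model
#'
#' Maximizes the quantile-bin multinomial likelihood under the sharing
#' constraints of `spec` via bounded multistart local optimization
#' (block-coordinate sweeps over per-block and shared parameters for the
#' constrained models; the `full` model decomposes into six independent
#' per-block fits). Deterministic given `seed`.
#'
#' @param trials data.frame with columns `block` (pre, tr1..tr5),
#'   `correct` (0/1) and `rt` (seconds) for one subject.
#' @param spec a [model_spec()] or model name.
#' @param sigma within-trial diffusion coefficient convention.
#' @param control a [fit_control()] list.
#' @param seed integer seed for the jittered multistarts.
#' @param init optional warm start: a `ddm_fit` result for a nested model
#'   whose block parameter matrix seeds the first start.
#' @return An object of class `ddm_fit`: per-block [ddm_params()],
#'   `loglik`, `n_free`, `n_trials`, `bic`, `converged`.
#' @export
fit_subject <- function(trials, spec = "DR-TH-Ter", sigma = 0.1,
                        control = fit_control(), seed = 1, init = NULL) {
  if (is.character(spec)) spec <- model_spec(spec)
  blocks <- prepare_blocks(trials, min_bin_n = control$min_bin_n)
  if (length(blocks) != spec$n_blocks)
    stop("expected ", spec$n_blocks, " blocks, found ", length(blocks))
  set.seed(as.integer(seed))
  bounds <- param_bounds(sigma)

  if (spec$name == "full") {
    # no shared parameters: six independent single-block problems
    sub <- model_spec("null", n_blocks = 1)
    fits <- lapply(seq_along(blocks), function(b) {
      tb <- trials[trials$block == blocks[[b]]$block, ]
      fit_subject(tb, sub, sigma = sigma, control = control,
                  seed = seed + b,
                  init = if (!is.null(init)) subset_fit(init, b) else NULL)
    })
    P <- do.call(rbind, lapply(fits, function(f) f$theta_matrix))
    ll <- sum(vapply(fits, function(f) f$loglik, numeric(1)))
    return(make_fit(spec, P, ll, blocks, sigma,
                    all(vapply(fits, function(f) f$converged, logical(1)))))
  }

  map <- theta_map(spec)
  ez <- build_initials(blocks, trials, spec, map, sigma, bounds, NULL)
  # start 1: warm start from a nested fit when given, else method-of-moments;
  # start 2 (if warm given): method-of-moments; further starts: jittered
  starts <- list(if (is.null(init)) ez
                 else build_initials(blocks, trials, spec, map, sigma, bounds, init))
  if (!is.null(init) && control$multistart >= 2) starts <- c(starts, list(ez))
  rng <- numeric(length(ez))
  for (nm in PARAM_NAMES)
    rng[map[[nm]]] <- bounds$upper[[nm]] - bounds$lower[[nm]]
  while (length(starts) < control$multistart)
    starts <- c(starts, list(ez + runif(length(ez), -0.15, 0.15) * rng))
  best <- NULL
  for (th0 in starts) {
    res <- fit_one_start(th0, spec, blocks, sigma, control, bounds)
    if (is.null(best) || res$value < best$value) best <- res
  }
  P <- theta_to_matrix(best$theta, map, spec$n_blocks)
  make_fit(spec, P, -best$value, blocks, sigma, best$converged)
}

subset_fit <- function(fit, b) {
  f <- fit
  f$theta_matrix <- fit$theta_matrix[b, , drop = FALSE]
  f
}

build_initials <- function(blocks, trials, spec, map, sigma, bounds, init) {
  nb <- length(blocks)
  if (!is.null(init)) {
    Pw <- init$theta_matrix
    theta <- numeric(attr(map, "length"))
    for (nm in PARAM_NAMES) {
      ix <- map[[nm]]
      theta[ix] <- if (length(ix) == 1) mean(Pw[, nm]) else Pw[, nm]
    }
    return(theta)
  }
  ez <- t(vapply(blocks, function(blk) {
    ez_init(trials[trials$block == blk$block, ], sigma, bounds)
  }, c(DR = 0, TH = 0, Ter = 0)))
  defaults <- c(s = 0.07 * sigma / 0.1, zr = 0.5, szr = 0.1, st = 0.08)
  theta <- numeric(attr(map, "length"))
  for (nm in PARAM_NAMES) {
    ix <- map[[nm]]
    v <- if (nm %in% colnames(ez)) ez[, nm] else rep(defaults[[nm]], nb)
    theta[ix] <- if (length(ix) == 1) mean(v) else v
  }
  theta
}

make_fit <- function(spec, P, loglik, blocks, sigma, converged) {
  n_trials <- sum(vapply(blocks, function(b) b$n, numeric(1)))
  params <- lapply(seq_len(nrow(P)), function(b) {
    ddm_params(DR = P[[b, "DR"]], s = P[[b, "s"]], TH = P[[b, "TH"]],
               z = P[[b, "zr"]] * P[[b, "TH"]],
               sz = P[[b, "szr"]] * P[[b, "TH"]],
               Ter = P[[b, "Ter"]], st = P[[b, "st"]], sigma = sigma)
  })
  names(params) <- vapply(blocks, function(b) b$block, character(1))[seq_len(nrow(P))]
  structure(list(spec = spec, params = params, theta_matrix = P,
                 loglik = loglik, n_free = spec$k, n_trials = n_trials,
                 bic = compute_bic(loglik, spec$k, n_trials),
                 converged = converged),
            class = "ddm_fit")
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat("ddm_fit:", x$spec$name, "| loglik", round(x$loglik, 2),
      "| k", x$n_free, "| N", x$n_trials, "| BIC", round(x$bic, 2),
      if (!x$converged) "| NOT CONVERGED" else "", "\n")
  invisible(x)
}

#' Bayesian information criterion
#'
#' `k * log(N) - 2 * loglik`; lower is better.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters.
#' @param N number of observations.
#' @export
compute_bic <- function(loglik, k, N) {
  stopifnot(N >= 1, k >= 0)
  k * log(N) - 2 * loglik
}

#' Fit all five model variants with warm starts
#'
#' Fits the family in nesting order (null, DR, DR-TH, DR-TH-Ter, full),
#' warm-starting each model from the previous one so the maximized
#' likelihoods respect the nesting ordering.
#'
#' @inheritParams fit_subject
#' @return named list of `ddm_fit` objects.
#' @export
fit_all_models <- function(trials, sigma = 0.1, control = fit_control(),
                           seed = 1) {
  fits <- list()
  prev <- NULL
  for (nm in MODEL_NAMES) {
    f <- fit_subject(trials, model_spec(nm), sigma = sigma, control = control,
                     seed = seed, init = prev)
    # warm start guarantees monotone likelihood up to optimizer noise
    if (!is.null(prev) && f$loglik < prev$loglik - 1e-6) {
      P <- prev$theta_matrix
      f2 <- make_fit(model_spec(nm), P, prev$loglik,
                     prepare_blocks(trials, min_bin_n = control$min_bin_n),
                     sigma, prev$converged)
      if (f2$loglik > f$loglik) f <- f2
    }
    fits[[nm]] <- f
    prev <- f
  }
  fits
}

#' Group-level model selection by mean BIC
#'
#' Selects the model with the lowest across-subject mean BIC; ties break
#' toward fewer free parameters. Accepts a named numeric vector of mean
#' BICs, a subjects-by-models BIC matrix, or a list (one element per
#' subject) of named lists of `ddm_fit` objects; subjects with missing or
#' unconverged fits are dropped with a message.
#'
#' @param x BIC summary in one of the three accepted forms.
#' @return list with `model` (chosen name) and `mean_bic` (named vector).
#' @export
select_model <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.numeric(x)) {
    keep <- vapply(x, function(s) {
      all(MODEL_NAMES %in% names(s)) &&
        all(vapply(s[MODEL_NAMES], function(f) isTRUE(f$converged), logical(1)))
    }, logical(1))
    if (any(!keep))
      message(sum(!keep), " subject(s) dropped (missing or unconverged fits)")
    if (!any(keep)) stop("no subject with converged fits for every model")
    x <- do.call(rbind, lapply(x[keep], function(s)
      vapply(s[MODEL_NAMES], function(f) f$bic, numeric(1))))
  }
  if (is.matrix(x)) x <- colMeans(x)
  if (!is.numeric(x) || is.null(names(x)) || !all(MODEL_NAMES %in% names(x)))
    stop("mean BICs must be named with the five model names")
  x <- x[MODEL_NAMES]
  k <- vapply(MODEL_NAMES, function(nm) model_spec(nm)$k, numeric(1))
  ord <- order(x, k)   # ties toward fewer parameters
  list(model = MODEL_NAMES[ord[1]], mean_bic = x)
}

#' Quantile-probability table
#'
#' Observed and predicted \{.1,.3,.5,.7,.9\} RT quantiles and response
#' proportions per block and response, for quantile-probability
#' inspection of a fit. Cells with too few observed responses report
#' predictions only and are flagged.
#'
#' @param fit a converged `ddm_fit`.
#' @param trials the trial data the fit was computed on.
#' @param probs quantile probabilities.
#' @param min_bin_n observation threshold below which a cell is flagged.
#' @return data.frame with columns `block`, `response`, `prob`, `q_obs`,
#'   `q_pred`, `prop_obs`, `prop_pred`, `flagged`.
#' @export
qp_table <- function(fit, trials, probs = c(.1, .3, .5, .7, .9),
                     min_bin_n = 5) {
  if (!isTRUE(fit$converged)) stop("qp_table requires a converged fit")
  blocks <- prepare_blocks(trials, probs, min_bin_n)
  out <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    p <- fit$params[[b]]
    tb <- trials[trials$block == blk$block, ]
    for (resp in c("correct", "error")) {
      upper <- resp == "correct"
      rts <- tb$rt[(tb$correct == 1) == upper]
      pb <- choice_probability(p, if (upper) "upper" else "lower")
      qpred <- predicted_quantiles(p, upper, probs, pb)
      flag <- length(rts) < min_bin_n
      out[[length(out) + 1]] <- data.frame(
        block = blk$block, response = resp, prob = probs,
        q_obs = if (flag) NA_real_ else rt_quantiles(rts, probs),
        q_pred = qpred,
        prop_obs = length(rts) / nrow(tb), prop_pred = pb, flagged = flag)
    }
  }
  do.call(rbind, out)
}

predicted_quantiles <- function(p, upper, probs, pb) {
  bnd <- if (upper) "upper" else "lower"
  lo <- max(1e-4, p$Ter - p$st / 2)
  hi <- lo + 30
  vapply(probs, function(pr) {
    uniroot(function(t) wiener_fpt_cdf(t, p, bnd) / pb - pr,
            lower = lo + 1e-6, upper = hi, tol = 1e-6)$root
  }, numeric(1))
}
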