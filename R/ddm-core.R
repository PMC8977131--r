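# Wiener diffusion core: parameter container, defective first-passage
# densities, choice probabilities and the trial simulator.

#' Drift diffusion model parameters
#'
#' Container for the seven parameters governing one block's choice/RT
#' distribution: mean drift rate and its across-trial SD, decision threshold
#' (boundary separation), mean start point and its uniform range, mean
#' nondecision time and its uniform range, plus the within-trial diffusion
#' coefficient convention.
#'
#' Evidence starts at `z` (absolute units, between 0 and `TH`), accumulates
#' with drift drawn per trial from Normal(`DR`, `s`), and is absorbed at `TH`
#' (upper boundary) or 0 (lower). Observed RT is decision time plus a
#' nondecision time drawn from Uniform(`Ter` +/- `st`/2). Under accuracy
#' coding the upper boundary is the correct response.
#'
#' @param DR mean drift rate (evidence units/s).
#' @param TH decision threshold / boundary separation, > 0.
#' @param Ter mean nondecision time in seconds, >= 0.
#' @param s across-trial SD of drift, >= 0.
#' @param z mean start point in absolute units; default `TH/2` (unbiased).
#' @param sz full width of the uniform start-point distribution, >= 0.
#' @param st full width of the uniform nondecision distribution, >= 0.
#' @param sigma within-trial diffusion coefficient; fixed at 0.1 by
#'   convention so parameter magnitudes are on the classic scale.
#' @return An object of class `ddm_params` (named list).
#' @examples
#' p <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3)
#' choice_probability(p, "upper")
#' @export
ddm_params <- function(DR, TH, Ter, s = 0, z = TH / 2, sz = 0, st = 0,
                       sigma = 0.1) {
  p <- structure(list(DR = DR, s = s, TH = TH, z = z, sz = sz,
                      Ter = Ter, st = st, sigma = sigma),
                 class = "ddm_params")
  validate_ddm_params(p)
  p
}

validate_ddm_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) stop("all ddm_params fields must be finite scalars")
  if (p$TH <= 0) stop("threshold TH must be > 0")
  if (p$sigma <= 0) stop("within-trial sigma must be > 0")
  if (p$s < 0 || p$sz < 0 || p$st < 0) stop("variability ranges must be >= 0")
  if (p$Ter < 0) stop("nondecision time Ter must be >= 0")
  if (p$z - p$sz / 2 <= 0 || p$z + p$sz / 2 >= p$TH)
    stop("start-point range must lie strictly inside (0, TH)")
  if (p$Ter - p$st / 2 < 0)
    stop("nondecision range must not extend below zero")
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (sigma =", x$sigma, ")\n")
  v <- unlist(x[c("DR", "s", "TH", "z", "sz", "Ter", "st")])
  print(round(v, 4))
  invisible(x)
}

check_boundary <- function(boundary) {
  boundary <- match.arg(boundary, c("upper", "lower"))
  boundary == "upper"
}

#' Defective first-passage-time density
#'
#' Density of absorption at the given boundary at observed RT `t`
#' (decision time plus nondecision time), marginalized over the normal
#' across-trial drift distribution (analytically) and the uniform
#' start-point and nondecision distributions (fixed-order Gauss-Legendre
#' quadrature). The density is defective: it integrates over `t` to the
#' boundary's choice probability. With `Ter = st = 0` the argument is pure
#' decision time.
#'
#' @param t vector of positive times in seconds.
#' @param params a [ddm_params()] object.
#' @param boundary `"upper"` or `"lower"`.
#' @param quad_order Gauss-Legendre order for the uniform start-point and
#'   nondecision marginals.
#' @return Numeric vector of densities, >= 0.
#' @export
wiener_fpt_density <- function(t, params, boundary = c("upper", "lower"),
                               quad_order = 10) {
  validate_ddm_params(params)
  upper <- check_boundary(boundary)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop("t must be positive and finite")
  wfpt_density_cpp(t, params$DR, params$s, params$TH, params$z, params$sz,
                   params$Ter, params$st, params$sigma, upper,
                   quad_order, quad_order)
}

#' Defective cumulative distribution at the given boundary
#'
#' Cumulative probability of having been absorbed at the boundary by each
#' (sorted, increasing) time in `t`, on the observed-RT scale.
#'
#' @inheritParams wiener_fpt_density
#' @param nseg Gauss-Legendre order per integration segment.
#' @return Nondecreasing vector of probabilities.
#' @export
wiener_fpt_cdf <- function(t, params, boundary = c("upper", "lower"),
                           quad_order = 10, nseg = 8) {
  validate_ddm_params(params)
  upper <- check_boundary(boundary)
  if (is.unsorted(t)) stop("t must be sorted increasing")
  wfpt_cdf_cpp(t, params$DR, params$s, params$TH, params$z, params$sz,
               params$Ter, params$st, params$sigma, upper,
               nseg, quad_order, quad_order)
}

#' Choice probability for one boundary
#'
#' Probability of absorption at the given boundary, marginal over drift and
#' start-point variability. With no across-trial variability the upper
#' probability has the closed form
#' \deqn{P = (1 - e^{-2 v z / \sigma^2}) / (1 - e^{-2 v a / \sigma^2}).}
#'
#' @inheritParams wiener_fpt_density
#' @param quad_order quadrature order for the drift and start marginals.
#' @return Probability in `[0, 1]`; upper and lower sum to 1.
#' @export
choice_probability <- function(params, boundary = c("upper", "lower"),
                               quad_order = 20) {
  validate_ddm_params(params)
  upper <- check_boundary(boundary)
  choice_prob_cpp(params$DR, params$s, params$TH, params$z, params$sz,
                  params$sigma, upper, quad_order, min(quad_order, 10))
}

#' Simulate diffusion trials
#'
#' Euler-Maruyama simulation with a Brownian-bridge boundary-crossing
#' correction within each step, which removes most of the first-order
#' boundary-overshoot bias so that moderate step sizes remain accurate.
#' Per-trial drift, start point and nondecision time are drawn from the
#' across-trial distributions. The remaining discretization bias is of
#' higher order in `dt`; without the bridge correction it is O(sqrt(dt)).
#'
#' @param params a [ddm_params()] object.
#' @param n number of trials, >= 1.
#' @param dt Euler step in seconds.
#' @param seed integer seed (mandatory; the simulator has its own stream).
#' @param bridge apply the within-step bridge crossing correction.
#' @param tmax guard time after which a trial is forced to the nearer
#'   boundary (practically unreachable for sane parameters).
#' @return data.frame with columns `boundary` (`"upper"`/`"lower"`) and
#'   `rt` (seconds, decision + nondecision).
#' @examples
#' p <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3)
#' head(simulate_trials(p, 5, seed = 1))
#' @export
simulate_trials <- function(params, n, dt = 1e-4, seed, bridge = TRUE,
                            tmax = 60) {
  validate_ddm_params(params)
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n >= 1, dt > 0)
  if (dt > 0.05 * (params$TH / params$sigma)^2)
    warning("dt is coarse relative to (TH/sigma)^2; discretization bias may be visible")
  sim <- simulate_trials_cpp(as.integer(n), params$DR, params$s, params$TH,
                             params$z, params$sz, params$Ter, params$st,
                             params$sigma, dt, as.integer(seed), bridge, tmax)
  data.frame(boundary = ifelse(sim$boundary == 1L, "upper", "lower"),
             rt = sim$rt, stringsAsFactors = FALSE)
}
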