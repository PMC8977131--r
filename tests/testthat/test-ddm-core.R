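# Wiener first-passage machinery: closed forms, normalization, symmetry,
# scale invariance, and simulator agreement.

total_mass <- function(p, upper_limit = 30) {
  integrate(function(t) wiener_fpt_density(t, p, "upper"), 0, upper_limit,
            rel.tol = 1e-7, subdivisions = 400)$value +
    integrate(function(t) wiener_fpt_density(t, p, "lower"), 0, upper_limit,
              rel.tol = 1e-7, subdivisions = 400)$value
}

test_that("parameter invariants are enforced", {
  expect_error(ddm_params(DR = 0.2, TH = -1, Ter = 0.3), "TH")
  expect_error(ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3, z = 0.09, sz = 0.03),
               "inside")
  expect_error(ddm_params(DR = 0.2, TH = 0.1, Ter = 0.05, st = 0.2), "below zero")
  expect_error(ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3, sigma = 0), "sigma")
  p <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3)
  expect_error(wiener_fpt_density(-1, p, "upper"), "positive")
  expect_error(wiener_fpt_density(0, p, "upper"), "positive")
})

test_that("unbiased zero-drift diffusion is symmetric across boundaries", {
  p <- ddm_params(DR = 0, TH = 0.12, Ter = 0.2, z = 0.06, sigma = 0.1)
  tt <- c(0.25, 0.4, 0.7, 1.5)
  expect_equal(wiener_fpt_density(tt, p, "upper"),
               wiener_fpt_density(tt, p, "lower"), tolerance = 1e-12)
  expect_equal(choice_probability(p, "upper"), 0.5, tolerance = 1e-12)
})

test_that("choice probability matches the closed form and is monotone in drift", {
  p <- ddm_params(DR = 1, TH = 2, Ter = 0, z = 1, sigma = 1)
  expect_lt(abs(choice_probability(p, "upper") - (1 - exp(-2)) / (1 - exp(-4))),
            1e-10)
  expect_equal(choice_probability(p, "upper") + choice_probability(p, "lower"),
               1, tolerance = 1e-12)
  pups <- vapply(c(0.05, 0.1, 0.2, 0.4), function(v)
    choice_probability(ddm_params(DR = v, TH = 0.1, Ter = 0.3, sigma = 0.1),
                       "upper"), numeric(1))
  expect_true(all(diff(pups) > 0))
  expect_true(all(pups > 0.5))
})

test_that("defective densities integrate to the choice probabilities and to unit total mass", {
  grid <- list(
    ddm_params(DR = 1, TH = 2, Ter = 0, z = 1, sigma = 1),
    ddm_params(DR = 0.15, TH = 0.1, Ter = 0.35, s = 0.08, sz = 0.03,
               st = 0.1, sigma = 0.1),
    ddm_params(DR = -0.1, TH = 0.08, Ter = 0.25, s = 0.12, z = 0.03,
               sz = 0.02, st = 0.05, sigma = 0.1),
    ddm_params(DR = 0.3, TH = 0.15, Ter = 0.4, s = 0.05, sigma = 0.1))
  for (p in grid) {
    up <- integrate(function(t) wiener_fpt_density(t, p, "upper"), 0, 30,
                    rel.tol = 1e-7, subdivisions = 400)$value
    expect_lt(abs(up - choice_probability(p, "upper")), 1e-4)
    expect_lt(abs(total_mass(p) - 1), 1e-4)
  }
})

test_that("analytic drift marginalization agrees with numerical integration over drift", {
  p <- ddm_params(DR = 0.15, TH = 0.1, Ter = 0.35, s = 0.08, sz = 0.03,
                  st = 0.1, sigma = 0.1)
  tt <- c(0.4, 0.5, 0.8, 1.5)
  numeric_marg <- vapply(tt, function(t1)
    integrate(function(v) {
      dnorm(v, p$DR, p$s) * vapply(v, function(vv) {
        q <- p; q$DR <- vv; q$s <- 0
        wiener_fpt_density(t1, q, "upper")
      }, numeric(1))
    }, p$DR - 6 * p$s, p$DR + 6 * p$s, rel.tol = 1e-9)$value, numeric(1))
  expect_equal(wiener_fpt_density(tt, p, "upper"), numeric_marg,
               tolerance = 1e-6)
})

test_that("density is smooth across the series switching region", {
  p <- ddm_params(DR = 1, TH = 2, Ter = 0, z = 1, sigma = 1)
  tt <- seq(0.02, 4, by = 0.002)
  f <- wiener_fpt_density(tt, p, "upper")
  expect_lt(max(abs(diff(f, differences = 2))), 1e-3)
})

test_that("choice probabilities and decision times are scale invariant", {
  p1 <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0, s = 0.06, z = 0.045,
                   sz = 0.02, sigma = 0.1)
  cc <- 10
  p2 <- ddm_params(DR = p1$DR * cc, TH = p1$TH * cc, Ter = 0, s = p1$s * cc,
                   z = p1$z * cc, sz = p1$sz * cc, sigma = p1$sigma * cc)
  expect_equal(choice_probability(p1, "upper"), choice_probability(p2, "upper"),
               tolerance = 1e-10)
  tt <- c(0.3, 0.6, 1.2)
  expect_equal(wiener_fpt_density(tt, p1, "upper"),
               wiener_fpt_density(tt, p2, "upper"), tolerance = 1e-8)
})

test_that("simulator is reproducible, respects the nondecision floor, and is unbiased at zero drift", {
  p <- ddm_params(DR = 0.3, TH = 0.1, Ter = 0.3, s = 0.05, sz = 0.02,
                  st = 0.08, sigma = 0.1)
  s1 <- simulate_trials(p, 2000, dt = 1e-3, seed = 5)
  s2 <- simulate_trials(p, 2000, dt = 1e-3, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$rt > p$Ter - p$st / 2))
  p0 <- ddm_params(DR = 0, TH = 0.1, Ter = 0.3, sigma = 0.1)
  s0 <- simulate_trials(p0, 1e5, dt = 1e-3, seed = 6)
  expect_lt(abs(mean(s0$boundary == "upper") - 0.5), 3 * sqrt(0.25 / 1e5))
})

test_that("simulated RT distribution matches the analytic defective CDF", {
  p <- ddm_params(DR = 0.15, TH = 0.1, Ter = 0.35, s = 0.08, sz = 0.03,
                  st = 0.1, sigma = 0.1)
  n <- 2e5
  sim <- simulate_trials(p, n, dt = 1e-3, seed = 11)
  pu <- choice_probability(p, "upper")
  phat <- mean(sim$boundary == "upper")
  expect_lt(abs(phat - pu), 3 * sqrt(pu * (1 - pu) / n))
  rts <- sort(sim$rt[sim$boundary == "upper"])
  qs <- quantile(rts, c(.1, .3, .5, .7, .9), names = FALSE)
  Fq <- wiener_fpt_cdf(qs, p, "upper") / pu
  # quantile-level MC tolerance: 3 * sqrt(p(1-p)/n_upper)
  n_up <- length(rts)
  tol <- 3 * sqrt(c(.1, .3, .5, .7, .9) * (1 - c(.1, .3, .5, .7, .9)) / n_up)
  expect_true(all(abs(Fq - c(.1, .3, .5, .7, .9)) < tol + 2e-3))
})

test_that("coarse time steps trigger the discretization warning", {
  p <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0.3, sigma = 0.1)
  expect_warning(simulate_trials(p, 10, dt = 0.2, seed = 1), "coarse")
  expect_error(simulate_trials(p, 10, dt = 1e-3), "seed")
})
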