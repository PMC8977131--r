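# Quantile-bin multinomial fitting, BIC machinery, model selection and
# quantile-probability diagnostics.

test_that("empirical quantiles interpolate order statistics and stay ordered", {
  expect_equal(rt_quantiles(seq(0.1, 0.9, by = 0.1), 0.5), 0.5)
  expect_equal(rt_quantiles(rep(0.37, 20)), rep(0.37, 5))
  expect_error(rt_quantiles(numeric(0)), "nonempty")
  expect_error(rt_quantiles(1:5, c(0.5, 0.2)), "increasing")
  set.seed(31)
  x <- rlnorm(200, meanlog = -1, sdlog = 0.5)
  probs <- c(.1, .3, .5, .7, .9)
  qtrue <- qlnorm(probs, -1, 0.5)
  se <- sqrt(probs * (1 - probs) / 200) / dlnorm(qtrue, -1, 0.5)
  expect_true(all(abs(rt_quantiles(x, probs) - qtrue) < 3 * se))
  expect_true(all(diff(rt_quantiles(x, probs)) >= 0))
})

test_that("the multinomial objective prefers the generating drift rate", {
  p <- ddm_params(DR = 0.2, TH = 0.1, Ter = 0.35, s = 0.07, sz = 0.01,
                  st = 0.1, sigma = 0.1)
  sim <- simulate_trials(p, 1e4, dt = 1e-3, seed = 21)
  trials <- data.frame(block = "pre", correct = as.integer(sim$boundary == "upper"),
                       rt = sim$rt)
  ll_at <- function(dr) {
    q <- p; q$DR <- dr
    multinomial_loglik(list(q), trials)
  }
  ll0 <- ll_at(0.2)
  expect_gt(ll0, ll_at(0.14))
  expect_gt(ll0, ll_at(0.26))
  # bounded above by the saturated multinomial maximum
  blk <- driftlearn:::prepare_blocks(trials)[[1]]
  counts <- c(blk$corr$counts, blk$err$counts)
  sat <- sum(counts[counts > 0] * log(counts[counts > 0] / sum(counts)))
  expect_lte(ll0, sat)
})

test_that("blocks without errors collapse to a single cell and stay finite", {
  set.seed(4)
  blocks <- c("pre", paste0("tr", 1:5))
  trials <- data.frame(block = rep(blocks, each = 50),
                       correct = 1L, rt = rlnorm(300, -0.7, 0.3) + 0.2)
  params <- replicate(6, ddm_params(DR = 0.3, TH = 0.1, Ter = 0.3, sigma = 0.1),
                      simplify = FALSE)
  ll <- multinomial_loglik(params, trials)
  expect_true(is.finite(ll))
})

test_that("BIC follows its definition and penalizes parameters", {
  expect_equal(compute_bic(0, 0, 100), 0)
  expect_equal(compute_bic(-100, 10, 600), 10 * log(600) + 200)
  expect_equal(round(compute_bic(-100, 10, 600), 2), 263.97)
  expect_gt(compute_bic(-50, 12, 600), compute_bic(-50, 7, 600))
  fits <- cached_ladder()
  for (f in fits)
    expect_equal(f$bic, f$n_free * log(f$n_trials) - 2 * f$loglik)
  expect_equal(unname(vapply(fits, function(f) f$n_free, numeric(1))),
               c(7, 12, 17, 22, 42))
})

test_that("fitting is deterministic under a fixed seed", {
  tr <- subject_one()
  f1 <- fit_subject(tr, "DR", control = lean_control(), seed = 99)
  f2 <- fit_subject(tr, "DR", control = lean_control(), seed = 99)
  expect_identical(f1$theta_matrix, f2$theta_matrix)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("maximized likelihoods respect the model nesting order", {
  fits <- cached_ladder()
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_gte(ll[["full"]], ll[["DR-TH-Ter"]] - 1e-3)
  expect_gte(ll[["DR-TH-Ter"]], ll[["DR-TH"]] - 1e-3)
  expect_gte(ll[["DR-TH"]], ll[["DR"]] - 1e-3)
  expect_gte(ll[["DR"]], ll[["null"]] - 1e-3)
  expect_gte(ll[["DR-TH-Ter"]], ll[["null"]] - 1e-3)
})

test_that("model selection takes the lowest mean BIC with ties toward parsimony", {
  bics <- c(null = 3246.22, DR = 3267.02, `DR-TH` = 3234.13,
            `DR-TH-Ter` = 3228.73, full = 3308.36)
  expect_equal(select_model(bics)$model, "DR-TH-Ter")
  ties <- setNames(rep(3000, 5), names(bics))
  expect_equal(select_model(ties)$model, "null")
  mat <- rbind(bics, bics + 10)
  expect_equal(select_model(mat)$model, "DR-TH-Ter")
  # subjects with unconverged fits are dropped with a message
  fits <- cached_ladder()
  bad <- fits
  bad[["full"]]$converged <- FALSE
  expect_message(sel <- select_model(list(fits, bad)), "dropped")
  expect_true(sel$model %in% names(bics))
})

test_that("free parameters track the generating trajectory", {
  coh <- small_cohort()
  traj <- attr(coh$truth, "trajectories")[[1]]
  f <- cached_ladder()[["DR-TH-Ter"]]
  expect_gt(cor(traj[, "DR"], f$theta_matrix[, "DR"]), 0.5)
  expect_gt(cor(traj[, "Ter"], f$theta_matrix[, "Ter"]), 0.5)
  expect_lt(mean(abs(f$theta_matrix[, "TH"] - traj[, "TH"])), 0.02)
})

test_that("quantile-probability tables are self-consistent on model-generated data", {
  p <- ddm_params(DR = 0.18, TH = 0.1, Ter = 0.35, s = 0.07, sz = 0.01,
                  st = 0.1, sigma = 0.1)
  set.seed(8)
  blocks <- c("pre", paste0("tr", 1:5))
  sim <- simulate_trials(p, 1800, dt = 1e-3, seed = 77)
  trials <- data.frame(block = rep(blocks, each = 300),
                       correct = as.integer(sim$boundary == "upper"),
                       rt = sim$rt)
  f <- fit_subject(trials, "null", control = lean_control(), seed = 3)
  qp <- qp_table(f, trials)
  expect_true(all(abs(tapply(qp$prop_obs[qp$prob == 0.5],
                             qp$block[qp$prob == 0.5], sum) - 1) < 1e-12))
  for (cell in split(qp, paste(qp$block, qp$response)))
    expect_true(all(diff(cell$q_pred) >= 0))
  ok <- !qp$flagged
  expect_lt(mean(abs(qp$q_obs[ok] - qp$q_pred[ok])), 0.05)
  expect_lt(max(abs(qp$prop_obs[ok] - qp$prop_pred[ok])), 0.1)
  f$converged <- FALSE
  expect_error(qp_table(f, trials), "converged")
})
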