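# Soft ICA cleanup, discrete-cosine high-pass, overlap masks,
# eigenvariates and Fisher-z connectivity.

test_that("soft cleanup subtracts only the unique noise contribution", {
  set.seed(5)
  N <- 300
  sig <- rnorm(N); sig <- sig - mean(sig)
  noi <- resid(lm(rnorm(N) ~ sig))          # exactly orthogonal in sample
  vox <- rbind(1.0 * noi + 0.5 * sig)
  C <- cbind(sig = sig, noi = noi)
  out <- soft_ica_cleanup(vox, C, noise_labels = 2)
  expect_lt(max(abs(out - 0.5 * sig)), 1e-8)
  # noise orthogonal to the voxel: unchanged after motion residualization
  vox2 <- rbind(0.5 * sig)
  out2 <- soft_ica_cleanup(vox2, C, noise_labels = 2)
  expect_lt(max(abs(out2 - vox2 + mean(vox2))), 1e-8)
})

test_that("cleanup limiting cases match plain regression residuals", {
  set.seed(6)
  N <- 200
  vox <- matrix(rnorm(3 * N), 3)
  C <- matrix(rnorm(2 * N), N)
  mot <- matrix(rnorm(2 * N), N)
  X <- cbind(1, mot)
  mot_resid <- t(resid(lm.fit(X, t(vox))))
  # no noise components: motion-only residualization
  expect_equal(soft_ica_cleanup(vox, C, integer(0), mot), mot_resid,
               tolerance = 1e-12)
  # all components noise: full component regression residual
  Cr <- resid(lm.fit(X, C))
  full_resid <- t(resid(lm.fit(cbind(1, Cr), t(mot_resid))))
  expect_equal(soft_ica_cleanup(vox, C, 1:2, mot), full_resid,
               tolerance = 1e-10)
})

test_that("collinear components are refused by name", {
  set.seed(7)
  N <- 100
  C <- matrix(rnorm(2 * N), N)
  C <- cbind(C, C[, 1])
  colnames(C) <- c("a", "b", "dup")
  vox <- matrix(rnorm(2 * N), 2)
  expect_error(soft_ica_cleanup(vox, C, 3), "dup")
  expect_error(soft_ica_cleanup(vox, C[1:50, 1:2], 1), "timepoint")
})

test_that("the discrete-cosine high-pass removes slow and keeps fast fluctuations", {
  tr <- 0.727; N <- 825
  tt <- (seq_len(N) - 1) * tr
  slow <- sin(2 * pi * 0.001 * tt)
  fast <- sin(2 * pi * 0.1 * tt)
  expect_lt(sd(highpass(slow, 0.01, tr)) / sd(slow), 0.1)
  expect_gt(sd(highpass(fast, 0.01, tr)) / sd(fast), 0.95)
  expect_lt(max(abs(highpass(rep(3, N), 0.01, tr))), 1e-10)
  expect_lt(abs(mean(highpass(slow + fast + 5, 0.01, tr))), 1e-10)
  expect_error(highpass(slow, cutoff_hz = 1, tr_seconds = 0.727), "Nyquist")
})

test_that("group overlap masks keep voxels present in at least half the subjects", {
  m <- list(c(TRUE, TRUE, FALSE, TRUE), c(TRUE, FALSE, FALSE, TRUE),
            c(FALSE, TRUE, FALSE, FALSE))
  keep <- group_overlap_mask(m)
  expect_equal(keep, c(TRUE, TRUE, FALSE, TRUE))   # 2/3, 2/3, 0/3, 2/3
  m2 <- list(c(TRUE, FALSE), c(FALSE, FALSE))
  expect_equal(group_overlap_mask(m2), c(TRUE, FALSE))  # exactly 50% kept
  expect_error(group_overlap_mask(list()), "empty")
  expect_error(group_overlap_mask(list(c(TRUE, FALSE), TRUE)), "common grid")
})

test_that("the first eigenvariate recovers the dominant time course", {
  set.seed(9)
  w <- rnorm(120)
  u <- runif(8, 0.5, 2)
  ev <- first_eigenvariate(u %*% t(w))
  expect_gt(abs(cor(ev, w)), 1 - 1e-10)
  expect_gte(cor(ev, w), 0)   # sign aligned with the voxel mean
  same <- matrix(rep(w, 5), nrow = 5, byrow = TRUE)
  expect_gt(abs(cor(first_eigenvariate(same), w)), 1 - 1e-10)
  # dominant cluster wins
  w2 <- resid(lm(rnorm(120) ~ w))
  mat <- rbind(matrix(rep(sqrt(10) * w, 6), 6, byrow = TRUE) +
                 0.05 * matrix(rnorm(720), 6),
               matrix(rep(w2, 6), 6, byrow = TRUE) +
                 0.05 * matrix(rnorm(720), 6))
  expect_gt(abs(cor(first_eigenvariate(mat, standardize = FALSE), w)), 0.99)
  expect_error(first_eigenvariate(matrix(1, 3, 10)), "zero-variance")
  expect_error(first_eigenvariate(matrix(w, 1)), "2 voxels")
})

test_that("connectivity is symmetric, scale invariant and correct on known inputs", {
  set.seed(10)
  a <- rnorm(400); b <- 0.5 * a + sqrt(0.75) * rnorm(400)
  r1 <- roi_connectivity(list(a), list(b))
  expect_equal(r1$fisher_z, atanh(r1$pearson_r))
  expect_equal(r1$mean_z, roi_connectivity(list(b), list(a))$mean_z)
  expect_equal(roi_connectivity(list(2 * a + 1), list(b))$mean_z, r1$mean_z)
  expect_error(roi_connectivity(list(a), list(2 * a)), "degenerate")
  expect_error(roi_connectivity(list(a), list(b[1:100])), "timepoint")
  # two runs average in z space
  r2 <- roi_connectivity(list(a, a), list(b, rev(b)))
  expect_equal(r2$mean_z, mean(r2$fisher_z))
  # latent r = 0.5: mean z over simulated subjects near atanh(0.5)
  zs <- replicate(100, {
    x <- rnorm(825); y <- 0.5 * x + sqrt(0.75) * rnorm(825)
    roi_connectivity(list(x), list(y))$mean_z
  })
  expect_lt(abs(mean(zs) - atanh(0.5)), 3 * sd(zs) / sqrt(100))
  # independent white noise: null within 3/sqrt(n-3)
  z0 <- roi_connectivity(list(rnorm(800)), list(rnorm(800)))$mean_z
  expect_lt(abs(z0), 3 / sqrt(800 - 3))
})

test_that("the subject-level chain removes a planted shared confound", {
  cfg <- cohort_config(n_subjects = 6, true_r = 0, noise_amp = 1.5, seed = 14)
  ts <- gen_roi_timeseries(cfg)
  naive <- vapply(ts, function(r) subject_connectivity(r, cleanup = FALSE)$mean_z,
                  numeric(1))
  clean <- vapply(ts, function(r) subject_connectivity(r)$mean_z, numeric(1))
  expect_gt(mean(naive), 0.3)
  expect_lt(abs(mean(clean)), 0.06)
})
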