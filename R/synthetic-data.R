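# Synthetic cohorts with the statistical structure the analysis assumes:
# behavioral trial tables generated from the diffusion model with
# block-wise learning trajectories, MRS quantification tables coupled to
# the behavioral ground truth through a Gaussian copula, ROI voxel time
# series with planted noise components, and a stimulated (anodal/sham)
# arm. Every generator is a pure function of (config, seed).

#' Cohort configuration
#'
#' Defaults mirror the study geometry this package emulates: 22 subjects,
#' 100 trials in each of 6 blocks (pre, tr1..tr5), 825 resting-state
#' timepoints per run at TR 0.727 s over 2 runs. The generating model is
#' the DR-TH-Ter family member: drift rate rises across blocks (subject
#' mean gain 0.10, SD 0.08 on the sigma = 0.1 scale), threshold falls
#' slightly, nondecision time falls slightly, and all three receive
#' block-to-block state jitter; the remaining four parameters are
#' constant across blocks. EV glutamate is coupled to each subject's true
#' drift-rate change through a Gaussian copula at `brainbehavior_corr`.
#'
#' @param n_subjects cohort size.
#' @param trials_per_block trials per block.
#' @param model generating family member: `"null"` (flat, no jitter),
#'   `"DR"`, `"DR-TH"`, or `"DR-TH-Ter"`.
#' @param dr_pre,th_pre,ter_pre pre-block means of drift rate, threshold
#'   and nondecision time.
#' @param dr_gain_mean,dr_gain_sd subject-level distribution of the total
#'   drift-rate gain from pre to the end of training.
#' @param th_change_mean,th_change_sd,ter_change_mean,ter_change_sd total
#'   trajectory changes for threshold and nondecision time.
#' @param subject_sd between-subject SDs of the pre-block parameters.
#' @param block_jitter block-to-block state jitter SDs for the learned
#'   parameters (zeroed for family members that hold them constant).
#' @param s,zr,szr,st shared across-trial variability parameters (start
#'   point and its range as fractions of threshold).
#' @param sigma within-trial diffusion coefficient convention.
#' @param brainbehavior_corr target correlation between true drift-rate
#'   change and EV glutamate.
#' @param glu_mean,glu_sd,gaba_mean,gaba_sd,naa_mean,naa_sd metabolite
#'   scales (institutional units, water-referenced).
#' @param qc_fail_frac fraction of MRS rows given failing quality metrics.
#' @param timepoints,runs,tr_seconds,true_r,n_voxels,noise_amp,voxel_signal
#'   resting time-series geometry: volumes per run, runs, TR, latent
#'   inter-ROI correlation, voxels per ROI, planted shared-noise
#'   amplitude, and per-voxel signal amplitude (voxel noise has SD 1).
#' @param n_anodal,n_sham stimulation-arm sizes.
#' @param est_noise_sd simulated estimation noise used by
#'   [gen_subject_measures()].
#' @param seed integer seed (below 2^31).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 22, trials_per_block = 100,
                          model = "DR-TH-Ter",
                          dr_pre = 0.07, dr_gain_mean = 0.10, dr_gain_sd = 0.08,
                          th_pre = 0.095, th_change_mean = -0.015,
                          th_change_sd = 0.008,
                          ter_pre = 0.40, ter_change_mean = -0.08,
                          ter_change_sd = 0.02,
                          subject_sd = c(DR = 0.02, TH = 0.008, Ter = 0.03),
                          block_jitter = c(DR = 0.025, TH = 0.008, Ter = 0.06),
                          s = 0.07, zr = 0.5, szr = 0.1, st = 0.10,
                          sigma = 0.1,
                          brainbehavior_corr = -0.5,
                          glu_mean = 8.5, glu_sd = 0.7,
                          gaba_mean = 2.6, gaba_sd = 0.35,
                          naa_mean = 12, naa_sd = 1,
                          qc_fail_frac = 0,
                          timepoints = 825, runs = 2, tr_seconds = 0.727,
                          true_r = 0.3, n_voxels = 40, noise_amp = 1,
                          voxel_signal = 1.5,
                          n_anodal = 18, n_sham = 14,
                          est_noise_sd = 0.05,
                          seed = 1) {
  stopifnot(abs(brainbehavior_corr) < 1, abs(true_r) < 1,
            seed == as.integer(seed), abs(seed) < 2^31)
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  cfg
}

# per-subject per-block generating parameter trajectories; only the
# parameters the generating family member frees vary across blocks
subject_trajectories <- function(cfg, n, learning = TRUE) {
  free <- model_spec(if (cfg$model == "null") "null" else cfg$model)$free_per_block
  nb <- 6
  frac <- c(0, seq_len(5) / 5)   # pre then linear over training blocks
  subj <- vector("list", n)
  for (i in seq_len(n)) {
    base <- c(DR = cfg$dr_pre + rnorm(1, 0, cfg$subject_sd[["DR"]]),
              TH = cfg$th_pre + rnorm(1, 0, cfg$subject_sd[["TH"]]),
              Ter = cfg$ter_pre + rnorm(1, 0, cfg$subject_sd[["Ter"]]))
    gain <- c(DR = rnorm(1, cfg$dr_gain_mean, cfg$dr_gain_sd),
              TH = rnorm(1, cfg$th_change_mean, cfg$th_change_sd),
              Ter = rnorm(1, cfg$ter_change_mean, cfg$ter_change_sd))
    traj <- matrix(NA_real_, nb, 3, dimnames = list(BLOCK_LEVELS, c("DR", "TH", "Ter")))
    for (nm in c("DR", "TH", "Ter")) {
      tr <- rep(base[[nm]], nb)
      if (learning && nm %in% free) {
        tr <- base[[nm]] + gain[[nm]] * frac +
          rnorm(nb, 0, cfg$block_jitter[[nm]])
      }
      traj[, nm] <- tr
    }
    # keep trajectories inside the valid parameter region
    traj[, "TH"] <- pmax(traj[, "TH"], 0.05)
    traj[, "Ter"] <- pmax(traj[, "Ter"], cfg$st / 2 + 0.02)
    subj[[i]] <- traj
  }
  subj
}

#' Generate a behavioral cohort
#'
#' Simulates per-subject, per-block trials from the diffusion model with
#' that subject's parameter trajectory. The true drift-rate change
#' (mean of the last two training blocks minus pre) is recorded as
#' ground truth for the brain-behavior coupling.
#'
#' @param cfg a [cohort_config()].
#' @param group group label attached to every trial.
#' @param learning if `FALSE` all trajectories are flat (used for the
#'   stimulated arm and for null cohorts).
#' @param dt simulation step passed to [simulate_trials()].
#' @return list with `trials` (behavioral table: subject, group, block,
#'   stimulus, response, correct, rt) and `truth` (per-subject true
#'   parameter changes plus the full trajectories as an attribute).
#' @export
gen_behavior_cohort <- function(cfg, group = "main", learning = TRUE,
                                dt = 1e-3) {
  set.seed(cfg$seed)
  n <- if (group == "anodal") cfg$n_anodal
       else if (group == "sham") cfg$n_sham else cfg$n_subjects
  trajs <- subject_trajectories(cfg, n, learning)
  sim_seeds <- matrix(sample.int(.Machine$integer.max, n * 6), n, 6)
  ids <- sprintf("%s%02d", substr(group, 1, 1), seq_len(n))
  rows <- vector("list", n * 6)
  for (i in seq_len(n)) {
    for (b in seq_len(6)) {
      p <- ddm_params(DR = trajs[[i]][b, "DR"], s = cfg$s,
                      TH = trajs[[i]][b, "TH"],
                      z = cfg$zr * trajs[[i]][b, "TH"],
                      sz = cfg$szr * trajs[[i]][b, "TH"],
                      Ter = trajs[[i]][b, "Ter"], st = cfg$st,
                      sigma = cfg$sigma)
      sim <- simulate_trials(p, cfg$trials_per_block, dt = dt,
                             seed = sim_seeds[i, b])
      stim <- sample(c("45", "135"), cfg$trials_per_block, replace = TRUE)
      correct <- as.integer(sim$boundary == "upper")
      resp <- ifelse(correct == 1, stim, ifelse(stim == "45", "135", "45"))
      rows[[(i - 1) * 6 + b]] <- data.frame(
        subject = ids[i], group = group, block = BLOCK_LEVELS[b],
        stimulus = stim, response = resp, correct = correct, rt = sim$rt,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  truth <- data.frame(
    subject = ids,
    delta_dr_true = vapply(trajs, function(tr)
      mean(tr[c("tr4", "tr5"), "DR"]) - tr["pre", "DR"], numeric(1)),
    delta_th_true = vapply(trajs, function(tr)
      mean(tr[c("tr4", "tr5"), "TH"]) - tr["pre", "TH"], numeric(1)),
    delta_ter_true = vapply(trajs, function(tr)
      mean(tr[c("tr4", "tr5"), "Ter"]) - tr["pre", "Ter"], numeric(1)),
    stringsAsFactors = FALSE)
  attr(truth, "trajectories") <- trajs
  list(trials = trials, truth = truth)
}

#' Generate an MRS quantification table coupled to behavior
#'
#' EV glutamate is drawn so its correlation with the supplied true
#' drift-rate changes approaches `brainbehavior_corr` (Gaussian copula on
#' the ground truth, so estimation noise attenuates observed correlations
#' realistically); GABA+ and the DLPFC metabolites are independent.
#' Quality metrics are drawn inside the usual acceptance ranges except
#' for a configurable fraction of planted failures.
#'
#' @param cfg a [cohort_config()].
#' @param delta_dr_true per-subject true drift-rate changes (defines the
#'   subject ids by position).
#' @param subjects subject identifiers.
#' @return data.frame in the MRS table dialect: subject, region,
#'   metabolite, conc, reference, crlb_pct, linewidth_hz, snr, gm, wm,
#'   csf, lipid_flag, gln_fit_ok.
#' @export
gen_mrs_table <- function(cfg, delta_dr_true,
                          subjects = sprintf("m%02d", seq_along(delta_dr_true))) {
  n <- length(delta_dr_true)
  if (n < 4) stop("need at least 4 subjects for a target correlation")
  set.seed(cfg$seed + 1L)
  zd <- as.numeric(scale(delta_dr_true))
  rho <- cfg$brainbehavior_corr
  glu_ev <- cfg$glu_mean + cfg$glu_sd *
    (rho * zd + sqrt(1 - rho^2) * rnorm(n))
  draw <- function(mean, sd) rnorm(n, mean, sd)
  grid <- expand.grid(metabolite = c("Glu", "GABA+", "NAA"),
                      region = c("EV", "DLPFC"), stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    met <- grid$metabolite[g]; reg <- grid$region[g]
    conc <- if (met == "Glu" && reg == "EV") glu_ev
            else if (met == "Glu") draw(cfg$glu_mean, cfg$glu_sd)
            else if (met == "GABA+") draw(cfg$gaba_mean, cfg$gaba_sd)
            else draw(cfg$naa_mean, cfg$naa_sd)
    csf <- runif(n, 0.08, 0.22)
    gm <- (1 - csf) * runif(n, 0.5, 0.65)
    data.frame(subject = subjects, region = reg, metabolite = met,
               conc = pmax(conc, 0.1), reference = "water",
               crlb_pct = runif(n, 3, 9), linewidth_hz = runif(n, 5.5, 9.5),
               snr = runif(n, 15, 40), gm = gm, wm = 1 - csf - gm, csf = csf,
               lipid_flag = FALSE, gln_fit_ok = TRUE,
               stringsAsFactors = FALSE)
  }))
  if (cfg$qc_fail_frac > 0) {
    bad <- which(runif(nrow(out)) < cfg$qc_fail_frac)
    half <- bad[seq_along(bad) %% 2 == 0]
    out$crlb_pct[setdiff(bad, half)] <- runif(length(setdiff(bad, half)), 10.5, 15)
    out$linewidth_hz[half] <- runif(length(half), 10.2, 13)
  }
  rownames(out) <- NULL
  out
}

ar1_series <- function(n, phi, innov) {
  as.numeric(stats::filter(innov, phi, method = "recursive")) /
    sqrt(1 / (1 - phi^2))
}

#' Generate ROI voxel time series with planted structure
#'
#' Two ROIs (EV, DLPFC) whose latent signals correlate at `true_r`, plus
#' an independent control ROI (M1). Voxel time courses are latent signal
#' plus voxel noise, a planted shared noise component (amplitude
#' `noise_amp`) and motion contributions. The component set (signal and
#' noise), noise labels and the 24-column motion regressor expansion are
#' returned for cleanup testing.
#'
#' @param cfg a [cohort_config()].
#' @param n_subjects number of subjects (defaults to the config value).
#' @return list per subject of lists per run with elements `ts` (named
#'   list of voxels-by-time matrices), `components` (time-by-K matrix),
#'   `noise_labels` (indices into components), `motion`
#'   (time-by-24 matrix) and `tr_seconds`.
#' @export
gen_roi_timeseries <- function(cfg, n_subjects = cfg$n_subjects) {
  set.seed(cfg$seed + 2L)
  N <- cfg$timepoints
  lapply(seq_len(n_subjects), function(i) {
    lapply(seq_len(cfg$runs), function(run) {
      r <- cfg$true_r
      e1 <- rnorm(N); e2 <- r * e1 + sqrt(1 - r^2) * rnorm(N)
      lat <- list(EV = ar1_series(N, 0.3, e1),
                  DLPFC = ar1_series(N, 0.3, e2),
                  M1 = ar1_series(N, 0.3, rnorm(N)))
      noise <- sapply(1:3, function(k) ar1_series(N, 0.9, rnorm(N)))
      noise <- scale(noise)
      comps <- cbind(scale(lat$EV + rnorm(N, 0, 0.3)),
                     scale(lat$DLPFC + rnorm(N, 0, 0.3)), noise)
      colnames(comps) <- c("sig1", "sig2", paste0("noise", 1:3))
      mot6 <- sapply(1:6, function(k) cumsum(rnorm(N, 0, 0.02)))
      motion <- motion_expand(mot6)
      mk_roi <- function(latent, shared_noise_amp) {
        t(sapply(seq_len(cfg$n_voxels), function(v) {
          cfg$voxel_signal * latent + rnorm(N) +
            shared_noise_amp * rnorm(1, 1, 0.1) * noise[, 1] +
            mot6 %*% rnorm(6, 0, 0.1)
        }))
      }
      list(ts = list(EV = mk_roi(lat$EV, cfg$noise_amp),
                     DLPFC = mk_roi(lat$DLPFC, cfg$noise_amp),
                     M1 = mk_roi(lat$M1, 0)),
           components = comps, noise_labels = 3:5, motion = motion,
           tr_seconds = cfg$tr_seconds)
    })
  })
}

# translation/rotation series expanded to the usual 24 regressors:
# the 6 series, their squares, their first differences and squared
# differences
motion_expand <- function(mot6) {
  d <- rbind(0, diff(mot6))
  cbind(mot6, mot6^2, d, d^2)
}

#' Generate a stimulated (anodal/sham) cohort
#'
#' The sham arm receives the learning trajectory; the anodal arm a flat
#' drift-rate trajectory (threshold and nondecision trajectories are kept,
#' matching an intervention that selectively disrupts evidence
#' accumulation). With `effect_on = FALSE` both arms are flat, for
#' type-I-error simulation.
#'
#' @param cfg a [cohort_config()].
#' @param effect_on whether the anodal arm's learning is suppressed while
#'   sham learns (`TRUE`) or both arms are flat (`FALSE`).
#' @param dt simulation step.
#' @return list with `trials` (both arms, group column set) and `truth`.
#' @export
gen_tdcs_cohort <- function(cfg, effect_on = TRUE, dt = 1e-3) {
  cfg_an <- cfg
  cfg_an$seed <- cfg$seed + 10L
  if (effect_on) {
    # anodal: drift gain suppressed, state jitter retained
    cfg_an$dr_gain_mean <- 0; cfg_an$dr_gain_sd <- 0.02
    an <- gen_behavior_cohort(cfg_an, group = "anodal", learning = TRUE, dt = dt)
    sh <- gen_behavior_cohort(modify_seed(cfg, 20L), group = "sham",
                              learning = TRUE, dt = dt)
  } else {
    an <- gen_behavior_cohort(cfg_an, group = "anodal", learning = FALSE, dt = dt)
    sh <- gen_behavior_cohort(modify_seed(cfg, 20L), group = "sham",
                              learning = FALSE, dt = dt)
  }
  list(trials = rbind(an$trials, sh$trials),
       truth = rbind(an$truth, sh$truth))
}

modify_seed <- function(cfg, inc) {
  cfg$seed <- cfg$seed + as.integer(inc)
  cfg
}

#' Subject-level measures for association-stage simulation
#'
#' Draws per-subject true drift-rate and threshold changes, adds
#' estimation noise of SD `est_noise_sd`, and couples EV glutamate to the
#' truth at `brainbehavior_corr` (GABA+ independent). Used to study the
#' operating characteristics of the association battery without refitting
#' the diffusion model.
#'
#' @param cfg a [cohort_config()].
#' @return data.frame with columns subject, d_dr, d_th, glu, gaba.
#' @export
gen_subject_measures <- function(cfg) {
  set.seed(cfg$seed + 3L)
  n <- cfg$n_subjects
  d_dr_true <- rnorm(n, cfg$dr_gain_mean, cfg$dr_gain_sd)
  d_th_true <- rnorm(n, cfg$th_change_mean, cfg$th_change_sd)
  rho <- cfg$brainbehavior_corr
  glu <- cfg$glu_mean + cfg$glu_sd *
    (rho * as.numeric(scale(d_dr_true)) + sqrt(1 - rho^2) * rnorm(n))
  data.frame(subject = sprintf("m%02d", seq_len(n)),
             d_dr = d_dr_true + rnorm(n, 0, cfg$est_noise_sd),
             d_th = d_th_true + rnorm(n, 0, cfg$est_noise_sd / 2),
             glu = glu, gaba = rnorm(n, cfg$gaba_mean, cfg$gaba_sd),
             stringsAsFactors = FALSE)
}
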