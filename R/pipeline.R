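# Orchestration: the full analysis sequence over a simulated (or
# supplied) cohort -- screening, constrained model fitting and selection,
# learning deltas, MRS preparation, connectivity, the association
# battery, and the stimulation-arm ANOVA.

#' Pipeline configuration
#'
#' @param preset `"main-study"` (behavior + MRS + connectivity +
#'   associations) or `"tdcs"` (two-arm behavioral experiment).
#' @param cohort a [cohort_config()]; its seed drives every stage.
#' @param behavior_path,mrs_path optional file inputs replacing the
#'   simulated tables (behavioral CSV dialect, MRS TSV dialect).
#' @param models model family members to fit.
#' @param rules screening rules ([screen_rules()]).
#' @param crlb_max,linewidth_max MRS quality thresholds.
#' @param min_overlap group-mask overlap fraction.
#' @param cutoff_hz connectivity high-pass cutoff.
#' @param fit_ctrl a [fit_control()].
#' @param out_dir optional directory for tidy TSV outputs.
#' @export
pipeline_config <- function(preset = c("main-study", "tdcs"),
                            cohort = cohort_config(),
                            behavior_path = NULL, mrs_path = NULL,
                            models = MODEL_NAMES,
                            rules = screen_rules(),
                            crlb_max = 10, linewidth_max = 10,
                            min_overlap = 0.5, cutoff_hz = 0.01,
                            fit_ctrl = fit_control(),
                            out_dir = NULL) {
  preset <- match.arg(preset)
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes screening, model fitting over the family, group-level model
#' selection, learning deltas, MRS preparation, connectivity and the
#' association battery (main-study preset), or the two-arm accuracy /
#' parameter ANOVAs (tdcs preset). Deterministic given the cohort seed.
#' Writes tidy TSVs plus a run log when `out_dir` is set; partial
#' results are written before a failing stage aborts.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (see elements `screening`, `selection`,
#'   `deltas`, `mrs`, `connectivity`, `associations`, `tdcs`, `log`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config$cohort
  log <- list()
  note <- function(stg, subject, reason)
    log[[length(log) + 1]] <<- data.frame(stage = stg, subject = subject,
                                          reason = reason,
                                          stringsAsFactors = FALSE)
  if (config$preset == "tdcs") {
    res <- stage("tdcs", run_tdcs(config))
    res$log <- if (length(log)) do.call(rbind, log) else NULL
    write_outputs(res, config)
    return(res)
  }

  trials <- stage("input", {
    if (!is.null(config$behavior_path)) read_behavior(config$behavior_path)
    else {
      coh <- gen_behavior_cohort(cfg)
      attr(coh$trials, "truth") <- coh$truth
      coh$trials
    }
  })
  if (nrow(trials) == 0) stop("pipeline stage 'screening' failed: empty behavioral table")
  truth <- attr(trials, "truth")

  subjects <- unique(trials$subject)
  screening <- stage("screening", {
    keep <- logical(length(subjects))
    for (i in seq_along(subjects)) {
      sc <- screen_subject(trials[trials$subject == subjects[i], ], config$rules)
      keep[i] <- sc$include
      if (!sc$include)
        note("screening", subjects[i], paste(sc$reasons, collapse = "; "))
    }
    data.frame(subject = subjects, included = keep, stringsAsFactors = FALSE)
  })
  retained <- subjects[screening$included]

  fits <- stage("fit", {
    out <- lapply(retained, function(s)
      fit_all_models(trials[trials$subject == s, ], sigma = cfg$sigma,
                     control = config$fit_ctrl, seed = cfg$seed))
    names(out) <- retained
    out
  })
  selection <- stage("select", select_model(fits))

  deltas <- stage("deltas", {
    rows <- list()
    for (s in retained) {
      f <- fits[[s]][[selection$model]]
      if (!isTRUE(f$converged)) { note("deltas", s, "fit not converged"); next }
      sm <- block_summaries(trials[trials$subject == s, ])
      rows[[s]] <- cbind(subject = s, learning_deltas(f, sm))
    }
    do.call(rbind, rows)
  })

  mrs <- stage("mrs", {
    raw <- if (!is.null(config$mrs_path)) read_mrs_table(config$mrs_path)
           else {
             td <- if (!is.null(truth)) truth$delta_dr_true
                   else rep(0, length(retained))
             gen_mrs_table(cfg, td, subjects = if (!is.null(truth))
               truth$subject else retained)
           }
    mrs_prepare(raw, crlb_max = config$crlb_max,
                linewidth_max = config$linewidth_max)
  })

  connectivity <- stage("connect", {
    ts <- gen_roi_timeseries(cfg, n_subjects = length(retained))
    z <- vapply(ts, function(runs)
      subject_connectivity(runs, cutoff_hz = config$cutoff_hz)$mean_z,
      numeric(1))
    data.frame(subject = retained, pair = "EV-DLPFC", mean_z = z,
               stringsAsFactors = FALSE)
  })

  associations <- stage("associate", {
    ev_glu <- with(mrs$measures,
                   setNames(conc[region == "EV" & metabolite == "Glu"],
                            subject[region == "EV" & metabolite == "Glu"]))
    ev_gaba <- with(mrs$measures,
                    setNames(conc[region == "EV" & metabolite == "GABA+"],
                             subject[region == "EV" & metabolite == "GABA+"]))
    tab <- data.frame(subject = deltas$subject,
                      d_dr = deltas$d_DR, d_th = deltas$d_TH,
                      glu = unname(ev_glu[deltas$subject]),
                      gaba = unname(ev_gaba[deltas$subject]),
                      conn_z = connectivity$mean_z[
                        match(deltas$subject, connectivity$subject)],
                      stringsAsFactors = FALSE)
    tab <- tab[stats::complete.cases(tab), ]
    list(table = tab,
         behavior = association_battery(tab, c("glu", "gaba", "conn_z"),
                                        c("d_dr", "d_th")),
         neurochemistry = association_battery(tab, "conn_z",
                                              c("glu", "gaba")))
  })

  res <- list(trials = trials, screening = screening, fits = fits,
              selection = selection, deltas = deltas, mrs = mrs,
              connectivity = connectivity, associations = associations,
              log = if (length(log)) do.call(rbind, log) else NULL)
  write_outputs(res, config)
  res
}

run_tdcs <- function(config) {
  coh <- gen_tdcs_cohort(config$cohort)
  subjects <- unique(coh$trials$subject)
  acc <- do.call(rbind, lapply(subjects, function(s) {
    tr <- coh$trials[coh$trials$subject == s, ]
    sm <- block_summaries(tr)
    mb <- max_training_block(sm)
    data.frame(subject = s, group = tr$group[1],
               pre = sm$accuracy[sm$block == "pre"],
               post = sm$accuracy[sm$block == mb], stringsAsFactors = FALSE)
  }))
  list(trials = coh$trials, accuracy = acc,
       anova_accuracy = rm_anova_2x2(acc$group, acc$pre, acc$post))
}

write_outputs <- function(res, config) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(obj, name) {
    if (!is.null(obj))
      write.table(obj, file.path(config$out_dir, paste0(name, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wt(res$screening, "screening")
  if (!is.null(res$selection))
    wt(data.frame(model = names(res$selection$mean_bic),
                  mean_bic = res$selection$mean_bic,
                  selected = names(res$selection$mean_bic) ==
                    res$selection$model),
       "mean_bic")
  wt(res$deltas, "deltas")
  wt(res$mrs$measures, "mrs_measures")
  wt(res$mrs$log, "mrs_exclusions")
  wt(res$connectivity, "connectivity")
  wt(res$associations$behavior, "associations_behavior")
  wt(res$associations$neurochemistry, "associations_neurochemistry")
  wt(res$accuracy, "tdcs_accuracy")
  wt(res$anova_accuracy, "tdcs_anova")
  wt(res$log, "exclusion_log")
  invisible(NULL)
}
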