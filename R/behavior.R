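# Trial-table QC, per-block accuracy, max-training-block selection and
# learning deltas.

#' Read / write the behavioral CSV dialect
#'
#' Header `subject,group,block,stimulus,response,correct,rt`; block labels
#' `pre,tr1..tr5`; RT in seconds; UTF-8.
#'
#' @param path file path.
#' @export
read_behavior <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "block", "stimulus", "response", "correct", "rt")
  if (!all(need %in% names(df)))
    stop("behavioral table must have columns: ", paste(need, collapse = ","))
  if (!all(df$block %in% BLOCK_LEVELS)) stop("unknown block labels")
  if (any(df$rt <= 0)) stop("RTs must be positive")
  df
}

#' @rdname read_behavior
#' @param trials behavioral table.
#' @export
write_behavior <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-block accuracy summaries for one subject
#'
#' @param trials one subject's trials (`block`, `correct`, `rt`).
#' @return data.frame with columns `block`, `n_trials`, `accuracy`.
#' @export
block_summaries <- function(trials) {
  blocks <- intersect(BLOCK_LEVELS, unique(as.character(trials$block)))
  do.call(rbind, lapply(blocks, function(b) {
    tb <- trials[trials$block == b, ]
    data.frame(block = b, n_trials = nrow(tb),
               accuracy = mean(tb$correct == 1), stringsAsFactors = FALSE)
  }))
}

#' Screening rules
#'
#' @param max_pre_accuracy exclude when pre-block accuracy exceeds this
#'   (high starting performance leaves no room to learn).
#' @param fast_rt_s RT below which a trial counts as implausibly fast.
#' @param max_fast_frac exclude when the fraction of fast trials exceeds
#'   this (the aggregation into a proportion rule is a package choice).
#' @export
screen_rules <- function(max_pre_accuracy = 0.75, fast_rt_s = 0.2,
                         max_fast_frac = 0.10) {
  list(max_pre_accuracy = max_pre_accuracy, fast_rt_s = fast_rt_s,
       max_fast_frac = max_fast_frac)
}

#' Screen one subject's trial table
#'
#' Excludes subjects with high starting performance (pre-block accuracy
#' above the threshold, strictly) or with too many implausibly fast
#' responses. Idempotent and independent of other subjects.
#'
#' @param trials one subject's trials.
#' @param rules a [screen_rules()] list.
#' @return list with `include` (flag) and `reasons` (character).
#' @export
screen_subject <- function(trials, rules = screen_rules()) {
  pre <- trials[trials$block == "pre", ]
  if (nrow(pre) == 0) stop("pre block missing")
  reasons <- character(0)
  if (mean(pre$correct == 1) > rules$max_pre_accuracy)
    reasons <- c(reasons, "high starting performance")
  if (mean(trials$rt < rules$fast_rt_s) > rules$max_fast_frac)
    reasons <- c(reasons, "atypical response times")
  list(include = length(reasons) == 0, reasons = reasons)
}

#' Max-training block
#'
#' The block with the higher accuracy among the last two training blocks
#' (accounting for potential end-of-training fatigue); ties go to the
#' later block.
#'
#' @param summaries a [block_summaries()] table.
#' @return `"tr4"` or `"tr5"`.
#' @export
max_training_block <- function(summaries) {
  a4 <- summaries$accuracy[summaries$block == "tr4"]
  a5 <- summaries$accuracy[summaries$block == "tr5"]
  if (length(a4) != 1 || length(a5) != 1) stop("tr4 and tr5 must be present")
  if (a4 > a5) "tr4" else "tr5"
}

#' Learning deltas (max-training minus pre)
#'
#' Changes in accuracy and in the fitted drift rate, threshold and
#' nondecision time between the max-training block and the pre block.
#'
#' @param fit a converged `ddm_fit` for the selected model.
#' @param summaries a [block_summaries()] table for the same subject.
#' @return data.frame row: `max_block`, `d_accuracy`, `d_DR`, `d_TH`,
#'   `d_Ter`.
#' @export
learning_deltas <- function(fit, summaries) {
  if (!isTRUE(fit$converged)) stop("fit did not converge; subject dropped")
  mb <- max_training_block(summaries)
  pa <- fit$params[["pre"]]; pm <- fit$params[[mb]]
  if (is.null(pa) || is.null(pm)) stop("fit lacks pre or max block parameters")
  data.frame(max_block = mb,
             d_accuracy = summaries$accuracy[summaries$block == mb] -
               summaries$accuracy[summaries$block == "pre"],
             d_DR = pm$DR - pa$DR, d_TH = pm$TH - pa$TH,
             d_Ter = pm$Ter - pa$Ter, stringsAsFactors = FALSE)
}
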