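# Post-processing of quantified MRS concentrations: quality filtering,
# CSF tissue correction and reference switching. Concentrations arrive
# pre-quantified (LCModel-style table); no spectral fitting happens here.

MRS_COLS <- c("subject", "region", "metabolite", "conc", "reference",
              "crlb_pct", "linewidth_hz", "snr", "gm", "wm", "csf",
              "lipid_flag", "gln_fit_ok")

#' Read / write the MRS table dialect
#'
#' Tab-separated with header `subject, region, metabolite, conc,
#' reference, crlb_pct, linewidth_hz, snr, gm, wm, csf, lipid_flag,
#' gln_fit_ok`.
#'
#' @param path file path.
#' @export
read_mrs_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(MRS_COLS %in% names(df)))
    stop("MRS table must have columns: ", paste(MRS_COLS, collapse = ","))
  bad <- abs(df$gm + df$wm + df$csf - 1) > 0.01
  if (any(bad)) stop("tissue fractions must sum to 1 within 0.01")
  df
}

#' @rdname read_mrs_table
#' @param measures MRS table.
#' @export
write_mrs_table <- function(measures, path) {
  write.table(measures, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' CSF tissue correction
#'
#' Divides a concentration by one minus the CSF fraction, compensating
#' for the metabolite-free fraction of the voxel. Linear in the
#' concentration; corrected values are never below the raw value.
#'
#' @param concentration concentration (any reference).
#' @param csf_frac CSF fraction in `[0, 1)`.
#' @export
csf_correct <- function(concentration, csf_frac) {
  if (any(csf_frac < 0 | csf_frac >= 1))
    stop("csf_frac must be in [0, 1)")
  concentration / (1 - csf_frac)
}

#' Switch the concentration reference
#'
#' Water mode returns the stored water-referenced concentrations
#' unchanged; NAA mode divides each metabolite by the NAA concentration
#' quantified in the same subject and region (voxel).
#'
#' @param measures MRS table (water-referenced).
#' @param target `"water"` or `"NAA"`.
#' @return the table with `conc` and `reference` updated (NAA rows are
#'   kept, re-expressed as 1 under NAA referencing).
#' @export
reference_concentration <- function(measures, target = c("water", "NAA")) {
  target <- match.arg(target)
  if (target == "water") return(measures)
  key <- paste(measures$subject, measures$region)
  naa <- measures[measures$metabolite == "NAA", ]
  naa_conc <- setNames(naa$conc, paste(naa$subject, naa$region))
  if (any(!key %in% names(naa_conc)))
    stop("missing NAA row for some subject/region")
  if (any(naa_conc[key] <= 0)) stop("NAA concentration must be positive")
  measures$conc <- measures$conc / naa_conc[key]
  measures$reference <- "NAA"
  measures
}

#' Quality filtering of MRS rows
#'
#' Removes rows whose CRLB or linewidth exceed the thresholds, rows
#' flagged for lipid contamination, and (when the glutamine-fit control
#' analysis is active) rows whose Gln fit failed. Idempotent; the
#' exclusion log accounts for every removed row.
#'
#' @param measures MRS table.
#' @param crlb_max maximum acceptable CRLB (percent of the estimate).
#' @param linewidth_max maximum acceptable linewidth (Hz).
#' @param exclude_lipid drop lipid-contaminated rows.
#' @param exclude_poor_gln drop rows with a failed glutamine fit
#'   (control analysis).
#' @return list with `retained` (filtered table) and `log` (data.frame
#'   subject, region, metabolite, reason).
#' @export
mrs_quality_filter <- function(measures, crlb_max = 10, linewidth_max = 10,
                               exclude_lipid = TRUE,
                               exclude_poor_gln = FALSE) {
  reason <- rep(NA_character_, nrow(measures))
  mark <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- mark(measures$crlb_pct >= crlb_max, "CRLB above threshold")
  reason <- mark(measures$linewidth_hz >= linewidth_max,
                 "linewidth above threshold")
  if (exclude_lipid)
    reason <- mark(as.logical(measures$lipid_flag), "lipid contamination")
  if (exclude_poor_gln)
    reason <- mark(!as.logical(measures$gln_fit_ok), "poor Gln fit")
  drop <- !is.na(reason)
  list(retained = measures[!drop, , drop = FALSE],
       log = data.frame(subject = measures$subject[drop],
                        region = measures$region[drop],
                        metabolite = measures$metabolite[drop],
                        reason = reason[drop], stringsAsFactors = FALSE))
}

#' Prepare MRS measures for association analysis
#'
#' Applies the quality filter, optionally switches the reference, then
#' CSF-corrects the retained concentrations (correction applied to the
#' referenced value).
#'
#' @inheritParams mrs_quality_filter
#' @param reference target reference.
#' @return list with `measures` (filtered, referenced, CSF-corrected) and
#'   `log`.
#' @export
mrs_prepare <- function(measures, reference = "water", crlb_max = 10,
                        linewidth_max = 10, exclude_lipid = TRUE,
                        exclude_poor_gln = FALSE) {
  flt <- mrs_quality_filter(measures, crlb_max, linewidth_max,
                            exclude_lipid, exclude_poor_gln)
  out <- reference_concentration(flt$retained, reference)
  out$conc <- csf_correct(out$conc, out$csf)
  list(measures = out, log = flt$log)
}
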