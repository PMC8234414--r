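# In-cell ELISA pMLC normalisation and simple blot densitometry ratios.
#
# The plate assay reads absorbance at 450 nm for phosphorylated MLC and total
# MLC wells per condition (plus blanks). The per-condition phosphorylation
# level is the blank-subtracted pMLC/total-MLC ratio of well means; percent
# changes versus control then use the study's percent-change convention.

#' ELISA plate of OD450 readings
#'
#' @param wells Data frame with columns `well` (well id), `analyte` (one of
#'   `"pMLC"`, `"totalMLC"`, `"blank"`), `condition` (label; ignored for
#'   blanks), `od450` (non-negative finite absorbance).
#' @return An object of class `elisa_plate` (validated data frame).
#' @export
elisa_plate <- function(wells) {
  req <- c("well", "analyte", "condition", "od450")
  if (!is.data.frame(wells) || !all(req %in% names(wells)))
    cf_stop("`wells` must have columns well, analyte, condition, od450",
            "clotforce_invalid_plate")
  if (!all(wells$analyte %in% c("pMLC", "totalMLC", "blank")))
    cf_stop("analyte must be one of pMLC, totalMLC, blank",
            "clotforce_invalid_plate")
  .check_numeric_vector(wells$od450, "od450", class = "clotforce_invalid_plate")
  if (any(wells$od450 < 0))
    cf_stop("od450 must be non-negative", "clotforce_invalid_plate")
  conds <- unique(wells$condition[wells$analyte != "blank"])
  for (cc in conds) {
    has_p <- any(wells$analyte == "pMLC" & wells$condition == cc)
    has_t <- any(wells$analyte == "totalMLC" & wells$condition == cc)
    if (!has_p || !has_t)
      cf_stop(sprintf("condition '%s' needs both pMLC and totalMLC wells", cc),
              "clotforce_invalid_plate")
  }
  structure(as.data.frame(wells), class = c("elisa_plate", "data.frame"))
}

#' Conditions present on a plate
#' @param plate An [elisa_plate()].
#' @return Character vector of non-blank condition labels.
#' @export
plate_conditions <- function(plate) {
  unique(plate$condition[plate$analyte != "blank"])
}

#' Normalised pMLC ratio for one condition
#'
#' `ratio = (mean(OD_pMLC) - mean(OD_blank)) / (mean(OD_totalMLC) -
#' mean(OD_blank))`. A plate without blank wells uses a blank of 0. A
#' denominator at or below zero (total-MLC signal not above background) is a
#' below-background error.
#'
#' @param plate An [elisa_plate()].
#' @param condition Condition label.
#' @return Normalised pMLC/total-MLC ratio (dimensionless, > 0).
#' @export
normalize_pmlc <- function(plate, condition) {
  stopifnot(inherits(plate, "elisa_plate"))
  if (!condition %in% plate_conditions(plate))
    cf_stop(sprintf("condition '%s' not on plate", condition),
            "clotforce_lookup_error")
  blank_od <- plate$od450[plate$analyte == "blank"]
  blank <- if (length(blank_od)) mean(blank_od) else 0
  p <- mean(plate$od450[plate$analyte == "pMLC" &
                          plate$condition == condition]) - blank
  t <- mean(plate$od450[plate$analyte == "totalMLC" &
                          plate$condition == condition]) - blank
  if (t <= 0)
    cf_stop("total-MLC signal does not exceed background",
            "clotforce_below_background")
  if (p <= 0)
    cf_stop("pMLC signal does not exceed background",
            "clotforce_below_background")
  p / t
}

#' Percent change in normalised pMLC versus control
#'
#' Applies [percent_change()] to the normalised ratios of the two conditions.
#'
#' @inheritParams normalize_pmlc
#' @param control Control condition label (default `"control"`).
#' @return Signed percent change in pMLC.
#' @export
phospho_percent_change <- function(plate, condition, control = "control") {
  percent_change(normalize_pmlc(plate, condition),
                 normalize_pmlc(plate, control))
}

#' Per-condition pMLC summary table for a plate
#'
#' @inheritParams phospho_percent_change
#' @return Data frame with columns `condition`, `pmlc_ratio`,
#'   `pct_change_vs_control` (control first, with percent change 0).
#' @export
plate_summary <- function(plate, control = "control") {
  conds <- plate_conditions(plate)
  if (!control %in% conds)
    cf_stop(sprintf("control condition '%s' not on plate", control),
            "clotforce_config_error")
  conds <- c(control, setdiff(conds, control))
  ratios <- vapply(conds, function(cc) normalize_pmlc(plate, cc), numeric(1))
  data.frame(condition = conds, pmlc_ratio = unname(ratios),
             pct_change_vs_control =
               vapply(unname(ratios), percent_change, numeric(1),
                      control_mean = ratios[[1L]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Western-blot lane intensities
#'
#' @param condition Condition label.
#' @param pmlc_intensity pMLC band intensity (> 0).
#' @param total_mlc_intensity Total-MLC band intensity (> 0).
#' @param loading_intensity Loading-control (beta-actin) band intensity (> 0).
#' @return An object of class `blot_lane`.
#' @export
blot_lane <- function(condition, pmlc_intensity, total_mlc_intensity,
                      loading_intensity) {
  for (nm in c("pmlc_intensity", "total_mlc_intensity", "loading_intensity"))
    .check_scalar_number(get(nm), nm, positive = TRUE,
                         class = "clotforce_invalid_lane")
  structure(list(condition = condition, pmlc_intensity = pmlc_intensity,
                 total_mlc_intensity = total_mlc_intensity,
                 loading_intensity = loading_intensity),
            class = "blot_lane")
}

#' Relative pMLC band intensity for a blot lane
#'
#' Normalises the pMLC band to the beta-actin loading control by default;
#' normalisation to the total-MLC band is available as an option (the total
#' band can equally serve to calibrate the change in phosphorylation).
#'
#' @param lane A [blot_lane()].
#' @param reference `"actin"` (default) or `"total_mlc"`.
#' @return Relative intensity (dimensionless).
#' @export
blot_ratio <- function(lane, reference = c("actin", "total_mlc")) {
  stopifnot(inherits(lane, "blot_lane"))
  reference <- match.arg(reference)
  denom <- if (reference == "actin") lane$loading_intensity
           else lane$total_mlc_intensity
  lane$pmlc_intensity / denom
}
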