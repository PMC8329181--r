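# Efficiency-corrected relative qPCR quantification.
#
# Efficiency is the per-cycle amplification factor (2 = perfect doubling).
# The efficiency-corrected relative expression is the Pfaffl-type ratio
# E_target^(-Ct_target) / E_ref^(-Ct_ref); with both efficiencies 2 it
# reduces exactly to 2^-dCt, and the fold change between two conditions to
# the classic 2^-ddCt.

#' Parse an amplification efficiency
#'
#' Accepts the amplification factor directly (1..2), a percent string such
#' as `"95%"` (-> 1.95), or a bare percentage > 2 (95 -> 1.95). Values
#' outside [1, 2] after conversion are flagged with a warning.
#'
#' @param x numeric or character vector.
#' @return Numeric amplification factor(s).
#' @export
parse_efficiency <- function(x) {
  if (is.character(x)) {
    pct <- grepl("%\\s*$", x)
    v <- as.numeric(sub("%\\s*$", "", x))
    v[pct] <- 1 + v[pct] / 100
    x <- v
  }
  x <- as.numeric(x)
  x[!is.na(x) & x > 2] <- 1 + x[!is.na(x) & x > 2] / 100
  if (any(!is.na(x) & (x < 1 | x > 2))) {
    warning("efficiency outside [1, 2] after conversion")
  }
  x
}

#' Efficiency-corrected relative expression (single-sample ratio)
#'
#' ratio = eff_target^(-ct_target) / eff_ref^(-ct_ref). With both
#' efficiencies equal to 2 this is exactly 2^-(ct_target - ct_ref).
#'
#' @param ct_target,ct_ref threshold cycles.
#' @param eff_target,eff_ref per-cycle amplification factors in [1, 2].
#' @return Positive numeric ratio.
#' @export
#' @examples
#' ratio_dct(20, 18, 2, 2) # 0.25
ratio_dct <- function(ct_target, ct_ref, eff_target = 2, eff_ref = 2) {
  stopifnot(all(ct_target > 0), all(ct_ref > 0))
  eff_target <- parse_efficiency(eff_target)
  eff_ref <- parse_efficiency(eff_ref)
  # log-space guard against overflow with efficiency near 1 and large Ct
  exp(-ct_target * log(eff_target) + ct_ref * log(eff_ref))
}

mean_ct <- function(measurements, gene) {
  m <- measurements[measurements$target == gene, , drop = FALSE]
  if (!nrow(m)) stop("no measurements for gene '", gene, "'")
  # technical replicates averaged on the Ct scale
  list(ct = mean(m$ct), eff = parse_efficiency(m$efficiency[1]))
}

#' Fold change between conditions (delta-delta-Ct)
#'
#' Computes the fold change of `target` in the sample condition relative to
#' the control condition, normalized to `reference_gene`. With
#' `efficiency_correction = TRUE` (default) the ratio-of-ratios Pfaffl form
#' is used; otherwise the classic 2^-ddCt. Technical replicates are
#' averaged on the Ct scale.
#'
#' @param sample_measurements,control_measurements data frames with columns
#'   `target`, `ct`, `efficiency`.
#' @param reference_gene name of the normalizer gene.
#' @param target target gene; inferred when the table has exactly one
#'   non-reference target.
#' @param efficiency_correction use per-assay efficiencies.
#' @return Positive numeric fold change.
#' @export
fold_change_ddct <- function(sample_measurements, control_measurements,
                             reference_gene, target = NULL,
                             efficiency_correction = TRUE) {
  for (m in list(sample_measurements, control_measurements)) {
    if (!reference_gene %in% m$target) {
      stop("reference gene '", reference_gene, "' missing from measurements")
    }
  }
  if (is.null(target)) {
    others <- setdiff(unique(c(sample_measurements$target,
                               control_measurements$target)), reference_gene)
    if (length(others) != 1L) {
      stop("cannot infer target; candidates: ", paste(others, collapse = ", "))
    }
    target <- others
  }
  ts <- mean_ct(sample_measurements, target)
  rs <- mean_ct(sample_measurements, reference_gene)
  tc <- mean_ct(control_measurements, target)
  rc <- mean_ct(control_measurements, reference_gene)
  if (!efficiency_correction) {
    ts$eff <- rs$eff <- tc$eff <- rc$eff <- 2
  }
  ratio_dct(ts$ct, rs$ct, ts$eff, rs$eff) /
    ratio_dct(tc$ct, rc$ct, tc$eff, rc$eff)
}

#' Scale relative expression to a calibrator
#'
#' Divides every ratio by the calibrator's ratio so the calibrator maps to
#' exactly 1 (e.g. adjusting all transcript-variant levels to a variant
#' arbitrarily set to one).
#'
#' @param ratios data frame with columns `id` and `ratio`, or a named
#'   numeric vector.
#' @param calibrator_id id of the calibrator entry.
#' @return Same shape as the input with calibrated ratios and a
#'   `calibrator` attribute.
#' @export
#' @examples
#' calibrate(c(v1 = 0.2, v2 = 1.0), "v1") # v1 = 1, v2 = 5
calibrate <- function(ratios, calibrator_id) {
  if (is.numeric(ratios)) {
    if (!calibrator_id %in% names(ratios)) stop("calibrator absent")
    cal <- ratios[[calibrator_id]]
    if (!is.finite(cal) || cal <= 0) stop("calibrator ratio must be > 0")
    out <- ratios / cal
  } else {
    i <- match(calibrator_id, ratios$id)
    if (is.na(i)) stop("calibrator absent")
    cal <- ratios$ratio[i]
    if (!is.finite(cal) || cal <= 0) stop("calibrator ratio must be > 0")
    out <- ratios
    out$ratio <- out$ratio / cal
  }
  attr(out, "calibrator") <- calibrator_id
  out
}

#' Compare replicate fold changes between two groups
#'
#' Routine support utility: a two-tailed unpaired t-test on log2 fold
#' changes (the scale on which qPCR ratios are approximately normal).
#'
#' @param fold_a,fold_b positive numeric vectors of replicate fold changes.
#' @param conf_level confidence level.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_fold_changes <- function(fold_a, fold_b, conf_level = 0.95) {
  stopifnot(all(fold_a > 0), all(fold_b > 0))
  stats::t.test(log2(fold_a), log2(fold_b), alternative = "two.sided",
                conf.level = conf_level)
}

#' Read a qPCR measurement table
#'
#' Tab-separated with header columns `sample`, `target`, `ct`,
#' `efficiency` (amplification factor or percent dialect) and optionally
#' `replicate`.
#'
#' @param path file path.
#' @return A validated data frame with `efficiency` parsed to the
#'   amplification-factor scale.
#' @export
read_qpcr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample", "target", "ct", "efficiency")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df$ct <- as.numeric(df$ct)
  if (any(!is.finite(df$ct) | df$ct <= 0)) stop("Ct values must be positive")
  df$efficiency <- parse_efficiency(df$efficiency)
  df
}
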