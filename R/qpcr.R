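# Validation-arm arithmetic: 2^-ddCt relative quantification and the
# Bax/Bcl-2 median-fluorescence-intensity ratio.

#' Relative quantification by the 2^-ddCt method
#'
#' Computes the group-versus-group expression fold change of a target assay
#' from replicate Ct values, normalized to one or more reference assays
#' (e.g. RNU6B and RNU44):
#'
#' * per (sample, assay), Ct is the mean of the replicates;
#' * per sample, the reference Ct is the arithmetic mean over the reference
#'   assays (equivalent to the geometric mean of reference quantities);
#' * dCt = Ct(target) - Ct(reference), averaged within each group;
#' * ddCt = dCt(test group) - dCt(calibrator group);
#' * fold = 2^-ddCt.
#'
#' The fold change is flagged significant under the two-sided rule
#' `max(fold, 1/fold) >= fold_threshold` (boundary inclusive): a 1.5-fold
#' change in either direction counts.
#'
#' @param samples Replicate-level Ct tibble from [read_qpcr()] (columns
#'   `sample_id`, `group`, `assay`, `replicate`, `ct`).
#' @param target_assay Assay whose fold change is quantified.
#' @param reference_assays Reference (housekeeping) assays; default
#'   `c("RNU6B", "RNU44")`.
#' @param group_test,group_calibrator Group labels contrasted (e.g. `"XX"`
#'   vs `"XY"`).
#' @param fold_threshold Two-sided significance threshold on the fold
#'   change (default 1.5).
#' @param per_sample Also return per-sample fold changes relative to the
#'   calibrator group mean dCt.
#' @return An object of class `xci_fold_change`: a list with `assay`,
#'   `group_test`, `group_calibrator`, `delta_ct_test`, `delta_ct_cal`,
#'   `ddct`, `fold`, `significant`, `fold_threshold`, and (when
#'   `per_sample = TRUE`) a `per_sample` tibble.
#' @export
delta_delta_ct <- function(samples, target_assay,
                           reference_assays = c("RNU6B", "RNU44"),
                           group_test = "XX", group_calibrator = "XY",
                           fold_threshold = 1.5, per_sample = FALSE) {
  needed <- c(target_assay, reference_assays)
  sub <- samples[samples$assay %in% needed, , drop = FALSE]
  ctm <- sub |>
    dplyr::group_by(.data$sample_id, .data$group, .data$assay) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")
  # every sample needs the target and all reference assays
  by_sample <- split(ctm, ctm$sample_id)
  for (sid in names(by_sample)) {
    miss <- setdiff(needed, by_sample[[sid]]$assay)
    if (length(miss) > 0) {
      stop("sample '", sid, "' is missing assay(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  dct <- vapply(by_sample, function(d) {
    d$ct[d$assay == target_assay] - mean(d$ct[d$assay %in% reference_assays])
  }, numeric(1))
  grp <- vapply(by_sample, function(d) d$group[1], character(1))
  if (!any(grp == group_test)) {
    stop("no samples in test group '", group_test, "'", call. = FALSE)
  }
  if (!any(grp == group_calibrator)) {
    stop("no samples in calibrator group '", group_calibrator, "'", call. = FALSE)
  }
  delta_ct_test <- mean(dct[grp == group_test])
  delta_ct_cal <- mean(dct[grp == group_calibrator])
  ddct <- delta_ct_test - delta_ct_cal
  fold <- 2^(-ddct)
  res <- list(
    assay = target_assay,
    group_test = group_test,
    group_calibrator = group_calibrator,
    delta_ct_test = delta_ct_test,
    delta_ct_cal = delta_ct_cal,
    ddct = ddct,
    fold = fold,
    significant = max(fold, 1 / fold) >= fold_threshold,
    fold_threshold = fold_threshold
  )
  if (per_sample) {
    res$per_sample <- tibble::tibble(
      sample_id = names(dct),
      group = unname(grp),
      delta_ct = unname(dct),
      fold_vs_calibrator = 2^(-(unname(dct) - delta_ct_cal))
    )
  }
  structure(res, class = "xci_fold_change")
}

#' @export
print.xci_fold_change <- function(x, ...) {
  cat(sprintf("2^-ddCt fold change: %s, %s vs %s\n",
              x$assay, x$group_test, x$group_calibrator))
  cat(sprintf("  dCt(%s) = %.4f, dCt(%s) = %.4f, ddCt = %.4f\n",
              x$group_test, x$delta_ct_test,
              x$group_calibrator, x$delta_ct_cal, x$ddct))
  cat(sprintf("  fold = %.4f (%ssignificant at the %.2g-fold rule)\n",
              x$fold, if (x$significant) "" else "not ", x$fold_threshold))
  invisible(x)
}

#' Median-fluorescence-intensity ratio
#'
#' Exact quotient of two MFI measurements, e.g. the Bax/Bcl-2 ratio used as
#' an apoptotic-proneness index. Both operands must be positive.
#'
#' @param numerator,denominator Positive MFI values (arbitrary units).
#' @param numerator_label,denominator_label Protein names.
#' @return A list of class `xci_mfi_ratio` with the labels, operands and
#'   `ratio`.
#' @export
mfi_ratio <- function(numerator, denominator,
                      numerator_label = "Bax", denominator_label = "Bcl-2") {
  if (!is.finite(numerator) || !is.finite(denominator) ||
      numerator <= 0 || denominator <= 0) {
    stop("MFI values must be finite and positive", call. = FALSE)
  }
  structure(list(
    numerator_label = numerator_label,
    denominator_label = denominator_label,
    numerator = numerator,
    denominator = denominator,
    ratio = numerator / denominator
  ), class = "xci_mfi_ratio")
}

#' @export
print.xci_mfi_ratio <- function(x, ...) {
  cat(sprintf("%s/%s MFI ratio = %.4f (%.4g / %.4g)\n",
              x$numerator_label, x$denominator_label,
              x$ratio, x$numerator, x$denominator))
  invisible(x)
}
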