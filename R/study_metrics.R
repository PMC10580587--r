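# Small explicitly defined non-transcriptomic study scores.

#' Immunohistochemistry staining index
#'
#' Index = staining intensity (0-3) x proportion of positive cells (0-4), the
#' usual immunoreactive-score convention. An index `>= 6` is classed `high`,
#' `<= 4` is classed `low`; under these component scales no product equals 5,
#' so the two cutoffs are exhaustive (`unclassified` is kept for completeness).
#'
#' @param intensity Integer(s) in `0..3`.
#' @param proportion Integer(s) in `0..4`.
#' @return `data.frame` with columns `intensity`, `proportion`, `index`,
#'   `category` (`high`/`low`/`unclassified`).
#' @examples
#' staining_index(3, 3)  # index 9, high
#' staining_index(2, 2)  # index 4, low
#' @export
staining_index <- function(intensity, proportion) {
  if (any(!is.finite(intensity)) || any(intensity != as.integer(intensity)) ||
      any(intensity < 0) || any(intensity > 3))
    stop_acetyl("domain_error", "intensity must be an integer in 0..3")
  if (any(!is.finite(proportion)) || any(proportion != as.integer(proportion)) ||
      any(proportion < 0) || any(proportion > 4))
    stop_acetyl("domain_error", "proportion must be an integer in 0..4")
  idx <- as.integer(intensity) * as.integer(proportion)
  data.frame(intensity = as.integer(intensity),
             proportion = as.integer(proportion),
             index = idx,
             category = ifelse(idx >= 6L, "high",
                               ifelse(idx <= 4L, "low", "unclassified")),
             stringsAsFactors = FALSE)
}

#' Xenograft tumour volume
#'
#' `volume = length * width^2 / 2` (mm^3 for mm inputs).
#'
#' @param length_mm,width_mm Non-negative calliper measurements with
#'   `length >= width`.
#' @return Numeric volume(s).
#' @examples
#' tumor_volume(10, 6)  # 180
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm < 0) || any(width_mm < 0))
    stop_acetyl("domain_error", "length and width must be finite and non-negative")
  if (any(length_mm < width_mm))
    stop_acetyl("domain_error", "length must be >= width")
  length_mm * width_mm^2 / 2
}

#' Relative expression fold change by the 2^(-ddCt) method
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) - (Ct_target,calibrator -
#' Ct_ref,calibrator)`; the fold change is `2^(-ddCt)`, always positive.
#'
#' @param ct_target_sample,ct_ref_sample Target and reference-gene Ct values
#'   in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator The same in the calibrator
#'   (control) sample.
#' @return Numeric fold change(s).
#' @examples
#' ddct_fold_change(24, 18, 25, 18)  # ddCt = -1, fold = 2
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts)))
    stop_acetyl("domain_error", "all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}
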