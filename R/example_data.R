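#' Published cataract-group code frequencies from two healthcare systems
#'
#' Endorsement frequencies of the non-rare ICD-10 codes in the cataract
#' phenotype group, as reported for two integrated healthcare systems
#' (site A and site B, the reference), together with the published
#' person-time-adjusted smoothed frequency ratios. The sites' total
#' person-times were not published; [calibrate_pt_ratio()] recovers their
#' ratio from the printed values. This table is the canonical worked
#' example of code substitution: group-level usage is nearly balanced
#' while specific/unspecified member codes diverge strongly.
#'
#' @return `data.table(code, description, f_a, f_b, printed_ratio)`.
#' @export
cataract_frequency_example <- function() {
  fread(system.file("extdata", "cataract_code_frequencies.csv",
                    package = "codeharmony"))
}

#' Calibrate the unpublished person-time ratio from printed ratios
#'
#' The smoothed frequency ratio factorizes as
#' \eqn{\rho_j = c \cdot (f_{A,j}+\kappa)/(f_{B,j}+\kappa)} where
#' \eqn{c = PT_B/PT_A} is the same for every code. Given printed ratios
#' rounded to two decimals, the per-row estimates \eqn{\rho_j / r_j} are
#' nearly constant and their median is a robust estimate of `c`; rows can
#' be excluded (leave-one-out) so a code's own printed ratio never enters
#' its reconstruction.
#'
#' @param tbl A table like [cataract_frequency_example()] with columns
#'   `code`, `f_a`, `f_b`, `printed_ratio`.
#' @param exclude Codes to leave out of the median.
#' @param kappa Smoothing count.
#' @return The estimated person-time ratio `c` (scalar).
#' @export
calibrate_pt_ratio <- function(tbl, exclude = character(), kappa = 10) {
  keep <- !tbl$code %in% exclude
  r <- (tbl$f_a[keep] + kappa) / (tbl$f_b[keep] + kappa)
  median(tbl$printed_ratio[keep] / r)
}

#' Reconstruct a code's smoothed frequency ratio from printed companions
#'
#' Leave-one-out reconstruction: calibrates the person-time ratio on all
#' other rows of the table, then evaluates the smoothed ratio formula for
#' the requested code via [smoothed_frequency_ratio()] with person-times
#' `(1, 1/c)`.
#'
#' @param tbl A table like [cataract_frequency_example()].
#' @param code Code to reconstruct.
#' @param kappa Smoothing count.
#' @return The reconstructed ratio (unrounded).
#' @export
reconstructed_ratio <- function(tbl, code, kappa = 10) {
  idx <- which(tbl$code == code)
  if (length(idx) != 1L) stop("code not found: ", code)
  row <- as.data.frame(tbl)[idx, ]
  cc <- calibrate_pt_ratio(tbl, exclude = code, kappa = kappa)
  smoothed_frequency_ratio(row$f_a, row$f_b, pt_a = 1, pt_b = cc,
                           kappa = kappa, code = code)$ratio
}
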