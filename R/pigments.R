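## Spectrophotometric pigment quantification in 80% acetone extracts.

#' Chlorophyll and carotenoid concentrations from absorbance readings
#'
#' Applies the standard 80%-acetone extinction formulas:
#' chlorophyll a (mg/L in extract) = 12.21*A663 - 2.81*A647;
#' chlorophyll b = 20.13*A647 - 5.03*A663;
#' carotenoid = (1000*A470 - 3.27*chl_a - 104*chl_b)/227.
#' Negative results (blank or scatter artifacts) are reported as-is with
#' a warning; negative absorbance inputs are an error.
#'
#' @param a663,a647,a470 absorbances at 663, 647 and 470 nm (unitless,
#'   non-negative; vectorized).
#' @param dilution multiplicative dilution factor applied to the results
#'   (e.g. 2 for a 1:2 diluted extract); default 1.
#' @return data frame with columns `chl_a`, `chl_b`, `carotenoid`
#'   (mg/L in extract).
#' @examples
#' pigment_concentrations(1, 0, 0)$chl_a  # 12.21
#' @export
pigment_concentrations <- function(a663, a647, a470, dilution = 1) {
  r <- cbind(a663, a647, a470)
  if (any(!is.finite(r)) || any(r < 0))
    stop("absorbances must be finite and non-negative")
  chl_a <- 12.21 * r[, 1] - 2.81 * r[, 2]
  chl_b <- 20.13 * r[, 2] - 5.03 * r[, 1]
  car <- (1000 * r[, 3] - 3.27 * chl_a - 104 * chl_b) / 227
  out <- data.frame(chl_a = chl_a * dilution, chl_b = chl_b * dilution,
                    carotenoid = car * dilution)
  rownames(out) <- NULL
  if (any(out < 0))
    warning("negative pigment concentration(s) reported as-is ",
            "(blank/scatter artifacts?)")
  out
}
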