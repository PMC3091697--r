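# Closed-form physiological calculations: radiotracer ion influx and qPCR
# standard-curve quantification.

#' Unidirectional ion influx from radiotracer counts
#'
#' `J_in = cpm / (SA * bw * t)`, in pmol per g body weight per hour.
#'
#' @param cpm whole-body radioactivity, counts per minute (>= 0).
#' @param SA specific activity of the tracer in the water, cpm per pmol.
#' @param bw body weight in g.
#' @param t flux duration in h.
#' @return influx in pmol g^-1 h^-1 (vectorised).
#' @export
zinc_influx <- function(cpm, SA, bw, t) {
  if (any(cpm < 0)) stopf("'cpm' must be >= 0")
  if (any(SA <= 0) || any(bw <= 0) || any(t <= 0))
    stopf("SA, bw and t must all be > 0")
  cpm / (SA * bw * t)
}

#' Specific activity of a radiotracer solution
#'
#' Labelled counts divided by total ion content, cpm per pmol.
#'
#' @param label_cpm_per_L tracer activity per litre (cpm L^-1).
#' @param total_pmol_per_L total ion concentration (pmol L^-1).
#' @return specific activity in cpm pmol^-1.
#' @export
specific_activity <- function(label_cpm_per_L, total_pmol_per_L) {
  if (any(total_pmol_per_L <= 0)) stopf("total ion concentration must be > 0")
  label_cpm_per_L / total_pmol_per_L
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template copies over a dilution
#' series. Also reports the amplification efficiency
#' `E = 10^(-1/slope) - 1` (1 = perfect doubling per cycle).
#'
#' @param ct observed Ct values.
#' @param copies template copy numbers (> 0) of the dilution series.
#' @return list with `slope`, `intercept`, `efficiency`, `r_squared`.
#' @export
fit_standard_curve <- function(ct, copies) {
  if (length(ct) != length(copies) || length(ct) < 2)
    stopf("need >= 2 paired (ct, copies) points")
  if (any(copies <= 0)) stopf("copy numbers must be > 0")
  fit <- lm(ct ~ log10(copies))
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope == 0) stopf("degenerate standard curve (zero slope)")
  list(slope = slope, intercept = intercept,
       efficiency = 10^(-1 / slope) - 1,
       r_squared = summary(fit)$r.squared)
}

#' Relative expression from a qPCR standard curve
#'
#' Copy number is read off the standard curve, `copies =
#' 10^((ct - intercept)/slope)`, then normalized to the relative copies of
#' the reference (18S rRNA) gene.
#'
#' @param ct observed Ct value(s).
#' @param slope,intercept standard curve of Ct on log10 copies.
#' @param reference_copies relative copies of the reference gene (> 0).
#' @return normalized expression (vectorised).
#' @export
qpcr_relative_expression <- function(ct, slope, intercept, reference_copies) {
  if (any(slope == 0)) stopf("'slope' must be nonzero")
  if (any(reference_copies <= 0)) stopf("'reference_copies' must be > 0")
  10^((ct - intercept) / slope) / reference_copies
}
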