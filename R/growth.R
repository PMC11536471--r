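#' Per-clone annual exponential growth rate (clonal fitness)
#'
#' Under the exponential clone model `VAF2 = VAF1 * (1 + CF)^t`, the clonal
#' fitness CF — the annual proportional growth of the clone's variant allele
#' fraction — is `CF = (VAF2 / VAF1)^(1 / t) - 1`. Computed in log space,
#' `exp(log(VAF2 / VAF1) / t) - 1`, which is stable at extreme VAF ratios
#' (e.g. an imputed 0.001 rising to 0.5 within a year).
#'
#' @param vaf1,vaf2 Variant allele fractions at the first and second
#'   timepoint, in (0, 1]. Vectorized.
#' @param dt_years Elapsed time between draws, in years (> 0).
#' @return CF, the annual proportional growth rate; always > -1. CF = 1 means
#'   the VAF doubles each year; CF = 0 means no change.
#' @seealso [project_vaf()] for the forward model.
#' @examples
#' compute_growth_rate(0.02, 0.08, 2)   # 1: quadrupled over 2 years
#' compute_growth_rate(0.10, 0.05, 3)   # about -0.206: halved over 3 years
#' @export
compute_growth_rate <- function(vaf1, vaf2, dt_years) {
  if (any(dt_years <= 0)) stop("dt_years must be > 0", call. = FALSE)
  if (any(vaf1 <= 0)) {
    stop("vaf1 must be > 0 (impute the detection floor before calling)",
         call. = FALSE)
  }
  if (any(vaf2 <= 0)) {
    stop("vaf2 must be > 0 (impute the detection floor before calling)",
         call. = FALSE)
  }
  exp(log(vaf2 / vaf1) / dt_years) - 1
}

#' Project a VAF forward under exponential clone growth
#'
#' Forward model `VAF2 = VAF1 * (1 + CF)^t`; the inverse of
#' [compute_growth_rate()]. Projections above 1 are clamped with a warning
#' (a clone cannot exceed the full allele fraction).
#'
#' @param vaf1 Starting VAF (> 0). Vectorized.
#' @param cf Annual proportional growth rate (> -1).
#' @param dt_years Projection horizon in years.
#' @return Projected VAF.
#' @examples
#' project_vaf(0.02, 1.0, 2)   # 0.08
#' @export
project_vaf <- function(vaf1, cf, dt_years) {
  if (any(vaf1 <= 0)) stop("vaf1 must be > 0", call. = FALSE)
  if (any(cf <= -1)) stop("cf must be > -1", call. = FALSE)
  out <- vaf1 * exp(dt_years * log1p(cf))
  if (any(out > 1)) {
    warning("projected VAF exceeds 1; clamped (clone cannot exceed the full fraction)",
            call. = FALSE)
    out <- pmin(out, 1)
  }
  out
}
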