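#' Published reference model summaries
#'
#' Annual model summaries reported for the motivating nine-year
#' shade-coffee ant-nest census (whose raw field data are not publicly
#' deposited): fitted Thomas parameters `sigma` (m) and `kappa` (scaled by
#' 1e4, per m^2) with bootstrap 95% CIs and MAD goodness-of-fit p-values
#' for the exogenous and endogenous cluster models, and the AIC of the
#' null, exogenous and endogenous Poisson models. These serve as worked
#' inputs for the reporting and comparison utilities; the pipeline itself
#' is exercised on synthetic censuses.
#'
#' @return `reference_thomas_summaries()`: a `data.frame` in the layout of
#'   [thomas_summary_table()]. `reference_aic()`: one row per year with
#'   columns `null`, `exogenous`, `endogenous`.
#' @export
reference_thomas_summaries <- function() {
  utils::read.csv(system.file("extdata", "reference_thomas_summaries.csv",
                              package = "nestpp"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_thomas_summaries
#' @export
reference_aic <- function() {
  utils::read.csv(system.file("extdata", "reference_aic.csv",
                              package = "nestpp"),
                  stringsAsFactors = FALSE)
}
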