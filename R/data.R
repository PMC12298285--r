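# Bundled reference data.

#' Capillary-blood method-comparison table
#'
#' Paired AT activities (percent) for ten volunteers measured on a
#' reference laboratory instrument (venous blood, standard workflow) and on
#' the microfluidic device (fingertip capillary blood), with the reported
#' per-sample relative difference. Used as the worked input for
#' \code{\link{relative_difference}} and the method-comparison stage.
#'
#' @return A data.frame with columns \code{sample_id},
#'   \code{reference_percent}, \code{device_percent},
#'   \code{reported_relative_difference_percent}.
#' @export
capillary_comparison <- function() {
  path <- system.file("extdata", "capillary_comparison.tsv",
                      package = "atquant", mustWork = TRUE)
  utils::read.delim(path)
}
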