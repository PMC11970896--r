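# Presentation-predictor interface.
#
# A predictor maps peptides to presented/absent calls (NA = "unclear", used
# for peptides containing 'X'). Implementations: the calibrated PWM
# classifier, the deterministic motif oracle of the synthetic-data module, a
# plain R function, and an optional external netMHCpan adapter.

#' Call a presentation predictor on peptides
#'
#' Generic dispatch over the predictor implementations: a calibrated
#' [build_pwm()] classifier, a [motif_oracle()], an arbitrary vectorized
#' function `character -> logical`, or a [netmhcpan_adapter()]. All
#' implementations are deterministic and return `NA` ("unclear") for peptides
#' containing `'X'`.
#'
#' @param predictor The predictor object.
#' @param peptides Character vector of peptides.
#' @return Logical vector, one call per peptide (`NA` = unclear).
#' @export
predict_presented <- function(predictor, peptides) {
  UseMethod("predict_presented")
}

#' @export
predict_presented.pwm_classifier <- function(predictor, peptides) {
  stats::predict(predictor, peptides)
}

#' @export
predict_presented.function <- function(predictor, peptides) {
  out <- rep(NA, length(peptides))
  clear <- !has_unknown_residue(peptides)
  out[clear] <- as.logical(predictor(peptides[clear]))
  out
}

predictor_name <- function(predictor) {
  if (inherits(predictor, "pwm_classifier")) return("pwm_classifier")
  if (inherits(predictor, "motif_oracle")) return("motif_oracle")
  if (inherits(predictor, "netmhcpan_adapter")) return("netmhcpan")
  if (is.function(predictor)) return("function")
  class(predictor)[1]
}
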