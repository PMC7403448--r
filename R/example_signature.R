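#' Reference three-lncRNA ovarian-cancer signature
#'
#' A fixed three-lncRNA risk signature for BRCA1/2 wild-type ovarian
#' cancer (LINC01619, DLX6-AS1, AC004943.2) with multivariate Cox weights
#' -0.571, -0.26 and -0.284 and a training-median cutoff of 0.175. All
#' three weights are negative: higher expression of each lncRNA is
#' protective. Used by the worked example in the README and by tests as a
#' concrete, fully specified signature.
#'
#' @return a `cerna_signature` (no fitted model object attached).
#' @examples
#' sig <- example_signature()
#' expr <- matrix(c(1, 0, 0), nrow = 1,
#'                dimnames = list("s1", sig$features))
#' risk_score(sig, expr) # score -0.571
#' @export
example_signature <- function() {
  sig <- list(
    features = c("LINC01619", "DLX6-AS1", "AC004943.2"),
    coefficients = c("LINC01619" = -0.571, "DLX6-AS1" = -0.26,
                     "AC004943.2" = -0.284),
    cutoff = 0.175,
    provenance = list(source = "reference ovarian-cancer signature")
  )
  class(sig) <- "cerna_signature"
  sig
}
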