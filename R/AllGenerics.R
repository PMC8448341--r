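#' @name entropyScore-generics
#' @title Generics defined by entropyScore
#' @keywords internal
NULL

#' Datatype of a count matrix
#'
#' Whether the `"counts"` assay holds UMI (molecule) counts or pre-collapse
#' read counts. Entropy scores are robust to this distinction (the design
#' goal checked by [umiCollapseRatio()]), but the flag is carried so that
#' read/UMI pairs can be matched.
#'
#' @param x An [EntropyExperiment-class].
#' @param value `"umi"` or `"reads"`.
#' @return `datatype(x)` returns a character scalar.
#' @export
setGeneric("datatype", function(x) standardGeneric("datatype"))

#' @rdname datatype
#' @export
setGeneric("datatype<-", function(x, value) standardGeneric("datatype<-"))

#' @rdname entropyScores
#' @export
setGeneric("entropyScores",
           function(x, ...) standardGeneric("entropyScores"))
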