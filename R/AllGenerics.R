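#' @name hldaKinetics-generics
#' @title Accessor generics
#' @description Small accessor generics shared by the package's S4 classes.
#'   Accessors are the supported way to read object contents; slot layout is
#'   not part of the API.
#' @param x,object an object of the appropriate class.
#' @param value replacement value.
#' @keywords internal
NULL

#' @rdname hldaKinetics-generics
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("frameStates", function(x) standardGeneric("frameStates"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("frameStates<-", function(x, value) standardGeneric("frameStates<-"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("cvWeights", function(x) standardGeneric("cvWeights"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("hldaEigenvalue", function(x) standardGeneric("hldaEigenvalue"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("latentX", function(x) standardGeneric("latentX"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("biasEnergy", function(x) standardGeneric("biasEnergy"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("accelFactor", function(x) standardGeneric("accelFactor"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("mfpt", function(x) standardGeneric("mfpt"))

#' @rdname hldaKinetics-generics
#' @export
setGeneric("rateConstant", function(x) standardGeneric("rateConstant"))
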