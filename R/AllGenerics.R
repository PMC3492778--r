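#' @include AllClasses.R
NULL

#' @export
setGeneric("expectedCounts", function(x, model = c("marginal_product", "uniform"))
    standardGeneric("expectedCounts"))

#' @export
setGeneric("psiCoefficients", function(x, model = c("marginal_product", "uniform"))
    standardGeneric("psiCoefficients"))

#' @export
setGeneric("ptiCoefficients", function(x, model = c("marginal_product", "uniform"))
    standardGeneric("ptiCoefficients"))

#' @export
setGeneric("ipsi", function(x, model = c("marginal_product", "uniform"))
    standardGeneric("ipsi"))

#' @export
setGeneric("bootstrapIsolation", function(x, model = c("marginal_product", "uniform"),
                                          nBoot = 10000L, seed = 1L)
    standardGeneric("bootstrapIsolation"))

#' @export
setGeneric("quantifyHC", function(x, ...) standardGeneric("quantifyHC"))

#' @export
setGeneric("logContrast", function(x, denominator,
                                   zeroPolicy = c("error", "replace"), ...)
    standardGeneric("logContrast"))

#' @export
setGeneric("phenoRatio", function(x, numeratorHC = "(Z)-7-C23:1",
                                  denominatorHC = "(Z)-7-C25:1")
    standardGeneric("phenoRatio"))

#' @export
setGeneric("survivalCurve", function(x, ...) standardGeneric("survivalCurve"))

#' @export
setGeneric("msd", function(x, method = c("interpolate", "step"))
    standardGeneric("msd"))

#' @export
setGeneric("msdCI", function(x, nBoot = 1000L, seed = 1L, level = 0.95,
                             method = c("interpolate", "step"))
    standardGeneric("msdCI"))

#' @export
setGeneric("simMatingTrials", function(model, ...) standardGeneric("simMatingTrials"))

#' @export
setGeneric("simPeakTables", function(model, ...) standardGeneric("simPeakTables"))

#' @export
setGeneric("simDesiccation", function(model, ...) standardGeneric("simDesiccation"))
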