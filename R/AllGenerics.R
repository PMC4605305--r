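#' @rdname RaslCountSet-class
#' @param x a \linkS4class{RaslCountSet}
#' @export
setGeneric("longCounts", function(x) standardGeneric("longCounts"))

#' @rdname RaslCountSet-class
#' @export
setGeneric("shortCounts", function(x) standardGeneric("shortCounts"))

#' @rdname RaslCountSet-class
#' @export
setGeneric("totalCounts", function(x) standardGeneric("totalCounts"))

#' @rdname ProbeLibrary-class
#' @param x a \linkS4class{ProbeLibrary}
#' @export
setGeneric("junctionLength", function(x) standardGeneric("junctionLength"))

#' @rdname demultiplexAndCount
#' @export
setGeneric("countingReport", function(x) standardGeneric("countingReport"))

#' @rdname computePsi
#' @export
setGeneric("psiValues", function(x) standardGeneric("psiValues"))

#' @rdname RaslCountSet-class
#' @export
setMethod("longCounts", "RaslCountSet", function(x)
    SummarizedExperiment::assay(x, "long"))

#' @rdname RaslCountSet-class
#' @export
setMethod("shortCounts", "RaslCountSet", function(x)
    SummarizedExperiment::assay(x, "short"))

#' @rdname RaslCountSet-class
#' @export
setMethod("totalCounts", "RaslCountSet", function(x)
    SummarizedExperiment::assay(x, "long") +
        SummarizedExperiment::assay(x, "short"))

#' @rdname RaslPsiSet-class
#' @param x a \linkS4class{RaslPsiSet}
#' @export
setMethod("totalCounts", "RaslPsiSet", function(x)
    SummarizedExperiment::assay(x, "total"))

#' @rdname ProbeLibrary-class
#' @export
setMethod("junctionLength", "ProbeLibrary", function(x)
    nchar(x$long_junction_seq[[1L]]))

#' @rdname demultiplexAndCount
#' @export
setMethod("countingReport", "RaslCountSet", function(x)
    metadata(x)$counting_report)

#' @rdname computePsi
#' @export
setMethod("psiValues", "RaslPsiSet", function(x)
    SummarizedExperiment::assay(x, "psi"))
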