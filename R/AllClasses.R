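#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.GENOTYPES <- c("WT", "PSF_KD", "TRAP150_KD")
.STIMULATIONS <- c("U", "S")
.DNA_BASES <- c("A", "C", "G", "T")

.is_dna <- function(x) {
    !is.na(x) & nzchar(x) & !grepl("[^ACGT]", x)
}

#' ProbeLibrary: RASL probe pairs for a set of cassette-exon events
#'
#' A \code{ProbeLibrary} is a \link[S4Vectors]{DataFrame} with one row per
#' interrogated splicing event and the columns \code{event_id},
#' \code{gene_symbol}, \code{long_junction_seq}, \code{short_junction_seq} and
#' \code{long_is_inclusion}. Each junction sequence is the concatenation of
#' the two ligation probes flanking one isoform's splice junction; the long
#' isoform is by convention the exon-inclusion isoform.
#'
#' Validity requires: unique \code{event_id}; all junction sequences unique
#' across the whole library (long and short pooled); \code{long_junction_seq
#' != short_junction_seq} within each event; A/C/G/T alphabet only; a single
#' common junction length across the library (fixed probe geometry).
#'
#' @name ProbeLibrary-class
#' @aliases ProbeLibrary-class
#' @exportClass ProbeLibrary
setClass("ProbeLibrary", contains = "DFrame")

setValidity("ProbeLibrary", function(object) {
    req <- c("event_id", "gene_symbol", "long_junction_seq",
             "short_junction_seq", "long_is_inclusion")
    missing_cols <- setdiff(req, colnames(object))
    if (length(missing_cols) > 0L)
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (nrow(object) == 0L)
        return("a ProbeLibrary must contain at least one event")
    if (anyDuplicated(object$event_id))
        return("event_id values must be unique")
    lj <- object$long_junction_seq
    sj <- object$short_junction_seq
    if (!all(.is_dna(lj)) || !all(.is_dna(sj)))
        return("junction sequences must be non-empty strings over A/C/G/T")
    if (any(lj == sj))
        return("long and short junction sequences must differ within an event")
    if (anyDuplicated(c(lj, sj)))
        return("junction sequences must be unique across the library")
    if (length(unique(nchar(c(lj, sj)))) != 1L)
        return("all junction sequences must share one common length")
    if (!is.logical(object$long_is_inclusion) ||
        anyNA(object$long_is_inclusion))
        return("long_is_inclusion must be logical without NAs")
    TRUE
})

#' Construct a ProbeLibrary
#'
#' @param event_id character vector of unique event identifiers.
#' @param gene_symbol character vector of gene symbols (may repeat).
#' @param long_junction_seq character vector of long-isoform junction
#'   sequences (A/C/G/T, one common length).
#' @param short_junction_seq character vector of short-isoform junction
#'   sequences.
#' @param long_is_inclusion logical; whether the long isoform is the
#'   exon-inclusion isoform (default \code{TRUE}).
#' @return A \linkS4class{ProbeLibrary}.
#' @examples
#' ProbeLibrary("ev1", "GENE1", "ACGTACGT", "TTGGCCAA")
#' @export
ProbeLibrary <- function(event_id, gene_symbol, long_junction_seq,
                         short_junction_seq, long_is_inclusion = TRUE) {
    df <- DataFrame(
        event_id = as.character(event_id),
        gene_symbol = as.character(gene_symbol),
        long_junction_seq = toupper(as.character(long_junction_seq)),
        short_junction_seq = toupper(as.character(short_junction_seq)),
        long_is_inclusion = rep_len(as.logical(long_is_inclusion),
                                    length(event_id)))
    rownames(df) <- df$event_id
    new("ProbeLibrary", df)
}

#' @describeIn ProbeLibrary-class compact display
#' @param object a \code{ProbeLibrary}
#' @export
setMethod("show", "ProbeLibrary", function(object) {
    cat(sprintf("ProbeLibrary with %d events (junction length %d nt)\n",
                nrow(object), junctionLength(object)))
    callNextMethod()
})

#' RaslSamples: barcoded sample sheet for a RASL-Seq experiment
#'
#' A \code{RaslSamples} is a \link[S4Vectors]{DataFrame} with one row per
#' sequencing sample and columns \code{sample_id}, \code{genotype} (one of
#' \code{WT}, \code{PSF_KD}, \code{TRAP150_KD}), \code{stimulation}
#' (\code{U} unstimulated or \code{S} PMA-stimulated), \code{replicate}
#' (integer >= 1), \code{condition} (\code{genotype_stimulation}) and
#' \code{barcode} (inline sample barcode).
#'
#' Validity requires unique (genotype, stimulation, replicate) triples and
#' unique, equal-length A/C/G/T barcodes.
#'
#' @name RaslSamples-class
#' @aliases RaslSamples-class
#' @exportClass RaslSamples
setClass("RaslSamples", contains = "DFrame")

setValidity("RaslSamples", function(object) {
    req <- c("sample_id", "genotype", "stimulation", "replicate",
             "condition", "barcode")
    missing_cols <- setdiff(req, colnames(object))
    if (length(missing_cols) > 0L)
        return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
    if (nrow(object) == 0L)
        return("a RaslSamples must contain at least one sample")
    if (!all(object$genotype %in% .GENOTYPES))
        return(paste("genotype must be one of:",
                     paste(.GENOTYPES, collapse = ", ")))
    if (!all(object$stimulation %in% .STIMULATIONS))
        return("stimulation must be 'U' or 'S'")
    rep_ok <- is.numeric(object$replicate) && !anyNA(object$replicate) &&
        all(object$replicate >= 1) && all(object$replicate == round(object$replicate))
    if (!rep_ok)
        return("replicate must be an integer >= 1")
    key <- paste(object$genotype, object$stimulation, object$replicate)
    if (anyDuplicated(key))
        return("(genotype, stimulation, replicate) must be unique")
    if (anyDuplicated(object$sample_id))
        return("sample_id values must be unique")
    bc <- object$barcode
    if (!all(.is_dna(bc)))
        return("barcodes must be non-empty strings over A/C/G/T")
    if (anyDuplicated(bc))
        return("barcodes must be unique")
    if (length(unique(nchar(bc))) != 1L)
        return("barcodes must be equal length")
    exp_cond <- paste(object$genotype, object$stimulation, sep = "_")
    if (!identical(as.character(object$condition), exp_cond))
        return("condition must equal genotype_stimulation")
    TRUE
})

#' Construct a RaslSamples sample sheet
#'
#' @param genotype character vector over \code{WT}, \code{PSF_KD},
#'   \code{TRAP150_KD}.
#' @param stimulation character vector over \code{U} (unstimulated) and
#'   \code{S} (PMA-stimulated).
#' @param replicate integer vector of biological-replicate indices (>= 1).
#' @param barcode character vector of unique, equal-length inline barcodes.
#' @return A \linkS4class{RaslSamples} with derived \code{sample_id}
#'   (\code{genotype_stimulation_repN}) and \code{condition} columns.
#' @examples
#' RaslSamples(c("WT", "WT"), c("U", "S"), c(1, 1), c("AAAA", "CCCC"))
#' @export
RaslSamples <- function(genotype, stimulation, replicate, barcode) {
    genotype <- as.character(genotype)
    stimulation <- as.character(stimulation)
    replicate <- as.integer(replicate)
    condition <- paste(genotype, stimulation, sep = "_")
    df <- DataFrame(
        sample_id = paste0(condition, "_rep", replicate),
        genotype = genotype,
        stimulation = stimulation,
        replicate = replicate,
        condition = condition,
        barcode = toupper(as.character(barcode)))
    rownames(df) <- df$sample_id
    new("RaslSamples", df)
}

#' @describeIn RaslSamples-class compact display
#' @param object a \code{RaslSamples}
#' @export
setMethod("show", "RaslSamples", function(object) {
    cat(sprintf("RaslSamples with %d samples over conditions: %s\n",
                nrow(object),
                paste(unique(object$condition), collapse = ", ")))
    callNextMethod()
})

#' RaslCountSet: per-event, per-sample isoform junction counts
#'
#' A \code{RaslCountSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with two integer assays,
#' \code{long} and \code{short}, holding the number of reads matching each
#' event's long- and short-isoform junction in each sample. \code{rowData}
#' carries the \linkS4class{ProbeLibrary} columns and \code{colData} the
#' \linkS4class{RaslSamples} columns. A demultiplexing report, when the
#' object was produced by \code{\link{demultiplexAndCount}}, is stored in
#' \code{metadata(x)$counting_report} (see \code{\link{countingReport}}).
#'
#' @name RaslCountSet-class
#' @aliases RaslCountSet-class
#' @exportClass RaslCountSet
setClass("RaslCountSet", contains = "SummarizedExperiment")

.validate_count_assays <- function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("long", "short") %in% an))
        return("assays 'long' and 'short' are required")
    for (nm in c("long", "short")) {
        a <- SummarizedExperiment::assay(object, nm)
        if (anyNA(a) || any(a < 0) || any(a != round(a)))
            return(sprintf("assay '%s' must be non-negative integers", nm))
    }
    TRUE
}

setValidity("RaslCountSet", .validate_count_assays)

#' Construct a RaslCountSet
#'
#' @param long,short integer matrices (events x samples) of junction counts.
#' @param probes a \linkS4class{ProbeLibrary} (rows matched by position).
#' @param samples a \linkS4class{RaslSamples} (columns matched by position).
#' @param metadata optional list stored as object metadata.
#' @return A \linkS4class{RaslCountSet}.
#' @export
RaslCountSet <- function(long, short, probes, samples, metadata = list()) {
    long <- as.matrix(long)
    short <- as.matrix(short)
    storage.mode(long) <- "integer"
    storage.mode(short) <- "integer"
    dimnames(long) <- dimnames(short) <-
        list(probes$event_id, samples$sample_id)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(long = long, short = short),
        rowData = as(probes, "DFrame"),
        colData = as(samples, "DFrame"),
        metadata = metadata)
    new("RaslCountSet", se)
}

#' RaslPsiSet: per-event, per-sample percent-spliced-in values
#'
#' A \code{RaslPsiSet} extends
#' \link[SummarizedExperiment]{SummarizedExperiment} with assays \code{psi}
#' (percent spliced in, \code{NA} where an event had zero coverage in a
#' sample) and \code{total} (the total junction reads backing each PSI
#' value). Produced by \code{\link{computePsi}}.
#'
#' @name RaslPsiSet-class
#' @aliases RaslPsiSet-class
#' @exportClass RaslPsiSet
setClass("RaslPsiSet", contains = "SummarizedExperiment")

setValidity("RaslPsiSet", function(object) {
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("psi", "total") %in% an))
        return("assays 'psi' and 'total' are required")
    psi <- SummarizedExperiment::assay(object, "psi")
    tot <- SummarizedExperiment::assay(object, "total")
    if (any(psi < 0 | psi > 100, na.rm = TRUE))
        return("psi values must lie in [0, 100]")
    if (!identical(is.na(psi), tot == 0L))
        return("psi must be NA exactly where total == 0")
    TRUE
})
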