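#' Tab-separated readers and writers for pipeline tables
#'
#' All pipeline artifacts are plain TSV files with a header line, so they
#' are greppable and diffable; each writer has a reader that round-trips
#' without loss.
#'
#' @param x the object to write.
#' @param path file path.
#' @return Writers return \code{path} invisibly; readers return the
#'   reconstructed object.
#' @name rasl-io
NULL

.write_tsv <- function(df, path) {
    utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.read_tsv <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname rasl-io
#' @export
writeProbeLibrary <- function(x, path) {
    stopifnot(is(x, "ProbeLibrary"))
    .write_tsv(x, path)
}

#' @rdname rasl-io
#' @export
readProbeLibrary <- function(path) {
    df <- .read_tsv(path)
    ProbeLibrary(df$event_id, df$gene_symbol, df$long_junction_seq,
                 df$short_junction_seq, df$long_is_inclusion)
}

#' @rdname rasl-io
#' @export
writeSampleSheet <- function(x, path) {
    stopifnot(is(x, "RaslSamples"))
    .write_tsv(x, path)
}

#' @rdname rasl-io
#' @export
readSampleSheet <- function(path) {
    df <- .read_tsv(path)
    RaslSamples(df$genotype, df$stimulation, df$replicate, df$barcode)
}

#' @rdname rasl-io
#' @export
writeCountTable <- function(x, path) {
    stopifnot(is(x, "RaslCountSet"))
    long <- longCounts(x)
    short <- shortCounts(x)
    df <- data.frame(
        event_id = rep(rownames(long), times = ncol(long)),
        sample_id = rep(colnames(long), each = nrow(long)),
        long_count = as.vector(long),
        short_count = as.vector(short))
    .write_tsv(df, path)
}

#' @rdname rasl-io
#' @param probes,samples the \linkS4class{ProbeLibrary} and
#'   \linkS4class{RaslSamples} the table was written from (row/column
#'   universe for the reconstructed \linkS4class{RaslCountSet}).
#' @export
readCountTable <- function(path, probes, samples) {
    df <- .read_tsv(path)
    n_ev <- nrow(probes)
    n_s <- nrow(samples)
    ev_i <- match(df$event_id, probes$event_id)
    s_i <- match(df$sample_id, samples$sample_id)
    if (anyNA(ev_i) || anyNA(s_i))
        stop("count table contains event or sample ids not in the ",
             "supplied library/sample sheet")
    long <- short <- matrix(0L, n_ev, n_s)
    long[cbind(ev_i, s_i)] <- as.integer(df$long_count)
    short[cbind(ev_i, s_i)] <- as.integer(df$short_count)
    RaslCountSet(long, short, probes, samples)
}

#' @rdname rasl-io
#' @export
writePsiTable <- function(x, path) {
    stopifnot(is(x, "RaslPsiSet"))
    psi <- psiValues(x)
    tot <- totalCounts(x)
    df <- data.frame(
        event_id = rep(rownames(psi), times = ncol(psi)),
        sample_id = rep(colnames(psi), each = nrow(psi)),
        psi = as.vector(psi),
        total_count = as.vector(tot))
    .write_tsv(df, path)
}

#' @rdname rasl-io
#' @export
writeResultTable <- function(x, path) {
    .write_tsv(as.data.frame(x), path)
}

#' @rdname rasl-io
#' @export
readResultTable <- function(path) {
    DataFrame(.read_tsv(path))
}
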