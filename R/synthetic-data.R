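#' Generate a synthetic RASL probe library
#'
#' Draws \code{n_events} cassette-exon events, each with a distinct pair of
#' junction probe sequences (long = exon inclusion, short = exon skipping).
#' Junctions are uniform random A/C/G/T strings of a fixed length, unique
#' across the whole library; with the default 40 nt geometry (two ligated
#' 20-mers) collisions are vanishingly rare but are resolved by redrawing, so
#' the invariants hold for any \code{n_events}.
#'
#' @param n_events number of splicing events (>= 1).
#' @param seed integer seed; the library is deterministic given the seed.
#' @param junction_length common junction length in nt (default 40, i.e. a
#'   ligated 20+20 probe pair).
#' @param gene_symbols optional character vector of gene symbols, recycled to
#'   \code{n_events}; defaults to synthetic \code{GENE...} symbols.
#' @return A \linkS4class{ProbeLibrary} with \code{n_events} rows.
#' @examples
#' lib <- makeProbeLibrary(10, seed = 1)
#' junctionLength(lib)
#' @export
makeProbeLibrary <- function(n_events, seed = NULL, junction_length = 40L,
                             gene_symbols = NULL) {
    stopifnot(n_events >= 1, junction_length >= 4)
    if (!is.null(seed))
        set.seed(seed)
    n_events <- as.integer(n_events)
    seqs <- .draw_unique_dna(2L * n_events, as.integer(junction_length))
    if (is.null(gene_symbols))
        gene_symbols <- sprintf("GENE%05d", seq_len(n_events))
    ProbeLibrary(
        event_id = sprintf("ev%05d", seq_len(n_events)),
        gene_symbol = rep_len(gene_symbols, n_events),
        long_junction_seq = seqs[seq_len(n_events)],
        short_junction_seq = seqs[n_events + seq_len(n_events)],
        long_is_inclusion = TRUE)
}

# draw n unique random DNA strings of length len (redraw on collision)
.draw_unique_dna <- function(n, len) {
    draw <- function(k) {
        m <- matrix(sample(.DNA_BASES, k * len, replace = TRUE), nrow = k)
        apply(m, 1L, paste0, collapse = "")
    }
    seqs <- draw(n)
    while (anyDuplicated(seqs)) {
        dup <- which(duplicated(seqs))
        seqs[dup] <- draw(length(dup))
    }
    seqs
}

#' Build a replicated, barcoded sample sheet
#'
#' Expands condition labels (\code{genotype_stimulation}, e.g. \code{WT_S} or
#' \code{PSF_KD_S}) into \code{replicates} biological replicates each and
#' assigns unique random inline barcodes.
#'
#' @param conditions character vector of condition labels; the segment after
#'   the last underscore is the stimulation (\code{U}/\code{S}), the rest the
#'   genotype.
#' @param replicates biological replicates per condition (default 3).
#' @param barcode_length barcode length in nt (default 8).
#' @param seed integer seed for barcode assignment.
#' @return A \linkS4class{RaslSamples}.
#' @examples
#' makeSampleSheet(c("WT_U", "WT_S", "PSF_KD_S"), replicates = 3, seed = 1)
#' @export
makeSampleSheet <- function(conditions = c("WT_U", "WT_S", "PSF_KD_S"),
                            replicates = 3L, barcode_length = 8L,
                            seed = NULL) {
    stopifnot(length(conditions) >= 1, replicates >= 1)
    if (!is.null(seed))
        set.seed(seed)
    stim <- sub("^.*_", "", conditions)
    geno <- sub("_[US]$", "", conditions)
    n <- length(conditions) * replicates
    RaslSamples(
        genotype = rep(geno, each = replicates),
        stimulation = rep(stim, each = replicates),
        replicate = rep(seq_len(replicates), times = length(conditions)),
        barcode = .draw_unique_dna(n, as.integer(barcode_length)))
}

#' Simulate a RASL-Seq count table
#'
#' For every event x sample, draws a total read depth and splits it between
#' the long and short isoform junctions. Totals follow a negative binomial
#' with mean \code{mean_depth} and size \code{dispersion} (variance
#' \code{mu + mu^2/dispersion}); \code{dispersion = Inf} gives the Poisson
#' limit. The long count is binomial on the total with success probability
#' \code{true_psi/100} for the sample's condition.
#'
#' @param probes a \linkS4class{ProbeLibrary}.
#' @param samples a \linkS4class{RaslSamples}.
#' @param true_psi numeric matrix (events x conditions, values in
#'   \code{[0, 100]}) of ground-truth percent spliced in; column names must
#'   cover every condition present in \code{samples}. A single row or an
#'   unnamed vector of length \code{nrow(probes)} is recycled across
#'   conditions.
#' @param mean_depth expected total reads per event per sample (default 300).
#' @param dispersion negative-binomial size parameter; \code{Inf} (Poisson)
#'   or a positive number (default 10, moderate overdispersion).
#' @param seed integer seed; counts are deterministic given the seed.
#' @return A \linkS4class{RaslCountSet} with the ground truth stored in
#'   \code{metadata(x)$true_psi}.
#' @examples
#' lib <- makeProbeLibrary(5, seed = 1)
#' ss <- makeSampleSheet(c("WT_U", "WT_S"), replicates = 2, seed = 1)
#' cs <- simulateCounts(lib, ss, true_psi = 50, mean_depth = 100, seed = 1)
#' totalCounts(cs)[1:3, ]
#' @export
simulateCounts <- function(probes, samples, true_psi, mean_depth = 300,
                           dispersion = 10, seed = NULL) {
    stopifnot(is(probes, "ProbeLibrary"), is(samples, "RaslSamples"),
              mean_depth > 0, dispersion > 0)
    n_ev <- nrow(probes)
    conds <- unique(samples$condition)
    true_psi <- .as_psi_matrix(true_psi, n_ev, conds)
    if (any(true_psi < 0 | true_psi > 100))
        stop("true_psi values must lie in [0, 100]")
    missing_cond <- setdiff(samples$condition, colnames(true_psi))
    if (length(missing_cond) > 0L)
        stop("true_psi lacks columns for conditions: ",
             paste(missing_cond, collapse = ", "))
    if (!is.null(seed))
        set.seed(seed)
    n_s <- nrow(samples)
    long <- short <- matrix(0L, n_ev, n_s)
    for (j in seq_len(n_s)) {
        tot <- if (is.finite(dispersion))
            stats::rnbinom(n_ev, mu = mean_depth, size = dispersion)
        else
            stats::rpois(n_ev, lambda = mean_depth)
        p <- true_psi[, samples$condition[j]] / 100
        long[, j] <- stats::rbinom(n_ev, size = tot, prob = p)
        short[, j] <- tot - long[, j]
    }
    RaslCountSet(long, short, probes, samples,
                 metadata = list(true_psi = true_psi,
                                 mean_depth = mean_depth,
                                 dispersion = dispersion,
                                 seed = seed))
}

.as_psi_matrix <- function(true_psi, n_events, conditions) {
    if (is.matrix(true_psi) || is.data.frame(true_psi)) {
        m <- as.matrix(true_psi)
        if (is.null(colnames(m)))
            stop("a true_psi matrix needs condition column names")
        if (nrow(m) == 1L)
            m <- m[rep(1L, n_events), , drop = FALSE]
        if (nrow(m) != n_events)
            stop("true_psi must have one row per event (or a single row)")
        return(m)
    }
    v <- rep_len(as.numeric(true_psi), n_events)
    matrix(v, n_events, length(conditions),
           dimnames = list(NULL, conditions))
}

#' Emit synthetic barcoded FASTQ reads from a count table
#'
#' Writes one read per counted ligation product: the sample's inline barcode
#' followed by the event's long- or short-isoform junction sequence,
#' optionally with per-base substitution noise. Quality strings are a
#' constant placeholder (the analysis never uses them). With
#' \code{error_rate = 0} the composition
#' \code{demultiplexAndCount(emitReads(x), ...)} is the identity on the
#' count table.
#'
#' @param counts a \linkS4class{RaslCountSet} whose \code{rowData}/
#'   \code{colData} carry the probe library and sample sheet.
#' @param path output FASTQ path (plain text, or gzip if it ends
#'   \code{.gz}); if \code{NULL} the reads are returned invisibly as a named
#'   character vector instead of written.
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer seed for the substitution noise.
#' @return \code{path} (invisibly), or the named read vector when
#'   \code{path} is \code{NULL}.
#' @export
emitReads <- function(counts, path = NULL, error_rate = 0, seed = NULL) {
    stopifnot(is(counts, "RaslCountSet"),
              error_rate >= 0, error_rate < 1)
    if (!is.null(seed))
        set.seed(seed)
    rd <- SummarizedExperiment::rowData(counts)
    cd <- SummarizedExperiment::colData(counts)
    long <- longCounts(counts)
    short <- shortCounts(counts)
    all_reads <- character(0)
    all_ids <- character(0)
    for (j in seq_len(ncol(counts))) {
        lam <- long[, j]
        sam <- short[, j]
        seqs <- c(rep(rd$long_junction_seq, lam),
                  rep(rd$short_junction_seq, sam))
        ev <- c(rep(rd$event_id, lam), rep(rd$event_id, sam))
        iso <- c(rep("long", sum(lam)), rep("short", sum(sam)))
        if (length(seqs) == 0L)
            next
        ids <- paste(cd$sample_id[j], ev, iso,
                     unlist(lapply(c(lam, sam), seq_len)), sep = ":")
        all_reads <- c(all_reads, paste0(cd$barcode[j], seqs))
        all_ids <- c(all_ids, ids)
    }
    if (error_rate > 0 && length(all_reads) > 0L)
        all_reads <- .substitute_bases(all_reads, error_rate)
    names(all_reads) <- all_ids
    if (is.null(path))
        return(invisible(all_reads))
    writeFastq(all_reads, path)
    invisible(path)
}

# iid per-base substitutions at rate `rate`; the new base always differs
.substitute_bases <- function(reads, rate) {
    len <- nchar(reads[[1L]])
    n_pos <- length(reads) * len
    n_mut <- stats::rbinom(1L, n_pos, rate)
    if (n_mut == 0L)
        return(reads)
    at <- sample.int(n_pos, n_mut)
    ri <- ((at - 1L) %/% len) + 1L
    pp <- ((at - 1L) %% len) + 1L
    for (k in seq_len(n_mut)) {
        cur <- substr(reads[[ri[k]]], pp[k], pp[k])
        substr(reads[[ri[k]]], pp[k], pp[k]) <-
            sample(setdiff(.DNA_BASES, cur), 1L)
    }
    reads
}

#' Write reads as a 4-line-record FASTQ file
#'
#' @param reads named character vector (names become read identifiers).
#' @param path output path; gzip-compressed if it ends in \code{.gz}.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
    ids <- names(reads)
    if (is.null(ids))
        ids <- paste0("read", seq_along(reads))
    qual <- strrep("I", nchar(reads))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
    on.exit(close(con))
    writeLines(as.vector(rbind(paste0("@", ids), unname(reads), "+", qual)),
               con)
    invisible(path)
}
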