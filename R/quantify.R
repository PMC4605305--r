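#' Filter events on minimum mean read coverage
#'
#' Retains exactly the events whose mean total junction-read count across
#' all samples (all conditions x replicates) is at least
#' \code{min_mean_reads}. The published analysis used a minimum of 10 reads
#' averaged across all biological replicates and conditions; the boundary is
#' inclusive (a mean of exactly 10 is retained).
#'
#' @param counts a \linkS4class{RaslCountSet}.
#' @param min_mean_reads non-negative coverage threshold (default 10).
#' @return The row-subset \linkS4class{RaslCountSet}.
#' @examples
#' lib <- makeProbeLibrary(20, seed = 1)
#' ss <- makeSampleSheet(c("WT_U", "WT_S"), replicates = 3, seed = 1)
#' cs <- simulateCounts(lib, ss, true_psi = 50, mean_depth = 12, seed = 1)
#' nrow(filterLowCoverage(cs, 10))
#' @export
filterLowCoverage <- function(counts, min_mean_reads = 10) {
    stopifnot(is(counts, "RaslCountSet"), min_mean_reads >= 0)
    keep <- rowMeans(totalCounts(counts)) >= min_mean_reads
    counts[keep, ]
}

#' Compute percent spliced in (PSI) per event and sample
#'
#' PSI is 100 x long / (long + short): the percentage of an event's junction
#' reads supporting the long (exon-inclusion) isoform. Events with zero
#' total reads in a sample get \code{NA} (undefined, not an error); such
#' replicates are excluded from condition means rather than imputed.
#'
#' @param counts a \linkS4class{RaslCountSet}.
#' @return A \linkS4class{RaslPsiSet} with assays \code{psi} and
#'   \code{total}.
#' @examples
#' lib <- makeProbeLibrary(2, seed = 1)
#' ss <- makeSampleSheet("WT_S", replicates = 1, seed = 1)
#' cs <- RaslCountSet(matrix(c(88L, 1L)), matrix(c(12L, 3L)), lib, ss)
#' psiValues(computePsi(cs))
#' @export
computePsi <- function(counts) {
    stopifnot(is(counts, "RaslCountSet"))
    long <- longCounts(counts)
    tot <- totalCounts(counts)
    psi <- 100 * long / tot
    psi[tot == 0L] <- NA_real_
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(psi = psi, total = tot),
        rowData = SummarizedExperiment::rowData(counts),
        colData = SummarizedExperiment::colData(counts),
        metadata = metadata(counts))
    new("RaslPsiSet", se)
}

#' Condition-mean PSI per event
#'
#' Arithmetic mean of the defined (non-\code{NA}) replicate PSI values
#' within each condition.
#'
#' @param psi a \linkS4class{RaslPsiSet}.
#' @return A \link[S4Vectors]{DataFrame} with \code{event_id},
#'   \code{gene_symbol} and one numeric column per condition (NaN when no
#'   replicate was defined).
#' @seealso \code{\link{replicatesUsed}} for the per-condition count of
#'   defined replicates backing each mean.
#' @export
conditionMeans <- function(psi) {
    stopifnot(is(psi, "RaslPsiSet"))
    m <- psiValues(psi)
    cond <- SummarizedExperiment::colData(psi)$condition
    rd <- SummarizedExperiment::rowData(psi)
    out <- DataFrame(event_id = rd$event_id, gene_symbol = rd$gene_symbol)
    for (cc in unique(cond))
        out[[cc]] <- rowMeans(m[, cond == cc, drop = FALSE], na.rm = TRUE)
    rownames(out) <- out$event_id
    out
}

#' Number of defined replicates per event and condition
#'
#' @param psi a \linkS4class{RaslPsiSet}.
#' @return Integer matrix (events x conditions) counting replicates with
#'   defined PSI (total count > 0).
#' @export
replicatesUsed <- function(psi) {
    stopifnot(is(psi, "RaslPsiSet"))
    m <- psiValues(psi)
    cond <- SummarizedExperiment::colData(psi)$condition
    vapply(unique(cond), function(cc)
        as.integer(rowSums(!is.na(m[, cond == cc, drop = FALSE]))),
        integer(nrow(m)))
}

#' Delta PSI between two conditions
#'
#' \code{delta_psi = mean_psi(condition_a) - mean_psi(condition_b)}; the
#' sign convention is always first-named minus second-named condition.
#'
#' @param means a condition-means table as returned by
#'   \code{\link{conditionMeans}} (or \code{\link{psfEventFixture}}): one row
#'   per event with a numeric column per condition.
#' @param condition_a,condition_b condition column names.
#' @return A \link[S4Vectors]{DataFrame} with \code{event_id},
#'   \code{condition_a}, \code{condition_b} and \code{delta_psi}.
#' @examples
#' fx <- psfEventFixture()
#' dp <- deltaPsi(fx, "WT_S", "PSF_KD_S")
#' dp[dp$event_id == "LEF1", "delta_psi"]   # +40
#' @export
deltaPsi <- function(means, condition_a, condition_b) {
    for (cc in c(condition_a, condition_b))
        if (!cc %in% colnames(means))
            stop("condition not present in the means table: ", cc)
    DataFrame(
        event_id = means$event_id,
        condition_a = condition_a,
        condition_b = condition_b,
        delta_psi = as.numeric(means[[condition_a]]) -
            as.numeric(means[[condition_b]]))
}

#' Welch two-sample test on replicate PSI values
#'
#' Two-sided Welch (unequal-variance) t test comparing the replicate PSI
#' values of one condition against another for a single event. Implemented
#' in closed form so degenerate inputs are well defined: with fewer than two
#' defined replicates on either side the p value is \code{NA} (untestable);
#' when both groups are constant the p value is 1 if their means are equal
#' and 0 otherwise.
#'
#' @param psi_a,psi_b numeric vectors of replicate PSI values (NAs dropped).
#' @return The two-sided p value in \code{[0, 1]}, or \code{NA}.
#' @examples
#' testPsiDifference(c(10, 11, 12), c(30, 31, 32))
#' testPsiDifference(c(10, 10, 10), c(10, 10, 10))   # 1
#' @export
testPsiDifference <- function(psi_a, psi_b) {
    a <- psi_a[!is.na(psi_a)]
    b <- psi_b[!is.na(psi_b)]
    n1 <- length(a); n2 <- length(b)
    if (n1 < 2L || n2 < 2L)
        return(NA_real_)
    v1 <- stats::var(a); v2 <- stats::var(b)
    se2 <- v1 / n1 + v2 / n2
    dm <- mean(a) - mean(b)
    if (se2 == 0)
        return(if (dm == 0) 1 else 0)
    tt <- dm / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    2 * stats::pt(-abs(tt), df)
}

#' Per-event Welch p values between two conditions of a RaslPsiSet
#'
#' Applies \code{\link{testPsiDifference}} to every event, comparing the
#' replicate PSI values of \code{condition_a} against \code{condition_b}.
#'
#' @param psi a \linkS4class{RaslPsiSet}.
#' @param condition_a,condition_b condition labels present in the samples.
#' @return Named numeric vector of p values (NA where untestable), one per
#'   event.
#' @export
psiDifferenceTest <- function(psi, condition_a, condition_b) {
    stopifnot(is(psi, "RaslPsiSet"))
    cond <- SummarizedExperiment::colData(psi)$condition
    for (cc in c(condition_a, condition_b))
        if (!cc %in% cond)
            stop("condition not present in the samples: ", cc)
    m <- psiValues(psi)
    ma <- m[, cond == condition_a, drop = FALSE]
    mb <- m[, cond == condition_b, drop = FALSE]
    p <- vapply(seq_len(nrow(m)), function(i)
        testPsiDifference(ma[i, ], mb[i, ]), numeric(1))
    names(p) <- rownames(m)
    p
}
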