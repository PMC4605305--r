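#' Curated PSF-dependent splicing events with published condition-mean PSI
#'
#' Returns the packaged table of 39 PMA-induced, PSF-dependent cassette-exon
#' events identified by RASL-Seq in JSL1 T cells, with the published
#' condition-mean percent-spliced-in values (integer-rounded) for
#' unstimulated wild type (\code{WT_U}), PMA-stimulated wild type
#' (\code{WT_S}) and PMA-stimulated PSF-knockdown cells (\code{PSF_KD_S}).
#'
#' The gene symbol SNHG3-RCC1 appears twice (two distinct events in the same
#' locus); the fixture disambiguates them as event ids \code{SNHG3-RCC1.a}
#' and \code{SNHG3-RCC1.b} in table order. Because only condition means are
#' available (no replicate-level values), downstream calling on this table
#' runs in magnitude-only mode (see \code{\link{callPsfDependentMethods}}).
#'
#' @return A \link[S4Vectors]{DataFrame} with 39 rows and columns
#'   \code{event_id}, \code{gene_symbol}, \code{WT_U}, \code{WT_S},
#'   \code{PSF_KD_S} (integer percent spliced in).
#' @examples
#' fx <- psfEventFixture()
#' fx[fx$event_id == "LEF1", ]
#' @export
psfEventFixture <- function() {
    path <- system.file("extdata", "psf_dependent_events.tsv",
                        package = "raslPSI", mustWork = TRUE)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
    out <- DataFrame(df)
    rownames(out) <- out$event_id
    for (cond in c("WT_U", "WT_S", "PSF_KD_S"))
        out[[cond]] <- as.integer(out[[cond]])
    out
}
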