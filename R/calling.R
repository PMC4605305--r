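#' Knockdown rescue fraction
#'
#' The proportion of the stimulation-induced PSI change reverted by PSF
#' knockdown: \code{(psi_wt_s - psi_kd_s) / (psi_wt_s - psi_wt_u)}. The
#' ratio is sign-aware — values >= 0.6 with numerator and denominator of the
#' same sign satisfy the rescue criterion, which makes the rule symmetric
#' for PSF-enhanced and PSF-repressed exons. Undefined (NA) when the
#' stimulation response \code{psi_wt_s - psi_wt_u} is zero.
#'
#' @param psi_wt_u,psi_wt_s,psi_kd_s numeric vectors of condition-mean PSI
#'   (percent) for unstimulated WT, stimulated WT and stimulated PSF-KD.
#' @return Numeric vector of rescue fractions (NA where undefined).
#' @examples
#' rescueFraction(36, 88, 48)   # LEF1: 40/52
#' rescueFraction(67, 33, 51)   # SESTD1: (-18)/(-34)
#' @export
rescueFraction <- function(psi_wt_u, psi_wt_s, psi_kd_s) {
    num <- psi_wt_s - psi_kd_s
    den <- psi_wt_s - psi_wt_u
    out <- num / den
    out[den == 0] <- NA_real_
    out
}

.require_conditions <- function(means, conds) {
    miss <- setdiff(conds, colnames(means))
    if (length(miss) > 0L)
        stop("means table lacks required condition column(s): ",
             paste(miss, collapse = ", "))
}

.base_call_frame <- function(means, p_values) {
    n <- nrow(means)
    p <- if (is.null(p_values)) rep(NA_real_, n) else {
        if (!is.null(names(p_values)))
            as.numeric(p_values[means$event_id])
        else
            as.numeric(rep_len(p_values, n))
    }
    wt_u <- if ("WT_U" %in% colnames(means))
        as.numeric(means$WT_U) else rep(NA_real_, n)
    DataFrame(
        event_id = means$event_id,
        gene_symbol = if ("gene_symbol" %in% colnames(means))
            means$gene_symbol else means$event_id,
        delta_psi_stim_response = as.numeric(means$WT_S) - wt_u,
        delta_psi_kd = as.numeric(means$WT_S) - as.numeric(means$PSF_KD_S),
        rescue_fraction = rescueFraction(wt_u, as.numeric(means$WT_S),
                                         as.numeric(means$PSF_KD_S)),
        p_value = p)
}

#' Call PSF-dependent events (absolute delta-PSI rule)
#'
#' The primary decision rule: an event is PSF dependent when the absolute
#' difference between the stimulated-WT and stimulated-PSF-KD condition-mean
#' PSI is at least \code{delta_threshold} (default 10, inclusive) and the
#' replicate-level p value is below \code{alpha}. When only condition means
#' are available (as in \code{\link{psfEventFixture}}) the call runs in
#' declared magnitude-only mode and the p-value term is skipped.
#'
#' @param means condition-means table (needs columns \code{WT_S},
#'   \code{PSF_KD_S}; \code{WT_U} used for ancillary fields when present).
#' @param p_values optional per-event p values (named by event id, or
#'   positional); \code{NULL} implies magnitude-only mode.
#' @param delta_threshold minimum \code{|WT_S - PSF_KD_S|} in PSI points
#'   (default 10, inclusive).
#' @param alpha significance level (default 0.05).
#' @param magnitude_only evaluate without the p-value term; defaults to
#'   \code{TRUE} exactly when \code{p_values} is \code{NULL}.
#' @return A \link[S4Vectors]{DataFrame} of event calls with the delta-PSI
#'   fields, \code{rescue_fraction}, \code{p_value}, \code{magnitude_only},
#'   \code{passes_methods_criterion} and \code{direction}
#'   (\code{PSF_enhanced} / \code{PSF_repressed}).
#' @examples
#' calls <- callPsfDependentMethods(psfEventFixture())
#' sum(calls$passes_methods_criterion)   # 39
#' @export
callPsfDependentMethods <- function(means, p_values = NULL,
                                    delta_threshold = 10, alpha = 0.05,
                                    magnitude_only = is.null(p_values)) {
    .require_conditions(means, c("WT_S", "PSF_KD_S"))
    calls <- .base_call_frame(means, p_values)
    sig <- if (magnitude_only) TRUE else
        !is.na(calls$p_value) & calls$p_value < alpha
    calls$magnitude_only <- magnitude_only
    calls$passes_methods_criterion <-
        abs(calls$delta_psi_kd) >= delta_threshold & sig
    classifyDirection(calls)
}

#' Call PSF-dependent events (stimulation-response + rescue rule)
#'
#' The composite decision rule: the event must respond to PMA stimulation in
#' wild-type cells (\code{|WT_S - WT_U| > stim_threshold}, strict, default
#' 9), PSF knockdown in stimulated cells must revert at least
#' \code{rescue_threshold} (default 0.6, inclusive) of that response with
#' knockdown and stimulation shifts of the same sign (see
#' \code{\link{rescueFraction}}), and the replicate-level p value must be
#' below \code{alpha} unless running magnitude-only. Events with zero
#' stimulation response have an undefined rescue fraction and are excluded
#' (flagged by \code{rescue_defined}).
#'
#' @inheritParams callPsfDependentMethods
#' @param stim_threshold minimum \code{|WT_S - WT_U|} in PSI points
#'   (default 9, strict).
#' @param rescue_threshold minimum rescue fraction (default 0.6, inclusive).
#' @return A \link[S4Vectors]{DataFrame} as for
#'   \code{\link{callPsfDependentMethods}}, with
#'   \code{passes_results_criterion} and \code{rescue_defined} columns.
#' @examples
#' calls <- callPsfDependentResults(psfEventFixture())
#' calls$event_id[!calls$passes_results_criterion]   # NFYA, SESTD1
#' @export
callPsfDependentResults <- function(means, p_values = NULL,
                                    stim_threshold = 9,
                                    rescue_threshold = 0.6, alpha = 0.05,
                                    magnitude_only = is.null(p_values)) {
    .require_conditions(means, c("WT_U", "WT_S", "PSF_KD_S"))
    calls <- .base_call_frame(means, p_values)
    sig <- if (magnitude_only) TRUE else
        !is.na(calls$p_value) & calls$p_value < alpha
    same_sign <- sign(calls$delta_psi_kd) ==
        sign(calls$delta_psi_stim_response)
    rescue_ok <- !is.na(calls$rescue_fraction) & same_sign &
        calls$rescue_fraction >= rescue_threshold
    calls$magnitude_only <- magnitude_only
    calls$rescue_defined <- !is.na(calls$rescue_fraction)
    calls$passes_results_criterion <-
        abs(calls$delta_psi_stim_response) > stim_threshold &
        rescue_ok & sig
    classifyDirection(calls)
}

#' Label the direction of PSF regulation
#'
#' \code{PSF_enhanced} when \code{WT_S - PSF_KD_S > 0} (knockdown lowers
#' inclusion, so PSF promotes inclusion of the exon in stimulated cells);
#' \code{PSF_repressed} when negative; \code{NA} (indeterminate) at exactly
#' zero.
#'
#' @param calls an event-call \link[S4Vectors]{DataFrame} with a
#'   \code{delta_psi_kd} column (as produced by the calling functions).
#' @return \code{calls} with a \code{direction} factor column added.
#' @examples
#' calls <- callPsfDependentMethods(psfEventFixture())
#' table(calls$direction)   # 13 enhanced, 26 repressed
#' @export
classifyDirection <- function(calls) {
    stopifnot("delta_psi_kd" %in% colnames(calls))
    dir <- rep(NA_character_, nrow(calls))
    dir[calls$delta_psi_kd > 0] <- "PSF_enhanced"
    dir[calls$delta_psi_kd < 0] <- "PSF_repressed"
    calls$direction <- factor(dir,
                              levels = c("PSF_enhanced", "PSF_repressed"))
    calls
}

#' Classify TRAP150 antagonism of PSF-regulated exons
#'
#' TRAP150 sequesters PSF in resting cells, so depleting TRAP150 in
#' unstimulated cells should shift a PSF-target exon's inclusion toward its
#' stimulated-cell value. An event is \code{antagonistic} when the
#' TRAP150-knockdown shift in resting cells
#' (\code{psi_trapkd_u - psi_wt_u}) has the same sign as the stimulation
#' shift (\code{psi_wt_s - psi_wt_u}) and magnitude at least \code{margin};
#' \code{same_direction} when the signs differ at or above the margin
#' (TRAP150 and PSF act alike); \code{indeterminate} when the knockdown
#' shift is below the margin. The default margin of 5 PSI points reflects
#' the assay's replicate standard deviation (<= 5).
#'
#' @param psi_wt_u,psi_trapkd_u,psi_wt_s numeric condition-mean PSI vectors
#'   for unstimulated WT, unstimulated TRAP150-KD and stimulated WT.
#' @param psi_psfkd_s optional stimulated PSF-KD means, used only for the
#'   ancillary \code{psf_direction} column.
#' @param margin minimum knockdown shift in PSI points (default 5).
#' @param event_id optional event identifiers.
#' @return A \link[S4Vectors]{DataFrame} with \code{event_id},
#'   \code{psf_direction}, \code{trap_kd_shift}, \code{stim_shift} and
#'   \code{label} (\code{antagonistic} / \code{same_direction} /
#'   \code{indeterminate}).
#' @examples
#' callTrap150Antagonism(20, 50, 60)        # antagonistic
#' callTrap150Antagonism(20, 10, 60)        # same_direction
#' callTrap150Antagonism(20, 22, 60)        # indeterminate
#' @export
callTrap150Antagonism <- function(psi_wt_u, psi_trapkd_u, psi_wt_s,
                                  psi_psfkd_s = NULL, margin = 5,
                                  event_id = NULL) {
    stopifnot(margin >= 0)
    n <- length(psi_wt_u)
    stopifnot(length(psi_trapkd_u) == n, length(psi_wt_s) == n)
    stim_shift <- psi_wt_s - psi_wt_u
    trap_kd_shift <- psi_trapkd_u - psi_wt_u
    lab <- rep("indeterminate", n)
    det <- abs(trap_kd_shift) >= margin
    lab[det & sign(trap_kd_shift) == sign(stim_shift)] <- "antagonistic"
    lab[det & sign(trap_kd_shift) != sign(stim_shift)] <- "same_direction"
    psf_dir <- if (is.null(psi_psfkd_s)) rep(NA_real_, n) else
        sign(psi_wt_s - psi_psfkd_s)
    DataFrame(
        event_id = if (is.null(event_id))
            paste0("ev", seq_len(n)) else as.character(event_id),
        psf_direction = psf_dir,
        trap_kd_shift = trap_kd_shift,
        stim_shift = stim_shift,
        label = factor(lab, levels = c("antagonistic", "same_direction",
                                       "indeterminate")))
}
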