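#' Pipeline configuration
#'
#' Assembles and validates the full set of tunable parameters for
#' \code{\link{runRaslPipeline}}. Defaults are the analysis conditions the
#' package models: 3 biological replicates of WT unstimulated, WT
#' PMA-stimulated and PSF-KD stimulated cells; a 10-read mean-coverage
#' filter; the absolute delta-PSI call rule at 10 PSI points with alpha
#' 0.05; the stimulation-response/rescue rule at 9 points and 0.6; and a
#' 5-point antagonism margin.
#'
#' @param n_events number of simulated splicing events.
#' @param conditions condition labels for the simulated sample sheet.
#' @param replicates biological replicates per condition.
#' @param mean_depth expected total reads per event per sample.
#' @param dispersion negative-binomial size (\code{Inf} = Poisson).
#' @param read_error_rate per-base substitution rate for emitted reads.
#' @param junction_length,barcode_length probe-geometry parameters (nt).
#' @param max_mismatches junction mismatch budget when counting.
#' @param min_mean_reads coverage filter threshold.
#' @param methods_delta absolute delta-PSI threshold (inclusive).
#' @param stim_delta stimulation-response threshold (strict).
#' @param rescue rescue-fraction threshold (inclusive).
#' @param alpha significance level, in (0, 1).
#' @param margin antagonism margin in PSI points.
#' @param criterion which call rule drives \code{event_calls.tsv}:
#'   \code{"methods"} (absolute delta-PSI; default) or \code{"results"}
#'   (stimulation response + rescue).
#' @param magnitude_only skip the p-value term of the call rule.
#' @param emit_fastq simulate through FASTQ emission and demultiplexing
#'   (\code{TRUE}) or hand the simulated counts directly to quantification.
#' @param seed master integer seed; every stochastic stage derives its seed
#'   from it.
#' @return A validated list of class \code{rasl_pipeline_config}.
#' @export
raslPipelineConfig <- function(n_events = 200L,
                               conditions = c("WT_U", "WT_S", "PSF_KD_S"),
                               replicates = 3L,
                               mean_depth = 300,
                               dispersion = 10,
                               read_error_rate = 0,
                               junction_length = 40L,
                               barcode_length = 8L,
                               max_mismatches = 1L,
                               min_mean_reads = 10,
                               methods_delta = 10,
                               stim_delta = 9,
                               rescue = 0.6,
                               alpha = 0.05,
                               margin = 5,
                               criterion = c("methods", "results"),
                               magnitude_only = FALSE,
                               emit_fastq = TRUE,
                               seed = 1L) {
    config <- list(
        n_events = as.integer(n_events), conditions = conditions,
        replicates = as.integer(replicates), mean_depth = mean_depth,
        dispersion = dispersion, read_error_rate = read_error_rate,
        junction_length = as.integer(junction_length),
        barcode_length = as.integer(barcode_length),
        max_mismatches = as.integer(max_mismatches),
        min_mean_reads = min_mean_reads, methods_delta = methods_delta,
        stim_delta = stim_delta, rescue = rescue, alpha = alpha,
        margin = margin, criterion = match.arg(criterion),
        magnitude_only = isTRUE(magnitude_only),
        emit_fastq = isTRUE(emit_fastq), seed = as.integer(seed))
    validatePipelineConfig(config)
    class(config) <- c("rasl_pipeline_config", "list")
    config
}

#' @rdname raslPipelineConfig
#' @param config a configuration list.
#' @return \code{validatePipelineConfig} returns \code{config} invisibly or
#'   stops with the first violated constraint.
#' @export
validatePipelineConfig <- function(config) {
    chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg,
                                           call. = FALSE)
    chk(config$n_events >= 1, "n_events must be >= 1")
    chk(config$replicates >= 1, "replicates must be >= 1")
    chk(config$mean_depth > 0, "mean_depth must be > 0")
    chk(config$dispersion > 0, "dispersion must be > 0")
    chk(config$read_error_rate >= 0 && config$read_error_rate < 1,
        "read_error_rate must lie in [0, 1)")
    for (nm in c("max_mismatches", "min_mean_reads", "methods_delta",
                 "stim_delta", "rescue", "margin"))
        chk(config[[nm]] >= 0, paste(nm, "must be non-negative"))
    chk(config$alpha > 0 && config$alpha < 1, "alpha must lie in (0, 1)")
    chk(config$criterion %in% c("methods", "results"),
        "criterion must be 'methods' or 'results'")
    invisible(config)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{\link{raslPipelineConfig}}; unset keys
#' take the defaults. The merged configuration is validated.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    user <- yaml::read_yaml(path)
    known <- names(formals(raslPipelineConfig))
    unknown <- setdiff(names(user), known)
    if (length(unknown) > 0L)
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    do.call(raslPipelineConfig, user)
}

.stage <- function(name, expr, verbose = TRUE) {
    if (verbose)
        message("[raslPSI] stage: ", name)
    tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full RASL-Seq analysis pipeline
#'
#' Executes simulate (or load) -> count -> coverage filter -> PSI ->
#' delta-PSI/test -> PSF-dependence calls -> TRAP150 antagonism (when a
#' \code{TRAP150_KD_U} condition is present), writing every intermediate
#' table as TSV plus a JSON counting report and run manifest into
#' \code{out_dir}. With a fixed seed and identical inputs, repeated runs
#' produce byte-identical outputs (no timestamps are written).
#'
#' @param out_dir output directory (created if missing).
#' @param config a \code{\link{raslPipelineConfig}} list.
#' @param probes optional \linkS4class{ProbeLibrary}; simulated from
#'   \code{config} when \code{NULL}.
#' @param samples optional \linkS4class{RaslSamples}; simulated when
#'   \code{NULL}.
#' @param true_psi optional ground-truth PSI matrix for the simulation;
#'   drawn uniformly on [5, 95] per event x condition when \code{NULL}.
#' @param reads optional existing FASTQ path; when supplied the simulation
#'   stages are skipped and counting starts from these reads.
#' @param verbose log stage progress to stderr.
#' @return Invisibly, a list with the principal objects (\code{counts},
#'   \code{psi}, \code{means}, \code{calls}, \code{antagonism},
#'   \code{manifest}).
#' @export
runRaslPipeline <- function(out_dir, config = raslPipelineConfig(),
                            probes = NULL, samples = NULL, true_psi = NULL,
                            reads = NULL, verbose = TRUE) {
    validatePipelineConfig(config)
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(out_dir, x)

    probes <- .stage("probe library", {
        if (is.null(probes))
            probes <- makeProbeLibrary(config$n_events, seed = config$seed,
                                       junction_length =
                                           config$junction_length)
        writeProbeLibrary(probes, fp("probe_library.tsv"))
        probes
    }, verbose)
    samples <- .stage("sample sheet", {
        if (is.null(samples))
            samples <- makeSampleSheet(config$conditions,
                                       replicates = config$replicates,
                                       barcode_length =
                                           config$barcode_length,
                                       seed = config$seed + 1L)
        writeSampleSheet(samples, fp("samples.tsv"))
        samples
    }, verbose)

    sim_counts <- NULL
    if (is.null(reads)) {
        sim_counts <- .stage("simulate counts", {
            if (is.null(true_psi)) {
                set.seed(config$seed + 2L)
                conds <- unique(samples$condition)
                true_psi <- matrix(
                    round(stats::runif(nrow(probes) * length(conds),
                                       5, 95), 1),
                    nrow(probes), length(conds),
                    dimnames = list(probes$event_id, conds))
            }
            .write_tsv(cbind(data.frame(event_id = probes$event_id),
                             as.data.frame(true_psi)),
                       fp("true_psi.tsv"))
            simulateCounts(probes, samples, true_psi,
                           mean_depth = config$mean_depth,
                           dispersion = config$dispersion,
                           seed = config$seed + 3L)
        }, verbose)
        if (config$emit_fastq)
            reads <- .stage("emit reads", {
                emitReads(sim_counts, fp("reads.fastq"),
                          error_rate = config$read_error_rate,
                          seed = config$seed + 4L)
                fp("reads.fastq")
            }, verbose)
    }

    counts <- if (!is.null(reads))
        .stage("demultiplex and count",
               demultiplexAndCount(reads, probes, samples,
                                   max_mismatches = config$max_mismatches),
               verbose)
    else
        sim_counts
    .stage("write counts", {
        writeCountTable(counts, fp("counts.tsv"))
        rep <- countingReport(counts)
        if (!is.null(rep))
            jsonlite::write_json(rep, fp("counting_report.json"),
                                 auto_unbox = TRUE, pretty = TRUE,
                                 digits = NA)
    }, verbose)

    filtered <- .stage("coverage filter", {
        x <- filterLowCoverage(counts, config$min_mean_reads)
        writeCountTable(x, fp("counts_filtered.tsv"))
        x
    }, verbose)
    if (nrow(filtered) == 0L)
        stop("pipeline stage 'coverage filter' failed: no events pass ",
             "the min_mean_reads threshold", call. = FALSE)

    psi <- .stage("compute PSI", {
        x <- computePsi(filtered)
        writePsiTable(x, fp("psi.tsv"))
        x
    }, verbose)
    means <- .stage("condition means", {
        m <- conditionMeans(psi)
        writeResultTable(m, fp("condition_means.tsv"))
        m
    }, verbose)

    conds <- unique(samples$condition)
    p_values <- NULL
    if (!config$magnitude_only &&
        all(c("WT_S", "PSF_KD_S") %in% conds) && config$replicates >= 2L)
        p_values <- .stage("significance test",
                           psiDifferenceTest(psi, "WT_S", "PSF_KD_S"),
                           verbose)

    calls <- .stage("PSF-dependence calls", {
        x <- if (config$criterion == "methods")
            callPsfDependentMethods(means, p_values,
                                    delta_threshold = config$methods_delta,
                                    alpha = config$alpha,
                                    magnitude_only =
                                        config$magnitude_only ||
                                        is.null(p_values))
        else
            callPsfDependentResults(means, p_values,
                                    stim_threshold = config$stim_delta,
                                    rescue_threshold = config$rescue,
                                    alpha = config$alpha,
                                    magnitude_only =
                                        config$magnitude_only ||
                                        is.null(p_values))
        x$delta_psi <- NULL
        writeResultTable(x, fp("event_calls.tsv"))
        dp <- deltaPsi(means, "WT_S", "PSF_KD_S")
        dp$p_value <- if (is.null(p_values)) NA_real_ else
            as.numeric(p_values[dp$event_id])
        writeResultTable(dp, fp("delta_psi.tsv"))
        x
    }, verbose)

    antagonism <- NULL
    if (all(c("WT_U", "WT_S", "TRAP150_KD_U") %in% colnames(means)))
        antagonism <- .stage("TRAP150 antagonism", {
            x <- callTrap150Antagonism(
                means$WT_U, means$TRAP150_KD_U, means$WT_S,
                psi_psfkd_s = if ("PSF_KD_S" %in% colnames(means))
                    means$PSF_KD_S else NULL,
                margin = config$margin, event_id = means$event_id)
            writeResultTable(x, fp("antagonism.tsv"))
            x
        }, verbose)

    pass_col <- if (config$criterion == "methods")
        "passes_methods_criterion" else "passes_results_criterion"
    manifest <- list(
        package = "raslPSI",
        version = as.character(utils::packageVersion("raslPSI")),
        config = unclass(config),
        n_events_library = nrow(probes),
        n_samples = nrow(samples),
        n_events_after_filter = nrow(filtered),
        n_events_called = sum(calls[[pass_col]], na.rm = TRUE),
        direction_counts = as.list(table(calls$direction)),
        antagonism_counts = if (is.null(antagonism)) NULL else
            as.list(table(antagonism$label)))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(counts = counts, psi = psi, means = means,
                   calls = calls, antagonism = antagonism,
                   manifest = manifest))
}
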