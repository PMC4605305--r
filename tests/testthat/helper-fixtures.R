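# small in-code builders shared across test files

tiny_library <- function(n = 4, seed = 11, junction_length = 12) {
    makeProbeLibrary(n, seed = seed, junction_length = junction_length)
}

tiny_samples <- function(conditions = c("WT_U", "WT_S", "PSF_KD_S"),
                         replicates = 2, seed = 12) {
    makeSampleSheet(conditions, replicates = replicates,
                    barcode_length = 6, seed = seed)
}

# a hand-built two-event library with controlled junction sequences
manual_library <- function() {
    ProbeLibrary(
        event_id = c("evA", "evB"),
        gene_symbol = c("GENEA", "GENEB"),
        long_junction_seq = c("AAAAAAAA", "GGGGGGGG"),
        short_junction_seq = c("CCCCCCCC", "TTTTTTTT"))
}

manual_samples <- function() {
    RaslSamples(genotype = c("WT", "WT"), stimulation = c("U", "S"),
                replicate = c(1, 1), barcode = c("ACGT", "TGCA"))
}

# condition-means table for a single synthetic event
one_event_means <- function(wt_u, wt_s, kd_s, id = "ev1") {
    S4Vectors::DataFrame(event_id = id, gene_symbol = id,
                         WT_U = wt_u, WT_S = wt_s, PSF_KD_S = kd_s)
}
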