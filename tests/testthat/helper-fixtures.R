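# shared fixtures, built once per test run; all seeds fixed
.fixtures <- new.env(parent = emptyenv())

fx <- function(name, builder) {
    if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
    .fixtures[[name]]
}

fx_family <- function() fx("family", function() syntheticFamily(seed = 101))

fx_blocks <- function() fx("blocks", function()
    extractBlocks(fx_family()$alignment, 10, 20, 30))

fx_blockset <- function() fx("blockset", function()
    calibrate(buildBlockSet(fx_blocks()), nSamples = 5000L,
              sampleLen = 100L, seed = 202))

# a small calibrated single profile for scoring tests
fx_hmm <- function() fx("hmm", function()
    calibrate(buildProfile(fx_blocks()[[1]]), nSamples = 2000L,
              sampleLen = 60L, seed = 303))

# write a tiny FASTA alignment to a temp file
write_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
    writeLines(unlist(lapply(names(seqs), function(id)
        c(paste0(">", id), seqs[[id]]))), path)
    path
}

write_boundary_table <- function(bounds, path = tempfile(fileext = ".tsv")) {
    writeLines(vapply(names(bounds), function(id)
        paste(id, paste(bounds[[id]], collapse = ","), sep = "\t"),
        character(1)), path)
    path
}

make_aln <- function(seqs, boundaries = list()) {
    s <- Biostrings::AAStringSet(unlist(seqs))
    names(s) <- names(seqs)
    new("AnnotatedAlignment", sequences = s, boundaries = boundaries)
}

random_aa <- function(n, seed) {
    set.seed(seed)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                 replace = TRUE), collapse = "")
}

# deterministic uniform-codon back-translation used to plant exact profile
# consensus sequences in scanning tests
back_translate_simple <- function(protein, seed = 1) {
    set.seed(seed)
    ct <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
    paste(vapply(strsplit(protein, "")[[1]], function(a)
        ct[[a]][sample.int(length(ct[[a]]), 1)], character(1)),
        collapse = "")
}

profile_consensus <- function(hmm) {
    M <- matchEmissions(hmm)
    paste(colnames(M)[apply(M, 1, which.max)], collapse = "")
}
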