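#' Default pipeline configuration
#'
#' Thresholds mirror the conservative published search settings: block
#' E-value cutoff 0.001 with 6 of 10 blocks required in order for
#' Dscam-like candidates; 0.01 with more than 10 of 37 for the longer
#' hypervariable-gene models; exon-variant cutoff 0.001; the best two
#' hits per (scaffold, HMM) retained.
#'
#' @return Named list of defaults; override any entry via the `config`
#'   argument of [runPipeline()].
#' @export
defaultConfig <- function() {
    list(
        alignment = NULL, boundaries = NULL, genome = NULL,
        regions_bed = NULL, exon_alignments = NULL,
        n_blocks = 10L, block_min = 20L, block_max = 30L,
        gene_e_cutoff = 0.001, k_min = 6L,
        hv_n_blocks = 37L, hv_k_min = 11L, hv_e_cutoff = 0.01,
        exon_e_cutoff = 0.001, top_m = 2L,
        alpha = 1, background = "robinson",
        cal_n_samples = 5000L, cal_sample_len = 100L,
        seed = 1L)
}

pipeline_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stopf("stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full block-scanning pipeline
#'
#' Executes blocks -> build -> calibrate -> scan -> call -> (optional)
#' exon discovery and writes all reports: hits TSV + GFF3, candidate
#' GFF3, variant FASTA/GFF3/TSV, a summary JSON, and a log whose first
#' entry records the resolved configuration and seed.
#'
#' @param config Named list (see [defaultConfig()]) or path to a YAML
#'   file with the same keys.  Required: `alignment` and `boundaries`
#'   (block-training inputs) and `genome` (multi-FASTA path or
#'   `DNAStringSet`).  Optional exon stage: `regions_bed` (BED of
#'   intronic regions, name column = cluster) plus `exon_alignments`
#'   (named list, cluster -> training alignment path).
#' @param outDir Output directory (created).
#' @return List with `hits`, `candidates`, `variants` (or `NULL`),
#'   `summary`, `blockset` and `paths`; the same summary is written as
#'   JSON.  Any stage error aborts with the failing stage named.
#' @export
runPipeline <- function(config = list(), outDir) {
    if (is.character(config) && length(config) == 1L)
        config <- yaml::read_yaml(config)
    cfg <- utils::modifyList(defaultConfig(), config)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    logPath <- file.path(outDir, "run.log")
    logf <- function(fmt, ...) cat(sprintf("[%s] %s\n", Sys.time(),
        sprintf(fmt, ...)), file = logPath, append = TRUE)
    cat(sprintf("[%s] resolved config: %s\n", Sys.time(),
        jsonlite::toJSON(cfg[!vapply(cfg, is.null, logical(1))],
                         auto_unbox = TRUE)), file = logPath)
    logf("package version %s", as.character(utils::packageVersion("dscamtools")))

    bg <- if (identical(cfg$background, "uniform")) uniformBackground()
          else robinsonBackground()

    aln <- pipeline_stage("blocks", {
        if (is.null(cfg$alignment)) stopf("no alignment configured")
        readAnnotatedAlignment(cfg$alignment, cfg$boundaries)
    })
    blocks <- pipeline_stage("blocks",
        extractBlocks(aln, cfg$n_blocks, cfg$block_min, cfg$block_max))
    logf("extracted %d blocks", length(blocks))
    blockset <- pipeline_stage("build",
        buildBlockSet(blocks, alpha = cfg$alpha, background = bg))
    blockset <- pipeline_stage("calibrate",
        calibrate(blockset, nSamples = cfg$cal_n_samples,
                  sampleLen = cfg$cal_sample_len, seed = cfg$seed))
    logf("calibrated %d block HMMs (n=%d, len=%d, seed=%d)",
         length(blockset), cfg$cal_n_samples, cfg$cal_sample_len, cfg$seed)

    genome <- pipeline_stage("scan", {
        if (is.null(cfg$genome)) stopf("no genome configured")
        if (is.character(cfg$genome)) {
            if (!file.exists(cfg$genome))
                stopf("genome file '%s' not found", cfg$genome)
            Biostrings::readDNAStringSet(cfg$genome)
        } else cfg$genome
    })
    hits <- pipeline_stage("scan",
        scanGenome(blockset, genome, eCutoff = cfg$gene_e_cutoff,
                   topM = cfg$top_m))
    logf("scan: %d hits at E <= %g", length(hits), cfg$gene_e_cutoff)
    cands <- pipeline_stage("call",
        callCandidates(hits, nBlocks = length(blockset), kMin = cfg$k_min))
    logf("call: %d candidates at k_min = %d", length(cands), cfg$k_min)

    variants <- NULL
    if (!is.null(cfg$regions_bed)) {
        variants <- pipeline_stage("exons", {
            regions <- readRegionsBED(cfg$regions_bed)
            if (is.null(cfg$exon_alignments))
                stopf("regions given but no exon_alignments configured")
            clusterHMMs <- lapply(cfg$exon_alignments, function(p) {
                a <- readAnnotatedAlignment(p)
                calibrate(buildProfile(a, alpha = cfg$alpha, background = bg),
                          nSamples = cfg$cal_n_samples,
                          sampleLen = cfg$cal_sample_len, seed = cfg$seed)
            })
            scanExonVariants(clusterHMMs, regions, genome,
                             eCutoff = cfg$exon_e_cutoff)
        })
        logf("exons: %d variant hits", length(variants))
    }

    paths <- list(
        hits_tsv = file.path(outDir, "hits.tsv"),
        hits_gff3 = file.path(outDir, "hits.gff3"),
        candidates_gff3 = file.path(outDir, "candidates.gff3"),
        summary_json = file.path(outDir, "summary.json"),
        log = logPath)
    pipeline_stage("report", {
        writeHitsTSV(hits, paths$hits_tsv)
        writeHitsGFF3(hits, paths$hits_gff3)
        writeCandidatesGFF3(cands, paths$candidates_gff3)
    })
    summary <- list(
        n_blocks = length(blockset),
        n_hits = length(hits),
        n_candidates = length(cands),
        candidates = if (length(cands)) lapply(seq_along(cands), function(i)
            list(scaffold = as.character(GenomeInfoDb::seqnames(cands))[i],
                 strand = as.character(BiocGenerics::strand(cands))[i],
                 matchedInOrder = cands$matchedInOrder[i],
                 totalScore = cands$totalScore[i])) else list())
    if (!is.null(variants)) {
        paths$variants_fasta <- file.path(outDir, "variants.fasta")
        paths$variants_gff3 <- file.path(outDir, "variants.gff3")
        paths$variant_summary <- file.path(outDir, "variant_summary.tsv")
        pipeline_stage("report", {
            writeVariants(variants, paths$variants_gff3, paths$variants_fasta)
            write.table(variantSummary(variants), paths$variant_summary,
                        sep = "\t", quote = FALSE, row.names = FALSE)
        })
        summary$variant_counts <- as.list(setNames(
            variantSummary(variants)$n, variantSummary(variants)$cluster))
    }
    pipeline_stage("report",
        jsonlite::write_json(summary, paths$summary_json, auto_unbox = TRUE,
                             digits = NA))
    logf("done")
    list(hits = hits, candidates = cands, variants = variants,
         summary = summary, blockset = blockset, paths = paths)
}
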