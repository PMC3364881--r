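#' Write a profile HMM to a plain-text file
#'
#' A small self-describing format: header, background and insert
#' emission lines, per-position match emission and transition tables
#' (full `%.17g` precision, so [readProfile()] round-trips exactly), and
#' an optional calibration line.
#'
#' @param hmm A [ProfileHMM-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(hmm, path) {
    stopifnot(is(hmm, "ProfileHMM"))
    num <- function(x) paste(sprintf("%.17g", x), collapse = " ")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
        "# dscamtools profile HMM v1",
        paste("NAME", hmm@name),
        paste("LENGTH", hmmLength(hmm)),
        paste("ALPHABET", paste(AA_ALPHABET, collapse = "")),
        paste("BACKGROUND", num(hmm@background)),
        paste("INSERT", num(hmm@insertEmissions))), con)
    if (isCalibrated(hmm))
        writeLines(paste("CALIBRATION",
                         num(hmm@calibration[c("mu", "lambda")])), con)
    writeLines("MATCH", con)
    writeLines(apply(hmm@matchEmissions, 1, num), con)
    writeLines("TRANSITIONS MM MI MD IM II DM DD", con)
    if (hmmLength(hmm) > 1L)
        writeLines(apply(hmm@transitions, 1, num), con)
    writeLines("END", con)
    invisible(path)
}

#' Read a profile HMM written by [writeProfile()]
#'
#' @param path Input file.
#' @return A [ProfileHMM-class].
#' @export
readProfile <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    field <- function(key) {
        ln <- grep(paste0("^", key, " "), lines, value = TRUE)
        if (length(ln) != 1L) stopf("profile file missing '%s' line", key)
        sub(paste0("^", key, " "), "", ln)
    }
    nums <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    name <- field("NAME")
    L <- as.integer(field("LENGTH"))
    background <- setNames(nums(field("BACKGROUND")), AA_ALPHABET)
    insert <- setNames(nums(field("INSERT")), AA_ALPHABET)
    cal_ln <- grep("^CALIBRATION ", lines, value = TRUE)
    cal <- if (length(cal_ln) == 1L) {
        v <- nums(sub("^CALIBRATION ", "", cal_ln))
        c(mu = v[1], lambda = v[2])
    } else numeric(0)
    mstart <- which(lines == "MATCH")
    tstart <- grep("^TRANSITIONS", lines)
    if (length(mstart) != 1L || length(tstart) != 1L)
        stopf("profile file missing MATCH/TRANSITIONS sections")
    M <- do.call(rbind, lapply(lines[(mstart + 1L):(mstart + L)], nums))
    colnames(M) <- AA_ALPHABET
    tr_names <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
    trans <- if (L > 1L)
        do.call(rbind, lapply(lines[(tstart + 1L):(tstart + L - 1L)], nums))
    else matrix(numeric(0), 0L, 7L)
    colnames(trans) <- tr_names
    new("ProfileHMM", name = name, matchEmissions = M,
        insertEmissions = insert, transitions = trans,
        background = background, calibration = cal)
}

#' Write every model of a BlockSet to a directory
#'
#' One `<name>.hmm` file per block plus a `blocks.json` index
#' ([writeBlocksJSON()] format when block windows are known).
#'
#' @param blockset A [BlockSet-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeBlockSet <- function(blockset, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(blockset@hmms))
        writeProfile(blockset@hmms[[i]],
                     file.path(dir, sprintf("block%02d.hmm", i)))
    utils::write.csv(blockset@blockInfo, file.path(dir, "blocks.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' Read a BlockSet written by [writeBlockSet()]
#'
#' @param dir Directory of `block*.hmm` files.
#' @return A [BlockSet-class].
#' @export
readBlockSet <- function(dir) {
    files <- sort(list.files(dir, pattern = "^block[0-9]+\\.hmm$",
                             full.names = TRUE))
    if (length(files) == 0L) stopf("no block*.hmm files in '%s'", dir)
    hmms <- lapply(files, readProfile)
    info_file <- file.path(dir, "blocks.csv")
    info <- if (file.exists(info_file)) utils::read.csv(info_file)
            else data.frame(index = seq_along(hmms), colStart = NA_integer_,
                            colEnd = NA_integer_)
    new("BlockSet", hmms = hmms, blockInfo = info)
}

#' Assemble a BlockSet from block definitions
#'
#' Builds one profile HMM per block (see [buildProfile()]) and wraps them
#' with the source-window table.
#'
#' @param blocks List of [BlockDefinition-class] from [extractBlocks()].
#' @inheritParams buildProfile
#' @return An uncalibrated [BlockSet-class].
#' @export
buildBlockSet <- function(blocks, alpha = 1, background = robinsonBackground()) {
    if (length(blocks) == 0L) stopf("no blocks supplied")
    hmms <- lapply(blocks, buildProfile, alpha = alpha, background = background)
    info <- data.frame(
        index = vapply(blocks, function(b) b@index, integer(1)),
        colStart = vapply(blocks, function(b) b@colStart, integer(1)),
        colEnd = vapply(blocks, function(b) b@colEnd, integer(1)))
    new("BlockSet", hmms = hmms, blockInfo = info)
}
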