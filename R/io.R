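# Dataset serialisation: one FASTQ per individual (Phred+33, constant
# placeholder qualities), a TSV truth table tying each read to its source
# locus/copy/haplotype, and a flat key=value config for sim_params.

#' Write a simulated dataset as FASTQ files plus a truth table
#'
#' @param sim a `rad_sim` (or a reads data.frame with the same columns).
#' @param dir output directory, created if needed.
#' @param quality_char constant placeholder quality character.
#' @return invisibly, the vector of files written.
#' @export
write_rad_fastq <- function(sim, dir, quality_char = "I") {
  reads <- if (inherits(sim, "rad_sim")) sim$reads else sim
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  for (ind in unique(reads$individual)) {
    sub <- reads[reads$individual == ind, , drop = FALSE]
    fp <- file.path(dir, paste0(ind, ".fastq"))
    dna <- Biostrings::DNAStringSet(sub$sequence)
    names(dna) <- sub$read_id
    qual <- Biostrings::PhredQuality(
      Biostrings::BStringSet(strrep(quality_char, nchar(sub$sequence))))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(dna, qual), fp)
    files <- c(files, fp)
  }
  if (inherits(sim, "rad_sim")) {
    tt <- file.path(dir, "truth.tsv")
    utils::write.table(
      sim$reads[, c("read_id", "individual", "population", "locus",
                    "copy", "haplotype")],
      tt, sep = "\t", quote = FALSE, row.names = FALSE)
    pm <- file.path(dir, "popmap.tsv")
    utils::write.table(sim$popmap, pm, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, tt, pm)
  }
  invisible(files)
}

#' Read a directory of per-individual FASTQ files back into a read table
#'
#' @param dir directory holding `<individual>.fastq` files.
#' @param popmap data.frame with `individual` and `population` columns; if
#'   missing, `popmap.tsv` in `dir` is read.
#' @param truth optional truth table (data.frame or path to `truth.tsv`);
#'   when present its tags are joined onto the reads.
#' @return reads data.frame compatible with [assemble_reads()].
#' @export
read_rad_fastq <- function(dir, popmap = NULL, truth = NULL) {
  if (is.null(popmap)) {
    pm_path <- file.path(dir, "popmap.tsv")
    if (!file.exists(pm_path)) stop("no popmap given and no popmap.tsv in ", dir)
    popmap <- utils::read.table(pm_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  chunks <- lapply(seq_len(nrow(popmap)), function(k) {
    fp <- file.path(dir, paste0(popmap$individual[k], ".fastq"))
    if (!file.exists(fp)) stop("missing FASTQ for individual ",
                               popmap$individual[k])
    dna <- Biostrings::readDNAStringSet(fp, format = "fastq")
    data.frame(read_id = names(dna),
               individual = popmap$individual[k],
               population = popmap$population[k],
               sequence = as.character(dna))
  })
  reads <- do.call(rbind, chunks)
  rownames(reads) <- NULL
  if (!is.null(truth)) {
    if (is.character(truth)) {
      truth <- utils::read.table(truth, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    }
    m <- match(reads$read_id, truth$read_id)
    reads$locus <- truth$locus[m]
    reads$copy <- truth$copy[m]
    reads$haplotype <- truth$haplotype[m]
  }
  reads
}

#' Write/read simulation parameters as a flat key=value config
#'
#' @param params a [sim_params()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a `sim_params`.
#' @export
write_sim_config <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  keys <- names(unclass(params))
  writeLines(sprintf("%s=%s", keys,
                     vapply(unclass(params), format, character(1),
                            digits = 17)),
             path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) as.numeric(trimws(x[2L]))),
    vapply(kv, function(x) trimws(x[1L]), character(1)))
  do.call(sim_params, vals)
}
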