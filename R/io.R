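#' Read footprint alignments
#'
#' Alignments live in transcript coordinates. The native format is a TSV
#' with columns `sample`, `transcript_id`, `five_prime_pos` (0-based) and
#' `read_length`. SAM/BAM against the transcript FASTA is also accepted
#' (requires Rsamtools): the 5' end is the leftmost aligned base of a
#' forward-strand record; reverse-strand and unmapped records are rejected
#' with a warning.
#'
#' @param path Input file.
#' @param format `"tsv"` (default), `"sam"` or `"bam"`.
#' @param sample Sample label to assign to SAM/BAM records (one file per
#'   sample); ignored for TSV.
#' @return `data.table` with the four alignment columns.
#' @export
read_alignments <- function(path, format = c("tsv", "sam", "bam"),
                            sample = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    aln <- data.table::fread(path, sep = "\t", header = TRUE)
    req <- c("sample", "transcript_id", "five_prime_pos", "read_length")
    miss <- setdiff(req, names(aln))
    if (length(miss) > 0L) stop("alignment TSV lacks columns: ",
                                paste(miss, collapse = ", "))
    return(aln[, req, with = FALSE])
  }
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM input requires the Rsamtools package")
  }
  if (is.null(sample)) {
    sample <- sub("\\.(sam|bam)$", "", basename(path))
  }
  bam_path <- path
  if (format == "sam") {
    bam_path <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                                 indexDestination = FALSE)
  }
  b <- Rsamtools::scanBam(
    bam_path,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth",
                                             "strand", "flag")))[[1]]
  mapped <- !is.na(b$pos)
  fwd <- as.character(b$strand) == "+"
  drop <- mapped & !fwd
  if (any(drop)) {
    warning(sum(drop), " reverse-strand record(s) rejected")
  }
  keep <- mapped & fwd
  data.table::data.table(
    sample = sample,
    transcript_id = as.character(b$rname)[keep],
    five_prime_pos = b$pos[keep] - 1L,  # SAM POS is 1-based
    read_length = b$qwidth[keep]
  )
}

#' Write a table as TSV
#'
#' Thin wrapper over [data.table::fwrite()] used by the command-line
#' interface for all tabular outputs (occupancy, signal, shift-test,
#' codon-usage, decile tables).
#'
#' @param x A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}
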