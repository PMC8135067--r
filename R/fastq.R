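#' Read a FASTQ file into a read table
#'
#' Reads Sanger (Phred+33) FASTQ via Biostrings and returns the plain
#' data.frame representation the deduplication functions operate on.
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {  # harmless: FASTQ records carry no mcols
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  data.frame(
    read_id  = names(x),
    sequence = as.character(x),
    quality  = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write a read table as FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` columns.
#' @param path output path (uncompressed Phred+33 FASTQ).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::PhredQuality(reads$quality)
  qs <- withCallingHandlers(
    Biostrings::QualityScaledDNAStringSet(x, q),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

check_reads <- function(reads) {
  need <- c("read_id", "sequence", "quality")
  if (!is.data.frame(reads) || !all(need %in% names(reads)))
    stop_invalid("reads must be a data.frame with read_id, sequence, quality")
  if (any(nchar(reads$sequence) != nchar(reads$quality)))
    stop_invalid("sequence and quality lengths differ for some reads")
  if (any(grepl("[^ACGTN]", reads$sequence)))
    stop_invalid("sequences must use the A/C/G/T/N alphabet")
  invisible(reads)
}

## mean Phred score per read (Sanger +33 encoding)
mean_phred <- function(quality) {
  vapply(quality, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}
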