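# FASTQ I/O. Reads are carried through the pipeline as plain data frames
# (id, comment, seq, qual); files are read and written through Biostrings.

#' Read a FASTQ file into a data frame
#'
#' @param path Path to an uncompressed or gzipped FASTQ file (Phred+33).
#' @return A data frame with columns `id` (identifier up to the first
#'   whitespace), `comment` (remainder of the header line, `""` if none),
#'   `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  header <- names(x)
  sp <- regexpr("\\s", header)
  id <- ifelse(sp > 0, substr(header, 1L, sp - 1L), header)
  comment <- ifelse(sp > 0, sub("^\\s+", "", substr(header, sp, nchar(header))), "")
  data.frame(
    id = unname(id),
    comment = unname(comment),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
    stringsAsFactors = FALSE
  )
}

#' Write a read data frame to FASTQ
#'
#' @param reads Data frame with columns `id`, `seq`, `qual` and optionally
#'   `comment` (appended to the header after a space).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$seq)
  header <- reads$id
  if (!is.null(reads$comment)) {
    has_comment <- !is.na(reads$comment) & nzchar(reads$comment)
    header[has_comment] <- paste(header[has_comment], reads$comment[has_comment])
  }
  names(x) <- header
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}
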