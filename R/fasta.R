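#' Read DNA sequences from a FASTA file
#'
#' Thin wrapper over Biostrings for the package's sequence inputs.
#'
#' @param path FASTA file path.
#' @return A named character vector of upper-case sequences.
#' @export
read_dna_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(toupper(as.character(x)), names(x)))
  }
  # minimal fallback when the Bioconductor stack is unavailable
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), function(x) {
    toupper(gsub("\\s", "", paste(x, collapse = "")))
  }, character(1))
  stats::setNames(seqs, sub("^>\\s*", "", lines[hdr]))
}
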