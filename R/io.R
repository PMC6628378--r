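# Plain-text sequence I/O, thin wrappers over Biostrings, tibble in/out.

#' Read and write FASTA as tibbles
#'
#' @param path file path.
#' @return `read_fasta()` returns a tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), sequence = as.character(x))
}

#' @param seqs tibble with columns `id`, `sequence`.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write FASTQ (Sanger Phred+33) as tibbles
#'
#' @param path file path.
#' @return `read_fastq()` returns a tibble with columns `id`, `sequence`,
#'   `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(id = names(x), sequence = as.character(x),
         quality = as.character(S4Vectors::mcols(x)$qualities))
}

#' @param reads tibble with columns `id`, `sequence`, `quality`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n", reads$quality),
             con, sep = "\n")
  invisible(path)
}

#' Collapse reads to unique sequences with counts
#'
#' Standard small RNA collapsing: identical inserts are merged and renamed
#' `seq_<n>_x<count>`.
#'
#' @param reads tibble with a `sequence` column.
#' @return tibble `id`, `sequence`, `count`, most abundant first.
#' @export
collapse_unique <- function(reads) {
  reads %>%
    count(.data$sequence, name = "count") %>%
    arrange(desc(.data$count), .data$sequence) %>%
    mutate(id = sprintf("seq_%d_x%d", row_number(), .data$count)) %>%
    select("id", "sequence", "count")
}
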