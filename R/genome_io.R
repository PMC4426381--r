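#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return Named `DNAStringSet`, one entry per chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome FASTA
#' @param genome Named `DNAStringSet`.
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 80L)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Accepts the plain four-column dialect (chrom, 0-based start, end, value);
#' a leading `track` line is skipped. Returned intervals are 1-based closed.
#'
#' @param path bedGraph file.
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "track") & !startsWith(lines, "#") & nzchar(lines)]
  df <- readr::read_tsv(I(lines), col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", progress = FALSE)
  mutate(df, start = .data$start + 1L)
}

#' Write a bedGraph coverage track
#' @param track Tibble with 1-based closed `chrom`, `start`, `end`, `value`.
#' @param path Output file.
#' @export
write_bedgraph <- function(track, path) {
  out <- transmute(track, .data$chrom, start = .data$start - 1L, .data$end,
                   value = .data$value)
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
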