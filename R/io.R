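#' Read a FASTA file as a named character vector
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning plain
#' uppercase character strings, the representation used throughout the
#' package.
#'
#' @param path path to a FASTA file (protein or nucleotide).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    cat(paste0(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               collapse = "\n"), "\n", sep = "", file = con)
  }
  invisible(path)
}

#' Write a hit table as TSV
#'
#' @param hits a `hit_table` (see [screen_proteomes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# split a sequence string into a character vector of residues
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# residues -> integer codes in AA_ORDER; gaps/ambiguity -> NA
aa_index <- function(chars) match(chars, AA_ORDER)

is_gap <- function(chars) {
  r <- chars %in% GAP_CHARS
  if (!is.null(dim(chars))) dim(r) <- dim(chars)
  r
}

# alignment (named character vector, equal lengths) -> residue matrix
aln_matrix <- function(aln) {
  n <- nchar(aln)
  if (length(unique(n)) != 1L)
    stop("alignment rows have unequal lengths")
  do.call(rbind, lapply(aln, seq_chars))
}

matrix_aln <- function(m) {
  out <- apply(m, 1L, paste0, collapse = "")
  names(out) <- rownames(m)
  out
}
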