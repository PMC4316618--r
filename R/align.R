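#' Multiple sequence alignment of proteins
#'
#' Thin wrapper around MAFFT (default settings, deterministic) operating on
#' named character vectors.  Precomputed alignments in aligned-FASTA form
#' can be ingested with [read_alignment()] instead; both routes yield the
#' same in-memory representation (a named character vector of equal-length
#' aligned sequences).
#'
#' @param seqs named character vector of unaligned protein sequences
#' @param mafft path to the mafft executable
#' @return named character vector of aligned sequences (uppercase, `-` gaps)
#' @export
align_proteins <- function(seqs, mafft = "mafft") {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  if (length(seqs) == 1L) return(seqs)
  if (Sys.which(mafft) == "") {
    stop("mafft executable not found on PATH; supply a precomputed ",
         "alignment via read_alignment() instead")
  }
  fin <- tempfile(fileext = ".faa")
  fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  # temporary safe ids: mafft mangles long/character-rich headers
  tmp_ids <- sprintf("s%06d", seq_along(seqs))
  write_fasta(setNames(unname(seqs), tmp_ids), fin)
  status <- system2(mafft, c("--quiet", "--auto", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- read_fasta(fout)
  setNames(unname(aln[tmp_ids]), names(seqs))
}

#' Read / write an aligned FASTA file
#'
#' @param path file path
#' @return named character vector of equal-length aligned sequences
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  if (length(unique(nchar(aln))) > 1L) {
    stop(path, ": aligned sequences have unequal lengths")
  }
  aln
}

#' @rdname read_alignment
#' @param aln named character vector of aligned sequences
#' @export
write_alignment <- function(aln, path) {
  if (length(unique(nchar(aln))) > 1L) {
    stop("aligned sequences have unequal lengths")
  }
  write_fasta(aln, path)
}
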