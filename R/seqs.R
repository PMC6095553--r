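# Sequence handling: plain uppercase character strings over {A,C,G,T,N},
# with Biostrings doing the FASTA/FASTQ heavy lifting.

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and validated against the DNA alphabet
#' `{A,C,G,T,N}`.
#'
#' @param path Path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  check_dna(out)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read long reads from FASTA or FASTQ
#'
#' @param path Input path; format is chosen by extension (`.fastq`/`.fq`
#'   read as FASTQ, anything else as FASTA).
#' @return Named character vector of read sequences.
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads as FASTQ with uniform placeholder qualities
#'
#' @param reads Named character vector of read sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(!is.null(names(reads)))
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", names(reads)), unname(reads),
                           "+", qual))
  writeLines(lines, path)
  invisible(path)
}

check_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, paste(utils::head(names(x)[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(x))) stop(sprintf("empty %s", what), call. = FALSE)
  invisible(x)
}

#' Reverse complement
#'
#' `N` complements to `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA at a target GC fraction
#'
#' Bases are drawn i.i.d. with P(G) = P(C) = gc/2.
#'
#' @param n Sequence length.
#' @param gc Target GC fraction.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A single DNA string.
#' @export
random_dna <- function(n, gc = 0.45, seed = NULL) {
  with_local_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  })
}

#' GC fraction of a sequence
#'
#' @param x DNA string(s); `N` bases are excluded from the denominator.
#' @return Numeric vector of GC fractions.
#' @export
gc_fraction <- function(x) {
  gc <- nchar(gsub("[^GC]", "", x))
  acgt <- nchar(gsub("[^ACGT]", "", x))
  gc / acgt
}

# substring on a circular sequence: positions may run past nchar(x) and wrap
circ_substr <- function(x, start, end) {
  L <- nchar(x)
  stopifnot(end >= start, end - start + 1 <= L)
  s <- ((start - 1) %% L) + 1
  e <- s + (end - start)
  if (e <= L) substr(x, s, e)
  else paste0(substr(x, s, L), substr(x, 1, e - L))
}
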