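#' Read a genome assembly from FASTA
#'
#' Loads a nucleotide FASTA file and computes the assembly-level composition
#' statistics used as denominators throughout the package: total assembly
#' size (all bases, ambiguity codes included), the number of determined
#' (unambiguous A/C/G/T) nucleotides, and the GC content computed over
#' determined nucleotides only ("GC content without ambiguity").
#'
#' Lowercase (soft-masked) bases are treated as their uppercase equivalents.
#' Any IUPAC ambiguity code (N, R, Y, ...) counts towards the assembly size
#' but neither towards the determined length nor the GC denominator.
#'
#' @param path path to a FASTA file. Alphabet restricted to IUPAC nucleotide
#'   codes (case-insensitive); any other character is an error that names
#'   the offending sequence and position.
#' @return a `genome_assembly` object: a list with elements
#'   `sequences` (a [Biostrings::DNAStringSet]), `seq_lengths` (named
#'   integer), `assembly_size`, `determined_length` and `gc_unambiguous`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_annodiff("FASTA file does not exist: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop_annodiff("FASTA file contains no sequences: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop_annodiff("duplicate sequence id(s) in FASTA: ",
                  paste(unique(dup), collapse = ", "))
  }
  names(raw) <- ids
  chr <- toupper(as.character(raw))
  bad <- regexpr("[^ACGTRYSWKMBDHVN]", chr)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop_annodiff(sprintf(
      "non-nucleotide character '%s' in sequence '%s' at position %d",
      substr(chr[i], bad[i], bad[i]), ids[i], bad[i]))
  }
  seqs <- Biostrings::DNAStringSet(chr)
  genome_assembly(seqs)
}

#' Construct a genome assembly object from sequences
#'
#' @param sequences a named [Biostrings::DNAStringSet] (or named character
#'   vector) of uppercase nucleotide sequences.
#' @return a `genome_assembly` object; see [read_genome_fasta()].
#' @export
genome_assembly <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  if (is.null(names(sequences)) || anyNA(names(sequences)) ||
      any(names(sequences) == "")) {
    stop_annodiff("all assembly sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop_annodiff("duplicate sequence id(s) in assembly")
  }
  freq <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
  acgt <- colSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  determined <- sum(acgt)
  total <- sum(Biostrings::width(sequences))
  gc <- if (determined > 0) 100 * (acgt[["G"]] + acgt[["C"]]) / determined
        else NA_real_
  structure(
    list(
      sequences = sequences,
      seq_lengths = stats::setNames(Biostrings::width(sequences),
                                    names(sequences)),
      assembly_size = total,
      determined_length = determined,
      gc_unambiguous = gc
    ),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf(
    "<genome_assembly> %d sequence(s), %d bp (%.1f%% determined), GC %.2f%%\n",
    length(x$sequences), x$assembly_size,
    100 * x$determined_length / x$assembly_size, x$gc_unambiguous))
  invisible(x)
}

#' GC content of genomic intervals
#'
#' Computes, for each interval, 100 * (G+C) / (A+C+G+T) over the bases it
#' covers. Ambiguity codes are excluded from both numerator and denominator;
#' an interval consisting entirely of ambiguous bases has undefined GC and
#' yields `NA`. GC content is strand-insensitive, so no strand argument is
#' taken. Coordinates are 0-based half-open.
#'
#' @param assembly a `genome_assembly`.
#' @param seq_id character vector of sequence ids.
#' @param start,end integer vectors, 0-based half-open interval bounds.
#' @return numeric vector of GC percentages (`NA` where undefined).
#' @export
feature_gc <- function(assembly, seq_id, start, end) {
  stopifnot(inherits(assembly, "genome_assembly"))
  n <- length(seq_id)
  stopifnot(length(start) == n, length(end) == n)
  if (n == 0L) return(numeric(0))
  unknown <- setdiff(unique(seq_id), names(assembly$sequences))
  if (length(unknown) > 0L) {
    stop_annodiff("unknown sequence id(s): ", paste(unknown, collapse = ", "))
  }
  lens <- assembly$seq_lengths[seq_id]
  if (any(start < 0 | end > lens | start >= end)) {
    stop_annodiff("interval out of sequence bounds")
  }
  out <- numeric(n)
  for (sid in unique(seq_id)) {
    idx <- which(seq_id == sid)
    parts <- Biostrings::extractAt(
      assembly$sequences[[sid]],
      IRanges::IRanges(start = start[idx] + 1L, end = end[idx]))
    freq <- Biostrings::alphabetFrequency(parts, baseOnly = TRUE)
    det <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- 100 * (freq[, "G"] + freq[, "C"]) / det
    gc[det == 0] <- NA_real_
    out[idx] <- gc
  }
  out
}
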