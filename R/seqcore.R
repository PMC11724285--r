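#' @import methods
#' @importFrom stats median quantile rbinom rlnorm runif setNames
#' @importFrom utils head write.csv read.csv
NULL

RNA_BASES <- c("A", "C", "G", "U")
DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("UAA", "UAG", "UGA")
# reverse complements of the stop codons; a duplex whose opposite strand is
# also translated must avoid these too
STOP_CODON_RC <- c("UUA", "CUA", "UCA")

#' Validate a nucleotide sequence
#'
#' Checks that `x` is a single string over the declared alphabet. The package
#' works internally in RNA space; DNA inputs are converted at the boundary.
#'
#' @param x Character scalar.
#' @param alphabet `"rna"`, `"dna"`, or `"auto"` (infer from T/U content;
#'   sequences without T or U are accepted under either tag).
#' @param allow_empty Permit the empty string.
#' @param allow_ambiguity Permit IUPAC ambiguity codes (N, R, Y, ...). Design
#'   inputs must be fully specified; sequencing reads may carry N.
#' @return The validated, upper-cased sequence with the resolved alphabet in
#'   attribute `"alphabet"`.
#' @export
validate_nuc <- function(x, alphabet = c("auto", "rna", "dna"),
                         allow_empty = FALSE, allow_ambiguity = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("sequence must be a single non-NA character string", call. = FALSE)
  }
  x <- toupper(x)
  if (nchar(x) == 0L) {
    if (!allow_empty) stop("empty sequence not permitted here", call. = FALSE)
    attr(x, "alphabet") <- if (alphabet == "auto") "rna" else alphabet
    return(x)
  }
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  if (alphabet == "auto") {
    alphabet <- if ("T" %in% chars && !("U" %in% chars)) "dna" else "rna"
  }
  ok <- if (alphabet == "rna") RNA_BASES else DNA_BASES
  if (allow_ambiguity) {
    ok <- c(ok, "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  }
  bad <- which(!(chars %in% ok))
  if (length(bad)) {
    stop(sprintf("non-%s character '%s' at position %d (0-based %d)",
                 toupper(alphabet), chars[bad[1L]], bad[1L], bad[1L] - 1L),
         call. = FALSE)
  }
  attr(x, "alphabet") <- alphabet
  x
}

#' Convert between DNA and RNA alphabets
#'
#' T and U are exchanged; the conversion is a bijection and round-trips
#' exactly.
#'
#' @param x Nucleotide string.
#' @return Converted string.
#' @export
as_rna <- function(x) chartr("Tt", "Uu", toupper(x))

#' @rdname as_rna
#' @export
as_dna <- function(x) chartr("Uu", "Tt", toupper(x))

#' Reverse complement
#'
#' Watson-Crick reverse complement in the sequence's own alphabet.
#'
#' @param seq Nucleotide string (RNA or DNA; auto-detected).
#' @return Reverse complement, same alphabet.
#' @examples
#' reverse_complement("UAG")   # "CUA"
#' reverse_complement("GATC")  # "GATC"
#' @export
reverse_complement <- function(seq) {
  seq <- validate_nuc(seq, allow_ambiguity = TRUE)
  alpha <- attr(seq, "alphabet")
  out <- if (alpha == "dna") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq)))
  }
  attr(out, "alphabet") <- alpha
  out
}

#' Complement a single base (RNA space)
#' @param base Single RNA base.
#' @return Its Watson-Crick complement.
#' @keywords internal
complement_base <- function(base) {
  chartr("ACGU", "UGCA", base)
}

split_chars <- function(x) strsplit(as.character(x), "", fixed = TRUE)[[1L]]

#' Translate an RNA sequence
#'
#' Standard genetic code, halting at the first stop codon. DNA input is
#' converted to RNA first. A trailing partial codon is ignored and flagged,
#' not an error.
#'
#' @param seq Nucleotide string.
#' @param frame_offset 0, 1 or 2.
#' @return List with `peptide` (one-letter string), `stopped` (logical: a stop
#'   codon was reached), and `partial_codon` (logical: 1-2 trailing bases were
#'   ignored).
#' @examples
#' translate_rna("AUGUAGGGG")$peptide  # "M", stopped
#' translate_rna("AUGUGGGGG")$peptide  # "MWG", runs through
#' @export
translate_rna <- function(seq, frame_offset = 0L) {
  seq <- as_rna(validate_nuc(seq))
  stopifnot(frame_offset %in% 0:2)
  body <- substr(seq, frame_offset + 1L, nchar(seq))
  n <- nchar(body)
  if (n < 3L) {
    return(list(peptide = "", stopped = FALSE, partial_codon = n > 0L))
  }
  n_codons <- n %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codons)
  codons <- substring(body, starts, starts + 2L)
  aa <- GENETIC_CODE_RNA[codons]
  stop_at <- which(aa == "*")
  stopped <- length(stop_at) > 0L
  keep <- if (stopped) seq_len(stop_at[1L] - 1L) else seq_len(n_codons)
  list(peptide = paste(aa[keep], collapse = ""),
       stopped = stopped,
       partial_codon = !stopped && (n %% 3L != 0L))
}

GENETIC_CODE_RNA <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), chartr("T", "U", names(gc)))
})

#' Audit a reading frame for stop codons
#'
#' Lists every in-frame stop codon (UAA, UAG, UGA) at the given frame offset.
#' Positions are 0-based indices of the codon's first base in the full
#' sequence.
#'
#' @param seq Nucleotide string (RNA; DNA converted).
#' @param frame_offset 0, 1 or 2.
#' @return List with `frame_offset`, `stop_positions` (strictly increasing
#'   integer vector) and `length_mod3`.
#' @export
audit_frame <- function(seq, frame_offset = 0L) {
  seq <- as_rna(validate_nuc(seq))
  stopifnot(frame_offset %in% 0:2)
  n <- nchar(seq)
  starts <- seq.int(frame_offset + 1L, by = 3L,
                    length.out = max(0L, (n - frame_offset) %/% 3L))
  stops <- integer(0)
  if (length(starts)) {
    codons <- substring(seq, starts, starts + 2L)
    stops <- starts[codons %in% STOP_CODONS] - 1L
  }
  list(frame_offset = as.integer(frame_offset),
       stop_positions = as.integer(stops),
       length_mod3 = n %% 3L)
}

#' Read and write FASTA
#'
#' Thin wrappers over Biostrings FASTA I/O returning plain named character
#' vectors with an alphabet tag. Output is wrapped at 60 columns.
#'
#' @param path File path.
#' @param alphabet `"auto"`, `"rna"` or `"dna"`.
#' @return `read_fasta`: named character vector with attribute `"alphabet"`.
#' @export
read_fasta <- function(path, alphabet = c("auto", "rna", "dna")) {
  alphabet <- match.arg(alphabet)
  x <- Biostrings::readBStringSet(path, format = "fasta")
  seqs <- toupper(as.character(x))
  if (alphabet == "auto") {
    alphabet <- if (any(grepl("U", seqs, fixed = TRUE))) "rna" else "dna"
  }
  out <- setNames(seqs, names(x))
  attr(out, "alphabet") <- alphabet
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path, alphabet = c("auto", "rna", "dna")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "rna") seqs[] <- vapply(seqs, as_rna, "")
  if (alphabet == "dna") seqs[] <- vapply(seqs, as_dna, "")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, format = "fasta", width = 60L)
  invisible(path)
}

#' Read and write FASTQ
#'
#' Reads a FASTQ file into a data frame of read records: `id`, `bases` (DNA,
#' possibly with N) and `quals` (Phred+33 string, same length as `bases`).
#'
#' @param path File path.
#' @return `read_fastq`: data frame with columns `id`, `bases`, `quals`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             bases = as.character(x),
             quals = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}

#' @rdname read_fastq
#' @param reads Data frame with `id`, `bases`, `quals` columns.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "bases", "quals") %in% names(reads)))
  set <- Biostrings::DNAStringSet(reads$bases)
  names(set) <- reads$id
  Biostrings::writeXStringSet(set, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

#' Phred conversion helpers
#' @param qual Phred+33 quality string.
#' @return Integer vector of Phred scores.
#' @keywords internal
phred_scores <- function(qual) utf8ToInt(qual) - 33L

phred_string <- function(scores) intToUtf8(scores + 33L)
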