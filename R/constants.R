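# Fixed cassette parts and default aptamer sequences. The reporter's
# fluorophore ORFs shipped here are deterministic stop-free SYNTHETIC
# surrogates (the cassette logic only needs in-frame, stop-free coding
# sequence of realistic length); swap in real BFP/GFP ORFs via
# assemble_reporter()'s flanks argument for wet-lab export.

#' Default cassette part sequences
#'
#' `P2A_RNA`: ribosomal-skipping P2A peptide coding sequence (22 codons,
#' GSG-linked). `LINKER_2XGGGGS_RNA`: flexible 2xGGGGS linker (10 codons).
#' `MS2_RNA`: 21-nt MS2 phage coat-protein binding hairpin (C-variant stem
#' loop with one closing pair; stop-free in frame 0). All RNA alphabet.
#'
#' @format Character scalars (RNA).
#' @name cassette_parts
NULL

#' @rdname cassette_parts
#' @export
P2A_RNA <- "GGAAGCGGAGCUACUAACUUCAGCCUGCUGAAGCAGGCUGGAGACGUGGAGGAGAACCCUGGACCU"

#' @rdname cassette_parts
#' @export
LINKER_2XGGGGS_RNA <- "GGAGGCGGUGGAAGCGGAGGCGGUGGAAGC"

#' @rdname cassette_parts
#' @export
MS2_RNA <- "GACAUGAGGAUCACCCAUGUC"

#' Default aptamer specifications
#'
#' `atp_aptamer_spec()`: the canonical 40-nt ATP RNA aptamer.
#' `nfkb_aptamer_spec()`: a 29-nt synthetic surrogate standing in for the
#' published NF-kB p50 RNA aptamer (Kd ~5 nM); the surrogate preserves length
#' and GC balance only and is documented as synthetic.
#'
#' @param blocker_window Integer pair (start, end), 0-based half-open window
#'   within the aptamer whose reverse complement forms the blocker.
#' @return An `aptamer_spec` list: `name`, `sequence` (RNA), `kd_note`,
#'   `blocker_window`.
#' @export
atp_aptamer_spec <- function(blocker_window = c(0L, 18L)) {
  aptamer_spec(name = "ATP-aptamer-40nt",
               sequence = "GGGUUGGGAAGAAACUGUGGCACUUCGGUGCCAGCAACCC",
               kd_note = "ATP RNA aptamer, low-micromolar Kd (literature)",
               blocker_window = blocker_window)
}

#' @rdname atp_aptamer_spec
#' @export
nfkb_aptamer_spec <- function(blocker_window = c(0L, 18L)) {
  aptamer_spec(name = "NFkB-aptamer-29nt-synthetic",
               sequence = "GGCACGUCCGGUCCAAGCGCGUCCGGCAC",
               kd_note = "synthetic 29-nt surrogate; published aptamer Kd 5 nM",
               blocker_window = blocker_window)
}

#' Build an aptamer specification
#'
#' @param name Aptamer name.
#' @param sequence RNA sequence.
#' @param kd_note Free-text affinity metadata.
#' @param blocker_window 0-based half-open (start, end) within the aptamer;
#'   its reverse complement is the blocker. Must lie inside the aptamer.
#' @return An `aptamer_spec` list.
#' @export
aptamer_spec <- function(name, sequence, kd_note = "",
                         blocker_window = c(0L, 18L)) {
  sequence <- as_rna(validate_nuc(sequence))
  bw <- as.integer(blocker_window)
  if (length(bw) != 2L || bw[1L] < 0L || bw[2L] > nchar(sequence) ||
      bw[2L] < bw[1L]) {
    stop("blocker_window must lie within the aptamer", call. = FALSE)
  }
  structure(list(name = name, sequence = as.character(sequence),
                 kd_note = kd_note, blocker_window = bw),
            class = "aptamer_spec")
}

# Deterministic stop-free surrogate ORF: cycles through a fixed codon set
# that contains no stop, no stop-prefix risk at codon joins (no codon ends
# in U followed by one starting AA/AG/GA) and no homopolymer > 3.
surrogate_orf <- function(n_codons, start_codon = TRUE, stop_codon = FALSE,
                          phase = 0L) {
  codons <- c("GCU", "GAC", "CUG", "AAG", "GAA", "UUC", "CAC", "AUC",
              "CCG", "AGC", "ACC", "GUG", "AAC", "CAG", "CGC", "GGA")
  body_n <- n_codons - as.integer(start_codon) - as.integer(stop_codon)
  idx <- ((phase + seq_len(body_n) - 1L) %% length(codons)) + 1L
  paste0(if (start_codon) "AUG" else "",
         paste(codons[idx], collapse = ""),
         if (stop_codon) "UAA" else "")
}

#' Surrogate fluorophore ORFs
#'
#' Deterministic synthetic stand-ins for the BFP and GFP open reading frames
#' of the reporter cassette: stop-free in frame 0, realistic length (120
#' codons). The BFP surrogate starts with AUG and carries no terminator (it
#' reads through P2A); the GFP surrogate ends with a UAA terminator.
#'
#' @param n_codons ORF length in codons (including start/stop where present).
#' @return RNA character scalar.
#' @export
bfp_surrogate_orf <- function(n_codons = 120L) {
  surrogate_orf(n_codons, start_codon = TRUE, stop_codon = FALSE, phase = 0L)
}

#' @rdname bfp_surrogate_orf
#' @export
gfp_surrogate_orf <- function(n_codons = 120L) {
  surrogate_orf(n_codons, start_codon = FALSE, stop_codon = TRUE, phase = 5L)
}
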