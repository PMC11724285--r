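# Deterministic stem-filler generation. Non-constrained stem positions are
# drawn from a seeded stream with two local rejections: no homopolymer run
# longer than 3, and no stop codon (UAA/UAG/UGA) or reverse-complement of a
# stop (UUA/CUA/UCA) anywhere in either reading direction -- a filler clean
# under this rule can sit at any frame offset, and so can its Watson-Crick
# partner strand.

FORBIDDEN_TRINUCS <- c("UAA", "UAG", "UGA", "UUA", "CUA", "UCA")

has_forbidden_motif <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) return(FALSE)
  tri <- substring(seq, 1:(n - 2L), 3:n)
  any(tri %in% FORBIDDEN_TRINUCS)
}

max_homopolymer <- function(seq) {
  if (nchar(seq) == 0L) return(0L)
  r <- rle(split_chars(seq))
  max(r$lengths)
}

# Draw one filler of length n given the bases immediately 5' of it. Greedy
# with shuffled candidates; every 2-base context leaves at least one legal
# base, so generation never stalls.
draw_filler <- function(n, context_left = "") {
  if (n == 0L) return("")
  out <- character(n)
  ctx <- split_chars(context_left)
  for (k in seq_len(n)) {
    cand <- sample(RNA_BASES)
    tail3 <- utils::tail(c(ctx, out[seq_len(k - 1L)]), 3L)
    for (b in cand) {
      win <- paste(c(utils::tail(tail3, 2L), b), collapse = "")
      run <- paste(c(tail3, b), collapse = "")
      if (!has_forbidden_motif(win) && max_homopolymer(run) <= 3L) {
        out[k] <- b
        break
      }
    }
    if (out[k] == "") out[k] <- "C"  # unreachable fallback
  }
  paste(out, collapse = "")
}

# Scan the designated core of a construct (everything except exempt ranges,
# e.g. the sensing arm and aptamer, which get frame-specific audits later)
# for forbidden trinucleotides. `exempt` is a list of 0-based half-open
# (start, end) pairs; the designated UAG codon is always exempt.
core_motif_clean <- function(seq, uag_start, exempt = list()) {
  n <- nchar(seq)
  if (n < 3L) return(TRUE)
  starts0 <- 0:(n - 3L)
  tri <- substring(seq, starts0 + 1L, starts0 + 3L)
  bad <- tri %in% FORBIDDEN_TRINUCS
  # windows overlapping the designated UAG codon or an exempt range are fine
  overlaps <- function(s, e) starts0 + 2L >= s & starts0 <= e - 1L
  bad[overlaps(uag_start, uag_start + 3L)] <- FALSE
  for (ex in exempt) bad[overlaps(ex[1L], ex[2L])] <- FALSE
  !any(bad)
}

with_design_seed <- function(seed, attempt, code) {
  withr::with_seed(as.integer((seed %% 1000000L) * 1009L + attempt), code)
}
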