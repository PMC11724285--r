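# Seeded generators for transcripts, edited amplicon reads and flow event
# tables. Every generator is a pure function of (config, seed): reruns are
# byte-identical, and each output carries a truth record so downstream
# estimates are compared against realized ground truth, never against
# re-simulated data.

#' Simulate a target transcript with planted sensor sites
#'
#' Generates a random transcript and optionally plants: a clean sensor site
#' (arm reverse complement free of in-frame stops, junction base compatible),
#' a stop-poisoned site (the arm acquires an in-frame stop codon), and an
#' SNV position. The manifest records ground-truth coordinates.
#'
#' @param length Transcript length (>= arm_length + 20).
#' @param seed Integer seed.
#' @param clean_site Window start for the clean site, or NULL.
#' @param poison_site Window start for the stop-poisoned site, or NULL.
#' @param snv List `(position, alt_base)` for a planted substitution pair,
#'   or NULL.
#' @param arm_length Arm length the sites are built for (default 39).
#' @param junction_base Base planted at the clean site's junction position
#'   (default G, pairing the retained sensor C).
#' @return List: `sequence` (RNA), `manifest` (list of planted features),
#'   and for SNV plants `mutant_sequence`.
#' @export
simulate_transcript <- function(length = 200L, seed = 7L, clean_site = 80L,
                                poison_site = NULL, snv = NULL,
                                arm_length = 39L, junction_base = "G") {
  L <- as.integer(arm_length)
  if (length < L + 20L) stop("transcript too short for the arm",
                             call. = FALSE)
  sites <- Filter(Negate(is.null), list(clean = clean_site,
                                        poison = poison_site))
  for (a in sites) for (b in sites) {
    if (!identical(a, b) && abs(a - b) < L + 1L) {
      stop("planted sites overlap", call. = FALSE)
    }
  }
  withr::with_seed(as.integer(seed), {
    seq_chars <- sample(RNA_BASES, length, replace = TRUE)
    manifest <- list(arm_length = L)
    plant_window <- function(ws, poisoned) {
      if (ws < 0L || ws + L >= length) stop("planted site out of range",
                                            call. = FALSE)
      # windows whose reverse complement (the arm) is free of stop motifs
      win <- draw_filler(L)
      arm <- reverse_complement(win)
      if (poisoned) {
        # place a stop at a codon-aligned arm offset: arm[0:3] == "UAG"
        # means the window ends with the reverse complement "CUA"
        substr(win, L - 2L, L) <- "CUA"
      }
      seq_chars[(ws + 1L):(ws + L)] <<- split_chars(win)
      seq_chars[ws + L + 1L] <<- junction_base
      list(window = c(ws, ws + L), junction_pos = ws + L)
    }
    if (!is.null(clean_site)) {
      manifest$clean <- plant_window(as.integer(clean_site), FALSE)
    }
    if (!is.null(poison_site)) {
      manifest$poison <- plant_window(as.integer(poison_site), TRUE)
    }
    sequence <- paste(seq_chars, collapse = "")
    mutant <- NULL
    if (!is.null(snv)) {
      pos <- as.integer(snv$position)
      ref <- substr(sequence, pos + 1L, pos + 1L)
      alt <- as_rna(toupper(snv$alt_base %||%
                              sample(setdiff(RNA_BASES, ref), 1L)))
      if (alt == ref) stop("requested alt equals the reference base",
                           call. = FALSE)
      mutant <- sequence
      substr(mutant, pos + 1L, pos + 1L) <- alt
      manifest$snv <- list(position = pos, ref_base = ref, alt_base = alt)
    }
    out <- list(sequence = sequence, manifest = manifest)
    if (!is.null(mutant)) out$mutant_sequence <- mutant
    out
  })
}

#' Simulate edited paired-end amplicon reads
#'
#' Each read pair covers the amplicon ends (R1 forward from the 5' end, R2
#' reverse-complemented from the 3' end) with a configured overlap. Per
#' fragment, the central-site A is drawn G with probability `edit_p` (and
#' any `bystander_p` sites likewise); sequencing errors substitute random
#' bases at `error_rate`; qualities follow a constant high-Q profile with a
#' fraction of low-Q positions to exercise trimming. The truth table records
#' realized per-site edited-read counts before errors.
#'
#' @param reference Amplicon sequence (DNA or RNA; reads are DNA).
#' @param central_site 0-based A position carrying the edit.
#' @param edit_p Per-read central edit probability.
#' @param depth Number of read pairs.
#' @param read_length Read length (default 120; must not exceed the
#'   reference).
#' @param error_rate Per-base substitution error rate (default 0.001).
#' @param bystander_p Named numeric vector of additional site probabilities
#'   (names = 0-based positions of reference As).
#' @param q_high,q_low,q_low_frac Quality profile: Phred `q_high` (36) with
#'   `q_low_frac` (2%) of positions at `q_low` (12).
#' @param seed Integer seed.
#' @return List: `r1`, `r2` (read data frames), `truth` (list with
#'   `edited`, `depth`, `edit_frac`, `bystander` counts, `central_site`).
#' @export
simulate_reads <- function(reference, central_site, edit_p = 0.6,
                           depth = 2000L, read_length = 120L,
                           error_rate = 0.001, bystander_p = NULL,
                           q_high = 36L, q_low = 12L, q_low_frac = 0.02,
                           seed = 11L) {
  reference <- as_dna(validate_nuc(reference))
  nref <- nchar(reference)
  if (read_length > nref) stop("read length exceeds the reference",
                               call. = FALSE)
  if (substr(reference, central_site + 1L, central_site + 1L) != "A") {
    stop("central_site does not hold an A", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    ref_chars <- split_chars(reference)
    frag <- matrix(rep(ref_chars, each = depth), nrow = depth)
    edited <- runif(depth) < edit_p
    frag[edited, central_site + 1L] <- "G"
    bys_counts <- integer(0)
    if (!is.null(bystander_p)) {
      bys_counts <- setNames(integer(length(bystander_p)),
                             names(bystander_p))
      for (k in seq_along(bystander_p)) {
        pos <- as.integer(names(bystander_p)[k])
        hit <- runif(depth) < bystander_p[k]
        frag[hit, pos + 1L] <- "G"
        bys_counts[k] <- sum(hit)
      }
    }
    err <- which(matrix(runif(depth * nref) < error_rate, nrow = depth),
                 arr.ind = TRUE)
    if (nrow(err)) {
      cur <- frag[err]
      frag[err] <- vapply(cur, function(b)
        sample(setdiff(DNA_BASES, b), 1L), "")
    }
    make_quals <- function(n) {
      q <- matrix(q_high, nrow = depth, ncol = n)
      low <- matrix(runif(depth * n) < q_low_frac, nrow = depth)
      q[low] <- q_low
      apply(q, 1L, phred_string)
    }
    r1_bases <- apply(frag[, seq_len(read_length), drop = FALSE], 1L,
                      paste, collapse = "")
    r2_fwd <- apply(frag[, (nref - read_length + 1L):nref, drop = FALSE],
                    1L, paste, collapse = "")
    r2_bases <- vapply(r2_fwd, function(x)
      as.character(reverse_complement(x)), "", USE.NAMES = FALSE)
    ids <- sprintf("read_%05d", seq_len(depth))
    list(r1 = data.frame(id = ids, bases = r1_bases,
                         quals = make_quals(read_length),
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = ids, bases = r2_bases,
                         quals = make_quals(read_length),
                         stringsAsFactors = FALSE),
         truth = list(central_site = as.integer(central_site),
                      edited = sum(edited), depth = depth,
                      edit_frac = sum(edited) / depth,
                      bystander = bys_counts))
  })
}

#' Simulate flow-cytometry event tables
#'
#' Produces plus-target, minus-target and vector-only control tables. BFP is
#' lognormal in transfected cells; GFP is proportional to BFP (shared
#' plasmid dose) times a baseline leak ratio, multiplied by the activation
#' factor in the plus condition, with per-cell lognormal noise. A fraction
#' of events is untransfected (autofluorescent BFP/GFP); a fraction are
#' doublets (SSC_A about twice SSC_H).
#'
#' @param n_events Events per condition (>= 100; default 10000).
#' @param activation Programmed fold activation (truth; default 100).
#' @param baseline_ratio GFP/BFP leak ratio without target (default 0.004).
#' @param bfp_meanlog,bfp_sdlog BFP lognormal parameters (default 4, 0.5).
#' @param noise_sdlog Per-cell multiplicative noise sdlog (default 0.2).
#' @param untransfected_frac Fraction of autofluorescent events
#'   (default 0.3).
#' @param doublet_frac Fraction of doublets (default 0.05).
#' @param seed Integer seed.
#' @return List: `plus`, `minus`, `control` (event data frames with a
#'   `condition` column), `truth` (list with `activation`,
#'   `untransfected_frac`).
#' @export
simulate_events <- function(n_events = 10000L, activation = 100,
                            baseline_ratio = 0.004, bfp_meanlog = 4,
                            bfp_sdlog = 0.5, noise_sdlog = 0.2,
                            untransfected_frac = 0.3, doublet_frac = 0.05,
                            seed = 1L) {
  if (n_events < 100L) stop("n_events must be >= 100", call. = FALSE)
  stopifnot(bfp_sdlog > 0, noise_sdlog >= 0, baseline_ratio > 0)
  withr::with_seed(as.integer(seed), {
    one_table <- function(act, condition, transfected_frac) {
      untr <- runif(n_events) < (1 - transfected_frac)
      bfp <- ifelse(untr,
                    rlnorm(n_events, meanlog = 0.3, sdlog = 0.4),
                    rlnorm(n_events, bfp_meanlog, bfp_sdlog))
      gfp <- ifelse(untr,
                    rlnorm(n_events, meanlog = 0.1, sdlog = 0.4),
                    bfp * baseline_ratio * act *
                      rlnorm(n_events, 0, noise_sdlog))
      fsc <- rlnorm(n_events, 7, 0.25)
      ssc_h <- rlnorm(n_events, 6.5, 0.3)
      doublet <- runif(n_events) < doublet_frac
      ssc_a <- ssc_h * ifelse(doublet, 2, rlnorm(n_events, 0, 0.05))
      data.frame(FSC_A = fsc, SSC_A = ssc_a, SSC_H = ssc_h,
                 BFP = bfp, GFP = gfp, condition = condition,
                 stringsAsFactors = FALSE)
    }
    plus <- one_table(activation, "plus", 1 - untransfected_frac)
    minus <- one_table(1, "minus", 1 - untransfected_frac)
    control <- one_table(1, "control", 0)
    list(plus = plus, minus = minus, control = control,
         truth = list(activation = activation,
                      untransfected_frac = untransfected_frac))
  })
}
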