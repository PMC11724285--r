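# Desk-scale amplicon editing quantification: end-quality trimming, paired
# read merging, fit alignment of merged reads into the reference amplicon,
# pileup, and per-site A-to-G percentages with bystander flags. Edits are
# counted as A->G on the reference sense strand (the sensor cDNA amplicon);
# reverse-strand reads are oriented before counting.

#' Quality-filter reads
#'
#' Trims both ends while the terminal base quality is below `q_cut`, then
#' discards reads whose N fraction exceeds `n_frac` (or that trim away
#' entirely).
#'
#' @param reads Data frame with `id`, `bases`, `quals` (Phred+33), as from
#'   [read_fastq()].
#' @param q_cut Phred threshold for end trimming (default 20).
#' @param n_frac Maximum tolerated N fraction (default 0.10).
#' @return List: `reads` (filtered data frame), `stats` (named counts:
#'   `input`, `kept`, `discarded_n`, `discarded_empty`, `bases_trimmed`).
#' @export
quality_filter <- function(reads, q_cut = 20L, n_frac = 0.10) {
  n_in <- nrow(reads)
  out <- vector("list", n_in)
  trimmed_total <- 0L
  disc_n <- 0L; disc_empty <- 0L
  for (r in seq_len(n_in)) {
    q <- phred_scores(reads$quals[r])
    lo <- 1L; hi <- length(q)
    while (lo <= hi && q[lo] < q_cut) lo <- lo + 1L
    while (hi >= lo && q[hi] < q_cut) hi <- hi - 1L
    trimmed_total <- trimmed_total + (length(q) - max(0L, hi - lo + 1L))
    if (hi < lo) {
      disc_empty <- disc_empty + 1L
      next
    }
    bases <- substr(reads$bases[r], lo, hi)
    n_count <- nchar(gsub("[^N]", "", bases))
    if (n_count / nchar(bases) > n_frac) {
      disc_n <- disc_n + 1L
      next
    }
    out[[r]] <- data.frame(id = reads$id[r], bases = bases,
                           quals = substr(reads$quals[r], lo, hi),
                           stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(kept)) {
    kept <- reads[0, c("id", "bases", "quals")]
  }
  rownames(kept) <- NULL
  list(reads = kept,
       stats = c(input = n_in, kept = nrow(kept), discarded_n = disc_n,
                 discarded_empty = disc_empty,
                 bases_trimmed = trimmed_total))
}

#' Merge a read pair into one amplicon-spanning record
#'
#' The mate is reverse-complemented, then the maximal-identity
#' suffix/prefix overlap of length >= `min_overlap` with identity >=
#' `min_identity` is taken (ties toward the longer overlap). Overlap
#' disagreements resolve toward the higher-quality base (read 1 on quality
#' ties).
#'
#' @param r1,r2 Single read records: lists/rows with `bases` and `quals`.
#' @param min_overlap Minimum overlap length (default 10).
#' @param min_identity Minimum overlap identity (default 0.9).
#' @return List: `merged` (logical) and, when merged, `read` (record with
#'   `id`, `bases`, `quals`) plus `overlap` and `identity`.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 10L, min_identity = 0.9) {
  b1 <- r1$bases; q1 <- phred_scores(r1$quals)
  b2 <- reverse_complement(r2$bases)
  q2 <- rev(phred_scores(r2$quals))
  n1 <- nchar(b1); n2 <- nchar(b2)
  raw1 <- charToRaw(b1); raw2 <- charToRaw(b2)
  best_ov <- 0L; best_ident <- -1
  for (ov in seq.int(min(n1, n2), min_overlap)) {
    m <- sum(raw1[(n1 - ov + 1L):n1] == raw2[seq_len(ov)])
    ident <- m / ov
    if (ident > best_ident) {
      best_ident <- ident; best_ov <- ov
      if (ident == 1) break
    }
  }
  if (best_ov < min_overlap || best_ident < min_identity) {
    return(list(merged = FALSE))
  }
  ov <- best_ov
  i1 <- (n1 - ov + 1L):n1
  i2 <- seq_len(ov)
  c1 <- split_chars(b1)[i1]; c2 <- split_chars(b2)[i2]
  take1 <- c1 == c2 | q1[i1] >= q2[i2]
  cons <- ifelse(take1, c1, c2)
  consq <- pmax(q1[i1], q2[i2])
  bases <- paste0(substr(b1, 1L, n1 - ov), paste(cons, collapse = ""),
                  substr(b2, ov + 1L, n2))
  tail2 <- if (ov < n2) q2[(ov + 1L):n2] else integer(0)
  quals <- phred_string(c(q1[seq_len(n1 - ov)], consq, tail2))
  list(merged = TRUE,
       read = data.frame(id = r1$id %||% "merged", bases = bases,
                         quals = quals, stringsAsFactors = FALSE),
       overlap = ov, identity = best_ident)
}

#' Merge a table of read pairs
#'
#' Row-wise [merge_pairs()] over two equal-length read data frames.
#'
#' @param r1,r2 Read data frames (`id`, `bases`, `quals`).
#' @inheritParams merge_pairs
#' @return List: `reads` (merged records), `stats` (`pairs`, `merged`,
#'   `unmerged`).
#' @export
merge_pair_table <- function(r1, r2, min_overlap = 10L, min_identity = 0.9) {
  stopifnot(nrow(r1) == nrow(r2))
  merged <- vector("list", nrow(r1))
  for (r in seq_len(nrow(r1))) {
    m <- merge_pairs(r1[r, ], r2[r, ], min_overlap, min_identity)
    if (m$merged) merged[[r]] <- m$read
  }
  keep <- Filter(Negate(is.null), merged)
  reads <- if (length(keep)) do.call(rbind, keep) else r1[0, ]
  rownames(reads) <- NULL
  list(reads = reads,
       stats = c(pairs = nrow(r1), merged = nrow(reads),
                 unmerged = nrow(r1) - nrow(reads)))
}

align_scoring <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                           baseOnly = FALSE)
}

#' Fit-align reads into the reference amplicon
#'
#' Global-in-read, local-in-reference alignment (match +2, mismatch -3, gap
#' open -5, extend -2) of each read on both strands; the better-scoring
#' strand wins (forward on ties). Reads scoring below `min_score` are
#' flagged unaligned.
#'
#' @param reads Read data frame (`id`, `bases`, `quals`) or a single record.
#' @param reference Amplicon sequence (DNA; length <= 2000).
#' @param min_score Score floor; default half the maximum attainable
#'   (`nchar(read)` per read, i.e. half of 2 per base).
#' @return Data frame: `id`, `offset` (0-based start of the read on the
#'   reference), `strand`, `score`, `aligned` (logical), `ref_seq` (the read
#'   projected into reference space: one character per covered reference
#'   position, `-` for deletions, insertions removed).
#' @export
align_to_amplicon <- function(reads, reference, min_score = NULL) {
  reference <- as_dna(validate_nuc(reference))
  if (nchar(reference) > 2000L) stop("reference longer than 2000 nt",
                                     call. = FALSE)
  if (!is.data.frame(reads)) reads <- as.data.frame(reads)
  if (nrow(reads) == 0L) {
    return(data.frame(id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0),
                      aligned = logical(0), ref_seq = character(0)))
  }
  fwd <- Biostrings::DNAStringSet(as_dna(reads$bases))
  rvc <- Biostrings::reverseComplement(fwd)
  subj <- Biostrings::DNAString(reference)
  mat <- align_scoring()
  pa_f <- Biostrings::pairwiseAlignment(fwd, subj, type = "global-local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
  pa_r <- Biostrings::pairwiseAlignment(rvc, subj, type = "global-local",
                                        substitutionMatrix = mat,
                                        gapOpening = 5, gapExtension = 2)
  use_rev <- Biostrings::score(pa_r) > Biostrings::score(pa_f)
  floor_score <- if (is.null(min_score)) nchar(reads$bases) else min_score
  score <- ifelse(use_rev, Biostrings::score(pa_r), Biostrings::score(pa_f))
  pick <- function(getter) ifelse(use_rev, getter(pa_r), getter(pa_f))
  starts <- pick(function(x) IRanges::start(Biostrings::subject(x)))
  ends <- pick(function(x) IRanges::end(Biostrings::subject(x)))
  # aligned() projects each read into subject coordinates (deletions kept as
  # '-', insertions dropped), padded to the full subject width
  proj <- pick(function(x) as.character(Biostrings::aligned(x)))
  ref_seq <- substr(proj, starts, ends)
  data.frame(id = reads$id, offset = starts - 1L,
             strand = ifelse(use_rev, "reverse", "forward"),
             score = score, aligned = score >= floor_score,
             ref_seq = ref_seq, stringsAsFactors = FALSE)
}

#' Per-site A-to-G editing rates from aligned reads
#'
#' Piles aligned reads up over the reference, then reports, for every
#' reference adenosine, `edit_pct = 100 * G / (A + G)` wherever the A+G
#' depth reaches `min_depth`. Non-central adenosines whose rate exceeds
#' `bystander_threshold` are flagged.
#'
#' @param alignments Output of [align_to_amplicon()].
#' @param reference Amplicon sequence (DNA).
#' @param central_site 0-based reference position of the designed editing
#'   site (must hold A).
#' @param min_depth Minimum A+G depth for a defined rate (default 50).
#' @param bystander_threshold Flagging threshold in percent (default 2).
#' @return An `editing_report`: `counts` (position x A/C/G/T/N/del matrix),
#'   `edit_pct` (per-A-position vector, NA below depth), `central_site`,
#'   `central_pct`, `central_depth`, `bystanders` (data frame), `status`
#'   (`"ok"` or `"insufficient_depth"`).
#' @export
editing_rates <- function(alignments, reference, central_site,
                          min_depth = 50L, bystander_threshold = 2) {
  reference <- as_dna(validate_nuc(reference))
  nref <- nchar(reference)
  central_site <- as.integer(central_site)
  if (substr(reference, central_site + 1L, central_site + 1L) != "A") {
    stop("central_site does not hold an A on the reference", call. = FALSE)
  }
  alignments <- alignments[alignments$aligned, , drop = FALSE]
  if (nrow(alignments) == 0L) {
    stop("no aligned reads", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T", "N", "del")
  counts <- matrix(0L, nrow = nref, ncol = length(bases),
                   dimnames = list(NULL, bases))
  widths <- nchar(alignments$ref_seq)
  all_chars <- unlist(strsplit(alignments$ref_seq, "", fixed = TRUE),
                      use.names = FALSE)
  all_pos <- rep(alignments$offset, widths) + sequence(widths)  # 1-based
  all_chars[all_chars == "-"] <- "del"
  code <- match(all_chars, bases)
  code[is.na(code)] <- match("N", bases)
  flat <- tabulate((all_pos - 1L) * length(bases) + code,
                   nbins = nref * length(bases))
  counts[] <- matrix(flat, nrow = nref, ncol = length(bases), byrow = TRUE)
  covered_central <- sum(alignments$offset < central_site + 1L &
                           alignments$offset + widths >= central_site + 1L)
  if (covered_central == 0L) {
    stop("no aligned read covers the central site", call. = FALSE)
  }
  ref_chars <- split_chars(reference)
  a_pos <- which(ref_chars == "A") - 1L
  ag_depth <- counts[a_pos + 1L, "A"] + counts[a_pos + 1L, "G"]
  pct <- ifelse(ag_depth >= min_depth,
                100 * counts[a_pos + 1L, "G"] / pmax(ag_depth, 1L), NA_real_)
  names(pct) <- a_pos
  central_depth <- unname(counts[central_site + 1L, "A"] +
                            counts[central_site + 1L, "G"])
  central_pct <- unname(100 * counts[central_site + 1L, "G"] /
                          max(central_depth, 1L))
  status <- if (central_depth >= min_depth) "ok" else "insufficient_depth"
  non_central <- a_pos != central_site
  flag <- non_central & !is.na(pct) & pct > bystander_threshold
  bystanders <- data.frame(position = a_pos[flag], edit_pct = pct[flag],
                           depth = ag_depth[flag])
  rownames(bystanders) <- NULL
  structure(list(counts = counts, edit_pct = pct,
                 central_site = central_site,
                 central_pct = central_pct, central_depth = central_depth,
                 bystanders = bystanders, status = status,
                 n_reads = nrow(alignments)),
            class = "editing_report")
}

#' @export
print.editing_report <- function(x, ...) {
  cat(sprintf(
    "<editing_report> central site %d: %.2f%% A->G (depth %d, %s); %d bystander flag(s)\n",
    x$central_site, x$central_pct, x$central_depth, x$status,
    nrow(x$bystanders)))
  invisible(x)
}

#' Run the full editing-quantification chain
#'
#' quality_filter -> merge_pair_table -> align_to_amplicon -> editing_rates.
#'
#' @param r1,r2 Paired read data frames (`r2 = NULL` for single-end).
#' @param reference Amplicon (DNA).
#' @param central_site 0-based editing-site position.
#' @param q_cut,n_frac,min_overlap,min_depth,bystander_threshold Stage
#'   parameters, as in the individual functions.
#' @return The `editing_report`, with the stage stats attached as
#'   `$pipeline_stats`.
#' @export
quantify_editing <- function(r1, r2 = NULL, reference, central_site,
                             q_cut = 20L, n_frac = 0.10, min_overlap = 10L,
                             min_depth = 50L, bystander_threshold = 2) {
  f1 <- quality_filter(r1, q_cut, n_frac)
  if (!is.null(r2)) {
    f2 <- quality_filter(r2, q_cut, n_frac)
    common <- intersect(f1$reads$id, f2$reads$id)
    m <- merge_pair_table(f1$reads[match(common, f1$reads$id), ],
                          f2$reads[match(common, f2$reads$id), ],
                          min_overlap = min_overlap)
    reads <- m$reads
    merge_stats <- m$stats
  } else {
    reads <- f1$reads
    merge_stats <- c(pairs = NA_integer_)
  }
  aln <- align_to_amplicon(reads, reference)
  rep <- editing_rates(aln, reference, central_site, min_depth,
                       bystander_threshold)
  rep$pipeline_stats <- list(filter = f1$stats, merge = merge_stats,
                             aligned = sum(aln$aligned))
  rep
}
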