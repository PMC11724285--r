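# Candidate-site scanning on a target transcript. Site selection in the wet
# lab was empirical (three to five candidate arms per target, best kept);
# the composite score here is an explicitly labelled heuristic that encodes
# the published context preferences and penalizes bystander-editable
# adenosines.

#' Scan a target transcript for candidate sensor sites
#'
#' Enumerates every arm-length window (scanning the given strand only; mRNA
#' targets are single-stranded), applies three filters -- (i) no ambiguity
#' codes, (ii) `stop_clean`: the arm's in-frame codons carry no stop codon,
#' (iii) the junction base next to the window pairs the retained sensor base
#' -- and ranks survivors by a composite score: `10 * context_tier -
#' bystander_count + 0.5 * GC count in the 6 nick-proximal target nt`. Ties
#' break toward fewer bystanders, then the 5'-most window. In
#' `cca_source = "target"` mode only windows whose 3' flank supplies the CCA
#' triplet are candidates and the tier grades that triplet; in
#' `"intramolecular"` mode (default) the sensor supplies the CCA and every
#' junction-compatible window holds the top tier.
#'
#' @param target Transcript (RNA or DNA; ambiguity codes tolerated but
#'   windows containing them are filtered).
#' @param config List overriding `arm_length` (39), `junction_pair`,
#'   `cca_source`, `triplet_opposite`.
#' @param top Keep the best `top` sites (Inf for all).
#' @return Data frame of `TargetSite` rows: `rank`, `start`, `end`,
#'   `junction_base`, `context_tier`, `stop_clean`, `bystander_count`,
#'   `composite_score`. Attribute `"reasons"` holds the filter histogram
#'   (named integer vector), also returned when no window passes.
#' @export
scan_target <- function(target, config = list(), top = 5L) {
  cfg <- default_design_config(config)
  target <- as_rna(validate_nuc(target, allow_ambiguity = TRUE))
  L <- as.integer(cfg$arm_length)
  n <- nchar(target)
  if (n < L + 1L) stop("target shorter than arm length + 1", call. = FALSE)
  cca_target <- cfg$cca_source == "target"
  flank <- if (cca_target) 4L else 1L
  starts <- 0:(n - L - flank)
  reasons <- c(ambiguity = 0L, stop = 0L, junction = 0L, motif = 0L)
  rows <- list()
  tch <- split_chars(target)
  for (ws in starts) {
    we <- ws + L
    window <- substr(target, ws + 1L, we)
    if (grepl("[^ACGU]", window)) {
      reasons["ambiguity"] <- reasons["ambiguity"] + 1L
      next
    }
    if (cca_target &&
        substr(target, we + 1L, we + 3L) != cfg$triplet_opposite) {
      reasons["motif"] <- reasons["motif"] + 1L
      next
    }
    arm <- reverse_complement(window)
    stop_clean <- length(arm_stop_codons(arm)) == 0L
    if (!stop_clean) {
      reasons["stop"] <- reasons["stop"] + 1L
      next
    }
    jpos <- if (cca_target) we + 3L else we
    jbase <- tch[jpos + 1L]
    if (jbase != cfg$junction_pair[2L]) {
      reasons["junction"] <- reasons["junction"] + 1L
      next
    }
    tier <- if (!cca_target) 3L else {
      trip <- substr(target, we + 1L, we + 3L)  # always CCA here
      context_tier(trip)
    }
    # bystanders: adenosines in the active duplex other than the edited one.
    # Sensor-strand As mirror target-strand Us; count As on both strands of
    # the arm:window helix plus the non-central As of the editing loop.
    wch <- tch[(ws + 1L):we]
    bystanders <- sum(wch == "A") + sum(wch == "U")
    gc6 <- sum(tch[max(ws + 1L, we - 5L):we] %in% c("G", "C"))
    score <- 10 * tier - bystanders + 0.5 * gc6
    rows[[length(rows) + 1L]] <- data.frame(
      start = ws, end = we, junction_base = jbase, context_tier = tier,
      stop_clean = TRUE, bystander_count = bystanders,
      composite_score = score, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), start = integer(0),
                      end = integer(0), junction_base = character(0),
                      context_tier = integer(0), stop_clean = logical(0),
                      bystander_count = integer(0),
                      composite_score = numeric(0))
    attr(out, "reasons") <- reasons
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$composite_score, out$bystander_count, out$start)
  out <- out[ord, , drop = FALSE]
  out <- utils::head(out, top)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "reasons") <- reasons
  out
}

# Ordinal context tiers for the target-supplied triplet opposite the UAG:
# middle C is required (tier 0 without it), a 5'-neighbouring C is preferred,
# CCA is the top performer.
context_tier <- function(triplet) {
  b <- split_chars(triplet)
  if (b[2L] != "C") return(0L)
  if (triplet == "CCA") return(3L)
  if (b[1L] == "C") return(2L)
  1L
}

#' Audit bystander-editable adenosines in an active duplex
#'
#' Lists every adenosine on either strand of the active-state duplex with
#' the base opposite it; non-central A:C oppositions are flagged high-risk
#' (they resemble the designed editing site).
#'
#' @param construct A `sensor_construct` with an active pairing map.
#' @param target Target sequence for external pairs (defaults to the
#'   attached target; ignored for pure substrates).
#' @return Data frame: `position` (0-based), `strand` (`"sensor"`/
#'   `"target"`), `base`, `opposite_base`, `high_risk`.
#' @export
bystander_audit <- function(construct, target = NULL) {
  p <- construct$pairs$active
  if (is.null(p) || nrow(p) == 0L) {
    stop("active-state pairing map unavailable", call. = FALSE)
  }
  target <- target %||%
    (if (!is.null(construct$target)) construct$target$sequence)
  sch <- split_chars(construct$sequence)
  tch <- if (is.null(target)) character(0) else split_chars(target)
  base_i <- sch[p$i + 1L]
  base_j <- ifelse(p$space == "intra", sch[p$j + 1L], tch[p$j + 1L])
  rows <- list()
  add <- function(pos, strand, base, opp, central) {
    data.frame(position = pos, strand = strand, base = base,
               opposite_base = opp,
               high_risk = !central & opp == "C", stringsAsFactors = FALSE)
  }
  central_i <- p$i == construct$edit_index
  central_j <- p$space == "intra" & p$j == construct$edit_index
  ai <- base_i == "A"
  aj <- base_j == "A"
  out <- rbind(
    if (any(ai)) add(p$i[ai], "sensor", "A", base_j[ai], central_i[ai]),
    if (any(aj)) add(p$j[aj],
                     ifelse(p$space[aj] == "intra", "sensor", "target"),
                     "A", base_i[aj], central_j[aj]))
  if (is.null(out)) {
    out <- data.frame(position = integer(0), strand = character(0),
                      base = character(0), opposite_base = character(0),
                      high_risk = logical(0))
  }
  rownames(out) <- NULL
  out[order(out$position), , drop = FALSE]
}
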