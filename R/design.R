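# Construction of hairpin substrates, inert sensors, RNA/SNV/aptamer sensors,
# MS2 augmentation and the full BFP-P2A-linker-sensor-GFP reporter cassette.
#
# Geometry conventions (0-based, half-open throughout):
#   * The hairpin stem is drawn as domains a:a* and b:b* flanking the editing
#     loop. Stem lengths len_a/len_b COUNT the boundary base pairs of the
#     UAG:CCA closure (the G:C pair belongs to a:a*, the U:A pair to b:b*),
#     so a 7/9 design is a 16-bp duplex and a 10/12 design spans 23 bp
#     including the central A-C mismatch.
#   * Feature tiling of a substrate, 5'->3':
#       [domain_a][triplet_opposite][domain_b_star][loop]
#       [domain_b][triplet_sensor][domain_a_star]
#     where domain_a/domain_a* carry len_a-1 filler bases each (likewise b),
#     and the triplets carry the boundary pairs plus the central mismatch.
#   * Sensing-mode constructs replace domain_a by the single retained
#     junction cytosine and domain_a* by the sensing arm (reverse complement
#     of the target window); the arm starts immediately 3' of the UAG's G.

WC_PARTNERS <- c(A = "U", U = "A", G = "C", C = "G")

is_wc <- function(a, b) !is.na(WC_PARTNERS[a]) & WC_PARTNERS[a] == b

#' Hairpin substrate parameters
#'
#' Stem lengths include the boundary pairs of the editing loop: `len_a`
#' counts the G:C pair of UAG:CCA, `len_b` the U:A pair. The defaults encode
#' the saturating design (10 + 12 bp, 23-bp duplex span); the model substrate
#' is `len_a = 7, len_b = 9` (16-bp duplex).
#'
#' @param len_a,len_b Stem lengths in base pairs (>= 1).
#' @param loop_seq Hairpin loop (length >= 3; default GAAA tetraloop).
#' @param triplet_sensor 3-mer carrying the editable A at its centre
#'   (default UAG).
#' @param triplet_opposite 3-mer opposite the sensor triplet (default CCA;
#'   its middle C opposite the A gives the preferred A-C mismatch).
#' @param junction_pair Ordered pair (sensor base, target base) closing the
#'   nick in sensing mode; default C:G.
#' @param junction_context Context base flanking the closure (metadata used
#'   by site scoring; default C).
#' @return A `hairpin_params` list.
#' @export
hairpin_params <- function(len_a = 10L, len_b = 12L, loop_seq = "GAAA",
                           triplet_sensor = "UAG", triplet_opposite = "CCA",
                           junction_pair = c("C", "G"),
                           junction_context = "C") {
  len_a <- as.integer(len_a); len_b <- as.integer(len_b)
  if (len_a < 1L || len_b < 1L) stop("len_a and len_b must be >= 1",
                                     call. = FALSE)
  loop_seq <- as_rna(validate_nuc(loop_seq))
  if (nchar(loop_seq) < 3L) stop("loop must be at least 3 nt", call. = FALSE)
  triplet_sensor <- as_rna(validate_nuc(triplet_sensor))
  triplet_opposite <- as_rna(validate_nuc(triplet_opposite))
  if (nchar(triplet_sensor) != 3L || substr(triplet_sensor, 2L, 2L) != "A") {
    stop("triplet_sensor must be a 3-mer with a central A", call. = FALSE)
  }
  if (nchar(triplet_opposite) != 3L) {
    stop("triplet_opposite must be a 3-mer", call. = FALSE)
  }
  structure(list(len_a = len_a, len_b = len_b,
                 loop_seq = as.character(loop_seq),
                 triplet_sensor = as.character(triplet_sensor),
                 triplet_opposite = as.character(triplet_opposite),
                 junction_pair = toupper(junction_pair),
                 junction_context = toupper(junction_context)),
            class = "hairpin_params")
}

feature_frame <- function(names, lens) {
  ends <- cumsum(lens)
  data.frame(name = names, start = ends - lens, end = ends,
             stringsAsFactors = FALSE)
}

feature_range <- function(construct, name) {
  f <- construct$features[construct$features$name == name, , drop = FALSE]
  if (nrow(f) == 0L) return(NULL)
  c(f$start[1L], f$end[1L])
}

pair_kind <- function(a, b) ifelse(is_wc(a, b), "wc", "mismatch")

new_construct <- function(sequence, features, pairs_resting, pairs_active,
                          mode, edit_index, params, target = NULL,
                          seed = NA_integer_) {
  ch <- split_chars(sequence)
  if (ch[edit_index + 1L] != "A") {
    stop("internal: editable position is not an A", call. = FALSE)
  }
  structure(list(sequence = sequence, features = features,
                 pairs = list(resting = pairs_resting, active = pairs_active),
                 mode = mode, edit_index = as.integer(edit_index),
                 params = params, target = target, seed = seed),
            class = "sensor_construct")
}

#' @export
print.sensor_construct <- function(x, ...) {
  cat(sprintf("<sensor_construct> mode=%s length=%d edit_index=%d\n",
              x$mode, nchar(x$sequence), x$edit_index))
  cat(" features:",
      paste(sprintf("%s[%d,%d)", x$features$name, x$features$start,
                    x$features$end), collapse = " "), "\n")
  invisible(x)
}

# Pairs between the two triplets: opposite[0]:sensor[2], the central
# opposite[1] vs A, opposite[2]:sensor[0].
triplet_pairs <- function(opp_start, sen_start, opp, sen) {
  o <- split_chars(opp); s <- split_chars(sen)
  data.frame(i = opp_start + 0:2,
             j = sen_start + 2:0,
             kind = pair_kind(o, s[3:1]),
             space = "intra", stringsAsFactors = FALSE)
}

stem_pairs <- function(start5, start3_last, n) {
  if (n == 0L) return(NULL)
  k <- 0:(n - 1L)
  data.frame(i = start5 + k, j = start3_last - k, kind = "wc",
             space = "intra", stringsAsFactors = FALSE)
}

bind_pairs <- function(...) {
  out <- do.call(rbind, Filter(Negate(is.null), list(...)))
  rownames(out) <- NULL
  out[order(out$i), , drop = FALSE]
}

#' Build a hairpin substrate
#'
#' Emits the self-contained editing substrate
#' `5'-[domain_a]-[CCA]-[domain_b*]-[loop]-[domain_b]-[UAG]-[domain_a*]-3'`
#' whose intended pairing map holds `len_a + len_b` Watson-Crick pairs plus
#' the annotated central A-C mismatch (duplex span `len_a + len_b + 1`).
#' Filler stem positions are drawn deterministically from `seed`, rejecting
#' homopolymer runs > 3 and any stop codon (or reverse-complement stop) in
#' any frame on either strand.
#'
#' @param params A [hairpin_params()] object.
#' @param seed Integer seed for filler generation.
#' @return A `sensor_construct` with mode `"substrate"`.
#' @examples
#' s <- build_substrate(hairpin_params(len_a = 7, len_b = 9))
#' sum(s$pairs$resting$kind == "wc")  # 16
#' @export
build_substrate <- function(params = hairpin_params(), seed = 1L) {
  fa <- params$len_a - 1L; fb <- params$len_b - 1L
  llen <- nchar(params$loop_seq)
  for (attempt in 0:49) {
    seq <- with_design_seed(seed, attempt, {
      a_fill <- draw_filler(fa)
      b_fill <- draw_filler(fb, context_left = params$loop_seq)
      list(a = a_fill, b = b_fill)
    })
    a_fill <- seq$a; b_fill <- seq$b
    bs_fill <- if (fb > 0L) reverse_complement(b_fill) else ""
    as_fill <- if (fa > 0L) reverse_complement(a_fill) else ""
    full <- paste0(a_fill, params$triplet_opposite, bs_fill, params$loop_seq,
                   b_fill, params$triplet_sensor, as_fill)
    u <- fa + 3L + fb + llen + fb
    if (core_motif_clean(full, u) && max_homopolymer(full) <= 3L) {
      feats <- feature_frame(
        c("domain_a", "triplet_opposite", "domain_b_star", "loop",
          "domain_b", "triplet_sensor", "domain_a_star"),
        c(fa, 3L, fb, llen, fb, 3L, fa))
      feats <- feats[feats$end > feats$start, , drop = FALSE]
      L <- nchar(full)
      pairs <- bind_pairs(
        stem_pairs(0L, L - 1L, fa),
        triplet_pairs(fa, u, params$triplet_opposite, params$triplet_sensor),
        stem_pairs(fa + 3L, u - 1L, fb))
      return(new_construct(full, feats, pairs, pairs, "substrate",
                           edit_index = u + 1L, params = params, seed = seed))
    }
  }
  stop("filler generation failed: could not avoid stop motifs after 50 ",
       "attempts; relax loop/triplet choices", call. = FALSE)
}

#' Build an inert (target-awaiting) sensor
#'
#' Domain a collapses to the single retained junction cytosine so the hairpin
#' is editing-silent at rest; domain a* is replaced by the sensing arm. In
#' the resting state only b:b* and the UAG:CCA closure pair; arm positions
#' await the target.
#'
#' @param params A [hairpin_params()] (only `len_b`, loop, triplets and
#'   junction are used).
#' @param arm Sensing arm sequence (RNA; placed 3' of the UAG's G).
#' @param seed Filler seed.
#' @param cca_source `"intramolecular"` (sensor carries its own CCA) or
#'   `"target"` (target must supply the CCA; the sensor keeps only the
#'   junction base on its 5' side).
#' @return A `sensor_construct` with mode `"rna_sensor"`.
#' @export
build_inert_sensor <- function(params = hairpin_params(), arm, seed = 1L,
                               cca_source = c("intramolecular", "target")) {
  cca_source <- match.arg(cca_source)
  if (missing(arm) || is.null(arm) || !nzchar(arm)) {
    stop("sensing arm must be non-empty", call. = FALSE)
  }
  arm <- as_rna(validate_nuc(arm))
  fb <- params$len_b - 1L
  llen <- nchar(params$loop_seq)
  jbase <- params$junction_pair[1L]
  opp <- if (cca_source == "intramolecular") params$triplet_opposite else ""
  head_len <- 1L + nchar(opp)
  for (attempt in 0:49) {
    b_fill <- with_design_seed(seed, attempt,
                               draw_filler(fb, context_left = params$loop_seq))
    bs_fill <- if (fb > 0L) reverse_complement(b_fill) else ""
    full <- paste0(jbase, opp, bs_fill, params$loop_seq, b_fill,
                   params$triplet_sensor, arm)
    u <- head_len + fb + llen + fb
    arm_start <- u + 3L
    if (core_motif_clean(full, u,
                         exempt = list(c(arm_start, nchar(full))))) {
      feat_names <- c("junction",
                      if (nchar(opp)) "triplet_opposite",
                      "domain_b_star", "loop", "domain_b",
                      "triplet_sensor", "sensing_arm")
      feat_lens <- c(1L, if (nchar(opp)) 3L, fb, llen, fb, 3L, nchar(arm))
      feats <- feature_frame(feat_names, feat_lens)
      feats <- feats[feats$end > feats$start, , drop = FALSE]
      resting <- bind_pairs(
        if (cca_source == "intramolecular")
          triplet_pairs(1L, u, opp, params$triplet_sensor),
        stem_pairs(head_len, u - 1L, fb))
      return(new_construct(full, feats, resting, resting, "rna_sensor",
                           edit_index = u + 1L, params = params, seed = seed))
    }
  }
  stop("filler generation failed for inert sensor", call. = FALSE)
}

default_design_config <- function(config = list()) {
  defaults <- list(arm_length = 39L, len_b = 12L, loop_seq = "GAAA",
                   triplet_sensor = "UAG", triplet_opposite = "CCA",
                   junction_pair = c("C", "G"), junction_context = "C",
                   cca_source = "intramolecular", seed = 1L)
  utils::modifyList(defaults, config)
}

config_params <- function(cfg) {
  hairpin_params(len_a = 1L, len_b = cfg$len_b, loop_seq = cfg$loop_seq,
                 triplet_sensor = cfg$triplet_sensor,
                 triplet_opposite = cfg$triplet_opposite,
                 junction_pair = cfg$junction_pair,
                 junction_context = cfg$junction_context)
}

# Frame-0 stop check on the arm (the arm begins at a codon boundary because
# the UAG is codon-aligned in the assembled cassette).
arm_stop_codons <- function(arm) {
  audit <- audit_frame(arm, 0L)
  audit$stop_positions
}

#' Design an RNA-detecting sensor for a target transcript window
#'
#' The sensing arm is the exact reverse complement of the chosen target
#' window; target hybridization at the arm restores the editable duplex. The
#' engineered A-C mismatch stays in the intramolecular UAG:CCA region, never
#' in the arm.
#'
#' @param target Target transcript (RNA or DNA; converted to RNA).
#' @param site Window start (0-based) on the target, or a row of
#'   [scan_target()] output (its `start` is used).
#' @param config Named list overriding `arm_length` (39), `len_b` (12),
#'   `loop_seq`, `junction_pair`, `cca_source`, `seed`.
#' @param force Skip the junction-compatibility check (stop-codon rejection
#'   always applies).
#' @return A `sensor_construct` with external target pairs in the active map.
#' @export
design_rna_sensor <- function(target, site, config = list(), force = FALSE) {
  cfg <- default_design_config(config)
  target <- as_rna(validate_nuc(target, allow_ambiguity = TRUE))
  if (is.data.frame(site) || is.list(site)) site <- site$start
  ws <- as.integer(site)
  L <- as.integer(cfg$arm_length)
  we <- ws + L
  cca_target <- cfg$cca_source == "target"
  need_end <- we + (if (cca_target) 4L else 1L)
  if (ws < 0L || need_end > nchar(target)) {
    stop("window does not fit on the target", call. = FALSE)
  }
  window <- substr(target, ws + 1L, we)
  if (grepl("[^ACGU]", window)) {
    stop("target window contains ambiguity codes", call. = FALSE)
  }
  arm <- reverse_complement(window)
  stops <- arm_stop_codons(arm)
  if (length(stops)) {
    codon <- substr(arm, stops[1L] + 1L, stops[1L] + 3L)
    stop(sprintf(
      "site rejected: arm carries in-frame stop codon %s at arm offset %d",
      codon, stops[1L]), call. = FALSE)
  }
  if (cca_target &&
      substr(target, we + 1L, we + 3L) != cfg$triplet_opposite) {
    stop(sprintf("site rejected: target does not supply %s opposite the %s",
                 cfg$triplet_opposite, cfg$triplet_sensor), call. = FALSE)
  }
  jpos <- if (cca_target) we + 3L else we
  jbase_target <- substr(target, jpos + 1L, jpos + 1L)
  if (!force && jbase_target != cfg$junction_pair[2L]) {
    stop(sprintf(
      "site rejected: junction base %s at target %d does not pair %s",
      jbase_target, jpos, cfg$junction_pair[1L]), call. = FALSE)
  }
  params <- config_params(cfg)
  con <- build_inert_sensor(params, arm, seed = cfg$seed,
                            cca_source = cfg$cca_source)
  attach_target(con, target, ws, we, jpos, cca_target)
}

attach_target <- function(con, target, ws, we, jpos, cca_target) {
  L <- we - ws
  arm_rng <- feature_range(con, "sensing_arm")
  tch <- split_chars(target)
  sch <- split_chars(con$sequence)
  k <- 0:(L - 1L)
  arm_pairs <- data.frame(
    i = arm_rng[1L] + k, j = we - 1L - k,
    kind = pair_kind(sch[arm_rng[1L] + k + 1L], tch[we - k]),
    space = "target", stringsAsFactors = FALSE)
  junction_pair <- data.frame(
    i = 0L, j = jpos,
    kind = pair_kind(sch[1L], tch[jpos + 1L]),
    space = "target", stringsAsFactors = FALSE)
  extra <- NULL
  if (cca_target) {
    u <- con$edit_index - 1L
    extra <- data.frame(
      i = u + 0:2, j = we + 2:0,
      kind = pair_kind(sch[u + 1:3], tch[we + 3:1]),
      space = "target", stringsAsFactors = FALSE)
  }
  con$pairs$active <- bind_pairs(con$pairs$resting, arm_pairs,
                                 junction_pair, extra)
  con$target <- list(sequence = target, window = c(ws, we),
                     junction_pos = jpos)
  con
}

#' Design an SNV-discriminating sensor
#'
#' The window is anchored so the variant base is the 3'-most position of the
#' arm-paired region; the discriminator (complement of the variant allele)
#' therefore sits at the arm position immediately adjacent to the G of the
#' UAG. Against the variant transcript the duplex carries only the central
#' A-C mismatch; against wild type it carries a second, closely spaced
#' mismatch that silences editing.
#'
#' @param target_wt Wild-type transcript (RNA or DNA).
#' @param variant List with `position` (0-based), `ref_base`, `alt_base`
#'   (substitution only; indels are deliberately not detected).
#' @param config As in [design_rna_sensor()].
#' @return A `sensor_construct`; `$target` records the wild-type sequence,
#'   `$variant` the substitution and the mutant sequence.
#' @export
design_snv_sensor <- function(target_wt, variant, config = list()) {
  cfg <- default_design_config(config)
  target_wt <- as_rna(validate_nuc(target_wt))
  pos <- as.integer(variant$position)
  ref <- as_rna(toupper(variant$ref_base))
  alt <- as_rna(toupper(variant$alt_base))
  if (identical(ref, alt)) stop("alt_base equals ref_base", call. = FALSE)
  if (substr(target_wt, pos + 1L, pos + 1L) != ref) {
    stop(sprintf("ref_base %s does not match target at %d", ref, pos),
         call. = FALSE)
  }
  L <- as.integer(cfg$arm_length)
  ws <- pos - L + 1L
  if (ws < 0L || pos + 2L > nchar(target_wt)) {
    stop("variant too close to the transcript edge for a full arm",
         call. = FALSE)
  }
  mut <- target_wt
  substr(mut, pos + 1L, pos + 1L) <- alt
  # keep the nick closed: the retained junction base is chosen complementary
  # to the target base adjacent to the variant (C against a G context, per
  # the preferred complete-CCA layout, otherwise the matching complement)
  jb_target <- substr(mut, pos + 2L, pos + 2L)
  con <- design_rna_sensor(mut, ws, config = utils::modifyList(
    cfg, list(cca_source = "intramolecular",
              junction_pair = c(complement_base(jb_target), jb_target))),
    force = TRUE)
  con$mode <- "snv_sensor"
  con$variant <- list(position = pos, ref_base = as.character(ref),
                      alt_base = as.character(alt),
                      mutant_sequence = as.character(mut),
                      wildtype_sequence = as.character(target_wt))
  con
}

#' Count duplex mismatches between a sensor and a target
#'
#' Re-evaluates the active-state pairing map of a sensing construct against
#' an arbitrary target sequence (e.g. wild type vs variant). Only strict
#' Watson-Crick opposition counts as a match; G:U wobble is scored as a
#' mismatch because hybridization discrimination, not folding, is at stake.
#' The annotated central A-C mismatch is included in the count.
#'
#' @param construct A sensing `sensor_construct`.
#' @param target Target sequence to oppose (defaults to the attached one).
#' @return List with `count` and a data frame `mismatches` (sensor index,
#'   partner index, bases, space).
#' @export
count_duplex_mismatches <- function(construct, target = NULL) {
  if (is.null(construct$target)) {
    stop("construct has no attached target window", call. = FALSE)
  }
  target <- if (is.null(target)) construct$target$sequence
            else as_rna(validate_nuc(target))
  sch <- split_chars(construct$sequence)
  tch <- split_chars(target)
  p <- construct$pairs$active
  base_i <- sch[p$i + 1L]
  base_j <- ifelse(p$space == "intra", sch[p$j + 1L], tch[p$j + 1L])
  mm <- !is_wc(base_i, base_j)
  list(count = sum(mm),
       mismatches = data.frame(i = p$i[mm], j = p$j[mm],
                               base_i = base_i[mm], base_j = base_j[mm],
                               space = p$space[mm], stringsAsFactors = FALSE))
}

#' Design an aptamer-gated (riboswitch-style) sensor
#'
#' The blocker (reverse complement of the aptamer's `blocker_window`)
#' sequesters the aptamer into an OFF-state stem that topologically excludes
#' both the a:a* stem and the UAG:CCA closure (the UAG sits in the OFF-stem
#' loop, the CCA on the 5' overhang). Ligand occupancy is modelled by forcing
#' the aptamer unpaired, which releases the blocker and lets the editable
#' duplex re-form. Only layouts passing [two_state_check()] are returned;
#' spacer lengths 0-4 are searched deterministically in increasing order.
#'
#' @param aptamer An [aptamer_spec()].
#' @param params A [hairpin_params()]; `len_a = 10, len_b = 12` is the ATP
#'   sensor default, `len_a = 25` the extended protein-sensor stem.
#' @param config List: `seed`, `spacer_max` (4), `weights` for folding.
#' @return A passing `sensor_construct` with mode `"aptamer_sensor"`.
#' @export
design_aptamer_sensor <- function(aptamer, params = hairpin_params(),
                                  config = list()) {
  cfg <- utils::modifyList(list(seed = 1L, spacer_max = 4L,
                                weights = c(GC = 1, AU = 1, GU = 1)), config)
  bw <- aptamer$blocker_window
  if (bw[2L] <= bw[1L]) {
    stop("blocker length 0: nothing can sequester the aptamer, so the OFF ",
         "state cannot be enforced", call. = FALSE)
  }
  blocker <- reverse_complement(substr(aptamer$sequence, bw[1L] + 1L,
                                       bw[2L]))
  best_diag <- NULL
  for (attempt in 0:4) {
    fills <- with_design_seed(cfg$seed, attempt, {
      list(a = draw_filler(params$len_a - 1L),
           b = draw_filler(params$len_b - 1L,
                           context_left = params$loop_seq))
    })
    for (s1 in 0:cfg$spacer_max) for (s2 in 0:cfg$spacer_max)
    for (s3 in 0:cfg$spacer_max) {
      con <- assemble_aptamer_layout(aptamer, blocker, params, fills,
                                     c(s1, s2, s3), cfg$seed, attempt)
      if (is.null(con)) next
      chk <- two_state_check(con, weights = cfg$weights)
      if (chk$pass) {
        con$two_state <- chk
        return(con)
      }
      if (is.null(best_diag)) best_diag <- chk
    }
  }
  stop(paste0("no passing aptamer-sensor layout in the search space; best ",
              "failing layout: ",
              paste(best_diag$diagnostics, collapse = "; ")), call. = FALSE)
}

# Layout (5'->3'): a_fill, CCA, s1, blocker, s2, b*_fill, loop, b_fill, UAG,
# s3, aptamer, a*_fill. The blocker:aptamer helix crosses exactly the
# UAG:CCA closure (CCA < blocker < UAG < aptamer interleave) while staying
# nested with both a:a* and b:b*, so the OFF-state optimum keeps the stems
# but is topologically barred from the closure; forcing the aptamer unpaired
# releases the blocker and the closure re-forms.
assemble_aptamer_layout <- function(aptamer, blocker, params, fills,
                                    spacers, seed, attempt) {
  fa <- params$len_a - 1L; fb <- params$len_b - 1L
  llen <- nchar(params$loop_seq)
  bl <- nchar(blocker)
  na <- nchar(aptamer$sequence)
  spc <- lapply(seq_along(spacers), function(k) {
    if (spacers[k] == 0L) "" else
      with_design_seed(seed, attempt * 101L + k, draw_filler(spacers[k]))
  })
  a_fill <- fills$a; b_fill <- fills$b
  bs_fill <- if (fb > 0L) reverse_complement(b_fill) else ""
  as_fill <- if (fa > 0L) reverse_complement(a_fill) else ""
  full <- paste0(a_fill, params$triplet_opposite, spc[[1L]], blocker,
                 spc[[2L]], bs_fill, params$loop_seq, b_fill,
                 params$triplet_sensor, spc[[3L]], aptamer$sequence,
                 as_fill)
  u <- fa + 3L + spacers[1L] + bl + spacers[2L] + fb + llen + fb
  apt_start <- u + 3L + spacers[3L]
  if (!core_motif_clean(full, u,
                        exempt = list(c(apt_start, apt_start + na)))) {
    return(NULL)
  }
  feats <- feature_frame(
    c("domain_a", "triplet_opposite", "spacer", "blocker", "spacer",
      "domain_b_star", "loop", "domain_b", "triplet_sensor", "spacer",
      "aptamer", "domain_a_star"),
    c(fa, 3L, spacers[1L], bl, spacers[2L], fb, llen, fb, 3L,
      spacers[3L], na, fa))
  feats <- feats[feats$end > feats$start, , drop = FALSE]
  active <- bind_pairs(
    stem_pairs(0L, apt_start + na + fa - 1L, fa),
    triplet_pairs(fa, u, params$triplet_opposite, params$triplet_sensor),
    stem_pairs(fa + 3L + spacers[1L] + bl + spacers[2L], u - 1L, fb))
  # OFF-state stem: blocker[k] pairs aptamer[bw2-1-k]
  bw <- aptamer$blocker_window
  off <- if (bl > 0L) {
    k <- 0:(bl - 1L)
    data.frame(i = fa + 3L + spacers[1L] + k,
               j = apt_start + bw[2L] - 1L - k,
               kind = "wc", space = "intra", stringsAsFactors = FALSE)
  } else NULL
  con <- new_construct(full, feats, off %||% active[0, ], active,
                       "aptamer_sensor", edit_index = u + 1L,
                       params = params, seed = seed)
  con$aptamer <- aptamer
  con
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prepend an MS2 coat-protein binding hairpin
#'
#' Adds the MS2 stem loop (plus a 3-nt spacer) at the 5' end so an MCP-ADAR
#' fusion can be tethered to the sensor. All feature and pair coordinates
#' shift downstream; frame padding is recomputed at cassette assembly.
#'
#' @param construct A `sensor_construct` without an existing ms2 feature.
#' @param ms2_seq MS2 hairpin sequence (default [MS2_RNA], 21 nt).
#' @param spacer Spacer between MS2 and the sensor (default `"CAC"`).
#' @return The shifted construct with `ms2` and `spacer` features prepended.
#' @export
add_ms2 <- function(construct, ms2_seq = MS2_RNA, spacer = "CAC") {
  if ("ms2" %in% construct$features$name) {
    stop("construct already carries an ms2 feature", call. = FALSE)
  }
  ms2_seq <- as_rna(validate_nuc(ms2_seq))
  shift <- nchar(ms2_seq) + nchar(spacer)
  construct$sequence <- paste0(ms2_seq, spacer, construct$sequence)
  f <- construct$features
  f$start <- f$start + shift; f$end <- f$end + shift
  pre <- data.frame(name = c("ms2", if (nzchar(spacer)) "spacer"),
                    start = c(0L, if (nzchar(spacer)) nchar(ms2_seq)),
                    end = c(nchar(ms2_seq), if (nzchar(spacer)) shift),
                    stringsAsFactors = FALSE)
  construct$features <- rbind(pre, f)
  construct$pairs <- lapply(construct$pairs, function(p) {
    p$i <- p$i + shift
    p$j <- ifelse(p$space == "intra", p$j + shift, p$j)
    p
  })
  construct$edit_index <- construct$edit_index + shift
  construct
}

#' Assemble the full reporter cassette
#'
#' Orders the cassette elements (default BFP ORF, P2A, 2xGGGGS linker, sensor
#' insert, GFP ORF with terminator), pads the insert with 0-2 neutral bases
#' on each side so it is a whole number of codons with the sensor UAG
#' codon-aligned, and audits frame 0: before editing, translation must stop
#' exactly at the sensor UAG and nowhere else until the GFP terminator.
#'
#' @param construct A `sensor_construct`.
#' @param flanks Named list of part sequences: `bfp`, `p2a`, `linker`, `gfp`
#'   (RNA). Defaults are the shipped surrogates/parts.
#' @param order Element order; `"sensor"` must appear before `"gfp"` for the
#'   stop-gate to control GFP.
#' @return A `reporter_cassette`: `sequence`, `elements` (tiling data frame),
#'   `sensor_offset`, `edit_index` (cassette coordinates), `audit`.
#' @export
assemble_reporter <- function(construct,
                              flanks = list(bfp = bfp_surrogate_orf(),
                                            p2a = P2A_RNA,
                                            linker = LINKER_2XGGGGS_RNA,
                                            gfp = gfp_surrogate_orf()),
                              order = c("bfp", "p2a", "linker", "sensor",
                                        "gfp")) {
  stopifnot("sensor" %in% order, "gfp" %in% order)
  if (which(order == "sensor") > which(order == "gfp")) {
    stop("sensor must precede gfp for the stop-gate to work", call. = FALSE)
  }
  pre_names <- order[seq_len(which(order == "sensor") - 1L)]
  prefix_len <- sum(vapply(flanks[pre_names], nchar, 0L))
  uag_start <- construct$edit_index - 1L
  sensor_len <- nchar(construct$sequence)
  pad_pool <- c("C", "G")
  pad5_len <- (3L - ((prefix_len + uag_start) %% 3L)) %% 3L
  pad3_len <- (3L - ((pad5_len + sensor_len) %% 3L)) %% 3L
  pad_options <- function(n) {
    if (n == 0L) return("")
    apply(do.call(expand.grid, rep(list(pad_pool), n)), 1L,
          paste, collapse = "")
  }
  for (p5 in pad_options(pad5_len)) for (p3 in pad_options(pad3_len)) {
    insert <- paste0(p5, construct$sequence, p3)
    parts <- lapply(order, function(nm) {
      if (nm == "sensor") insert else flanks[[nm]]
    })
    lens <- vapply(parts, nchar, 0L)
    cassette <- paste(unlist(parts), collapse = "")
    elements <- feature_frame(order, lens)
    sensor_offset <- elements$start[elements$name == "sensor"] + nchar(p5)
    edit_index <- sensor_offset + construct$edit_index
    audit <- audit_frame(cassette, 0L)
    terminator <- nchar(cassette) - 3L
    expected <- c(sensor_offset + uag_start, terminator)
    if (identical(audit$stop_positions, as.integer(expected))) {
      return(structure(list(sequence = cassette, elements = elements,
                            sensor_offset = sensor_offset,
                            edit_index = as.integer(edit_index),
                            pads = c(p5 = p5, p3 = p3),
                            construct = construct, audit = audit),
                       class = "reporter_cassette"))
    }
  }
  audit <- audit_frame(paste0(pad_options(pad5_len)[1L], construct$sequence,
                              pad_options(pad3_len)[1L]), 0L)
  stop(sprintf(
    "cassette assembly failed: unexpected in-frame stop(s) at insert %s",
    paste(audit$stop_positions, collapse = ",")), call. = FALSE)
}

#' @export
print.reporter_cassette <- function(x, ...) {
  cat(sprintf(
    "<reporter_cassette> length=%d sensor_offset=%d edit_index=%d\n",
    nchar(x$sequence), x$sensor_offset, x$edit_index))
  invisible(x)
}

#' Apply an in-silico A-to-G edit
#'
#' @param x A `reporter_cassette`, `sensor_construct`, or plain sequence.
#' @param index 0-based position to edit (defaults to the object's
#'   `edit_index`); must currently hold an A.
#' @return The edited sequence (character scalar).
#' @export
apply_edit <- function(x, index = NULL) {
  seq <- if (is.character(x)) x else x$sequence
  if (is.null(index)) {
    if (is.character(x)) stop("index required for a bare sequence",
                              call. = FALSE)
    index <- x$edit_index
  }
  if (substr(seq, index + 1L, index + 1L) != "A") {
    stop("edit position does not hold an A", call. = FALSE)
  }
  substr(seq, index + 1L, index + 1L) <- "G"
  as.character(seq)
}

#' Write a design record as JSON
#'
#' Emits the sequence (RNA and DNA dialects), feature table and pairing maps
#' with 0-based half-open coordinates, plus mode, seed and config echo.
#'
#' @param construct A `sensor_construct`.
#' @param path Output path.
#' @param config Optional config echo to embed.
#' @return The path, invisibly.
#' @export
write_design <- function(construct, path, config = NULL) {
  rec <- list(
    mode = construct$mode,
    alphabet = "rna",
    sequence = construct$sequence,
    sequence_dna = as_dna(construct$sequence),
    edit_index = construct$edit_index,
    features = construct$features,
    pairs_resting = construct$pairs$resting,
    pairs_active = construct$pairs$active,
    seed = construct$seed,
    config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
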