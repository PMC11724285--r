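# Secondary-structure verification: maximum-pairing (Nussinov) folding with
# forced-unpaired constraints, intended-pair verification, duplex metrics and
# the two-state riboswitch check. Pair-count scoring (optionally GC/AU/GU
# weighted) replaces thermodynamic folding: the design checks only need
# presence/absence of intended helices, and the dynamic program is exactly
# verifiable against brute-force enumeration.

MIN_LOOP <- 3L  # minimum unpaired bases in a hairpin loop (j - i >= 4)

pair_score_matrix <- function(chars, weights, forced_unpaired = integer(0)) {
  n <- length(chars)
  w <- c(weights, setNames(weights, c("CG", "UA", "UG")))
  duo <- outer(chars, chars, paste0)
  s <- matrix(-Inf, n, n)
  for (nm in names(w)) s[duo == nm] <- w[[nm]]
  if (length(forced_unpaired)) {
    idx <- forced_unpaired + 1L
    s[idx, ] <- -Inf
    s[, idx] <- -Inf
  }
  s
}

#' Maximum-pairing RNA fold (Nussinov) with constraints
#'
#' Computes a maximum-score nested (pseudoknot-free) pairing with a minimum
#' hairpin loop of 3 unpaired bases. Scoring is per-pair: `weights["GC"]` for
#' G:C, `weights["AU"]` for A:U, `weights["GU"]` for G:U wobble (set the GU
#' weight to `-Inf` to forbid wobble, e.g. for DNA). Traceback is
#' deterministic: position i prefers pairing over bifurcation/skipping, and
#' the smallest admissible partner wins ties.
#'
#' @param seq RNA (or DNA, converted) sequence, length <= 5000.
#' @param constraints Integer vector of 0-based positions forced unpaired.
#' @param weights Named numeric vector `c(GC=, AU=, GU=)`; default all 1
#'   (pair counting).
#' @return A `fold_result`: `pairs` (data frame `i`, `j`, 0-based, i < j),
#'   `objective`, `constraints`, `dot_bracket`, `n`.
#' @export
nussinov_fold <- function(seq, constraints = integer(0),
                          weights = c(GC = 1, AU = 1, GU = 1)) {
  seq <- as_rna(validate_nuc(seq))
  n <- nchar(seq)
  if (n > 5000L) stop("sequence longer than 5000 nt", call. = FALSE)
  constraints <- as.integer(constraints)
  if (length(constraints) && (min(constraints) < 0L ||
                              max(constraints) >= n)) {
    stop("constraint index out of range", call. = FALSE)
  }
  chars <- split_chars(seq)
  S <- pair_score_matrix(chars, weights, constraints)
  # M is padded by one row/col of zeros on each side so that empty
  # subintervals index cleanly: M[i+1, j+1] holds the score of [i, j].
  M <- matrix(0, n + 2L, n + 2L)
  if (n >= MIN_LOOP + 2L) {
    for (span in (MIN_LOOP + 1L):(n - 1L)) {
      for (i in 1:(n - span)) {
        j <- i + span
        ks <- (i + MIN_LOOP + 1L):j
        cand <- S[i, ks] + M[i + 2L, ks] + M[ks + 2L, j + 1L]
        M[i + 1L, j + 1L] <- max(M[i + 2L, j + 1L], cand)
      }
    }
  }
  # deterministic traceback
  pairs_i <- integer(0); pairs_j <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || j - i <= MIN_LOOP) next
    target <- M[i + 1L, j + 1L]
    if (target == 0) next
    ks <- (i + MIN_LOOP + 1L):j
    cand <- S[i, ks] + M[i + 2L, ks] + M[ks + 2L, j + 1L]
    hit <- which(cand == target)
    if (length(hit)) {
      k <- ks[hit[1L]]
      pairs_i <- c(pairs_i, i); pairs_j <- c(pairs_j, k)
      stack <- c(stack, list(c(i + 1L, k - 1L)), list(c(k + 1L, j)))
    } else {
      stack <- c(stack, list(c(i + 1L, j)))
    }
  }
  pairs <- data.frame(i = pairs_i - 1L, j = pairs_j - 1L)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  objective <- M[2L, n + 1L]
  structure(list(pairs = pairs, objective = objective,
                 constraints = constraints, n = n,
                 dot_bracket = dot_bracket(pairs, n)),
            class = "fold_result")
}

#' Dot-bracket string for a nested pairing
#'
#' @param pairs Data frame with 0-based columns `i`, `j`.
#' @param n Sequence length.
#' @return Character scalar of `.`/`(`/`)`.
#' @export
dot_bracket <- function(pairs, n) {
  db <- rep(".", n)
  db[pairs$i + 1L] <- "("
  db[pairs$j + 1L] <- ")"
  paste(db, collapse = "")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> n=%d objective=%g\n%s\n", x$n, x$objective,
              x$dot_bracket))
  invisible(x)
}

has_pair <- function(fold, i, j) {
  any(fold$pairs$i == i & fold$pairs$j == j)
}

# Fold a construct in a given state. Active-state sensing folds concatenate
# the sensor with the relevant target region through a 10-nt forced-unpaired
# linker; target-space pair coordinates are mapped through the offset.
fold_construct <- function(construct, state = c("resting", "active"),
                           weights = c(GC = 1, AU = 1, GU = 1)) {
  state <- match.arg(state)
  n_sensor <- nchar(construct$sequence)
  if (state == "resting" || is.null(construct$target)) {
    fold <- nussinov_fold(construct$sequence, weights = weights)
    return(list(fold = fold, offset = NA_integer_, region = NULL))
  }
  tgt <- construct$target
  ext <- construct$pairs$active[construct$pairs$active$space == "target", ]
  rs <- min(tgt$window[1L], ext$j)
  re <- max(tgt$window[2L], ext$j + 1L)
  region <- substr(tgt$sequence, rs + 1L, re)
  linker_len <- 10L
  concat <- paste0(construct$sequence, strrep("A", linker_len), region)
  forced <- n_sensor + 0:(linker_len - 1L)
  fold <- nussinov_fold(concat, constraints = forced, weights = weights)
  list(fold = fold, offset = n_sensor + linker_len - rs,
       region = c(rs, re))
}

#' Verify a construct's intended pairs against a fold
#'
#' Returns the fraction of intended Watson-Crick pairs of the given state
#' that are present in the optimal fold. Active-state verification folds the
#' sensor concatenated with its target region (10 forced-unpaired linker
#' positions in between); without an attached target the arm pairs count as
#' absent.
#'
#' @param construct A `sensor_construct`.
#' @param state `"resting"` or `"active"`.
#' @param fold Optional precomputed result of the internal constrained fold;
#'   when supplied it must come from the same state geometry.
#' @param weights Folding weights.
#' @return Fraction in [0, 1].
#' @export
verify_intended_pairs <- function(construct, state = c("resting", "active"),
                                  fold = NULL,
                                  weights = c(GC = 1, AU = 1, GU = 1)) {
  state <- match.arg(state)
  intended <- construct$pairs[[state]]
  intended <- intended[intended$kind == "wc", , drop = FALSE]
  if (nrow(intended) == 0L) {
    stop("no intended WC pairs recorded for this state", call. = FALSE)
  }
  fc <- if (is.null(fold)) fold_construct(construct, state, weights)
        else fold
  if (!is.list(fc) || is.null(fc$fold)) {
    stop("fold must be the result of the construct's state fold",
         call. = FALSE)
  }
  j_map <- ifelse(intended$space == "intra", intended$j,
                  if (is.na(fc$offset)) NA_integer_
                  else intended$j + fc$offset)
  present <- mapply(function(i, j) !is.na(j) && has_pair(fc$fold, i, j),
                    intended$i, j_map)
  mean(present)
}

#' Duplex metrics of a pairing map
#'
#' @param map Pairing-map data frame (`i`, `j`, `kind`, `space`).
#' @return List: `n_paired` (WC pairs), `span` (positions covered by the
#'   longest contiguous duplex run including annotated mismatches),
#'   `mismatch_count`, `max_contiguous` (longest unbroken WC run).
#' @examples
#' duplex_metrics(build_substrate()$pairs$resting)  # 22 WC, span 23
#' @export
duplex_metrics <- function(map) {
  if (is.null(map) || nrow(map) == 0L) stop("empty pairing map",
                                            call. = FALSE)
  map <- map[order(map$i), , drop = FALSE]
  step <- c(1L, diff(map$i))
  run_id <- cumsum(step != 1L)
  span <- max(tabulate(run_id + 1L))
  # longest consecutive-i run of WC pairs: break runs at mismatches too
  brk <- cumsum(step != 1L | map$kind != "wc")
  wc_len <- tabulate(brk[map$kind == "wc"] + 1L)
  list(n_paired = sum(map$kind == "wc"),
       span = span,
       mismatch_count = sum(map$kind == "mismatch"),
       max_contiguous = if (length(wc_len)) max(wc_len) else 0L)
}

#' Two-state check for aptamer-gated sensors
#'
#' OFF state: unconstrained optimal fold; must lack every UAG:CCA-region
#' pair. ON state: optimal fold with all aptamer positions forced unpaired
#' (ligand-occupancy proxy); must contain every intended b:b* and
#' UAG:CCA-region pair.
#'
#' @param construct A `sensor_construct` with mode `"aptamer_sensor"`.
#' @param weights Folding weights.
#' @return List: `pass`, `diagnostics` (character), `off`, `on` (folds).
#' @export
two_state_check <- function(construct, weights = c(GC = 1, AU = 1, GU = 1)) {
  if (construct$mode != "aptamer_sensor") {
    stop("two_state_check requires an aptamer_sensor construct",
         call. = FALSE)
  }
  apt <- feature_range(construct, "aptamer")
  off <- nussinov_fold(construct$sequence, weights = weights)
  on <- nussinov_fold(construct$sequence,
                      constraints = apt[1L]:(apt[2L] - 1L),
                      weights = weights)
  act <- construct$pairs$active
  trip_o <- feature_range(construct, "triplet_opposite")
  trip_s <- feature_range(construct, "triplet_sensor")
  closure <- act[act$kind == "wc" &
                   act$i >= trip_o[1L] & act$i < trip_o[2L] &
                   act$j >= trip_s[1L] & act$j < trip_s[2L], , drop = FALSE]
  bstar <- feature_range(construct, "domain_b_star")
  bpairs <- if (is.null(bstar)) act[0, ] else {
    act[act$kind == "wc" & act$i >= bstar[1L] & act$i < bstar[2L], ,
        drop = FALSE]
  }
  off_active <- any(mapply(function(i, j) has_pair(off, i, j),
                           closure$i, closure$j))
  on_rows <- rbind(closure, bpairs)
  on_ok <- all(mapply(function(i, j) has_pair(on, i, j),
                      on_rows$i, on_rows$j))
  diagnostics <- c(
    if (off_active) "OFF state active (UAG:CCA closure pairs in rest fold)",
    if (!on_ok) "ON state incomplete (intended b:b*/UAG:CCA pairs missing)")
  list(pass = !off_active && on_ok,
       diagnostics = if (length(diagnostics)) diagnostics else "ok",
       off = off, on = on)
}
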