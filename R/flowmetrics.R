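# Flow-cytometry computations: scatter/singlet/BFP gating and GFP/BFP fold
# activation. Event tables are plain data frames with numeric columns FSC_A,
# SSC_A, SSC_H, BFP, GFP (CSV exported from any cytometry tool is the
# contract; FCS parsing is out of scope).

FLOW_COLUMNS <- c("FSC_A", "SSC_A", "SSC_H", "BFP", "GFP")

check_flow_table <- function(table) {
  missing <- setdiff(FLOW_COLUMNS, names(table))
  if (length(missing)) {
    stop(sprintf("event table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (nrow(table) < 1L) stop("event table is empty", call. = FALSE)
  invisible(table)
}

#' Build a gating configuration
#'
#' Thresholds default to quantiles of a vector-only control table (cells
#' carrying the empty vector serve as the gating control); fixed numeric
#' thresholds may be supplied instead. The live gate is an FSC_A/SSC_A
#' rectangle, the singlet gate an SSC_A/SSC_H ratio band, positivity a BFP
#' (and optionally GFP) threshold.
#'
#' @param control Optional control event table for quantile-derived
#'   thresholds.
#' @param live_q Two quantiles bounding the live-scatter rectangle
#'   (default 0.01, 0.99).
#' @param singlet_band SSC_A/SSC_H ratio band retaining singlets
#'   (default 0.75-1.35; doublets sit near 2).
#' @param positivity_q Control quantile defining BFP positivity
#'   (default 0.995).
#' @param fsc_range,ssc_range,bfp_threshold Explicit numeric overrides.
#' @return A `gate_config` list.
#' @export
gate_config <- function(control = NULL, live_q = c(0.01, 0.99),
                        singlet_band = c(0.75, 1.35), positivity_q = 0.995,
                        fsc_range = NULL, ssc_range = NULL,
                        bfp_threshold = NULL) {
  if (!is.null(control)) {
    check_flow_table(control)
    fsc_range <- fsc_range %||% unname(quantile(control$FSC_A, live_q))
    ssc_range <- ssc_range %||% unname(quantile(control$SSC_A, live_q))
    bfp_threshold <- bfp_threshold %||%
      unname(quantile(control$BFP, positivity_q))
  }
  if (is.null(bfp_threshold)) {
    stop("supply a control table or an explicit bfp_threshold",
         call. = FALSE)
  }
  stopifnot(is.finite(bfp_threshold), all(singlet_band > 0))
  structure(list(fsc_range = fsc_range, ssc_range = ssc_range,
                 singlet_band = singlet_band,
                 bfp_threshold = bfp_threshold),
            class = "gate_config")
}

#' Gate a flow event table
#'
#' Applies, in order: the live scatter rectangle, the singlet SSC_A/SSC_H
#' ratio band, and the BFP-positivity threshold. Events retained at each
#' stage are counted.
#'
#' @param table Event table (`FSC_A`, `SSC_A`, `SSC_H`, `BFP`, `GFP`).
#' @param config A [gate_config()].
#' @return List: `events` (gated table), `counts` (named vector `input`,
#'   `live`, `singlet`, `bfp_positive`).
#' @export
gate_events <- function(table, config) {
  check_flow_table(table)
  n_input <- nrow(table)
  live <- table
  if (!is.null(config$fsc_range)) {
    live <- live[live$FSC_A >= config$fsc_range[1L] &
                 live$FSC_A <= config$fsc_range[2L] &
                 live$SSC_A >= config$ssc_range[1L] &
                 live$SSC_A <= config$ssc_range[2L], , drop = FALSE]
  }
  ratio <- live$SSC_A / pmax(live$SSC_H, .Machine$double.eps)
  singlet <- live[ratio >= config$singlet_band[1L] &
                  ratio <= config$singlet_band[2L], , drop = FALSE]
  pos <- singlet[singlet$BFP > config$bfp_threshold, , drop = FALSE]
  list(events = pos,
       counts = c(input = n_input, live = nrow(live),
                  singlet = nrow(singlet), bfp_positive = nrow(pos)))
}

#' GFP/BFP fold activation
#'
#' Normalized fluorescence is the per-cell GFP/BFP ratio summarized by the
#' configured statistic (median by default; robust to lognormal channel
#' tails); fold activation is the plus-condition summary divided by the
#' minus-condition summary. `statistic = "population"` uses the
#' population-level mean(GFP)/mean(BFP) ratio instead of per-cell ratios.
#'
#' @param table_plus,table_minus Event tables with and without the target.
#' @param config A [gate_config()]; set `NULL` if both tables are already
#'   gated.
#' @param statistic `"median"`, `"mean"` (per-cell ratios) or
#'   `"population"`.
#' @param min_events Minimum BFP-positive events per condition
#'   (default 100).
#' @return List: `normalized_plus`, `normalized_minus`, `fold`, `n_plus`,
#'   `n_minus`, `statistic`.
#' @export
fold_activation <- function(table_plus, table_minus, config = NULL,
                            statistic = c("median", "mean", "population"),
                            min_events = 100L) {
  statistic <- match.arg(statistic)
  if (!is.null(config)) {
    table_plus <- gate_events(table_plus, config)$events
    table_minus <- gate_events(table_minus, config)$events
  }
  check_flow_table(table_plus); check_flow_table(table_minus)
  if (nrow(table_plus) < min_events || nrow(table_minus) < min_events) {
    stop(sprintf("fewer than %d BFP-positive events after gating",
                 min_events), call. = FALSE)
  }
  summarize <- function(tab) {
    switch(statistic,
           median = median(tab$GFP / tab$BFP),
           mean = mean(tab$GFP / tab$BFP),
           population = mean(tab$GFP) / mean(tab$BFP))
  }
  np <- summarize(table_plus)
  nm <- summarize(table_minus)
  if (!is.finite(nm) || nm <= .Machine$double.eps) {
    stop("near-zero normalized intensity in the minus condition; apply a ",
         "fluorescence floor before dividing", call. = FALSE)
  }
  list(normalized_plus = np, normalized_minus = nm, fold = np / nm,
       n_plus = nrow(table_plus), n_minus = nrow(table_minus),
       statistic = statistic)
}
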