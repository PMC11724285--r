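# Shared fixtures: built in code, no binary files.

# single read record
make_read <- function(bases, scores = rep(40L, nchar(bases)),
                      id = "read_1") {
  data.frame(id = id, bases = bases,
             quals = intToUtf8(scores + 33L), stringsAsFactors = FALSE)
}

# brute-force maximum-weight nested pairing (independent oracle: plain
# recursion over all nested pairings, no memoization, no shared code with
# the DP)
oracle_max_pairing <- function(seq, weights = c(GC = 1, AU = 1, GU = 1),
                               constraints = integer(0)) {
  chars <- strsplit(toupper(chartr("T", "U", seq)), "")[[1L]]
  n <- length(chars)
  pair_w <- function(i, j) {
    if ((i - 1L) %in% constraints || (j - 1L) %in% constraints) {
      return(NA_real_)
    }
    duo <- paste0(chars[i], chars[j])
    w <- c(GC = weights[["GC"]], CG = weights[["GC"]],
           AU = weights[["AU"]], UA = weights[["AU"]],
           GU = weights[["GU"]], UG = weights[["GU"]])
    if (duo %in% names(w)) w[[duo]] else NA_real_
  }
  best <- function(i, j) {
    if (j - i < 4L) return(0)
    acc <- best(i + 1L, j)
    for (k in (i + 4L):j) {
      w <- pair_w(i, k)
      if (!is.na(w)) {
        inner <- if (k - 1L >= i + 1L) best(i + 1L, k - 1L) else 0
        outer <- if (j >= k + 1L) best(k + 1L, j) else 0
        acc <- max(acc, w + inner + outer)
      }
    }
    acc
  }
  if (n < 2L) return(0)
  best(1L, n)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# transcript where exactly one window can pass every scan filter: the only
# junction-compatible G sits right after the planted window
single_site_transcript <- function(arm_length = 12L, lead = 20L,
                                   tail = 20L) {
  win <- strrep("C", arm_length)           # arm = all G, stop-free
  paste0(strrep("C", lead), win, "G", strrep("C", tail))
}
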