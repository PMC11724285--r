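test_that("folding reproduces brute-force optima on worked examples", {
  expect_equal(nussinov_fold("GCGAAACGC")$objective, 3)
  expect_equal(nussinov_fold("AAAAAA")$objective, 0)
  expect_equal(nussinov_fold("GGGGAAAACCCC")$objective, 4)
  # the dot-bracket mirrors the pair list
  f <- nussinov_fold("GGGGAAAACCCC")
  expect_equal(nchar(f$dot_bracket), 12L)
  expect_equal(sum(strsplit(f$dot_bracket, "")[[1]] == "("),
               nrow(f$pairs))
})

test_that("dynamic program equals exhaustive enumeration up to 12 nt", {
  # exhaustive sweep over all short sequences on a reduced alphabet, then
  # randomized longer cases under a fixed seed
  for (n in 4:6) {
    combos <- do.call(expand.grid,
                      rep(list(c("A", "C", "G", "U")), n))
    # subsample the 4^n grid deterministically to keep the sweep brisk
    idx <- seq(1, nrow(combos), by = max(1L, nrow(combos) %/% 96L))
    for (r in idx) {
      s <- paste(unlist(combos[r, ]), collapse = "")
      expect_equal(nussinov_fold(s)$objective, oracle_max_pairing(s),
                   info = s)
    }
  }
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- sample(7:12, 1)
      s <- random_rna(n)
      expect_equal(nussinov_fold(s)$objective, oracle_max_pairing(s),
                   info = s)
      # weighted scoring agrees with the weighted oracle
      w <- c(GC = 3, AU = 2, GU = 1)
      expect_equal(nussinov_fold(s, weights = w)$objective,
                   oracle_max_pairing(s, weights = w), info = s)
    }
  })
})

test_that("forcing positions unpaired never increases the objective", {
  withr::with_seed(17, {
    for (rep in 1:25) {
      s <- random_rna(sample(8:30, 1))
      base <- nussinov_fold(s)$objective
      k <- sample(0:(nchar(s) - 1), sample(1:4, 1))
      constrained <- nussinov_fold(s, constraints = k)$objective
      expect_lte(constrained, base)
      # constrained positions are absent from the returned pairing
      p <- nussinov_fold(s, constraints = k)$pairs
      expect_false(any(p$i %in% k | p$j %in% k))
    }
  })
  expect_error(nussinov_fold("ACGU", constraints = 9), "out of range")
})

test_that("constrained folds match the constrained oracle", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      s <- random_rna(sample(8:12, 1))
      k <- sample(0:(nchar(s) - 1), 2)
      expect_equal(nussinov_fold(s, constraints = k)$objective,
                   oracle_max_pairing(s, constraints = k), info = s)
    }
  })
})

test_that("intended-pair verification separates resting, inert and rescued states", {
  s <- build_substrate()
  expect_equal(verify_intended_pairs(s, "resting"), 1.0)

  tr <- simulate_transcript(length = 200, seed = 7, clean_site = 80)
  con <- design_rna_sensor(tr$sequence, tr$manifest$clean$window[1])
  # the sensor alone cannot satisfy the active map: arm pairs are missing
  alone <- con
  alone$target <- NULL
  expect_lt(verify_intended_pairs(alone, "active"), 1.0)
  # with its matched target the full active map must form
  expect_equal(verify_intended_pairs(con, "active"), 1.0)
  # at rest the free arm may poach a stem pair under max-pairing ties, so
  # the design threshold (0.9) is the bar, not exact completeness
  expect_gte(verify_intended_pairs(con, "resting"), 0.9)
})

test_that("duplex metrics summarize pairing maps correctly", {
  m <- duplex_metrics(build_substrate()$pairs$resting)
  expect_equal(m[c("n_paired", "span", "mismatch_count")],
               list(n_paired = 22L, span = 23L, mismatch_count = 1L))
  expect_equal(m$max_contiguous, 12L)

  model <- duplex_metrics(build_substrate(
    hairpin_params(len_a = 7, len_b = 9))$pairs$resting)
  expect_equal(model$n_paired, 16L)

  single <- data.frame(i = 0L, j = 9L, kind = "wc", space = "intra")
  expect_equal(duplex_metrics(single),
               list(n_paired = 1L, span = 1L, mismatch_count = 0L,
                    max_contiguous = 1L))
  expect_error(duplex_metrics(single[0, ]), "empty")
})

test_that("two-state check accepts the designed switch and rejects broken ones", {
  atp <- design_aptamer_sensor(atp_aptamer_spec(),
                               hairpin_params(len_a = 10, len_b = 12))
  chk <- two_state_check(atp)
  expect_true(chk$pass)
  # OFF fold keeps the blocker:aptamer stem
  off_pairs <- chk$off$pairs
  blocker <- atp$features[atp$features$name == "blocker", ]
  expect_gt(sum(off_pairs$i >= blocker$start & off_pairs$i < blocker$end),
            12L)

  # deleting the blocker leaves the OFF state active
  no_blocker <- atp
  f <- no_blocker$features
  b <- f[f$name == "blocker", ]
  keep <- paste0(substr(atp$sequence, 1, b$start),
                 substr(atp$sequence, b$end + 1, nchar(atp$sequence)))
  shift <- function(x) ifelse(x >= b$end, x - (b$end - b$start), x)
  no_blocker$sequence <- keep
  no_blocker$features <- f[f$name != "blocker", ]
  no_blocker$features$start <- shift(no_blocker$features$start)
  no_blocker$features$end <- shift(no_blocker$features$end)
  no_blocker$pairs$active$i <- shift(no_blocker$pairs$active$i)
  no_blocker$pairs$active$j <- shift(no_blocker$pairs$active$j)
  no_blocker$edit_index <- shift(no_blocker$edit_index)
  chk2 <- two_state_check(no_blocker)
  expect_false(chk2$pass)

  # scrambling b* starves the ON state of its intended stem
  scrambled <- atp
  bs <- scrambled$features[scrambled$features$name == "domain_b_star", ]
  substr(scrambled$sequence, bs$start + 1, bs$end) <-
    strrep("A", bs$end - bs$start)
  chk3 <- two_state_check(scrambled)
  expect_false(chk3$pass)
  expect_match(paste(chk3$diagnostics, collapse = " "), "ON state")

  expect_error(two_state_check(build_substrate()), "aptamer_sensor")
})
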