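test_that("substrate geometry reproduces the published stem arithmetic", {
  model <- build_substrate(hairpin_params(len_a = 7, len_b = 9))
  expect_equal(sum(model$pairs$resting$kind == "wc"), 16L)

  optimal <- build_substrate(hairpin_params(len_a = 10, len_b = 12))
  m <- duplex_metrics(optimal$pairs$resting)
  expect_equal(m$n_paired, 22L)
  expect_equal(m$span, 23L)
  expect_equal(m$mismatch_count, 1L)

  tiny <- build_substrate(hairpin_params(len_a = 1, len_b = 1,
                                         loop_seq = "GAAA"))
  expect_equal(sum(tiny$pairs$resting$kind == "wc"), 2L)
  expect_equal(sum(tiny$pairs$resting$kind == "mismatch"), 1L)
  expect_equal(nchar(tiny$sequence), 10L)
})

test_that("substrate stem pairs equal len_a + len_b across a parameter sweep", {
  withr::with_seed(3, {
    for (rep in 1:12) {
      la <- sample(1:25, 1); lb <- sample(1:25, 1)
      s <- build_substrate(hairpin_params(len_a = la, len_b = lb),
                           seed = rep)
      expect_equal(duplex_metrics(s$pairs$resting)$n_paired, la + lb)
      expect_equal(duplex_metrics(s$pairs$resting)$span, la + lb + 1L)
    }
  })
})

test_that("designed constructs carry exactly one editable A opposite a C", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      s <- build_substrate(hairpin_params(len_a = sample(2:20, 1),
                                          len_b = sample(2:20, 1)),
                           seed = rep)
      expect_equal(substr(s$sequence, s$edit_index + 1, s$edit_index + 1),
                   "A")
      opp <- s$pairs$resting[s$pairs$resting$j == s$edit_index, ]
      expect_equal(nrow(opp), 1L)
      expect_equal(substr(s$sequence, opp$i + 1, opp$i + 1), "C")
      expect_equal(opp$kind, "mismatch")
      # features tile the sequence disjointly and exactly
      f <- s$features[order(s$features$start), ]
      expect_equal(f$start, c(0L, utils::head(f$end, -1)))
      expect_equal(utils::tail(f$end, 1), nchar(s$sequence))
    }
  })
})

test_that("inert sensor collapses domain a to the junction base and reports arm length", {
  con <- build_inert_sensor(arm = strrep("G", 39), seed = 2)
  arm <- con$features[con$features$name == "sensing_arm", ]
  expect_equal(arm$end - arm$start, 39L)
  expect_equal(con$features$end[con$features$name == "junction"], 1L)
  # resting pairs: b:b* including the U:A boundary pair, plus the G:C pair
  expect_equal(sum(con$pairs$resting$kind == "wc"), 12L + 1L)
  expect_equal(sum(con$pairs$resting$kind == "mismatch"), 1L)
  expect_error(build_inert_sensor(arm = ""), "non-empty")
})

test_that("rna sensor arm is the exact reverse complement of the chosen window", {
  tr <- simulate_transcript(length = 200, seed = 7, clean_site = 80)
  win <- tr$manifest$clean$window
  con <- design_rna_sensor(tr$sequence, win[1])
  arm_rng <- con$features[con$features$name == "sensing_arm", ]
  arm <- substr(con$sequence, arm_rng$start + 1, arm_rng$end)
  expect_equal(arm, as.character(reverse_complement(
    substr(tr$sequence, win[1] + 1, win[2]))))
  # active duplex is mismatch-free apart from the central A-C
  mm <- count_duplex_mismatches(con)
  expect_equal(mm$count, 1L)
  expect_equal(mm$mismatches$i, con$edit_index - con$features$start[
    con$features$name == "triplet_sensor"] - 1 + 2)
})

test_that("short arms are honoured and stop-bearing windows are rejected", {
  tr <- simulate_transcript(length = 120, seed = 5, clean_site = 40,
                            arm_length = 9)
  con <- design_rna_sensor(tr$sequence, 40, config = list(arm_length = 9))
  arm_rng <- con$features[con$features$name == "sensing_arm", ]
  expect_equal(arm_rng$end - arm_rng$start, 9L)

  poisoned <- simulate_transcript(length = 160, seed = 5, clean_site = NULL,
                                  poison_site = 60)
  expect_error(
    design_rna_sensor(poisoned$sequence, 60, force = TRUE),
    "stop codon")
})

test_that("snv sensor discriminates mutant from wild type for every substitution", {
  combos <- expand.grid(ref = c("A", "C", "G", "U"),
                        alt = c("A", "C", "G", "U"),
                        stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  for (r in seq_len(nrow(combos))) {
    ref <- combos$ref[r]; alt <- combos$alt[r]
    # stop-free fixture: C-rich window ending at the variant, G junction
    wt <- paste0(strrep("C", 50), strrep("C", 20), ref, "G",
                 strrep("C", 30))
    mut <- wt
    substr(mut, 71, 71) <- alt
    con <- design_snv_sensor(wt, list(position = 70, ref_base = ref,
                                      alt_base = alt),
                             config = list(arm_length = 21))
    expect_equal(count_duplex_mismatches(con, mut)$count, 1L,
                 info = paste(ref, ">", alt))
    expect_equal(count_duplex_mismatches(con, wt)$count, 2L,
                 info = paste(ref, ">", alt))
    # the discriminator sits immediately 3' of the UAG's G
    arm_start <- con$features$start[con$features$name == "sensing_arm"]
    expect_equal(substr(con$sequence, arm_start + 1, arm_start + 1),
                 chartr("ACGU", "UGCA", alt))
  }
})

test_that("snv sensor rejects degenerate variants and edge positions", {
  tr <- simulate_transcript(length = 100, seed = 3, clean_site = NULL)
  ref <- substr(tr$sequence, 51, 51)
  expect_error(design_snv_sensor(tr$sequence,
                                 list(position = 50, ref_base = ref,
                                      alt_base = ref)),
               "equals")
  alt <- setdiff(c("A", "C", "G", "U"), substr(tr$sequence, 6, 6))[1]
  expect_error(design_snv_sensor(tr$sequence,
                                 list(position = 5,
                                      ref_base = substr(tr$sequence, 6, 6),
                                      alt_base = alt)),
               "edge")
})

test_that("ms2 augmentation shifts coordinates once and only once", {
  s <- build_substrate()
  before <- s$edit_index
  m <- add_ms2(s)
  shift <- nchar(MS2_RNA) + 3L
  expect_equal(m$features$start[m$features$name == "ms2"], 0L)
  expect_equal(m$features$end[m$features$name == "ms2"], nchar(MS2_RNA))
  expect_equal(m$edit_index, before + shift)
  expect_equal(substr(m$sequence, m$edit_index + 1, m$edit_index + 1), "A")
  expect_error(add_ms2(m), "already")
  # still assembles into a clean single-stop cassette
  cas <- assemble_reporter(m)
  expect_equal(length(cas$audit$stop_positions), 2L)
})

test_that("reporter cassette stops exactly at the sensor UAG until edited", {
  cas <- assemble_reporter(build_substrate())
  tx <- translate_rna(cas$sequence)
  expect_true(tx$stopped)
  expect_equal(nchar(tx$peptide) * 3, cas$sensor_offset +
                 cas$construct$edit_index - 1)

  edited <- apply_edit(cas)
  tx2 <- translate_rna(edited)
  expect_gt(nchar(tx2$peptide), nchar(tx$peptide))
  codon <- (cas$edit_index - 1) / 3
  expect_equal(substr(tx2$peptide, codon + 1, codon + 1), "W")
  # post-edit: only the terminator stop remains
  expect_equal(audit_frame(edited)$stop_positions,
               nchar(edited) - 3L)
})

test_that("a planted extra in-frame stop aborts cassette assembly", {
  s <- build_substrate()
  # plant UGA into the loop, in what will be the cassette frame
  loop <- s$features[s$features$name == "loop", ]
  bad <- s
  u_start <- bad$edit_index - 1
  phase <- (loop$start - u_start) %% 3
  pos <- loop$start + (3 - phase) %% 3
  substr(bad$sequence, pos + 1, pos + 3) <- "UGA"
  expect_error(assemble_reporter(bad), "stop")
})

test_that("aptamer sensors reproduce the published part lengths", {
  atp <- design_aptamer_sensor(atp_aptamer_spec(),
                               hairpin_params(len_a = 10, len_b = 12))
  f <- atp$features
  expect_equal(f$end[f$name == "blocker"] - f$start[f$name == "blocker"],
               18L)
  expect_equal(f$end[f$name == "aptamer"] - f$start[f$name == "aptamer"],
               40L)
  expect_true(atp$two_state$pass)

  expect_error(
    design_aptamer_sensor(atp_aptamer_spec(blocker_window = c(0, 0))),
    "OFF state")
})
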