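test_that("end trimming and N-fraction filtering follow the QC rules", {
  # Q15 terminal bases on both ends, Q30 core: 4 bases trimmed in total
  r <- make_read("ACGTACGTAC",
                 c(15L, 15L, 30L, 30L, 30L, 30L, 30L, 30L, 15L, 15L))
  out <- quality_filter(r, q_cut = 20L)
  expect_equal(out$reads$bases, "GTACGT")
  expect_equal(unname(out$stats["bases_trimmed"]), 4L)

  # 20-nt read with 3 N (15% > 10%) is discarded
  rn <- make_read(paste0("ACGNACGNACGNACGTACGT"))
  expect_equal(nrow(quality_filter(rn)$reads), 0L)
  expect_equal(unname(quality_filter(rn)$stats["discarded_n"]), 1L)

  # pristine read passes unchanged
  rq <- make_read("ACGTACGT")
  expect_equal(quality_filter(rq)$reads$bases, "ACGTACGT")

  # fully low-quality read trims away entirely
  rl <- make_read("ACGT", c(5L, 5L, 5L, 5L))
  expect_equal(unname(quality_filter(rl)$stats["discarded_empty"]), 1L)
})

test_that("pair merging finds the overlap and resolves disagreements by quality", {
  # constructed 8-nt exact overlap: fragment = 12 nt, reads of 10
  frag <- "ACGTACGTACCG"
  r1 <- make_read(substr(frag, 1, 10))
  r2 <- make_read(as.character(reverse_complement(substr(frag, 3, 12))))
  m <- merge_pairs(r1, r2, min_overlap = 6)
  expect_true(m$merged)
  expect_equal(nchar(m$read$bases), 12L)
  expect_equal(m$read$bases, frag)

  # disjoint reads stay unmerged
  expect_false(merge_pairs(make_read("AAAACCCCGG"),
                           make_read("TTTTTGGGGG"),
                           min_overlap = 6)$merged)

  # a single disagreement in a 10-nt overlap (identity 0.9) resolves toward
  # the higher-quality base
  frag2 <- "ACGGTTCAGGCATG"
  bad <- substr(frag2, 3, 14)
  substr(bad, 3, 3) <- "A"  # fragment position 5 (T) miscalled as A
  r1b <- make_read(substr(frag2, 1, 12), scores = rep(40L, 12))
  r2b <- make_read(as.character(reverse_complement(bad)),
                   scores = rep(10L, 12))
  m2 <- merge_pairs(r1b, r2b, min_overlap = 6)
  expect_true(m2$merged)
  expect_equal(substr(m2$read$bases, 5, 5), substr(frag2, 5, 5))
  # and toward the mate when the mate is the confident one
  r1c <- make_read(substr(frag2, 1, 12), scores = rep(10L, 12))
  r2c <- make_read(as.character(reverse_complement(bad)),
                   scores = rep(40L, 12))
  m3 <- merge_pairs(r1c, r2c, min_overlap = 6)
  expect_equal(substr(m3$read$bases, 5, 5), "A")
})

test_that("fit alignment recovers offsets on both strands with one scheme", {
  withr::with_seed(31, {
    ref <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  })
  read <- make_read(substr(ref, 101, 140))
  aln <- align_to_amplicon(read, ref)
  expect_equal(aln$offset, 100L)
  expect_equal(aln$strand, "forward")
  expect_true(aln$aligned)
  expect_equal(aln$ref_seq, substr(ref, 101, 140))

  rc <- make_read(as.character(reverse_complement(substr(ref, 101, 140))))
  aln2 <- align_to_amplicon(rc, ref)
  expect_equal(aln2$offset, 100L)
  expect_equal(aln2$strand, "reverse")

  # junk below the score floor is flagged unaligned
  junk <- make_read(strrep("A", 40))
  expect_false(align_to_amplicon(junk,
                                 paste0(strrep("C", 100),
                                        strrep("G", 100)))$aligned)
})

test_that("with two candidate loci the higher-scoring one wins", {
  # exact copy at offset 30, one-mismatch copy at offset 80: score
  # arithmetic (40 vs 40 - 5) must place the read left
  locus <- "ACGGTTCAGGCCATTGACGG"
  near <- locus
  substr(near, 10, 10) <- "T"
  ref <- paste0(strrep("T", 30), locus, strrep("T", 30), near,
                strrep("T", 30))
  aln <- align_to_amplicon(make_read(locus), ref)
  expect_equal(aln$offset, 30L)
  expect_equal(aln$score, 40)
  # and symmetrically when the exact copy sits right
  ref2 <- paste0(strrep("T", 30), near, strrep("T", 30), locus,
                 strrep("T", 30))
  expect_equal(align_to_amplicon(make_read(locus), ref2)$offset, 80L)
})

test_that("editing rates compute pileup percentages and bystander flags", {
  # direct arithmetic on a constructed pileup: 60 G reads, 40 A reads
  ref <- paste0(strrep("C", 10), "A", strrep("C", 9))
  reads <- do.call(rbind, c(
    lapply(1:60, function(i) {
      r <- ref; substr(r, 11, 11) <- "G"
      make_read(r, id = sprintf("g%02d", i))
    }),
    lapply(1:40, function(i) make_read(ref, id = sprintf("a%02d", i)))))
  aln <- align_to_amplicon(reads, ref)
  rep <- editing_rates(aln, ref, central_site = 10L)
  expect_equal(rep$central_pct, 60)
  expect_equal(rep$central_depth, 100L)
  expect_equal(rep$status, "ok")
  expect_equal(nrow(rep$bystanders), 0L)

  # no G anywhere: flat zero, no flags
  reads0 <- do.call(rbind, lapply(1:60, function(i)
    make_read(ref, id = sprintf("r%02d", i))))
  rep0 <- editing_rates(align_to_amplicon(reads0, ref), ref, 10L)
  expect_equal(rep0$central_pct, 0)
  expect_true(all(rep0$edit_pct == 0, na.rm = TRUE))

  # per-position counts sum to the covering read count
  expect_equal(unname(rowSums(rep$counts)), rep(100L, nchar(ref)))

  # depth below min_depth is reported, not hidden
  few <- do.call(rbind, lapply(1:10, function(i)
    make_read(ref, id = sprintf("f%02d", i))))
  repf <- editing_rates(align_to_amplicon(few, ref), ref, 10L)
  expect_equal(repf$status, "insufficient_depth")
})

test_that("the pipeline recovers simulated editing within binomial noise", {
  tr <- simulate_transcript(length = 200, seed = 7, clean_site = 80)
  cas <- assemble_reporter(design_rna_sensor(tr$sequence,
                                             tr$manifest$clean$window[1]))
  ref <- as_dna(substr(cas$sequence, cas$edit_index - 100 + 1,
                       cas$edit_index + 100))
  sim <- simulate_reads(ref, central_site = 100, edit_p = 0.6,
                        depth = 600, error_rate = 0.001,
                        bystander_p = c("60" = 0.01), seed = 11)
  rep <- quantify_editing(sim$r1, sim$r2, ref, 100)
  # central estimate within 3 binomial sigma of the programmed truth
  sigma <- sqrt(0.6 * 0.4 / 600) * 100
  expect_lt(abs(rep$central_pct - 60), 3 * sigma)
  # and equals the realized truth closely (errors only)
  expect_lt(abs(rep$central_pct - sim$truth$edit_frac * 100), 1)
  # the 1% bystander stays under the 2% flag threshold
  expect_false(60 %in% rep$bystanders$position)
})

test_that("the quantification chain is deterministic given identical input", {
  tr <- simulate_transcript(length = 200, seed = 7, clean_site = 80)
  cas <- assemble_reporter(design_rna_sensor(tr$sequence,
                                             tr$manifest$clean$window[1]))
  ref <- as_dna(substr(cas$sequence, cas$edit_index - 80 + 1,
                       cas$edit_index + 80))
  sim <- simulate_reads(ref, central_site = 80, edit_p = 0.5, depth = 150,
                        seed = 4)
  rep1 <- quantify_editing(sim$r1, sim$r2, ref, 80)
  rep2 <- quantify_editing(sim$r1, sim$r2, ref, 80)
  expect_identical(rep1$counts, rep2$counts)
  expect_identical(rep1$central_pct, rep2$central_pct)
})
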