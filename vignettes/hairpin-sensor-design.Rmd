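---
title: "Designing and verifying ADAR-recruiting hairpin RNA sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and verifying ADAR-recruiting hairpin RNA sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adarsense)
```

## The sensing principle

ADAR deaminases edit adenosine to inosine (read as guanosine) inside
double-stranded RNA, with a strong preference for an A:C mismatch in a
5'-UAG-3' context. A hairpin transcript that carries an in-frame UAG stop
codon opposite a CCA triplet therefore behaves as a translational switch:
while the hairpin is intact, ribosomes stop at the UAG and only the upstream
fluorophore (BFP) is made; once ADAR converts the UAG to UIG (read UGG,
tryptophan), translation runs through into the downstream GFP. Anything that
controls whether the editable duplex exists — a hybridizing transcript, a
single-nucleotide variant, a ligand-bound aptamer — becomes a measurable
signal, reported as the GFP/BFP ratio.

`adarsense` implements this design space end to end: hairpin substrates,
inert sensors re-activated by target RNA, variant-discriminating sensors,
aptamer-gated (riboswitch-style) sensors, MS2 tethering, and full reporter
cassettes, together with the two readout computations (A-to-G editing
quantification from amplicon reads; GFP/BFP fold activation from flow
events) and seeded simulators that make everything testable offline.

## Hairpin geometry and its parameters

A substrate hairpin is laid out 5'→3' as

    [domain a][CCA][domain b*][loop][domain b][UAG][domain a*]

with stems `a:a*` and `b:b*` flanking the editing loop. Stem lengths are
counted the way the construct diagrams count them: **`len_a` includes the
G:C pair of the UAG:CCA closure and `len_b` the U:A pair**. A 7 + 9 design
is therefore a 16-bp duplex and the saturating 10 + 12 default spans 23 bp
including the central A-C mismatch. The editable A is the single designated
adenosine of the UAG; `build_substrate()` asserts that invariant.

Key defaults and their origin:

| parameter | default | rationale |
|---|---|---|
| `len_a`, `len_b` | 10, 12 bp | saturating stem lengths of the activation series |
| `triplet_opposite` | `CCA` | the most active context opposite the UAG |
| junction pair | C:G | top-performing nick closure (with U:A) |
| sensing arm | 39 nt | optimum of the 9/18/27/39/48-nt series |
| loop | `GAAA` tetraloop | stable tetraloop; the loop sequence is not constrained by the design rules and is configurable |
| blocker | 18 nt | the aptamer's partial complement length |

Non-constrained stem positions are drawn deterministically from a seeded
stream that rejects homopolymer runs longer than 3 and any stop codon — or
reverse complement of a stop codon — in any frame on either strand, so a
filler can sit at any codon offset and so can its Watson–Crick partner. The
published supplementary sequences are not reproduced here; fillers are
reproducible surrogates, and the shipped fluorophore ORFs are deterministic
stop-free synthetic stand-ins of realistic length (swap in real ORFs through
`assemble_reporter()`'s `flanks` argument when exporting a construct).

## Sensing modes

**RNA sensor.** Domain a collapses to the single retained junction cytosine
(near-zero background; the complete CCA can still oppose the UAG) and
domain a* is replaced by a sensing arm, the exact reverse complement of a
39-nt target window — the engineered mismatch always stays in the
intramolecular UAG:CCA region, never in the arm. The arm is placed 3' of
the UAG's G; the mirrored orientation is not offered because the variant
rule below fixes the discriminator adjacent to that G. By default the
sensor supplies its own CCA (`cca_source = "intramolecular"`, no sequence
requirement on the target); `cca_source = "target"` restricts candidate
sites to windows whose 3' flank supplies the CCA, for designs where the
target provides the editing context.

**SNV sensor.** The window is anchored so the variant is the arm's
3'-most paired base: the discriminator (complement of the variant allele)
sits immediately adjacent to the UAG's G. Against the variant the duplex
carries only the central A-C mismatch; against wild type a second, closely
spaced mismatch (e.g. A-A for an A>U variant) destabilizes the editing
loop. Mismatch counting is strict Watson–Crick — G:U wobble is *not* a
match here, because hybridization discrimination is the point. The retained
junction base is chosen complementary to the target base adjacent to the
variant so the nick stays closed in both alleles. Insertions and deletions
are deliberately outside the discrimination model.

**Aptamer sensor.** The blocker (reverse complement of the aptamer's
`blocker_window`, default its first 18 nt) and the aptamer form an OFF-state
stem. The layout

    [a][CCA][blocker][b*][loop][b][UAG][aptamer][a*]

interleaves CCA < blocker < UAG < aptamer, so under pseudoknot-free folding
the 18-bp blocker:aptamer helix *crosses* exactly the UAG:CCA closure while
remaining nested with both stems. The OFF-state optimum therefore keeps
a:a* and b:b* but is topologically barred from the closure at any stem
length — which is what lets the protein-sensor stem extend to 25 bp without
breaking the switch. Ligand occupancy is modelled as forcing all aptamer
positions unpaired (`two_state_check()`'s ON state); whether rewarding
aptamer self-structure would be a better proxy cannot be decided from the
design rules alone, and forcing-unpaired is the documented choice. A layout
passes only if the OFF fold lacks every closure pair and the ON fold
contains all intended b:b* and closure pairs; spacers of 0–4 nt are
searched in deterministic lexicographic order and the first passing layout
is returned. A zero-length blocker is rejected outright: with nothing to
sequester the aptamer there is no designed OFF state, whatever an
unconstrained fold happens to look like.

## Folding model

`nussinov_fold()` maximizes base-pair score (optionally GC/AU/GU weighted
3/2/1; default pure counting) over nested structures with a minimum hairpin
loop of 3 nt, honouring forced-unpaired constraints. Pair-count folding
replaces thermodynamic prediction deliberately: the design checks only need
presence/absence of intended helices, and the dynamic program is exactly
verifiable against brute-force enumeration of all nested pairings (the test
suite does this for all short sequences and randomized 7–12-mers, including
weighted and constrained cases). Traceback is deterministic — a position
prefers pairing over skipping, smallest admissible partner first — so
re-runs are byte-identical. G:U wobble pairs score in RNA folding but never
count as matches in duplex-mismatch auditing. Active-state verification
concatenates sensor and target window through 10 forced-unpaired linker
positions; `verify_intended_pairs()` reports the fraction of intended pairs
present, with 0.9 as the default design threshold (a free 39-nt arm can
poach a stem pair under max-pairing ties without compromising the design).

## Site scanning and bystander auditing

`scan_target()` enumerates every arm-length window on the given strand
(mRNA targets are single-stranded), filters on ambiguity codes, on
stop-clean arms (the arm starts at a codon boundary in the cassette, so its
frame-0 codons are checked), and on junction-base compatibility, then ranks
by `10*tier − bystanders + 0.5*GC` in the six nick-proximal nucleotides.
The published site choices were empirical screens, so the composite score
is an explicitly labelled heuristic; ties break toward fewer bystanders,
then the 5'-most window. `bystander_audit()` lists every duplex adenosine
with its opposite base and flags non-central A:C oppositions — the
geometry most likely to recruit unintended editing.

## Readout computations

**Editing quantification** mirrors an amplicon pipeline at desk scale:
trim read ends below Q20, discard reads over 10% N, merge pairs on the
maximal-identity overlap (≥ 10 nt, ≥ 90% identity, disagreements to the
higher-quality base), fit-align into the amplicon (match +2, mismatch −3,
gap open −5, extend −2, better-scoring strand, score floor at half the
maximum), and pile up. Edits are counted as A→G on the reference sense
strand only; `edit_pct = 100·G/(A+G)` is reported wherever A+G depth
reaches 50, and non-central adenosines above 2% are flagged — the 2%
threshold mirrors the bystander ceiling the sensor is expected to respect.
The external tools a sequencing core would use for these stages are
intentionally replaced by in-package code so the whole chain is
deterministic and testable; parameter parity with any particular external
pipeline is not claimed.

**Flow metrics** gate live cells (scatter rectangle from control
quantiles), singlets (SSC_A/SSC_H within 0.75–1.35; doublets sit near 2),
and BFP-positive cells (99.5th percentile of a vector-only control), then
summarize the per-cell GFP/BFP ratio by its median — robust to lognormal
channel tails — and divide plus-target by minus-target. Whether normalized
intensity should be per-cell or population-level is not derivable from the
description of the computation, so `statistic = "mean"` and `"population"`
are provided alongside the default.

## What the simulators emulate — and what they do not

`simulate_transcript()` plants windows with known properties (stop-free
arm, compatible junction, optional stop poison, optional SNV pair);
`simulate_reads()` draws per-read central-site edits at a programmed
probability, substitution errors at 0.001, and a constant-Q36 profile with
2% Q12 positions to exercise trimming; `simulate_events()` draws lognormal
BFP, GFP proportional to per-cell BFP times baseline leak times activation,
an untransfected autofluorescent fraction (30%), and 5% doublets. All
generators are pure functions of (config, seed) and ship truth records, so
downstream tests compare estimates against realized ground truth rather
than re-simulated data.

The simulators do *not* model PCR duplicates or chimeras, indels in reads,
position-dependent quality decay, spectral spillover, or cellular
covariates of transfection. Passing tests therefore demonstrate that the
estimators are calibrated and the designs are structurally sound under the
stated generative assumptions — not that any particular wet-lab efficiency
will be achieved; fold activations and conversion rates in cells are
measurements, not computable predictions.

## Numerical choices and problem sizes

Frame padding uses C first, then G (stop codons contain no C). Cassette
audits require exactly one in-frame stop (the sensor UAG) before the GFP
terminator. Coordinates are 0-based half-open everywhere, including JSON
output; only human-readable reports are 1-based. Exact positional ties in
read placement follow the underlying aligner's deterministic convention;
strand ties go to the forward strand. The test suite folds sequences up to
about 140 nt (the largest aptamer sensor), quantifies editing at depth
2000 over 20 simulation seeds, and gates 10,000-event tables over 10 seeds
— sizes chosen so the full suite runs in minutes on a single core while
keeping binomial noise well below the tolerances being asserted.

## Known limitations

Pair-count folding cannot rank near-isoenergetic structures the way a
thermodynamic model would; the two-state check is a topological argument,
not a free-energy one. The aptamer sequences shipped as defaults include a
canonical ATP aptamer and a synthetic surrogate for the protein-binding
aptamer (the published supplementary sequences are not in the main text);
both are user-overridable, and constructs intended for synthesis should
carry validated aptamer and fluorophore sequences. Genome-scale off-target
search, RNA accessibility prediction, and FCS binary parsing are out of
scope.
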