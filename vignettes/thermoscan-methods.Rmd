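---
title: "Methods: thermodynamic z-score scanning and consensus structure modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic z-score scanning and consensus structure modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoscan)
```

## Scope and model

`thermoscan` identifies transcript regions whose secondary structure is
more stable than their nucleotide composition alone predicts, and turns
the per-window evidence into a single consensus structure model with a
motif dictionary, an element census and genome-browser tracks. This
vignette records the scientific and numerical decisions behind each
stage, what the synthetic test data do and do not establish, and the
known limitations.

### The folding engine

All thermodynamics run on a simplified nearest-neighbour free-energy
model, chosen so that the dynamic-programming engine and an exhaustive
enumeration oracle can share *exactly* the same energy function:

* allowed pairs: Watson–Crick plus GU wobble;
* stacked pairs score a 6×6 table of stacking free energies (kcal/mol);
* hairpin, bulge and internal loops pay a length-dependent initiation
  penalty tabulated for 1–30 unpaired nucleotides, extrapolated beyond
  30 with the Jacobson–Stockmayer form `E(n) = E(30) + c·ln(n/30)`,
  `c = 1.75·RT ≈ 1.079 kcal/mol`;
* multibranch loops pay an affine `a + b·(branches + 1) + c·unpaired`
  (3.4, 0.4, 0.1 kcal/mol);
* minimum hairpin loop 3 nt; internal/bulge loops are capped at 30
  unpaired nt total (larger ones are disallowed rather than
  extrapolated, keeping the DP and the oracle identical);
* no dangling ends, no coaxial stacking, no pseudoknots or
  G-quadruplexes;
* temperature 310.15 K, so RT = 0.0019872·310.15 ≈ 0.6163 kcal/mol.

The parameter values are Turner-flavoured but deliberately *not*
claimed to reproduce any published parameterization: every quantitative
test in the package validates internal consistency (engine versus
enumeration) rather than parameter provenance, and all downstream
algorithms are engine-agnostic behind the `fold_engine` interface. An
optional adapter (`rnafold_engine()`) delegates MFE calls to an
installed ViennaRNA `RNAfold` binary for users who want production
Turner energies; no package functionality requires it. Consequently,
absolute MFE/ED values from the built-in model should not be compared
numerically against databases built on Turner 2004 energies — the
*z*-score, which is internally standardized, transfers much better.

`mfe_fold()` is a Zuker-style O(n²·s² + n³) dynamic program (s = the
internal-loop span cap); `partition_function()` is a McCaskill-style
inside–outside computation on the same recursions, returning the pair
probability matrix and log Z. `enumerate_all_structures()` generates
every legal structure (guarded at ≤ 22 nt) and scores each with
`structure_energy()`, a direct loop-decomposition implementation kept
independent of the DP code path; the test suite compares the two
routes on hundreds of random sequences (MFE to 1e-9; pair
probabilities and ensemble diversity to 1e-9, observed agreement is at
machine precision). Ensemble diversity is defined as
`ED = 2·Σ p(i,j)(1−p(i,j))`, the expected base-pair symmetric-difference
distance between two independent ensemble draws; the factor of 2 is
pinned by that expectation identity (verified against double
enumeration), and may differ from other tools' ED conventions.

Ties between equal-energy structures are broken deterministically
during traceback by scanning candidate pairs 5′→3′, so identical input
always yields an identical structure string.

### The scan

`scan_transcript()` slides a window (default 120 nt, step 1 — the
window length at which local structure prediction is known to work
well, and the default the database pipeline uses) along the transcript,
within the pipeline's transcript length bounds of 120–200 000 nt
(inclusive; the bounds are stated as strict exclusions of shorter/longer
transcripts, so the boundary lengths themselves are accepted). Per
window it computes the native MFE and structure, the MFE of
`n_shuffles` shuffled windows, the z-score, and the ED.

Decisions worth recording:

* **Shuffle algorithms.** Mononucleotide shuffling is a uniform
  permutation. Dinucleotide shuffling uses the Altschul–Erickson
  Eulerian-path construction — a random last-edge in-tree to the
  terminal letter is drawn by rejection sampling, remaining edge lists
  are permuted, and the Eulerian walk is read off — preserving the
  dinucleotide count multiset exactly and the first/last nucleotide by
  construction.
* **Shuffle count.** Default 50 per window: enough for a usable null
  standard deviation at desk-scale runtime; configurable.
* **Standard deviation convention.** Population (divide-by-n) sd. With
  a degenerate null (sd < 1e-9, e.g. homopolymer windows) the z-score
  is set to 0 and a warning is raised, never NaN.
* **Seeding.** Each window derives its RNG substream from
  `(master seed, window start)`, so scans are reproducible and
  independent of evaluation order; the caller's RNG state is restored.
* **Null behaviour.** For i.i.d.-random sequences the native window is
  exchangeable with its mononucleotide shuffles, so E[z] ≈ 0; the
  finite-shuffle sd estimate and the left skew of MFE nulls leave a
  small negative bias (≈ −0.1 at 50 shuffles in the acceptance run),
  comfortably inside the ±0.2 band the calibration check uses.

### Consensus building

Every pair predicted in a window adds that window's z to the pair's
Zsum; `count` tracks how many windows predict the pair, and
Znorm = Zsum / count. The normalization matters because coverage ramps
at the transcript ends (with step 1, interior positions sit in
`window_length` windows, terminal positions in one), which a raw sum
would conflate with evidence strength.

* **Znorm denominator.** The per-pair window count is the default. The
  phrase "windows in which that nucleotide participates in a pair" is
  genuinely ambiguous between per-pair and per-nucleotide counting;
  `znorm_mode = "nucleotide"` switches the partner-ranking denominator
  to the per-nucleotide count, while stored Znorm values remain
  per-pair so the two modes stay comparable.
* **Selection.** Per nucleotide the minimal-Znorm partner is proposed;
  pairs are kept only when mutual. A nucleotide whose minimum is
  attained by more than one partner (tie tolerance 1e-9) is left
  unpaired — competing partners are dropped, not guessed.
* **Crossing conflicts.** Survivors are processed in ascending Znorm
  (ties: smaller 5′ index); a pair crossing an already-kept pair is
  dropped. This greedy rule is deterministic and favours the strongest
  evidence; for pairwise-independent conflicts it provably coincides
  with the exhaustive maximum-|Znorm| non-crossing subset, which is how
  the oracle tests are constructed. When one candidate crosses two or
  more retained pairs the greedy answer can differ from the global
  optimum; the greedy rule is kept because it is the documented,
  reproducible behaviour.
* **Thresholds.** Filtered structures retain exactly the pairs with
  Znorm ≤ τ, produced at τ = −1 and −2; nesting
  pairs(−2) ⊆ pairs(−1) ⊆ pairs(all) holds by construction and is
  asserted end-to-end.
* **No global refold.** The consensus pairs *are* the final structure;
  retained pairs are also emitted as a constraint file for downstream
  constrained folding by external tools, rather than performing an
  unspecified refold step here.

### Motif dictionary and regions

`extract_submotifs()` walks the consensus dot-bracket with a bond-order
counter (+1 per `(`, −1 per `)`); each maximal interval over which the
counter is positive is one motif. Unbalanced inputs raise a structured
error naming the first offending position — they are counted by the
caller, never auto-repaired, mirroring how consensus pipelines surface
their parsing failures. Flanks (default 0) are annotation context only:
they are excluded from the balance invariant and from region
assignment, which uses the core span.

Motif MFE and ED are *recomputed* on the excised subsequence (the
alternative — inheriting window metrics — is not well defined when a
motif spans many windows); identical motif sequences therefore always
carry identical metrics.

Region assignment works in transcript coordinates of the unspliced
pre-mRNA (contiguous genomic span; plus strand maps position p to
`gene_start + p − 1`, minus strand to `gene_end − p + 1`). UTR labels
take precedence over exon (UTRs lie within exons in GFF3), `exon` means
non-UTR exonic, gaps between exons are introns, and any motif touching
more than one region is labelled `multi_region` rather than forced into
a category.

### Element census

`parse_elements()` decomposes a dot-bracket completely and disjointly:
stems are maximal stacked runs; every unpaired position belongs to
exactly one hairpin loop, bulge (one-sided), symmetric/asymmetric
internal loop, multibranch loop (≥ 2 branches), or the exterior loop —
which is never counted as a multibranch loop. Hairpin records walk from
the apical loop outward to the first multibranch/exterior junction:
`fully_paired` systems have no interrupting bulge or internal loop, and
substructure distances are measured in stacked base pairs strictly
between the apical-loop-closing pair and the feature's apical-side
boundary pair (a bulge below a 3-bp apical stem is at distance 2).
Census percentages default to counting per motif (a motif counts once
per category it contains); `unit = "element"` counts occurrences, in
which case mutually exclusive category rows sum to 100. Both modes
exist because the counting unit behind published percentage figures is
not always stated. LOGO support stops at position-frequency matrices
with per-column information content `IC = 2 − H` bits (no
pseudocounts); rendering is left to dedicated logo tools.

### Tracks and formats

Internal coordinates are 1-based inclusive everywhere; conversion to
0-based half-open BED happens through a single function pair, property
tested by round trip. WIG output is fixedStep anchored at the genomic
coordinate of transcript position 1 (values reversed on the minus
strand so the file ascends genomically). Arc colors follow the z-score
convention blue ≤ −2 < green ≤ −1 < yellow ≤ 0; the boundary values
−2 and −1 fall in the stronger class so the partition is total, and
positive-Znorm pairs are omitted by default. FASTA parsing is
delegated to Biostrings and GFF3 parsing to rtracklayer; WIG, CT and
DBN writers are package code (byte-deterministic, fixed 6-decimal
formatting), with WIG reads cross-checked against rtracklayer in the
test suite.

## What the synthetic data show — and what they do not

The fixture module generates i.i.d. backgrounds with controlled
composition, perfect planted inverted-repeat hairpins (no wobble, so
expected detection is unambiguous), random structure corpora from a
stochastic stem/loop grammar, and toy 2–4-exon pre-mRNA gene models
with UTRs on either strand. Passing tests on these fixtures establish
algorithmic correctness: oracle-exact folding, exact shuffle
invariants, a centred z null, recovery of strongly stable planted
signal, parser agreement, format round trips and bundle determinism.
They do *not* establish biological performance on real transcriptomes:
real sequences have repeat families, composition biases, wobble-riddled
stems and alternative structure, none of which the generator emulates.
Transcriptome-scale census percentages depend on a full annotation run
and are out of scope here; this package reproduces the computations,
validated on synthetic corpora.

## Problem sizes and runtime choices

The validation experiments run at sizes chosen to exercise the claims
on a single CPU in minutes: 200 sequences of 8–18 nt for enumeration
agreement; 1000 sequences for shuffle exactness; 48 random 600-nt
sequences at step 60 and 50 shuffles/window (432 windows) for the null
calibration; 50 seeded 600-nt backgrounds with one planted 30-bp
GC-rich hairpin, scanned at step 10 with 20 shuffles/window, for
recovery; 500–1000 grammar structures for parser agreement; and a toy
gene model scanned twice for byte-determinism. The planted-hairpin scan
uses a coarser step and fewer shuffles than the production defaults
because the planted signal is many standard deviations deep — the
defaults remain 1 and 50.

## Known limitations

* The energy model is simplified; absolute energies are not
  Turner-calibrated (use the `RNAfold` adapter where that matters).
* No pseudoknots or G-quadruplexes, by design.
* Coordinate arithmetic targets unspliced pre-mRNA; mature-mRNA
  (spliced) coordinate mapping is not implemented.
* The greedy crossing resolution can deviate from the global
  maximum-evidence pair set in chain-conflict topologies.
* `run_full_pipeline()` processes transcripts serially; per-transcript
  independence makes parallel scheduling safe, but any such scheduling
  must reproduce the serial bundle byte-for-byte.
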