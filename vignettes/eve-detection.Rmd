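---
title: "Detecting endogenized dinoRNAV elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting endogenized dinoRNAV elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dinoflagellate-infecting +ssRNA viruses (dinoRNAVs, relatives of
*Heterocapsa circularisquama* RNA virus) carry a two-ORF genome: a major
capsid protein (*MCP*) and an RNA-dependent RNA polymerase (*RdRp*).
Although these viruses have no DNA stage and encode no integration
machinery, fragmentary copies of both ORFs occur inside Symbiodiniaceae
genome assemblies — endogenous viral elements (EVEs), most plausibly
deposited by host-provisioned retroelements acting on viral mRNAs.
Detecting them is a needle-in-a-haystack screen with several
characteristic failure modes: the elements are degraded (substitutions,
indels, internal stop codons), they may lack complete ORFs entirely, and
an apparent integration may be an assembly chimera rather than a
biological junction.

`dinoeve` implements that screen as a tested pipeline:

1. **Homology**: six-frame translated (BLASTx-style) search of each
   scaffold against a curated viral protein panel, with Karlin–Altschul
   E-values and the exclusion filters E ≤ 1e-5, bit ≥ 50, identity ≥
   30%, and — in genome mode only — alignment length ≥ 100 aa.
2. **ORF layer**: deterministic stop-to-stop ORF calling, annotation of
   each ORF against the viral and a cellular panel (E ≤ 1e-3, bit ≥ 50),
   and two-tier verification of every retained hit: a complete ORF of
   the same gene class confirms it directly; otherwise the hit region
   ±300 nt of flank is re-searched against the viral panel
   (`confirmed_flank`), and hits failing both tiers are rejected.
3. **EVE calling**: confirmed loci are merged, and MCP/RdRp loci on one
   scaffold are paired greedily by ascending noncoding gap; a pair
   within 1.5 kbp becomes a `genomic` call (candidate whole-genome
   integration), everything else a single-ORF call.
4. **Context**: a 22-nt spliced-leader (dinoSL) relict scan within 500
   nt of the call (seed word 9, two configurable mismatch-exempt
   positions), neighborhood annotation within 20 kbp with retroelement
   flagging, and a read-depth uniformity screen against chimeras.
5. **Evolutionary layer**: global identity, codon back-alignment,
   Nei–Gojobori (1986) dN/dS with Jukes–Cantor correction, and a
   neighbor-joining tree utility.
6. **Reporting**: per-assembly scaffold counts (RdRp-only / MCP-only /
   both), an OLS count model across host genera with type-II F tests and
   Tukey-adjusted pairwise genus contrasts, and benchmark scoring.

## The alignment engine

The search core is an exact Gotoh local aligner (BLOSUM62, gap open 11 /
extend 1, BLAST convention) implemented in C++. Multiple locally optimal
alignments per frame/protein pair are produced by iterative masking: the
best alignment's query interval is masked and the DP rerun until the
score drops below the reporting floor. We chose the exact DP over a
seeded heuristic deliberately: at the scale this package targets (tens
of scaffolds against a small curated panel) the full DP costs about two
minutes for the default benchmark, is fully deterministic, and means the
scores the pipeline filters on are exactly the scores an independent
Smith–Waterman computes — a property the test suite checks directly
against a second implementation.

E-values use the Karlin–Altschul form `E = K m n exp(-λS)` with the
standard gapped BLOSUM62 constants (λ = 0.267, K = 0.041), where `m` is
the total translated residue count of the scanned assembly and `n` the
panel residue count. The thresholds are interpreted with BLAST cutoff
semantics: a hit exactly at a threshold is retained. Percent identity
uses alignment columns (gaps included) as the denominator, matching the
BLAST convention the thresholds come from.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `max_evalue` | 1e-5 | — | homology screen operating point |
| `min_bit` / `min_identity` | 50 / 30 | bits / % | exclusion filters |
| `min_len_aa` | 100 | aa | genome mode only; metagenome scaffolds are short, so no length penalty there |
| `orf_min_len_aa` | 60 | aa | ORFs are annotation units; EVEs are fragmented, so no start-codon requirement |
| `annot_evalue` / `annot_min_bit` | 1e-3 / 50 | — | ORF annotation and flank re-search |
| `flank_nt` | 300 | nt | verification flanks around incomplete candidates |
| `pairing_nt` | 1500 | nt | MCP–RdRp gap ceiling for a whole-genome call |
| `sl_window` / `sl_word` | 500 / 9 | nt | spliced-leader scan window and exact seed |
| `sl_min_matches` | 18 of 20 | — | ≥90% identity over non-exempt positions |
| `neighbor_window` | 20000 | nt | covers reported distal retroelement neighbors (~17 kbp) |
| `cov_diff` / `cov_cv` | 0.25 / 0.5 | — | coverage screen thresholds |

A "complete ORF" is defined explicitly as *terminated by a stop codon
and at least `orf_min_len_aa` residues*; the sources this pipeline
follows leave that implicit, so the package states its criterion and
tests it. The dinoSL query itself is configuration: the bundled default
is the canonical conserved 22-mer with its degenerate first base fixed
to T, and the two mismatch-exempt positions default to 1 (the degenerate
base) and 22 (the splice junction). Both are package defaults, not
values asserted from any one source, and can be replaced via
`sl_query()`.

## The synthetic benchmark

`make_benchmark()` generates the ground-truthed world every stage is
tested in. It emulates:

* GC-matched host background (default 50% GC, 7-kb scaffolds) with
  planted cellular genes from a decoy panel;
* planted viral ORFs as *degraded back-translations* of the bundled
  panel proteins — amino-acid substitutions at a configured divergence,
  then per-nucleotide indels (length a multiple of 3 with probability
  1/2, otherwise frameshifting), then an in-frame internal stop with
  probability `stop_rate`, layered in that fixed order for
  reproducibility;
* whole-genome integrations as MCP + RdRp pairs separated by noncoding
  gaps spanning the observed few-hundred-nt range plus probes at 1200
  and 1501 nt around the pairing rule;
* 22-nt spliced-leader relicts at a known offset 5′ of the RdRp, and a
  LINE-like retroelement gene 95 nt downstream of every other EVE;
* EVE-free negative scaffolds, and chimeric scaffolds built from two
  unrelated halves whose error-free read set covers only the half
  carrying the EVE, producing a sharp depth discontinuity at the
  junction.

Back-translation picks synonymous codons weighted toward the host GC so
planted elements do not stand out compositionally. All randomness is
driven by one seed; identical configurations are byte-identical.

**What the benchmark does not emulate** — and therefore what passing
tests do not show about real data: sequencing error and coverage noise,
repeat-induced misassembly other than the binary chimera construction,
host gene structure (introns, UTRs, real codon usage), homology between
the decoy panel and the viral panel, and panel incompleteness (real
screens are limited by the curated reference set; the benchmark's
detector sees the same panel the generator used). The bundled panels are
deterministic synthetic stand-ins with realistic lengths and class
structure, not real viral or dinoflagellate proteins.

The bundled defaults are the benchmark's study conditions: 24 single-ORF
plants across a 0–0.5 divergence grid, 6 genomic pairs at divergence ≤
0.2, `stop_rate` 0.3, `indel_rate` 0.001/nt, 10 negatives, 5 chimeras,
30× depth. The recovery properties the package commits to — sensitivity
≥ 0.95 for plants at ≤ 30% divergence, no calls on negatives, every
chimera flagged, the 1.5-kbp rule respected exactly — are evaluated on
those conditions in `tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`.

## NG86 and its conventions

The dN/dS layer uses the Nei–Gojobori (1986) counting estimator on
pal2nal-style codon back-alignments: per-codon synonymous site fractions
averaged over both sequences, observed differences averaged over all
equally weighted mutational pathways, and Jukes–Cantor correction
`d = -3/4 log(1 - 4p/3)`. Conventions the implementation fixes (and the
tests pin):

* substitutions creating a stop codon count as nonsynonymous in site
  counting;
* pathways passing through an intermediate stop codon are excluded
  unless every pathway is blocked;
* codon columns containing a gap or an in-frame stop are skipped
  (pal2nal-compatible), with a note on the result;
* the correction is undefined at p ≥ 3/4 and `omega` is `NA` when dS is
  0 — both flagged rather than silently clamped.

This is a deliberate estimator choice: counting methods are
self-contained and desk-scale, and the property that matters for the
biological claim — ORFs drifting without selective constraint give
omega ≈ 1 — is directly testable. The neutral simulator suppresses
stop-creating substitutions (a drifting pseudogene still cannot fix a
nonsense change without ceasing to be alignable), which leaves a small
known downward bias: over 50 replicates of RdRp-length ORF pairs the
median omega lands around 0.9–1.0, within the committed [0.8, 1.2]
neutral band.

Maximum-likelihood codon models and ML phylogenies are out of scope;
`nj_tree()` (neighbor joining via ape, with input validation) is
provided as the lightweight tree utility.

## The count model

`fit_count_model()` regresses the per-assembly number of EVE-containing
scaffolds on host genus plus assembly-quality metrics (query length,
N50, BUSCO-style completeness), using OLS with type-II F tests (via car)
and all pairwise genus contrasts through emmeans. Tukey adjustment is
the default (Holm available) — the contrast machinery is standard, the
adjustment is a package default since sources that name the tool rarely
name the adjustment. Degenerate inputs are reported, not papered over: a
constant response flags undefined F statistics, collinear metrics raise
an error naming the aliased terms, and a single genus is refused.

A scaffold carrying both ORF classes is counted once, in the `both`
category; totals are the sum of the three exclusive categories. This is
stated explicitly because per-ORF and per-scaffold tallies differ by
exactly the double-counted scaffolds.

## Numerical and degenerate-input choices

* All internal coordinates are 0-based half-open; GFF3 output converts
  to 1-based inclusive at the boundary. One convention, converted only
  at I/O.
* Locus merging takes the best hit per merged interval with ties broken
  by higher identity then lexicographic subject id; pairing ties (equal
  gaps) resolve to the leftmost MCP. Outputs are therefore independent
  of input row order.
* Empty inputs degrade cleanly: no-hit scaffolds produce empty frames,
  empty panels warn and leave ORFs unannotated, absent depth marks
  coverage `untested`, an all-zero depth profile fails with an explicit
  zero-coverage reason, and an empty assembly is an error.
* Problem sizes were chosen for a single CPU at desk scale: the default
  benchmark (45 scaffolds × 7 kb against a 1.6-kaa panel) scans in
  about two minutes; oracle comparisons run on 300-nt/100-aa instances,
  1000-case scanner sweeps, and 200-replicate power simulations.

## Known limitations

* The detector and generator share the synthetic panel; absolute
  sensitivity on real assemblies depends on panel curation, which this
  package treats as an input.
* E-value calibration uses ungapped-approximation constants applied to
  gapped scores (the common practical approximation); thresholds are
  configurable where a different calibration is wanted.
* The chimera screen is depth-based only; chimeras with matched
  coverage on both halves are invisible to it.
* Spliced-leader scanning is ungapped by design (a 22-mer relict with
  an indel is below the scanner's evidentiary bar).
* `plant_eve()` places features on the forward strand by default;
  detection itself is strand-symmetric (tested by reverse-complement
  invariance), but benchmark truth for spliced-leader offsets is
  defined in forward orientation.
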