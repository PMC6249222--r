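---
title: "Methods: dual-score essentiality calling from Tn-seq libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-score essentiality calling from Tn-seq libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnseqr)
```

## The inference problem

Saturating transposon mutagenesis followed by junction sequencing (Tn-seq)
identifies genes required for growth: a transposon landing in an essential
gene removes that cell from the population, so essential genes appear as
insertion deserts. `tnseqr` implements the full inference chain for a
compact archaeal chromosome (~2.59 Mb, ~2300 protein-coding genes, 35% G+C,
grown as three independent Tn5 insertion libraries), from raw junction-read
filtering to a per-gene consensus call, plus the downstream comparative
analysis of where the resulting essential genome sits on the tree of life.

Tn-seq cannot distinguish strictly essential genes from genes whose loss
causes a severe growth defect; every "essential" call below carries that
caveat.

## Read filtering and insertion extraction

Junction reads are kept only if they are at least 50 bp long, have a summary
Phred quality of at least 30, and contain the 23-bp transposon end sequence
verbatim; kept reads are trimmed to the sequence 3′ of the tag. Two of these
rules involve conventions the data do not pin down, so both are explicit
configuration:

* *Quality summary.* "Read quality ≥ 30" is interpreted as the mean
  per-base Phred score; `filter_config(quality_summary = "min")` switches to
  the stricter minimum-over-bases reading.
* *Tag matching.* Matching is exact (zero mismatches). One mismatch in the
  tag rejects the read; this is deliberate, since the tag doubles as a
  demultiplexing check.

Alignments are consumed, not produced: `extract_insertions()` takes SAM
records, drops unmapped, short (< 11 aligned bp) and multi-mapping records
(secondary flag, `NH > 1`, or MAPQ below 2 — the MAPQ threshold is
configurable), and reduces reads to (position, strand) junction events. The
junction coordinate is the leftmost aligned base for `+` reads and the
rightmost for `-` reads; with single-end junction sequencing both ends
abut the transposon, and fixing this convention makes results stable even
though either choice would be defensible. Events at the same position on
opposite strands, or in different libraries, are always counted as
independent events.

Two read-count floors are applied at different points, mirroring how the
two scores were designed to be used: events with ≥ 3 reads enter
library-level statistics and fold-change scoring, while the essentiality
index counts only sites with ≥ 4 reads, because 1–3-read sites are vastly
over-represented and of uncertain origin.

## Per-gene scoring

Both scores are computed on the *trimmed gene body*: the first 5% of each
gene (tolerating misannotated start codons) and the last 20% (tolerating
dispensable C-termini) are excluded, strand-aware, with `round()` applied to
both trim points so the trimmed length stays within one base of 75% of the
gene length.

**log₂FC** (`compute_log2fc`). Under the null of uniform insertion, a
gene's expected read mass is `total_reads × trimmed_length /
genome_length`. The score is

    log2FC = log2((observed + 1) / (expected + 1))

with a pseudocount of 1 to keep fully depleted genes finite. A ~900-bp gene
in a library of ~2.5 M reads then scores about −9.5 when empty and about 0
when neutral. No per-library rescaling is applied before pooling: the
expected-reads model is already proportional to library size. This is a
deliberately transparent stand-in for negative-binomial machinery: with
tens of expected insertions per gene the binary depleted/neutral signal
dominates dispersion modelling, and every modelling choice here is visible
and testable.

**EI** (`compute_ei`). The essentiality index is the number of distinct
(position, strand) insertion sites with ≥ 4 reads inside the trimmed body,
pooled across libraries. This preserves the "absolute number of insertions"
semantics and the scale of the conventional `EI < 4` essential cutoff; it
is a documented re-interpretation, not a bit-compatible reimplementation of
any specific sliding-window tool, and it is calibrated here by synthetic
recovery rather than by tool comparison.

**Repeat masking** (`uniqueness_mask`). A base is masked when any 50-mer
covering it occurs at least twice in the genome (forward or
reverse-complement). Genes more than half masked are scored `NA`: reads in
repeated sequence cannot be attributed to one locus, and misplaced
multi-mapped reads would otherwise fake depletion. k = 50 matches the
post-trim read length scale at which mapping ambiguity actually arises.

**Consensus call** (`classify`). A gene is `essential` only if it meets
*both* criteria (`log2FC ≤ −5.1` and `EI < 4`), `non_essential` if it meets
neither, and `unassigned` if it meets exactly one — the conservative
treatment that keeps single-criterion candidates out of the essential set.
Tie handling at the boundaries is exactly `≤` for log₂FC and strict `<` for
EI. Manual overrides (e.g. removing genes whose apparent depletion is a
mapping artefact, or genes shown dispensable by targeted knockout) are
applied last and flagged in the output, never silently.

## Automatic cutoff detection

`find_cutoff()` fits a Gaussian KDE (Silverman's rule-of-thumb bandwidth,
512-point grid) to the finite scores and returns the density minimum
between the two highest local maxima. Numerical choices:

* NA (repeat-masked) genes are excluded before fitting.
* At least 50 finite scores are required.
* A *prominence guard* rejects pseudo-bimodality: the valley must dip below
  80% of the smaller peak's density. Without it, sampling wiggles in large
  unimodal samples occasionally produce two technical local maxima; with
  genuinely bimodal essentiality scores the valley is orders of magnitude
  below both peaks, so the guard costs nothing.
* If no interior, prominent valley exists the function raises a
  "no bimodality" error rather than returning a silent cutoff.

The package defaults pin the classification cutoffs at −5.1 and 4 (the
values at which the dual-criterion consensus was originally operated), but
`find_cutoff()` recomputes a data-driven valley, and on the synthetic
defaults the two agree to within ~1 score unit.

## Library statistics

* `required_colonies(P, g, G)` is the Poisson saturation plan
  `N = ln(1−P)/ln(1−f)`, `f = g/G`, ceiling-rounded because fractional
  colonies cannot be plated. At `P = 0.9999`, `g = 900.64`,
  `G = 2,586,647` it gives 26,448 colonies per library.
* `insertion_density()` reports mean spacing `G/n` and the per-average-gene
  expectation `g / spacing`.
* `coverage_simulation()` cross-checks the plan by Monte Carlo: the mean
  fraction of genes hit converges on `1 − (1−f)^N` (verified at 3 standard
  errors).
* `site_bias_profile()` measures insertion-site composition: the ±20-bp
  flanks of every junction (reverse-complemented for `-` events so offset 0
  is always the junction-proximal base in insertion orientation) are
  stacked and compared against an equal number of uniform random sites
  drawn with replacement, with enrichment normalized by the genome's base
  composition. The profile reports the maximum per-offset enrichment and a
  two-fold flag, the working criterion for "is the bias strong enough to
  distort essentiality calls".

## The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions the rest of the package is validated under:

| parameter | default | rationale |
|---|---|---|
| genome length | 2,586,647 bp | compact crenarchaeal chromosome scale |
| genes | 2300, mean 900.64 bp | realistic archaeal gene count/length |
| gene length law | gamma, shape 3, floor 90 bp | right-skewed with CV ≈ 0.58, as in real annotations; floor = 30 codons |
| essential fraction | 440/2300 | typical archaeal essential-genome size |
| libraries | 3 × 30,000 insertions | three independent transposomes |
| read counts | geometric, mean 30 | heavy right tail; the true tail shape of real libraries is unknown, so it is exposed in the config |
| essential leak | 0.005 per gene per library | rare second-site or border insertions |
| G+C | 35% | genome composition |
| site bias | 1.0 (none) | bias is opt-in for bias-recovery experiments |

Insertions are placed uniformly (or bias-weighted) over the genome
*excluding essential trimmed bodies*, without replacement within a library,
so each library emits exactly its configured event count and ground truth
is exact. `site_bias_strength` is defined as the *realized* fold-enrichment
of G+C at the junction relative to background — the quantity a bias profile
actually measures — and the internal sampling weight is solved from the
genome composition (`w = b(1−p)/(1−bp)`); the ±1..5 flanks get a mild
palindromic A/T preference scaling with the same strength. The genome is
treated as linear for placement; at 2.5 Mb the two edge windows are
negligible.

What the generator deliberately does not emulate: sequencing error
profiles, replication-origin coverage waves (origin normalization is out of
scope by design), operon polarity, and growth-defect intermediate
phenotypes. Passing recovery tests therefore demonstrates that the scoring
machinery is correct and well-calibrated under the stated statistical
structure — not that real libraries meet that structure.

Under these defaults (seeds 1–5) the pipeline recovers the planted
essential set with sensitivity ≥ 0.95 and specificity ≥ 0.98, the score
distribution is bimodal on every seed, and the recovered valley lies near
the pinned −5.1 default. The residual errors are structural, not bugs:
very short genes can be insertion-free by chance (false essentials), and
leak insertions plus trim-boundary reads push a few true essentials over a
cutoff.

## Phyletic analysis

`assign_category()` places each ortholog presence profile into exactly one
of Universal, EA (Eukarya/Archaea), Archaea, TACK, Sulfolobales, or Other:
a category is met when the ortholog is present in ≥ 50% of the taxa of
*each* defining group, categories are tested broad to narrow, and the first
met wins. The broad-to-narrow precedence is the only ordering under which
per-category counts sum to the set size while a universally conserved gene
still counts as Universal rather than as a member of its narrowest clade.
Group membership is supplied as data (a taxon→groups table), not
hard-coded, with the nesting Sulfolobales ⊆ TACK ⊆ Archaea enforced.

`permutation_null()` tests whether observed category counts could arise
from genes of the same prevalence scattered at random: each ortholog keeps
its carrier count while carriers are redrawn uniformly without replacement,
100 times by default, and one-sided p-values are the literal fraction of
replicates at or beyond the observation with denominator exactly
`n_perm` — no +1 correction, ties counted in both tails. With two 5% tails
this makes "non-extreme everywhere" hold ~90–96% of the time on truly
random matrices, which is the calibration property the tests check.

`fitch_score()` is a two-pass Fitch/Hartigan dynamic program over binary
characters, exact for the basal trifurcation of unrooted trees, verified
against exhaustive enumeration of ancestral assignments on every 6-taxon
topology. `exhaustive_parsimony_search()` enumerates all unrooted binary
topologies (feasible to 9 taxa; larger panels are refused with an explicit
error rather than a silent heuristic) and `parsimony_bootstrap()` resamples
characters with replacement, attaching to each internal bipartition of the
reference tree the fraction of replicates whose maximum-parsimony tree set
contains it. Supports attach to bipartitions, not node ids, avoiding
rooting ambiguity; when a replicate has several equally parsimonious trees
a bipartition counts if any of them contains it.

`simulate_presence_absence()` generates matrices with known category
structure (retention 0.9 inside defining groups, 0.02 noise elsewhere,
focal taxon always present); at those defaults category recovery is exact,
and the noiseless and saturating limits behave as forced (100% recovery;
all-Universal).

## Pipeline and problem sizes

`run_pipeline()` chains simulate → score → stats → phyletics into a run
directory with a JSON manifest (stage files, md5 checksums, row counts);
stage seeds are derived from the global seed and the stage name, so any
stage can be rerun in isolation and a rerun reproduces every file
byte-identically. `report_run()` recomputes its summary from the emitted
files only.

The validation suite runs the generator at full study scale (2.59 Mb, 2300
genes, 90,000 insertions) for the recovery experiments and at reduced scale
(hundreds of kb) for format and property tests; the bias experiments use
10⁵ sites on 400-kb genomes, where binomial noise on per-offset frequencies
is below 1% and the 1.1× null bound is meaningful. These sizes were chosen
so every distributional check has comfortable statistical resolution.

## Known limitations

* The expected-reads log₂FC ignores overdispersion; its scale matches the
  conventional −5.1 cutoff under the defaults here, but on libraries with
  very different read depth the data-driven `find_cutoff()` value should be
  preferred over the pinned default.
* The EI is a site count, not a sliding-window index; genes much longer
  than the mean get proportionally higher EI, which the dual-criterion
  consensus (not EI alone) compensates for.
* Orthology is consumed as a precomputed presence/absence matrix; building
  one (orthologous-group membership, reciprocal-best-hit searches) is
  outside the package.
* Exhaustive parsimony is intentionally capped at 9 taxa.
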