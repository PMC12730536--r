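---
title: "Predicting cross-kingdom miRNA targets: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cross-kingdom miRNA targets: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xkmir)
```

# The problem

Plant microRNAs ingested with food can survive the gastrointestinal
tract, reach the circulation, and — at least in documented cases such as
rice MIR168a repressing the human *LDLRAP1* transcript — engage host
mRNAs. `xkmir` implements the standard in silico screen for such
cross-kingdom interactions: which plant miRNAs have credible binding
sites in a host transcriptome, where those sites fall, which genes and
pathways they converge on, and whether the plant miRNAs resemble
endogenous host miRNAs (seed mimicry) or are conserved across edible
plant species.

Everything runs offline on five inputs: a plant miRNA table with
deep-sequencing read counts, a host transcriptome (FASTA plus a
transcript-coordinate annotation), a host miRNA table, a multi-species
mature-miRNA collection, and gene sets in GMT format. A seeded simulator
(`simulate_dataset()`) emulates all five with planted ground truth.

# Models and procedures

## miRNA quality filter

`filter_mirnas()` applies three criteria: read count strictly greater
than 1400 ("more than 1400" is read as an exclusive bound, so exactly
1400 is rejected), mature length between 19 and 25 nt inclusive, and
forward 5'→3' orientation. Orientation is not derivable from a mature
sequence alone, so it is modeled as an optional per-record flag that
defaults to compliant; records carrying `"reverse"` are rejected with a
`BAD_ORIENTATION` code. Read counts are likewise not part of standard
mature-sequence FASTA files; they live in a sidecar column of the TSV
dialect, and a table without them can either fail criterion (1)
(`require_read_counts = TRUE`, the default) or skip it. Filtering never
errors: every record lands in `kept` or in `rejected` with reason codes,
and the two partitions always sum to the input.

## Seed-anchored site search

Animal-style miRNA targeting is anchored by the seed (nt 2–7); the
screen implemented here uses the stricter extended seed, nt 2–13.
`find_sites()` reports every exact occurrence of the reverse complement
of the extended seed in every transcript. This is deliberately an exact
12-mer scan rather than an alignment-tool call: a 12-nt query retained
only at 100% identity and >99% coverage *is* an exact full-length match,
so the scan reproduces the retained-hit set while removing the external
dependency and its E-value machinery. Only antisense matches are
candidates — a transcript containing the miRNA's own (sense) sequence
cannot hybridize with it. Overlapping occurrences are all reported, and
the output order `(transcript_id, site_start, mirna_id)` is fixed so
downstream results are deterministic. The test suite checks equivalence
against a naive sliding-window oracle on random inputs.

Coordinates everywhere are 0-based, half-open, transcript-local. One
convention at every boundary (annotation TSV, site tables, CDS spans)
eliminates the usual off-by-one class of bugs; converters belong at the
package boundary only.

## The duplex energy model

`hybridize()` scores a miRNA:window duplex with an intermolecular
nearest-neighbor model: a structure is an ordered list of base pairs
(miRNA position strictly increasing, target position strictly
decreasing — antiparallel, no pseudoknots, no intramolecular pairs), and

```
energy = helix_init + sum(stacks) + sum(bulge/internal penalties)
```

* **Admissible pairs**: AU, UA, CG, GC and the G·U/U·G wobbles.
* **Stacking table** (`energy_parameters()`): 6×6, kcal/mol at 37 °C,
  Watson–Crick entries from the standard RNA nearest-neighbor (Turner)
  rules, wobble-containing stacks at representative published values.
  The table is data, not code: any entry can be overridden, and a TSV
  reader/writer (`read_energy_parameters()`) round-trips full parameter
  sets.
* **Loops**: affine penalties, `3.3 + 0.5·size` for bulges and
  `2.9 + 0.4·size` (total size) for internal loops, capped at size 15 on
  both — the customary defaults for hybridization tools of this type.
  Dangling ends and terminal-AU corrections are deliberately excluded
  from the default model; they shift absolute energies without changing
  the architecture, and the acceptance threshold is configurable.
* **Initiation**: +4.09 kcal/mol. Unpaired terminal nucleotides cost 0.

Two seed constraints implement the selection criteria: `require_seed_wc`
demands that miRNA nt 2–7 are all paired and Watson–Crick;
`forbid_seed_gu` bans wobbles there. `passes_criteria()` then applies
the strict energy cutoff (MFE < −25 kcal/mol; exactly −25.0 fails). When
the constraints are unsatisfiable the result is an explicit
`"no_structure"` status, distinct from any numeric energy, so a
threshold can never accidentally pass.

Because the published MFE values this style of screen reports were
produced by a web server whose exact parameter vintage is unknowable,
printed energies from the literature should be treated as *inputs* to
downstream filters, not as regeneration targets; this package promises
internal consistency (DP optimum = exhaustive optimum under its own
parameter set), not reproduction of another tool's absolute energies.

### Numerical and algorithmic choices

The optimum is found by dynamic programming over suffixes: `S[i, j]` is
the best continuation energy of a structure whose 5'-most remaining pair
is `(i, j)`. Seed-coverage constraints propagate as a cap on how far the
miRNA index may advance between consecutive pairs (no seed position may
be skipped), a restriction of start positions to nt ≤ 2, and a terminal
condition requiring nt ≥ 7 before the structure may end. Ties between
co-optimal structures are broken toward the lexicographically smallest
pair list (5'-proximal miRNA position, then 5'-proximal target
position), making every output deterministic. Energies are reported at
0.01 kcal/mol — the resolution of the parameter table — which also makes
the decimal TSV representation lossless on round-trip.

`brute_force_mfe()` is an independent oracle: direct enumeration of all
antiparallel non-crossing pairings (miRNA ≤ 10 nt, window ≤ 12 nt). The
acceptance suite compares the two on 10³ random instances across
parameter sets and constraint settings and requires exact agreement.

Hybridization windows (`make_window()`) are anchored at the 12-mer:
`[site_start − (L − 13) − flank, site_end + 1 + flank)`, leaving room
for 3' pairing of miRNA nt 14..L, one downstream position for nt 1, and
`flank = 10` nt of slack per side for bulges, clipped at transcript
edges.

## Annotation, summaries, deduplication

`classify_region()` labels a site by its start position: 5'UTR before
`cds_start`, CDS inside the half-open span, 3'UTR after, `NCRNA` for
non-coding transcripts. Sites straddling a boundary take their start's
region — the single stored anchor coordinate, applied deterministically.
`summarize_interactions()` bins MFEs in 5-kcal/mol intervals, left-closed
toward more negative values (−30.0 falls in [−30,−35)). `dedup_genes()`
drops ncRNA interactions and collapses isoforms to one record per gene;
the representative is the minimum-MFE interaction (the strongest
predicted binding, the natural "most likely genuine target" choice),
with `(transcript_id, site_start)` as the deterministic tie-break.

## Over-representation analysis

`enrich()` is a standard one-sided hypergeometric ORA with
Benjamini–Hochberg FDR, the offline equivalent of what web enrichment
services report as their adjusted p-value (proprietary combined scores
that depend on precomputed background ranks are out of scope). The tail
probability is accumulated in log space (`lchoose` + log-sum-exp), and
tests cross-check it against `phyper` and against direct combinatorics.
The background defaults to all coding genes of the supplied
transcriptome; multiple GMT collections are tested and FDR-adjusted
independently, matching the per-analysis top-10 reporting convention.

The hypergeometric test is discrete, hence conservative:
`P(p < α) ≤ α` under the null, with the gap set by the granularity of
attainable p-values. The calibration diagnostic
(`null_pvalue_calibration()`) therefore simulates the null directly —
the overlap of a uniformly drawn query with a fixed set is exactly
hypergeometric, so each draw is one `rhyper` variate scored by the
package's own tail function — and the acceptance check runs it at counts
large enough (background 10⁵, set and query 2×10⁴, overlap s.d. ≈ 50)
that the granularity sits below Monte-Carlo resolution at 10⁴ draws. At
gene-scale counts the unit test asserts the one-sided (conservative)
bound instead.

## Homology analyses

`find_seed_mimics()` reports all plant×host pairs with identical nt 2–7;
`mimic_hybridize()` re-scores each mimicking host against the
transcripts its plant partner hit — not the whole transcriptome, since
the question is whether the host miRNA could engage the *same* targets —
with seed constraints active and no MFE cutoff, because mimics sharing
only a 6-mer seed usually bind far more weakly and the weak energies are
themselves the finding. `find_conserved()` requires exact full-length
mature-sequence identity in a different species (species parsed from the
miRBase-style id prefix, overridable), reporting "Not detected"
otherwise. T/U normalization precedes all identity comparisons.

# The synthetic-data generator

`simulate_dataset()` emulates the real inputs at desk scale with ground
truth recorded in a manifest. Defaults (all overridable in
`simulation_config()`):

* **Transcriptome**: 80 genes (80% coding, 25% chance of a second
  isoform), i.i.d. sequence at GC 0.5, lengths 300–1500 nt, 15%/55%/30%
  5'UTR/CDS/3'UTR splits. No codon structure — irrelevant to every
  stage.
* **Plant miRNAs**: 30, lengths drawn from 17–27 nt (mass on 19–25),
  log-normal read counts centered on the 1400-read threshold
  (`meanlog = log 1400`, `sdlog = 1.5`) so the QC filter genuinely
  bisects the input, and two reverse-oriented records.
* **Planted sites**: 30 true sites (5/10/12/3 across
  5'UTR/CDS/3'UTR/ncRNA — a 3'UTR/CDS-heavy mix as in real screens),
  substituted (never inserted) so annotation spans stay valid, placed
  non-overlapping within a single region. Extension probability 0.95
  per 3' nucleotide gives most sites enough 3' complementarity to clear
  −25 kcal/mol while leaving a realistic minority below threshold.
* **Decoys**: 5 each of `SEED_GU` (one seed-facing base corrupted into a
  wobble or mismatch), `SEED_ONLY` (only the 6-mer seed complement
  present) and `SHUFFLED` (permuted 12-mer). The first two are invisible
  to an exact nt 2–13 scan *by construction*; `SHUFFLED` can only
  reappear at the background rate, whose expectation
  `(L − 11)/4¹²` per miRNA–transcript pair is printed in the run log.
* **Host miRNAs**: 20, of which 30% share a seed with a site-bearing
  plant miRNA; the rest are rejection-sampled to share no plant seed, so
  the expected mimicry pairs are exact.
* **Conservation**: 30% of plant miRNAs duplicated verbatim under 1–2
  other synthetic species; background records are rejection-sampled
  against accidental identity.
* **Gene sets**: 10 sets of 20 genes over the coding background; one
  planted term draws 80% of its members from the genes that actually
  carry true sites. At these dimensions the planted term's
  hypergeometric p is orders of magnitude below the null sets', which is
  what makes the ≥95% top-rank recovery check meaningful rather than
  marginal.

What the simulator does *not* emulate — realistic expression levels,
splice isoforms sharing planted sites, sequencing error, codon usage,
phylogenetic structure among species — bounds what passing tests show: a
green suite certifies the algorithms (exact recovery, correct rejection,
calibrated statistics, determinism), not the biological realism of any
particular prediction on real data.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed and restores the
caller's RNG state; identical configuration + seed gives byte-identical
bundles and pipeline outputs (verified by hashing in the tests). The
shipped checks use desk-scale sizes chosen to exercise each property
well: 10³ random DP-vs-enumeration instances, 10⁴ null draws for
calibration, 100 seeded replicates (50 in the acceptance script) for
planted-term recovery, and full-pipeline runs on the default 30-miRNA /
~95-transcript bundle.

# Known limitations

* Absolute duplex energies depend on the parameter table; comparisons to
  energies from other tools require using that tool's parameters.
* Target-site accessibility (intramolecular structure of the mRNA),
  suboptimal structures, and extreme-value p-values for MFEs are out of
  scope.
* Criterion (3) of the QC stage (orientation) is only as informative as
  the input flag; mature-sequence tables rarely carry it.
* Region classification uses the site start; a 12-mer straddling a
  boundary is counted once, in its start's region.
* Database-scale results (thousands of interactions against a real
  transcriptome) are supported as external runs of `run_pipeline()` but
  depend on database versions and are not reproduced by the offline
  suite. A useful external positive control is the rice
  MIR168a–*LDLRAP1* interaction: with real miRBase and RefSeq inputs the
  pipeline should report maize miR168 homologs (identical in sequence to
  the rice miRNA) hitting *LDLRAP1*.
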