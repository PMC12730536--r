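# xkmir — cross-kingdom microRNA target prediction

`xkmir` is an R package for predicting cross-kingdom regulation of host
(human) mRNAs by dietary plant microRNAs — for example, maize miRNAs that
survive digestion and may engage human transcripts. It is aimed at
computational biologists who want the whole in silico workflow (miRNA
quality filtering through functional enrichment and homology analysis) as
ordinary, testable R functions that run offline, plus a seeded synthetic
dataset generator with planted ground truth so every stage can be
validated without database downloads.

## The method

Given a table of mature plant miRNAs with deep-sequencing read counts, a
host transcriptome (FASTA + a transcript-coordinate annotation of CDS
spans), host miRNAs, a multi-species mature-miRNA collection and gene-set
collections (GMT), the pipeline runs these stages in fixed order:

1. **miRNA QC** — keep miRNAs with read count > 1400 (strict), length in
   the inclusive range 19–25 nt, and forward (5'→3') orientation.
2. **Site search** — candidate target sites are the exact occurrences of
   the reverse complement of miRNA nucleotides 2–13 (the extended seed)
   in each transcript; overlapping occurrences are all reported. A 12-nt
   query at 100% identity and full coverage makes this equivalent to a
   short-word alignment stage, with no external aligner.
3. **Duplex MFE** — each candidate is scored by an intermolecular
   nearest-neighbor dynamic program over all antiparallel, non-crossing
   pairings: energy = helix initiation + Σ stacking energies + affine
   bulge/internal-loop penalties. A site is accepted iff the seed (nt
   2–7) is perfectly Watson–Crick paired, contains no G·U wobble, and
   the minimum free energy is strictly below −25 kcal/mol. An
   enumeration oracle (`brute_force_mfe()`) provides exact validation on
   small instances.
4. **Annotation + deduplication** — sites are classified by region
   (5'UTR / CDS / 3'UTR / ncRNA) at the site start, summarized as region
   counts and a 5-kcal/mol MFE histogram, and collapsed to unique
   protein-coding genes (non-coding transcripts dropped, isoforms merged,
   minimum-MFE site as representative).
5. **Enrichment** — one-sided hypergeometric over-representation of the
   gene list against each GMT collection, with Benjamini–Hochberg FDR;
   the report keeps the top 10 terms at FDR < 0.05.
6. **Homology** — host miRNAs sharing an identical seed with the
   predicted plant regulators ("seed mimicry") are re-hybridized against
   the targeted transcripts with no MFE cutoff, and the plant miRNAs are
   checked for exact full-length mature-sequence conservation in other
   species.

## Worked example

Plant a strong binding site for the maize miRNA `zma-miR156a-3p` into a
toy transcript, then run the core stages:

```r
library(xkmir)

mirnas <- maize_mirna_fixture()          # 15 mature maize miRNAs
mirnas$read_count <- 2000L               # counts are user-supplied input
mir <- mirnas$sequence[mirnas$mirna_id == "zma-miR156a-3p"]

seed_region(mir)                         # "CUCACU"      (nt 2-7)
extended_seed(mir)                       # "CUCACUUCUCUC" (nt 2-13)
reverse_complement(extended_seed(mir))   # "GAGAGAAGUGAG" = search pattern

set.seed(3)
tx_seq <- paste(sample(c("A","C","G","U"), 300, TRUE), collapse = "")
tx_seq <- plant_site(tx_seq, mir, 150, extend_prob = 1)$sequence
tx <- data.frame(transcript_id = "TX1", gene_symbol = "BCL2",
                 biotype = "coding", sequence = tx_seq,
                 cds_start = 45L, cds_end = 210L)

qc    <- filter_mirnas(mirnas)           # all 15 pass at 2000 reads
sites <- find_sites(qc$kept, tx)
sites
#>         mirna_id transcript_id site_start site_end site_sequence
#> 1 zma-miR156a-3p           TX1        150      162  GAGAGAAGUGAG

accepted <- score_sites(sites, qc$kept, tx)
annotate_interactions(accepted, tx)
#>         mirna_id transcript_id gene_symbol region site_start    mfe
#> 1 zma-miR156a-3p           TX1        BCL2    CDS        150 -38.55
```

The site is found at exactly the planted coordinate (0-based 150),
classified as CDS (it lies inside the 45–210 CDS span), and its duplex —
fully complementary here — scores −38.55 kcal/mol, well below the −25
kcal/mol acceptance threshold. `hybridize()` also returns a text diagram
of the duplex in the usual 4-line target-over-miRNA layout.

For a full run, generate a synthetic bundle and execute every stage:

```r
bundle <- simulate_dataset(simulation_config(seed = 11))
dir <- tempfile(); write_bundle(bundle, dir)
res <- run_pipeline(pipeline_config(
  mirna_path        = file.path(dir, "mirnas.tsv"),
  transcripts_fasta = file.path(dir, "transcripts.fa"),
  annotation_path   = file.path(dir, "annotation.tsv"),
  out_dir           = file.path(dir, "out"),
  gmt_paths         = file.path(dir, "gene_sets.gmt"),
  host_mirna_path   = file.path(dir, "host_mirnas.tsv"),
  multispecies_fasta = file.path(dir, "multispecies.fa")))
#> qc: 30 miRNAs in, 10 kept, 20 rejected
#> site_search: 10 kept miRNAs vs 95 transcripts -> 30 candidate sites
#> duplex: 24 of 30 sites pass (seed WC, no seed G:U, MFE < -25.0)
#> dedup: 24 interactions -> 20 unique protein-coding genes
```

Each stage writes its table under `out/` (interactions, gene summaries,
region/MFE summaries, enrichment, mimicry, conservation, an edge list for
network tools, and a run log).

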