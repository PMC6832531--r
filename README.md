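# venomsplice

Venom glands of pit vipers express a handful of multigene toxin families —
snake-venom metalloproteinases (svMP), serine proteases (svSP),
phospholipases A2 and VEGF among them — and long-read (Iso-Seq style)
sequencing shows that a few of these families multiply their protein
repertoire not by gene number alone but by alternative splicing: exon
skipping, full and partial intron retention, alternative first exons and
polyadenylation sites, and even trans-splicing across tandemly clustered
paralogs. Because each full-length read is one transcript molecule, every
splice variant can be read off directly — provided the reads are classified
carefully against annotated gene models.

`venomsplice` implements that classification as a reusable, fully tested R
pipeline for anyone analyzing isoform repertoires of clustered multigene
families with long reads:

* **Gene models** (`gene_model()`, `read_gene_models()`,
  `write_gene_models()`): annotated multi-exon genes carried in GFF3 with
  domain blocks (signal / prepro / MP / disintegrin / Cys-rich), protein
  motifs such as the zinc-binding motif `HEXGHNLGXXHD` (X = any residue),
  catalytic residues (His57/Asp102/Ser195 of the serine-protease triad) and
  `AATAAA` polyadenylation signals. `derive_model()` expresses the family's
  structural genealogy: the ancestral 17-exon MP architecture loses the
  Cys-rich exons 15–16 (→ 15 exons) and then the disintegrin exons 13–14
  (→ 13 exons), always conserving the terminal exon; a serine-protease
  paralog gains two 3'UTR exons (6 → 8).
* **Full-length filter** (`classify_read()`, `filter_batch()`): a read is
  kept only if it contains a start Met codon (canonical, or re-gained for
  alternative-first-exon variants) *and* an `AATAAA` signal 10–40 nt
  upstream of a terminal polyA tail.
* **Splice-event calling** (`assign_gene()`, `call_events()`): each exon
  chain is assigned to the gene sharing the most exact splice junctions and
  every deviation is classified: `EXON_SKIP`, `INTRON_RETENTION`,
  `PARTIAL_INTRON_RETENTION` (≥10 nt into the intron), `ALT_DONOR` /
  `ALT_ACCEPTOR`, `ALT_FIRST_EXON` (including annotated sub-exons 1b–1e),
  `ALT_POLYA`, `NOVEL_EXON`.
* **ORF re-projection** (`project_orf()`, `locate_motifs()`,
  `check_catalytic()`, `type_mp()`): translation from the (re)located start
  to the first in-frame stop, with the stop mapped back through the chain
  and classified as annotated exon / downstream exon / retained intron;
  frameshift detection; motif and catalytic-residue status; and MP
  structural typing — P-III (MP + disintegrin + Cys-rich), P-II
  (MP + disintegrin), P-I (MP only).
* **Catalog** (`isoform_catalog()`, `collapse_variants()`,
  `detect_chimeras()`, `catalog_summary()`, `write_catalog()`): reads
  collapse into named variants (`gene-v1..vN`, v1 = the "original"
  transcript matching the model) on a structural key, trans-spliced
  chimeras over gene clusters are segmented by donor gene and validated for
  colinearity, and per-gene / per-family summaries are emitted as TSV and
  JSON.
* **Synthetic data** (`build_locus()`, `build_cluster()`, `emit_reads()`,
  `simulate_scenario()`): a deterministic generator of venom-like loci
  (templates `MP17`, `MP15`, `MP13`, `SP6`, `SP8`, `VEGF6`, `PLA2_4`),
  reads with injected events, chimeras and truncations, and a ground-truth
  table whose protein consequences are computed by an independent
  brute-force ORF scan — so every pipeline stage is testable offline.

## Worked example

The canned VEGF scenario plans the eight variant structures of a
single-copy venom VEGF locus — the original, an intron-5 retention, four
intron-3 retentions differing in exon 5/6 usage, an intron-1 retention, and
an exon-2 skip:

```r
library(venomsplice)
sc <- simulate_scenario("svVEGF_suite", seed = 1)
ct <- isoform_catalog(sc$sim$reads, sc$sim$chains, sc$models, sc$clusters)
ct
#> <isoform_catalog>
#>   reads: 13 total, 13 full-length, 0 discarded, 0 unassigned
#>   variants: 8 across 1 gene(s); chimeras: 0 structure(s) in 0 cluster(s)
#>   families with alternative splicing: 1

ct$variants[, c("name", "events", "support", "protein_length")]
#>          name                                  events support protein_length
#> 1 svVEGF01-v1                                               5            182
#> 2 svVEGF01-v2                     INTRON_RETENTION{3}       2             92
#> 3 svVEGF01-v3                            EXON_SKIP{2}       1             43
#> 4 svVEGF01-v4                     INTRON_RETENTION{5}       1            165
#> 5 svVEGF01-v5        ALT_POLYA{2};INTRON_RETENTION{3}       1             92
#> 6 svVEGF01-v6 INTRON_RETENTION{3};INTRON_RETENTION{5}       1             92
#> 7 svVEGF01-v7        EXON_SKIP{5};INTRON_RETENTION{3}       1             92
#> 8 svVEGF01-v8                     INTRON_RETENTION{1}       1             22
```

Reading the output: 13 reads collapse into 8 variants; the four intron-3
retention variants (v2, v5, v6, v7) all stop at the same premature stop
codon in retained intron 3 and therefore translate one and the same 92-aa
protein despite their different 3' structures, the intron-1 retention (v8)
truncates the protein almost immediately, and only the original v1
translates the full 182-aa reference. `summary(ct)` adds per-event-kind
counts and the per-family alternative-splicing flags.

The serine-protease cluster scenario (`simulate_scenario("svSP_clusters")`)
adds two tandem 3-gene clusters and six trans-spliced chimera structures
with two or three donor genes; `isoform_catalog()` reports them separately
from the per-gene variant totals.

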