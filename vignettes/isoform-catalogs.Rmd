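---
title: "Isoform catalogs for venom gene families: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform catalogs for venom gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomsplice)
```

## The problem

Long-read cDNA sequencing yields one read per transcript molecule, so the
isoform repertoire of a gene family can be read off directly — if each read
is classified carefully against annotated gene models. Venom gene families
are a demanding test case: tandem clusters of recently duplicated paralogs
with nearly identical exon architectures, extensive alternative splicing in
a few families (metalloproteinases, serine proteases, VEGF) and none in
others (phospholipases A2), protein consequences that flip a
metalloproteinase between structural classes, and chimeric transcripts that
trans-splice exons from two or three neighboring genes.

`venomsplice` decomposes the analysis into five stages — gene models,
full-length filtering, splice-event calling, ORF re-projection, and
cataloging — plus a synthetic-data generator that makes each stage testable
without any external download. This vignette documents the procedure, its
assumptions, the tunable parameters, and the design choices made where the
problem left the design open.

## Gene models and the exon gain/loss genealogy

A `gene_model` carries exons (0-based half-open genomic coordinates,
indexed 1..n in the gene's transcription order regardless of strand, with
optional lettered sub-exons such as 1b–1e that are not part of the original
transcript), the canonical CDS in transcript coordinates, domain blocks as
inclusive exon ranges, protein motifs with `X` wildcards, catalytic
residues with explicit linear protein positions, and the genomic positions
of annotated `AATAAA` polyadenylation signals. All annotation layers travel
as attributes of the mRNA feature in a documented GFF3 dialect, so a single
file is the source of truth; `write_gene_models()` / `read_gene_models()`
round-trip models field-for-field and byte-stably.

The metalloproteinase family's architecture is generated by descent:
`derive_model()` applies exon-loss/gain edits, re-indexes surviving exons,
drops domain blocks that reference removed exons, and refuses to delete the
terminal exon — the ancestral last exon is conserved in every reduced
paralog. The 17-exon ancestral model loses exons 15–16 (Cys-rich domain) to
give the 15-exon P-II-type architecture and then exons 13–14 (disintegrin)
to give the 13-exon form; a serine-protease paralog gains two exons after
exon 6, both landing in the 3'UTR. Derived models are *structural*: CDS
coordinates are clamped to the new transcript length and sequence-level
re-annotation is the caller's job (the generator builds each template from
scratch instead).

Clusters are inferred by single-linkage over gene spans with a default gap
of 50 kb — the data motivating the package report cluster regions of tens
of kilobases but no explicit gap rule, so the gap is a configurable
parameter, not a fact.

## Full-length filtering

A read is full-length iff it has **both** a start Met codon and a polyA
signal. The start check accepts the model's canonical start position when
the chain covers it; when the chain lacks the canonical start exon entirely
but still begins at an annotated (possibly alternative) first exon, any
`ATG` in the read counts — this keeps exon-2-skipped serine-protease
variants with a re-gained start in exon 3, and sub-exon-initiated
metalloproteinase variants, in the analysis, while 5'-truncated fragments
of ordinary transcripts are discarded. The polyA check requires a terminal
tail of ≥10 adenines whose cleavage point has `AATAAA` 10–40 nt upstream.
The tail-length threshold and signal window are package defaults (the
underlying study names only the hexamer); both are arguments of
`classify_read()`.

## Splice-event calling

`assign_gene()` gives a chain to the gene sharing the most exact splice
junctions, requiring at least one shared junction and ≥50% of the read's
junctions matching; ties break by exonic overlap, then lexicographic gene
id; single-block chains assign by exonic overlap. The junction tolerance is
0 nt by default because synthetic data is exact; a ±ε slack is exposed for
noisy real alignments.

`call_events()` is pure interval algebra in an orientation-normalized
coordinate system (minus-strand genes are mirrored, so all rules are
written once and are strand-symmetric by construction):

* a default exon with no coverage inside the chain span → `EXON_SKIP`
  (maximal runs grouped);
* a block running contiguously across a whole intron → `INTRON_RETENTION`;
* a junction boundary extending ≥10 nt into an intron, contiguous with the
  flanking exon but not reaching the next one → `PARTIAL_INTRON_RETENTION`
  with the side recorded (`5p` = upstream exon extended); smaller
  extensions are treated as alignment jitter. The literature's "extended
  exon" and "partial retain of intron" are the same signal quantitatively
  and both map here;
* a junction boundary shifted *into* an exon → `ALT_DONOR`/`ALT_ACCEPTOR`;
* sub-exon use, or a first block that misses the default first exon →
  `ALT_FIRST_EXON` with the labels of the index-1 exons used;
* a terminal end within ±8 nt of a non-default annotated polyA site →
  `ALT_POLYA`;
* a block overlapping no annotated exon → `NOVEL_EXON`.

A perfect match returns an empty list. Chains whose blocks overlap the
exons of two or more genes bypass event calling and go to chimera
detection.

## ORF re-projection and protein consequences

`project_orf()` translates from the canonical start when present (ATG-only
starts, standard genetic code), otherwise from the first `ATG` of the read;
it walks codons to the first stop and maps the stop's transcript position
back through the chain to genomic space, classifying it as an annotated
exon, a downstream (3'UTR) exon, or a retained intron. The frameshift flag
compares the chain's included exonic length against the model's over the
same genomic span modulo 3. A transcript with no in-frame stop is flagged
run-through and reported to the transcript end (reads carry their polyA
tail, so a run-through protein ends in a lysine run — the same answer the
brute-force oracle gives).

`type_mp()` types metalloproteinase variants from domain-block coverage: a
block counts only when every exon in its range is fully present, translated
in the original frame, and entirely upstream of the stop. P-III needs
MP + disintegrin + Cys-rich, P-II the first two, P-I the MP domain alone; a
variant whose MP domain itself is interrupted is reported `non_functional`
rather than typed. Two consequences of the strict full-exon rule are worth
noting: a variant with a shortened (alternative-donor) exon 14 is *not*
credited with the disintegrin domain, and retention of intron 11 stops
translation before exon 12, so the MP block is incomplete — both are
deliberate, conservative readings. P-IV typing is out of scope: it is a
protein-level disulfide-linked complex and not decidable from transcripts.

`locate_motifs()` matches motif patterns (X = wildcard) against the
projected protein and back-maps matched codons to the exon holding the
majority of them; `check_catalytic()` aligns the variant protein to the
reference by shared prefix (frameshift-aware) and reports each residue as
present, substituted (observed ≠ expected at an alignable position) or
absent.

## Variant collapse, chimeras, summaries

Reads collapse on a structural key: the exact junction chain, the
polyA-site class (nearest annotated signal within ±8 nt of the terminal
end) and the start class. Single-nucleotide (allelic) substitutions never
split variants — so allelic pairs distinguished in manual curation
(e.g. Glu/Lys at one position of an otherwise identical transcript) fold
into one record here; the summary therefore exposes both the inclusive
variant count and a *structural* count that additionally ignores
polyA-site-only differences. Names are `gene-v1..vN` with v1 the original
when present, then support-descending order with deterministic
tie-breaking.

Multi-gene chains are segmented at the junctions where the donor gene
switches; a chimera is kept when it has ≥2 donors, all in one cluster, at
strictly increasing positions along the tandem array. An intervening
cluster member may be skipped: the motivating data contain a read joining
the first gene of a three-gene array directly to the third, which a strict
adjacent-pairs rule would discard. Chimeric reads are cataloged separately
and never counted into per-gene variant totals, and the per-gene
conservation invariant (variant supports sum to assigned full-length reads)
is enforced at run time.

## The synthetic-data generator

`build_locus()` realizes family templates — 17/15/13-exon
metalloproteinase-like, 6/8-exon serine-protease-like, 6-exon VEGF-like and
4-exon phospholipase-A2-like — with fixed exon/intron layouts and seeded
random sequence. Guarantees built into every locus:

* the CDS is free of internal stops; the zinc-binding motif's codons lie
  wholly inside exon 11 of MP templates; the serine-protease triad sits at
  protein positions 57/102/195;
* every intron carries stop codons in all three frames within its first
  60 nt, so any retention event deterministically yields a premature stop
  (this mirrors the observed retention variants, all of which gain stops in
  the retained intron, and makes ground truth computable);
* `AATAAA` signals are placed 20 nt upstream of each cleavage site, with
  the 5'UTR scrubbed of spurious `ATG`s and the 3'UTR scrubbed of spurious
  signals; polyA tails are 30 nt;
* the VEGF template has six exons — the count is not printed in the
  motivating study and is inferred from the intron/exon indices it
  discusses;
* the serine-protease template carries one in-frame `AATAAA` (coding
  Asn-Lys, placed phase-0 so it cannot create a stop) near the 3' end of
  exon 5, emulating the cryptic signal used by a described chimera that
  terminates at exon 5 of its second donor gene.

`emit_reads()` turns read plans (event lists or chimera segment lists, with
read support and truncation modes) into spliced read sequences, BED12-style
exon chains, and a truth table whose protein consequence is computed by
`scan_orf()` — a plain string scan independent of the coordinate machinery
it later validates. Canned scenarios reproduce the described variant
structures: an 18-variant metalloproteinase locus with sub-exons, the
8-structure VEGF suite, two serine-protease clusters with six chimeras, an
18-family genome with splicing confined to three families, and no-splicing
negative controls.

What the generator does *not* emulate: base-level sequencing error (a
uniform substitution option exists but defaults off), expression levels
calibrated to read counts, allelic variation, and alignment ambiguity.
Passing tests therefore demonstrate the correctness of the classification
logic on exact alignments, not robustness to noisy real-world BLAT/PASA
output — for real data the junction tolerance ε and the partial-retention
threshold are the knobs to open.

## Numerical and testing choices

Internally all coordinates are 0-based half-open; GFF3 I/O converts to
1-based inclusive. Determinism is end-to-end: a seed fixes the genome, the
reads, and every name in the catalog, and seeded generation
saves/restores the caller's RNG state.

The test suite checks the implementation against independent oracles: a
per-base coverage-set oracle for event calling (1015 random (chain, model)
pairs across all seven templates, plus every scenario read), a plain
string-translation oracle for ORF projection (every simulated full-length
read), brute-force single-linkage for clustering, and exact recovery of all
injected events, variant counts, metalloproteinase types and chimeras on
noise-free simulations, with zero false positives on the
phospholipase-like negative controls. Scenario sizes (tens of reads per
locus, support 1–10 per variant) match the scale of the venom-gland
full-length read sets they emulate while keeping the whole suite fast on a
single CPU.

## Known limitations

* Assignment thresholds (≥1 shared junction, ≥50% matching) are sensible
  defaults, not fitted values; paralogs sharing most junctions can absorb
  each other's damaged reads under large ε.
* The strict full-exon domain rule under-calls domain retention for
  variants with small in-frame truncations of a domain exon.
* Trans-splicing detection requires annotated clusters; chimeras across
  scaffolds are not modeled.
* Splice-site motif (GT–AG) validation and spliced alignment itself are out
  of scope — alignments are consumed, not computed.

```{r demo}
sc <- simulate_scenario("svVEGF_suite", seed = 1)
ct <- isoform_catalog(sc$sim$reads, sc$sim$chains, sc$models, sc$clusters)
summary(ct)
```
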