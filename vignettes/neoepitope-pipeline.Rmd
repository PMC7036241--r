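---
title: "Identifying candidate neoantigens from somatic variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying candidate neoantigens from somatic variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoepitopes)
```

## The problem

Somatic mutations in tumor cells can produce peptides absent from normal
tissue. When such a mutant peptide is presented by an HLA molecule on the
cell surface it can be recognized by T cells — a *neoantigen*. Finding good
candidates from sequencing data means walking a chain of inferences: a
somatic variant call, its effect on a coding transcript, the mutant protein
it produces, the peptide fragments that cover the altered residues, their
predicted affinity for the patient's HLA alleles, and whether the gene is
expressed at all. Each link drops false positives. This package implements
that chain as composable, deterministic functions, plus the cohort-level
summaries (shared-neoantigen recurrence, per-residue binder coverage, and
an RNA-seq variant-calling concordance benchmark) used to interpret results
across many tumors.

## The model, stage by stage

**Transcript models.** All reconstruction happens against user-supplied
transcript models (`TranscriptModel`): CDS sequence, exon intervals in
transcript orientation, strand. Validity ties the exon widths to the CDS
length and the stored protein to `translateCds()`, so a malformed model
cannot enter the pipeline — `loadTranscripts()` rejects it with a warning
instead. Because variants are validated against the models themselves
(reference-allele match at the mapped CDS position), the package is
assembly-agnostic: any genome build whose coordinates match the annotation
works. Coordinates are 1-based inclusive throughout, matching VCF.

**Translation.** Standard genetic code; translation stops at (and excludes)
the first stop codon; a trailing partial codon is ignored; codons containing
`N` become `X`. A CDS whose length is not a multiple of three is accepted
with a warning — tolerant ingestion of imperfect models beats hard failure
here, since the trailing bases cannot affect any upstream residue.

**Variants and effects.** `readVcfRecords()` (built on
`VariantAnnotation::readVcf`) emits one record per (sample, biallelic alt)
with a called non-reference genotype; multi-allelic sites are split and star
alleles dropped. Depth comes from FORMAT `DP` (INFO `DP` fallback), alt
support from FORMAT `AD`; unknown values are flagged and conservatively fail
the RNA-seq quality filter (`filterRnaseqVariants()`, defaults DP ≥ 10 and
≥ 5 alt-supporting reads — "supported by at least five reads" is read as
alt-allele support, which is the stricter and more natural reading of an AD
field). Effects are classified by applying the variant to the CDS
(strand-aware, reverse-complementing alleles on minus-strand transcripts)
and comparing translations. One ordering subtlety: an indel whose length is
not a multiple of three is always a `frameshift`, even in the rare case
where the shifted frame re-encodes an identical protein; only then is
protein identity consulted (`synonymous`), then inframe indels, then
single-residue substitution (`missense`); stop-gain/loss, start-loss and
multi-residue substitutions fall into `other` and produce no windows.

**Windows.** For missense and inframe effects the neoepitope window is the
21-mer of the mutant protein with the first altered residue at the center
(position 11). Fewer than 10 residues before (after) the alteration
triggers the edge rule: the window is the first (last) 21 residues. A
protein shorter than 21 residues is emitted whole. Frameshifts get up to 10
wild-type residues of context plus the entire novel C-terminal tail, and no
wild-type window: no positionally matched wild-type counterpart exists for
a shifted frame, so downstream DAI is suppressed rather than fabricated.
For inframe indels the window centers the *first* altered residue (the
deterministic anchor) and `alteredSpan` records the run length; a wild-type
window is still written to FASTA for reference, but per-offset peptide
pairing — and hence DAI — is restricted to missense, where offsets
correspond one-to-one.

**Candidate peptides and scoring.** `enumerateCandidatePeptides()` slides a
k-mer across the window keeping every k-mer that overlaps at least one
altered residue. Class I defaults to lengths 8–11, class II to 15.
Scoring goes through an adapter contract — a function
`(peptides, allele) -> IC50 vector (nM, order-preserving)` — with the
registry (`methodRegistry()`) naming the seven IEDB class I algorithms,
MHCflurry, and the four IEDB class II algorithms as external adapter
descriptors. The external models are deliberately not bundled (licensing,
reproducibility); the package ships only the deterministic `toyPredict()`,
a fixed position-weight scheme keyed on peptide and allele, stable across
platforms, with values in (0, 50000] nM. It makes every downstream stage
exercisable and testable; its numbers are not biological predictions, and
any conclusion about real binding requires plugging in a real predictor.

**DAI and tiers.** The differential agretopicity index is the wild-type to
mutant fold change, `IC50_wt / IC50_mut`, so DAI > 1 flags mutations that
improve binding. Tier boundaries: strong < 50 nM, intermediate [50, 250],
weak (250, 500), non-binding ≥ 500. The bracket placement at 50 and 250 is
pinned here so the four labels exactly partition the positive axis;
reported tables use the display vocabulary High/Moderate/Low/Non-binding.

**Expression filter.** Transcript TPM tables (the de-facto pseudo-aligner
layout) are aggregated to genes by summation — the filter is stated at gene
level while quantification is per transcript, and summation is the standard
aggregation. Candidates from genes below 1 TPM (strictly: exactly 1.0 is
kept) are excluded; genes with no expression data are kept and flagged
`noExpressionData`, because expression input is optional and silent
dropping would be worse than an honest flag.

**Cohort analytics.** `recurrenceTable()` counts distinct carrier samples
per (gene, amino-acid change, peptide, allele) — the allele is part of the
identity, since the same peptide restricted by different alleles is a
different therapeutic hypothesis — and reports percentages rounded half-up
to two decimals (17 of 466 → 3.65). `coverageProfile()` builds the
per-residue binder track with a baseline of 1 at every residue, so regions
never covered by a binder stay visible. `genotypeConcordance()` is the
fraction of called variants whose (chrom, pos, ref, alt) site appears in a
truth genotype set; zygosity is not compared.

## Synthetic data: what it emulates and what it does not

`simulateFixtures()` generates a complete, self-contained input set:
random two-exon coding transcripts on alternating strands (ATG start,
terminal stop, no internal stops), per-sample VCFs, abundance tables, an
allele list and a truth table. Its defaults *are* the study conditions the
package's cohort checks run under: a 466-sample cohort with recurrent
missense variants planted in 17, 6 and 5 carriers — the carrier profile of
the most recurrent shared neoantigens in a melanoma-sized cohort — with
about 1.5 private background variants per sample (background mutational
noise at a scale that keeps a full cohort run in the minutes range).
Planted variants always carry filter-passing depths and are chosen without
randomness, so carrier sets are identical under any seed; background
variants draw seeded DP in 3–40 and AD in 0–DP, deliberately straddling
the (10, 5) filter bounds; abundance tables pin one gene below 1 TPM and
planted genes above it, straddling the expression bound.

What passing tests on these fixtures show: coordinate arithmetic, effect
classification, window rules, enumeration, filtering, recurrence counting
and report plumbing are correct. What they do not show: anything about
real mutational signatures, splice complexity, HLA typing accuracy, or
true binding affinity — real transcript models, real calls and a real
predictor are needed for that.

## Numerical and degenerate-input choices

- Rounding of cohort percentages is half-up (`floor(x·100 + 0.5)/100`),
  not banker's rounding, to match how such frequencies are conventionally
  printed.
- Ties and anchors: multi-residue inframe changes anchor on the first
  altered residue; candidate tables sort canonically by (sample, gene,
  transcript, label, allele, length, offset), so results are invariant to
  input order and to the scoring batch size (`batchSize` affects only
  adapter call granularity; a failing batch drops only its own candidates
  and is recorded in the `batchErrors` attribute).
- Degenerate inputs: an empty mutant protein (immediate stop) skips window
  production with a warning; `k` longer than the window warns and yields
  nothing; an empty cohort or allele list yields empty tables, not errors;
  unknown DP/AD fails the variant filter rather than passing it.
- Problem sizes: the bundled checks run the full 466-sample cohort once
  with one allele and 9-mers, and exercise everything else on small
  constructed proteins; these sizes are the package's own test design
  choices and complete in a few minutes on one CPU.

## Known limitations

No proteasomal-cleavage or TAP modelling; no fusion or splice-derived
neoantigens; no HLA typing (alleles are an input); no percentile-rank
calibration of predictors; expression filtering is bulk gene-level TPM,
not allele-specific; concordance is site-level, not zygosity-aware.

## A short worked example

```{r example, eval = FALSE}
fx <- simulateFixtures(tempfile("fx"), fixtureSpec(nSamples = 12L,
  plantedVariants = data.frame(geneIndex = 1L, effectClass = "missense",
                               proteinPos = 29L, nCarriers = 5L)))
tx <- loadTranscripts(fx$reference$cdsFasta, fx$reference$annotation)
cand <- cohortCandidates(dirname(fx$cohort$vcfPaths[[1]]), tx,
                         "HLA-A*02:01", lengths = 9L)
recurrenceTable(cand, 12L, categoryFilter = c("strong", "intermediate",
                                              "weak", "non-binding"))
```
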