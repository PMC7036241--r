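# neoepitopes

Identification of candidate tumor neoantigens from annotated somatic
variants: an R package for the full chain from VCF to ranked,
expression-filtered, HLA-restricted neoepitope candidates, with cohort-level
recurrence and coverage analytics.

## What it does, and for whom

Tumor-specific somatic mutations can create peptides absent from normal
tissue; presented on HLA molecules, these *neoantigens* are targets for
personalized vaccines and engineered T cells. This package is for
computational immunologists and cancer-genomics analysts who have somatic
variant calls (VCF), transcript models (CDS FASTA + exon table), an HLA
allele list, and optionally transcript abundances (TPM), and want a tested,
deterministic implementation of the standard prioritization chain:

1. **Variant ingestion and quality filtering** — single- or multi-sample
   VCF; biallelic splitting; for RNA-seq-derived calls, keep variants with
   read depth DP ≥ 10 supported by ≥ 5 alt reads.
2. **Effect classification** — missense, inframe insertion/deletion,
   frameshift, synonymous, other; strand-aware application of the variant
   to the transcript CDS and translate-and-compare.
3. **Neoepitope windows** — the 21-mer of the mutant protein with the
   altered residue at the center; near a protein end, the 20 following or
   preceding residues complete the window; frameshifts carry the whole
   novel tail and have no wild-type pairing.
4. **Candidate enumeration and binding annotation** — every k-mer covering
   an altered residue (class I lengths 8–11, class II 15), scored through a
   pluggable predictor adapter; the registry names the seven IEDB class I
   algorithms, MHCflurry, and four IEDB class II algorithms; a
   deterministic built-in predictor makes the pipeline testable without
   external software.
5. **DAI and binder tiers** — the differential agretopicity index
   DAI = IC50_wt / IC50_mut (DAI > 1: the mutation improves binding);
   tiers strong < 50 nM, intermediate 50–250 nM, weak 250–500 nM,
   non-binding ≥ 500 nM.
6. **Expression filter** — candidates from genes under 1 TPM (transcript
   TPM summed per gene) are excluded; genes without expression data are
   kept and flagged.
7. **Cohort analytics** — shared-neoantigen recurrence tables with carrier
   frequencies (e.g. 17/466 = 3.65%), per-residue binder coverage profiles
   (baseline 1 per residue, +1 per covering peptide), and a site-level
   genotype-concordance benchmark for RNA-seq-derived calls.

A seeded synthetic-data generator (`simulateFixtures()`) emits complete
reference/cohort/abundance fixtures, so everything above is testable
offline.

## Worked example

Simulate a 12-sample cohort with a recurrent missense variant planted in 5
samples, then recover it:

```r
library(neoepitopes)

fx <- simulateFixtures(file.path(tempdir(), "fx"),
  fixtureSpec(nSamples = 12L,
              plantedVariants = data.frame(geneIndex = 1L,
                                           effectClass = "missense",
                                           proteinPos = 29L,
                                           nCarriers = 5L),
              seed = 42L))
tx <- loadTranscripts(fx$reference$cdsFasta, fx$reference$annotation)
tx[[1]]
#> TranscriptModel TX001 (GENE001, chrS+)
#>    2 exon(s), 327 nt CDS, 108 aa protein

cand <- cohortCandidates(file.path(tempdir(), "fx", "vcf"), tx,
                         "HLA-A*02:01", lengths = 9L)
head(cand[, c("sampleId", "label", "mutPeptide", "ic50Mut", "dai", "category")], 3)
#>    sampleId label mutPeptide  ic50Mut       dai    category
#> 1 sample001  M29L  RSPTRKLGL 2436.619 0.5979248 non-binding
#> 2 sample001  M29L  SPTRKLGLS 2305.622 0.8031897 non-binding
#> 3 sample001  M29L  PTRKLGLSQ 1512.427 0.5025453 non-binding

tab <- recurrenceTable(cand, 12L,
  categoryFilter = c("strong", "intermediate", "weak", "non-binding"))
head(tab, 1)
#>   geneSymbol aaChange   peptide      allele nSamples cohortSize frequencyPct
#> 1    GENE001     M29L GLSQISLHG HLA-A*02:01        5         12        41.67
```

Each row of the candidate table is one mutant 9-mer restricted by one
allele: `ic50Mut`/`ic50Wt` are the predicted affinities (here from the
built-in deterministic predictor — replace with a real adapter for
biological use), `dai` their wild-type/mutant ratio, and `category` the
IC50 tier. The recurrence table counts distinct carrier samples per
(gene, change, peptide, allele): the planted variant is found in exactly
its 5 carriers (41.67% of 12).

The end-to-end per-sample pipeline with report files
(`candidates.tsv`, `windows.fasta`, run manifest) is `runPipeline()`; a
thin command-line front end with subcommands
`run | predict | cohort | benchmark | simulate` is installed at
`system.file("cli", "neoepitopes.R", package = "neoepitopes")`.

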