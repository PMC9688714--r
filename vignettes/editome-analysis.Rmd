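---
title: "Calling and comparing RNA editomes with editomeR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and comparing RNA editomes with editomeR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editomeR)
```

## The problem

RNA editing rewrites single bases of a transcript after transcription.
In mammals the dominant chemistries are deamination reactions:
adenosine-to-inosine (A-to-I, by ADAR enzymes) and cytidine-to-uridine
(C-to-U, by APOBEC enzymes). Inosine base-pairs like guanosine, so A-to-I
editing appears in RNA-seq as an A>G mismatch against the genome; C-to-U
appears as C>T. On a gene transcribed from the minus strand the same events
read as T>C and G>A on the reference strand. The complete set of editing
events called in a sample is its *editome*.

Detecting editing from RNA-seq means distinguishing genuine RNA:DNA
differences (RDDs) from sequencing errors, alignment artifacts and genomic
polymorphism. editomeR implements a stringent post-alignment pipeline for
this problem and applies it to a staged disease design — for example murine
experimental autoimmune encephalomyelitis (EAE), where microglial editomes
are compared across naïve, pre-clinical and acute stages — together with
the orthogonal statistics used to validate individual sites at the bench.

## The calling model

`build_pileup()` tallies quality-passing bases per reference position from a
coordinate-sorted SAM/BAM of ungapped alignments. Three artifact filters act
at this stage:

* **Base quality.** Bases below Phred 25 are discarded (`min_base_quality`).
* **Read-end trimming.** Bases within `end_trim` (default 6) bases of either
  read end are ignored. Libraries primed with random hexamers mis-pair near
  fragment ends, inflating apparent mismatches there; trimming at pileup
  time is equivalent to FASTQ trimming for mismatch counting and keeps the
  pipeline alignment-native.
* **Multimappers.** Reads with mapping quality 0 (the conventional
  multimapper signal, and the simulator's contract) are dropped when
  `exclude_multimapped = TRUE`; a different MAPQ floor can be set with
  `max_multimap_mapq` for aligners with other conventions.

`call_rdd_sites()` treats every pileup position carrying at least one
non-reference base as a candidate. The variant base is the most abundant
non-reference base, with ties broken lexicographically (A < C < G < T) so
that calls are deterministic. A candidate becomes a call only if **all** of
the following hold (defaults in parentheses):

1. not present in the SNP mask (a VCF of known polymorphisms, standing in
   for a dbSNP subset);
2. quality-passing depth ≥ `min_depth` (10);
3. variant support ≥ `min_alt_support` (3 reads);
4. editing frequency = alt/depth ≥ `min_freq` (0.1);
5. both per-site exact tests significant at `alpha` (0.05), with FDR
   control as described next.

### Two per-site tests and where the FDR acts

Editing pipelines gain specificity by intersecting independent callers. We
mirror that with two statistics per site, both against an explicit
sequencing-error null with rate `error_rate` (default 0.01, a typical
post-Q25 error ceiling — deliberately above the true error rate so the null
is conservative):

* `binomial_site_test()`: the REDItools-style error model,
  $p = P(X \ge k)$ for $X \sim \mathrm{Binomial}(n, \varepsilon)$ with $k$
  variant reads out of $n$;
* `fisher_site_test()`: the VarScan-style contingency, a one-sided Fisher's
  exact test of $[[k, n-k], [e, n-e]]$ with $e = \mathrm{round}(\varepsilon
  n)$ expected error reads. At depths where $e$ rounds to 0 this test is
  weak — that is a documented property of the design, not corrected for.

Multiple testing is controlled with the Benjamini–Hochberg step-up applied
to the **binomial** p-values across all candidates, while the Fisher test is
thresholded at its raw p-value. This pairing — FDR on the error-model
statistic, a plain significance cut on the contingency test — reflects how
the two families of callers are conventionally gated, and it keeps the FDR
universe independent of the deterministic thresholds, which in turn makes
the caller *monotone*: tightening any threshold can only remove calls. We
considered FDR on the per-site maximum of the two p-values instead; at desk
scale that combination is dominated by the weak Fisher tail at moderate
depth and needlessly discards true sites, so it was rejected.

All candidates are retained in the output with per-filter failure flags, so
every removal is auditable and `call_attrition()` can telescope counts
(candidates = passed + removed-per-filter) exactly.

## Editome classification and comparison

`classify_mismatch()` maps each call onto the 12 reference-strand mismatch
types. `resolve_editing_class()` then resolves biology by the annotated
gene strand: A>G on a plus-strand gene or T>C on a minus-strand gene is
A-to-I; C>T / G>A likewise for C-to-U; everything else is `other`. Sites in
unannotated (intergenic) regions have no strand; their class is assigned on
the plus-strand reading and flagged `strand_confidence = "low"` rather than
guessed from read orientation, because library strandedness is not modeled.

`annotate_region()` assigns genomic features with the precedence
`exonic > 5'UTR > 3'UTR > ncRNA-exonic > intronic > ncRNA-intronic >
upstream/downstream`, and `intergenic` when nothing overlaps. Annotators
differ in this ordering; coding-exon-first is the common behavior and ties
between genes go to the smallest gene identifier for determinism.
Upstream and downstream flanks are one merged category with a 1 kb window
by default.

`summarize_editome()` reports totals, per-class and per-feature counts, the
per-feature percentages (plain rounding to 0.1 — so a summary row can sum
to slightly off 100; with eight categories the drift is bounded by ±0.4 and
is typically within ±0.2), and the 12-type histogram, which doubles as a
quality control: with only deamination events planted, the four signature
types should dominate. `compare_editomes()` reports percent reductions
(total and per class) of a case stage against a baseline and per-feature
shifts in percentage points.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_reference()` + `plant_sites()` +
`simulate_alignments()` produce a complete miniature dataset with ground
truth, emulating the statistical structure of pooled-microglia bulk
RNA-seq libraries at desk scale:

* a random single-chromosome genome (default 100 kb; the test suite and the
  acceptance script use 10–20 kb genomes with 2–4 transcripts, sizes chosen
  so that every run finishes in seconds while each feature class still
  receives planted sites);
* alternating coding and non-coding transcript models on both strands, so
  all seven annotated feature classes exist, plus intergenic space;
* planted A-to-I and C-to-U sites on strand-appropriate bases, each with a
  true frequency drawn from `edit_freq_range` (default 0.2–0.8, the range
  over which a depth-50 library gives reliably callable support);
* heterozygous SNPs (alt fraction ~0.5) that *pass* every caller threshold
  and can only be removed by the VCF mask — making the SNP-exclusion test
  non-vacuous — plus an optional homozygous fraction;
* uniform read placement at `mean_depth` (default 50×, 75 bp reads), base
  qualities around Q35 with a 5% tail below Q25 to exercise the quality
  filter, per-base substitution errors at `error_rate` (default 0.005)
  boosted 3× within 6 bases of read ends to mimic random-hexamer
  mispriming, and a `multimap_fraction` of MAPQ-0 reads.

Everything is deterministic given the seed: identical configurations yield
byte-identical FASTA/SAM/VCF/TSV outputs.

The simulator deliberately does **not** model splicing, indels, soft-clips,
fragment-length or GC biases, strand-specific protocols, or alignment
itself — reads are emitted pre-aligned because mismatch calling downstream
of alignment is the object under test. Consequently, passing recovery tests
demonstrates that the filters and statistics behave as specified on clean
ungapped alignments; they do not certify performance against splice-site
artifacts or misalignment around indels, which real data add on top.

## Validation statistics

The bench-side module quantifies editing orthogonally to RNA-seq:

* `clone_editing_frequency()`: the fraction of sequenced cDNA clones
  carrying the edited base; `detection_summary()` calls a predicted
  position *verified* when at least one replicate yields at least one
  edited clone, the natural criterion for low-frequency sites;
* `peak_editing_frequency()`: G/(A+G) chromatogram peak-height ratio for
  direct Sanger traces (used where editing is frequent enough to see);
* `one_tailed_unpaired_t()`: Student's pooled-variance unpaired t-test with
  one-tailed p — pooled variance because that is the historical "unpaired
  t-test" of the field's software; Welch is a switch (`var_equal = FALSE`).
  Zero-variance degeneracies are reported explicitly (p = 0.5 at equal
  means; 0/1 with a flag otherwise);
* `ddct_fold_change()`: the 2^-ΔΔCt relative-expression estimator against a
  reference gene such as *Gapdh*;
* `clinical_course_stats()`: per-animal maximal score (MS), trapezoidal
  area under the score–day curve (AUC) over the observed window (no
  extrapolation), and day of onset (first day at score ≥ 1, the "limp
  tail" threshold, configurable). Animals never reaching onset are excluded
  from the onset mean with the exclusion count reported, since silently
  imputing them would bias the statistic. Group summaries are mean ± SE
  with two-tailed unpaired t-tests between two groups.

## Numerical and design choices

* Coordinates are 1-based inclusive for sites, truth tables and VCF; BED is
  converted on read/write. SAM follows its own standard.
* The Fisher expected-error row uses `e = round(error_rate * depth)`,
  allowing `e = 0` at low depth rather than inventing a pseudo-count.
* The alt-base tie-break and the multi-gene feature tie-break are both
  lexicographic, purely for reproducibility.
* All threshold predicates are conjunctive; no filter is applied "before"
  another in a way that changes the passing set (only the attrition
  attribution is ordered).
* Simulated replicate structure is not asserted: the generator exposes one
  library per condition, and pooling strategies beyond a single SAM are out
  of scope.
* Empty inputs degrade explicitly: zero-depth configurations yield valid
  empty SAM files, empty editomes warn and report zero percentages, empty
  p-value vectors adjust to empty vectors.

## Reproducing the pipeline end to end

```{r pipeline, eval = FALSE}
cfg <- list(
  seed = 1, outdir = "editome_run", baseline = "naive",
  conditions = list(
    naive       = list(sim = list(genome_length = 20000L,
                                  n_transcripts = 4L, mean_depth = 50)),
    preclinical = list(sim = list(genome_length = 20000L,
                                  n_transcripts = 4L, mean_depth = 50)),
    acute       = list(sim = list(genome_length = 20000L,
                                  n_transcripts = 4L, mean_depth = 50))))
report <- run_pipeline(validate_config(cfg))
names(report$comparisons)   # "preclinical" "acute"
```

Each condition directory receives the simulated reference, BED/GFF3
annotation, SAM reads, VCF SNP mask, truth table, all candidate calls with
filter flags, and annotated passing edits; `report.json` consolidates
attrition, summaries and baseline comparisons. Reruns with the same
configuration are bit-identical.

## Known limitations

* Only ungapped alignments are consumed; spliced BAMs must be projected or
  filtered upstream.
* The Fisher test is weak wherever `round(error_rate * depth) = 0`; at the
  default thresholds this matters below roughly 50× depth, where the
  binomial test and the hard filters carry the specificity.
* Editing classes at unannotated sites are plus-strand guesses flagged
  low-confidence; resolving them properly requires a stranded protocol.
* Frequency estimates at a site are binomial proportions: at 50× their
  sampling error is several percentage points, so per-site frequencies
  should be read with binomial error bars, and validation-grade frequency
  claims belong to the clone/peak estimators.
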