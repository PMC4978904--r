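---
title: "PAM site repertoires: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PAM site repertoires: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamscape)
```

# The problem

Cas9 nucleases only cut next to a protospacer-adjacent motif (PAM), so the
choice of nuclease fixes the set of targetable loci.  SpCas9 (NGG), the
VQR variant (NGA), SaCas9 (NNGRRT) and KKH SaCas9 (NNNRRT) together span a
much larger repertoire than NGG alone.  `pamscape` quantifies that
repertoire: it enumerates candidate sites genome-wide on both strands,
annotates which fall in coding exons, compares observed site densities
with a closed-form model, designs transcription templates for selected
guides, and classifies the indel outcomes of editing experiments.

# The site model

A PAM class is a degenerate IUPAC pattern plus a protospacer length
(default 20 bp, the canonical Cas9 spacer; SaCas9 guides are often 21–23
and the length is configurable per class).  A *site* is a protospacer
immediately 5' of a PAM match, reported in 0-based half-open forward
coordinates with sequences as read on the targeted strand.  Three rules
shape the enumeration:

* **Ambiguity is disqualifying.** A genomic `N` matches no pattern
  position, including pattern `N`, and an `N` anywhere in the protospacer
  suppresses the site: an ambiguous assembly base cannot be designed
  against.  This is a deliberate asymmetry between pattern degeneracy
  (allowed) and sequence degeneracy (excluded).
* **Record edges drop, not truncate.** A match without full spacer room is
  discarded; a 20-bp guide cannot be designed at a 12-bp margin.
* **Everything else is kept.** Overlapping sites, dyad-symmetric sites and
  double matches at one locus are all reported, with no deduplication, so
  counts compose cleanly with the density model below.

Case is folded on ingest and soft-masking is ignored — lowercase in a
genome FASTA carries no information here, since the repertoire question is
about sequence, not chromatin.

BED output spans the union of protospacer and PAM by default (the whole
editable locus, which is what exon intersection should see); a `pam`-only
span is available for the narrower reading where only the motif itself is
of interest.

# Density: closed form vs scan

Under an i.i.d. base model with probabilities $p_A..p_T$, the per-strand
match probability of a pattern with allowed sets $S_1..S_k$ is
$p=\prod_j \sum_{b\in S_j} p_b$; both strands give rate $2p$ per bp and
mean spacing $1/(2p)$.  Uniform composition yields:

```{r}
sapply(names(pam_six_classes()),
       function(cl) expected_density(cl)$expected_spacing)
```

The NNGRRT value — one SaCas9 site per 32 bp of random DNA — is the
motivating number; the others follow from the same product formula.  Two
approximations are documented rather than corrected:

* **Edge effects** ($L-k+1$ windows vs $L$ positions) are ignored; the
  spacing is an asymptotic rate with bias $O(k/L)$, negligible at genome
  scale.
* **Overlap correlations** between nearby windows are ignored in the
  z-diagnostic, which treats the count as Poisson:
  $z=(\mathrm{obs}-E)/\sqrt{E}$.  For these patterns the correlation is
  weak and the diagnostic is meant to catch scanner bugs and composition
  mismatch, not to be an exact test.  Markov composition models and exact
  overlapping-word statistics are out of scope.

Real genomes are not i.i.d.: the zebrafish assembly the repertoire
question comes from is AT-rich, which shifts every spacing.  For that
reason the density report can be run with `composition = "empirical"`,
which estimates base frequencies from the scanned genome itself; the
32-bp figure is asserted only under the uniform model it belongs to.

A palindromic double-match at one position counts as two sites (one per
strand), consistently in the scanner and in the factor of 2 in the rate.

# Exon intersection

Sites intersect exons under `any_overlap` (default: at least 1 bp of the
protospacer+PAM union overlaps an exon — the reading that matches a
browser-track view of sites in exons) or `full_containment` (the union
lies inside a single exon — the strict design criterion).  Coordinates are
half-open, so adjacency is not overlap.  Exon strand is recorded but
ignored: a double-strand break from either strand disrupts the exon.
Overlapping exon annotations are not merged for the per-site lists (each
overlapping exon is named once, name-sorted so input order is
irrelevant), but the per-kb-of-exon density in the availability summary
uses the merged exon footprint, so duplicated annotation intervals do not
double-count target space.  Overlap itself is delegated to IRanges; the
test suite checks it against a literal O(n·m) double loop.

# Guide template design

The cloning-free route to a gRNA builds its in vitro transcription
template by overlap PCR of two oligos: a forward oligo (T7 promoter +
spacer + the first 20 bases of the scaffold) and a reverse scaffold
oligo.  Design choices:

* **Scaffolds are required inputs.**  Sp- and Sa-family scaffolds differ
  and are not universal constants; hard-coding one risks silently
  designing the wrong chimera, so the profile demands an explicit
  scaffold sequence (the packaged example config carries a clearly
  labelled synthetic placeholder, not a real scaffold).
* **T7 initiation** strongly prefers transcripts starting with G; the
  profile requires a configurable number of leading G's (default 2) and
  satisfies it by prepending (default, matching the cloning-free
  protocol's practice of lengthening the spacer), substituting the first
  bases, or rejecting the spacer.
* **Annealing overlaps** default to 20/20 nt with a 15-nt floor.
* Warnings (never errors) flag spacers with GC outside 0.30–0.80 or
  homopolymer runs of 5+.

`enumerate_guides()` is deliberately capped at 100 kb: it is a locus
tool; genome-scale enumeration goes through the scanner.

# Indel classification

Alleles are aligned to the reference amplicon by global (end-to-end)
Needleman–Wunsch with affine gaps (match +1, mismatch −1, gap open −5,
gap extend −1; Biostrings supplies the alignment).  Maximal gap runs
become events — allele-row gaps are deletions, reference-row gaps are
insertions — and events are then left-aligned to their lowest reference
coordinate (the VCF convention): a deletion shifts left while the base
before the run equals its last base; an insertion shifts left while its
last base equals the preceding reference base, rotating the inserted
sequence.  Within a homopolymer an indel's placement is inherently
ambiguous; left-alignment makes the reported position canonical, which is
why recovery tests compare positions after canonicalizing the planted
truth the same way.  Substitutions are counted but are not events: a
substitution-only allele is a zero-indel call, not an error.  Sequences
must be unambiguous A/C/G/T; base-call ambiguities should be resolved
before classification.

The T7E1 estimator converts relative band intensities to a cleaved
fraction $c=\sum \text{cleaved}/(\text{uncut}+\sum\text{cleaved})$ and
reports both $c$ and the corrected indel fraction $1-\sqrt{1-c}$ (from
cleaved $=1-(1-f)^2$ under random reannealing); published numbers are
sometimes the uncorrected $c$, so both are kept.

# Synthetic data: what it emulates and what it does not

All tests run on generated data: i.i.d. genomes with configurable
composition, uniformly placed (possibly overlapping) exon intervals,
planted concrete PAM windows with full spacer room, and mutant alleles
built by applying specified events.  A single integer seed makes every
generator deterministic, and generators restore the caller's RNG state.
These fixtures validate coordinate arithmetic, strand handling, counting
and recovery — they do not contain repeats, GC isochores, real exon
structure or sequencing error, so passing tests demonstrate correctness
of the algorithms, not performance claims about any particular genome.
Planted-allele events are spaced ≥ 65 bp apart; events closer than an
alignment gap's span can legitimately merge and are outside the recovery
guarantee.

Problem sizes were chosen to make the statistics sharp at interactive
cost: the NNGRRT spacing check uses a 10 Mb genome (3 binomial standard
errors is then ±0.17 bp around 32), the six-class z-test uses 1 Mb with
|z| ≤ 4, scanner–oracle equivalence uses 200 sequences of 50–10,000 bp
across three compositions with ambiguous-base injection, and indel
recovery uses 100 alleles of 1–3 events of 1–25 bp.

# Pipeline determinism

`run_pipeline()` validates all inputs before writing anything, writes
every artifact atomically (temp file + rename), logs stages to stderr
only, and finishes with an MD5 manifest.  Given a config with a seed —
including the fully synthetic packaged config — reruns are byte-identical,
which the test suite asserts file by file.  Failure classes map to stable
exit codes in the CLI wrapper (missing input 2, parse failure 3, internal
invariant 4).

# Known limitations

* No off-target scoring, mismatch-tolerant search or efficiency
  prediction — this package counts and locates exact-PAM sites.
* The density model is i.i.d.; compositional heterogeneity along real
  chromosomes makes local densities deviate in ways the global z cannot
  see.
* Exon annotation is transcript-model-agnostic (no CDS frame or UTR
  logic).
* Allele classification assumes clonal Sanger sequences; mixed-trace
  deconvolution of bulk amplicons is a different problem.
* Wet-lab editing efficiencies (phenotype penetrance, per-locus indel
  frequencies) depend on delivery and chromatin and cannot be computed
  from sequence; nothing here predicts them.
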