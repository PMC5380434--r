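---
title: "Mining glycine-zipper bacteriocins with cdzminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining glycine-zipper bacteriocins with cdzminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cdzminer discovers candidate contact-dependent glycine-zipper bacteriocins
(Cdz-like toxins) in bacterial genomes. Cdz toxins are small (roughly 60–150
residue) proteins secreted through a dedicated type I secretion system
(T1SS); they carry an N-terminal leader removed at a `G[G/A/S]` site, one or
two glycine-zipper motifs (glycines spaced four residues apart), and a short
charged/polar C-terminal tail. Because they are short and fast-evolving,
plain sequence similarity search misses most of the family; the approach
implemented here combines a profile hidden Markov model built from a small
seed alignment with hard structural rules, and requires each candidate to sit
near a T1SS gene pair.

This vignette explains the methods; `?scan_genomes` documents the API.

## The glocal profile HMM

`build_profile()` turns a seed alignment into a profile HMM. Columns with a
gap fraction above `gap_threshold` become insert columns; the rest are match
columns. Emissions and transitions are maximum a posteriori estimates with
Laplace pseudocounts scaled by `pseudocount_weight`, so every probability
vector is strictly positive and normalised.

Scoring is *glocal*: the model must be traversed from its first to its last
column, but the sequence may overhang on both sides. The dynamic programme
(`score_forward()`, `align_viterbi()`) implements the overhangs as free,
zero-cost flanks: the model may be entered at match column 1 after any prefix
of the sequence, and any suffix after the final column is ignored. Insert
states emit from the background distribution, so insertions contribute only
transition costs in the log-odds score (reported in bits). One subtlety
matters for validation: the all-delete traversal (entering at `B→D1` and
deleting every column) is reachable from every split of the sequence into
N-flank and C-flank, so for a sequence of length *n* it contributes *n*+1
identical path terms to the forward sum. The exhaustive path-enumeration
oracle in the test suite enumerates exactly this (offset, state-walk) space,
and forward/Viterbi are checked against it for every small model.

## Score calibration

Raw bit scores have no universal acceptance threshold, so
`calibrate_threshold()` simulates `cal_n_random` background sequences of the
model's match length from the background residue frequencies, scores them
with the forward algorithm, and sets the threshold at the empirical
`1 - cal_alpha` quantile. Calibration uses a private RNG stream
(`cal_seed`) and restores the session RNG state, which is part of how two
runs with the same configuration produce byte-identical reports.

## Structural rules

`classify_toxin()` applies the family's hard rules to each candidate protein:

* length 60–151 residues;
* a leader ending in `G[G/A/S]` with the cleavage point 10–35 residues in;
* one or two maximal glycine-zipper motifs in the mature peptide — at least
  three glycines at period 4 with no proline, cysteine or charged residue in
  between — each flanked (within three residues or at a terminus) by a
  proline or charged residue on at least one side;
* a C-terminal tail of at most 20 residues in which charged plus polar
  residues make up at least 40% of positions;
* no long polar/charged span (more than four charged+polar residues in any
  window of six) in the mature region upstream of the tail.

Failure of any rule rejects the candidate; rules that cannot be evaluated
(for example, no leader found) count as failures.

## Iterative search

`run_iterative_search()` mirrors an iterative jackhmmer-style loop with the
structural rules applied between iterations. Round 0 scores all open reading
frames (60–200 residues, all in-frame starts) in the anchor windows against
the seed-alignment model; ORFs above the calibrated threshold that also pass
`classify_toxin()` are accepted and Viterbi-aligned into the alignment. Each
subsequent round rebuilds the model from the grown alignment, recalibrates,
and rescans. The loop stops when a round adds nothing or after `n_iter`
rounds (default 2). The accepted set is monotone: later rounds only add.

Because all in-frame starts are enumerated, a spurious upstream in-frame
`GTG`/`TTG` can create a second accepted ORF sharing a stop codon with a real
gene. `assemble_clusters()` therefore collapses accepted ORFs that share
(contig, strand, stop-side coordinate), keeping the highest-scoring (tie:
shortest) — one gene, one stop codon.

## Anchoring to the secretion system

`find_anchors()` locates T1SS ABC-transporter and membrane-fusion (adaptor)
genes by scoring annotated CDS translations (or, in `six_frame` mode,
long ORFs) against reference profiles with per-profile calibrated
thresholds; hits within `anchor_group_gap_nt` are grouped into loci. Only
windows of `flank_nt` (10 kb) around anchor loci are searched, and
`assemble_clusters()` drops any accepted toxin farther than `flank_nt` from
every anchor. A BED file of known anchors can bypass profile search.

## The synthetic benchmark

`generate_synthetic()` builds genomes with known truth for end-to-end
validation. Its defaults are the study conditions: 20 genomes of 120 kb,
each carrying one T1SS operon, 1–3 nearby toxins from a mutated family, and
five decoys each violating exactly one rule (interrupted zipper, wrong
length, no leader, no tail, and a sequence-perfect toxin placed far from any
anchor). Three generator details keep the benchmark honest:

* `reverse_translate()` never emits an internal in-frame `ATG`/`GTG`/`TTG`,
  so planted coordinates match enumerated ORF coordinates exactly;
* intergenic background is *stop-salted* so that no spurious ORF of 60+
  residues survives in any of the six frames by chance;
* all randomness flows from one seed through a private RNG, and files
  (including GenBank records, which carry a fixed date stamp) are
  byte-deterministic.

Limits worth knowing: the mutation model is i.i.d. per-residue within the
toxin's structural blocks (no indel phylogeny), background composition is a
single GC dial, and decoys probe the rules one at a time rather than
adversarially. The benchmark measures whether the machinery does what it
claims on sequences like its training family — not sensitivity on real,
divergent genomes.

## Reproducing the headline numbers

```{r}
library(cdzminer)
x <- generate_synthetic(synth_params())        # 20 genomes, seed 1
res <- scan_genomes(x$genomes, x$seed_msa, t1ss_refs = x$t1ss_refs,
                    out_dir = "scan_out")
res
summarize_clusters(res$clusters)$class_distribution
```

or, from the shell, `Rscript scripts/acceptance.R --seed 1 --out report.json`.
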