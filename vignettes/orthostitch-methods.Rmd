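---
title: "Methods: reference-guided marker stitching in orthostitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-guided marker stitching in orthostitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthostitch)
```

## The problem

Low-coverage whole-genome ("genome skimming") data yields fragmented
assemblies with low N50: a protein-coding gene is typically scattered
across several short contigs, and introns break its coding sequence into
pieces even within one contig. `orthostitch` recovers protein-coding
phylogenetic markers — typically a curated set of universal single-copy
orthologs (USCOs) — from such data by using reference protein sequences
as scaffolds: translated-search hits from many contigs (or reads) against
one reference are merged into a single continuous amino-acid sequence.

## The procedure

1. **Reference pooling and search.** All reference proteins are pooled
   into one FASTA. Hits are obtained either from an external translated
   aligner (`blastx`/`diamond` via `run_external_search()`; the database
   and tabular files are kept for reuse), from a precomputed tabular file
   (`parse_tabular()`), or from the package's own six-frame translated
   local search (`builtin_search()`). Alignments are scored with BLOSUM62
   and affine gap costs: gap open 11, gap extend 1, a gap of length $L$
   costing $11 + L$.

2. **Hit stitching** (`stitch()`). Per reference, hits are sorted by how
   they align to it and pushed onto a stack. Whenever the top of the
   stack overlaps the next region, both candidates are realigned — only
   over the reference interval in which they overlap — against that
   reference slice, and up to three sliced parts are pushed back: the
   left flank of the earlier region, the better-scoring candidate's
   overlap segment, and the right flank of the region reaching further
   right. Passes repeat until no overlaps remain. Containment is handled
   as a degenerate overlap; regions from the same contig may be joined.

3. **Masking** (`mask_region()`). Residues aligned to no reference
   position (insertions) are removed; ambiguous residues (B = D/N,
   J = I/L, X = unknown, Z = E/Q) and stop codons (`*`) are removed
   unless `--retain-ambiguous` / `--retain-stops`. Removed query
   residues become deletions, so reference coordinates are preserved.

4. **Concatenation, realignment, trimming** (`finalize_marker()`). The
   ordered non-overlapping regions are concatenated and realigned to the
   full reference, then a sliding window scans the realignment and cuts
   every column that lies in no window whose gap-excluded distance
   $1 - \mathrm{identical}/\mathrm{aligned}$ is at or below the
   threshold. Output is available as amino acids and, through per-residue
   codon provenance, as nucleotides.

5. **Reporting** (`marker_stats()`, `aggregate_reports()`). Per
   reference: reference/query length, matches, mismatches, deletions,
   query coverage, gap-excluded identity; aggregated as
   mean/min/median/max plus the combined accuracy/completeness measure

   $$p_{\mathrm{identical,cov}} = 100 \cdot
     \frac{n_\mathrm{match}}{n_\mathrm{aligned}} \cdot
     \frac{\sum \mathrm{len}(s_\mathrm{recovered})}
          {\sum \mathrm{len}(s_\mathrm{reference})},$$

   which multiplies accuracy by completeness so that recovering few
   markers at high identity cannot flatter the result.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| substitution matrix | BLOSUM62 (25 letters, incl. B J Z X `*`) | scoring of aligned residue pairs; NCBI-format custom matrices via `--matrix` |
| gap open / extend | 11 / 1 | affine gap costs (length-$L$ gap costs $11 + L$) |
| `window_size` | 15 columns | sliding-window width for trimming |
| `distance_threshold` | 0.5 | maximum tolerated window distance (strictly-above columns are cut) |
| `min_score` | 40 (raw) | built-in search hit floor, applied after end anchoring |
| `seed_length` | 5 residues | exact-match seed for the built-in search prefilter and hit end anchoring |
| `min_bitscore` | off | optional bit-score filter before stitching; by default all hits enter stitching |
| `masking` | 0 (off) | external-aligner query low-complexity masking; leaving it off raises query coverage |

The trimming defaults are this package's own choices: a
15-column window is wide enough that a single incorrect-looking but
genuine match cannot dominate the distance, and 0.5 cuts regions whose
gap-excluded identity falls below one half — far below what noncoding
read-through typically attains against a homologous reference. Both are
plain flags and are recorded in the run's `config.yaml`, so results are
reproducible.

## Numerical and design choices

* **Traceback determinism.** The affine-gap dynamic program breaks score
  ties with fixed priority diagonal > up > left, so every alignment (and
  every downstream artifact) is bit-reproducible.
* **Overlap realignment mode.** The overlap interval is fixed by the two
  regions' coordinates, so each candidate's residues are realigned
  *globally* against that reference slice; global scores over the same
  slice are directly comparable. Ties keep the earlier region's segment
  (lower start, then lexicographically smaller query id). The choice is
  isolated in one function, so a local-mode variant is a one-line
  substitution.
* **Final realignment.** Semiglobal: the concatenated marker aligns end
  to end, while unaligned reference overhangs (the parts of the
  reference the marker does not reach) are free. Penalizing those
  overhangs would only shift scores by a constant per marker length and
  could distort the trimming window at the sequence ends.
* **Trimming granularity.** A column is kept iff it lies in at least one
  passing window, so overlapping passing windows protect isolated
  bad-but-correct matches; windows containing no aligned column count as
  distance 1 (at threshold 1.0 nothing is ever cut). Cut insertion
  columns are dropped outright; cut aligned columns become deletions so
  coordinates are stable. This makes trimming idempotent and monotone in
  the threshold, both of which are asserted as property tests.
* **Built-in search hit ends.** Hits are seeded by exact 5-mers and
  their termini are trimmed back to the outermost run of 5 consecutive
  identities. A Smith–Waterman-optimal local alignment may otherwise end
  in a short net-positive spurious extension (e.g. read-through into an
  intron whose translation happens to score positively for a few
  residues); anchored ends keep every hit inside its true coding
  interval on error-free data, which the fixture ground truth asserts
  exactly. External aligner output is taken as-is.
* **Degenerate inputs.** Empty alignments score 0; an all-deletion
  stitched region contributes nothing to the final sequence; a reference
  whose regions are entirely masked or trimmed away is reported as
  absent rather than as an empty row.

## Greedy stitching is not globally optimal (and that is faithful)

The stack procedure commits each overlap, in sorted order, wholly to the
better-scoring candidate. On a small fraction of three-region
geometries (the acceptance suite's fixed-seed sweep finds 12 of 1,000
random instances) this is measurably below the optimum over all
per-overlap winner assignments. A minimal counterexample, asserted as a
unit test, with reference `LDFLQKQQWNWGHHDTP`:

* region A `[1..17]` with one substitution at position 5,
* region B `[5..17]` with substitutions at positions 6 and 16,
* region C `[7..17]` exact.

The stack first resolves A-vs-B over `[5..17]`, where A scores higher,
so B is discarded wholesale and A's wrong residue at position 5 survives
(final score 100). Letting B win `[5..17]` instead would allow exact C
to reclaim `[7..17]` afterwards, leaving B only `[5..6]` where it is the
better candidate (final score 102). The greedy whole-overlap commitment
is what makes the procedure fast and single-pass-per-iteration, and it
is kept deliberately, so the enumeration-equality check in the
acceptance suite
is expected to report these rare shortfalls; the properties that do hold
— greedy never exceeds the enumeration optimum, two-region resolutions
are exactly optimal, and every resolved overlap keeps the
higher-scoring candidate — are asserted as green tests.

## What the synthetic fixtures emulate — and what they do not

`generate_markers()` draws random reference proteins (default 120–300
residues), back-translates them deterministically (alphabetically first
codon per residue), interrupts each gene with 1–3 random introns of
60–300 nt placed between codons (a flag allows phase-breaking introns),
optionally applies uniform per-site substitutions, and cuts the gene
into 300–500 nt fragments overlapping by 90 nt, randomly
reverse-complemented — emulating the highly discontinuous, low-N50
assemblies typical of low-coverage data. Intron placement keeps every
exon at least 45 nt so each coding stretch is long enough to be found by
a seeded search; the 90 nt tiling overlap guarantees every coding
position sits comfortably inside some fragment. `simulate_reads()` adds
paired-end reads (Poisson pair counts at the requested fold coverage,
fixed insert size, uniform substitution errors) and `subsample_pairs()`
thins them with mate pairing intact.

The generator does *not* emulate: indel sequencing errors or
quality-dependent error profiles, splice-site motifs, codon usage bias,
paralogy (so chimera formation is not exercised), assembly artifacts
beyond fragmentation, or real intergenic sequence. Passing the
ideal-case tests therefore demonstrates correctness of the mechanics —
search, stitching, masking, trimming, coordinate bookkeeping — not
robustness to biological divergence, which on real data is governed by
the reference choice and the trimming threshold.

## Problem sizes used by the test-suite studies

The ideal-case recovery study runs 200 intron-bearing genes (about 700
fragments of at most 500 nt) through the whole pipeline with the
built-in search; the stitching enumeration sweep uses 1,000 random
instances of two or three overlapping regions on references of at most
40 residues; the pairwise oracle compares 500 random pairs of at most 12
residues against a plain-R affine DP; subsampling checks 4-sigma
binomial bounds on ~10,000 simulated pairs. These sizes make every
derived expectation exhaustively checkable while each suite file still
runs in seconds to a few minutes.

## Known limitations

* Chimeric stitching across paralogs is possible by construction; the
  guard is using (near-)single-copy reference sets.
* The built-in search is a testing and small-scale path; for large data
  sets an external seed-and-extend aligner is the intended search
  engine.
* Frameshift placeholder characters from frameshift-aware external
  searches are treated as unaligned rather than corrected.
* Codon-aware realignment and premature-stop repair are out of scope;
  downstream tools handle them.

## A worked call

```{r example, eval = FALSE}
fx <- generate_markers(fixture_spec(n_markers = 20, seed = 1))
cfg <- run_config(query = fx$paths$contigs,
                  references = fx$paths$references,
                  out = "demo_run", engine = "builtin")
res <- run_pipeline(cfg)
res$aggregate
```
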