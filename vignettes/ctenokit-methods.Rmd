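---
title: "Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ctenokit` implements the custom computational stages of a compact
invertebrate genome project as plain, testable functions. This vignette
records the models, parameter choices and numerical conventions behind
each stage, and what the synthetic-data generators do and do not
emulate.

## In-silico mate pairs and gap handling

A mate-pair library transfers long-range contiguity from a donor
assembly to a scaffolder without trusting the donor's base-level
accuracy. `make_mate_pairs()` tiles fixed-length fragments along each
donor sequence (1-based starts `1, 1+step, …` while the fragment fits)
and emits the two fragment ends as a read pair. For a donor of length
`L` this yields exactly `floor((L − insert)/step) + 1` pairs (before
N-filtering), which the tests assert against brute-force window
enumeration.

Tunables:

* `insert_sizes` (bp) — presets 2/5/10/15 kb for short-read donors and
  2/5/10/20/50/75/100 kb for long-read donors, the ladders used when
  scaffolding with libraries derived from alternative assemblies.
* `read_length` (default 100 bp) and `step` (default 500 bp) — the tools
  this stage feeds accept short reads; 100 bp mimics them, and a 500 bp
  step gives dense joins at desk scale. Neither value is canonical;
  both are configurable.
* `orientation` — `FR` (read2 reverse-complemented) or `RF` (read1
  reverse-complemented). Scaffolder library files declare orientation,
  so correctness reduces to emitting it consistently; the manifest line
  written by `write_mate_pair_libraries()` records it, with a default
  insert-size error fraction of 0.25.
* `max_n_fraction` (default 0.1) — pairs dominated by gap Ns carry no
  linking signal and are dropped (and counted).

`break_at_gaps()` splits scaffolds at runs of `N` strictly longer than
`max_gap` (default 5000 bp) and drops pieces shorter than
`min_piece_length` (default 200 bp). A run of exactly 5000 N is left
intact — the boundary is strict. Gaps are runs of `N` only; lowercase
soft-masking has no gap semantics here. The operation is idempotent and
conserves non-gap bases (pieces + dropped pieces + removed runs
reconstruct the input), both enforced by tests on randomized
assemblies. Whether the 200 bp floor applies to scaffolds or to reads
is ambiguous in common pipelines; `filter_min_length()` is generic and
the package applies it to assembly sequences by default.

## Assembly statistics

`compute_stats()` uses the cumulative-half N50 definition (always the
length of an actual sequence), counts GC as `100·(G+C)/(A+C+G+T)` —
gap `N`s excluded from the denominator, the sensible convention for
scaffolded assemblies — and reports bases in sequences ≥ 25 kb with an
inclusive cutoff. All reported percentages round half *up* (away from
zero), not half-even: `completeness_percent()` must reproduce printed
two-decimal scores deterministically, and `round_half_up()` is exposed
for the same reason. `gigabases()` rounds to one decimal.

## Missed-gene rescue

The rescue pipeline formalizes a simple argument: if an orthogroup
contains focal-species transcripts and outgroup proteins but no focal
gene model, the locus exists and the predictor missed it.

1. `find_candidates()` — focal model column empty, focal transcript
   column non-empty, at least one outgroup column non-empty.
2. `confirm_novel()` — a candidate transcript with a hit to an existing
   gene model at `evalue < 1e-6` (strict) is not novel
   (`rejected:has_model_hit`). A hit at exactly 1e-6 does not reject.
3. `extract_orfs()` / `longest_orf()` — six-frame scan; an ORF is a
   maximal stop-free codon run ending at a stop or the frame end,
   starting at the first `ATG` of the run, or (with
   `allow_partial = TRUE`, the default) at the frame start without
   `ATG`, in which case the model is flagged 5'-partial rather than
   coordinate-adjusted. Ties break by frame order
   `+1,+2,+3,−1,−2,−3`, then smaller forward-strand start. The floor is
   30 codons (configurable): a TransDecoder-like minimum that prevents
   spurious two-codon "genes" on random sequence. Note that under
   `allow_partial` a long partial run in any frame can out-rank a short
   complete `ATG…` ORF — `allow_partial = FALSE` restricts the scan to
   genuine start-codon ORFs.
4. `place_on_genome()` — only scaffold *identity* matters: a coding
   region hitting two distinct scaffolds is ambiguous
   (`rejected:multi_scaffold`), many HSPs on one scaffold are fine. How
   widely-separated same-scaffold HSPs should be treated is genuinely
   open; they are accepted here.
5. `emit_rescued_models()` — writes `gene`/`mRNA`/`CDS` features with
   ids `rescue.<orthogroup>`, mapping ORF coordinates through the
   best-scoring hit under a collinear ungapped alignment assumption.
   Spliced alignments are outside this writer's contract (the
   noise-free synthetic case satisfies it; real spliced placements
   would need an alignment-aware lift-over).

One coding region is emitted per candidate orthogroup (the longest ORF
over its transcripts); alternates are counted in the ledger. Statuses
partition candidates at every stage, so counts always reconcile — a
property test, not just a convention.

## Single-copy ortholog consolidation

Three evidence routes feed one final set:

* **direct** — orthogroups with exactly one member of each focal
  species (other species ignored), per clustering run;
  `union_runs()` unions runs and removes any gene seen with two
  distinct partners across runs (the conservative reading: the gene and
  *all* its pairs go).
* **tree** — `cherry_rescue()` scans rooted gene trees for strict
  cherries (internal nodes with exactly two leaf children) holding one
  gene of each focal species. Trees with fewer than 4 leaves are
  skipped by default, mirroring the build-trees-for-4-plus-gene
  orthogroups workflow. A clade that collapses to one gene per focal
  species only after pruning other species is *not* accepted by
  default — the strict cherry is the declared reading; relax
  `min_leaves` for the permissive variant. Genes in more than one
  distinct cherry pairing are ambiguous and dropped.
* **isoform** — `isoform_rescue()` collapses members through a
  transcript-to-locus map (default suffix pattern `\.(t|i)\d+$`) and
  accepts orthogroups that become one-locus-per-species. By default
  only orthogroups actually *blocked* by isoform expansion are emitted
  (`only_blocked = TRUE`); plain one-to-ones are the direct route's
  job, and the blocked-only reading matches what an isoform-rescue
  count means. Locus pairs conflicting across runs are discarded.

`finalize_orthologs()` unions the routes with precedence
`direct > tree > isoform` for provenance ordering; the same pair from
two routes merges, a gene with two different partners is removed
entirely and reported. The result is always a partial matching.

`midpoint_root()` places the root halfway along the longest
leaf-to-leaf path, computed from exact node distances; if the midpoint
falls exactly on an internal node the tree is rooted there, and ties
among equally longest paths break by the lexicographically smallest
sorted leaf-label pair. All-zero branch lengths cannot be
midpoint-rooted: the tree is rooted at its first internal node with a
warning. The implementation is checked against an independent
edge-list DFS oracle on thousands of random trees.

Leaf labels map to species by the prefix before the first underscore
(`Bo_g1`-style); a custom `species_of` function overrides this for
other label schemes. Unparseable labels are a hard error naming the
leaf.

## Chitinase motif scanning and classification

True chitinases and chitinase-like proteins share the Glyco_hydro_18
domain and chitin binding; only the former carry the chitin-degrading
catalytic site. `scan_motif()` searches peptides — or all six frames of
a genome — for `FDG[^*]?D[^*]D[^*]E`, with matches enumerated leftmost
non-overlapping and the optional residue matched greedily (the longer
variant wins at equal start; only reporting, not presence/absence,
depends on this choice). Codons containing `N` translate to `X`, which
fails literal positions but satisfies the `[^*]` classes;
`strict_x = TRUE` makes `X` fail the classes too. Genome-level hits
carry forward-strand coordinates spanning exactly `3 ×` the peptide
length, so translating the reported span reproduces the match — a
round-trip the tests enforce on both strands. Translation does not
splice: a motif interrupted by an intron in real genomic sequence is
missed, which is why protein-level scanning remains the primary route
and the genome scan is a safety net.

`reciprocal_best_hits()` takes bitscore as the "top hit" metric
(stable under database-size changes, unlike E-values), breaking ties by
smaller evalue then lexicographic subject id, with tie events counted.
`classify_chitinases()` then calls a protein `chitinase` if it is an
RBH to a true-chitinase query *and* carries the motif;
`chitinase_like` if it has a Glyco_hydro_18 domain at independent
E-value strictly below 0.05 but lacks the motif; otherwise `neither`.

## Conserved differential expression

A cross-species tissue marker should be strongly significant in one
species and at least nominally significant in the other:
`conserved_de()` requires the strict criterion (FDR ≤ 0.001 and
|log2FC| ≥ 2) in one species and the relaxed one (FDR ≤ 0.01) in the
other, in either role, with all thresholds inclusive. Fold-change signs
must agree by default — the biological claim is "higher in the same
tissue in both species" — with `require_direction = FALSE` available
for sensitivity analysis. Isoform-level rows are reduced to the
minimum-FDR row per gene before filtering. Tables carry a declared
contrast orientation; combining tables with different declared
orientations is a hard error rather than a silent sign flip.
`pca_input_matrix()` joins per-sample TPM tables over ortholog pairs as
`log2(TPM + 1)` for external ordination; the PCA itself is standard and
not re-implemented.

## Macrosynteny

`assign_scaffolds()` tests each (scaffold, chromosome) cell holding at
least `min_orthologs` (default 3 — no single-gene "blocks") with a
one-sided hypergeometric enrichment p-value from the cell against the
genome-wide margins, BH-corrected across all tested cells at
`alpha = 0.05`. A scaffold's primary chromosome is its most
ortholog-rich significant cell (ties: smaller q, then lexicographic
chromosome id, logged). The chromosome count is the number of distinct
primary chromosomes, and `flag_translocations()` reports scaffolds
whose secondary chromosome holds ≥ 5 orthologs, ≥ 10% of the
scaffold's total, in a cell that is itself significant.

Degenerate case: with a single reference chromosome every cell
saturates its margins and the enrichment p-value is identically 1, so
no assignment could ever be "significant". The package treats this as a
vacuous test — deterministic assignment with `NA` p-values — rather
than reporting an absurd non-assignment.

Two statistical properties worth noting because they shape sensible
problem sizes. First, permuting chromosome labels destroys all
significance in ≈ 99% of replicates at 26 scaffolds × 50 orthologs
(13 chromosomes); at very small tables (13 × 20) chance concentrations
survive BH a few percent of the time, so the null-destruction property
is asserted at the former scale. Second, a translocated block is only
detectable when it is *enriched given the margins*: with two scaffolds
per chromosome, an 8-gene block is statistically invisible (expected
count ≈ observed), whereas at 8 scaffolds per chromosome the same
block has p ≈ 5·10⁻⁵. Fixtures and the acceptance run use the finer
fragmentation.

Gene positions are midpoints (`(start + end)/2`); gene order within
scaffolds is deliberately ignored, as the assignment concerns content,
not collinearity. `dotplot_table()` lays sequences end to end in a
supplied order and emits cumulative-offset coordinates for an Oxford
dot plot.

## Synthetic data

The generators produce every input the pipeline consumes, with
ground-truth manifests, under a single local seed
(`with_seed()` restores the caller's RNG state, so generation never
perturbs other randomness).

`simulate_two_species_genomes()` builds a chromosome-level species B
and a fragmented species A sharing colinear one-to-one genes (defaults:
13 chromosomes — a typical ctenophore karyotype — 1300 genes of 900 bp
with 300 bp spacers, 4 scaffolds per chromosome). Species A scaffolds
carry one small N run each and, on a fraction of scaffolds, one run
strictly over 5 kb, exercising the gap-breaker. Linkage is respected
except for planted block translocations (a block of genes from another
chromosome appended to a scaffold) and uniform placement shuffling
(`shuffle_rate`, the 2% noise used in the chromosome-count
experiments). With `sequences = FALSE` only the layout is built, which
is what the placement-level experiments need and is much faster.

`simulate_orthogroups()` perturbs the true orthogroups: rescue targets
lose their focal protein model but keep a transcript with one planted
dominant ORF; isoform genes get `.t1/.t2` focal models; cherry genes
gain a blocking outgroup paralog plus a four-leaf gene tree whose only
focal/outgroup cherry is the planted pair; per-run mis-clustering moves
outgroup members between orthogroups, degrading recall across runs
without creating false pairs.

`simulate_de_tables()` plants conserved genes with log2FC from
Normal(±3, 0.5) and p-values from the lower tail of Beta(0.01, 1),
with nulls at Normal(0, 0.5) and Uniform(0, 1), and computes the FDR
column by BH within each table. The planted draws are truncated —
effects redrawn until they clear |log2FC| ≥ 2, p-values scaled into
the extreme tail (≤ 10⁻⁸) — so that planted genes clear the reporting
thresholds *by construction* and recovery tests are exact rather than
probabilistic. The null tail is untouched, so family-wise control is
still exercised (zero-planted runs return an empty conserved set in
≥ 95% of seeds).

`plant_motifs()` back-translates motif realizations with uniform codon
choice (no codon-usage model — adequate for scanner testing, not for
sequence realism) into non-overlapping genome positions on either
strand, recording exact spans and frames.

What the generators do **not** emulate: sequencing errors and read
data, real codon usage and base composition, spliced gene structures
(genes are contiguous), unequal gene spacing, assembly redundancy/
haplotigs, and count-level expression data (DE tables are emitted at
the statistic level). Passing tests therefore demonstrate the *logic*
of each stage — thresholds, joins, conservation laws, statistical
machinery — on data whose ground truth is known exactly, not
performance on noisy real data.

## Problem sizes and reproducibility

The test suite and acceptance script run at desk scale: oracle
equivalence on 1000 random instances per statistic (N50, longest ORF,
RBH, midpoint rooting, hypergeometric tail), pipeline recovery on
650–1300-gene layouts, and chromosome-count recovery over 20 seeded
replicates of a 5000-ortholog, 200-scaffold, 2%-noise simulation —
sizes chosen so the full suite completes in minutes on one core while
every statistical property still has comfortable power. All randomness
is seed-derived; `scripts/acceptance.R --seed N` is byte-reproducible.

## Known limitations

* Genome-level motif scanning does not splice across introns.
* `emit_rescued_models()` assumes collinear ungapped transcript-to-
  genome alignments; spliced placements need an external lift-over.
* Strict reciprocal best hits admit at most one partner per query, so
  a reference set with fewer queries than true family members cannot
  label them all; supply one query per expected member.
* The conserved-DE filter consumes externally computed DE statistics;
  it does not refit expression models.
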