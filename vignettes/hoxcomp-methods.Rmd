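---
title: "Comparative Hox-cluster analysis: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative Hox-cluster analysis: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoxcomp)
```

## What the package computes

`hoxcomp` implements the computational core of a comparative analysis of
vertebrate Hox gene clusters: which noncoding stretches are conserved across
deep vertebrate divergences (CNEs), how repeat-rich each cluster is, and
whether one lineage's sequences evolve measurably slower than another's.
Its stages are deliberately small and composable:

* windowed percent-identity scanning of pairwise global alignments and CNE
  calling at the classical cutoff (≥65% identity over ≥50 bp);
* classification of CNEs into phylogenetic depth groups (gnathostome,
  osteichthyan, sarcopterygian, tetrapod) by shared presence with diagnostic
  species;
* library-free discovery of direct and inverted repeat pairs by
  seed-and-extend self comparison, with repeat-density and hotspot
  statistics;
* Tajima's relative rate test (RRT) over gene batteries, synthesised into
  Hasse diagrams of "significantly slower than" orderings and genome-wide
  count matrices;
* terminal branch-length fold comparisons from externally estimated trees.

Every stage is testable end to end because the package ships its own
generator of multi-species cluster sequences with known ground truth.

## The synthetic-data generator

`simulate_clusters()` draws a root sequence uniformly over `{A,C,G,T}` and
evolves it along a fixed Newick tree under the Jukes–Cantor model. For a
branch of length $b$ (expected substitutions/site) the per-site probability
of observing a change is the JC transition probability
$\tfrac{3}{4}\left(1 - e^{-4b/3}\right)$, and `jc_expected_divergence()`
exposes the same closed form for the expected proportion of differing sites
along a path — the independent yardstick used by the tests.

Design choices, and why:

* **Jukes–Cantor only.** The downstream analyses consume identities and
  substitution counts, not model fits; JC gives closed forms the acceptance
  checks can be scored against.
* **Lineage rates are terminal-branch multipliers.** `rate_multipliers`
  scale the tip-side branch of each named species; internal branches evolve
  at the base rate. This is the conventional reading of lineage-specific
  rates and keeps the mapping species → rate unambiguous.
* **Site classes.** Sites inside a planted CNE evolve at
  `conservation_scaling` times the branch length (smaller = more
  conserved); exon sites evolve at 0.1, the strong-constraint floor of the
  CNE scaling range.
* **CNE loss is replacement, not deletion.** A species outside a CNE's
  `retained_in` set has that interval overwritten with fresh random
  sequence. Coordinates therefore stay comparable across species, which
  keeps ground-truth bookkeeping exact; it is a simplification (real loss
  is often deletional).
* **Repeats are planted per species, after tree simulation, in place.**
  Planting overwrites the target window (the sequence keeps its length),
  again to keep coordinates stable. The second arm of an inverted repeat is
  the reverse complement of the first before any per-copy mutation.
* **Planted repeats are made locally maximal.** An ungapped finder reports
  the maximal-scoring span on a diagonal, so a planted arm flanked by a
  lucky matching base would legitimately be reported one base longer. The
  planting functions therefore resample the few flanking/spacer bases whose
  diagonal partner would extend the match. This is what makes "the planted
  coordinates are the truth" literally true, and noise-free recovery exact
  rather than exact-up-to-boundary-luck.
* **Background divergence default.** The stock test configurations use
  0.75 substitutions/site per branch (≈35% aligned background identity,
  the saturation regime of gnathostome-depth noncoding comparisons). At
  materially shallower divergence (≈45% identity) a 50-bp/65% window scan
  starts to pass by chance at a rate of tens of clusters per 100 kb, which
  would say more about the scan's null behaviour than about recovery; the
  chosen default keeps the expected chance rate below one call per 100 kb.

What the generator does **not** emulate: insertions/deletions along the
tree (so synthetic alignments are positional), GC and rate heterogeneity
along the sequence beyond the three site classes, transposon family
structure, and alignment uncertainty. Passing recovery tests therefore
demonstrate correctness of the scanning and calling logic under the stated
model — not robustness to alignment error in real data.

## CNE calling

`call_cnes()` uses a seed–merge–trim procedure as the normative definition
of a CNE call (the peak-extension behaviour of interactive conservation
browsers is not published, so the package fixes a reproducible one):

1. every window of `min_length` alignment columns with ≥ `min_identity`
   percent matching columns is a seed (gap and `N` columns count as
   mismatches — the conservative reading of "no gaps");
2. overlapping passing windows are merged into column intervals;
3. each interval is trimmed so it starts and ends on matching columns;
4. an interval is kept when it still spans ≥ `min_length` *reference
   bases* and its overall column identity is ≥ `min_identity`;
5. intervals overlapping the coding mask are cut to their noncoding
   remainder, re-trimmed, and re-checked against both thresholds.

Lengths are measured in reference bases while identity is measured over
alignment columns; with positional (indel-free) alignments the two
coincide. CNEs lying inside a gene span but outside exons are flagged
intronic. Cross-species correspondence (`match_cnes()`) uses ≥1 bp overlap
after projecting through the alignment, deliberately permissive because
long elements in one species often break into several shorter ones in
another. Classification assigns each CNE the deepest clade (gnathostome >
osteichthyan > sarcopterygian) whose diagnostic species overlaps it by
≥1 bp; everything else falls through to tetrapod, and an element claimed by
one group is never recounted by a shallower one.

## Repeat discovery

`find_repeat_pairs()` finds ungapped arm pairs by exact 12-mer seeding
(direct: sequence vs itself; inverted: sequence vs its reverse complement),
skipping seeds with ≤2 distinct bases to suppress homopolymer and
dinucleotide artifacts. Extension explores along the diagonal while the
running identity of the grown span stays above `min_arm_identity − 5`
percentage points, and the reported arm is the maximal-scoring span
(match +1, mismatch −1, first maximum kept) — the standard ungapped-HSP
trim. Arms never overlap (`spacer ≥ 0`), pairs are deduplicated and
mirror-duplicates removed, and overlapping same-orientation pairs are
merged keeping the longer arm. Explicit `min_arm_length`/`min_arm_identity`
thresholds replace e-value cutoffs, which depend on database size and are
not reproducible in a self-contained tool; "long" inverted repeats are
those with arms strictly longer than 100 bp. Density statistics use union
semantics (overlapping hits count once) and can be restricted to retained
regions, excluding e.g. windows homologous to assembly gaps.

## Relative rate testing

For two ingroups $A$, $B$ and an outgroup $O$, after complete deletion of
columns containing gaps or ambiguity symbols (`N` for nucleotide;
`X/B/Z/J` for protein), `tajima_rrt()` counts $m_A$ (sites where only $A$
differs, i.e. $B = O \neq A$) and $m_B$ (symmetrically). Under rate
constancy $E[m_A] = E[m_B]$ and

$$\chi^2 = \frac{(m_A - m_B)^2}{m_A + m_B} \sim \chi^2_1,$$

with no continuity correction, as in the original formulation. When
$m_A + m_B = 0$ the gene is uninformative and $p = 1$ rather than an error,
so short conserved genes do not abort a battery. Significance is tiered at
$p \le 0.01$ ("high", drawn solid) and $0.01 < p \le 0.05$ ("significant",
drawn dashed). Raw p-values are used at those fixed tiers — no
multiple-testing correction — because the per-gene tier counts *are* the
reported quantity, not a family-wise claim. Protein and nucleotide modes
share one code path; only the ambiguity alphabet differs. Gene alignments
are consumed pre-aligned; column stripping is applied per triplet, so
different species pairs of the same gene may retain different columns.

`build_hasse()` turns one gene's pairwise results into a partial order:
an edge runs faster → slower for each result at $p \le 0.05$ (the lineage
with fewer unique substitutions is the slower one), non-significant pairs
stay incomparable, and the displayed edge set is the transitive reduction.
A two-node contradiction is impossible by construction (each pair yields a
single directed result); a cycle through three or more pairwise results is
logically possible though rarely observed, and is resolved by dropping the
weakest (largest-p) edges with a warning until the order is acyclic.
`genome_matrix()` tallies, for a three-ingroup design, how many genes place
each species significantly slower or faster than each other species at each
tier, plus the derived percentages (slower than at least one, slower than
both) that summarise genome-wide rate asymmetry.

## Branch-length folds

`branch_fold()` compares *terminal* branch lengths by default: the quoted
per-lineage comparisons are tip-branch figures, so the tip-branch reading
is the package's convention, with root-to-tip path sums available via
`from_root = TRUE`. Ratios are rounded half-up (so 0.34/0.13 prints as
2.6), matching how such folds are conventionally reported; note that base
R's `round()` rounds half to even, which is why the package carries its own
rounding helper.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GFF3's 1-based
  closed convention is converted at the parsing boundary, BED passes
  through. One convention internally prevents off-by-one drift.
* Non-ACGTN characters in sequence input become `N` with a warning
  (deposited records contain IUPAC ambiguity codes); `N` never matches
  anything in any scan.
* `global_align()` scores a length-$k$ gap as `gap_open + (k−1) ·
  gap_extend` and caps inputs at 50 kb (quadratic dynamic programming);
  the traceback is deterministic.
* Sequences shorter than two minimum arms yield an empty repeat table with
  a warning, not an error; empty CNE output is likewise legal.
* All simulation randomness flows from explicit integer seeds; identical
  seeds give byte-identical output, and `run_pipeline()` derives per-stage
  seeds from one master seed and stamps every output table with a config
  hash so re-runs are byte-identical.

## Problem sizes used by the test suite

The suite exercises the stages at sizes chosen to make the statistical
checks sharp while staying desk-scale: CNE recovery on 100 replicate
20-kb two-species clusters with four planted elements each (recovery and
false-call rates over 2 Mb of background); RRT size on 1,000 null genes of
1,000 sites (the exact binomial 95% band for a 5% test is
[0.037, 0.064]) and power on 100 genes per rate ratio; repeat-finder
equivalence against an exhaustive per-diagonal oracle on fifty ≤2-kb
sequences; transitive reduction verified against an independent
reachability oracle on all 543 labeled 4-node DAGs and all 29,281 labeled
5-node DAGs.

## Known limitations

* The in-repo aligner is quadratic; cluster-scale (>50 kb) comparisons
  should use positional alignments (indel-free simulations) or external
  alignments supplied as aligned FASTA.
* Repeat arms are ungapped by design; a tandem pair whose arms have
  accumulated indels relative to each other will be reported as shorter
  split pairs.
* CNE calling is pairwise; multi-species simultaneous conservation is
  composed from pairwise calls against one reference rather than estimated
  jointly.
* The RRT assumes the outgroup is a genuine outgroup and sites are
  independent; within-gene rate correlation inflates neither count
  asymmetry nor the chi-square calibration in the JC simulations used
  here, but may in real data.
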