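---
title: "Designing and simulating CRISPR-Cas9 repeat depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating CRISPR-Cas9 repeat depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatclean)
library(dplyr)
```

## The method

In a genome dominated by repetitive DNA, most whole-genome sequencing reads
land on repeats and contribute nothing to genotyping. Repeat depletion
attacks this before sequencing: a large pool of Cas9 ribonucleoproteins, each
programmed by a 20-nt guide against an abundant repeat, cuts library
fragments that contain repeat sequence. A cut fragment loses one of its two
adapters and cannot amplify, so the sequenced library shifts its reads from
repeats to single-copy DNA — genes, regulatory regions, and unique sequence —
where depth then crosses the genotypability threshold at a fraction of the
sequencing cost.

`repeatclean` covers the design of such a guide set, a simulator for the
depletion reaction, and the evaluation metrics used to judge it. This
vignette records the model, the tunable parameters, and the design choices
made where the procedure leaves freedom.

## Coordinates and the cut site

All intervals are 0-based, half-open, on every module boundary; GFF3 input is
converted on read. One convention everywhere removes off-by-one drift between
the scanner, the selector, the footprint and the simulator.

A guide's cleavage site is the blunt double-strand break between protospacer
positions 17 and 18, i.e. 3 bp 5′ of the NGG PAM — the standard SpCas9 cut.
We store it as the single base coordinate immediately 3′ of the break on the
plus strand. A candidate belongs to a target interval when its **cut
position** lies inside the interval, not when the protospacer merely overlaps
it: cutting, not binding, is what depletes a fragment.

Softmasked (lowercase) genome sequence is kept as a mask but deliberately
**not** treated as repeat annotation; targets come only from explicit
interval files, which is how the design is meant to be driven. Windows
containing N are skipped — a guide cannot be validated against ambiguous
bases.

## Guide discovery

`scan_pam_sites()` enumerates every 20-mer with an adjacent NGG on both
strands of the merged target intervals, deduplicating by protospacer: a
synthesized gRNA is one molecule no matter how many sites it hits.
`count_on_target_sites()` then locates all exact protospacer+NGG matches
genome-wide (the same single pass that enumerated windows, joined by
sequence) and splits them into on-target sites (cut inside a target interval)
and off-interval exact matches. Only on-target sites count toward the
selection threshold; whether the original design counted genome-wide or
in-target sites is unstated, and counting in-target is the conservative
reading (off-interval matches are still reported). Repeat-interval strand is
ignored: guides are found on both genome strands regardless.

## The filter cascade

Sequence-quality thresholds are free parameters of the method, so the defaults are ordinary
gRNA-design practice, all configurable through `filter_config()`:

| parameter | default | meaning |
|---|---|---|
| `gc_min`, `gc_max` | 0.25, 0.75 | admissible GC fraction |
| `max_homopolymer` | 4 | longest single-base run allowed |
| `max_dinucleotide_repeat` | 4 | most AB-unit repetitions allowed (ATATAT = 3) |
| `max_hairpin_stem` | 6 | guide fails at a self-complementary stem ≥ 6 bp (loop ≥ 3 nt) |
| `efficiency_min` | 0.2 | minimum predicted cleavage score |
| `offtarget_max_mismatches` | 3 | Hamming tolerance of the protected-region screen |

The pipeline is threshold-robust by construction: tightening any threshold
can only shrink the survivor set (a property the tests assert), so these
defaults gate rather than tune the design.

The hairpin statistic is the longest pair of non-overlapping substrings where
the 3′ one is the reverse complement of the 5′ one with a loop of ≥ 3 nt,
computed by dynamic programming over complementary position pairs and checked
in tests against an exhaustive enumeration.

Efficiency scoring is a pluggable interface. A trained model of in vitro
cleavage efficiency is a regression over thousands of measured guides and is
out of scope here; the default `efficiency_score()` is an explicit heuristic —
a GC-optimum bonus peaking at 50% GC plus a weight on the PAM-proximal base
(G rewarded, T penalized) — bounded in [0.15, 0.85], deterministic, and
provably monotone for the position-20 T→G change. Any
`function(protospacer, context)` returning values in [0, 1] can replace it.
Guides whose 30-nt scoring context is truncated by a contig edge receive the
neutral score 0.5 and a flag.

## Off-target exclusion

A guide is excluded if it has any complementary site within 3 mismatches in a
protected region (genes plus ATAC open chromatin). Two decisions:

* **A functional PAM is required** at the putative off-target (NGG adjacent),
  matching Cas9 biochemistry; `pam_free_offtarget = TRUE` switches to the
  stricter reading where any complementary 20-mer counts.
* **Membership is by any overlap** of the 23-mer with a protected interval —
  conservative protection of functional regions, in contrast to the
  cut-position rule used for targeting.

The batched search is exact by pigeonhole: the 20-mer is split into four
disjoint 5-nt bands; any hit with ≤ 3 mismatches is mismatch-free in at least
one band, so four banded dictionary scans (mismatches allowed outside the
band) united over bands recover exactly the naive Hamming hit set. Tests
verify equality with a brute-force mismatch scan, exhaustively over all
guides scanned from a 50-kb random genome.

## Selection, pools, groups, dosing

The method constrains every guide to keep **no fewer than 25 cleavage
sites** and accepted sites to maintain **≥ 500 bp spacing**, without fixing
the algorithm that achieves them. We use a deterministic greedy
procedure: visit passing guides by descending on-target site count
(lexicographic protospacer tie-break); for each, discard sites within 500 bp
of any already-accepted site, thin the rest left-to-right (which yields the
maximum spaced subset within the guide), and accept the guide iff ≥ 25 sites
remain — with exactly those sites. Spacing is enforced between accepted sites
genome-wide, since the constraint's purpose is cut-site distribution, and the
whole selection is seed-free and reproducible.

Pools (11 by default) bin guides by cutting frequency into near-equal sizes
(differing by ≤ 1, remainders to the lowest pools — so 5 guides over 11 pools
occupy pools 1–5 singly); pool 1 holds the lowest frequencies. Sequential
groups (3 by default) are contiguous pool blocks used in order of increasing
cutting frequency, the empirically better order. Dosing gives each guide
mass ∝ its cleavage-site count, totalling 620 ng (1240 ng for the double
protocol), with Cas9 volume 0.0029 µL per ng of gRNA (1:2.5 protein:gRNA).

## Targetable footprint

"Targetable at insert length L" is formalized as: a position is targetable
iff every possible fragment of length L covering it contains a cleavage site
— equivalently, iff its maximal cut-free run of positions is shorter than L
(cut positions themselves are always targetable). This formalization is the package's own, and
tests pin it to an exhaustive fragment enumeration. Note a consequence of the
spacing constraint: with ≥ 500 bp between accepted sites and 500-bp inserts,
inter-site gaps hover at the boundary of this strict rule, so the strict
footprint of a spaced design is small even where depletion is still likely —
the rule asks that *no* fragment can escape, not that most are cut.

## The synthetic genome

`synthetic_genome_spec()` defaults describe a ~200-kb nuclear contig that is
~72% repetitive — three LTR/LINE-like families of 50–70 copies, consensus
lengths 400–1200 bp, per-copy i.i.d. divergence of 2–5% — plus 20 genes
(~1 kb), 30 open-chromatin peaks (300 bp), and 20/30-kb chloroplast and
mitochondrial contigs. Features are placed without overlap (repeats never
touch genes or peaks, as the real design excludes repeats overlapping
functional regions) in random order, with the single-copy filler distributed
as random gaps, so the planted composition is exact by construction and
generation is deterministic given the seed. Organelle sampling weights
default to 0.05/0.03, giving organelles ~1% of library reads: because the
organelle contigs here are proportionally far larger relative to the nuclear
contig than in a real plant genome, per-base weights below 1 are what
reproduce a realistic organelle read share (in a full-size genome the same
share requires weights far above 1). Multi-copy behaviour is modelled by the
weight, not by literal repeated sequence.

What the generator does **not** emulate: nested/truncated repeat copies,
indels within copies (divergence is substitution-only), GC bias, PCR
duplication, or mapping error (read placements are truth). Passing tests
therefore show the pipeline's logic is correct under the stated model — not
that a particular wet-lab depletion efficiency will be achieved. One
structural artefact matters when interpreting simulations: the single-copy
filler between features is fragmented into short gaps, so fragments whose
midpoint is single-copy often extend into flanking repeats; under aggressive
cutting, single-copy positions hugging repeat boundaries lose coverage. Real
genomes hold their single-copy DNA in much longer blocks.

## The simulator

Fragments are uniform over contigs weighted by length × weight, with normal
insert lengths (mean 500 bp, sd 15%, truncated to [100, 2 × mean]). Each
contained cleavage site is cut independently with probability `p_cut`, so a
fragment with k sites survives with `(1 − p_cut)^k`; with `p_cut = 1`
survival is exactly "contains no site". There is no cooperative cutting —
the simplest model consistent with the adapter-loss mechanism — but
`cut_model(density_boost =)` lets the effective per-site probability depend
on local site density to emulate the observed density dependence.
`sample_reads()` draws equal read counts for the depleted (survivors only)
and non-depleted conditions, normalizing to the same sequencing input.
Every operation is deterministic under its seed.

## Evaluation

* **Variation of mapped reads** = `(depleted − nondepleted) / nondepleted`,
  per class per sample (means across samples reported; per-sample averaging
  is the variance-honest choice over pooling counts).
* **Read classes** are assigned by fragment midpoint against the *repeat*
  intervals only. Nuclear placements outside repeats are `single_copy` —
  which by definition includes genes and regulatory DNA, everything outside
  the gRNA targets. The midpoint rule gives every placement exactly one
  class, so counts conserve.
* **log2 coverage variation** = `log2(mean_dep / mean_nondep)` per repeat
  region; regions with zero coverage in either condition are excluded and
  booked as zero-in-depleted, zero-in-nondepleted, zero-in-both, with
  excluded fraction `(zd + zn − zboth) / total`. Exclusion bookkeeping always
  satisfies excluded + retained = total.
* **Genotypability**: PASS positions are single-copy positions at depth ≥ 5
  (inclusive); intersections of PASS sets across samples give the
  common-position counts.
* **Heterozygote detection** is modelled as
  `P(alt ≥ min_alt | Binomial(depth, allele fraction))` with defaults 0.5 and
  2 — the allelic-imbalance mechanism behind low-coverage false negatives.
  Real variant calling (haplotype assembly, base qualities, filters) is
  deliberately replaced by this depth model; the package evaluates coverage
  redistribution, not caller behaviour. `het_recovery_gain()` averages the
  detection probability over *all* single-copy positions of each condition,
  so it can sit below 1 when depletion leaves zero-coverage pockets even
  while the PASS-position gain is large.
* **Density relation**: per-region cleavage sites per kbp against log2
  variation — Pearson correlation plus the fraction of regions with a read
  reduction above and below the 8 sites/kbp threshold. With constant density
  the correlation is undefined and reported as missing.
* SAM/BAM placements can be ingested with `read_placements_sam()`, which
  keeps primary alignments only (drops flag-2308 records) so multimapping
  reads are counted once.

## Problem sizes and numerical choices

The test and acceptance runs use sizes a laptop handles in seconds to a few
minutes: the full design runs on the ~200-kb seeded genome; oracle
equivalences run exhaustively on 50-kb (off-target), 10-kb (PAM scan and
footprint) genomes; simulation checks use 10^5 sampled reads and 3-standard-
error tolerances; closed-form identities are exact. Ties are always broken
lexicographically by protospacer so no result depends on hash or sort
instability. Degenerate inputs are defined, not errors, wherever a valid
empty answer exists: an empty design (no guide reaches 25 sites) is a warning
plus an empty object; zero non-depleted counts make the variation undefined
(missing), as does constant density for the correlation.

## Known limitations

* The efficiency scorer is a stated heuristic, not a trained model; designs
  meant for synthesis should swap in an external scorer.
* The strict footprint rule interacts with the spacing constraint (above);
  treat the footprint as a lower bound on depletable territory.
* Divergence is substitution-only; repeat families with frequent indels will
  yield fewer exact-match sites than the generator suggests.
* At the default desk scale only a handful of guides satisfy 25 sites ×
  500 bp spacing, so simulated depletion with *designed* guides is weak
  (~1 site/kbp, below the 8/kbp regime); the simulator accepts arbitrary cut
  sets to explore denser designs.
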