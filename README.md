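# repeatclean

Sequencing-based genotyping wastes most of its reads in species whose genomes
are dominated by repetitive DNA: in a large plant genome that is >80%
transposable elements, the informative single-copy fraction (genes, regulatory
and unique DNA) receives only a sliver of the coverage. One countermeasure is
CRISPR-Cas9 repeat depletion: a genome-scale pool of guide RNAs programs Cas9
to cut library fragments that carry repeats, cut fragments lose an adapter and
fail amplification, and the surviving library concentrates its reads on
single-copy DNA — raising the number of genotypable positions and rescuing
heterozygous calls that low coverage would otherwise miss.

`repeatclean` implements that method end to end as an R package:

* **Guide design.** Enumerate every 20-nt protospacer with an NGG PAM on
  either strand of the target (repeat) intervals; count genome-wide exact
  cleavage sites (blunt cut 3 bp 5′ of the PAM); filter on GC content,
  homopolymers, dinucleotide repeats, hairpin stems and a pluggable
  efficiency score; exclude guides with complementary sites (up to 3
  mismatches, NGG-adjacent) in protected regions (genes and ATAC-seq open
  chromatin); then greedily select guides so each keeps ≥ 25 cleavage sites
  with ≥ 500 bp between accepted sites, assign 11 cutting-frequency pools and
  3 sequential reaction groups, and dose each guide ∝ its site count
  (620 ng total, 0.0029 µL Cas9 per ng).
* **Synthetic genomes.** A generator plants diverged repeat families, genes,
  open-chromatin peaks and organelle contigs with ground-truth annotation, so
  the whole pipeline runs without any download.
* **Depletion simulation.** Random-primed multiplex libraries, per-site
  independent cutting (fragment survival `(1 − p_cut)^k`), and read sampling
  normalized to a common input.
* **Evaluation.** The depletion and genotyping metrics: variation of mapped reads
  `(dep − nondep) / nondep` per repeat class, per-region
  `log2(mean coverage ratio)` with zero-coverage exclusion bookkeeping,
  PASS positions at depth ≥ 5 in single-copy regions, intersections across
  samples, the binomial model of heterozygote detection
  `P(alt ≥ k | Binom(depth, 0.5))`, and the gRNA-density/depletion relation.

Everything is tidyverse-native: interval sets, candidates, verdicts, cut
sites, fragments, placements and reports are tibbles; fitted objects have
`tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(repeatclean)
library(dplyr)

syn <- generate_genome(synthetic_genome_spec(seed = 42))
targets   <- filter(syn$annotation, !class_label %in% c("gene", "atac_peak"))
protected <- filter(syn$annotation,  class_label %in% c("gene", "atac_peak"))

design <- design_guides(syn$genome, targets, protected)
design
#> <guide_design> 3 guide(s), 127 accepted cleavage site(s)
#>   constraints: >= 25 sites/guide, >= 500 bp spacing
#>   dosing: 620 ng gRNA, 1.798 uL Cas9 (1:2.5 protein/gRNA)
glance(design)
#>   n_candidates n_guides n_sites min_accepted_sites min_spacing_bp total_ng cas9_ul
#> 1         9126        3     127                 37            517      620    1.80
```

From 9126 candidate protospacers in ~144 kb of planted repeats, three guides
survive the filter cascade *and* keep ≥ 25 exactly matching cleavage sites at
≥ 500 bp spacing — every selected guide here exceeds both design constraints
(minimum 37 sites, minimum gap 517 bp). At this desk scale the accepted-site
density (~0.9 sites/kbp) sits far below the > 8 gRNAs/kbp regime where
depletion becomes reliable, so to demonstrate the downstream machinery we
plant a dense cut-site set (1 site/100 bp, i.e. 10 sites/kbp) in the same
repeats and simulate:

```r
dense <- purrr::list_rbind(purrr::map(seq_len(nrow(targets)), function(i)
  tibble(contig = targets$contig[i],
         cut = as.integer(seq(targets$start[i] + 20, targets$end[i] - 1, by = 100)))))

frags <- simulate_library(syn$genome, 2e5, n_samples = 3,
                          weights = syn$weights, seed = 7)
dep <- apply_depletion(frags, dense, cut_model(p_cut = 0.9), seed = 8)
placements <- bind_rows(sample_reads(dep,   1e5, "depleted",    seed = 9),
                        sample_reads(frags, 1e5, "nondepleted", seed = 10))
report <- evaluate_depletion(placements, syn$annotation, syn$genome, sites = dense)
report$class_variation
#>   class_label   mean_variation n_samples
#> 1 LINE                  -0.997         3
#> 2 LTR_Copia             -0.997         3
#> 3 LTR_Gypsy             -0.997         3
#> 4 chloroplast            7.15          3
#> 5 mitochondrial          6.97          3
#> 6 single_copy            2.34          3
#> 7 total_repeats         -0.997         3
```

Reads mapping to repeats drop by 99.7% while single-copy reads rise 2.3-fold
at the same sequencing input (organelles, untargeted in this run and ~1% of
the library, are enriched too). At a low-coverage input (1000 reads per
sample), the depleted condition genotypes ~5.4× more single-copy positions
(PASS at depth ≥ 5), with 26,986 PASS positions common to all three depleted
samples against 25 in the non-depleted ones:

```r
low <- bind_rows(sample_reads(dep,   3000, "depleted",    seed = 9),
                 sample_reads(frags, 3000, "nondepleted", seed = 10))
glance(evaluate_depletion(low, syn$annotation, syn$genome))$genotypability_gain
#> [1] 5.43
```

`autoplot(design)`, `autoplot(report)` and `plot_density_depletion(report)`
give the standard figures.

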