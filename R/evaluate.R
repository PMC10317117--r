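#' Count read placements by repeat class
#'
#' Each placement is assigned to the repeat class of the interval containing
#' its midpoint (`floor((start + end) / 2)`); ties between overlapping
#' classes go to the interval that starts first. Nuclear placements whose
#' midpoint falls in no repeat interval are `single_copy` — by definition all
#' nuclear DNA outside the repeat targets, so genes and open chromatin count
#' as single copy. Placements on organelle contigs outside any interval get
#' their compartment name. A `total_repeats` roll-up sums the repeat classes.
#'
#' @param placements tibble (`contig`, `start`, `end`, `sample_id`,
#'   `condition`).
#' @param annotation interval tibble with `class_label`; non-repeat classes
#'   (`gene`, `atac_peak` by default) are ignored for classification.
#' @param genome a [genome_seq()] object (for compartments and bounds).
#' @param repeat_classes the classes used for midpoint assignment and summed
#'   into `total_repeats`; default all annotation classes except `gene` and
#'   `atac_peak`.
#' @return Tibble of counts per (`condition`, `sample_id`, `class_label`),
#'   including `total_repeats` rows.
#' @export
count_reads_by_class <- function(placements, annotation, genome,
                                 repeat_classes = NULL) {
  lens <- contig_lengths(genome)
  if (any(!placements$contig %in% names(lens))) {
    abort("placement on contig absent from genome")
  }
  if (any(placements$start < 0 | placements$end > lens[placements$contig])) {
    abort("placement outside contig bounds")
  }
  repeat_classes <- repeat_classes %||%
    setdiff(unique(annotation$class_label), c("gene", "atac_peak"))
  annotation <- annotation[annotation$class_label %in% repeat_classes, ]
  mid <- (placements$start + placements$end) %/% 2L
  cls <- rep(NA_character_, nrow(placements))
  for (ctg in unique(placements$contig)) {
    sub <- annotation[annotation$contig == ctg, ]
    sel <- which(placements$contig == ctg)
    if (nrow(sub) == 0) next
    sub <- arrange(sub, .data$start)
    ir <- IRanges::IRanges(sub$start + 1L, sub$end)
    q <- IRanges::IRanges(mid[sel] + 1L, width = 1L)
    hit <- IRanges::findOverlaps(q, ir, select = "first")
    cls[sel[!is.na(hit)]] <- sub$class_label[hit[!is.na(hit)]]
  }
  comp <- genome$compartment[placements$contig]
  cls[is.na(cls) & comp == "nuclear"] <- "single_copy"
  cls[is.na(cls)] <- unname(comp[is.na(cls)])
  counts <- tibble(condition = placements$condition,
                   sample_id = placements$sample_id,
                   class_label = cls) |>
    count(.data$condition, .data$sample_id, .data$class_label,
          name = "reads")
  totals <- counts |>
    filter(.data$class_label %in% repeat_classes) |>
    group_by(.data$condition, .data$sample_id) |>
    summarise(class_label = "total_repeats", reads = sum(.data$reads),
              .groups = "drop")
  bind_rows(counts, totals) |>
    arrange(.data$condition, .data$sample_id, .data$class_label)
}

#' Variation of mapped reads after depletion
#'
#' `(depleted - nondepleted) / nondepleted`: the signed fractional change in
#' primary-placement counts, so -0.40 is a 40% depletion and +1.60 a 160%
#' increase. Undefined (NA) when the non-depleted count is zero.
#'
#' @param depleted,nondepleted numeric vectors of read counts.
#' @return Numeric vector of signed fractions.
#' @export
variation_of_mapped_reads <- function(depleted, nondepleted) {
  ifelse(nondepleted > 0, (depleted - nondepleted) / nondepleted, NA_real_)
}

#' Log2 coverage variation per region, with zero-coverage exclusions
#'
#' For each region with positive mean coverage in both conditions, computes
#' `log2(mean_depleted / mean_nondepleted)`. Regions with zero coverage in
#' either condition are excluded and booked: counts of zero-in-depleted,
#' zero-in-nondepleted, zero-in-both, and the excluded fraction
#' `(zd + zn - zboth) / total`.
#'
#' @param track tibble with per-region `mean_cov_depleted` and
#'   `mean_cov_nondepleted` (any id columns are carried through).
#' @return List with `values` (retained regions + `log2_variation`) and
#'   `exclusions` (one-row tibble: `total`, `zero_depleted`,
#'   `zero_nondepleted`, `zero_both`, `excluded`, `excluded_fraction`).
#' @export
log2_coverage_variation <- function(track) {
  zd <- track$mean_cov_depleted == 0
  zn <- track$mean_cov_nondepleted == 0
  keep <- !zd & !zn
  values <- track[keep, ] |>
    mutate(log2_variation = log2(.data$mean_cov_depleted /
                                   .data$mean_cov_nondepleted))
  exclusions <- tibble(
    total = nrow(track),
    zero_depleted = sum(zd),
    zero_nondepleted = sum(zn),
    zero_both = sum(zd & zn),
    excluded = sum(!keep),
    excluded_fraction = sum(!keep) / nrow(track)
  )
  list(values = values, exclusions = exclusions)
}

#' Positions genotypable at a depth threshold
#'
#' Counts positions whose sequencing depth reaches the PASS threshold
#' (default >= 5 reads).
#'
#' @param depths integer vector of per-position depths.
#' @param min_depth inclusive depth threshold (default 5).
#' @return Count of PASS positions.
#' @export
genotypable_positions <- function(depths, min_depth = 5L) {
  sum(depths >= min_depth)
}

#' Genotyped positions common to all samples
#'
#' @param position_sets list (>= 2 elements) of PASS-position identifiers
#'   (any vector type).
#' @return Size of the intersection.
#' @export
common_genotyped_positions <- function(position_sets) {
  stopifnot(length(position_sets) >= 2)
  length(Reduce(intersect, position_sets))
}

#' Heterozygote detection probability at a given depth
#'
#' Probability that at least `min_alt_reads` reads carry the alternate allele
#' when `depth` reads sample the two alleles binomially with alternate-allele
#' fraction `allele_fraction` — the allelic-imbalance mechanism by which low
#' coverage turns heterozygous sites into false-negative reference calls.
#'
#' @param depth integer vector of depths (>= 0).
#' @param allele_fraction alternate-allele sampling probability (default 0.5).
#' @param min_alt_reads minimum alternate reads for a call (default 2).
#' @return `P(alt >= min_alt_reads | Binomial(depth, allele_fraction))`.
#' @export
het_detection_probability <- function(depth, allele_fraction = 0.5,
                                      min_alt_reads = 2L) {
  stopifnot(all(depth >= 0))
  pbinom(min_alt_reads - 1L, size = depth, prob = allele_fraction,
         lower.tail = FALSE)
}

#' Expected heterozygote-recovery gain between two depth distributions
#'
#' Averages the per-position detection probability over each condition's
#' depth vector and reports the expected gain of the depleted condition.
#'
#' @param depths_depleted,depths_nondepleted integer depth vectors over the
#'   same positions (single-copy regions).
#' @inheritParams het_detection_probability
#' @return One-row tibble: `expected_depleted`, `expected_nondepleted`,
#'   `gain` (ratio, NA when the non-depleted expectation is 0).
#' @export
het_recovery_gain <- function(depths_depleted, depths_nondepleted,
                              allele_fraction = 0.5, min_alt_reads = 2L) {
  ed <- mean(het_detection_probability(depths_depleted, allele_fraction,
                                       min_alt_reads))
  en <- mean(het_detection_probability(depths_nondepleted, allele_fraction,
                                       min_alt_reads))
  tibble(expected_depleted = ed, expected_nondepleted = en,
         gain = ifelse(en > 0, ed / en, NA_real_))
}

#' Relate gRNA density to depletion per region
#'
#' @param table tibble with `density` (cleavage sites per kbp) and
#'   `log2_variation` per region.
#' @param threshold density threshold in gRNAs/kbp (default 8): regions above
#'   it are expected to show a read reduction in most cases.
#' @return One-row tibble: Pearson `correlation` (NA when density is
#'   constant), `fraction_reduced_above` and `fraction_reduced_below` (share
#'   of regions with `log2_variation < 0` with density `> threshold` and
#'   `<= threshold`), and the region counts on each side.
#' @export
density_vs_depletion <- function(table, threshold = 8) {
  tab <- filter(table, !is.na(.data$log2_variation), !is.na(.data$density))
  if (nrow(tab) == 0) abort("no usable regions after exclusions")
  corr <- if (length(unique(tab$density)) < 2 ||
              length(unique(tab$log2_variation)) < 2) {
    NA_real_
  } else {
    cor(tab$density, tab$log2_variation, method = "pearson")
  }
  above <- tab$density > threshold
  frac <- function(x) if (length(x)) mean(x < 0) else NA_real_
  tibble(correlation = corr,
         fraction_reduced_above = frac(tab$log2_variation[above]),
         fraction_reduced_below = frac(tab$log2_variation[!above]),
         n_above = sum(above), n_below = sum(!above))
}

#' Per-region mean coverage and per-position depths from placements
#'
#' `region_mean_coverage()` computes, per region, the mean per-base depth
#' contributed by the placements (sum of overlap bases / region length).
#' `region_depths()` returns the per-position depth vector over the regions'
#' bases (concatenated in region order).
#'
#' @param placements placement tibble (`contig`, `start`, `end`).
#' @param regions interval tibble.
#' @return For `region_mean_coverage()`: `regions` plus `mean_cov`; for
#'   `region_depths()`: an integer vector.
#' @export
region_mean_coverage <- function(placements, regions) {
  out <- rep(0, nrow(regions))
  for (ctg in unique(regions$contig)) {
    rsel <- which(regions$contig == ctg)
    p <- placements[placements$contig == ctg, ]
    if (nrow(p) == 0) next
    cov <- IRanges::coverage(IRanges::IRanges(p$start + 1L, p$end))
    r <- IRanges::IRanges(regions$start[rsel] + 1L, regions$end[rsel])
    # views beyond coverage length are zero-padded
    cov <- c(cov, S4Vectors::Rle(0L, max(0, max(regions$end[rsel]) -
                                           length(cov))))
    out[rsel] <- IRanges::viewSums(IRanges::Views(cov, r)) /
      IRanges::width(r)
  }
  mutate(regions, mean_cov = out)
}

#' @rdname region_mean_coverage
#' @export
region_depths <- function(placements, regions) {
  out <- vector("list", length(unique(regions$contig)))
  names(out) <- unique(regions$contig)
  for (ctg in unique(regions$contig)) {
    r <- regions[regions$contig == ctg, ]
    p <- placements[placements$contig == ctg, ]
    if (nrow(p) == 0) {
      out[[ctg]] <- rep(0L, sum(r$end - r$start))
      next
    }
    cov <- IRanges::coverage(IRanges::IRanges(p$start + 1L, p$end))
    cov <- c(cov, S4Vectors::Rle(0L, max(0, max(r$end) - length(cov))))
    v <- IRanges::Views(cov, IRanges::IRanges(r$start + 1L, r$end))
    out[[ctg]] <- unlist(lapply(seq_along(v),
                                function(i) as.integer(v[[i]])),
                         use.names = FALSE)
  }
  unlist(out, use.names = FALSE)
}

#' Single-copy regions of a genome
#'
#' The nuclear complement of the repeat (target) intervals: all nuclear DNA
#' outside the gRNA target regions, which includes genes and regulatory
#' regions.
#'
#' @param genome a [genome_seq()] object.
#' @param annotation interval tibble.
#' @param repeat_classes classes treated as repeat targets; default all
#'   annotation classes except `gene` and `atac_peak`.
#' @return Interval tibble with class `single_copy`.
#' @export
single_copy_regions <- function(genome, annotation, repeat_classes = NULL) {
  repeat_classes <- repeat_classes %||%
    setdiff(unique(annotation$class_label), c("gene", "atac_peak"))
  annotation <- annotation[annotation$class_label %in% repeat_classes, ]
  lens <- contig_lengths(genome)
  nuclear <- names(lens)[genome$compartment == "nuclear"]
  out <- list()
  for (ctg in nuclear) {
    ann <- merge_intervals(annotation[annotation$contig == ctg, ],
                           by_class = FALSE)
    if (nrow(ann) == 0) {
      out[[ctg]] <- tibble(contig = ctg, start = 0L, end = lens[[ctg]],
                           class_label = "single_copy", strand = ".")
      next
    }
    starts <- c(0L, ann$end)
    ends <- c(ann$start, lens[[ctg]])
    keep <- ends > starts
    out[[ctg]] <- tibble(contig = ctg, start = starts[keep],
                         end = ends[keep], class_label = "single_copy",
                         strand = ".")
  }
  list_rbind(out)
}

#' Read placements from a SAM/BAM file
#'
#' Converts primary alignments into the placement table, discarding records
#' with any of the SAM flag bits in 2308 (unmapped, secondary,
#' supplementary), so multimapping reads are counted once.
#'
#' @param path SAM or BAM file.
#' @param sample_id,condition labels attached to the placements.
#' @return Placement tibble (`contig`, `start`, `end`, `sample_id`,
#'   `condition`).
#' @export
read_placements_sam <- function(path, sample_id = "s1",
                                condition = "nondepleted") {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("SAM/BAM input needs the Rsamtools package")
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "cigar")))[[1]]
  keep <- !is.na(res$pos) & bitwAnd(res$flag, 2308L) == 0L
  width <- cigar_ref_width(res$cigar[keep])
  tibble(contig = as.character(res$rname[keep]),
         start = res$pos[keep] - 1L,
         end = res$pos[keep] - 1L + width,
         sample_id = sample_id, condition = condition)
}

# reference-space width of CIGAR strings (M/D/N/=/X consume reference)
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, list(ops))[[1]]
    op <- substring(toks, nchar(toks), nchar(toks))
    len <- as.integer(substring(toks, 1, nchar(toks) - 1L))
    sum(len[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}
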