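eval_genome <- function() {
  genome_seq(c(nuc1 = random_seq(2000, seed = 50),
               chloroplast = random_seq(300),
               mitochondrion = random_seq(300)),
             compartment = c(nuc1 = "nuclear", chloroplast = "chloroplast",
                             mitochondrion = "mitochondrial"))
}

test_that("placements are classified by midpoint with conservation", {
  g <- eval_genome()
  ann <- dplyr::bind_rows(iv("nuc1", 100, 400, "LTR_Gypsy"),
                          iv("nuc1", 600, 800, "gene"))
  pl <- tibble::tibble(
    contig = c("nuc1", "nuc1", "nuc1", "chloroplast"),
    start = c(150L, 380L, 650L, 10L),
    end = c(250L, 500L, 750L, 110L),
    sample_id = "s1", condition = "nondepleted")
  # midpoints: 200 (repeat), 440 (outside despite straddling), 700 (a gene,
  # i.e. nuclear DNA outside the repeat targets = single copy)
  counts <- count_reads_by_class(pl, ann, g)
  cnt <- function(cl) counts$reads[counts$class_label == cl]
  expect_identical(cnt("LTR_Gypsy"), 1L)
  expect_identical(cnt("single_copy"), 2L)
  expect_identical(cnt("chloroplast"), 1L)
  expect_identical(cnt("total_repeats"), 1L)
  base <- counts[counts$class_label != "total_repeats", ]
  expect_identical(sum(base$reads), nrow(pl))
  expect_error(count_reads_by_class(
    dplyr::mutate(pl, contig = "nope"), ann, g), "absent")
})

test_that("read-count variation follows its defining arithmetic", {
  expect_equal(variation_of_mapped_reads(30, 50), -0.40)
  expect_equal(variation_of_mapped_reads(50, 50), 0)
  expect_equal(variation_of_mapped_reads(130, 50), 1.60)
  expect_true(is.na(variation_of_mapped_reads(10, 0)))
})

test_that("log2 coverage variation excludes zero-coverage regions with bookkeeping", {
  track <- tibble::tibble(
    region_id = 1:6,
    mean_cov_depleted = c(2, 1, 0, 0, 3, 0.5),
    mean_cov_nondepleted = c(1, 1, 2, 0, 4, 2))
  out <- log2_coverage_variation(track)
  expect_equal(out$values$log2_variation, c(1, 0, log2(3 / 4), -2))
  ex <- out$exclusions
  expect_identical(ex$zero_depleted, 2L)
  expect_identical(ex$zero_nondepleted, 1L)
  expect_identical(ex$zero_both, 1L)
  expect_identical(ex$excluded, 2L)
  expect_equal(ex$excluded_fraction, (2 + 1 - 1) / 6)
  # excluded + retained = total
  expect_identical(ex$excluded + nrow(out$values), ex$total)
})

test_that("genotypable positions honour the inclusive PASS threshold", {
  expect_identical(genotypable_positions(rep(5L, 100)), 100L)
  expect_identical(genotypable_positions(rep(4L, 100)), 0L)
  expect_identical(genotypable_positions(c(0L, 5L, 10L, 4L, 6L)), 3L)
  # monotone non-increasing in min_depth
  set.seed(2)
  d <- rpois(500, 4)
  counts <- vapply(1:10, function(k) genotypable_positions(d, k), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("common genotyped positions is a plain set intersection", {
  expect_identical(common_genotyped_positions(list(1:10, 1:10)), 10L)
  expect_identical(common_genotyped_positions(list(1:5, 6:10)), 0L)
  expect_identical(common_genotyped_positions(list(1:10, 6:15, 6:8)), 3L)
})

test_that("heterozygote detection follows the binomial closed form", {
  expect_identical(het_detection_probability(0, 0.5, 1), 0)
  expect_equal(het_detection_probability(5, 0.5, 1), 1 - 0.5^5)
  expect_equal(het_detection_probability(5, 0.5, 2), 1 - 6 / 32)
  # Monte-Carlo agreement within 3 SE for a grid of cases
  set.seed(33)
  for (case in list(c(3, 0.5, 1), c(10, 0.3, 2), c(30, 0.5, 5))) {
    draws <- rbinom(1e5, case[1], case[2])
    mc <- mean(draws >= case[3])
    p <- het_detection_probability(case[1], case[2], case[3])
    se <- sqrt(p * (1 - p) / 1e5)
    expect_lt(abs(mc - p), 3 * se + 1e-12)
  }
  gain <- het_recovery_gain(rep(10L, 100), rep(2L, 100))
  expect_gt(gain$gain, 1)
})

test_that("density-depletion summary matches a direct Pearson computation", {
  tab <- tibble::tibble(density = c(1, 3, 6, 9, 12, 20),
                        log2_variation = c(0.2, 0.1, -0.1, -0.8, -1.5, -2.5))
  out <- density_vs_depletion(tab, threshold = 8)
  num <- sum((tab$density - mean(tab$density)) *
               (tab$log2_variation - mean(tab$log2_variation)))
  den <- sqrt(sum((tab$density - mean(tab$density))^2) *
                sum((tab$log2_variation - mean(tab$log2_variation))^2))
  expect_equal(out$correlation, num / den)
  expect_equal(out$fraction_reduced_above, 1)
  expect_equal(out$fraction_reduced_below, 1 / 3)
  # degenerate: constant density has no defined correlation
  flat <- dplyr::mutate(tab, density = 5)
  expect_true(is.na(density_vs_depletion(flat)$correlation))
  expect_error(density_vs_depletion(tab[0, ]), "no usable")
})

test_that("coverage helpers agree with direct per-base accounting", {
  pl <- tibble::tibble(contig = "nuc1",
                       start = c(0L, 5L, 5L), end = c(10L, 15L, 8L),
                       sample_id = "s1", condition = "nondepleted")
  region <- iv("nuc1", 0, 20)
  depths <- region_depths(pl, region)
  manual <- integer(20)
  for (i in seq_len(nrow(pl))) {
    idx <- (pl$start[i] + 1):pl$end[i]
    manual[idx] <- manual[idx] + 1L
  }
  expect_identical(depths, manual)
  mc <- region_mean_coverage(pl, region)
  expect_equal(mc$mean_cov, mean(manual))
})

test_that("SAM ingestion keeps primary placements only", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unknown",
    "@SQ\tSN:nuc1\tLN:2000",
    paste("r1", 0, "nuc1", 101, 60, "50M", "*", 0, 0,
          strrep("A", 50), "*", sep = "\t"),
    paste("r2", 16, "nuc1", 201, 60, "20M5D25M", "*", 0, 0,
          strrep("A", 45), "*", sep = "\t"),
    paste("r3", 256, "nuc1", 301, 60, "50M", "*", 0, 0,
          "*", "*", sep = "\t"),        # secondary: dropped
    paste("r4", 2048, "nuc1", 401, 60, "25M", "*", 0, 0,
          strrep("A", 25), "*", sep = "\t"),  # supplementary: dropped
    paste("r5", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("A", 25), "*", sep = "\t")), # unmapped: dropped
    sam)
  pl <- read_placements_sam(sam, sample_id = "x", condition = "depleted")
  expect_identical(nrow(pl), 2L)
  expect_identical(pl$start, c(100L, 200L))
  # 20M5D25M consumes 50 reference bases
  expect_identical(pl$end, c(150L, 250L))
  expect_identical(unique(pl$condition), "depleted")
})

test_that("single-copy regions are the nuclear annotation complement", {
  g <- eval_genome()
  ann <- dplyr::bind_rows(iv("nuc1", 0, 100, "LTR_Gypsy"),
                          iv("nuc1", 500, 700, "gene"))
  sc <- single_copy_regions(g, ann)
  # genes stay single copy: only the repeat target is complemented
  expect_identical(sc$start, 100L)
  expect_identical(sc$end, 2000L)
  expect_true(all(sc$contig == "nuc1"))
})
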