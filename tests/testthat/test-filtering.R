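test_that("GC content is a simple base fraction", {
  expect_identical(gc_content(strrep("A", 20)), 0)
  expect_identical(gc_content(paste0(strrep("G", 10), strrep("A", 10))), 0.5)
  expect_identical(gc_content(strrep("GC", 10)), 1)
})

test_that("homopolymer and dinucleotide runs are counted exactly", {
  expect_identical(max_homopolymer_run("AAAATGCTTGCATGCATGCA"), 4L)
  expect_identical(max_dinucleotide_units("ATATATATGCAGTCAGTCAG"), 4L)
  # period-4 sequence has no homopolymer and no dinucleotide repeat
  expect_identical(max_homopolymer_run(strrep("ACGT", 5)), 1L)
  expect_identical(max_dinucleotide_units(strrep("ACGT", 5)), 1L)
  # a homopolymer is not a two-distinct-base dinucleotide repeat
  expect_identical(max_dinucleotide_units(strrep("A", 20)), 1L)
  expect_identical(max_homopolymer_run(strrep("A", 20)), 20L)
})

test_that("hairpin stem detection matches the exhaustive oracle", {
  s <- paste0("GGGGCC", "AAA", "GGCCCC", "AAAAA")
  expect_gte(hairpin_stem(s), 6L)
  expect_identical(hairpin_stem(strrep("A", 20)), 0L)
  set.seed(7)
  guides <- vapply(1:25, function(i) random_seq(20), character(1))
  expect_identical(hairpin_stem(guides),
                   vapply(guides, oracle_hairpin, integer(1),
                          USE.NAMES = FALSE))
})

test_that("the default efficiency scorer is deterministic, bounded and monotone", {
  set.seed(11)
  guides <- vapply(1:50, function(i) random_seq(20), character(1))
  s1 <- efficiency_score(guides)
  s2 <- efficiency_score(guides)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # changing the PAM-proximal base T -> G never decreases the score
  base <- substring(guides, 1, 19)
  expect_true(all(efficiency_score(paste0(base, "G")) >=
                    efficiency_score(paste0(base, "T"))))
  # truncated context falls back to the neutral score
  expect_identical(efficiency_score("ACGTACGTACGTACGTACGT",
                                    context = NA_character_), 0.5)
})

test_that("off-target hits honour mismatch tolerance and the PAM requirement", {
  proto <- "ACGGATCCTAGGCATCAGGA"
  flip <- function(x, at) {
    for (i in at) {
      substr(x, i, i) <- setdiff(c("A", "C", "G", "T"),
                                 substr(x, i, i))[1]
    }
    x
  }
  pad <- function(core, pam) {
    paste0(strrep("T", 30), core, pam, strrep("T", 30))
  }
  protected <- iv("c1", 0, 200, "gene")
  # exact hit with NGG in a protected region: counted
  g <- make_genome(c1 = pad(proto, "TGG"))
  expect_gte(offtarget_hits(proto, g, protected), 1L)
  # exactly 3 mismatches: counted; 4: not
  g3 <- make_genome(c1 = pad(flip(proto, c(2, 9, 16)), "TGG"))
  expect_identical(offtarget_hits(proto, g3, protected, max_mm = 3), 1L)
  g4 <- make_genome(c1 = pad(flip(proto, c(2, 9, 16, 19)), "TGG"))
  expect_identical(offtarget_hits(proto, g4, protected, max_mm = 3), 0L)
  # close match but a non-NGG PAM: not counted unless pam-free mode
  gp <- make_genome(c1 = pad(proto, "TAA"))
  expect_identical(offtarget_hits(proto, gp, protected), 0L)
  expect_gte(offtarget_hits(proto, gp, protected, require_pam = FALSE), 1L)
})

test_that("pigeonhole batch search equals the naive Hamming oracle", {
  n <- 4000
  s <- random_seq(n, seed = 31)
  g <- make_genome(c1 = s)
  protected <- dplyr::bind_rows(iv("c1", 200, 900, "gene"),
                                iv("c1", 2000, 2600, "atac_peak"))
  cand <- scan_pam_sites(g, iv("c1", 1000, 1900))
  got <- repeatclean:::batch_offtarget_hits(cand$protospacer, g, protected)
  want <- vapply(cand$protospacer, oracle_offtarget_hits, integer(1),
                 seqs = list(c1 = s), protected = protected,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
  # the single-guide entry point agrees too
  idx <- which(want > 0)
  for (i in head(c(idx, 1, 2), 5)) {
    expect_identical(offtarget_hits(cand$protospacer[i], g, protected),
                     want[i])
  }
})

test_that("the filter cascade flags independently and passes conjunctively", {
  expect_identical(nrow(apply_guide_filters(
    tibble::tibble(guide_id = character(), protospacer = character(),
                   contig = character(), cut = integer(),
                   strand = character()),
    make_genome(c1 = "ACGT"), iv("c1", 0, 0)[0, ])), 0L)

  # 85% GC fails the GC filter only (no long runs, no stem, good score)
  gcfail <- "GCGGCAGCGGCAGGCCTGCG"
  g <- make_genome(c1 = paste0(strrep("T", 25), gcfail, "TGG",
                               strrep("T", 25)))
  cand <- scan_pam_sites(g, iv("c1", 0, nchar(g$seq[["c1"]])))
  v <- apply_guide_filters(cand[cand$protospacer == gcfail, ], g,
                           iv("c1", 0, 0)[0, ])
  expect_false(v$pass_gc)
  expect_true(v$pass_homopolymer && v$pass_dinucleotide)
  expect_false(v$pass)
  # off-target search skipped for sequence-filter failures
  expect_true(is.na(v$offtarget_hits))
})

test_that("verdicts are pure and the survivor set is order-independent", {
  n <- 6000
  s <- random_seq(n, seed = 17)
  g <- make_genome(c1 = s)
  protected <- iv("c1", 4000, 5500, "gene")
  cand <- scan_pam_sites(g, iv("c1", 0, 3000))
  cfg <- filter_config()
  v1 <- suppressMessages(apply_guide_filters(cand, g, protected, cfg))
  v2 <- suppressMessages(apply_guide_filters(cand, g, protected, cfg))
  expect_identical(v1, v2)
  # survivors = intersection of single-filter survivor sets, evaluated
  # without the cascade's skipping
  all_hits <- repeatclean:::batch_offtarget_hits(
    cand$protospacer, g, protected, max_mm = cfg$offtarget_max_mismatches)
  indep <- cand$guide_id[
    gc_content(cand$protospacer) >= cfg$gc_min &
      gc_content(cand$protospacer) <= cfg$gc_max &
      max_homopolymer_run(cand$protospacer) <= cfg$max_homopolymer &
      max_dinucleotide_units(cand$protospacer) <=
        cfg$max_dinucleotide_repeat &
      hairpin_stem(cand$protospacer) < cfg$max_hairpin_stem &
      efficiency_score(cand$protospacer,
                       repeatclean:::discovery_context(cand, g)) >=
        cfg$efficiency_min &
      all_hits == 0L]
  expect_setequal(v1$guide_id[v1$pass], indep)
})

test_that("tightening any threshold never grows the survivor set", {
  n <- 5000
  s <- random_seq(n, seed = 23)
  g <- make_genome(c1 = s)
  protected <- iv("c1", 3500, 4500, "gene")
  cand <- scan_pam_sites(g, iv("c1", 0, 2500))
  loose <- filter_config(gc_min = 0.1, gc_max = 0.9, max_homopolymer = 8,
                         max_dinucleotide_repeat = 8, max_hairpin_stem = 10,
                         efficiency_min = 0)
  tight <- filter_config()
  sv <- function(cfg) {
    v <- suppressMessages(apply_guide_filters(cand, g, protected, cfg))
    v$guide_id[v$pass]
  }
  expect_true(all(sv(tight) %in% sv(loose)))
})
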