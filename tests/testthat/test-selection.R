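# minimal builders for selection inputs
fake_candidates <- function(protos, counts) {
  tibble::tibble(guide_id = paste0("g", seq_along(protos)),
                 protospacer = protos,
                 on_target_sites = as.integer(counts))
}
fake_sites <- function(guide_ids, cuts, contig = "c1") {
  tibble::tibble(contig = contig, cut = as.integer(cuts), strand = "+",
                 guide_id = guide_ids, on_target = TRUE)
}

test_that("within-guide thinning keeps the maximum spaced subset", {
  cand <- fake_candidates("ACGTACGTACGTACGTACGT", 3)
  sites <- fake_sites(rep("g1", 3), c(0, 300, 600))
  d <- select_guides(cand, sites, min_sites = 1, min_spacing = 500)
  expect_identical(d$sites$cut, c(0L, 600L))
  # greedy equals the exhaustive maximum on random site sets
  set.seed(5)
  for (rep in 1:10) {
    cuts <- sort(sample(0:3000, 12))
    d <- select_guides(fake_candidates("A", 12),
                       fake_sites(rep("g1", 12), cuts),
                       min_sites = 1, min_spacing = 400)
    expect_identical(nrow(d$sites), oracle_max_spaced_subset(cuts, 400))
  }
})

test_that("the site-count constraint is a hard boundary", {
  cand <- fake_candidates("ACGTACGTACGTACGTACGT", 24)
  sites <- fake_sites(rep("g1", 24), seq(0, by = 1000, length.out = 24))
  expect_warning(d <- select_guides(cand, sites, min_sites = 25),
                 "no guide")
  expect_identical(nrow(d$guides), 0L)
  d <- select_guides(cand, sites, min_sites = 24)
  expect_identical(nrow(d$guides), 1L)
  expect_identical(d$guides$accepted_sites, 24L)
})

test_that("ties break lexicographically and interleaved guides conflict", {
  # two guides with equal counts; sites interleave at 250-bp offsets
  protos <- c("CCCCACGTACGTACGTACGT", "AAAAACGTACGTACGTACGT")
  cand <- fake_candidates(protos, c(4, 4))
  cuts1 <- c(0, 500, 1000, 1500)        # guide 1 (lexicographically second)
  cuts2 <- cuts1 + 250                  # guide 2 (lexicographically first)
  sites <- dplyr::bind_rows(fake_sites(rep("g1", 4), cuts1),
                            fake_sites(rep("g2", 4), cuts2))
  d <- select_guides(cand, sites, min_sites = 3, min_spacing = 500)
  # g2 ("AAAA...") visited first, accepted; g1's spaced subset then < 3
  expect_identical(d$guides$guide_id, "g2")
})

test_that("selection output always satisfies both design constraints", {
  set.seed(41)
  for (rep in 1:5) {
    n_guides <- 15
    protos <- vapply(seq_len(n_guides), function(i) random_seq(20),
                     character(1))
    counts <- sample(5:40, n_guides, replace = TRUE)
    sites <- purrr::list_rbind(purrr::map(seq_len(n_guides), function(i) {
      fake_sites(rep(paste0("g", i), counts[i]),
                 sample(0:20000, counts[i]))
    }))
    d <- suppressWarnings(select_guides(fake_candidates(protos, counts),
                                        sites, min_sites = 8,
                                        min_spacing = 300))
    if (nrow(d$guides) > 0) {
      expect_true(all(d$guides$accepted_sites >= 8))
      expect_gte(min_site_spacing(d$sites), 300)
    }
  }
})

test_that("pool assignment balances sizes and orders by cutting frequency", {
  d22 <- structure(list(
    guides = fake_candidates(vapply(1:22, function(i) random_seq(20),
                                    character(1)), sample(10:200, 22)) |>
      dplyr::mutate(accepted_sites = on_target_sites),
    sites = fake_sites(character(), integer()),
    params = list()), class = "guide_design")
  p <- assign_pools(d22, 11)
  tab <- table(p$guides$pool)
  expect_identical(unname(as.integer(tab)), rep(2L, 11))
  # pool index increases with cutting frequency
  m <- p$guides |> dplyr::group_by(pool) |>
    dplyr::summarise(lo = min(on_target_sites), hi = max(on_target_sites))
  expect_true(all(diff(m$lo) >= 0))

  # equal counts: stable protospacer tie-break, sizes differ by <= 1
  deq <- d22
  deq$guides$on_target_sites <- 50L
  p2 <- assign_pools(deq, 4)
  expect_lte(diff(range(table(p2$guides$pool))), 1)
  expect_identical(p2$guides$protospacer[order(p2$guides$pool,
                                               p2$guides$protospacer)],
                   sort(deq$guides$protospacer))

  # more pools than guides: lowest pools occupied singly
  d5 <- d22
  d5$guides <- d5$guides[1:5, ]
  expect_warning(p3 <- assign_pools(d5, 11), "empty")
  expect_setequal(p3$guides$pool, 1:5)
})

test_that("sequential groups are contiguous frequency blocks, lowest first", {
  d <- structure(list(
    guides = fake_candidates(vapply(1:22, function(i) random_seq(20),
                                    character(1)), sample(10:200, 22)) |>
      dplyr::mutate(accepted_sites = on_target_sites),
    sites = fake_sites(character(), integer()),
    params = list()), class = "guide_design")
  d <- assign_pools(d, 11)
  d <- group_for_sequential(d, 3)
  sizes <- d$guides |> dplyr::distinct(pool, group) |> dplyr::count(group)
  expect_identical(sizes$n, c(4L, 4L, 3L))
  byg <- d$guides |> dplyr::group_by(group) |>
    dplyr::summarise(lo = min(on_target_sites), hi = max(on_target_sites))
  expect_true(all(byg$hi[-nrow(byg)] <= byg$lo[-1]))

  d3 <- assign_pools(d, 3)
  d3 <- group_for_sequential(d3, 3)
  expect_identical(
    nrow(dplyr::distinct(d3$guides, pool, group)), 3L)
})

test_that("dosing splits mass proportionally and obeys the Cas9 volume rule", {
  d <- structure(list(
    guides = fake_candidates(c("AAAAAAAAAAAAAAAAAAAA",
                               "CCCCCCCCCCCCCCCCCCCC"), c(100, 300)) |>
      dplyr::mutate(accepted_sites = on_target_sites,
                    pool = c(1L, 2L)),
    sites = fake_sites(character(), integer()),
    params = list(n_pools = 2L)), class = "guide_design")
  d <- compute_dosing(d, total_ng = 620)
  expect_equal(d$dosing$per_pool$nanograms, c(155, 465))
  expect_equal(d$dosing$cas9_ul, 0.0029 * 620)
  expect_equal(sum(d$guides$nanograms), 620)
  dd <- compute_dosing(d, total_ng = 620, double = TRUE)
  expect_equal(dd$dosing$total_ng, 1240)
  expect_equal(sum(dd$guides$nanograms), 1240)
})

test_that("footprint follows the cut-free-run rule and matches enumeration", {
  g401 <- make_genome(c1 = random_seq(401, seed = 1))
  fp <- targetable_footprint(tibble::tibble(contig = "c1", cut = c(0L, 400L)),
                             g401, insert_size = 500)
  expect_identical(fp$targetable_bp, 401)

  g1001 <- make_genome(c1 = random_seq(1001, seed = 2))
  fp2 <- targetable_footprint(tibble::tibble(contig = "c1",
                                             cut = c(0L, 1000L)),
                              g1001, insert_size = 500)
  expect_identical(fp2$targetable_bp, 2)   # only the two cut positions

  fp0 <- targetable_footprint(tibble::tibble(contig = character(),
                                             cut = integer()),
                              g1001, insert_size = 500)
  expect_identical(fp0$targetable_bp, 0)

  set.seed(3)
  for (rep in 1:4) {
    L <- sample(2000:6000, 1)
    cuts <- sort(sample(0:(L - 1), sample(3:12, 1)))
    ins <- sample(c(200, 500, 800), 1)
    g <- make_genome(c1 = random_seq(L))
    fp <- targetable_footprint(tibble::tibble(contig = "c1", cut = cuts),
                               g, insert_size = ins)
    expect_identical(fp$targetable_bp, as.numeric(oracle_footprint(cuts, L, ins)))
  }
})

test_that("footprint is monotone in insert size and in the site set", {
  g <- make_genome(c1 = random_seq(5000, seed = 13))
  cuts <- sort(sample(0:4999, 8))
  fps <- vapply(c(100, 300, 600, 1200),
                function(ins) targetable_footprint(
                  tibble::tibble(contig = "c1", cut = cuts), g,
                  insert_size = ins)$targetable_bp, numeric(1))
  expect_true(all(diff(fps) >= 0))
  sub <- vapply(c(2, 5, 8), function(k) targetable_footprint(
    tibble::tibble(contig = "c1", cut = cuts[seq_len(k)]), g,
    insert_size = 400)$targetable_bp, numeric(1))
  expect_true(all(diff(sub) >= 0))
})
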