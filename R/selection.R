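#' Select guides under cleavage-site count and spacing constraints
#'
#' Greedy reduction of the passing candidate set: guides are visited in order
#' of decreasing on-target cleavage-site count (ties broken lexicographically
#' by protospacer). For each guide, the on-target sites at least `min_spacing`
#' from every already-accepted site are thinned left-to-right within each
#' contig so consecutive accepted sites stay `>= min_spacing` apart; if at
#' least `min_sites` sites remain, the guide is accepted with exactly those
#' sites. The result satisfies both design constraints: every guide
#' keeps no fewer than `min_sites` cleavage sites and all accepted sites on a
#' contig are `>= min_spacing` apart.
#'
#' @param candidates tibble from [count_on_target_sites()]`$candidates`
#'   (needs `guide_id`, `protospacer`, `on_target_sites`).
#' @param sites cut-site index tibble (`contig`, `cut`, `strand`, `guide_id`,
#'   `on_target`).
#' @param verdicts optional tibble from [apply_guide_filters()]; only guides
#'   with `pass == TRUE` are considered.
#' @param min_sites minimum accepted cleavage sites per guide (default 25).
#' @param min_spacing minimum spacing between accepted sites in bp
#'   (default 500).
#' @return A `guide_design` object: list with `guides` (selected guides with
#'   `accepted_sites` counts), `sites` (accepted cleavage sites), and the
#'   selection parameters. Empty (with a warning) when no guide qualifies.
#' @export
select_guides <- function(candidates, sites, verdicts = NULL,
                          min_sites = 25L, min_spacing = 500L) {
  cand <- candidates
  if (!is.null(verdicts)) {
    keep <- verdicts$guide_id[verdicts$pass]
    cand <- filter(cand, .data$guide_id %in% keep)
  }
  cand <- arrange(cand, desc(.data$on_target_sites), .data$protospacer)
  on_sites <- filter(sites, .data$on_target) |>
    arrange(.data$contig, .data$cut)
  site_list <- split(on_sites, on_sites$guide_id)
  accepted <- list()   # per-contig sorted numeric vectors of accepted cuts
  acc_guides <- character()
  acc_rows <- list()
  for (i in seq_len(nrow(cand))) {
    gid <- cand$guide_id[i]
    gs <- site_list[[gid]]
    if (is.null(gs)) next
    kept <- list()
    n_kept <- 0L
    for (ctg in unique(gs$contig)) {
      cuts <- gs$cut[gs$contig == ctg]
      prior <- accepted[[ctg]]
      free <- if (is.null(prior)) {
        cuts
      } else {
        # distance to nearest already-accepted site >= min_spacing
        idx <- findInterval(cuts, prior)
        d_lo <- ifelse(idx > 0, cuts - prior[pmax(idx, 1L)], Inf)
        d_hi <- ifelse(idx < length(prior),
                       prior[pmin(idx + 1L, length(prior))] - cuts, Inf)
        cuts[pmin(d_lo, d_hi) >= min_spacing]
      }
      if (length(free) == 0) next
      # left-to-right greedy thinning gives the maximum spaced subset
      sel <- free[1]
      last <- free[1]
      for (p in free[-1]) {
        if (p - last >= min_spacing) {
          sel <- c(sel, p)
          last <- p
        }
      }
      kept[[ctg]] <- sel
      n_kept <- n_kept + length(sel)
    }
    if (n_kept >= min_sites) {
      acc_guides <- c(acc_guides, gid)
      for (ctg in names(kept)) {
        accepted[[ctg]] <- sort(c(accepted[[ctg]], kept[[ctg]]))
      }
      acc_rows[[gid]] <- imap(kept, function(cuts, ctg) {
        tibble(contig = ctg, cut = cuts, guide_id = gid)
      }) |> list_rbind()
    }
  }
  if (length(acc_guides) == 0) {
    warn("no guide satisfies the site-count constraint; empty design")
    guides <- cand[0, ] |> mutate(accepted_sites = integer())
    acc <- tibble(contig = character(), cut = integer(),
                  guide_id = character())
  } else {
    acc <- list_rbind(acc_rows) |>
      left_join(select(on_sites, "contig", "cut", "strand", "guide_id"),
                by = c("contig", "cut", "guide_id")) |>
      distinct(.data$contig, .data$cut, .data$guide_id,
               .keep_all = TRUE) |>
      arrange(.data$contig, .data$cut)
    guides <- cand |>
      filter(.data$guide_id %in% acc_guides) |>
      left_join(count(acc, .data$guide_id, name = "accepted_sites"),
                by = "guide_id") |>
      arrange(desc(.data$on_target_sites), .data$protospacer)
  }
  structure(list(guides = guides, sites = acc,
                 params = list(min_sites = as.integer(min_sites),
                               min_spacing = as.integer(min_spacing))),
            class = "guide_design")
}

#' Assign guides to synthesis pools by cutting frequency
#'
#' Guides are ranked by on-target cleavage-site count (cutting frequency) and
#' binned into `n_pools` pools of near-equal size (differing by at most one
#' guide, remainders filling the lowest pools); pool 1 holds the
#' lowest-frequency guides. Ties are broken by protospacer for a stable,
#' seed-free assignment.
#'
#' @param design a `guide_design` from [select_guides()].
#' @param n_pools number of pools (default 11).
#' @return The design with a `pool` column on `$guides`.
#' @export
assign_pools <- function(design, n_pools = 11L) {
  g <- design$guides
  n <- nrow(g)
  if (n == 0) abort("empty design")
  if (n_pools > n) {
    warn(paste0(n_pools - n, " pool(s) will be empty (more pools than guides)"))
  }
  sizes <- rep(n %/% n_pools, n_pools)
  extra <- n %% n_pools
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  g <- arrange(g, .data$on_target_sites, .data$protospacer)
  g$pool <- rep(seq_len(n_pools), times = sizes)[seq_len(n)]
  design$guides <- arrange(g, .data$pool, .data$on_target_sites,
                           .data$protospacer)
  design$params$n_pools <- as.integer(n_pools)
  design
}

#' Partition pools into sequential reaction groups
#'
#' Pools are split into `n_groups` contiguous blocks by cutting frequency
#' (block sizes differ by at most one, remainders to the lowest blocks) and
#' are meant to be used sequentially in order of increasing cutting
#' frequency: group 1 (lowest-frequency pools) first.
#'
#' @param design a pooled `guide_design`.
#' @param n_groups number of sequential groups (default 3).
#' @return The design with a `group` column on `$guides`.
#' @export
group_for_sequential <- function(design, n_groups = 3L) {
  g <- design$guides
  if (is.null(g$pool)) abort("assign pools before grouping")
  n_pools <- design$params$n_pools
  sizes <- rep(n_pools %/% n_groups, n_groups)
  extra <- n_pools %% n_groups
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  pool_group <- rep(seq_len(n_groups), times = sizes)
  g$group <- pool_group[g$pool]
  design$guides <- g
  design$params$n_groups <- as.integer(n_groups)
  design
}

#' Compute the gRNA dosing plan
#'
#' Each guide's mass is proportional to its on-target cleavage-site
#' count (the guide's cutting frequency), so high-frequency guides are
#' synthesized at higher copy number. The
#' default reaction uses 620 ng of total gRNA (1240 ng with `double = TRUE`,
#' the double sequential protocol) and 0.0029 uL of diluted Cas9 per ng of
#' gRNA (a 1:2.5 protein:gRNA molar ratio).
#'
#' @param design a `guide_design` (pooled or not).
#' @param total_ng total gRNA mass in ng (default 620).
#' @param double double the reaction (total becomes `2 * total_ng`).
#' @param cas9_ul_per_ng Cas9 volume per ng of gRNA (default 0.0029).
#' @return The design with a `nanograms` column on `$guides` and a `dosing`
#'   element: list with `per_pool` tibble (when pools are assigned),
#'   `total_ng`, `cas9_ul` and `ratio_note`.
#' @export
compute_dosing <- function(design, total_ng = 620, double = FALSE,
                           cas9_ul_per_ng = 0.0029) {
  g <- design$guides
  if (nrow(g) == 0) abort("empty design")
  total_sites <- sum(g$on_target_sites)
  if (total_sites == 0) abort("design has zero on-target cleavage sites")
  total <- if (isTRUE(double)) 2 * total_ng else total_ng
  g$nanograms <- total * g$on_target_sites / total_sites
  per_pool <- NULL
  if (!is.null(g$pool)) {
    per_pool <- g |>
      group_by(.data$pool) |>
      summarise(n_guides = n(), sites = sum(.data$on_target_sites),
                nanograms = sum(.data$nanograms), .groups = "drop")
  }
  design$guides <- g
  design$dosing <- list(per_pool = per_pool, total_ng = total,
                        cas9_ul = cas9_ul_per_ng * total,
                        ratio_note = "1:2.5 protein/gRNA")
  design
}

#' Targetable genome footprint at a given insert size
#'
#' A position is targetable when every possible library fragment of
#' `insert_size` bp covering it contains at least one cleavage site —
#' equivalently, when the maximal cut-free run of positions containing it is
#' shorter than `insert_size` (cut positions themselves are always
#' targetable).
#'
#' @param sites cut-site tibble (`contig`, `cut`); only distinct positions
#'   matter.
#' @param genome a [genome_seq()] object.
#' @param insert_size library insert length in bp (default 500).
#' @param annotation optional interval tibble; when given, the targetable
#'   fraction of its covered bases is also reported.
#' @return One-row tibble: `targetable_bp`, `fraction_nuclear` (of nuclear
#'   genome bp) and `fraction_annotation` (`NA` without `annotation`).
#' @export
targetable_footprint <- function(sites, genome, insert_size = 500L,
                                 annotation = NULL) {
  lens <- contig_lengths(genome)
  nuclear <- names(lens)[genome$compartment == "nuclear"]
  targetable <- list()
  total_bp <- 0
  for (ctg in names(lens)) {
    L <- lens[[ctg]]
    cuts <- sort(unique(sites$cut[sites$contig == ctg]))
    if (length(cuts) == 0) {
      targetable[[ctg]] <- tibble(contig = character(), start = integer(),
                                  end = integer())
      next
    }
    # cut-free runs between consecutive cut positions and at contig ends
    run_start <- c(0L, cuts + 1L)
    run_end <- c(cuts, L)
    run_len <- run_end - run_start
    blocked <- run_len >= insert_size
    # targetable = contig minus blocked runs
    tb <- tibble(contig = ctg, start = run_start[blocked],
                 end = run_end[blocked])
    cover <- L - sum(run_len[blocked])
    total_bp <- total_bp + cover
    # record targetable intervals (complement of blocked runs)
    bs <- c(0L, run_end[blocked])
    be <- c(run_start[blocked], L)
    keep <- be > bs
    targetable[[ctg]] <- tibble(contig = ctg, start = bs[keep],
                                end = be[keep], class_label = "targetable",
                                strand = ".")
  }
  tgt_iv <- list_rbind(targetable)
  frac_nuc <- {
    nuc_iv <- tgt_iv[tgt_iv$contig %in% nuclear, ]
    denom <- sum(lens[nuclear])
    if (denom > 0) sum(nuc_iv$end - nuc_iv$start) / denom else NA_real_
  }
  frac_ann <- NA_real_
  if (!is.null(annotation) && nrow(annotation) > 0 && nrow(tgt_iv) > 0) {
    ann <- merge_intervals(annotation, by_class = FALSE)
    inter <- 0
    for (ctg in unique(ann$contig)) {
      a <- ann[ann$contig == ctg, ]
      t <- tgt_iv[tgt_iv$contig == ctg, ]
      if (nrow(t) == 0) next
      ia <- IRanges::IRanges(a$start + 1L, a$end)
      it <- IRanges::IRanges(t$start + 1L, t$end)
      ov <- IRanges::intersect(ia, it)
      inter <- inter + sum(IRanges::width(ov))
    }
    frac_ann <- inter / interval_bp(annotation)
  } else if (!is.null(annotation) && nrow(annotation) > 0) {
    frac_ann <- 0
  }
  tibble(targetable_bp = total_bp, fraction_nuclear = frac_nuc,
         fraction_annotation = frac_ann)
}
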