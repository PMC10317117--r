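#' Run the full guide-design pipeline
#'
#' Scan target intervals for PAM-adjacent protospacers, count genome-wide
#' exact cleavage sites, apply the sequence-quality and off-target filter
#' cascade, select guides under the site-count and spacing constraints, and
#' assign pools, sequential groups and dosing.
#'
#' @param genome a [genome_seq()] object.
#' @param targets interval tibble of repeat regions to deplete.
#' @param protected interval tibble of protected regions (genes + open
#'   chromatin) screened for off-targets; may be empty.
#' @param config a [filter_config()].
#' @param min_sites,min_spacing selection constraints (defaults 25 sites,
#'   500 bp).
#' @param n_pools,n_groups pool and sequential-group counts (defaults 11, 3).
#' @param total_ng,double,cas9_ul_per_ng dosing parameters, see
#'   [compute_dosing()].
#' @param scorer efficiency scorer passed to [apply_guide_filters()].
#' @return A `guide_design` with `guides`, `sites`, `dosing`, `params`, plus
#'   `verdicts` (all filter verdicts) and `n_candidates`.
#' @export
design_guides <- function(genome, targets, protected = NULL,
                          config = filter_config(),
                          min_sites = 25L, min_spacing = 500L,
                          n_pools = 11L, n_groups = 3L,
                          total_ng = 620, double = FALSE,
                          cas9_ul_per_ng = 0.0029,
                          scorer = efficiency_score) {
  targets <- merge_intervals(targets, by_class = FALSE)
  protected <- protected %||% tibble(contig = character(), start = integer(),
                                     end = integer(),
                                     class_label = character())
  cand <- scan_pam_sites(genome, targets)
  counted <- count_on_target_sites(cand, genome, targets)
  verdicts <- apply_guide_filters(counted$candidates, genome, protected,
                                  config = config, scorer = scorer)
  design <- select_guides(counted$candidates, counted$sites,
                          verdicts = verdicts,
                          min_sites = min_sites, min_spacing = min_spacing)
  design$verdicts <- verdicts
  design$n_candidates <- nrow(counted$candidates)
  if (nrow(design$guides) > 0) {
    design <- assign_pools(design, n_pools = n_pools)
    design <- group_for_sequential(design, n_groups = n_groups)
    design <- compute_dosing(design, total_ng = total_ng, double = double,
                             cas9_ul_per_ng = cas9_ul_per_ng)
  }
  design
}

#' @export
print.guide_design <- function(x, ...) {
  cat("<guide_design> ", nrow(x$guides), " guide(s), ",
      nrow(x$sites), " accepted cleavage site(s)\n", sep = "")
  cat("  constraints: >= ", x$params$min_sites, " sites/guide, >= ",
      x$params$min_spacing, " bp spacing\n", sep = "")
  if (!is.null(x$dosing)) {
    cat("  dosing: ", format(x$dosing$total_ng), " ng gRNA, ",
        format(round(x$dosing$cas9_ul, 3)), " uL Cas9 (",
        x$dosing$ratio_note, ")\n", sep = "")
  }
  if (nrow(x$guides) > 0) print(head(x$guides, 5))
  invisible(x)
}

#' @rdname design_guides
#' @param x a `guide_design`.
#' @param ... unused.
#' @method tidy guide_design
#' @export
tidy.guide_design <- function(x, ...) {
  as_tibble(x$guides)
}

#' @rdname design_guides
#' @method glance guide_design
#' @export
glance.guide_design <- function(x, ...) {
  g <- x$guides
  spacing <- min_site_spacing(x$sites)
  tibble(
    n_candidates = x$n_candidates %||% NA_integer_,
    n_guides = nrow(g),
    n_sites = nrow(x$sites),
    min_accepted_sites = if (nrow(g)) min(g$accepted_sites) else NA_integer_,
    min_spacing_bp = spacing,
    total_ng = x$dosing$total_ng %||% NA_real_,
    cas9_ul = x$dosing$cas9_ul %||% NA_real_
  )
}

#' Minimum gap between consecutive cleavage sites per contig
#'
#' @param sites tibble with `contig` and `cut` columns.
#' @return Smallest gap in bp across all contigs (`Inf` when no contig has
#'   two sites).
#' @export
min_site_spacing <- function(sites) {
  if (nrow(sites) < 2) return(Inf)
  gaps <- sites |>
    group_by(.data$contig) |>
    summarise(g = if (n() > 1) min(diff(sort(.data$cut))) else Inf,
              .groups = "drop")
  min(gaps$g)
}

#' Write and read a guide design
#'
#' `write_guides()` writes the selected guides as a tab-separated table
#' (guide_id, protospacer, on_target_sites, pool, group, nanograms) and,
#' alongside it, a BED track of accepted cleavage sites (score column =
#' the guide's accepted-site count). `read_guides()` reads the table back.
#'
#' @param design a `guide_design`.
#' @param path output TSV path; the BED goes to `sub("\\.tsv$", "", path)`
#'   + `"_sites.bed"` unless `bed_path` is given.
#' @param bed_path optional explicit BED path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(design, path, bed_path = NULL) {
  g <- design$guides
  tab <- tibble(
    guide_id = g$guide_id %||% character(),
    protospacer = g$protospacer %||% character(),
    on_target_sites = g$on_target_sites %||% integer(),
    pool = g$pool %||% rep(NA_integer_, nrow(g)),
    group = g$group %||% rep(NA_integer_, nrow(g)),
    nanograms = g$nanograms %||% rep(NA_real_, nrow(g))
  )
  readr::write_tsv(tab, path)
  bed_path <- bed_path %||% paste0(sub("\\.tsv$", "", path), "_sites.bed")
  if (nrow(design$sites) > 0) {
    counts <- count(design$sites, .data$guide_id, name = "n_sites")
    s <- left_join(design$sites, counts, by = "guide_id")
    readr::write_tsv(
      tibble(contig = s$contig,
             start = format(s$cut, scientific = FALSE, trim = TRUE),
             end = format(s$cut + 1L, scientific = FALSE, trim = TRUE),
             name = s$guide_id, score = s$n_sites,
             strand = s$strand %||% "."),
      bed_path, col_names = FALSE)
  } else {
    file.create(bed_path)
  }
  invisible(path)
}

#' @rdname write_guides
#' @export
read_guides <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    guide_id = "c", protospacer = "c",
                    on_target_sites = "i", pool = "i", group = "i",
                    nanograms = "d"))
}
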