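#' Build a depletion report from placements
#'
#' Computes every evaluation metric from one placement table holding both
#' conditions: per-class read counts and per-sample read-count variation,
#' per-region log2 coverage variation with zero-coverage exclusion
#' bookkeeping, genotypable (PASS) positions in single-copy regions per
#' condition and sample plus the common-position intersection, and — when a
#' cut-site set is supplied — the gRNA-density-versus-depletion relation.
#'
#' @param placements placement tibble with both `condition` values
#'   (`"depleted"`, `"nondepleted"`) and `sample_id`.
#' @param annotation ground-truth/annotation interval tibble.
#' @param genome a [genome_seq()] object.
#' @param sites optional cut-site tibble (`contig`, `cut`) for the density
#'   analysis.
#' @param min_depth PASS depth threshold (default 5).
#' @param density_threshold gRNAs/kbp threshold (default 8).
#' @param repeat_classes see [count_reads_by_class()].
#' @return A `depletion_report`: list with `class_counts`,
#'   `class_variation` (per-sample and mean), `coverage` (per-region values +
#'   `exclusions`), `genotypability` (per condition/sample counts and common
#'   positions), `density` (or NULL), and `params`.
#' @export
evaluate_depletion <- function(placements, annotation, genome, sites = NULL,
                               min_depth = 5L, density_threshold = 8,
                               repeat_classes = NULL) {
  stopifnot(all(c("depleted", "nondepleted") %in% placements$condition))
  counts <- count_reads_by_class(placements, annotation, genome,
                                 repeat_classes = repeat_classes)
  per_sample <- counts |>
    tidyr::pivot_wider(names_from = "condition", values_from = "reads",
                       values_fill = 0L) |>
    mutate(variation = variation_of_mapped_reads(.data$depleted,
                                                 .data$nondepleted))
  class_variation <- per_sample |>
    group_by(.data$class_label) |>
    summarise(mean_variation = mean(.data$variation, na.rm = TRUE),
              n_samples = n(), .groups = "drop")
  # per-region coverage over repeat regions (pooled across samples)
  rep_classes <- repeat_classes %||%
    setdiff(unique(annotation$class_label), c("gene", "atac_peak"))
  regions <- annotation |>
    filter(.data$class_label %in% rep_classes) |>
    mutate(region_id = row_number())
  dep <- filter(placements, .data$condition == "depleted")
  non <- filter(placements, .data$condition == "nondepleted")
  track <- regions |>
    mutate(mean_cov_depleted =
             region_mean_coverage(dep, regions)$mean_cov,
           mean_cov_nondepleted =
             region_mean_coverage(non, regions)$mean_cov)
  coverage <- log2_coverage_variation(track)
  # genotypability over single-copy regions
  sc <- single_copy_regions(genome, annotation)
  geno <- placements |>
    dplyr::group_split(.data$condition, .data$sample_id) |>
    map(function(p) {
      d <- region_depths(p, sc)
      tibble(condition = p$condition[1], sample_id = p$sample_id[1],
             pass_positions = genotypable_positions(d, min_depth),
             pass_set = list(which(d >= min_depth)))
    }) |>
    list_rbind()
  common <- geno |>
    group_by(.data$condition) |>
    summarise(common_positions = if (n() >= 2) {
      common_genotyped_positions(.data$pass_set)
    } else {
      .data$pass_positions[1]
    }, .groups = "drop")
  density <- NULL
  if (!is.null(sites) && nrow(coverage$values) > 0) {
    vals <- coverage$values
    nsites <- integer(nrow(vals))
    for (ctg in unique(vals$contig)) {
      cuts <- sort(sites$cut[sites$contig == ctg])
      sel <- vals$contig == ctg
      if (length(cuts) == 0) next
      nsites[sel] <- findInterval(vals$end[sel] - 0.5, cuts) -
        findInterval(vals$start[sel] - 0.5, cuts)
    }
    dens_tab <- vals |>
      mutate(density = 1000 * nsites / (.data$end - .data$start)) |>
      select("region_id", "class_label", "density", "log2_variation")
    density <- list(table = dens_tab,
                    summary = density_vs_depletion(dens_tab,
                                                   density_threshold))
  }
  structure(list(class_counts = counts,
                 class_variation = class_variation,
                 per_sample_variation = per_sample,
                 coverage = coverage,
                 genotypability = list(per_sample = select(geno, -"pass_set"),
                                       common = common),
                 density = density,
                 params = list(min_depth = as.integer(min_depth),
                               density_threshold = density_threshold)),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat("<depletion_report>\n")
  cat("  mean variation of mapped reads by class:\n")
  print(x$class_variation, n = 15)
  cat("  zero-coverage exclusions: ", x$coverage$exclusions$excluded,
      " of ", x$coverage$exclusions$total, " regions (",
      sprintf("%.1f%%", 100 * x$coverage$exclusions$excluded_fraction),
      ")\n", sep = "")
  invisible(x)
}

#' @rdname evaluate_depletion
#' @param x a `depletion_report`.
#' @param ... unused.
#' @method tidy depletion_report
#' @export
tidy.depletion_report <- function(x, ...) {
  x$per_sample_variation
}

#' @rdname evaluate_depletion
#' @method glance depletion_report
#' @export
glance.depletion_report <- function(x, ...) {
  v <- x$class_variation
  pick <- function(cl) {
    m <- v$mean_variation[v$class_label == cl]
    if (length(m)) m else NA_real_
  }
  geno <- x$genotypability$per_sample |>
    group_by(.data$condition) |>
    summarise(pass = mean(.data$pass_positions), .groups = "drop")
  gd <- geno$pass[geno$condition == "depleted"]
  gn <- geno$pass[geno$condition == "nondepleted"]
  tibble(
    repeat_variation = pick("total_repeats"),
    single_copy_variation = pick("single_copy"),
    excluded_fraction = x$coverage$exclusions$excluded_fraction,
    pass_depleted = if (length(gd)) gd else NA_real_,
    pass_nondepleted = if (length(gn)) gn else NA_real_,
    genotypability_gain = if (length(gd) && length(gn) && gn > 0) {
      gd / gn
    } else {
      NA_real_
    },
    density_correlation = if (!is.null(x$density)) {
      x$density$summary$correlation
    } else {
      NA_real_
    }
  )
}
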