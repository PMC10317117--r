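#' Cut model for depletion simulation
#'
#' A fragment survives depletion when none of the cleavage sites it contains
#' is cut; sites are cut independently with probability `p_cut`. The optional
#' `density_boost` hook lets the effective per-site cut probability depend on
#' the local gRNA density (cleavage sites per kbp of the fragment), emulating
#' the empirical density dependence of depletion efficiency.
#'
#' @param p_cut per-site cut probability in `[0, 1]`.
#' @param density_boost optional `function(p_cut, density_per_kbp)` returning
#'   the effective per-site cut probability (clamped to `[0, 1]`).
#' @return A list of class `cut_model`.
#' @export
cut_model <- function(p_cut, density_boost = NULL) {
  stopifnot(p_cut >= 0, p_cut <= 1)
  structure(list(p_cut = p_cut, density_boost = density_boost),
            class = "cut_model")
}

#' Simulate a random-primed multiplex sequencing library
#'
#' Fragment start positions are uniform over the genome with per-contig
#' sampling weights proportional to contig length times its copy-number
#' weight (so organelles can be over-represented without storing multi-copy
#' sequence). Fragment lengths are normal with mean `insert_mean` and sd
#' `0.15 * insert_mean`, truncated to `[100, 2 * insert_mean]`; fragments are
#' placed entirely within their contig. Samples are assigned round-robin.
#'
#' @param genome a [genome_seq()] object.
#' @param n_fragments number of fragments.
#' @param n_samples number of multiplexed samples.
#' @param insert_mean mean insert size in bp (default 500).
#' @param weights optional named per-contig copy-number weights (default 1).
#' @param seed integer seed.
#' @return Tibble of fragments: `contig`, `start`, `end` (0-based half-open),
#'   `sample_id`.
#' @export
simulate_library <- function(genome, n_fragments, n_samples = 1L,
                             insert_mean = 500L, weights = NULL, seed = 1L) {
  stopifnot(n_fragments > 0)
  lens <- contig_lengths(genome)
  w <- rep(1, length(lens))
  names(w) <- names(lens)
  if (!is.null(weights)) w[names(weights)] <- weights
  prob <- lens * w
  withr::with_seed(seed, {
    ctg <- sample(names(lens), n_fragments, replace = TRUE,
                  prob = prob / sum(prob))
    len <- pmin(pmax(round(rnorm(n_fragments, insert_mean,
                                 0.15 * insert_mean)), 100L),
                2L * insert_mean)
    len <- pmin(len, lens[ctg])  # degenerate tiny contigs
    start <- floor(runif(n_fragments) * (lens[ctg] - len + 1L))
    tibble(contig = unname(ctg), start = as.integer(start),
           end = as.integer(start + len),
           sample_id = paste0("s", rep_len(seq_len(n_samples), n_fragments)))
  })
}

# number of cut positions of `sites` falling in [start, end) per fragment
count_sites_in_fragments <- function(fragments, sites) {
  n <- rep(0L, nrow(fragments))
  for (ctg in unique(fragments$contig)) {
    cuts <- sort(sites$cut[sites$contig == ctg])
    if (length(cuts) == 0) next
    sel <- fragments$contig == ctg
    n[sel] <- findInterval(fragments$end[sel] - 0.5, cuts) -
      findInterval(fragments$start[sel] - 0.5, cuts)
  }
  as.integer(n)
}

#' Apply Cas9 depletion to library fragments
#'
#' Each cleavage site contained in a fragment is cut independently with the
#' model's effective probability; a fragment survives (keeps both adapters
#' and amplifies) only when no contained site is cut, i.e. with probability
#' `(1 - p_eff)^k` for `k` contained sites. With `p_cut = 1`, survival is
#' exactly "contains no site".
#'
#' @param fragments tibble from [simulate_library()].
#' @param sites cut-site tibble (`contig`, `cut`); typically the accepted
#'   sites of a `guide_design`.
#' @param model a [cut_model()].
#' @param seed integer seed.
#' @return `fragments` with columns `n_sites` and `survived`.
#' @export
apply_depletion <- function(fragments, sites, model, seed = 1L) {
  stopifnot(inherits(model, "cut_model"))
  k <- count_sites_in_fragments(fragments, sites)
  p <- rep(model$p_cut, nrow(fragments))
  if (!is.null(model$density_boost)) {
    dens <- 1000 * k / (fragments$end - fragments$start)
    p <- pmin(pmax(model$density_boost(model$p_cut, dens), 0), 1)
  }
  surv_prob <- (1 - p)^k
  withr::with_seed(seed, {
    survived <- runif(nrow(fragments)) < surv_prob
  })
  mutate(fragments, n_sites = k, survived = survived)
}

#' Sample sequenced read placements from a library
#'
#' Draws `n_reads` placements uniformly with replacement: from surviving
#' fragments for the depleted condition, from all fragments for the
#' non-depleted condition. Sampling both conditions to the same `n_reads`
#' normalizes them to the same sequencing input.
#'
#' @param fragments tibble from [apply_depletion()] (non-depleted sampling
#'   also accepts fragments without a `survived` column).
#' @param n_reads number of placements to draw.
#' @param condition `"depleted"` or `"nondepleted"`.
#' @param seed integer seed.
#' @return Placement tibble: `contig`, `start`, `end`, `sample_id`,
#'   `condition`.
#' @export
sample_reads <- function(fragments, n_reads,
                         condition = c("depleted", "nondepleted"),
                         seed = 1L) {
  condition <- match.arg(condition)
  pool <- fragments
  if (condition == "depleted") {
    if (is.null(pool$survived)) abort("run apply_depletion() first")
    pool <- filter(pool, .data$survived)
    if (nrow(pool) == 0) abort("no surviving fragments to sample")
  }
  withr::with_seed(seed, {
    idx <- sample.int(nrow(pool), n_reads, replace = TRUE)
  })
  pool[idx, c("contig", "start", "end", "sample_id")] |>
    mutate(condition = condition)
}
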