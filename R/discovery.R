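# Enumerate every SpCas9 (NGG) protospacer window in the genome, both
# strands. Returns one row per window: contig, cut (0-based coordinate of
# the base immediately 3' of the blunt cut, i.e. between protospacer
# positions 17 and 18, 3 bp from the PAM), strand, protospacer (spacer
# sequence, 5'->3'). Windows whose protospacer or PAM contain a non-ACGT
# base are excluded.
enumerate_pam_windows <- function(genome) {
  out <- imap(genome$seq, function(s, ctg) {
    L <- nchar(s)
    rows <- list()
    # plus strand: PAM = NGG at 1-based q-1..q+1, protospacer q-21..q-2
    gg <- overlapping_match_pos(s, "GG")
    gg <- gg[gg >= 22L & gg + 1L <= L]
    if (length(gg)) {
      proto <- substring(s, gg - 21L, gg - 2L)
      pamN <- substring(s, gg - 1L, gg - 1L)
      ok <- !grepl("N", proto, fixed = TRUE) & pamN != "N"
      rows[["+"]] <- tibble(contig = ctg, cut = gg[ok] - 5L, strand = "+",
                            protospacer = proto[ok])
    }
    # minus strand: plus-strand CCN at p..p+2, protospacer (rev-comp of
    # plus-strand p+3..p+22)
    cc <- overlapping_match_pos(s, "CC")
    cc <- cc[cc + 22L <= L]
    if (length(cc)) {
      plus20 <- substring(s, cc + 3L, cc + 22L)
      pamN <- substring(s, cc + 2L, cc + 2L)
      ok <- !grepl("N", plus20, fixed = TRUE) & pamN != "N"
      if (any(ok)) {
        rows[["-"]] <- tibble(contig = ctg, cut = cc[ok] + 5L, strand = "-",
                              protospacer = revcomp(plus20[ok]))
      }
    }
    list_rbind(rows)
  }) |> list_rbind()
  if (is.null(out) || nrow(out) == 0) {
    return(tibble(contig = character(), cut = integer(),
                  strand = character(), protospacer = character()))
  }
  arrange(out, match(.data$contig, names(genome$seq)), .data$cut)
}

# 1-based start positions of (possibly overlapping) fixed-pattern matches
overlapping_match_pos <- function(s, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), s, perl = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

#' Scan target intervals for candidate Cas9 guides
#'
#' Enumerates all 20-nt protospacers with an adjacent NGG PAM, on both genome
#' strands, whose predicted blunt-cut position (3 bp 5' of the PAM) falls
#' inside a target interval. Candidates are deduplicated by protospacer
#' sequence: one synthesized gRNA is one molecule regardless of how many
#' genomic sites it matches. Windows containing N are skipped.
#'
#' @param genome a [genome_seq()] object.
#' @param targets interval tibble of target (repeat) regions; merged
#'   internally. Interval strand is ignored.
#' @return Tibble of candidates: `guide_id`, `protospacer`, `contig`, `cut`,
#'   `strand` (the discovery site = first site in genome order) and
#'   `n_target_windows` (number of PAM windows in targets carrying this
#'   protospacer).
#' @export
scan_pam_sites <- function(genome, targets) {
  known <- targets$contig %in% names(genome$seq)
  if (any(!known)) {
    warn(paste0("skipping ", sum(!known),
                " target interval(s) on unknown contigs"))
    targets <- targets[known, ]
  }
  win <- enumerate_pam_windows(genome)
  inside <- positions_in_intervals(win$contig, win$cut, targets)
  win <- win[inside, ]
  cand <- win |>
    group_by(.data$protospacer) |>
    summarise(contig = .data$contig[1], cut = .data$cut[1],
              strand = .data$strand[1], n_target_windows = n(),
              .groups = "drop")
  cand <- mutate(cand, guide_id = guide_hash(.data$protospacer)) |>
    select("guide_id", "protospacer", "contig", "cut", "strand",
           "n_target_windows") |>
    arrange(match(.data$contig, names(genome$seq)), .data$cut)
  cand
}

# short, stable id from the protospacer sequence (FNV-1a over bytes);
# guaranteed unique within a set by suffixing rare collisions
guide_hash <- function(proto) {
  h <- vapply(proto, function(p) {
    x <- utf8ToInt(p)
    acc <- 17
    for (b in x) acc <- (acc * 31 + b) %% 268435399
    sprintf("g%07x", acc)
  }, character(1), USE.NAMES = FALSE)
  make.unique(h, sep = "_")
}

#' Locate and count genome-wide cleavage sites of candidate guides
#'
#' Every exact protospacer+NGG match of each candidate is located genome-wide
#' on both strands. Matches whose cut position lies inside a target interval
#' are on-target; candidates with zero on-target sites are dropped.
#'
#' @param candidates tibble from [scan_pam_sites()] (needs `guide_id`,
#'   `protospacer`).
#' @param genome a [genome_seq()] object.
#' @param targets target interval tibble (same set used for scanning).
#' @return List with `candidates` (input rows that retain at least one
#'   on-target site, with `on_target_sites` and `off_interval_sites` counts)
#'   and `sites`, the cut-site index: a tibble (`contig`, `cut`, `strand`,
#'   `guide_id`, `on_target`) sorted by contig and cut position.
#' @export
count_on_target_sites <- function(candidates, genome, targets) {
  win <- enumerate_pam_windows(genome)
  sites <- win |>
    dplyr::inner_join(select(candidates, "guide_id", "protospacer"),
                      by = "protospacer") |>
    mutate(on_target = positions_in_intervals(.data$contig, .data$cut,
                                              targets)) |>
    select("contig", "cut", "strand", "guide_id", "on_target") |>
    arrange(match(.data$contig, names(genome$seq)), .data$cut)
  tally <- sites |>
    group_by(.data$guide_id) |>
    summarise(on_target_sites = sum(.data$on_target),
              off_interval_sites = sum(!.data$on_target), .groups = "drop")
  cand <- candidates |>
    left_join(tally, by = "guide_id") |>
    mutate(on_target_sites = dplyr::coalesce(.data$on_target_sites, 0L),
           off_interval_sites = dplyr::coalesce(.data$off_interval_sites, 0L)) |>
    filter(.data$on_target_sites >= 1L)
  sites <- filter(sites, .data$guide_id %in% cand$guide_id)
  list(candidates = cand, sites = sites)
}
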