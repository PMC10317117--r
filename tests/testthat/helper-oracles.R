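# Independent brute-force oracles used to validate the optimized paths.
# These deliberately avoid the package's scanning/matching internals.

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, "", fixed = TRUE),
                                function(ch) paste(rev(ch), collapse = ""),
                                character(1)))
}

# naive sliding-window PAM scan over both strands; returns all windows
# (contig, cut, strand, protospacer), no interval restriction
oracle_pam_windows <- function(seqs) {
  out <- list()
  for (ctg in names(seqs)) {
    s <- seqs[[ctg]]
    L <- nchar(s)
    for (i in seq_len(max(0L, L - 22L))) {   # 1-based window start
      w <- substr(s, i, i + 22L)
      core <- substr(w, 1, 20)
      if (!grepl("[^ACGT]", core) && substr(w, 22, 23) == "GG" &&
          !grepl("[^ACGT]", substr(w, 21, 21))) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, cut = (i - 1L) + 17L, strand = "+",
          protospacer = core)
      }
      if (substr(w, 1, 2) == "CC" && !grepl("[^ACGT]", substr(w, 3, 3)) &&
          !grepl("[^ACGT]", substr(w, 4, 23))) {
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, cut = (i - 1L) + 6L, strand = "-",
          protospacer = oracle_revcomp(substr(w, 4, 23)))
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(), cut = integer(),
                      strand = character(), protospacer = character()))
  }
  do.call(rbind, out)
}

# per-offset Hamming distances of `pattern` against every 20-mer of `s`,
# computed with indicator vectors (no string matching library involved)
oracle_mismatch_profile <- function(pattern, s) {
  x <- utf8ToInt(s)
  p <- utf8ToInt(pattern)
  w <- length(p)
  L <- length(x)
  if (L < w) return(integer())
  mm <- integer(L - w + 1L)
  for (k in seq_len(w)) {
    mm <- mm + (x[k:(L - w + k)] != p[k])
  }
  mm
}

# naive mismatch-tolerant off-target count for one guide: all positions on
# either strand with Hamming distance <= max_mm, adjacent NGG (unless
# pam_free), 23-mer overlapping a protected interval
oracle_offtarget_hits <- function(proto, seqs, protected, max_mm = 3,
                                  require_pam = TRUE) {
  hits <- 0L
  overlaps <- function(ctg, s0, e0) {
    p <- protected[protected$contig == ctg, , drop = FALSE]
    any(p$start < e0 & p$end > s0)
  }
  for (ctg in names(seqs)) {
    s <- seqs[[ctg]]
    L <- nchar(s)
    # plus strand
    mm <- oracle_mismatch_profile(proto, s)
    for (i in which(mm <= max_mm)) {
      if (i + 22L > L) next
      if (require_pam && substr(s, i + 21L, i + 22L) != "GG") next
      if (overlaps(ctg, i - 1L, i + 22L)) hits <- hits + 1L
    }
    # minus strand
    mm <- oracle_mismatch_profile(oracle_revcomp(proto), s)
    for (i in which(mm <= max_mm)) {
      if (i < 4L) next
      if (require_pam && substr(s, i - 3L, i - 2L) != "CC") next
      if (overlaps(ctg, i - 4L, i + 19L)) hits <- hits + 1L
    }
  }
  hits
}

# exhaustive hairpin-stem oracle: all (start1, start2, length) triples
oracle_hairpin <- function(s) {
  n <- nchar(s)
  best <- 0L
  for (l in seq_len(n %/% 2L)) {
    for (i in seq_len(n - l + 1L)) {
      for (j in seq_len(n - l + 1L)) {
        if (j < i + l + 3L) next   # loop gap >= 3 between s1 end and s2 start
        if (substr(s, j, j + l - 1L) ==
            oracle_revcomp(substr(s, i, i + l - 1L))) {
          best <- max(best, l)
        }
      }
    }
  }
  best
}

# exhaustive fragment-enumeration footprint oracle: position p (0-based) is
# targetable iff no insert-length fragment inside the contig covers p without
# containing a cut position
oracle_footprint <- function(cuts, L, insert) {
  cutset <- rep(FALSE, L)
  cutset[cuts + 1L] <- TRUE
  targetable <- 0L
  for (p in 0:(L - 1L)) {
    escape <- FALSE
    s_lo <- max(0L, p - insert + 1L)
    s_hi <- min(p, L - insert)
    if (s_hi >= s_lo) {
      for (s in s_lo:s_hi) {
        if (!any(cutset[(s + 1L):(s + insert)])) {
          escape <- TRUE
          break
        }
      }
    }
    if (!escape) targetable <- targetable + 1L
  }
  targetable
}

# exhaustive maximum spaced subset (for validating the greedy thinning)
oracle_max_spaced_subset <- function(pos, spacing) {
  n <- length(pos)
  best <- 0L
  for (mask in 0:(2^n - 1L)) {
    sel <- pos[bitwAnd(bitwShiftR(mask, seq_len(n) - 1L), 1L) == 1L]
    if (length(sel) < 2L || all(diff(sort(sel)) >= spacing)) {
      best <- max(best, length(sel))
    }
  }
  best
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_genome <- function(...) {
  genome_seq(c(...))
}

iv <- function(contig, start, end, class_label = "region", strand = ".") {
  tibble::tibble(contig = contig, start = as.integer(start),
                 end = as.integer(end), class_label = class_label,
                 strand = strand)
}

# the seeded synthetic design run shared by the acceptance checks: computed
# once per test session
acceptance_design_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_genome_spec(seed = 42)
      syn <- generate_genome(spec)
      targets <- dplyr::filter(syn$annotation,
                               !class_label %in% c("gene", "atac_peak"))
      protected <- dplyr::filter(syn$annotation,
                                 class_label %in% c("gene", "atac_peak"))
      design <- suppressWarnings(suppressMessages(
        design_guides(syn$genome, targets, protected)))
      cache <<- list(spec = spec, syn = syn, targets = targets,
                     protected = protected, design = design)
    }
    cache
  }
})
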