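#' Guide filter configuration
#'
#' Thresholds for the sequence-quality filter cascade and the off-target
#' exclusion. The filter cascade removes guides with extreme GC content,
#' long homopolymers, dinucleotide repeats, self-complementary (hairpin)
#' stems, or a low predicted cleavage-efficiency score; surviving guides are
#' then screened against protected regions (genes, open chromatin) allowing
#' mismatches.
#'
#' @param gc_min,gc_max admissible GC fraction range (inclusive).
#' @param max_homopolymer longest admissible single-base run; a guide fails
#'   when its run is strictly longer.
#' @param max_dinucleotide_repeat longest admissible repetition (in units) of
#'   a 2-mer with two distinct bases; fails when strictly exceeded.
#' @param max_hairpin_stem a guide fails when it contains a self-pairing stem
#'   of at least this many base pairs (loop >= 3 nt).
#' @param efficiency_min minimum predicted efficiency score in `[0, 1]`.
#' @param offtarget_max_mismatches Hamming-distance tolerance of the
#'   protected-region off-target search (default 3).
#' @param pam_free_offtarget if `TRUE`, off-target hits are counted without
#'   requiring an adjacent NGG PAM (a stricter reading of "complementary
#'   sites"); default `FALSE`, matching Cas9 biochemistry.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(gc_min = 0.25, gc_max = 0.75,
                          max_homopolymer = 4L,
                          max_dinucleotide_repeat = 4L,
                          max_hairpin_stem = 6L,
                          efficiency_min = 0.2,
                          offtarget_max_mismatches = 3L,
                          pam_free_offtarget = FALSE) {
  stopifnot(gc_min >= 0, gc_min < gc_max, gc_max <= 1,
            offtarget_max_mismatches >= 0)
  structure(list(gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 max_dinucleotide_repeat = as.integer(max_dinucleotide_repeat),
                 max_hairpin_stem = as.integer(max_hairpin_stem),
                 efficiency_min = efficiency_min,
                 offtarget_max_mismatches = as.integer(offtarget_max_mismatches),
                 pam_free_offtarget = isTRUE(pam_free_offtarget)),
            class = "filter_config")
}

#' GC fraction of protospacers
#'
#' @param protospacer character vector of 20-nt A/C/G/T strings.
#' @return Numeric vector: (#G + #C) / 20.
#' @export
gc_content <- function(protospacer) {
  stringr::str_count(protospacer, "[GC]") / nchar(protospacer)
}

# 20-nt strings -> integer matrix (rows = guides, 20 columns of A/C/G/T codes)
proto_matrix <- function(protospacer) {
  n <- length(protospacer)
  if (n == 0) return(matrix(integer(), 0, 20))
  m <- matrix(utf8ToInt(paste(protospacer, collapse = "")),
              nrow = n, ncol = nchar(protospacer[1]), byrow = TRUE)
  m
}

#' Longest homopolymer run and dinucleotide repeat
#'
#' `max_homopolymer_run()` returns the length of the longest single-base run.
#' `max_dinucleotide_units()` returns the maximal number of consecutive
#' repetitions of any 2-mer composed of two distinct bases (so `ATATAT` is 3
#' units, and a pure homopolymer scores 1).
#'
#' @param protospacer character vector of equal-length A/C/G/T strings.
#' @return Integer vector.
#' @export
max_homopolymer_run <- function(protospacer) {
  m <- proto_matrix(protospacer)
  if (nrow(m) == 0) return(integer())
  w <- ncol(m)
  cur <- rep(1L, nrow(m)); best <- cur
  for (k in seq_len(w - 1L)) {
    same <- m[, k + 1L] == m[, k]
    cur <- ifelse(same, cur + 1L, 1L)
    best <- pmax(best, cur)
  }
  as.integer(best)
}

#' @rdname max_homopolymer_run
#' @export
max_dinucleotide_units <- function(protospacer) {
  m <- proto_matrix(protospacer)
  if (nrow(m) == 0) return(integer())
  w <- ncol(m)
  # run of positions k where base k+2 repeats base k AND bases k, k+1 differ;
  # a run of length r corresponds to floor(r / 2) + 1 repeat units
  cur <- rep(0L, nrow(m)); best <- cur
  for (k in seq_len(w - 2L)) {
    # the unit must be a two-distinct-base 2-mer along the whole run;
    # breaking whenever adjacent bases are equal enforces that
    ok <- (m[, k + 2L] == m[, k]) & (m[, k] != m[, k + 1L])
    cur <- ifelse(ok, cur + 1L, 0L)
    best <- pmax(best, cur)
  }
  as.integer(best %/% 2L + 1L)
}

#' Longest self-complementary (hairpin) stem of a protospacer
#'
#' Length of the longest contiguous stem formed by two non-overlapping
#' substrings of the guide (the 3' one the reverse complement of the 5' one)
#' separated by a loop of at least 3 nt. Computed by dynamic programming over
#' complementary position pairs.
#'
#' @param protospacer character vector of equal-length A/C/G/T strings.
#' @return Integer vector of stem lengths (0 when nothing can pair).
#' @export
hairpin_stem <- function(protospacer) {
  m <- proto_matrix(protospacer)
  n <- nrow(m)
  if (n == 0) return(integer())
  w <- ncol(m)
  comp <- m
  codes <- utf8ToInt("ACGT")
  compc <- utf8ToInt("TGCA")
  for (i in 1:4) comp[m == codes[i]] <- compc[i]
  # D[, i, j] = length of contiguous inward pairing starting at outer pair
  # (i, j); stem usable at (i, j) = min(D, floor((j - i - 2) / 2))
  best <- rep(0L, n)
  D <- array(0L, dim = c(n, w, w))
  for (i in seq(w - 1L, 1L)) {
    for (j in seq(i + 1L, w)) {
      pair <- m[, i] == comp[, j]
      inner <- if (i + 1L <= j - 1L) D[, i + 1L, j - 1L] else rep(0L, n)
      D[, i, j] <- ifelse(pair, 1L + inner, 0L)
      cap <- (j - i - 2L) %/% 2L
      if (cap > 0L) best <- pmax(best, pmin(D[, i, j], cap))
    }
  }
  as.integer(best)
}

#' Heuristic cleavage-efficiency score
#'
#' A deterministic position-weight heuristic standing behind the pluggable
#' scorer interface: an optimum-GC bonus peaking at 50% GC plus a weight on
#' the PAM-proximal base (position 20; G rewarded, T penalised). Scores lie
#' in `[0.15, 0.85]`; changing the position-20 base from T to G never
#' decreases the score. Any function with the same signature can replace it
#' in [apply_guide_filters()].
#'
#' @param protospacer character vector of 20-nt guides.
#' @param context optional character vector of 30-nt windows (4 nt upstream +
#'   protospacer + 3-nt PAM + 3 nt downstream); `NA` where the window was
#'   truncated at a contig edge, in which case the guide receives the neutral
#'   score 0.5.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
efficiency_score <- function(protospacer, context = NULL) {
  gc <- gc_content(protospacer)
  last <- substring(protospacer, nchar(protospacer), nchar(protospacer))
  w20 <- c(G = 0.15, C = 0.05, A = -0.05, T = -0.15)[last]
  score <- 0.3 + 0.4 * (1 - 4 * (gc - 0.5)^2) + unname(w20)
  score <- pmin(pmax(score, 0), 1)
  if (!is.null(context)) score[is.na(context)] <- 0.5
  score
}

#' Mismatch-tolerant off-target hits of one guide in protected regions
#'
#' Counts genomic positions, on either strand, where the guide matches a
#' 20-mer within `max_mm` mismatches (Hamming distance), an NGG PAM is
#' adjacent, and the protospacer+PAM 23-mer overlaps a protected interval.
#' A guide with any such hit is excluded from the design.
#'
#' @param protospacer single 20-nt guide sequence.
#' @param genome a [genome_seq()] object.
#' @param protected interval tibble (genes + open chromatin), any overlap of
#'   the 23-mer counts.
#' @param max_mm mismatch tolerance (default 3).
#' @param require_pam require the adjacent NGG (default `TRUE`).
#' @return Integer hit count.
#' @export
offtarget_hits <- function(protospacer, genome, protected, max_mm = 3L,
                           require_pam = TRUE) {
  stopifnot(length(protospacer) == 1L)
  hits <- 0L
  for (ctg in names(genome$seq)) {
    subj <- Biostrings::DNAString(genome$seq[[ctg]])
    L <- length(subj)
    # plus strand
    m <- Biostrings::matchPattern(protospacer, subj, max.mismatch = max_mm)
    st <- Biostrings::start(m)
    ok <- st + 22L <= L
    st <- st[ok]
    if (length(st) && require_pam) {
      pam <- substring(genome$seq[[ctg]], st + 21L, st + 22L)
      st <- st[pam == "GG"]
    }
    if (length(st)) {
      keep <- ranges_overlap_intervals(rep(ctg, length(st)), st - 1L,
                                       st + 22L, protected)
      hits <- hits + sum(keep)
    }
    # minus strand: match the reverse complement on the plus sequence,
    # PAM = CCN immediately 5' of the match
    m <- Biostrings::matchPattern(revcomp(protospacer), subj,
                                  max.mismatch = max_mm)
    st <- Biostrings::start(m)
    ok <- st >= 4L
    st <- st[ok]
    if (length(st) && require_pam) {
      pam <- substring(genome$seq[[ctg]], st - 3L, st - 2L)
      st <- st[pam == "CC"]
    }
    if (length(st)) {
      keep <- ranges_overlap_intervals(rep(ctg, length(st)), st - 4L,
                                       st + 19L, protected)
      hits <- hits + sum(keep)
    }
  }
  hits
}

# Batched off-target search for many guides: pigeonhole over four disjoint
# 5-nt trusted bands (any hit with <= 3 mismatches is exact in at least one
# band), each band searched with Biostrings::matchPDict allowing max_mm
# mismatches outside the band; the union over bands is the complete hit set.
# Returns the per-guide count of PAM-valid hits whose 23-mer overlaps a
# protected interval.
batch_offtarget_hits <- function(protospacer, genome, protected,
                                 max_mm = 3L, require_pam = TRUE) {
  nG <- length(protospacer)
  counts <- rep(0L, nG)
  if (nG == 0 || nrow(protected) == 0) return(counts)
  w <- nchar(protospacer[1])
  n_bands <- max_mm + 1L
  band <- floor(seq(0, w, length.out = n_bands + 1L))
  fwd <- Biostrings::DNAStringSet(protospacer)
  rev <- Biostrings::reverseComplement(fwd)
  for (ctg in names(genome$seq)) {
    prot_ctg <- protected[protected$contig == ctg, ]
    if (nrow(prot_ctg) == 0) next
    subj <- Biostrings::DNAString(genome$seq[[ctg]])
    L <- length(subj)
    for (dict in list(list(set = fwd, strand = "+"),
                      list(set = rev, strand = "-"))) {
      hit_g <- integer(); hit_s <- integer()
      for (b in seq_len(n_bands)) {
        pd <- Biostrings::PDict(dict$set, tb.start = band[b] + 1L,
                                tb.end = band[b + 1L])
        m <- Biostrings::matchPDict(pd, subj, max.mismatch = max_mm)
        st <- Biostrings::startIndex(m)
        len <- lengths(st)
        if (sum(len) == 0) next
        hit_g <- c(hit_g, rep(seq_len(nG), len))
        hit_s <- c(hit_s, unlist(st, use.names = FALSE))
      }
      if (length(hit_g) == 0) next
      keep <- !duplicated(cbind(hit_g, hit_s))
      hit_g <- hit_g[keep]; hit_s <- hit_s[keep]
      if (dict$strand == "+") {
        ok <- hit_s + 22L <= L
        hit_g <- hit_g[ok]; hit_s <- hit_s[ok]
        if (require_pam && length(hit_s)) {
          pam <- substring(genome$seq[[ctg]], hit_s + 21L, hit_s + 22L)
          hit_g <- hit_g[pam == "GG"]; hit_s <- hit_s[pam == "GG"]
        }
        span0 <- hit_s - 1L; span1 <- hit_s + 22L
      } else {
        ok <- hit_s >= 4L
        hit_g <- hit_g[ok]; hit_s <- hit_s[ok]
        if (require_pam && length(hit_s)) {
          pam <- substring(genome$seq[[ctg]], hit_s - 3L, hit_s - 2L)
          hit_g <- hit_g[pam == "CC"]; hit_s <- hit_s[pam == "CC"]
        }
        span0 <- hit_s - 4L; span1 <- hit_s + 19L
      }
      if (length(hit_g) == 0) next
      inprot <- ranges_overlap_intervals(rep(ctg, length(hit_g)),
                                         span0, span1, prot_ctg)
      if (any(inprot)) {
        tab <- table(hit_g[inprot])
        idx <- as.integer(names(tab))
        counts[idx] <- counts[idx] + as.integer(tab)
      }
    }
  }
  counts
}

#' Apply the guide filter cascade
#'
#' Evaluates the sequence-quality filters (GC, homopolymer, dinucleotide
#' repeat, hairpin stem, efficiency score) and then the mismatch-tolerant
#' off-target exclusion against protected regions. The off-target search is
#' skipped (hits recorded as `NA`) for guides that already fail a sequence
#' filter; a guide passes overall iff every sequence flag passes and it has
#' zero protected-region off-target hits.
#'
#' @param candidates tibble with `guide_id`, `protospacer` and discovery-site
#'   columns (`contig`, `cut`, `strand`) from [scan_pam_sites()].
#' @param genome a [genome_seq()] object.
#' @param protected interval tibble of protected regions (merged internally).
#' @param config a [filter_config()].
#' @param scorer efficiency scorer, any function
#'   `(protospacer, context) -> [0, 1]`; defaults to [efficiency_score()].
#' @return Tibble of verdicts: one row per candidate with measured values,
#'   per-filter `pass_*` flags, `offtarget_hits` and overall `pass`.
#' @export
apply_guide_filters <- function(candidates, genome, protected,
                                config = filter_config(),
                                scorer = efficiency_score) {
  if (nrow(candidates) == 0) {
    return(tibble(guide_id = character(), protospacer = character(),
                  gc = numeric(), homopolymer_run = integer(),
                  dinucleotide_units = integer(), hairpin = integer(),
                  efficiency = numeric(), pass_gc = logical(),
                  pass_homopolymer = logical(), pass_dinucleotide = logical(),
                  pass_hairpin = logical(), pass_efficiency = logical(),
                  offtarget_hits = integer(), pass_offtarget = logical(),
                  pass = logical()))
  }
  ctx <- discovery_context(candidates, genome)
  v <- tibble(
    guide_id = candidates$guide_id,
    protospacer = candidates$protospacer,
    gc = gc_content(candidates$protospacer),
    homopolymer_run = max_homopolymer_run(candidates$protospacer),
    dinucleotide_units = max_dinucleotide_units(candidates$protospacer),
    hairpin = hairpin_stem(candidates$protospacer),
    efficiency = scorer(candidates$protospacer, ctx)
  ) |>
    mutate(
      pass_gc = .data$gc >= config$gc_min & .data$gc <= config$gc_max,
      pass_homopolymer = .data$homopolymer_run <= config$max_homopolymer,
      pass_dinucleotide =
        .data$dinucleotide_units <= config$max_dinucleotide_repeat,
      pass_hairpin = .data$hairpin < config$max_hairpin_stem,
      pass_efficiency = .data$efficiency >= config$efficiency_min
    )
  seq_pass <- v$pass_gc & v$pass_homopolymer & v$pass_dinucleotide &
    v$pass_hairpin & v$pass_efficiency
  hits <- rep(NA_integer_, nrow(v))
  if (any(seq_pass)) {
    prot <- merge_intervals(protected, by_class = FALSE)
    hits[seq_pass] <- batch_offtarget_hits(
      candidates$protospacer[seq_pass], genome, prot,
      max_mm = config$offtarget_max_mismatches,
      require_pam = !config$pam_free_offtarget)
  }
  if (sum(!seq_pass) > 0) {
    inform(paste0("off-target search skipped for ", sum(!seq_pass),
                  " guide(s) failing sequence filters"))
  }
  v |>
    mutate(offtarget_hits = hits,
           pass_offtarget = !is.na(hits) & hits == 0L,
           pass = seq_pass & .data$pass_offtarget)
}

# 30-nt scoring context (4 nt upstream + protospacer + PAM + 3 nt downstream)
# at each candidate's discovery site; NA where truncated by a contig edge
discovery_context <- function(candidates, genome) {
  len <- contig_lengths(genome)[candidates$contig]
  out <- rep(NA_character_, nrow(candidates))
  plus <- candidates$strand == "+"
  # plus strand: protospacer starts at 0-based cut - 17
  s0 <- candidates$cut - 17L
  from <- s0 - 4L + 1L           # 1-based
  to <- s0 + 26L                 # 20 + 3 PAM + 3 down
  ok <- plus & from >= 1L & to <= len
  out[ok] <- substring(genome$seq[candidates$contig[ok]], from[ok], to[ok])
  # minus strand: plus-strand span [cut - 6, cut + 17) holds PAM+protospacer
  from_m <- candidates$cut - 6L - 3L + 1L   # 3 nt "downstream" in guide frame
  to_m <- candidates$cut + 17L + 4L
  okm <- !plus & from_m >= 1L & to_m <= len
  out[okm] <- revcomp(substring(genome$seq[candidates$contig[okm]],
                                from_m[okm], to_m[okm]))
  out
}
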