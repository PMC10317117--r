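#' Specification of a synthetic genome
#'
#' Describes a small genome with the structure the depletion method assumes:
#' a nuclear contig carrying planted, diverged repeat families plus genes and
#' open-chromatin (ATAC-peak) intervals, and two organelle contigs sampled at
#' elevated copy number. Repeat copies never overlap genes or open chromatin,
#' mirroring a design that excludes repetitive DNA overlapping functional
#' regions. Defaults give a ~200-kb nuclear genome that is ~72% repetitive,
#' with LTR-retrotransposon-dominated families of 50-100 copies diverged at
#' 2-5% — a down-scaled caricature of a large, highly repetitive plant
#' genome.
#'
#' @param nuclear_length nuclear contig length in bp.
#' @param repeat_families tibble with columns `class_label`,
#'   `consensus_length`, `copies`, `divergence` (per-base substitution rate
#'   applied independently to each copy).
#' @param n_genes,gene_length_mean number of genes and mean length (lengths
#'   are uniform in `[0.5, 1.5] *` mean).
#' @param n_atac,atac_length number and fixed length of open-chromatin peaks.
#' @param chloroplast_length,mitochondrion_length organelle contig lengths.
#' @param chloroplast_weight,mitochondrion_weight per-base sampling weights of
#'   the organelle contigs relative to nuclear DNA, modelling their effective
#'   per-cell representation. Defaults give organelles ~1% of sampled reads:
#'   at this scale the organelle contigs are proportionally much larger
#'   relative to the nuclear contig than in a real plant genome, so the
#'   weights sit below 1 (in a full-size genome the same read share requires
#'   weights far above 1).
#' @param seed integer seed making generation deterministic.
#' @return A list of class `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(
    nuclear_length = 200000L,
    repeat_families = tibble(
      class_label = c("LTR_Gypsy", "LTR_Copia", "LINE"),
      consensus_length = c(1200L, 800L, 400L),
      copies = c(70L, 50L, 50L),
      divergence = c(0.03, 0.05, 0.02)),
    n_genes = 20L, gene_length_mean = 1000L,
    n_atac = 30L, atac_length = 300L,
    chloroplast_length = 20000L, mitochondrion_length = 30000L,
    chloroplast_weight = 0.05, mitochondrion_weight = 0.03,
    seed = 1L) {
  spec <- list(nuclear_length = as.integer(nuclear_length),
               repeat_families = as_tibble(repeat_families),
               n_genes = as.integer(n_genes),
               gene_length_mean = as.integer(gene_length_mean),
               n_atac = as.integer(n_atac),
               atac_length = as.integer(atac_length),
               chloroplast_length = as.integer(chloroplast_length),
               mitochondrion_length = as.integer(mitochondrion_length),
               chloroplast_weight = chloroplast_weight,
               mitochondrion_weight = mitochondrion_weight,
               seed = as.integer(seed))
  class(spec) <- "synthetic_genome_spec"
  spec
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# mutate a consensus string with i.i.d. substitutions at rate `div`
diverge_copy <- function(consensus, div) {
  if (div <= 0) return(consensus)
  n <- nchar(consensus)
  hit <- which(runif(n) < div)
  if (length(hit) == 0) return(consensus)
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with ground-truth annotation
#'
#' Features (repeat copies, genes, ATAC peaks) are laid out without overlap
#' in a random order along the nuclear contig, with the remaining sequence
#' filled by random single-copy DNA distributed as random-length gaps between
#' features, so the planted repeat fraction is exact by construction.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return List with `genome` (a [genome_seq()]; contigs `nuc1`,
#'   `chloroplast`, `mitochondrion`), `annotation` (ground-truth interval
#'   tibble: repeat classes, `gene`, `atac_peak`), and `weights` (per-contig
#'   sampling weights for library simulation).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  withr::with_seed(spec$seed, {
    fam <- spec$repeat_families
    # one consensus per family
    fam$consensus <- map_chr(fam$consensus_length, random_dna)
    feat <- list()
    for (i in seq_len(nrow(fam))) {
      feat[[length(feat) + 1L]] <- tibble(
        class_label = fam$class_label[i],
        seq = map_chr(seq_len(fam$copies[i]),
                      ~ diverge_copy(fam$consensus[i], fam$divergence[i])))
    }
    if (spec$n_genes > 0) {
      glen <- as.integer(round(runif(spec$n_genes,
                                     0.5 * spec$gene_length_mean,
                                     1.5 * spec$gene_length_mean)))
      feat[[length(feat) + 1L]] <- tibble(class_label = "gene",
                                          seq = map_chr(glen, random_dna))
    }
    if (spec$n_atac > 0) {
      feat[[length(feat) + 1L]] <- tibble(
        class_label = "atac_peak",
        seq = map_chr(rep(spec$atac_length, spec$n_atac), random_dna))
    }
    features <- list_rbind(feat)
    features <- features[sample.int(nrow(features)), ]
    used <- sum(nchar(features$seq))
    leftover <- spec$nuclear_length - used
    if (leftover < 0) {
      abort(paste0("requested features (", used,
                   " bp) exceed nuclear length (", spec$nuclear_length, ")"))
    }
    # single-copy filler split into random gaps around the features
    n_gaps <- nrow(features) + 1L
    gaps <- as.vector(rmultinom(1, leftover, rep(1, n_gaps)))
    pieces <- character(2L * nrow(features) + 1L)
    ann <- vector("list", nrow(features))
    pos <- 0L
    for (i in seq_len(nrow(features))) {
      pieces[2L * i - 1L] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      pieces[2L * i] <- features$seq[i]
      ann[[i]] <- tibble(contig = "nuc1", start = pos,
                         end = pos + nchar(features$seq[i]),
                         class_label = features$class_label[i],
                         strand = ".")
      pos <- pos + nchar(features$seq[i])
    }
    pieces[2L * nrow(features) + 1L] <- random_dna(gaps[n_gaps])
    nuc <- paste(pieces, collapse = "")
    chl <- random_dna(spec$chloroplast_length)
    mit <- random_dna(spec$mitochondrion_length)
    genome <- genome_seq(
      c(nuc1 = nuc, chloroplast = chl, mitochondrion = mit),
      compartment = c(nuc1 = "nuclear", chloroplast = "chloroplast",
                      mitochondrion = "mitochondrial"))
    annotation <- arrange(list_rbind(ann), .data$start)
    weights <- c(nuc1 = 1, chloroplast = spec$chloroplast_weight,
                 mitochondrion = spec$mitochondrion_weight)
    list(genome = genome, annotation = annotation, weights = weights)
  })
}
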