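#' Genome sequence container
#'
#' A light container for a (small) genome held in memory: one uppercase
#' nucleotide string per contig, a compartment label per contig
#' (`nuclear`, `chloroplast` or `mitochondrial`), and the softmasked
#' (lowercase-in-FASTA) stretches kept as an interval tibble. Softmasked
#' bases are *not* treated as repeat annotation anywhere in the pipeline;
#' only explicit interval files define targets.
#'
#' @param seq named character vector of uppercase sequences (A/C/G/T/N;
#'   any other IUPAC character is converted to N).
#' @param compartment named character vector parallel to `seq`; defaults
#'   to `"nuclear"` for every contig.
#' @param softmask tibble with columns `contig`, `start`, `end`
#'   (0-based half-open) marking softmasked stretches.
#'
#' @return An object of class `genome_seq`.
#' @export
genome_seq <- function(seq, compartment = NULL, softmask = NULL) {
  if (is.null(names(seq)) || anyNA(names(seq)) || any(names(seq) == "")) {
    abort("every contig must be named")
  }
  if (anyDuplicated(names(seq))) {
    abort(paste0("duplicate contig name: ",
                 names(seq)[duplicated(names(seq))][1]))
  }
  if (any(nchar(seq) == 0L)) abort("empty sequence record")
  seq <- toupper(seq)
  # collapse every non-ACGT IUPAC character to N
  seq <- setNames(gsub("[^ACGT]", "N", seq), names(seq))
  compartment <- compartment %||%
    setNames(rep("nuclear", length(seq)), names(seq))
  stopifnot(all(names(seq) %in% names(compartment)))
  softmask <- softmask %||% tibble(contig = character(), start = integer(),
                                   end = integer())
  structure(list(seq = seq, compartment = compartment[names(seq)],
                 softmask = softmask),
            class = "genome_seq")
}

#' @export
print.genome_seq <- function(x, ...) {
  cat("<genome_seq> ", length(x$seq), " contig(s), ",
      format(sum(contig_lengths(x)), big.mark = ","), " bp\n", sep = "")
  df <- tibble(contig = names(x$seq), length = unname(nchar(x$seq)),
               compartment = unname(x$compartment))
  print(df, n = 10)
  invisible(x)
}

#' Contig lengths of a genome
#'
#' @param genome a [genome_seq()] object.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  setNames(nchar(genome$seq), names(genome$seq))
}

#' Read a genome from a FASTA file
#'
#' Sequences are uppercased on read; lowercase (softmasked) stretches are
#' preserved as an interval mask on the returned object. Contig order follows
#' the file. Compartment labels are inferred from contig names by regex
#' (overridable).
#'
#' @param path FASTA file.
#' @param organelle_patterns named character vector of regexes matched
#'   (case-insensitively) against contig names; names are compartment labels.
#' @return A [genome_seq()] object.
#' @export
read_genome_fasta <- function(path,
                              organelle_patterns = c(
                                chloroplast = "chloro|cpdna|^chr?c$|plastid",
                                mitochondrial = "mito|mtdna|^chr?m$")) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(nm)) abort(paste0("duplicate contig name: ",
                                      nm[duplicated(nm)][1]))
  if (any(Biostrings::width(raw) == 0L)) abort("empty FASTA record")
  chr <- setNames(as.character(raw), nm)
  # softmask = runs of lowercase letters, recorded 0-based half-open
  softmask <- imap(chr, function(s, ctg) {
    m <- gregexpr("[a-z]+", s)[[1]]
    if (m[1] == -1L) return(NULL)
    tibble(contig = ctg, start = as.integer(m) - 1L,
           end = as.integer(m) + attr(m, "match.length") - 1L)
  }) |> list_rbind()
  comp <- setNames(rep("nuclear", length(chr)), nm)
  for (lab in names(organelle_patterns)) {
    comp[grepl(organelle_patterns[[lab]], nm, ignore.case = TRUE)] <- lab
  }
  genome_seq(chr, comp, softmask)
}

#' Write a genome to a FASTA file
#'
#' @param genome a [genome_seq()] object.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(genome$seq)) {
    writeLines(paste0(">", ctg), con)
    s <- genome$seq[[ctg]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# reverse complement for plain character vectors (vectorised, C speed)
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
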