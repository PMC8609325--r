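#' Construct a karyotype
#'
#' A karyotype bundles a species' chromosome table with the clade-specific
#' size threshold that separates microchromosomes from macrochromosomes
#' (35 Mb for birds and snakes; larger for turtles, rearranged lizards, tegu
#' and alligator) and the expected haploid chromosome number from cytology.
#'
#' @param species Species identifier.
#' @param chromosomes A data.frame with at least columns `name` (unique
#'   identifiers) and `length` (bp, > 0). Optional columns: `gc` (fraction in
#'   \[0,1\]), `n_genes` (non-negative integer), `chrom_class` (`"macro"`,
#'   `"micro"` or `"unassigned"`), `centromere` (bp position or `NA`).
#' @param micro_threshold Size threshold in bp: chromosomes strictly smaller
#'   are microchromosomes. May be `NA` if explicit `chrom_class` labels are
#'   supplied.
#' @param expected_n Expected haploid chromosome number (cytological n);
#'   defaults to the number of rows.
#' @return An object of class `karyotype`.
#' @export
karyotype <- function(species, chromosomes, micro_threshold = NA_real_,
                      expected_n = nrow(chromosomes)) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  if (anyDuplicated(chromosomes$name))
    stop("chromosome names must be unique")
  if (any(chromosomes$length <= 0))
    stop("chromosome lengths must be positive")
  if (!is.na(micro_threshold) && micro_threshold <= 0)
    stop("micro_threshold must be positive")
  if (expected_n < 1) stop("expected_n must be >= 1")
  for (col in c("gc", "n_genes", "centromere"))
    if (is.null(chromosomes[[col]])) chromosomes[[col]] <- NA_real_
  if (is.null(chromosomes$chrom_class))
    chromosomes$chrom_class <- "unassigned"
  bad_gc <- !is.na(chromosomes$gc) &
    (chromosomes$gc < 0 | chromosomes$gc > 1)
  if (any(bad_gc)) stop("gc values must lie in [0, 1]")
  structure(list(species = species,
                 chromosomes = chromosomes,
                 micro_threshold = as.numeric(micro_threshold),
                 expected_n = as.integer(expected_n)),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cl <- table(factor(x$chromosomes$chrom_class,
                     levels = c("macro", "micro", "unassigned")))
  cat(sprintf("karyotype of %s: %d chromosomes (%d macro, %d micro, %d unassigned)\n",
              x$species, nrow(x$chromosomes), cl[["macro"]], cl[["micro"]],
              cl[["unassigned"]]))
  cat(sprintf("  micro threshold: %s bp; expected n = %d\n",
              format(x$micro_threshold, big.mark = ","), x$expected_n))
  invisible(x)
}

#' Classify chromosomes as macro or micro by size threshold
#'
#' Assigns `chrom_class = "micro"` to every chromosome strictly smaller than
#' the karyotype's `micro_threshold` and `"macro"` otherwise (a chromosome
#' exactly at the threshold is a macrochromosome). Explicit labels supplied in
#' the `chrom_class` column win over the size rule when `respect_labels` is
#' `TRUE` (the default), mirroring the practice of assigning class from
#' published karyotype data where assembly sizes are ambiguous.
#'
#' @param kar A [karyotype].
#' @param respect_labels Keep pre-existing `"macro"`/`"micro"` labels.
#' @return The karyotype with every chromosome labeled.
#' @export
classify_chromosomes <- function(kar, respect_labels = TRUE) {
  stopifnot(inherits(kar, "karyotype"))
  chroms <- kar$chromosomes
  explicit <- chroms$chrom_class %in% c("macro", "micro") & respect_labels
  if (is.na(kar$micro_threshold) && !all(explicit))
    stop("micro_threshold is not set and not all chromosomes carry explicit class labels")
  by_size <- ifelse(chroms$length < kar$micro_threshold, "micro", "macro")
  chroms$chrom_class <- ifelse(explicit, chroms$chrom_class, by_size)
  kar$chromosomes <- chroms
  kar
}

#' GC content of a nucleotide sequence
#'
#' (G + C) / (A + C + G + T), case-insensitive. Ambiguity codes (including N)
#' are excluded from both numerator and denominator; soft-masked lowercase
#' bases count normally.
#'
#' @param sequence A character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @return Numeric vector of GC fractions.
#' @export
gc_content <- function(sequence) {
  if (is.character(sequence))
    sequence <- Biostrings::DNAStringSet(toupper(sequence))
  freq <- Biostrings::alphabetFrequency(sequence, baseOnly = TRUE)
  acgt <- freq[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(acgt)
  if (any(denom == 0))
    stop("sequence has no unambiguous A/C/G/T bases; GC content undefined")
  unname((acgt[, "G"] + acgt[, "C"]) / denom)
}

#' Per-chromosome GC content from a FASTA file
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA and fills the `gc`
#' column of the karyotype for every chromosome whose name matches a record.
#'
#' @param kar A [karyotype].
#' @param fasta_path Path to a FASTA file.
#' @return The karyotype with `gc` filled in where sequences were found.
#' @export
add_gc_from_fasta <- function(kar, fasta_path) {
  stopifnot(inherits(kar, "karyotype"))
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  hit <- kar$chromosomes$name %in% names(seqs)
  if (any(hit)) {
    kar$chromosomes$gc[hit] <-
      gc_content(seqs[kar$chromosomes$name[hit]])
  }
  kar
}

#' Gene density in genes per Mb
#'
#' @param n_genes Number of annotated genes (non-negative).
#' @param length Chromosome length in bp (> 0).
#' @return Genes per megabase.
#' @export
gene_density <- function(n_genes, length) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(n_genes < 0)) stop("n_genes must be non-negative")
  n_genes / (length / 1e6)
}

#' GC-versus-size table
#'
#' One row per chromosome with name, length, GC and class, sorted by
#' descending length — the table behind GC-content-versus-size scatter plots
#' of macro- and microchromosomes.
#'
#' @param kar A classified [karyotype] with `gc` present.
#' @return A data.frame with columns `name`, `length`, `gc`, `chrom_class`.
#' @export
gc_vs_size_table <- function(kar) {
  stopifnot(inherits(kar, "karyotype"))
  chroms <- kar$chromosomes
  out <- chroms[order(-chroms$length),
                c("name", "length", "gc", "chrom_class")]
  rownames(out) <- NULL
  out
}

#' Read a karyotype table
#'
#' Tab-separated with header; columns `species`, `chrom`, `length` and
#' optionally `class`, `n_genes`, `gc`, `centromere`.
#'
#' @param path Path to a TSV file.
#' @param micro_threshold Clade size threshold in bp (optional if the file
#'   carries a `class` column).
#' @param expected_n Expected haploid chromosome number; defaults to the
#'   number of chromosomes in the file.
#' @return A [karyotype].
#' @export
read_karyotype <- function(path, micro_threshold = NA_real_,
                           expected_n = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "chrom", "length")
  if (!all(need %in% names(tab)))
    stop("karyotype table must have columns species, chrom, length")
  chroms <- data.frame(name = tab$chrom, length = as.numeric(tab$length),
                       stringsAsFactors = FALSE)
  if (!is.null(tab$class)) chroms$chrom_class <- tab$class
  if (!is.null(tab$n_genes)) chroms$n_genes <- tab$n_genes
  if (!is.null(tab$gc)) chroms$gc <- tab$gc
  if (!is.null(tab$centromere)) chroms$centromere <- tab$centromere
  karyotype(species = tab$species[1], chromosomes = chroms,
            micro_threshold = micro_threshold,
            expected_n = if (is.null(expected_n)) nrow(chroms) else expected_n)
}

#' Write a karyotype table
#'
#' @param kar A [karyotype].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_karyotype <- function(kar, path) {
  stopifnot(inherits(kar, "karyotype"))
  ch <- kar$chromosomes
  out <- data.frame(species = kar$species, chrom = ch$name,
                    length = ch$length, class = ch$chrom_class,
                    n_genes = ch$n_genes, gc = ch$gc,
                    centromere = ch$centromere, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# named class lookup used across modules
chrom_class_of <- function(kar) {
  stats::setNames(kar$chromosomes$chrom_class, kar$chromosomes$name)
}

chrom_length_of <- function(kar) {
  stats::setNames(kar$chromosomes$length, kar$chromosomes$name)
}
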