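#' Homology profile of one chromosome
#'
#' Summarises which partner chromosomes a focal chromosome aligns to, how
#' much, and where. Partners whose total aligned length falls below
#' `min_support` are dropped — the operational meaning of "sufficient
#' homology". Remaining partners are sorted by descending aligned length.
#'
#' @param chrom Focal chromosome name.
#' @param blocks Syntenic-block table (one species pair).
#' @param min_support Minimum total aligned bp per partner (default 100 kb,
#'   the vertebrate chain filter).
#' @param side Which side of the block table the focal chromosome lives on.
#' @return A list with `chrom`, `partners` (data.frame: `partner`,
#'   `aligned_bp`, `n_blocks`) and `blocks` (the supporting block rows).
#' @export
homology_profile <- function(chrom, blocks, min_support = 1e5,
                             side = c("query", "target")) {
  side <- match.arg(side)
  own <- if (side == "query") "q_chrom" else "t_chrom"
  oth <- if (side == "query") "t_chrom" else "q_chrom"
  if (!chrom %in% c(blocks$q_chrom, blocks$t_chrom))
    stop(sprintf("chromosome '%s' not found in block table", chrom))
  sub <- blocks[blocks[[own]] == chrom, , drop = FALSE]
  agg <- stats::aggregate(list(aligned_bp = sub$aligned_bp),
                          by = list(partner = sub[[oth]]), FUN = sum)
  agg$n_blocks <- as.integer(table(sub[[oth]])[agg$partner])
  agg <- agg[agg$aligned_bp >= min_support, , drop = FALSE]
  agg <- agg[order(-agg$aligned_bp), , drop = FALSE]
  rownames(agg) <- NULL
  list(chrom = chrom, partners = agg,
       blocks = sub[sub[[oth]] %in% agg$partner, , drop = FALSE])
}

#' Micro-to-micro alignment fraction
#'
#' The length-weighted fraction of a query species' microchromosome
#' alignment that lands on target-species microchromosomes: the sum of
#' aligned bp over blocks whose query chromosome is micro AND whose target
#' chromosome is micro, divided by the sum over all blocks whose query
#' chromosome is micro. Length-weighting makes the statistic invariant to
#' chain fragmentation.
#'
#' @param blocks Syntenic-block table for one ordered species pair.
#' @param query_kar,target_kar Classified [karyotype]s.
#' @param weight `"length"` (default) weights each block by aligned bp;
#'   `"count"` counts blocks.
#' @return A single fraction in \[0, 1\].
#' @export
micro_fraction <- function(blocks, query_kar, target_kar,
                           weight = c("length", "count")) {
  weight <- match.arg(weight)
  qcl <- chrom_class_of(query_kar)[blocks$q_chrom]
  tcl <- chrom_class_of(target_kar)[blocks$t_chrom]
  if (anyNA(qcl))
    stop("block query chromosomes missing from query karyotype: ",
         paste(unique(blocks$q_chrom[is.na(qcl)]), collapse = ", "))
  if (anyNA(tcl))
    stop("block target chromosomes missing from target karyotype: ",
         paste(unique(blocks$t_chrom[is.na(tcl)]), collapse = ", "))
  w <- if (weight == "length") blocks$aligned_bp else rep(1, nrow(blocks))
  denom <- sum(w[qcl == "micro"])
  if (denom == 0)
    stop("no alignment from query microchromosomes; fraction undefined")
  sum(w[qcl == "micro" & tcl == "micro"]) / denom
}

#' Micro-fraction matrix across species pairs
#'
#' Builds the query-by-target grid of micro-to-micro alignment fractions.
#' The diagonal is 1 by convention (self-alignment is not computed); pairs
#' without data are `NA`, not 0.
#'
#' @param pairs A list of entries, each a list with elements `query`,
#'   `target` (species names) and `blocks` (syntenic-block table for that
#'   ordered pair).
#' @param karyotypes Named list of classified [karyotype]s covering every
#'   species that appears in `pairs`.
#' @param weight Passed to [micro_fraction()].
#' @return A list with `fraction` (matrix, query rows x target columns) and
#'   `weight_bp` (total micro-query aligned bp per cell).
#' @export
micro_fraction_matrix <- function(pairs, karyotypes,
                                  weight = c("length", "count")) {
  weight <- match.arg(weight)
  species <- names(karyotypes)
  frac <- matrix(NA_real_, length(species), length(species),
                 dimnames = list(query = species, target = species))
  wbp <- frac
  diag(frac) <- 1
  for (p in pairs) {
    if (!p$query %in% species || !p$target %in% species)
      stop("pair references species without a karyotype")
    qcl <- chrom_class_of(karyotypes[[p$query]])[p$blocks$q_chrom]
    frac[p$query, p$target] <-
      micro_fraction(p$blocks, karyotypes[[p$query]],
                     karyotypes[[p$target]], weight = weight)
    wbp[p$query, p$target] <- sum(p$blocks$aligned_bp[qcl == "micro"])
  }
  list(fraction = frac, weight_bp = wbp)
}

#' Genome-proportional coordinates for homology plots
#'
#' Rescales each genome to \[0, 1\] (chromosome sizes as a proportion of
#' genome length, laid out end to end, optionally in a user-supplied order)
#' and maps each syntenic block to the scaled coordinates of both genomes.
#'
#' @param query_kar,target_kar [karyotype]s.
#' @param blocks Syntenic-block table for the pair.
#' @param query_order,target_order Optional character vectors giving the
#'   plotting order of chromosomes; must name only known chromosomes.
#' @return A list with `chromosomes` (data.frame: `species`, `name`,
#'   `length`, `chrom_class`, `x0`, `x1` scaled span) and `blocks`
#'   (the block table with added `q_x0`, `q_x1`, `t_x0`, `t_x1`).
#' @export
resize_for_plot <- function(query_kar, target_kar, blocks,
                            query_order = NULL, target_order = NULL) {
  layout_one <- function(kar, ord) {
    ch <- kar$chromosomes
    if (!is.null(ord)) {
      unknown <- setdiff(ord, ch$name)
      if (length(unknown))
        stop("order list names unknown chromosome(s): ",
             paste(unknown, collapse = ", "))
      ch <- ch[match(ord, ch$name), , drop = FALSE]
    }
    total <- sum(ch$length)
    x1 <- cumsum(ch$length) / total
    data.frame(species = kar$species, name = ch$name, length = ch$length,
               chrom_class = ch$chrom_class,
               x0 = c(0, utils::head(x1, -1)), x1 = x1,
               stringsAsFactors = FALSE)
  }
  ql <- layout_one(query_kar, query_order)
  tl <- layout_one(target_kar, target_order)
  scale_pos <- function(layout, chrom, pos) {
    i <- match(chrom, layout$name)
    layout$x0[i] + (pos / layout$length[i]) * (layout$x1[i] - layout$x0[i])
  }
  b <- blocks
  b$q_x0 <- scale_pos(ql, b$q_chrom, b$q_start)
  b$q_x1 <- scale_pos(ql, b$q_chrom, b$q_end)
  b$t_x0 <- scale_pos(tl, b$t_chrom, b$t_start)
  b$t_x1 <- scale_pos(tl, b$t_chrom, b$t_end)
  list(chromosomes = rbind(ql, tl), blocks = b)
}

#' Write a micro-fraction matrix as TSV
#'
#' @param mat Result of [micro_fraction_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_micro_fraction_matrix <- function(mat, path) {
  utils::write.table(cbind(query = rownames(mat$fraction),
                           as.data.frame(mat$fraction)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
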