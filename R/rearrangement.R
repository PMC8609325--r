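#' Ancestral composition of a derived chromosome
#'
#' Aggregates the syntenic blocks landing on one target (derived-genome)
#' chromosome into its ancestral (query-genome) composition: which query
#' chromosomes contribute, how much aligned length, and where their material
#' sits along the target chromosome. Ancestors supported by fewer than
#' `min_support` aligned bp are dropped.
#'
#' @param target_chrom Target chromosome name.
#' @param blocks Syntenic-block table for the pair (query = putative
#'   ancestor-like genome, target = derived genome).
#' @param query_kar,target_kar Classified [karyotype]s.
#' @param min_support Minimum aligned bp for an ancestor to count.
#' @return A list with `target_chrom`, `target_class`, `target_length`,
#'   `covered_fraction` (of the target chromosome, by all retained
#'   ancestors), and `ancestors`, a data.frame ordered by target-side
#'   position with columns `q_chrom`, `q_class`, `aligned_bp`, `t_start`,
#'   `t_end`, `q_coverage` (aligned bp / ancestor length), `t_coverage`
#'   (aligned bp / target length).
#' @export
compose <- function(target_chrom, blocks, query_kar, target_kar,
                    min_support = 1e5) {
  tlen <- chrom_length_of(target_kar)[target_chrom]
  if (is.na(tlen))
    stop(sprintf("chromosome '%s' not in target karyotype", target_chrom))
  tcl <- chrom_class_of(target_kar)[target_chrom]
  sub <- blocks[blocks$t_chrom == target_chrom, , drop = FALSE]
  if (nrow(sub) == 0L) {
    anc <- data.frame(q_chrom = character(0), q_class = character(0),
                      aligned_bp = numeric(0), t_start = numeric(0),
                      t_end = numeric(0), q_coverage = numeric(0),
                      t_coverage = numeric(0), stringsAsFactors = FALSE)
    return(list(target_chrom = target_chrom, target_class = unname(tcl),
                target_length = unname(tlen), covered_fraction = 0,
                ancestors = anc))
  }
  qlen <- chrom_length_of(query_kar)
  qcl <- chrom_class_of(query_kar)
  if (anyNA(qcl[sub$q_chrom]))
    stop("block query chromosomes missing from query karyotype")
  agg <- do.call(rbind, lapply(split(sub, sub$q_chrom), function(d) {
    data.frame(q_chrom = d$q_chrom[1],
               q_class = unname(qcl[d$q_chrom[1]]),
               aligned_bp = sum(d$aligned_bp),
               t_start = min(d$t_start), t_end = max(d$t_end),
               q_coverage = sum(d$aligned_bp) / qlen[d$q_chrom[1]],
               t_coverage = sum(d$aligned_bp) / tlen,
               stringsAsFactors = FALSE)
  }))
  agg <- agg[agg$aligned_bp >= min_support, , drop = FALSE]
  agg <- agg[order(agg$t_start), , drop = FALSE]
  agg$q_coverage <- unname(agg$q_coverage)
  agg$t_coverage <- unname(agg$t_coverage)
  rownames(agg) <- NULL
  list(target_chrom = target_chrom, target_class = unname(tcl),
       target_length = unname(tlen),
       covered_fraction = unname(sum(agg$aligned_bp) / tlen),
       ancestors = agg)
}

#' Call a fusion/fission event from a composition
#'
#' Decision cascade over a derived chromosome's ancestral composition:
#' \enumerate{
#'   \item one ancestor of the same class, reciprocally intact (both the
#'     target chromosome and the ancestor covered at `f_intact` or more) →
#'     `conserved_micro` / `conserved_macro`;
#'   \item two or more micro ancestors and no macro ancestor →
#'     `micro_micro_fusion`;
#'   \item micro and macro ancestors together: if a centromere position is
#'     supplied and a micro ancestor makes up at least `f_intact` of one
#'     whole arm → `macro_micro_fusion_centric`; otherwise, if every micro
#'     ancestor's target-side span sits within `d_term` of a chromosome
#'     end → `macro_micro_fusion_terminal`;
#'   \item two or more macro ancestors and no micro ancestor →
#'     `macro_macro_fusion`;
#'   \item all ancestors fragments of a single query macrochromosome (the
#'     ancestor itself not intact) → `fission_new_micro` for a micro-class
#'     target, `fission_new_macro` for a macro-class target;
#'   \item otherwise `unresolved`.
#' }
#' "Within `d_term` of an end" is measured from the span's outer edge to the
#' nearest chromosome end, so a fused microchromosome longer than `d_term`
#' still reads as terminal when nothing lies between it and the telomere.
#' Without a centromere position, chain data cannot separate terminal from
#' centric fusion, so centric fusions surface under the terminal label.
#'
#' @param composition Result of [compose()].
#' @param d_term Distance defining "terminal"; default
#'   `min(5 Mb, 10%% of the target chromosome length)`.
#' @param centromere Optional centromere position (bp) on the target
#'   chromosome.
#' @param f_intact Reciprocal coverage needed to call a chromosome intact.
#' @return A list of class `rearrangement_call`: `target_chrom`, `event`,
#'   `ancestors` (data.frame as in [compose()]), `notes`.
#' @export
call_event <- function(composition, d_term = NULL, centromere = NA,
                       f_intact = 0.8) {
  if (!is.null(d_term) && d_term <= 0)
    stop("d_term must be positive")
  L <- composition$target_length
  if (is.null(d_term)) d_term <- min(5e6, 0.1 * L)
  anc <- composition$ancestors
  tcl <- composition$target_class
  notes <- character(0)
  mk <- function(event) structure(
    list(target_chrom = composition$target_chrom, target_class = tcl,
         event = event, ancestors = anc, notes = notes),
    class = "rearrangement_call")

  if (nrow(anc) == 0L) {
    notes <- "no ancestors above min_support"
    return(mk("unresolved"))
  }
  n_mic <- sum(anc$q_class == "micro")
  n_mac <- sum(anc$q_class == "macro")

  # 1. conserved 1:1
  if (nrow(anc) == 1L && anc$q_class == tcl &&
      anc$t_coverage >= f_intact && anc$q_coverage >= f_intact) {
    return(mk(if (tcl == "micro") "conserved_micro" else "conserved_macro"))
  }
  # 2. pure micro-micro fusion
  if (n_mic >= 2L && n_mac == 0L) return(mk("micro_micro_fusion"))
  # 3. micro(s) fused with macro(s)
  if (n_mic >= 1L && n_mac >= 1L) {
    mic <- anc[anc$q_class == "micro", , drop = FALSE]
    # a whole fused arm is also positionally terminal, so when a centromere
    # is known the Robertsonian (whole-arm) pattern is tested first
    if (!is.na(centromere)) {
      arm_cov <- ifelse(mic$t_end <= centromere, mic$aligned_bp / centromere,
                 ifelse(mic$t_start >= centromere,
                        mic$aligned_bp / (L - centromere), 0))
      if (any(arm_cov >= f_intact)) return(mk("macro_micro_fusion_centric"))
    }
    edge_dist <- pmin(mic$t_start, L - mic$t_end)
    if (all(edge_dist <= d_term)) return(mk("macro_micro_fusion_terminal"))
    notes <- "mixed micro/macro ancestry, micro span neither terminal nor a whole arm"
    return(mk("unresolved"))
  }
  # 4. macro-macro fusion
  if (n_mac >= 2L && n_mic == 0L) return(mk("macro_macro_fusion"))
  # 5. fission: fragment(s) of one non-intact query macro
  if (n_mac == 1L && n_mic == 0L && anc$q_coverage[1] < f_intact &&
      anc$t_coverage[1] >= f_intact) {
    return(mk(if (tcl == "micro") "fission_new_micro" else "fission_new_macro"))
  }
  notes <- "composition matches no event pattern"
  mk("unresolved")
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat(sprintf("%s (%s): %s [%s]\n", x$target_chrom, x$target_class, x$event,
              paste(x$ancestors$q_chrom, collapse = "+")))
  invisible(x)
}

#' Call events for every target chromosome
#'
#' Runs [compose()] and [call_event()] across all chromosomes of the target
#' karyotype. Deterministic given the block set and parameters.
#'
#' @param blocks Syntenic-block table (query = ancestor-like genome).
#' @param query_kar,target_kar Classified [karyotype]s; the target karyotype
#'   may carry a `centromere` column, used for centric-fusion calls.
#' @param min_support,d_term,f_intact See [compose()] and [call_event()].
#' @return A data.frame with one row per target chromosome: `target_chrom`,
#'   `target_class`, `event`, `n_ancestors`, `ancestors`
#'   (comma-separated), plus a `calls` attribute holding the full call
#'   objects.
#' @export
call_events <- function(blocks, query_kar, target_kar, min_support = 1e5,
                        d_term = NULL, f_intact = 0.8) {
  cents <- stats::setNames(target_kar$chromosomes$centromere,
                           target_kar$chromosomes$name)
  calls <- lapply(target_kar$chromosomes$name, function(tc) {
    call_event(compose(tc, blocks, query_kar, target_kar, min_support),
               d_term = d_term, centromere = cents[[tc]],
               f_intact = f_intact)
  })
  out <- data.frame(
    target_chrom = vapply(calls, `[[`, character(1), "target_chrom"),
    target_class = vapply(calls, `[[`, character(1), "target_class"),
    event = vapply(calls, `[[`, character(1), "event"),
    n_ancestors = vapply(calls, function(x) nrow(x$ancestors), integer(1)),
    ancestors = vapply(calls, function(x)
      paste(x$ancestors$q_chrom, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  attr(out, "calls") <- calls
  out
}

#' Event-type summary counts
#'
#' @param calls Data.frame from [call_events()] (or anything with an `event`
#'   column).
#' @return Named integer vector over all event types; sums to the number of
#'   calls.
#' @export
event_table <- function(calls) {
  levels <- c("conserved_micro", "conserved_macro", "micro_micro_fusion",
              "macro_micro_fusion_terminal", "macro_micro_fusion_centric",
              "macro_macro_fusion", "fission_new_micro", "fission_new_macro",
              "unresolved")
  tab <- table(factor(calls$event, levels = levels))
  stats::setNames(as.integer(tab), levels)
}

#' Four-way ancestral-state region map
#'
#' Labels each block's target-side interval by the (query class, target
#' class) pair: macro/macro → `macro`, micro/micro → `micro`, micro in the
#' query but macro in the target → `new_macro`, macro in the query but micro
#' in the target → `new_micro`. Overlapping blocks are resolved in favour of
#' the higher-scoring (then longer) block, so every classified base carries
#' exactly one state; unaligned target regions are left unlabeled.
#'
#' @param blocks Syntenic-block table (query = reference/ancestor-like
#'   species, target = focal species).
#' @param query_kar,target_kar Classified [karyotype]s.
#' @return A data.frame (`chrom`, `start`, `end`, `state`) sorted by
#'   chromosome and position; intervals within a chromosome do not overlap.
#' @export
classify_regions_four_way <- function(blocks, query_kar, target_kar) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), state = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(blocks) == 0L) return(empty)
  qcl <- chrom_class_of(query_kar)[blocks$q_chrom]
  tcl <- chrom_class_of(target_kar)[blocks$t_chrom]
  if (anyNA(qcl) || anyNA(tcl))
    stop("blocks reference chromosomes missing from a karyotype")
  state <- ifelse(qcl == "macro" & tcl == "macro", "macro",
           ifelse(qcl == "micro" & tcl == "micro", "micro",
           ifelse(qcl == "micro" & tcl == "macro", "new_macro", "new_micro")))
  ord <- order(-blocks$score, -(blocks$t_end - blocks$t_start))
  claimed <- list()
  pieces <- list()
  for (k in ord) {
    chrom <- blocks$t_chrom[k]
    cand <- IRanges::IRanges(start = blocks$t_start[k] + 1,
                             end = blocks$t_end[k])
    free <- if (is.null(claimed[[chrom]])) cand else
      IRanges::setdiff(cand, claimed[[chrom]])
    if (length(free) == 0L || sum(IRanges::width(free)) == 0) next
    claimed[[chrom]] <- IRanges::reduce(
      if (is.null(claimed[[chrom]])) free else c(claimed[[chrom]], free))
    pieces[[length(pieces) + 1L]] <- data.frame(
      chrom = chrom, start = IRanges::start(free) - 1,
      end = IRanges::end(free), state = state[k], stringsAsFactors = FALSE)
  }
  if (length(pieces) == 0L) return(empty)
  map <- do.call(rbind, pieces)
  map <- map[order(map$chrom, map$start), , drop = FALSE]
  rownames(map) <- NULL
  map
}

#' Write a region class map as BED-like TSV
#'
#' BED6-like: chrom, start, end, state, 0, `.`.
#'
#' @param map Region map from [classify_regions_four_way()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  bed <- data.frame(map$chrom,
                    format(map$start, scientific = FALSE, trim = TRUE),
                    format(map$end, scientific = FALSE, trim = TRUE),
                    map$state, 0, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
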