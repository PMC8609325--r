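#' Construct a binned contact matrix
#'
#' Sparse symmetric container for binned Hi-C counts. Bins tile each scaffold
#' without overlap (the last bin of a scaffold may be short); counts are
#' stored once per unordered bin pair (`i <= j`), with the symmetric entry
#' implied. Entries with `i > j` are folded and duplicate pairs summed.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), sorted by scaffold then position.
#' @param counts data.frame with columns `i`, `j` (row indices into `bins`)
#'   and `count` (>= 0).
#' @param bin_size Bin width in bp (default 50 kb).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, counts, bin_size = 5e4) {
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)),
            all(c("i", "j", "count") %in% names(counts)))
  if (any(counts$count < 0)) stop("contact counts must be non-negative")
  if (nrow(counts)) {
    swap <- counts$i > counts$j
    tmp <- counts$i[swap]; counts$i[swap] <- counts$j[swap]
    counts$j[swap] <- tmp
    nb <- nrow(bins)
    key <- (as.numeric(counts$i) - 1) * nb + as.numeric(counts$j)
    o <- order(key)
    key <- key[o]
    cnt <- counts$count[o]
    if (anyDuplicated(key)) {
      grp <- cumsum(c(TRUE, diff(key) > 0))
      cnt <- as.numeric(rowsum(cnt, grp))
      key <- key[!duplicated(key)]
    }
    counts <- data.frame(i = as.integer((key - 1) %/% nb + 1),
                         j = as.integer((key - 1) %% nb + 1),
                         count = cnt)
  }
  rownames(bins) <- NULL; rownames(counts) <- NULL
  structure(list(bin_size = bin_size, bins = bins,
                 counts = counts[, c("i", "j", "count")]),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d bp) on %d scaffolds, %d non-zero pairs, total %.6g\n",
              nrow(x$bins), x$bin_size, length(unique(x$bins$chrom)),
              nrow(x$counts), sum(x$counts$count)))
  invisible(x)
}

#' Scaffold lengths of a contact matrix
#'
#' Length of each scaffold as covered by its bins.
#' @param cm A [contact_matrix].
#' @return Named numeric vector.
#' @export
scaffold_lengths <- function(cm) {
  vapply(split(cm$bins$end, cm$bins$chrom), max, numeric(1))
}

#' Read a 7-column GInteractions contact table
#'
#' The format carries one bin pair per line: origin scaffold, origin start,
#' origin end, target scaffold, target start, target end, and the number of
#' interactions between the bins. Exactly seven whitespace-separated columns
#' are required; duplicate (i,j)/(j,i) lines are merged by summing.
#'
#' @param path Path to the text file.
#' @param bin_size Bin width in bp; starts must be multiples of it (the tail
#'   bin of a scaffold may be short).
#' @return A [contact_matrix].
#' @export
read_ginteractions <- function(path, bin_size = 5e4) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    bins <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), stringsAsFactors = FALSE)
    counts <- data.frame(i = integer(0), j = integer(0), count = numeric(0))
    return(contact_matrix(bins, counts, bin_size))
  }
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 7L)
    stop(sprintf("GInteractions file must have exactly 7 columns, found %d",
                 ncol(tab)))
  names(tab) <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
                  "count")
  if (any(tab$count < 0)) stop("negative interaction count")
  starts <- c(tab$start1, tab$start2)
  if (any(starts %% bin_size != 0))
    stop("bin starts must be multiples of bin_size")
  ends <- c(tab$end1, tab$end2)
  if (any(ends <= starts) || any(ends - starts > bin_size))
    stop("bin intervals must be positive and at most bin_size wide")
  chroms <- sort(unique(c(tab$chrom1, tab$chrom2)))
  bin_list <- lapply(chroms, function(ch) {
    maxend <- max(ends[c(tab$chrom1, tab$chrom2) == ch])
    n <- ceiling(maxend / bin_size)
    data.frame(chrom = ch, start = (seq_len(n) - 1) * bin_size,
               end = pmin(seq_len(n) * bin_size, maxend),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, bin_list)
  n_per <- vapply(bin_list, nrow, integer(1))
  offset <- stats::setNames(cumsum(c(0, utils::head(n_per, -1))), chroms)
  idx <- function(chrom, start)
    as.integer(offset[chrom] + start %/% bin_size + 1)
  counts <- data.frame(i = idx(tab$chrom1, tab$start1),
                       j = idx(tab$chrom2, tab$start2),
                       count = tab$count)
  contact_matrix(bins, counts, bin_size)
}

#' Write a contact matrix as 7-column GInteractions text
#'
#' Emits the canonical dialect (tab-separated, pairs ordered `i <= j`,
#' sorted); [read_ginteractions()] followed by `write_ginteractions()` is
#' byte-identical on files in this dialect.
#'
#' @param cm A [contact_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ginteractions <- function(cm, path) {
  fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)
  b <- cm$bins; ct <- cm$counts
  lines <- paste(b$chrom[ct$i], fmt(b$start[ct$i]), fmt(b$end[ct$i]),
                 b$chrom[ct$j], fmt(b$start[ct$j]), fmt(b$end[ct$j]),
                 fmt(ct$count), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Lint a GInteractions file
#'
#' Non-throwing format check; a clean file yields an empty data.frame.
#' @param path Path to the file.
#' @return data.frame with columns `file`, `finding`.
#' @export
validate_ginteractions_file <- function(path, bin_size = 5e4) {
  res <- tryCatch({ read_ginteractions(path, bin_size); NULL },
                  error = conditionMessage)
  if (is.null(res))
    data.frame(file = character(0), finding = character(0))
  else data.frame(file = path, finding = res, stringsAsFactors = FALSE)
}

#' Restrict a contact matrix to the largest scaffolds
#'
#' Keeps the `expected_n` largest scaffolds (the expected haploid chromosome
#' number from karyotype information), so that unplaced fragments do not
#' enter chromosome-level statistics. Ties are broken by scaffold name.
#'
#' @param cm A [contact_matrix].
#' @param expected_n Number of scaffolds to keep, or a [karyotype] whose
#'   `expected_n` is used.
#' @return A [contact_matrix] restricted to those scaffolds.
#' @export
select_top_scaffolds <- function(cm, expected_n) {
  if (inherits(expected_n, "karyotype")) expected_n <- expected_n$expected_n
  lens <- scaffold_lengths(cm)
  if (expected_n > length(lens))
    stop(sprintf("expected_n (%d) exceeds number of scaffolds (%d)",
                 expected_n, length(lens)))
  keep <- names(lens)[order(-lens, names(lens))][seq_len(expected_n)]
  sel <- cm$bins$chrom %in% keep
  new_id <- cumsum(sel)
  counts <- cm$counts[sel[cm$counts$i] & sel[cm$counts$j], , drop = FALSE]
  counts$i <- new_id[counts$i]; counts$j <- new_id[counts$j]
  contact_matrix(cm$bins[sel, , drop = FALSE], counts, cm$bin_size)
}

#' Inter-scaffold interaction heat map
#'
#' Each cell (A, B) is the mean of interaction values over all bin pairs
#' between scaffolds A and B (absent pairs count as 0), with scaffolds
#' ordered from largest to smallest. The result is symmetric.
#'
#' @param cm A [contact_matrix].
#' @return A numeric matrix with scaffold names as dimnames.
#' @export
interaction_heatmap <- function(cm) {
  lens <- scaffold_lengths(cm)
  scaffolds <- names(lens)[order(-lens, names(lens))]
  ns <- length(scaffolds)
  nbins <- table(cm$bins$chrom)[scaffolds]
  sums <- matrix(0, ns, ns, dimnames = list(scaffolds, scaffolds))
  ct <- cm$counts
  si <- match(cm$bins$chrom[ct$i], scaffolds)
  sj <- match(cm$bins$chrom[ct$j], scaffolds)
  diag_pair <- ct$i == ct$j
  for (k in seq_len(nrow(ct))) {
    sums[si[k], sj[k]] <- sums[si[k], sj[k]] + ct$count[k]
    if (!diag_pair[k])
      sums[sj[k], si[k]] <- sums[sj[k], si[k]] + ct$count[k]
  }
  denom <- outer(as.numeric(nbins), as.numeric(nbins))
  sums / denom
}

#' Assign contact-matrix bins to region states
#'
#' Each bin takes the state covering the majority of it; on a tie, the state
#' of the earlier (left-most) interval wins. Bins not touched by the map
#' stay `NA`.
#'
#' @param cm A [contact_matrix].
#' @param region_map data.frame (`chrom`, `start`, `end`, `state`), e.g.
#'   from [classify_regions_four_way()].
#' @return Character vector of states, one per bin.
#' @export
assign_bin_states <- function(cm, region_map) {
  states <- rep(NA_character_, nrow(cm$bins))
  for (ch in unique(region_map$chrom)) {
    bsel <- which(cm$bins$chrom == ch)
    if (length(bsel) == 0L) next
    rsub <- region_map[region_map$chrom == ch, , drop = FALSE]
    bir <- IRanges::IRanges(start = cm$bins$start[bsel] + 1,
                            end = cm$bins$end[bsel])
    rir <- IRanges::IRanges(start = rsub$start + 1, end = rsub$end)
    hits <- IRanges::findOverlaps(bir, rir)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(bir[qh], rir[sh]))
    df <- data.frame(bin = qh, state = rsub$state[sh], ov = ov,
                     rstart = rsub$start[sh])
    agg <- stats::aggregate(cbind(ov = df$ov),
                            by = list(bin = df$bin, state = df$state),
                            FUN = sum)
    agg$rstart <- stats::aggregate(
      cbind(rstart = df$rstart),
      by = list(bin = df$bin, state = df$state), FUN = min)$rstart
    for (b in unique(agg$bin)) {
      rows <- agg[agg$bin == b, , drop = FALSE]
      rows <- rows[order(-rows$ov, rows$rstart), , drop = FALSE]
      states[bsel[b]] <- rows$state[1]
    }
  }
  states
}

#' Partition a contact matrix by region state
#'
#' Splits the matrix into per-state sub-matrices: bins are assigned to
#' states by majority overlap with the region map, and each sub-matrix keeps
#' the pairs whose two bins share the state.
#'
#' @param cm A [contact_matrix].
#' @param region_map data.frame (`chrom`, `start`, `end`, `state`).
#' @return Named list of [contact_matrix] objects, one per state present.
#' @export
partition_matrix_by_state <- function(cm, region_map) {
  states <- assign_bin_states(cm, region_map)
  out <- list()
  for (st in sort(unique(states[!is.na(states)]))) {
    sel <- !is.na(states) & states == st
    new_id <- cumsum(sel)
    counts <- cm$counts[sel[cm$counts$i] & sel[cm$counts$j], , drop = FALSE]
    counts$i <- new_id[counts$i]; counts$j <- new_id[counts$j]
    out[[st]] <- contact_matrix(cm$bins[sel, , drop = FALSE], counts,
                                cm$bin_size)
  }
  out
}

resolve_bin_classes <- function(cm, classes) {
  if (inherits(classes, "karyotype")) {
    map <- chrom_class_of(classes)
    out <- unname(map[cm$bins$chrom])
  } else if (is.data.frame(classes)) {
    out <- assign_bin_states(cm, classes)
  } else if (!is.null(names(classes))) {
    out <- unname(classes[cm$bins$chrom])
  } else stop("classes must be a karyotype, a region map, or a named vector")
  out
}

#' Distance-dependent contact probability P(s)
#'
#' For each chromosome class, the mean intra-scaffold contact value as a
#' function of genomic separation s: in each distance bin, the sum of counts
#' over bin pairs at those separations (both bins in the class, same
#' scaffold) divided by the number of such pairs, zeros included. Distance
#' bins are logarithmic between `min_dist` and `max_dist`. In
#' `mode = "probability"` each curve is additionally normalized to unit sum
#' over its defined bins.
#'
#' @param cm A [contact_matrix].
#' @param classes A classified [karyotype], a region map data.frame, or a
#'   named scaffold-to-class vector. Use the string `"all"` inside
#'   `which_classes` to pool every bin.
#' @param which_classes Classes to compute curves for; defaults to all
#'   classes present.
#' @param max_dist Maximum separation in bp (default 1e8).
#' @param min_dist Lower edge of the first distance bin (default one bin).
#' @param n_dist_bins Number of logarithmic distance bins.
#' @param mode `"mean"` (mean counts per valid pair) or `"probability"`
#'   (unit-sum normalized).
#' @return data.frame with columns `class`, `s_lo`, `s_hi`, `s_mid`
#'   (geometric midpoint), `n_pairs`, `sum_counts`, `p` (`NA` where no pair
#'   exists at those separations).
#' @export
ps_curve <- function(cm, classes, which_classes = NULL, max_dist = 1e8,
                     min_dist = cm$bin_size, n_dist_bins = 30,
                     mode = c("mean", "probability")) {
  mode <- match.arg(mode)
  bin_states <- resolve_bin_classes(cm, classes)
  if (is.null(which_classes))
    which_classes <- sort(unique(bin_states[!is.na(bin_states)]))
  edges <- exp(seq(log(min_dist), log(max_dist), length.out = n_dist_bins + 1))
  edges[1] <- min_dist; edges[length(edges)] <- max_dist
  out <- list()
  scaffold <- cm$bins$chrom
  # per-scaffold local bin index
  local_idx <- stats::ave(seq_along(scaffold), scaffold,
                          FUN = seq_along)
  for (cl in which_classes) {
    in_cl <- if (cl == "all") !is.na(bin_states) | is.na(bin_states)
             else !is.na(bin_states) & bin_states == cl
    if (sum(in_cl) == 0L)
      stop(sprintf("no bins in class '%s'", cl))
    max_b <- max(table(scaffold[in_cl]))
    if (max_b < 2L)
      stop(sprintf("class '%s' has fewer than 2 bins on every scaffold; P(s) undefined", cl))
    # valid pair counts per separation d (in bins) via autocorrelation
    pair_at_d <- numeric(0)
    for (ch in unique(scaffold[in_cl])) {
      sel <- scaffold == ch
      z <- as.numeric(in_cl[sel])
      B <- length(z)
      if (sum(z) < 2) next
      ac <- stats::convolve(z, rev(z), type = "open")  # index B+d -> pairs at d
      d_counts <- round(ac[(B + 1):(2 * B - 1)])
      if (length(d_counts) > length(pair_at_d)) {
        pair_at_d <- c(pair_at_d,
                       numeric(length(d_counts) - length(pair_at_d)))
      }
      pair_at_d[seq_along(d_counts)] <-
        pair_at_d[seq_along(d_counts)] + d_counts
    }
    ds <- seq_along(pair_at_d)
    s_of_d <- ds * cm$bin_size
    dbin_of_d <- findInterval(s_of_d, edges, rightmost.closed = TRUE)
    dbin_of_d[s_of_d < edges[1] | s_of_d > edges[length(edges)]] <- NA
    n_pairs <- rep(0, n_dist_bins)
    ok <- !is.na(dbin_of_d)
    if (any(ok)) {
      tp <- tapply(pair_at_d[ok], dbin_of_d[ok], sum)
      n_pairs[as.integer(names(tp))] <- tp
    }
    # observed counts per distance bin
    ct <- cm$counts
    same_sc <- scaffold[ct$i] == scaffold[ct$j] & ct$i != ct$j &
      in_cl[ct$i] & in_cl[ct$j]
    sum_counts <- rep(0, n_dist_bins)
    if (any(same_sc)) {
      d <- abs(local_idx[ct$j[same_sc]] - local_idx[ct$i[same_sc]])
      s <- d * cm$bin_size
      db <- findInterval(s, edges, rightmost.closed = TRUE)
      db[s < edges[1] | s > edges[length(edges)]] <- NA
      okc <- !is.na(db)
      if (any(okc)) {
        tc <- tapply(ct$count[same_sc][okc], db[okc], sum)
        sum_counts[as.integer(names(tc))] <- tc
      }
    }
    p <- ifelse(n_pairs > 0, sum_counts / n_pairs, NA_real_)
    if (mode == "probability") {
      tot <- sum(p, na.rm = TRUE)
      if (tot > 0) p <- p / tot
    }
    out[[cl]] <- data.frame(
      class = cl, s_lo = edges[-length(edges)], s_hi = edges[-1],
      s_mid = sqrt(edges[-length(edges)] * edges[-1]),
      n_pairs = n_pairs, sum_counts = sum_counts, p = p,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fit the decay exponent of a P(s) curve
#'
#' Least-squares fit of log P(s) against log s over the distance bins with at
#' least one valid pair and positive P, optionally restricted to a distance
#' window. Returns the exponent alpha of P(s) ~ s^(-alpha).
#'
#' @param curve One class' rows from [ps_curve()].
#' @param s_range Length-2 numeric window of separations to use.
#' @return Fitted alpha (positive for decaying curves).
#' @export
fit_ps_exponent <- function(curve, s_range = c(-Inf, Inf)) {
  use <- !is.na(curve$p) & curve$p > 0 & curve$n_pairs > 0 &
    curve$s_mid >= s_range[1] & curve$s_mid <= s_range[2]
  if (sum(use) < 3L) stop("fewer than 3 usable distance bins; cannot fit exponent")
  fit <- stats::lm(log(curve$p[use]) ~ log(curve$s_mid[use]))
  -unname(stats::coef(fit)[2])
}

#' Mean trans contact by chromosome-class pair
#'
#' Mean interaction value per inter-scaffold bin pair, split by the class
#' pair of the two scaffolds (micro-micro, macro-micro, macro-macro). Absent
#' pairs count as zero, as in [interaction_heatmap()].
#'
#' @param cm A [contact_matrix].
#' @param classes A classified [karyotype] or named scaffold-to-class vector.
#' @return data.frame with `pair_class`, `n_pairs`, `sum_counts`, `mean`.
#' @export
trans_mean_by_class <- function(cm, classes) {
  bin_states <- resolve_bin_classes(cm, classes)
  scaffold <- cm$bins$chrom
  pc_of <- function(a, b) {
    paste(sort(c(a, b)), collapse = "-")
  }
  # all scaffold pairs
  lens <- table(scaffold)
  scl <- vapply(names(lens), function(ch)
    bin_states[match(ch, scaffold)], character(1))
  combos <- utils::combn(names(lens), 2)
  pair_class <- apply(combos, 2, function(p) pc_of(scl[p[1]], scl[p[2]]))
  n_pairs <- apply(combos, 2, function(p)
    as.numeric(lens[p[1]]) * as.numeric(lens[p[2]]))
  ct <- cm$counts
  trans <- scaffold[ct$i] != scaffold[ct$j]
  key <- paste(pmin(scaffold[ct$i], scaffold[ct$j])[trans],
               pmax(scaffold[ct$i], scaffold[ct$j])[trans])
  combo_key <- paste(pmin(combos[1, ], combos[2, ]),
                     pmax(combos[1, ], combos[2, ]))
  sums <- rep(0, ncol(combos))
  if (any(trans)) {
    tt <- tapply(ct$count[trans], key, sum)
    m <- match(names(tt), combo_key)
    sums[m[!is.na(m)]] <- tt[!is.na(m)]
  }
  agg <- stats::aggregate(cbind(n_pairs = n_pairs, sum_counts = sums),
                          by = list(pair_class = pair_class), FUN = sum)
  agg$mean <- agg$sum_counts / agg$n_pairs
  agg
}
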