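#' Read a UCSC chain file
#'
#' Parses pairwise alignment chains (the output of axtChain-style chaining).
#' Each chain is a scored gapped alignment between a target and a query
#' assembly: a header line
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id`
#' followed by alignment-block lines `size dt dq` (the last line carries only
#' `size`) and a blank line. Coordinates are 0-based half-open; negative-strand
#' query coordinates are kept as given (on the reverse-complemented sequence) —
#' see [chain_query_forward()] to convert.
#'
#' @param path Path to a chain file (gzip transparent).
#' @return A list of chains, each a list with `score`, target fields
#'   (`t_name`, `t_size`, `t_strand`, `t_start`, `t_end`), query fields
#'   (`q_name`, ...), `id`, and `blocks`, a data.frame of `size`, `dt`, `dq`
#'   (gaps on target/query after each block; 0 on the final block).
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "chain"))
      stop(sprintf("line %d: expected chain header, got '%s'", i, lines[i]))
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(hdr) != 13L)
      stop(sprintf("line %d: chain header must have 13 fields, found %d",
                   i, length(hdr)))
    ch <- list(score  = as.numeric(hdr[2]),
               t_name = hdr[3], t_size = as.numeric(hdr[4]),
               t_strand = hdr[5],
               t_start = as.numeric(hdr[6]), t_end = as.numeric(hdr[7]),
               q_name = hdr[8], q_size = as.numeric(hdr[9]),
               q_strand = hdr[10],
               q_start = as.numeric(hdr[11]), q_end = as.numeric(hdr[12]),
               id = as.integer(hdr[13]))
    if (!ch$t_strand %in% c("+", "-") || !ch$q_strand %in% c("+", "-"))
      stop(sprintf("line %d: strand must be + or -", i))
    hdr_line <- i
    i <- i + 1L
    sizes <- numeric(0); dts <- numeric(0); dqs <- numeric(0)
    repeat {
      if (i > n) stop(sprintf("line %d: chain truncated at end of file", n))
      fields <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(fields) == 3L) {
        sizes <- c(sizes, as.numeric(fields[1]))
        dts <- c(dts, as.numeric(fields[2]))
        dqs <- c(dqs, as.numeric(fields[3]))
        i <- i + 1L
      } else if (length(fields) == 1L && nzchar(fields[1])) {
        sizes <- c(sizes, as.numeric(fields[1]))
        dts <- c(dts, 0); dqs <- c(dqs, 0)
        i <- i + 1L
        break
      } else {
        stop(sprintf("line %d: malformed block line '%s'", i, lines[i]))
      }
    }
    ch$blocks <- data.frame(size = sizes, dt = dts, dq = dqs)
    t_span <- sum(sizes) + sum(dts)
    q_span <- sum(sizes) + sum(dqs)
    if (t_span != ch$t_end - ch$t_start)
      stop(sprintf("line %d: block sizes + target gaps (%g) do not sum to target span (%g)",
                   hdr_line, t_span, ch$t_end - ch$t_start))
    if (q_span != ch$q_end - ch$q_start)
      stop(sprintf("line %d: block sizes + query gaps (%g) do not sum to query span (%g)",
                   hdr_line, q_span, ch$q_end - ch$q_start))
    if (ch$t_start < 0 || ch$t_start >= ch$t_end || ch$t_end > ch$t_size ||
        ch$q_start < 0 || ch$q_start >= ch$q_end || ch$q_end > ch$q_size)
      stop(sprintf("line %d: coordinates out of range", hdr_line))
    chains[[length(chains) + 1L]] <- ch
  }
  chains
}

#' Write chains in UCSC chain format
#'
#' Emits the canonical dialect: space-separated header, tab-separated block
#' lines, a bare `size` on the final block, one blank line after each record.
#' [read_chain()] followed by `write_chain()` is byte-identical on files in
#' this dialect.
#'
#' @param chains List of chains as returned by [read_chain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  fmt_num <- function(x) format(x, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", fmt_num(ch$score), ch$t_name, fmt_num(ch$t_size),
                     ch$t_strand, fmt_num(ch$t_start), fmt_num(ch$t_end),
                     ch$q_name, fmt_num(ch$q_size), ch$q_strand,
                     fmt_num(ch$q_start), fmt_num(ch$q_end), ch$id), con)
    b <- ch$blocks
    nb <- nrow(b)
    if (nb > 1L)
      writeLines(paste(fmt_num(b$size[-nb]), fmt_num(b$dt[-nb]),
                       fmt_num(b$dq[-nb]), sep = "\t"), con)
    writeLines(fmt_num(b$size[nb]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Aligned bases of a chain
#'
#' Sum of ungapped block sizes.
#' @param chain A single chain, or a list of chains (vectorised).
#' @return Numeric.
#' @export
chain_aligned_bp <- function(chain) {
  if (!is.null(chain$blocks)) return(sum(chain$blocks$size))
  vapply(chain, function(ch) sum(ch$blocks$size), numeric(1))
}

#' Query span of a chain on the forward strand
#'
#' Chain query coordinates on the `-` strand refer to the reverse-complemented
#' sequence; this converts them to forward-strand coordinates.
#'
#' @param chain A single chain.
#' @return Numeric vector `c(start, end)`, 0-based half-open, forward strand.
#' @export
chain_query_forward <- function(chain) {
  if (chain$q_strand == "+") c(chain$q_start, chain$q_end)
  else c(chain$q_size - chain$q_end, chain$q_size - chain$q_start)
}

#' Filter chains by aligned length
#'
#' Keeps chains whose aligned bases reach `min_len`, preserving order. The
#' thresholds used for vertebrate comparisons and for amphioxus are 100 kb
#' and 5 kb respectively.
#'
#' @param chains List of chains.
#' @param min_len Minimum aligned bp (>= 0).
#' @return Filtered list of chains.
#' @export
filter_chains <- function(chains, min_len) {
  stopifnot(min_len >= 0)
  if (length(chains) == 0L) return(chains)
  chains[chain_aligned_bp(chains) >= min_len]
}

#' Reduce chains to reciprocal-best syntenic blocks
#'
#' Single-level greedy netting: chains are processed in descending score
#' (ties broken by ascending chain id) and a chain is accepted iff its span
#' overlaps the spans of previously accepted chains by at most `overlap_tol`
#' bp on the query genome and at most `overlap_tol` bp on the target genome.
#' Accepted chains become syntenic blocks — units of conserved homology that
#' all downstream statistics consume. With the default `overlap_tol = 0` the
#' accepted blocks are strictly non-overlapping on both genomes.
#'
#' @param chains List of chains (one species pair; chromosome sizes must be
#'   consistent across chains).
#' @param overlap_tol Maximum tolerated overlap in bp with already-accepted
#'   spans, per genome side.
#' @return A data.frame of syntenic blocks: `q_chrom`, `q_start`, `q_end`
#'   (forward strand), `t_chrom`, `t_start`, `t_end`, `orientation`
#'   (`"same"`/`"inverted"`), `aligned_bp`, `score`, `chain_id`.
#' @export
reciprocal_best <- function(chains, overlap_tol = 0) {
  stopifnot(overlap_tol >= 0)
  empty <- data.frame(q_chrom = character(0), q_start = numeric(0),
                      q_end = numeric(0), t_chrom = character(0),
                      t_start = numeric(0), t_end = numeric(0),
                      orientation = character(0), aligned_bp = numeric(0),
                      score = numeric(0), chain_id = integer(0),
                      stringsAsFactors = FALSE)
  if (length(chains) == 0L) return(empty)
  sizes <- list()
  for (ch in chains) {
    for (side in list(c(ch$q_name, ch$q_size, "q"),
                      c(ch$t_name, ch$t_size, "t"))) {
      key <- paste0(side[3], ":", side[1])
      if (!is.null(sizes[[key]]) && sizes[[key]] != as.numeric(side[2]))
        stop(sprintf("inconsistent size for chromosome %s across chains", side[1]))
      sizes[[key]] <- as.numeric(side[2])
    }
  }
  ord <- order(-vapply(chains, `[[`, numeric(1), "score"),
               vapply(chains, `[[`, integer(1), "id"))
  # claimed spans per genome side and chromosome, kept as disjoint sorted
  # (start, end) matrices so overlap against the union is a vector op
  accepted <- new.env(parent = emptyenv())
  ov_union <- function(key, s, e) {
    m <- accepted[[key]]
    if (is.null(m)) return(0)
    sum(pmax(0, pmin(e, m[, 2]) - pmax(s, m[, 1])))
  }
  claim <- function(key, s, e) {
    m <- accepted[[key]]
    if (is.null(m)) {
      accepted[[key]] <- matrix(c(s, e), 1)
      return(invisible())
    }
    hit <- m[, 2] >= s & m[, 1] <= e   # touching or overlapping rows merge
    if (any(hit)) {
      s <- min(s, m[hit, 1]); e <- max(e, m[hit, 2])
      m <- m[!hit, , drop = FALSE]
    }
    m <- rbind(m, c(s, e))
    accepted[[key]] <- m[order(m[, 1]), , drop = FALSE]
  }
  out <- list()
  for (ch in chains[ord]) {
    qf <- chain_query_forward(ch)
    q_key <- paste0("q:", ch$q_name)
    t_key <- paste0("t:", ch$t_name)
    if (ov_union(q_key, qf[1], qf[2]) > overlap_tol ||
        ov_union(t_key, ch$t_start, ch$t_end) > overlap_tol)
      next
    claim(q_key, qf[1], qf[2])
    claim(t_key, ch$t_start, ch$t_end)
    out[[length(out) + 1L]] <- data.frame(
      q_chrom = ch$q_name, q_start = qf[1], q_end = qf[2],
      t_chrom = ch$t_name, t_start = ch$t_start, t_end = ch$t_end,
      orientation = if (ch$q_strand == ch$t_strand) "same" else "inverted",
      aligned_bp = sum(ch$blocks$size), score = ch$score, chain_id = ch$id,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Swap the query and target sides of a syntenic-block table
#'
#' Chains are directional (one genome is the target of the alignment run);
#' homology statistics sometimes need the opposite orientation of the same
#' block set.
#'
#' @param blocks A syntenic-block data.frame from [reciprocal_best()].
#' @return The block table with query and target columns exchanged.
#' @export
invert_blocks <- function(blocks) {
  out <- blocks
  out$q_chrom <- blocks$t_chrom; out$q_start <- blocks$t_start
  out$q_end <- blocks$t_end
  out$t_chrom <- blocks$q_chrom; out$t_start <- blocks$q_start
  out$t_end <- blocks$q_end
  out
}

#' Export syntenic blocks as BED
#'
#' Writes the query- or target-side intervals of a block table as BED3+
#' (chrom, start, end, partner, score, strand).
#'
#' @param blocks Syntenic-block data.frame.
#' @param path Output path.
#' @param side `"query"` or `"target"`.
#' @return `path`, invisibly.
#' @export
blocks_to_bed <- function(blocks, path, side = c("target", "query")) {
  side <- match.arg(side)
  p <- if (side == "target") c("t_", "q_") else c("q_", "t_")
  bed <- data.frame(blocks[[paste0(p[1], "chrom")]],
                    format(blocks[[paste0(p[1], "start")]], scientific = FALSE,
                           trim = TRUE),
                    format(blocks[[paste0(p[1], "end")]], scientific = FALSE,
                           trim = TRUE),
                    blocks[[paste0(p[2], "chrom")]],
                    blocks$score,
                    ifelse(blocks$orientation == "same", "+", "-"))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Lint a chain file
#'
#' Non-throwing format check: returns one finding per problem instead of
#' raising. A clean file yields an empty data.frame.
#'
#' @param path Path to a chain file.
#' @return data.frame with columns `file`, `finding`.
#' @export
validate_chain_file <- function(path) {
  res <- tryCatch({ read_chain(path); NULL }, error = conditionMessage)
  if (is.null(res))
    data.frame(file = character(0), finding = character(0))
  else data.frame(file = path, finding = res, stringsAsFactors = FALSE)
}
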