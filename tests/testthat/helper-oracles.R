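# Brute-force oracles and small fixture builders shared across tests.
# Oracles are deliberately naive re-derivations, independent of the package
# implementations they check.

# naive greedy netting: plain loops and interval arithmetic, no IRanges
greedy_net_oracle <- function(chains, overlap_tol = 0) {
  if (length(chains) == 0L) return(integer(0))
  scores <- vapply(chains, `[[`, numeric(1), "score")
  ids <- vapply(chains, `[[`, integer(1), "id")
  ord <- order(-scores, ids)
  acc_q <- list(); acc_t <- list()   # chrom -> matrix of (start, end)
  accepted <- integer(0)
  ov_len <- function(intervals, s, e) {
    if (is.null(intervals)) return(0)
    tot <- 0
    for (r in seq_len(nrow(intervals))) {
      tot <- tot + max(0, min(e, intervals[r, 2]) - max(s, intervals[r, 1]))
    }
    tot
  }
  for (k in ord) {
    ch <- chains[[k]]
    qf <- if (ch$q_strand == "+") c(ch$q_start, ch$q_end) else
      c(ch$q_size - ch$q_end, ch$q_size - ch$q_start)
    if (ov_len(acc_q[[ch$q_name]], qf[1], qf[2]) > overlap_tol) next
    if (ov_len(acc_t[[ch$t_name]], ch$t_start, ch$t_end) > overlap_tol) next
    acc_q[[ch$q_name]] <- rbind(acc_q[[ch$q_name]], qf)
    acc_t[[ch$t_name]] <- rbind(acc_t[[ch$t_name]], c(ch$t_start, ch$t_end))
    accepted <- c(accepted, ch$id)
  }
  sort(accepted)
}

# dense symmetric matrix from a contact_matrix
dense_contacts <- function(cm) {
  n <- nrow(cm$bins)
  m <- matrix(0, n, n)
  for (r in seq_len(nrow(cm$counts))) {
    i <- cm$counts$i[r]; j <- cm$counts$j[r]
    m[i, j] <- m[i, j] + cm$counts$count[r]
    if (i != j) m[j, i] <- m[j, i] + cm$counts$count[r]
  }
  m
}

# double-loop mean interaction between scaffolds, largest first
heatmap_oracle <- function(cm) {
  m <- dense_contacts(cm)
  lens <- vapply(split(cm$bins$end, cm$bins$chrom), max, numeric(1))
  scaffolds <- names(lens)[order(-lens, names(lens))]
  out <- matrix(0, length(scaffolds), length(scaffolds),
                dimnames = list(scaffolds, scaffolds))
  for (a in scaffolds) for (b in scaffolds) {
    ia <- which(cm$bins$chrom == a); ib <- which(cm$bins$chrom == b)
    tot <- 0
    for (x in ia) for (y in ib) tot <- tot + m[x, y]
    out[a, b] <- tot / (length(ia) * length(ib))
  }
  out
}

# enumerate every intra-scaffold bin pair for one class
ps_oracle <- function(cm, scaffold_class, cl, max_dist = 1e8,
                      min_dist = cm$bin_size, n_dist_bins = 30) {
  m <- dense_contacts(cm)
  edges <- exp(seq(log(min_dist), log(max_dist), length.out = n_dist_bins + 1))
  edges[1] <- min_dist; edges[length(edges)] <- max_dist
  n_pairs <- rep(0, n_dist_bins); sum_counts <- rep(0, n_dist_bins)
  for (ch in names(scaffold_class)[scaffold_class == cl]) {
    idx <- which(cm$bins$chrom == ch)
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      s <- (b - a) * cm$bin_size
      db <- NA
      for (q in seq_len(n_dist_bins)) {
        if (s >= edges[q] &&
            (s < edges[q + 1] ||
             (q == n_dist_bins && s <= edges[q + 1]))) { db <- q; break }
      }
      if (is.na(db)) next
      n_pairs[db] <- n_pairs[db] + 1
      sum_counts[db] <- sum_counts[db] + m[idx[a], idx[b]]
    }
  }
  ifelse(n_pairs > 0, sum_counts / n_pairs, NA_real_)
}

# random chain set on fixed small genomes (consistent sizes)
random_chains <- function(n, seed, q_chroms = c(qA = 5e5, qB = 4e5),
                          t_chroms = c(tA = 6e5, tB = 3e5)) {
  set.seed(seed)
  lapply(seq_len(n), function(k) {
    qn <- sample(names(q_chroms), 1); tn <- sample(names(t_chroms), 1)
    size <- round(runif(1, 1e3, 8e4))
    qs <- round(runif(1, 0, q_chroms[[qn]] - size))
    ts <- round(runif(1, 0, t_chroms[[tn]] - size))
    list(score = round(runif(1, 1, 1000)),
         t_name = tn, t_size = t_chroms[[tn]], t_strand = "+",
         t_start = ts, t_end = ts + size,
         q_name = qn, q_size = q_chroms[[qn]],
         q_strand = sample(c("+", "-"), 1),
         q_start = qs, q_end = qs + size,
         id = k, blocks = data.frame(size = size, dt = 0, dq = 0))
  })
}

# random sparse contact matrix on <= 100 bins
random_cm <- function(seed, scaffold_bins = c(s1 = 7, s2 = 5),
                      bin_size = 5e4, density = 0.4) {
  set.seed(seed)
  bins <- do.call(rbind, lapply(names(scaffold_bins), function(ch) {
    n <- scaffold_bins[[ch]]
    data.frame(chrom = ch, start = (seq_len(n) - 1) * bin_size,
               end = seq_len(n) * bin_size, stringsAsFactors = FALSE)
  }))
  n <- nrow(bins)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < density
  counts <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                       count = round(runif(sum(keep), 0.5, 20), 1))
  contact_matrix(bins, counts, bin_size)
}

# two-species toy karyotypes for hand-built block tables
toy_karyotype <- function(species, lengths, threshold = 35e6,
                          centromere = NULL) {
  ch <- data.frame(name = names(lengths), length = unname(lengths),
                   stringsAsFactors = FALSE)
  if (!is.null(centromere)) ch$centromere <- centromere
  classify_chromosomes(karyotype(species, ch, threshold))
}

# hand-built syntenic block row
block_row <- function(q_chrom, q_start, q_end, t_chrom, t_start, t_end,
                      score = q_end - q_start, aligned_bp = q_end - q_start,
                      orientation = "same", chain_id = 1L) {
  data.frame(q_chrom = q_chrom, q_start = q_start, q_end = q_end,
             t_chrom = t_chrom, t_start = t_start, t_end = t_end,
             orientation = orientation, aligned_bp = aligned_bp,
             score = score, chain_id = chain_id, stringsAsFactors = FALSE)
}
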