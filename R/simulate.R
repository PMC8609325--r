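#' Simulate an ancestral amniote-like karyotype
#'
#' Draws a bi-modal karyotype of the kind shared by birds and many reptiles:
#' a few large macrochromosomes and many small, GC-rich, gene-dense
#' microchromosomes. Defaults echo the inferred ancestral bird/reptile state
#' of 9 macrochromosomes and about 30 microchromosomes below a 35-Mb
#' threshold, with microchromosome GC elevated by a fixed offset and gene
#' density roughly 40 genes/Mb on micros versus 17 on macros.
#'
#' @param n_macro,n_micro Chromosome counts per class.
#' @param micro_threshold Size threshold in bp.
#' @param macro_size_range,micro_size_range Uniform length ranges (bp); the
#'   macro range must sit at or above the threshold and the micro range
#'   strictly below it.
#' @param gc_macro_mean Mean GC of macrochromosomes.
#' @param gc_offset Added to the macro mean to give the micro GC mean.
#' @param gc_sd Per-chromosome GC standard deviation.
#' @param gene_density_macro,gene_density_micro Mean genes per Mb.
#' @param species Species label.
#' @param seed Integer seed; identical seed and parameters give identical
#'   output.
#' @return A classified [karyotype].
#' @export
simulate_ancestor <- function(n_macro = 9, n_micro = 30,
                              micro_threshold = 35e6,
                              macro_size_range = c(45e6, 210e6),
                              micro_size_range = c(4e6, 30e6),
                              gc_macro_mean = 0.41, gc_offset = 0.06,
                              gc_sd = 0.01,
                              gene_density_macro = 17,
                              gene_density_micro = 40,
                              species = "ancestor", seed = NULL) {
  if (micro_size_range[2] >= micro_threshold)
    stop("micro size range must lie strictly below the threshold")
  if (macro_size_range[1] < micro_threshold)
    stop("macro size range must lie at or above the threshold")
  if (!is.null(seed)) set.seed(seed)
  mac_len <- sort(round(stats::runif(n_macro, macro_size_range[1],
                                     macro_size_range[2]), -4),
                  decreasing = TRUE)
  mic_len <- sort(round(stats::runif(n_micro, micro_size_range[1],
                                     micro_size_range[2]), -4),
                  decreasing = TRUE)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  gc <- clamp(c(stats::rnorm(n_macro, gc_macro_mean, gc_sd),
                stats::rnorm(n_micro, gc_macro_mean + gc_offset, gc_sd)),
              0.25, 0.70)
  dens <- c(stats::rnorm(n_macro, gene_density_macro,
                         0.1 * gene_density_macro),
            stats::rnorm(n_micro, gene_density_micro,
                         0.1 * gene_density_micro))
  lens <- c(mac_len, mic_len)
  chroms <- data.frame(
    name = c(sprintf("mac%d", seq_len(n_macro)),
             sprintf("mic%d", seq_len(n_micro))),
    length = lens, gc = gc,
    n_genes = round(pmax(dens, 1) * lens / 1e6),
    stringsAsFactors = FALSE)
  classify_chromosomes(karyotype(species, chroms, micro_threshold,
                                 expected_n = n_macro + n_micro))
}

# internal chromosome state during event replay: list(name, segments
# data.frame(anc_chrom, anc_start, anc_end), gaps (unaligned derived bp
# after each segment), centromere)
new_state <- function(kar) {
  lapply(seq_len(nrow(kar$chromosomes)), function(i) {
    ch <- kar$chromosomes[i, ]
    list(name = ch$name,
         segments = data.frame(anc_chrom = ch$name, anc_start = 0,
                               anc_end = ch$length,
                               stringsAsFactors = FALSE),
         gaps = 0, centromere = NA_real_)
  })
}

state_len <- function(st)
  sum(st$segments$anc_end - st$segments$anc_start) + sum(st$gaps)

#' Apply fusion/fission/expansion events to a karyotype
#'
#' Replays an explicit event list, or draws random events, on an ancestral
#' karyotype and returns the full history: derived karyotype, event log, and
#' the segment map tying every derived interval back to its ancestral
#' source. Supported event types:
#' \describe{
#'   \item{micro_micro_fusion}{two (or more) microchromosomes joined end to
#'     end (`placement = "tandem"`) or at their centromeres
#'     (`placement = "centric"`, records the junction as a centromere).}
#'   \item{macro_micro_fusion}{a microchromosome joined to a macrochromosome
#'     terminus (`placement = "terminal"`, `end = "start"`/`"end"`) or as a
#'     whole new arm (`placement = "centric"`).}
#'   \item{macro_macro_fusion}{two macrochromosomes joined end to end.}
#'   \item{fission}{one chromosome split at `breakpoint` (bp; random in the
#'     25-75\% interior if missing).}
#'   \item{expansion}{derived length scaled by `factor` through insertion of
#'     unaligned sequence (transposable-element-like), spread proportionally
#'     between conserved segments.}
#' }
#' Fused chromosomes take the name `A+B`; fission products `A_p1`, `A_p2`.
#' Derived GC is the length-weighted mean of the ancestral sources; a
#' chromosome cannot fuse with itself. In random mode each ancestral
#' chromosome participates in at most one event; explicit event lists may
#' reference event products.
#'
#' @param kar Ancestral classified [karyotype].
#' @param events Explicit list of events (each a list with `type` and the
#'   fields above), or `NULL` to draw randomly.
#' @param n_events Number of random events when `events` is `NULL`.
#' @param event_weights Named sampling weights over
#'   `c("micro_micro_fusion", "macro_micro_fusion", "fission")` for random
#'   mode.
#' @param seed Integer seed.
#' @return A `simulated_history`: list with `ancestor`, `derived`
#'   ([karyotype]s), `events` (log, with `products` filled in), `segments`
#'   (data.frame `der_chrom`, `der_start`, `der_end`, `anc_chrom`,
#'   `anc_start`, `anc_end`) and `seed`.
#' @export
apply_events <- function(kar, events = NULL, n_events = 10,
                         event_weights = c(micro_micro_fusion = 1,
                                           macro_micro_fusion = 1,
                                           fission = 1),
                         seed = NULL) {
  stopifnot(inherits(kar, "karyotype"))
  if (!is.null(seed)) set.seed(seed)
  state <- new_state(kar)
  names(state) <- vapply(state, `[[`, character(1), "name")
  classes <- chrom_class_of(kar)

  if (is.null(events)) {
    events <- list()
    used <- character(0)
    avail <- function(cl) setdiff(names(classes)[classes == cl], used)
    types <- names(event_weights)
    for (e in seq_len(n_events)) {
      drawn <- FALSE
      for (attempt in seq_len(50)) {
        ty <- sample(types, 1, prob = event_weights)
        if (ty == "micro_micro_fusion" && length(avail("micro")) >= 2) {
          parts <- sample(avail("micro"), 2)
          events[[length(events) + 1]] <-
            list(type = ty, parts = parts, placement = "tandem")
          used <- c(used, parts); drawn <- TRUE; break
        }
        if (ty == "macro_micro_fusion" && length(avail("macro")) >= 1 &&
            length(avail("micro")) >= 1) {
          parts <- c(sample(avail("macro"), 1), sample(avail("micro"), 1))
          events[[length(events) + 1]] <-
            list(type = ty, parts = parts, placement = "terminal",
                 end = sample(c("start", "end"), 1))
          used <- c(used, parts); drawn <- TRUE; break
        }
        if (ty == "fission" && length(avail("macro")) >= 1) {
          part <- sample(avail("macro"), 1)
          events[[length(events) + 1]] <- list(type = ty, parts = part)
          used <- c(used, part); drawn <- TRUE; break
        }
      }
      if (!drawn) stop("could not draw an event; chromosomes exhausted")
    }
  }

  log <- list()
  for (ev in events) {
    ty <- ev$type
    parts <- ev$parts
    missing <- setdiff(parts, names(state))
    if (length(missing))
      stop("event references unknown chromosome(s): ",
           paste(missing, collapse = ", "))
    if (anyDuplicated(parts))
      stop("cannot fuse a chromosome with itself")
    if (ty %in% c("micro_micro_fusion", "macro_micro_fusion",
                  "macro_macro_fusion")) {
      placement <- if (is.null(ev$placement)) "tandem" else ev$placement
      sts <- state[parts]
      if (ty == "macro_micro_fusion" &&
          !is.null(ev$end) && ev$end == "start") {
        sts <- rev(sts)  # micro goes in front of the macro
      }
      merged <- list(
        name = paste(parts, collapse = "+"),
        segments = do.call(rbind, lapply(sts, `[[`, "segments")),
        gaps = unlist(lapply(sts, `[[`, "gaps")),
        centromere = NA_real_)
      rownames(merged$segments) <- NULL
      if (placement == "centric")
        merged$centromere <- state_len(sts[[1]])
      state[parts] <- NULL
      state[[merged$name]] <- merged
      log[[length(log) + 1]] <- list(type = ty, parts = parts,
                                     placement = placement,
                                     products = merged$name)
    } else if (ty == "fission") {
      st <- state[[parts]]
      L <- state_len(st)
      bp <- if (is.null(ev$breakpoint))
        round(stats::runif(1, 0.25, 0.75) * L) else ev$breakpoint
      if (bp <= 0 || bp >= L) stop("fission breakpoint outside chromosome")
      seg_len <- st$segments$anc_end - st$segments$anc_start
      der_end <- cumsum(seg_len + st$gaps)
      der_start <- der_end - seg_len - st$gaps
      left_segs <- list(); left_gaps <- numeric(0)
      right_segs <- list(); right_gaps <- numeric(0)
      for (i in seq_len(nrow(st$segments))) {
        s <- st$segments[i, ]
        s0 <- der_start[i]; s1 <- s0 + seg_len[i]
        if (s1 <= bp) {
          left_segs[[length(left_segs) + 1]] <- s
          left_gaps <- c(left_gaps, min(st$gaps[i], bp - s1))
        } else if (s0 >= bp) {
          right_segs[[length(right_segs) + 1]] <- s
          right_gaps <- c(right_gaps, st$gaps[i])
        } else {          # split this segment
          cut <- bp - s0
          sl <- s; sl$anc_end <- s$anc_start + cut
          sr <- s; sr$anc_start <- s$anc_start + cut
          left_segs[[length(left_segs) + 1]] <- sl
          left_gaps <- c(left_gaps, 0)
          right_segs[[length(right_segs) + 1]] <- sr
          right_gaps <- c(right_gaps, st$gaps[i])
        }
      }
      p1 <- list(name = paste0(st$name, "_p1"),
                 segments = do.call(rbind, left_segs), gaps = left_gaps,
                 centromere = NA_real_)
      p2 <- list(name = paste0(st$name, "_p2"),
                 segments = do.call(rbind, right_segs), gaps = right_gaps,
                 centromere = NA_real_)
      state[[parts]] <- NULL
      state[[p1$name]] <- p1
      state[[p2$name]] <- p2
      log[[length(log) + 1]] <- list(type = ty, parts = parts,
                                     breakpoint = bp,
                                     products = c(p1$name, p2$name))
    } else if (ty == "expansion") {
      factor <- ev$factor
      if (is.null(factor) || factor < 1) stop("expansion factor must be >= 1")
      targets <- if (is.null(parts)) names(state) else parts
      for (nm in targets) {
        st <- state[[nm]]
        seg_len <- st$segments$anc_end - st$segments$anc_start
        add <- (factor - 1) * state_len(st)
        st$gaps <- st$gaps + round(add * seg_len / sum(seg_len))
        state[[nm]] <- st
      }
      log[[length(log) + 1]] <- list(type = ty, parts = targets,
                                     factor = factor, products = targets)
    } else stop("unknown event type: ", ty)
  }

  # derived karyotype + segment map
  anc <- kar$chromosomes
  anc_gc <- stats::setNames(anc$gc, anc$name)
  anc_genes <- stats::setNames(anc$n_genes, anc$name)
  anc_len <- stats::setNames(anc$length, anc$name)
  der_rows <- list(); seg_rows <- list()
  for (st in state) {
    seg_len <- st$segments$anc_end - st$segments$anc_start
    L <- state_len(st)
    der_end <- cumsum(seg_len + st$gaps) - st$gaps
    der_start <- der_end - seg_len
    w <- seg_len / sum(seg_len)
    der_rows[[length(der_rows) + 1]] <- data.frame(
      name = st$name, length = L,
      gc = sum(w * anc_gc[st$segments$anc_chrom]),
      n_genes = round(sum(seg_len / anc_len[st$segments$anc_chrom] *
                            anc_genes[st$segments$anc_chrom])),
      centromere = st$centromere, stringsAsFactors = FALSE)
    seg_rows[[length(seg_rows) + 1]] <- data.frame(
      der_chrom = st$name, der_start = der_start, der_end = der_end,
      anc_chrom = st$segments$anc_chrom,
      anc_start = st$segments$anc_start, anc_end = st$segments$anc_end,
      stringsAsFactors = FALSE)
  }
  derived <- classify_chromosomes(karyotype(
    species = paste0(kar$species, "_derived"),
    chromosomes = do.call(rbind, der_rows),
    micro_threshold = kar$micro_threshold,
    expected_n = length(state)))
  segments <- do.call(rbind, seg_rows)
  rownames(segments) <- NULL
  structure(list(ancestor = kar, derived = derived, events = log,
                 segments = segments, seed = seed),
            class = "simulated_history")
}

#' @export
print.simulated_history <- function(x, ...) {
  cat(sprintf("simulated_history: %d -> %d chromosomes, %d events\n",
              nrow(x$ancestor$chromosomes), nrow(x$derived$chromosomes),
              length(x$events)))
  for (ev in x$events)
    cat(sprintf("  %s(%s) -> %s\n", ev$type,
                paste(ev$parts, collapse = ","),
                paste(ev$products, collapse = ",")))
  invisible(x)
}

#' Expected rearrangement calls implied by a simulated history
#'
#' Translates the ground-truth event log into the call the rearrangement
#' caller should make for each derived chromosome: fusion products carry
#' their fusion type (terminal placement maps to
#' `macro_micro_fusion_terminal`), fission products map to
#' `fission_new_micro`/`fission_new_macro` by their derived size class, and
#' untouched or merely expanded chromosomes are `conserved_micro`/`_macro`.
#'
#' @param history A `simulated_history`.
#' @return data.frame with `target_chrom` and `expected`.
#' @export
expected_event_calls <- function(history) {
  der <- history$derived$chromosomes
  expected <- stats::setNames(
    ifelse(der$chrom_class == "micro", "conserved_micro", "conserved_macro"),
    der$name)
  for (ev in history$events) {
    if (ev$type == "micro_micro_fusion")
      expected[ev$products] <- "micro_micro_fusion"
    else if (ev$type == "macro_micro_fusion")
      expected[ev$products] <- if (!is.null(ev$placement) &&
                                   ev$placement == "centric")
        "macro_micro_fusion_centric" else "macro_micro_fusion_terminal"
    else if (ev$type == "macro_macro_fusion")
      expected[ev$products] <- "macro_macro_fusion"
    else if (ev$type == "fission") {
      cls <- der$chrom_class[match(ev$products, der$name)]
      expected[ev$products] <- ifelse(cls == "micro", "fission_new_micro",
                                      "fission_new_macro")
    }
  }
  data.frame(target_chrom = names(expected), expected = unname(expected),
             stringsAsFactors = FALSE)
}

#' Score event recovery against a simulated history
#'
#' Recall: among derived chromosomes whose ground truth is a rearrangement
#' (not conserved), the fraction whose called event type matches exactly.
#' Precision: among chromosomes called with a rearrangement type, the
#' fraction whose ground truth matches exactly.
#'
#' @param calls data.frame from [call_events()].
#' @param history A `simulated_history` (or a data.frame as returned by
#'   [expected_event_calls()]).
#' @return list with `recall`, `precision`, `n_truth`, `n_called`.
#' @export
score_event_recovery <- function(calls, history) {
  expected <- if (inherits(history, "simulated_history"))
    expected_event_calls(history) else history
  m <- merge(calls[, c("target_chrom", "event")], expected,
             by = "target_chrom")
  is_event <- function(x) !x %in% c("conserved_micro", "conserved_macro",
                                    "unresolved")
  truth <- m[is_event(m$expected), , drop = FALSE]
  called <- m[is_event(m$event), , drop = FALSE]
  list(recall = if (nrow(truth)) mean(truth$event == truth$expected) else NA,
       precision = if (nrow(called))
         mean(called$event == called$expected) else NA,
       n_truth = nrow(truth), n_called = nrow(called))
}

#' Emit alignment chains for a simulated history
#'
#' Produces the chain set a whole-genome aligner would recover between the
#' ancestor (query side) and the derived genome (target side). Every
#' conserved segment yields at least one chain; fragmentation noise splits
#' segments into several chains separated by small unaligned gaps. Scores
#' are proportional to aligned length; chain ids are sequential along the
#' derived genome.
#'
#' @param history A `simulated_history`.
#' @param frag_rate Expected number of chain breaks per Mb of conserved
#'   segment (0 disables fragmentation).
#' @param gap_frac Fraction of each fragmented segment lost to unaligned
#'   gaps at the break points.
#' @param seed Integer seed.
#' @param path Optional output path; when given, the chains are also written
#'   in UCSC chain format.
#' @return List of chains (see [read_chain()]).
#' @export
emit_chains <- function(history, frag_rate = 0.5, gap_frac = 0.05,
                        seed = NULL, path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc_len <- chrom_length_of(history$ancestor)
  der_len <- chrom_length_of(history$derived)
  chains <- list()
  id <- 0L
  segs <- history$segments
  for (r in seq_len(nrow(segs))) {
    s <- segs[r, ]
    len <- s$anc_end - s$anc_start
    n_cuts <- if (frag_rate > 0) stats::rpois(1, frag_rate * len / 1e6) else 0L
    cuts <- if (n_cuts > 0)
      sort(unique(round(stats::runif(n_cuts, 0.02, 0.98) * len))) else numeric(0)
    n_cuts <- length(cuts)
    g <- if (n_cuts > 0) floor(gap_frac * len / n_cuts) else 0
    lo <- c(0, cuts + ceiling(g / 2))
    hi <- c(cuts - floor(g / 2), len)
    keep <- hi - lo > 0
    lo <- lo[keep]; hi <- hi[keep]
    for (k in seq_along(lo)) {
      id <- id + 1L
      size <- hi[k] - lo[k]
      chains[[id]] <- list(
        score = size,
        t_name = s$der_chrom, t_size = unname(der_len[s$der_chrom]),
        t_strand = "+",
        t_start = s$der_start + lo[k], t_end = s$der_start + hi[k],
        q_name = s$anc_chrom, q_size = unname(anc_len[s$anc_chrom]),
        q_strand = "+",
        q_start = s$anc_start + lo[k], q_end = s$anc_start + hi[k],
        id = id,
        blocks = data.frame(size = size, dt = 0, dq = 0))
    }
  }
  if (!is.null(path)) write_chain(chains, path)
  chains
}

#' Simulate a binned Hi-C contact matrix
#'
#' Generates Poisson counts with power-law intra-chromosomal decay and
#' class-dependent trans contacts. Within a chromosome the expected count of
#' a bin pair at separation d bins is `intra_scale * d^(-alpha)`, with alpha
#' chosen by the chromosome's class (microchromosomes decay more slowly,
#' i.e. are more compact). Between chromosomes the expectation is
#' `trans_base * f(a) * f(b)` where the per-chromosome contact propensity
#' `f` is `sqrt(micro_trans_factor)` for microchromosomes and 1 for
#' macrochromosomes — so micro-micro pairs are enriched
#' `micro_trans_factor`-fold over macro-macro pairs and mixed pairs sit at
#' the geometric midpoint, reproducing the graded trans-contact ordering of
#' real bird Hi-C maps.
#'
#' @param kar Classified [karyotype].
#' @param alpha_macro,alpha_micro Intra-chromosomal decay exponents (> 0).
#' @param intra_scale Expected count at one-bin separation.
#' @param trans_base Expected count per macro-macro trans bin pair.
#' @param micro_trans_factor Micro-micro trans enrichment factor (>= 1).
#' @param bin_size Bin width in bp (default 50 kb); must not exceed the
#'   smallest chromosome.
#' @param seed Integer seed.
#' @return A [contact_matrix].
#' @export
simulate_hic <- function(kar, alpha_macro = 1.5, alpha_micro = 1.0,
                         intra_scale = 50, trans_base = 0.3,
                         micro_trans_factor = 3, bin_size = 5e4,
                         seed = NULL) {
  stopifnot(inherits(kar, "karyotype"))
  if (alpha_macro <= 0 || alpha_micro <= 0) stop("alpha values must be > 0")
  if (micro_trans_factor < 1) stop("micro_trans_factor must be >= 1")
  ch <- kar$chromosomes
  if (bin_size > min(ch$length))
    stop("bin_size larger than the smallest chromosome")
  if (!all(ch$chrom_class %in% c("macro", "micro")))
    stop("karyotype must be classified first")
  if (!is.null(seed)) set.seed(seed)
  n_bins <- ceiling(ch$length / bin_size)
  offset <- cumsum(c(0, utils::head(n_bins, -1)))
  bins <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    n <- n_bins[i]
    data.frame(chrom = ch$name[i], start = (seq_len(n) - 1) * bin_size,
               end = pmin(seq_len(n) * bin_size, ch$length[i]),
               stringsAsFactors = FALSE)
  }))
  li <- list(); lj <- list(); lc <- list(); np <- 0L
  add <- function(i, j, cnt) {
    np <<- np + 1L
    li[[np]] <<- i; lj[[np]] <<- j; lc[[np]] <<- cnt
  }
  # intra-chromosomal decay
  for (c1 in seq_len(nrow(ch))) {
    alpha <- if (ch$chrom_class[c1] == "micro") alpha_micro else alpha_macro
    n <- n_bins[c1]
    for (d in seq_len(n - 1)) {
      lambda <- intra_scale * d^(-alpha)
      cnt <- stats::rpois(n - d, lambda)
      nz <- which(cnt > 0)
      if (length(nz))
        add(offset[c1] + nz, offset[c1] + nz + d, cnt[nz])
    }
  }
  # trans contacts: total Poisson + uniform placement == iid Poisson cells
  f <- ifelse(ch$chrom_class == "micro", sqrt(micro_trans_factor), 1)
  for (c1 in seq_len(nrow(ch) - 1)) {
    for (c2 in seq(c1 + 1, nrow(ch))) {
      lambda <- trans_base * f[c1] * f[c2]
      total <- stats::rpois(1, lambda * n_bins[c1] * n_bins[c2])
      if (total > 0) {
        a <- sample.int(n_bins[c1], total, replace = TRUE)
        b <- sample.int(n_bins[c2], total, replace = TRUE)
        add(offset[c1] + a, offset[c2] + b, rep(1, total))
      }
    }
  }
  contact_matrix(bins, data.frame(i = unlist(li), j = unlist(lj),
                                  count = unlist(lc)), bin_size)
}

#' Write a simulated genome as FASTA
#'
#' Emits one record per chromosome with i.i.d. bases at the chromosome's GC
#' content. Intended for reduced-scale karyotypes (sequence emission at full
#' chromosome sizes is rarely needed; lengths and GC values carry the same
#' information for the pipeline).
#'
#' @param kar A [karyotype] with `gc` present.
#' @param path Output FASTA path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
simulate_fasta <- function(kar, path, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- kar$chromosomes
  seqs <- vapply(seq_len(nrow(ch)), function(i) {
    gc <- ch$gc[i]
    paste(sample(c("A", "C", "G", "T"), ch$length[i], replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  }, character(1))
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ch$name
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Write the ground-truth event log as JSON
#'
#' @param history A `simulated_history`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(history, path) {
  jsonlite::write_json(
    list(seed = history$seed,
         n_ancestral = nrow(history$ancestor$chromosomes),
         n_derived = nrow(history$derived$chromosomes),
         events = history$events),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
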