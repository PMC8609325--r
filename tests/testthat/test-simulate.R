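test_that("simulate_ancestor respects counts, threshold and determinism", {
  kar <- simulate_ancestor(seed = 1)
  expect_equal(nrow(kar$chromosomes), 39)
  cls <- chrom_class_of(kar)
  expect_equal(sum(cls == "macro"), 9)
  expect_equal(sum(cls == "micro"), 30)
  lens <- chrom_length_of(kar)
  expect_true(all(lens[cls == "macro"] >= 35e6))
  expect_true(all(lens[cls == "micro"] < 35e6))

  expect_identical(simulate_ancestor(seed = 1), kar)
  expect_false(identical(simulate_ancestor(seed = 2), kar))

  # impossible constraints are configuration errors
  expect_error(simulate_ancestor(micro_size_range = c(30e6, 40e6)),
               "below the threshold")
  expect_error(simulate_ancestor(macro_size_range = c(10e6, 20e6)),
               "at or above")
})

test_that("realized GC offset between classes matches the configured offset", {
  diffs <- vapply(1:30, function(s) {
    kar <- simulate_ancestor(gc_offset = 0.06, seed = s)
    cls <- kar$chromosomes$chrom_class
    mean(kar$chromosomes$gc[cls == "micro"]) -
      mean(kar$chromosomes$gc[cls == "macro"])
  }, numeric(1))
  # sampling error of the mean difference: sd ~ gc_sd*sqrt(1/30+1/9) ~ 0.004
  expect_equal(mean(diffs), 0.06, tolerance = 0.01)
})

test_that("fusion, fission and expansion arithmetic is exact", {
  ch <- data.frame(name = c("A", "B", "M"),
                   length = c(10e6, 8e6, 100e6),
                   gc = c(0.50, 0.44, 0.40))
  kar <- classify_chromosomes(karyotype("toy", ch, 35e6))

  fus <- apply_events(kar, events = list(
    list(type = "micro_micro_fusion", parts = c("A", "B"))))
  d <- fus$derived$chromosomes
  expect_equal(d$length[d$name == "A+B"], 18e6)
  # GC is the length-weighted mean of the parts, exactly
  expect_equal(d$gc[d$name == "A+B"], (10 * 0.50 + 8 * 0.44) / 18)

  fis <- apply_events(kar, events = list(
    list(type = "fission", parts = "M", breakpoint = 30e6)))
  d2 <- fis$derived$chromosomes
  expect_equal(sort(d2$length[grepl("M_p", d2$name)]), c(30e6, 70e6))
  expect_equal(d2$chrom_class[d2$name == "M_p1"], "micro")  # 30 Mb < 35 Mb
  expect_equal(d2$chrom_class[d2$name == "M_p2"], "macro")

  exp_all <- apply_events(kar, events = list(
    list(type = "expansion", factor = 1.5)))
  d3 <- exp_all$derived$chromosomes
  expect_equal(d3$length[match(c("A", "B", "M"), d3$name)] /
                 ch$length, rep(1.5, 3), tolerance = 1e-6)
  # genome-wide scaling preserves the macro/micro size ordering
  expect_equal(order(d3$length), order(ch$length))

  expect_error(apply_events(kar, events = list(
    list(type = "micro_micro_fusion", parts = c("A", "A")))), "itself")
})

test_that("random histories are deterministic per seed and replay-consistent", {
  anc <- simulate_ancestor(seed = 10)
  h1 <- apply_events(anc, n_events = 10, seed = 20)
  h2 <- apply_events(anc, n_events = 10, seed = 20)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$derived, h2$derived)
  # the segment map reconstructs every derived chromosome's aligned length
  seg_len <- tapply(h1$segments$anc_end - h1$segments$anc_start,
                    h1$segments$der_chrom, sum)
  der_len <- chrom_length_of(h1$derived)
  expect_true(all(seg_len[names(der_len)] <= der_len))
  # without expansions the derived lengths equal the segment totals
  expect_equal(as.numeric(seg_len[names(der_len)]), unname(der_len))
  # ancestral material is conserved: every ancestor appears exactly once
  anc_cover <- tapply(h1$segments$anc_end - h1$segments$anc_start,
                      h1$segments$anc_chrom, sum)
  expect_equal(as.numeric(anc_cover[anc$chromosomes$name]),
               anc$chromosomes$length)
})

test_that("emit_chains at zero noise yields one full-length chain per segment", {
  anc <- simulate_ancestor(seed = 30)
  h <- apply_events(anc, events = list(), seed = 31)   # no events
  chains <- emit_chains(h, frag_rate = 0, seed = 32)
  expect_length(chains, 39)
  expect_equal(chain_aligned_bp(chains), unname(chrom_length_of(anc)))

  # tandem fusion: two chains on one derived chromosome with abutting spans
  hf <- apply_events(anc, events = list(
    list(type = "micro_micro_fusion", parts = c("mic1", "mic2"))))
  cf <- emit_chains(hf, frag_rate = 0)
  on_fused <- Filter(function(ch) ch$t_name == "mic1+mic2", cf)
  expect_length(on_fused, 2)
  spans <- t(vapply(on_fused, function(ch) c(ch$t_start, ch$t_end),
                    numeric(2)))
  spans <- spans[order(spans[, 1]), ]
  expect_equal(spans[2, 1], spans[1, 2])   # abutting
})

test_that("fragmentation keeps unaligned loss within the configured gap fraction", {
  anc <- simulate_ancestor(seed = 40)
  h <- apply_events(anc, n_events = 8, seed = 41)
  total <- sum(h$segments$anc_end - h$segments$anc_start)
  for (s in 1:5) {
    chains <- emit_chains(h, frag_rate = 0.5, gap_frac = 0.05, seed = s)
    aligned <- sum(chain_aligned_bp(chains))
    expect_lte(aligned, total)
    expect_gte(aligned, (1 - 0.05) * total)
  }
  # emitted chains are valid UCSC chains (round-trip through the parser)
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain(emit_chains(h, seed = 1), f)
  expect_silent(read_chain(f))
})

test_that("simulate_hic honours the null and enriched trans models", {
  kar <- simulate_ancestor(n_macro = 2, n_micro = 4,
                           macro_size_range = c(36e6, 40e6),
                           micro_size_range = c(5e6, 10e6), seed = 50)
  # k = 1: all trans pair classes share a mean, within sampling error
  cm1 <- simulate_hic(kar, micro_trans_factor = 1, seed = 51)
  tm1 <- trans_mean_by_class(cm1, kar)
  expect_lt(max(tm1$mean) / min(tm1$mean), 1.1)

  # k = 3: micro-micro enriched threefold over macro-macro
  ratios <- vapply(1:5, function(s) {
    cm <- simulate_hic(kar, micro_trans_factor = 3, seed = 100 + s)
    tm <- trans_mean_by_class(cm, kar)
    tm$mean[tm$pair_class == "micro-micro"] /
      tm$mean[tm$pair_class == "macro-macro"]
  }, numeric(1))
  expect_equal(mean(ratios), 3, tolerance = 0.15)

  expect_error(simulate_hic(kar, bin_size = 20e6), "smallest")
  expect_error(simulate_hic(kar, alpha_macro = -1), "alpha")
})

test_that("identical seeds give byte-identical simulator outputs", {
  kar <- simulate_ancestor(n_macro = 2, n_micro = 3,
                           macro_size_range = c(36e6, 40e6),
                           micro_size_range = c(4e6, 8e6), seed = 60)
  expect_identical(simulate_hic(kar, seed = 61), simulate_hic(kar, seed = 61))
  h <- apply_events(kar, n_events = 2, seed = 62)
  expect_identical(emit_chains(h, seed = 63), emit_chains(h, seed = 63))
})

test_that("event log serializes to JSON with products recorded", {
  anc <- simulate_ancestor(seed = 70)
  h <- apply_events(anc, n_events = 5, seed = 71)
  f <- withr::local_tempfile(fileext = ".json")
  write_event_log(h, f)
  log <- jsonlite::read_json(f)
  expect_length(log$events, 5)
  expect_true(all(vapply(log$events, function(e) !is.null(e$products),
                         logical(1))))
})
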