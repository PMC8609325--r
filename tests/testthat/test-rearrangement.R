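test_that("compose aggregates ancestors in target-side order", {
  qk <- toy_karyotype("q", c(micA = 10e6, micB = 8e6, mac1 = 100e6))
  tk <- toy_karyotype("t", c(fus = 18e6))
  blocks <- rbind(block_row("micB", 0, 8e6, "fus", 10e6, 18e6),
                  block_row("micA", 0, 10e6, "fus", 0, 10e6))
  comp <- compose("fus", blocks, qk, tk)
  expect_equal(comp$ancestors$q_chrom, c("micA", "micB"))  # positional order
  expect_equal(comp$covered_fraction, 1)

  # 1:1 conserved micro
  tk2 <- toy_karyotype("t", c(m = 10e6))
  c2 <- compose("m", block_row("micA", 0, 9.5e6, "m", 0, 9.5e6), qk, tk2)
  expect_equal(nrow(c2$ancestors), 1)
  expect_gte(c2$covered_fraction, 0.9)

  # no blocks -> empty composition
  c3 <- compose("m", blocks[0, ], qk, tk2)
  expect_equal(nrow(c3$ancestors), 0)
  expect_equal(c3$covered_fraction, 0)

  # min_support prunes weak ancestors
  weak <- rbind(blocks, block_row("mac1", 0, 5e4, "fus", 9e6, 9.05e6))
  expect_equal(nrow(compose("fus", weak, qk, tk)$ancestors), 2)
})

test_that("call_event cascade distinguishes the event taxonomy", {
  qk <- toy_karyotype("q", c(mic1 = 10e6, mic2 = 8e6, mac1 = 100e6,
                             mac2 = 90e6))
  # conserved micro
  tk <- toy_karyotype("t", c(m = 10e6))
  cons <- call_event(compose("m", block_row("mic1", 0, 9.5e6, "m", 0, 9.5e6),
                             qk, tk))
  expect_equal(cons$event, "conserved_micro")

  # micro-micro fusion
  tkf <- toy_karyotype("t", c(f = 18e6))
  mm <- call_event(compose("f", rbind(
    block_row("mic1", 0, 10e6, "f", 0, 10e6),
    block_row("mic2", 0, 8e6, "f", 10e6, 18e6)), qk, tkf))
  expect_equal(mm$event, "micro_micro_fusion")

  # terminal macro-micro fusion: micro at the very end of a macro target
  tkt <- toy_karyotype("t", c(big = 110e6))
  term <- call_event(compose("big", rbind(
    block_row("mac1", 0, 99e6, "big", 0, 99e6),
    block_row("mic1", 0, 10e6, "big", 100e6, 110e6)), qk, tkt))
  expect_equal(term$event, "macro_micro_fusion_terminal")

  # centric: micro constitutes one whole arm of the target
  tkc <- toy_karyotype("t", c(rob = 40e6), threshold = 35e6)
  cen <- call_event(compose("rob", rbind(
    block_row("mac2", 0, 30e6, "rob", 10e6, 40e6),
    block_row("mic1", 0, 10e6, "rob", 0, 10e6)), qk, tkc),
    centromere = 10e6, d_term = 1e6)
  expect_equal(cen$event, "macro_micro_fusion_centric")

  # internal insertion with centromere elsewhere stays unresolved
  tki <- toy_karyotype("t", c(ins = 110e6))
  ins <- call_event(compose("ins", rbind(
    block_row("mac1", 0, 50e6, "ins", 0, 50e6),
    block_row("mic1", 0, 10e6, "ins", 50e6, 60e6),
    block_row("mac2", 0, 50e6, "ins", 60e6, 110e6)), qk, tki),
    d_term = 5e6)
  expect_equal(ins$event, "unresolved")

  # fission products: fragment of one macro
  tkp <- toy_karyotype("t", c(p1 = 30e6))
  fis <- call_event(compose("p1", block_row("mac1", 0, 30e6, "p1", 0, 30e6),
                            qk, tkp))
  expect_equal(fis$event, "fission_new_micro")

  # macro-macro fusion
  tkmm <- toy_karyotype("t", c(gg = 190e6))
  mmf <- call_event(compose("gg", rbind(
    block_row("mac1", 0, 100e6, "gg", 0, 100e6),
    block_row("mac2", 0, 90e6, "gg", 100e6, 190e6)), qk, tkmm))
  expect_equal(mmf$event, "macro_macro_fusion")

  # bad configuration
  expect_error(call_event(compose("m", block_row("mic1", 0, 9e6, "m", 0, 9e6),
                                  qk, tk), d_term = -1), "d_term")
})

test_that("event_table counts sum to the number of calls", {
  calls <- data.frame(event = c("micro_micro_fusion", "micro_micro_fusion",
                                "micro_micro_fusion", "conserved_micro"))
  tab <- event_table(calls)
  expect_equal(tab[["micro_micro_fusion"]], 3)
  expect_equal(sum(tab), nrow(calls))
  expect_equal(sum(event_table(calls[0, , drop = FALSE])), 0)
})

test_that("four-way region classes follow the (query, target) class pair", {
  qk <- toy_karyotype("chicken", c(qmac = 100e6, qmic = 10e6))
  tk <- toy_karyotype("eagle", c(tmac = 100e6, tmic = 10e6))
  blocks <- rbind(
    block_row("qmac", 0, 20e6, "tmac", 0, 20e6),      # macro in both
    block_row("qmic", 0, 8e6, "tmac", 30e6, 38e6),    # micro -> macro
    block_row("qmac", 30e6, 38e6, "tmic", 0, 8e6),    # macro -> micro
    block_row("qmic", 8e6, 10e6, "tmic", 8e6, 10e6))  # micro in both
  map <- classify_regions_four_way(blocks, qk, tk)
  st <- function(chrom, start) map$state[map$chrom == chrom & map$start == start]
  expect_equal(st("tmac", 0), "macro")
  expect_equal(st("tmac", 30e6), "new_macro")
  expect_equal(st("tmic", 0), "new_micro")
  expect_equal(st("tmic", 8e6), "micro")
  expect_equal(nrow(classify_regions_four_way(blocks[0, ], qk, tk)), 0)
})

test_that("overlapping blocks resolve by score and conserve every base once", {
  qk <- toy_karyotype("q", c(qmac = 100e6, qmic = 10e6))
  tk <- toy_karyotype("t", c(tmac = 100e6))
  blocks <- rbind(
    block_row("qmac", 0, 10e6, "tmac", 0, 10e6, score = 100),
    block_row("qmic", 0, 6e6, "tmac", 6e6, 12e6, score = 50))
  map <- classify_regions_four_way(blocks, qk, tk)
  # higher-scoring macro block claims 0-10 Mb; micro block keeps 10-12 Mb
  expect_equal(map$state[map$start == 0], "macro")
  expect_equal(map[map$state == "new_macro", "start"], 10e6)
  expect_equal(map[map$state == "new_macro", "end"], 12e6)
  # no double-counting within a chromosome
  for (ch in unique(map$chrom)) {
    sub <- map[map$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
  }
  # total labeled length = union of target spans
  expect_equal(sum(map$end - map$start), 12e6)
})

test_that("region maps export as BED-like TSV", {
  map <- data.frame(chrom = "c", start = 0, end = 5e6, state = "micro")
  f <- withr::local_tempfile(fileext = ".bed")
  write_region_map(map, f)
  expect_equal(strsplit(readLines(f), "\t")[[1]][4], "micro")
})
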