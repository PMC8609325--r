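test_that("GInteractions lines populate a symmetric sparse matrix", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\t0\t50000\ts1\t50000\t100000\t12.5",
               "s1\t50000\t100000\ts1\t0\t50000\t2.5"), f)
  cm <- read_ginteractions(f)
  # duplicate (i,j)/(j,i) lines merged by sum
  expect_equal(nrow(cm$counts), 1)
  expect_equal(cm$counts$count, 15)
  expect_equal(dense_contacts(cm)[1, 2], dense_contacts(cm)[2, 1])

  # empty file -> empty matrix
  f0 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), f0)
  expect_equal(nrow(read_ginteractions(f0)$bins), 0)
})

test_that("the seven-column contract and bin grid are enforced", {
  f6 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t0\t50000\ts1\t50000\t100000", f6)
  expect_error(read_ginteractions(f6), "7 columns")
  expect_equal(nrow(validate_ginteractions_file(f6)), 1)

  fneg <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t0\t50000\ts1\t50000\t100000\t-3", fneg)
  expect_error(read_ginteractions(fneg), "negative")

  foff <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t10\t50010\ts1\t50000\t100000\t3", foff)
  expect_error(read_ginteractions(foff), "multiples")

  fwide <- withr::local_tempfile(fileext = ".tsv")
  writeLines("s1\t0\t120000\ts1\t0\t120000\t3", fwide)
  expect_error(read_ginteractions(fwide), "bin_size")
})

test_that("GInteractions read -> write -> read round-trips byte-identically", {
  for (seed in 1:5) {
    cm <- random_cm(seed)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    write_ginteractions(cm, f1)
    back <- read_ginteractions(f1)
    f2 <- withr::local_tempfile(fileext = ".tsv")
    write_ginteractions(back, f2)
    expect_identical(readLines(f2), readLines(f1))
    expect_equal(back$counts, cm$counts)
  }
})

test_that("select_top_scaffolds keeps the expected_n largest, ties by name", {
  cm <- random_cm(7, scaffold_bins = c(a = 4, b = 6, c = 6, d = 2, e = 8))
  top3 <- select_top_scaffolds(cm, 3)
  # b and c tie at 6 bins; name order keeps b
  expect_setequal(unique(top3$bins$chrom), c("e", "b", "c"))
  expect_error(select_top_scaffolds(cm, 9), "exceeds")
  same <- select_top_scaffolds(cm, 5)
  expect_equal(same$bins, cm$bins)
  expect_equal(sum(same$counts$count), sum(cm$counts$count))
})

test_that("interaction_heatmap equals the brute-force double loop", {
  for (seed in 1:10) {
    cm <- random_cm(seed, scaffold_bins = c(s1 = 7, s2 = 5, s3 = 3))
    expect_equal(interaction_heatmap(cm), heatmap_oracle(cm),
                 info = paste("seed", seed))
  }
  # two scaffolds, one nonzero trans pair among 4 -> mean = value/4
  bins <- data.frame(chrom = c("a", "a", "b", "b"),
                     start = c(0, 5e4, 0, 5e4), end = c(5e4, 1e5, 5e4, 1e5))
  cm1 <- contact_matrix(bins, data.frame(i = 1, j = 3, count = 8))
  expect_equal(interaction_heatmap(cm1)["a", "b"], 2)
  # uniform matrix -> constant table
  n <- nrow(bins)
  pairs <- which(upper.tri(diag(n), diag = TRUE), arr.ind = TRUE)
  cmu <- contact_matrix(bins, data.frame(i = pairs[, 1], j = pairs[, 2],
                                         count = 5))
  expect_true(all(abs(interaction_heatmap(cmu) - 5) < 1e-12))
})

test_that("ps_curve matches brute-force enumeration of bin pairs", {
  classes <- c(s1 = "macro", s2 = "micro", s3 = "micro")
  for (seed in 1:10) {
    cm <- random_cm(seed, scaffold_bins = c(s1 = 40, s2 = 30, s3 = 20))
    for (cl in c("macro", "micro")) {
      got <- ps_curve(cm, classes, which_classes = cl, max_dist = 3e6,
                      n_dist_bins = 12)
      expect_equal(got$p, ps_oracle(cm, classes, cl, max_dist = 3e6,
                                    n_dist_bins = 12),
                   info = paste(cl, "seed", seed))
    }
  }
})

test_that("ps_curve reproduces hand-computable contact layouts", {
  # 4-bin scaffold with contacts only between adjacent bins, value c
  bins <- data.frame(chrom = "s", start = (0:3) * 5e4, end = (1:4) * 5e4)
  cmadj <- contact_matrix(bins, data.frame(i = 1:3, j = 2:4, count = 7))
  cur <- ps_curve(cmadj, c(s = "all_one"), which_classes = "all_one",
                  max_dist = 2e5, n_dist_bins = 3)
  expect_equal(cur$p[cur$n_pairs > 0][1], 7)       # separation 1 bin
  expect_true(all(cur$p[cur$n_pairs > 0][-1] == 0))  # nothing beyond

  # uniform intra contacts -> flat curve
  pairs <- which(upper.tri(diag(4)), arr.ind = TRUE)
  cmu <- contact_matrix(bins, data.frame(i = pairs[, 1], j = pairs[, 2],
                                         count = 3))
  curu <- ps_curve(cmu, c(s = "x"), which_classes = "x", max_dist = 2e5,
                   n_dist_bins = 3)
  expect_true(all(curu$p[curu$n_pairs > 0] == 3))

  # probability mode sums to one over defined bins
  curp <- ps_curve(cmu, c(s = "x"), which_classes = "x", max_dist = 2e5,
                   n_dist_bins = 3, mode = "probability")
  expect_equal(sum(curp$p, na.rm = TRUE), 1)

  # a class with fewer than 2 bins anywhere is undefined
  lone <- contact_matrix(data.frame(chrom = c("s", "t"), start = 0,
                                    end = 5e4),
                         data.frame(i = 1, j = 2, count = 1))
  expect_error(ps_curve(lone, c(s = "a", t = "b"), which_classes = "a"),
               "fewer than 2 bins")
})

test_that("bin-state assignment uses majority overlap with left-state ties", {
  bins <- data.frame(chrom = "s", start = (0:3) * 5e4, end = (1:4) * 5e4)
  cm <- contact_matrix(bins, data.frame(i = 1, j = 2, count = 1))
  map <- data.frame(chrom = "s",
                    start = c(0, 75e3, 125e3),
                    end = c(75e3, 125e3, 200e3),
                    state = c("micro", "new_macro", "macro"))
  st <- assign_bin_states(cm, map)
  expect_equal(st[1], "micro")          # fully covered
  expect_equal(st[2], "micro")          # 25k micro vs 25k new_macro: earlier interval wins
  expect_equal(st[3], "new_macro")      # 25k vs 25k: new_macro interval starts earlier
  expect_equal(st[4], "macro")
})

test_that("partitioning preserves intra-state counts and drops cross-state pairs", {
  cm <- random_cm(3, scaffold_bins = c(s1 = 6, s2 = 4))
  map <- data.frame(chrom = c("s1", "s2"), start = 0,
                    end = c(3e5, 2e5), state = c("micro", "macro"))
  parts <- partition_matrix_by_state(cm, map)
  expect_setequal(names(parts), c("micro", "macro"))
  # one whole scaffold per state here, so sub-matrices are the scaffold blocks
  expect_equal(sum(parts$micro$counts$count),
               sum(cm$counts$count[cm$bins$chrom[cm$counts$i] == "s1" &
                                     cm$bins$chrom[cm$counts$j] == "s1"]))
  expect_lte(sum(vapply(parts, function(p) sum(p$counts$count), numeric(1))),
             sum(cm$counts$count))
  expect_equal(sum(vapply(parts, function(p) nrow(p$bins), integer(1))),
               nrow(cm$bins))
})
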