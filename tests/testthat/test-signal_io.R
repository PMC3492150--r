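test_that("probe tables are read, sorted, deduplicated and NA-filtered", {
  df <- data.frame(chrom = "chr1", position = c(40000, 80000, 120000),
                   value = c(1.5, 1.6, 1.7))
  path <- write_probe_tsv(df)
  sig <- read_probe_table(path)
  expect_length(sig, 1)
  expect_identical(sig$chr1$positions, df$position)
  expect_identical(sig$chr1$values, df$value)

  # shuffling rows must not change the result
  path2 <- write_probe_tsv(df[c(3, 1, 2), ])
  expect_identical(read_probe_table(path2)$chr1, sig$chr1)

  # one NA value among 5 rows -> 4 probes survive
  df5 <- data.frame(chrom = "chr1",
                    position = seq(40000, by = 40000, length.out = 5),
                    value = c(1.1, NA, 1.3, 1.4, 1.5))
  sig5 <- suppressMessages(read_probe_table(write_probe_tsv(df5)))
  expect_length(sig5$chr1$positions, 4)

  # duplicate positions collapse by mean
  dfd <- data.frame(chrom = "chr1", position = c(40000, 40000, 80000),
                    value = c(1.0, 2.0, 1.5))
  sigd <- read_probe_table(write_probe_tsv(dfd))
  expect_equal(sigd$chr1$values, c(1.5, 1.5))

  # chromosome with a single probe is excluded with a warning
  dfm <- rbind(df, data.frame(chrom = "chr2", position = 40000, value = 1))
  expect_warning(out <- read_probe_table(write_probe_tsv(dfm)), "chr2")
  expect_named(out, "chr1")

  # unparseable text reports the offending line
  dfb <- df; dfb$value <- as.character(dfb$value); dfb$value[2] <- "oops"
  expect_error(read_probe_table(write_probe_tsv(dfb)), "line 3")
})

test_that("probe_signal validates its invariants", {
  expect_error(probe_signal("c", c(1, 1), c(1, 2)), "increasing")
  expect_error(probe_signal("c", c(1, 2), c(1, NA)), "finite")
  expect_error(probe_signal("c", 1, 1), "at least 2")
  expect_error(probe_signal("c", c(1, 2), c(1, 2, 3)), "equal length")
})

test_that("BED export applies the single-bp probe footprint convention", {
  fit <- segmentation_from_truth(list(
    signal = make_signal(c(1.5, 1.5)),
    truth = list(clean_values = c(1.5, 1.5),
                 true_type = c("CTR", "CTR"),
                 true_breakpoints = integer(0),
                 segments = data.frame(start_idx = 1, end_idx = 2,
                                       type = "CTR"))
  ))
  path <- tempfile(fileext = ".bed")
  write_segments_bed(fit, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(nrow(bed), 1)
  expect_equal(bed$V2, 39999)   # probe at 40 kb, 0-based footprint start
  expect_equal(bed$V3, 80000)
  expect_equal(bed$V4, "CTR")
  expect_true(bed$V5 >= 0 && bed$V5 <= 1000)

  # three segments -> three records in genomic order, non-overlapping
  fit3 <- three_segment_fit()
  path3 <- tempfile(fileext = ".bed")
  write_segments_bed(fit3, path3)
  bed3 <- read.delim(path3, header = FALSE)
  expect_equal(nrow(bed3), 3)
  expect_equal(bed3$V4, c("CTR", "TTR", "CTR"))
  expect_true(all(diff(bed3$V2) > 0))
  expect_true(all(bed3$V3[-3] <= bed3$V2[-1]))

  empty <- fit3; empty$segments <- empty$segments[0, ]
  expect_error(write_segments_bed(empty, tempfile()), "empty")
})

test_that("bedGraph export round-trips fitted values on disjoint footprints", {
  fit <- three_segment_fit(n = 10, j1 = 4, j2 = 7)
  path <- tempfile(fileext = ".bedGraph")
  write_fitted_bedgraph(fit, path)
  bg <- read.delim(path, header = FALSE)
  expect_equal(nrow(bg), 10)
  expect_equal(bg$V4, fit$fitted, tolerance = 1e-6)
  # pairwise disjoint footprints
  expect_true(all(bg$V3[-10] <= bg$V2[-1]))
  expect_true(all(bg$V3 - bg$V2 == 1))
})

test_that("regions BED reader validates coordinates", {
  path <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t1000\tgeneA", "chr1\t5000\t9000\tgeneB"), path)
  rg <- read_regions_bed(path)
  expect_equal(rg$start, c(0, 5000))
  expect_equal(rg$name, c("geneA", "geneB"))
  writeLines("chr1\t100\t50", path)
  expect_error(read_regions_bed(path), "invalid")
})
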