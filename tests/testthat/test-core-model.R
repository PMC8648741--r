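test_that("merging collapses overlaps, preserves coverage and is idempotent", {
  t1 <- merge_track(bp_track(c("c1", "c1"), c(0, 5), c(10, 20)))
  expect_equal(as.data.frame(t1)[, c("start", "end")],
               data.frame(start = 0, end = 20))
  expect_true(is_merged(t1))

  t2 <- merge_track(bp_track(c("c2", "c1"), c(0, 0), c(10, 10)))
  expect_equal(nrow(t2), 2)                     # disjoint chromosomes kept
  expect_equal(t2$chrom, c("c1", "c2"))         # sorted

  expect_equal(as.data.frame(merge_track(t1)), as.data.frame(t1))

  ## coverage conservation on random tracks (bitmap oracle)
  set.seed(101)
  for (rep in 1:5) {
    n <- 40
    s <- floor(runif(n, 0, 950))
    tr <- bp_track(rep("c1", n), s, s + sample(5:60, n, TRUE))
    expect_equal(cumulative_length(merge_track(tr)),
                 oracle_union_length(list(tr), c(c1 = 1000)))
  }
})

test_that("cumulative length sums merged interval sizes", {
  expect_equal(cumulative_length(bp_track("c1", 0, 20)), 20)
  expect_equal(cumulative_length(bp_track(c("c1", "c1"), c(0, 5), c(10, 20))),
               20)
  expect_equal(cumulative_length(bp_track(character(0), numeric(0),
                                          numeric(0))), 0)
})

test_that("invalid intervals and coordinates are rejected", {
  expect_error(bp_track("c1", 10, 10), "coordinate")
  expect_error(bp_track("c1", -1, 5), "coordinate")
  expect_error(bp_genome(c(a = 0)), "positive")
  expect_error(bp_genome(c(a = 10), readable_size = 11), "exceed")
})

test_that("breakpoint counting uses half-open membership and matches a scan oracle", {
  g <- bp_genome(c(c1 = 1000, c2 = 1000))
  tr <- bp_track("c1", 0, 10)
  mk <- function(pos, chrom = "c1")
    bp_catalog(data.frame(sample_id = "S", chrom = chrom, pos = pos,
                          sv_id = "v1", side = 1:2),
               check_pairing = FALSE)
  expect_equal(count_breakpoints_in_track(mk(c(5, 500)), tr, g), 1)
  expect_equal(count_breakpoints_in_track(mk(c(10, 500)), tr, g), 0)
  expect_equal(count_breakpoints_in_track(mk(c(0, 9)), tr, g), 2)
  expect_error(
    count_breakpoints_in_track(mk(5, chrom = "cX"), tr, g), "unknown")

  set.seed(7)
  trk <- bp_track(sample(c("c1", "c2"), 15, TRUE),
                  s <- floor(runif(15, 0, 900)), s + sample(10:80, 15, TRUE))
  pos <- floor(runif(100, 0, 1000))
  chrom <- sample(c("c1", "c2"), 100, TRUE)
  cat <- bp_catalog(data.frame(sample_id = "S", chrom = chrom, pos = pos,
                               sv_id = rep(paste0("v", 1:50), each = 2),
                               side = rep(1:2, 50)))
  expect_equal(count_breakpoints_in_track(cat, trk, g),
               oracle_count_in_track(pos, chrom, merge_track(trk)))
})

test_that("per-track counts over a genome partition sum to TBPc", {
  set.seed(8)
  g <- bp_genome(c(c1 = 1000))
  cuts <- c(0, sort(sample(1:999, 5)), 1000)
  parts <- lapply(seq_len(length(cuts) - 1), function(i)
    bp_track("c1", cuts[i], cuts[i + 1]))
  cat <- make_uniform_catalog(60, 1000)
  counts <- vapply(parts, function(tr)
    count_breakpoints_in_track(cat, tr, g), numeric(1))
  expect_equal(sum(counts), unname(tbpc(cat)))
})

test_that("SV sides classify as intra/inter and sum to TBPc", {
  mk <- function(chrom, partner) bp_catalog(data.frame(
    sample_id = "S", chrom = chrom, pos = seq_along(chrom) * 10,
    sv_id = rep(paste0("v", seq_len(length(chrom) / 2)), each = 2),
    side = rep(1:2, length(chrom) / 2)))
  expect_equal(classify_sv_sides(mk(c("c1", "c1"))),
               c(n_bpsv_intra = 2, n_bpsv_inter = 0))
  expect_equal(classify_sv_sides(mk(c("c1", "c2"))),
               c(n_bpsv_intra = 0, n_bpsv_inter = 2))

  ## mixed toy catalog of 5 SVs vs per-SV enumeration
  chroms <- c("c1", "c1",  "c1", "c2",  "c3", "c3",  "c2", "c1",  "c2", "c2")
  cat5 <- mk(chroms)
  per_sv <- matrix(chroms, nrow = 2)
  n_intra <- 2 * sum(per_sv[1, ] == per_sv[2, ])
  res <- classify_sv_sides(cat5)
  expect_equal(unname(res["n_bpsv_intra"]), n_intra)
  expect_equal(sum(res), 10)
  expect_error(
    bp_catalog(data.frame(sample_id = "S", chrom = "c1", pos = 1,
                          sv_id = "v", side = 1)),
    "structural")
})

test_that("BED, breakpoint and clinical files round-trip", {
  tmp <- tempfile(fileext = ".bed")
  tr <- bp_track(c("c1", "c2"), c(100, 0), c(200, 50), element_class = "GQ")
  write_bed(tr, tmp)
  rt <- read_bed(tmp)
  expect_equal(as.data.frame(rt), as.data.frame(tr))
  expect_equal(element_class(rt), "GQ")

  ## multi-class file splits by name
  tmp2 <- tempfile(fileext = ".bed")
  writeLines(c("c1\t0\t10\tA", "c1\t20\t30\tB", "c2\t5\t9\tA"), tmp2)
  trks <- read_bed(tmp2, split_by_name = TRUE)
  expect_named(trks, c("A", "B"))
  expect_equal(nrow(trks$A), 2)

  set.seed(3)
  cat <- make_uniform_catalog(20, 1e4)
  tmp3 <- tempfile(fileext = ".tsv")
  write_breakpoints(cat, tmp3)
  expect_equal(as.data.frame(read_breakpoints(tmp3)), as.data.frame(cat))

  cl <- data.frame(sample_id = c("a", "b"), time_years = c(1.5, 2),
                   event = c(1, 0), treatment = c("yes", "no"))
  tmp4 <- tempfile(fileext = ".csv")
  write_clinical(cl, tmp4)
  expect_equal(read_clinical(tmp4), cl)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(sample_id = "a", time_years = -1, event = 1), bad,
            row.names = FALSE)
  expect_error(read_clinical(bad), "positive")
})

test_that("the BED dialect matches rtracklayer's", {
  skip_if_not_installed("rtracklayer")
  tr <- bp_track(c("c1", "c2"), c(100, 0), c(200, 50), element_class = "x")
  tmp <- tempfile(fileext = ".bed")
  write_bed(tr, tmp, name = FALSE)
  gr <- rtracklayer::import(tmp, format = "BED")
  expect_equal(GenomicRanges::start(gr), c(101, 1))  # 1-based closed
  expect_equal(GenomicRanges::end(gr), c(200, 50))
})
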