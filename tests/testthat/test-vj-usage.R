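airr_rows <- function(v, j, n) {
  data.frame(sequence_id = paste0("r", seq_along(v)),
             v_call = v, j_call = j, duplicate_count = n)
}

test_that("allele suffixes collapse to gene level and counts aggregate", {
  p <- write_airr_fixture(airr_rows(c("TRBV19*01", "TRBV19*02"),
                                    c("TRBJ2-1*01", "TRBJ2-1*01"),
                                    c(3L, 2L)))
  tab <- read_airr_rearrangements(p)
  # both alleles map to the same gene pair -> collapsed to one clonotype
  expect_equal(nrow(tab$records), 1L)
  expect_equal(tab$records$v_call, "TRBV19")
  expect_equal(tab$records$j_call, "TRBJ2-1")
  expect_equal(tab$records$count, 5L)
})

test_that("single-row file gives one clonotype with its clonal count", {
  p <- write_airr_fixture(airr_rows("TRBV5-1*01", "TRBJ1-2*01", 5L))
  tab <- read_airr_rearrangements(p)
  expect_equal(nrow(tab$records), 1L)
  expect_equal(sum(tab$records$count), 5L)
})

test_that("a 10-row fixture matches hand-counted VJ tallies", {
  v <- c("TRBV19*01", "TRBV19*01", "TRBV19*02", "TRBV5-1*01", "TRBV5-1*01",
         "TRBV5-1*02", "TRBV5-1*03", "TRBV12-3*01", "TRBV12-3*01",
         "TRBV12-3*01")
  j <- c(rep("TRBJ2-1*01", 3), rep("TRBJ1-2*01", 4), rep("TRBJ2-7*01", 3))
  p <- write_airr_fixture(airr_rows(v, j, rep(1L, 10)))
  tab <- read_airr_rearrangements(p)
  # hand count: 3 distinct gene pairs after allele stripping
  expect_equal(nrow(tab$records), 3L)
  tallies <- stats::setNames(tab$records$count,
                             paste(tab$records$v_call, tab$records$j_call,
                                   sep = "/"))
  expect_equal(tallies[["TRBV19/TRBJ2-1"]], 3L)
  expect_equal(tallies[["TRBV5-1/TRBJ1-2"]], 4L)
  expect_equal(tallies[["TRBV12-3/TRBJ2-7"]], 3L)
})

test_that("ambiguous multi-gene calls resolve to the first gene", {
  p <- write_airr_fixture(airr_rows("TRBV6-2*01,TRBV6-3*01", "TRBJ2-3*01", 1L))
  tab <- read_airr_rearrangements(p)
  expect_equal(tab$records$v_call, "TRBV6-2")
})

test_that("format errors name the offending column", {
  df <- data.frame(sequence_id = "r1", j_call = "TRBJ2-1", duplicate_count = 1)
  p <- write_airr_fixture(df)
  expect_error(read_airr_rearrangements(p), "v_call")
  p2 <- write_airr_fixture(df[0, ], name = "empty.tsv")
  expect_error(read_airr_rearrangements(p2), "empty")
})

test_that("usage matrix matches hand-computed fractions and rows sum to 1", {
  t1 <- clonotype_table("s1", data.frame(
    v_call = c("TRBV19", "TRBV19", "TRBV5-1", "TRBV12-3"),
    j_call = c("TRBJ2-1", "TRBJ2-2", "TRBJ1-2", "TRBJ2-7"),
    count = c(2L, 1L, 1L, 1L)))
  t2 <- clonotype_table("s2", data.frame(
    v_call = c("TRBV19", "TRBV19"), j_call = c("TRBJ2-1", "TRBJ2-1"),
    count = c(1L, 4L)))
  t3 <- clonotype_table("s3", data.frame(
    v_call = c("TRBV19", "TRBV5-1"), j_call = c("TRBJ2-1", "TRBJ1-2"),
    count = c(3L, 3L)))
  M <- compute_vj_usage(list(t1, t2, t3))
  # s1: 4 unique clonotypes, one per pair
  expect_equal(M["s1", "TRBV19/TRBJ2-1"], 0.25)
  # s2: duplicate records collapse to a single clonotype using one pair
  expect_equal(M["s2", "TRBV19/TRBJ2-1"], 1)
  expect_equal(sum(M["s2", ] != 0), 1L)
  expect_equal(M["s3", "TRBV5-1/TRBJ1-2"], 0.5)
  expect_equal(unname(rowSums(M)), rep(1, 3), tolerance = 1e-12)
  expect_true(all(M >= 0 & M <= 1))
})

test_that("usage is invariant to record order and read splitting", {
  rec <- data.frame(v_call = c("TRBV19", "TRBV5-1"),
                    j_call = c("TRBJ2-1", "TRBJ1-2"), count = c(4L, 2L))
  split_rec <- data.frame(
    v_call = c("TRBV5-1", "TRBV19", "TRBV19", "TRBV19"),
    j_call = c("TRBJ1-2", "TRBJ2-1", "TRBJ2-1", "TRBJ2-1"),
    count = c(2L, 1L, 2L, 1L))
  M1 <- compute_vj_usage(list(clonotype_table("s", rec)))
  M2 <- compute_vj_usage(list(clonotype_table("s", split_rec)))
  expect_equal(unclass(M1), unclass(M2))
})

test_that("log2 usage ratios behave like the defining formula", {
  t1 <- clonotype_table("s1", data.frame(
    v_call = c("TRBV19", "TRBV5-1"), j_call = c("TRBJ2-1", "TRBJ1-2"),
    count = c(1L, 1L)))
  t2 <- clonotype_table("s2", data.frame(
    v_call = "TRBV19", j_call = "TRBJ2-1", count = 2L))
  M <- compute_vj_usage(list(t1, t2))
  # identical timepoints -> identically zero
  expect_true(all(log2_usage_ratio(M, M) == 0))
  # doubling far above the pseudocount gives ~1
  pc <- 1e-6
  A <- usage_matrix(matrix(0.4, 1, 1, dimnames = list("s", "TRBV19/TRBJ2-1")))
  B <- usage_matrix(matrix(0.2, 1, 1, dimnames = list("s", "TRBV19/TRBJ2-1")))
  expect_equal(as.numeric(log2_usage_ratio(A, B, pc)), 1, tolerance = 1e-4)
  # a pair absent at both timepoints is exactly 0 under the formula
  A2 <- usage_matrix(matrix(c(1, 0), 1, 2,
                            dimnames = list("s", c("a/b", "c/d"))))
  B2 <- usage_matrix(matrix(c(1, 0), 1, 2,
                            dimnames = list("s", c("a/b", "c/d"))))
  r <- log2_usage_ratio(A2, B2, 1e-4)
  expect_identical(as.numeric(r[, "c/d"]), 0)
  # mismatched samples refuse to align
  C <- usage_matrix(matrix(0.5, 1, 1, dimnames = list("other", "a/b")))
  expect_error(log2_usage_ratio(A2, C), "same samples")
})

test_that("repertoire summaries match a sort-based computation", {
  tabs <- lapply(1:5, function(i) {
    clonotype_table(paste0("s", i), data.frame(
      v_call = paste0("TRBV", 1:(i + 1)), j_call = rep("TRBJ1-1", i + 1),
      count = seq_len(i + 1) * 10L))
  })
  s <- summarize_repertoire(tabs)
  uniq <- sort(vapply(tabs, function(t) nrow(t$records), numeric(1)))
  expect_equal(s$median[s$statistic == "unique_clonotypes"], uniq[3])
  expect_equal(s$min[s$statistic == "unique_clonotypes"], uniq[1])
  expect_equal(s$max[s$statistic == "unique_clonotypes"], uniq[5])
  reads <- sort(vapply(tabs, function(t) sum(t$records$count), numeric(1)))
  expect_equal(s$median[s$statistic == "clonal_counts"], reads[3])
  # single sample: degenerate range
  s1 <- summarize_repertoire(tabs[1])
  expect_equal(s1$min[1], s1$max[1])
  expect_equal(s1$median[1], s1$min[1])
})
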