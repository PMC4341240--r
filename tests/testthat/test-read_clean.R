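ad <- default_adapters()

read_of <- function(insert, read_length = 36) {
  substr(paste0(insert, ad$adapter3, strrep("G", read_length)), 1, read_length)
}
q_of <- function(n = 36) strrep("I", n)

test_that("assess_read applies the fixed-order screening rules", {
  ins <- "ACGTACGTACGTACGTACGTA"  # 21 nt
  r <- read_of(ins)
  expect_equal(assess_read(r, q_of())$category, "clean")
  expect_equal(assess_read(r, q_of())$insert, ins)

  # any N fails quality before categorization
  rn <- r; substr(rn, 5, 5) <- "N"
  expect_equal(assess_read(rn, q_of())$category, "low_quality")

  # quality thresholds: >4 bases Q<10 fails, exactly 4 passes
  q5 <- paste0(strrep("*", 5), strrep("I", 31))  # '*' = Q9
  expect_equal(assess_read(r, q5)$category, "low_quality")
  q4 <- paste0(strrep("*", 4), strrep("I", 32))
  expect_equal(assess_read(r, q4)$category, "clean")
  # >6 bases Q<13 fails, exactly 6 passes ('-' = Q12)
  q7 <- paste0(strrep("-", 7), strrep("I", 29))
  expect_equal(assess_read(r, q7)$category, "low_quality")
  q6 <- paste0(strrep("-", 6), strrep("I", 30))
  expect_equal(assess_read(r, q6)$category, "clean")

  # no adapter anywhere
  expect_equal(assess_read(strrep("ACGT", 9), q_of())$category,
               "adapter3_null")
  # adapter at read start: null insert
  expect_equal(assess_read(read_of(""), q_of())$category, "insert_null")
  # insert beginning with an 8-nt 5' adapter prefix
  r5 <- read_of(paste0(substr(ad$adapter5, 1, 12), "ACGTACGTAC"))
  expect_equal(assess_read(r5, q_of())$category, "adapter5_contaminant")
  # poly(A) insert (>= 80% A), checked before the length rule
  expect_equal(assess_read(read_of(strrep("A", 22)), q_of())$category, "polyA")
  expect_equal(assess_read(read_of(strrep("A", 16)), q_of())$category, "polyA")
  # 17-nt insert: smaller than 18
  expect_equal(assess_read(read_of("ACGTACGTACGTACGTA"), q_of())$category,
               "shorter_18")
  # 31-nt insert: the distinct longer-than-30 category
  r31 <- read_of(strrep("ACGT", 8), read_length = 40)
  expect_equal(assess_read(r31, q_of(40))$category, "longer_30")
  # one adapter mismatch is tolerated
  rmm <- read_of(ins)
  substr(rmm, 25, 25) <- if (substr(rmm, 25, 25) == "A") "C" else "A"
  expect_equal(assess_read(rmm, q_of())$category, "clean")

  expect_error(assess_read(r, "III"), "length")
})

test_that("published per-stage accounting reproduces from category counts", {
  s1 <- cleaning_summary(
    raw_reads = 17160426, high_quality = 17087884,
    removed = c(adapter3_null = 2578, insert_null = 2292,
                adapter5_contaminant = 152282, shorter_18 = 104474,
                polyA = 6353))
  expect_equal(s1$count[s1$category == "clean_reads"], 16819905)
  expect_equal(s1$percent[s1$category == "clean_reads"], 98.43)

  s2 <- cleaning_summary(
    raw_reads = 19055129, high_quality = 18975347,
    removed = c(adapter3_null = 2945, insert_null = 1415,
                adapter5_contaminant = 83280, shorter_18 = 31266,
                polyA = 3093))
  expect_equal(s2$count[s2$category == "clean_reads"], 18853348)
  expect_equal(s2$percent[s2$category == "clean_reads"], 99.36)

  # percentages recompute from counts
  expect_equal(s1$percent[-1],
               round(100 * s1$count[-1] / 17087884, 2))
  expect_error(cleaning_summary(10, 20, c(polyA = 1)), "exceeds")
})

test_that("clean_library partitions reads and collapses unique tags", {
  inserts <- c(rep("ACGTACGTACGTACGTACGTA", 5),
               rep("TTGCATGCAAGGCTTCAGTCAAGG", 3),
               "CCCGGGAAATTTCCCGGGAAA")
  reads <- wrap_reads(inserts)
  # add one of each artifact
  reads$sequence <- c(reads$sequence,
                      strrep("ACGT", 9),                      # no adapter
                      read_of(""),                            # null insert
                      read_of(strrep("A", 20)),               # polyA
                      read_of("ACGTACGTACGTA"))               # short
  reads$quality <- c(reads$quality, rep(q_of(), 4))

  res <- clean_library(reads)
  sm <- res$summary
  counts <- setNames(sm$count, sm$category)
  expect_equal(counts[["high_quality"]],
               counts[["clean_reads"]] +
                 sum(counts[c("adapter3_null", "insert_null",
                              "adapter5_contaminant", "shorter_18",
                              "polyA", "longer_30")]))
  expect_equal(counts[["clean_reads"]], 9)
  expect_equal(nrow(res$tags), 3)
  expect_equal(sum(res$tags$count), 9)
  expect_equal(res$tags$count[res$tags$sequence == "ACGTACGTACGTACGTACGTA"], 5L)

  # idempotence: re-wrapping the cleaned inserts gives the same tag table
  rewrapped <- wrap_reads(rep(res$tags$sequence, res$tags$count))
  res2 <- clean_library(rewrapped)
  expect_equal(res2$tags, res$tags)
})

test_that("clean_library handles FASTQ files and empty input", {
  dir <- withr::local_tempdir()
  fq <- file.path(dir, "x.fastq")
  writeLines(c("@r1", read_of("ACGTACGTACGTACGTACGTA"), "+", q_of()), fq)
  res <- clean_library(fq)
  expect_equal(res$tags$sequence, "ACGTACGTACGTACGTACGTA")

  empty <- list(sequence = character(0), quality = character(0))
  res0 <- clean_library(empty)
  expect_equal(nrow(res0$tags), 0)
  expect_true(all(res0$summary$count == 0))

  bad <- file.path(dir, "bad.fastq")
  writeLines(c("@r1", "ACGT"), bad)
  expect_error(clean_library(bad), "malformed FASTQ")
})

test_that("length distribution tallies reads, not unique tags", {
  tags <- data.frame(sequence = c(strrep("A", 21), strrep("C", 21),
                                  strrep("G", 24)),
                     length = c(21, 21, 24), count = c(3, 2, 3))
  ld <- length_distribution(tags)
  expect_equal(ld$reads[ld$length == 21], 5)
  expect_equal(ld$reads[ld$length == 24], 3)
  expect_equal(sum(ld$reads), sum(tags$count))
  expect_equal(ld$reads[!(ld$length %in% c(21, 24))], rep(0, 11))
})

test_that("simulated stage-3-like libraries have modal length 21 and conserve reads", {
  b <- make_reference(seed = 1)
  profiles <- default_stage_profiles()
  sim <- simulate_libraries(b, profiles, seed = 9)
  cl <- clean_library(sim$reads$stage3)
  ld <- length_distribution(cl$tags)
  expect_equal(sum(ld$reads),
               cl$summary$count[cl$summary$category == "clean_reads"])
  expect_equal(sum(cl$tags$count),
               cl$summary$count[cl$summary$category == "clean_reads"])
  expect_false(any(duplicated(cl$tags$sequence)))
  expect_equal(ld$length[which.max(ld$reads)], 21)
})
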