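test_that("window excision arithmetic, clipping and strand handling", {
  contig <- paste(rep("ACGT", 100), collapse = "")
  b <- list(contigs = c(c1 = contig))
  w <- excise_windows(list(contig = "c1", start = 100, end = 121,
                           strand = "+"), b, flank = 70, small = 15)
  expect_equal(c(w[[1]]$start, w[[1]]$end), c(30, 136))
  expect_equal(c(w[[2]]$start, w[[2]]$end), c(85, 191))
  expect_equal(w[[1]]$sequence, substr(contig, 31, 136))
  expect_equal(substr(w[[1]]$sequence, w[[1]]$mature_start + 1,
                      w[[1]]$mature_end),
               substr(contig, 101, 121))

  # contig edge: clipped, no failure
  we <- excise_windows(list(contig = "c1", start = 5, end = 26,
                            strand = "+"), b, flank = 70, small = 15)
  expect_equal(we[[1]]$start, 0)
  expect_equal(we[[1]]$mature_start, 5)

  # '-' strand: sequence reverse-complemented, mature coordinates flipped
  wm <- excise_windows(list(contig = "c1", start = 100, end = 121,
                            strand = "-"), b, flank = 70, small = 15)[[1]]
  expect_equal(wm$sequence, revcomp(substr(contig, 31, 136)))
  expect_equal(substr(wm$sequence, wm$mature_start + 1, wm$mature_end),
               revcomp(substr(contig, 101, 121)))

  expect_error(excise_windows(list(contig = "c1", start = 390, end = 405,
                                   strand = "+"), b), "outside")
})

test_that("folding matches intuition on degenerate sequences", {
  f <- fold_rna("GGGGAAAACCCC")
  expect_equal(f$structure, "((((....))))")
  expect_lt(f$mfe, 0)
  a30 <- fold_rna(strrep("A", 30))
  expect_equal(a30$mfe, 0)
  expect_equal(a30$structure, strrep(".", 30))
  expect_error(fold_rna("GGGGAAAXCCCC"), "non-ACGU")
})

test_that("the DP fold equals exhaustive enumeration on short sequences", {
  set.seed(3)
  for (i in 1:10) {
    L <- sample(8:14, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
               collapse = "")
    expect_equal(fold_rna(s)$mfe, oracle_mfe(s), tolerance = 1e-12,
                 label = paste("mfe of", s))
    # T <-> U spelling invariance on the same draws
    expect_identical(fold_rna(chartr("U", "T", s))$mfe, fold_rna(s)$mfe)
  }
})

test_that("planted hairpins are accepted with star support; defects are rejected", {
  b <- make_reference(seed = 6)
  hp <- b$hairpins[1, ]
  locus <- list(contig = hp$contig, start = hp$mature_start,
                end = hp$mature_end, strand = "+")
  wins <- excise_windows(locus, b)
  counts <- setNames(c(100, 10), c(hp$mature_seq, hp$star_seq))
  cands <- lapply(wins, evaluate_candidate, tag_counts = counts)
  acc <- Filter(function(x) x$accepted, cands)
  expect_gte(length(acc), 1)
  cand <- acc[[1]]
  expect_true(all(cand$criteria_flags))
  expect_lte(cand$mfe, -18)
  expect_gte(cand$hairpin_length, 47)
  expect_lte(cand$hairpin_length, 354)
  expect_equal(cand$arm, "5p")
  expect_equal(cand$star$sequence, hp$star_seq)
  expect_false(cand$star$more_abundant_than_mature)
  # near-equal star abundance flags, but does not reject
  counts2 <- setNames(c(10, 14), c(hp$mature_seq, hp$star_seq))
  cand2 <- Filter(function(x) x$accepted,
                  lapply(wins, evaluate_candidate, tag_counts = counts2))[[1]]
  expect_true(cand2$accepted)
  expect_true(cand2$star$more_abundant_than_mature)

  # a mature spanning the terminal loop is rejected
  A <- b$config$hairpin_stem_ext; M <- b$config$mature_length
  L <- b$config$hairpin_loop_len
  mid <- list(contig = hp$contig, start = hp$start + A + M - 5,
              end = hp$start + A + M + L + 5, strand = "+")
  wmid <- excise_windows(mid, b)
  for (w in wmid) {
    cm <- evaluate_candidate(w)
    expect_false(cm$criteria_flags[["mature_in_one_arm"]])
    expect_false(cm$accepted)
  }

  # a weak hairpin folds, but fails the MFE criterion
  arm <- "AUAUAUAU"
  weak <- paste0(arm, "GAAAC", revcomp(chartr("U", "T", arm)))
  wk <- list(contig = "x", start = 0, end = nchar(weak), strand = "+",
             sequence = weak, mature_start = 0, mature_end = 8)
  cw <- evaluate_candidate(wk)
  expect_false(cw$criteria_flags[["mfe_ok"]])
  expect_gt(cw$mfe, -18)
  expect_false(cw$accepted)
})

test_that("full novel prediction recovers planted hairpins only", {
  b <- make_reference(seed = 1)
  sim <- simulate_libraries(b, default_stage_profiles(), seed = 7)
  cleaned <- lapply(sim$reads, clean_library)
  merged <- merge_tag_tables(lapply(cleaned, `[[`, "tags"))
  cl <- classify_tags(merged, b)
  nv <- predict_novel(cl$annotation, cl$loci, b)

  hp <- b$hairpins
  for (i in seq_len(nrow(hp))) {
    hit <- nv[nv$contig == hp$contig[i] & nv$start < hp$end[i] &
                nv$end > hp$start[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$mature_sequence, hp$mature_seq[i])
    expect_equal(hit$star_sequence, hp$star_seq[i])
    expect_false(hit$star_flag)
    expect_gte(sum(hit[, c("stage1", "stage2", "stage3")]), 5)
  }
  expect_true(all(nv$hairpin_length >= 47 & nv$hairpin_length <= 354))
  expect_true(all(nv$mfe <= -18))
  # non-overlapping accepted precursors after deduplication
  for (cg in unique(nv$contig)) {
    d <- nv[nv$contig == cg, ]
    d <- d[order(d$start), ]
    if (nrow(d) > 1)
      expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
  }
})
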