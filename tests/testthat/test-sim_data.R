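test_that("reference generation is deterministic and respects the layout", {
  b1 <- make_reference(seed = 1)
  b2 <- make_reference(seed = 1)
  expect_identical(b1, b2)
  b3 <- make_reference(seed = 2)
  expect_false(identical(b1$contigs, b3$contigs))

  # planted sequences occur verbatim (or reverse-complemented) at their loci
  for (r in seq_len(nrow(b1$planted_loci))) {
    l <- b1$planted_loci[r, ]
    slice <- substr(b1$contigs[[l$contig]], l$start + 1, l$end)
    planted <- switch(l$kind,
      known_miRNA = b1$mature_catalog$sequence[
        b1$mature_catalog$name == l$name],
      hairpin = b1$hairpins$precursor[b1$hairpins$name == l$name],
      novel_mature = b1$hairpins$mature_seq[
        paste0(b1$hairpins$name, ".mature") == l$name],
      novel_star = b1$hairpins$star_seq[
        paste0(b1$hairpins$name, ".star") == l$name],
      b1$ncrna_catalog$sequence[b1$ncrna_catalog$name == l$name])
    expect_identical(slice, if (l$strand == "-") revcomp(planted) else planted)
  }
  expect_false(anyDuplicated(b1$planted_loci$name) > 0)
  expect_false(any(grepl("[^ACGT]", b1$contigs)))
})

test_that("hairpin geometry is configurable and stays in the plant precursor range", {
  b <- make_reference(seed = 4)
  expect_true(b$hairpin_length >= 47 && b$hairpin_length <= 354)
  # a 21-nt mature in a 90-nt hairpin: 2 * (21 + 19) + 10
  cfg <- sim_config(hairpin_stem_ext = 19, hairpin_loop_len = 10)
  b90 <- make_reference(cfg, seed = 4)
  expect_equal(b90$hairpin_length, 90)
  expect_true(b90$hairpin_length >= 47 && b90$hairpin_length <= 354)
  hl <- b90$planted_loci[b90$planted_loci$kind == "hairpin", ]
  expect_true(all(hl$end - hl$start == 90))
})

test_that("planted hairpins fold into negative-MFE stems (enumeration-checked on a trimmed stem)", {
  cfg <- sim_config(hairpin_loop_len = 3)
  b <- make_reference(cfg, seed = 5)
  A <- cfg$hairpin_stem_ext; M <- cfg$mature_length; L <- cfg$hairpin_loop_len
  for (prec in b$hairpins$precursor) {
    expect_lt(fold_rna(prec)$mfe, -18)
    # trim to a 5-bp closing stem + terminal loop (13 nt) and compare the
    # DP fold with exhaustive enumeration of all nested pairings
    trimmed <- substr(prec, A + M - 4, A + M + L + 5)
    expect_equal(nchar(trimmed), 13)
    o <- oracle_mfe(trimmed)
    expect_lt(o, 0)
    expect_equal(fold_rna(trimmed)$mfe, o, tolerance = 1e-12)
  }
})

test_that("libraries are deterministic and clean perfectly when artifact-free", {
  b <- make_reference(seed = 1)
  profiles <- default_stage_profiles()
  for (i in seq_along(profiles)) {
    profiles[[i]]$target_clean_reads <- 2000
    profiles[[i]]$artifact_rates[] <- 0
    profiles[[i]]$quality_error_rate <- 0
    profiles[[i]]$n_rate <- 0
  }
  s1 <- simulate_libraries(b, profiles, seed = 3)
  s2 <- simulate_libraries(b, profiles, seed = 3)
  expect_identical(s1, s2)

  # no artifacts, no quality loss: every emitted read survives cleaning
  for (st in names(s1$reads)) {
    expect_equal(length(s1$reads[[st]]$sequence), 2000)
    cl <- clean_library(s1$reads[[st]])
    sm <- cl$summary
    expect_equal(sm$count[sm$category == "clean_reads"], 2000)
    expect_equal(sm$percent[sm$category == "clean_reads"], 100)
  }
})

test_that("emission counts follow the configured rates and planted truth", {
  b <- make_reference(seed = 1)
  profiles <- default_stage_profiles()
  sim <- simulate_libraries(b, profiles, seed = 7)
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    r <- sim$reads[[p$stage]]
    n_emit <- round(p$target_clean_reads / (1 - sum(p$artifact_rates)))
    expect_equal(length(r$sequence), n_emit)
    # artifact classes within binomial 3 sigma of their configured rates
    for (a in names(p$artifact_rates)) {
      expected <- n_emit * p$artifact_rates[[a]]
      tol <- 3 * sqrt(n_emit * p$artifact_rates[[a]] *
                        (1 - p$artifact_rates[[a]]))
      expect_lte(abs(sum(r$class == a) - expected), max(tol, 1))
    }
  }

  # miR156a-like decline: realized counts within multinomial 3 sigma of
  # the 505,759 : 50,613 : 16,238-proportional expectations
  tr <- sim$truth[sim$truth$name == "rsa-miR156a", ]
  for (i in 1:3) {
    f <- profiles[[i]]$abundance[["rsa-miR156a"]]
    n <- profiles[[i]]$target_clean_reads
    expect_lte(abs(tr[[paste0("realized_s", i)]] - n * f),
               3 * sqrt(n * f * (1 - f)))
  }
  expect_equal(tr$log2fc_s2_s1, log2(0.0054 / 0.06))

  # flat planted entities have true log2FC 0 in both transitions
  null <- sim$truth[sim$truth$name == "rsa-miR159a", ]
  expect_equal(null$log2fc_s2_s1, 0)
  expect_equal(null$log2fc_s3_s2, 0)
  expect_false(null$true_de)

  # truth fold changes are consistent with expected counts after
  # per-million scaling
  for (r in seq_len(nrow(sim$truth))) {
    t <- sim$truth[r, ]
    rpm2 <- t$expected_s2 / profiles[[2]]$target_clean_reads * 1e6
    rpm1 <- t$expected_s1 / profiles[[1]]$target_clean_reads * 1e6
    expect_equal(t$log2fc_s2_s1, log2(max(rpm2, 0.01) / max(rpm1, 0.01)),
                 tolerance = 1e-12)
  }
})

test_that("library simulation validates its inputs", {
  b <- make_reference(seed = 1)
  profiles <- default_stage_profiles()
  expect_error(simulate_libraries(b, profiles[1:2], seed = 1),
               "stage")
  bad <- profiles
  bad[[1]]$target_clean_reads <- 10
  expect_error(simulate_libraries(b, bad, seed = 1), ">= 1000")
  cfg <- sim_config(contig_length = 100)
  expect_error(make_reference(cfg, seed = 1), "shorter")
})

test_that("bundle files round-trip through the writers", {
  b <- make_reference(seed = 1)
  dir <- withr::local_tempdir()
  write_reference(b, dir)
  fa <- Biostrings::readDNAStringSet(file.path(dir, "contigs.fa"))
  expect_identical(as.character(fa), b$contigs)
  mat <- Biostrings::readDNAStringSet(file.path(dir, "mature.fa"))
  expect_identical(unname(as.character(mat)), b$mature_catalog$sequence)
  expect_true(all(grepl("\\|", names(mat))))

  sim <- simulate_libraries(b, seed = 2, outdir = dir)
  fq <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(file.path(dir, "stage1.fastq")))
  expect_identical(as.character(fq), setNames(sim$reads$stage1$sequence,
                                              names(as.character(fq))))
})
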