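#' Default simulation configuration
#'
#' Describes the toy reference genome and the planted ground truth used by
#' [make_reference()]: contig layout, known mature miRNAs (with family
#' labels), novel hairpin loci, and non-coding RNA contaminants.  Planted
#' abundances live in the stage profiles ([default_stage_profiles()]), not
#' here; this object defines *what* exists in the genome.
#'
#' Hairpin geometry: each planted precursor is
#' `ext + mature + loop + revcomp(mature + ext)`, a perfect-complement stem
#' of `stem_ext + 21` bp closed by a `loop_len`-nt terminal loop.  The
#' miRNA* (star) sequence is the opposite-arm sequence with canonical 2-nt
#' 3' overhang geometry.  Defaults give 60-nt hairpins, inside the 47-354 nt
#' range spanned by plant precursors.
#'
#' @param n_contigs number of reference contigs.
#' @param contig_length length (nt) of each contig.
#' @param mature_length length (nt) of planted mature miRNAs.
#' @param hairpin_loop_len terminal loop length of planted hairpins (nt).
#' @param hairpin_stem_ext extra stem base pairs flanking the mature/star
#'   duplex on each arm (nt); hairpin length is
#'   `2 * (mature_length + hairpin_stem_ext) + hairpin_loop_len`.
#' @param read_length fixed instrument read length (nt).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_contigs = 3, contig_length = 4000,
                       mature_length = 21, hairpin_loop_len = 10,
                       hairpin_stem_ext = 4, read_length = 36) {
  known <- data.frame(
    name = c("rsa-miR156a", "rsa-miR172c", "rsa-miR397a", "rsa-miR5763",
             "rsa-miR159a", "rsa-miR160a", "rsa-miR166a", "rsa-miR168a",
             "rsa-miR169a", "rsa-miR396a", "rsa-miR398a", "rsa-miR408a"),
    family = c("miR156", "miR172", "miR397", "miR5763", "miR159", "miR160",
               "miR166", "miR168", "miR169", "miR396", "miR398", "miR408"),
    strand = c("+", "+", "+", "+", "+", "-", "+", "+", "+", "+", "+", "+"),
    stringsAsFactors = FALSE)
  ncrna <- data.frame(
    name = c("rrn1", "trn1", "snr1", "sno1"),
    kind = c("rRNA", "tRNA", "snRNA", "snoRNA"),
    length = c(150, 80, 120, 100),
    stringsAsFactors = FALSE)
  hairpins <- data.frame(
    name = c("nhp1", "nhp2", "nhp3"),
    stringsAsFactors = FALSE)
  structure(list(
    n_contigs = n_contigs, contig_length = contig_length,
    mature_length = mature_length, hairpin_loop_len = hairpin_loop_len,
    hairpin_stem_ext = hairpin_stem_ext, read_length = read_length,
    known = known, ncrna = ncrna, hairpins = hairpins),
    class = "sim_config")
}

#' Default stage profiles
#'
#' Three stage profiles (stage1/stage2/stage3, i.e. pre-cortex splitting,
#' cortex splitting and expanding taproot) giving target clean-read counts,
#' per-entity expected read fractions, and library-preparation artifact
#' rates.  Library sizes are the published clean totals scaled down ~1000x
#' (16,820 / 18,853 / 17,083).  The planted miR156a-like entity declines in
#' proportion to 505,759 : 50,613 : 16,238 reads across the three stages
#' (here at twice the per-million fraction so that even the stage-3 count
#' stays comfortably above sampling noise).  Several entities are planted
#' flat (null) to measure the false-positive rate of the DE screen.
#'
#' @return list of three `stage_profile` lists with fields `stage`,
#'   `target_clean_reads`, `abundance` (named fractions), `artifact_rates`
#'   (named: `adapter5_contaminant`, `adapter3_null`, `insert_null`,
#'   `shorter_18`, `polyA`), `quality_error_rate`, `n_rate`.
#' @export
default_stage_profiles <- function() {
  ab <- function(s1, s2, s3) rbind(s1 = s1, s2 = s2, s3 = s3)
  frac <- cbind(
    `rsa-miR156a` = c(0.0600, 0.0054, 0.0019),
    `rsa-miR172c` = c(0.0040, 0.0320, 0.0040),
    `rsa-miR397a` = c(0.0320, 0.0040, 0.0040),
    `rsa-miR5763` = c(0.0016, 0.0128, 0.0512),
    `rsa-miR159a` = c(0.0100, 0.0100, 0.0100),
    `rsa-miR160a` = c(0.0160, 0.0160, 0.0160),
    `rsa-miR166a` = c(0.0240, 0.0240, 0.0240),
    `rsa-miR168a` = c(0.0400, 0.0400, 0.0400),
    `rsa-miR169a` = c(0.0060, 0.0060, 0.0060),
    `rsa-miR396a` = c(0.0120, 0.0120, 0.0120),
    `rsa-miR398a` = c(0.0040, 0.0040, 0.0040),
    `rsa-miR408a` = c(0.0080, 0.0080, 0.0080),
    `nhp1.mature` = c(0.0080, 0.0080, 0.0080),
    `nhp1.star`   = c(0.0008, 0.0008, 0.0008),
    `nhp2.mature` = c(0.0060, 0.0120, 0.0060),
    `nhp2.star`   = c(0.0006, 0.0012, 0.0006),
    `nhp3.mature` = c(0.0100, 0.0100, 0.0010),
    `nhp3.star`   = c(0.0010, 0.0010, 0.0001),
    rrn1 = c(0.040, 0.040, 0.040),
    trn1 = c(0.025, 0.025, 0.025),
    snr1 = c(0.012, 0.012, 0.012),
    sno1 = c(0.008, 0.008, 0.008))
  targets <- c(16820, 18853, 17083)
  art <- list(
    c(adapter5_contaminant = 0.0089, adapter3_null = 0.00015,
      insert_null = 0.00013, shorter_18 = 0.0061, polyA = 0.00037),
    c(adapter5_contaminant = 0.0044, adapter3_null = 0.00016,
      insert_null = 0.00007, shorter_18 = 0.0016, polyA = 0.00016),
    c(adapter5_contaminant = 0.0033, adapter3_null = 0.00014,
      insert_null = 0.00007, shorter_18 = 0.0027, polyA = 0.00008))
  lapply(1:3, function(i) {
    structure(list(
      stage = paste0("stage", i),
      target_clean_reads = targets[i],
      abundance = frac[i, ],
      artifact_rates = art[[i]],
      quality_error_rate = 0.01,
      n_rate = 0.0005), class = "stage_profile")
  })
}

validate_profile <- function(p) {
  stopifnot(is.list(p), !is.null(p$stage), !is.null(p$abundance))
  if (p$target_clean_reads < 1000)
    stop("target_clean_reads must be >= 1000")
  if (any(p$abundance < 0)) stop("abundance fractions must be >= 0")
  if (sum(p$abundance) > 1) stop("abundance fractions must sum to <= 1")
  if (any(p$artifact_rates < 0) || sum(p$artifact_rates) > 1)
    stop("artifact rates must be fractions summing to <= 1")
  invisible(p)
}

#' Build a reference bundle with planted ground truth
#'
#' Generates toy reference contigs and plants, at recorded loci: known
#' mature miRNAs (verbatim, reverse-complemented for '-' strand loci),
#' novel miRNA hairpins whose mature arm is perfectly complementary to the
#' star arm, and ncRNA contaminant sequences.  All coordinates are 0-based
#' half-open; all sequences are uppercase DNA.
#'
#' @param config a [sim_config()] object.
#' @param seed integer RNG seed; identical `(config, seed)` gives a
#'   byte-identical bundle.
#' @return a `ReferenceBundle` list: `contigs` (named character),
#'   `ncrna_catalog` (data.frame name/kind/sequence), `mature_catalog`
#'   (data.frame name/family/sequence), `hairpins` (data.frame with
#'   precursor locus, mature/star sequences and loci), `planted_loci`
#'   (data.frame name/contig/start/end/strand/kind), `config`.
#' @export
make_reference <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(config$known) < 1 || nrow(config$hairpins) < 1 ||
      nrow(config$ncrna) < 1)
    stop("config must plant at least one known miRNA, hairpin and ncRNA locus")
  nm <- c(config$known$name, config$hairpins$name, config$ncrna$name)
  if (anyDuplicated(nm)) stop("duplicate planted entity names")

  with_seed(seed, {
    M <- config$mature_length
    A <- config$hairpin_stem_ext
    L <- config$hairpin_loop_len
    if (A < 2) stop("hairpin_stem_ext must be >= 2 (star 3' overhang)")

    known <- config$known
    known$sequence <- random_dna(rep(M, nrow(known)))

    ncrna <- config$ncrna
    ncrna$sequence <- random_dna(ncrna$length)

    hp <- config$hairpins
    hp$mature_seq <- random_dna(rep(M, nrow(hp)))
    arm5 <- paste0(random_dna(rep(A, nrow(hp))), hp$mature_seq)
    hp$precursor <- paste0(arm5,
                           random_dna(rep(L, nrow(hp))),
                           revcomp(arm5))
    H <- 2 * (A + M) + L
    # star: opposite-arm partner region of the mature, shifted 2 nt 3'
    hp$star_seq <- substr(hp$precursor, A + M + L + 3, A + 2 * M + L + 2)

    # distribute features across contigs round-robin, with random spacers
    feats <- data.frame(
      name = c(known$name, ncrna$name, hp$name),
      kind = c(rep("known_miRNA", nrow(known)), ncrna$kind,
               rep("hairpin", nrow(hp))),
      strand = c(known$strand, rep("+", nrow(ncrna)), rep("+", nrow(hp))),
      sequence = c(known$sequence, ncrna$sequence, hp$precursor),
      stringsAsFactors = FALSE)
    feats$planted <- ifelse(feats$strand == "-",
                            revcomp(feats$sequence), feats$sequence)
    feats$contig <- paste0("contig", (seq_len(nrow(feats)) - 1) %%
                             config$n_contigs + 1)

    contigs <- character(config$n_contigs)
    names(contigs) <- paste0("contig", seq_len(config$n_contigs))
    loci <- list()
    for (cg in names(contigs)) {
      f <- feats[feats$contig == cg, , drop = FALSE]
      pos <- 0L  # 0-based cursor
      parts <- character(0)
      for (r in seq_len(nrow(f))) {
        gap <- sample(80:220, 1)
        parts <- c(parts, random_dna(gap), f$planted[r])
        start <- pos + gap
        end <- start + nchar(f$planted[r])
        loci[[length(loci) + 1]] <- data.frame(
          name = f$name[r], contig = cg, start = start, end = end,
          strand = f$strand[r], kind = f$kind[r], stringsAsFactors = FALSE)
        pos <- end
      }
      if (pos > config$contig_length)
        stop("contig ", cg, " shorter than requested feature layout")
      parts <- c(parts, random_dna(config$contig_length - pos))
      contigs[cg] <- paste(parts, collapse = "")
    }
    loci <- do.call(rbind, loci)

    # mature/star loci inside each hairpin (0-based half-open, '+' strand)
    hl <- loci[loci$kind == "hairpin", ]
    hp <- merge(hp, hl[, c("name", "contig", "start", "end")], by = "name",
                sort = FALSE)
    hp$mature_start <- hp$start + A
    hp$mature_end <- hp$start + A + M
    hp$star_start <- hp$start + A + M + L + 2
    hp$star_end <- hp$start + A + 2 * M + L + 2
    extra <- rbind(
      data.frame(name = paste0(hp$name, ".mature"), contig = hp$contig,
                 start = hp$mature_start, end = hp$mature_end, strand = "+",
                 kind = "novel_mature", stringsAsFactors = FALSE),
      data.frame(name = paste0(hp$name, ".star"), contig = hp$contig,
                 start = hp$star_start, end = hp$star_end, strand = "+",
                 kind = "novel_star", stringsAsFactors = FALSE))
    loci <- rbind(loci, extra)

    structure(list(
      contigs = contigs,
      ncrna_catalog = ncrna[, c("name", "kind", "sequence")],
      mature_catalog = known[, c("name", "family", "sequence")],
      hairpins = hp,
      planted_loci = loci,
      hairpin_length = H,
      config = config), class = "ReferenceBundle")
  })
}

## entity name -> insert sequence lookup for the simulator
entity_sequences <- function(bundle) {
  c(setNames(bundle$mature_catalog$sequence, bundle$mature_catalog$name),
    setNames(bundle$hairpins$mature_seq, paste0(bundle$hairpins$name, ".mature")),
    setNames(bundle$hairpins$star_seq, paste0(bundle$hairpins$name, ".star")))
}

## sample background inserts avoiding planted intervals
sample_background <- function(bundle, n) {
  if (n == 0) return(character(0))
  cls <- nchar(bundle$contigs)
  masks <- lapply(names(bundle$contigs), function(cg) {
    m <- logical(cls[cg])
    pl <- bundle$planted_loci[bundle$planted_loci$contig == cg, ]
    for (r in seq_len(nrow(pl))) m[(pl$start[r] + 1):pl$end[r]] <- TRUE
    m
  })
  names(masks) <- names(bundle$contigs)
  out <- character(0)
  while (length(out) < n) {
    k <- n - length(out)
    cg <- sample(names(bundle$contigs), k, replace = TRUE)
    len <- sample(18:24, k, replace = TRUE)
    pos <- floor(runif(k) * (cls[cg] - len)) + 1  # 1-based start
    ok <- vapply(seq_len(k), function(i)
      !any(masks[[cg[i]]][pos[i]:(pos[i] + len[i] - 1)]), logical(1))
    s <- substr(bundle$contigs[cg[ok]], pos[ok], pos[ok] + len[ok] - 1)
    minus <- runif(sum(ok)) < 0.5
    s[minus] <- revcomp(s[minus])
    out <- c(out, s)
  }
  out
}

## sample random 18-26 nt fragments of ncRNA catalog entries
sample_ncrna_fragment <- function(seqs, n_each) {
  unlist(lapply(seq_along(seqs), function(i) {
    k <- n_each[i]
    if (k == 0) return(character(0))
    len <- sample(18:26, k, replace = TRUE)
    pos <- floor(runif(k) * (nchar(seqs[i]) - len)) + 1
    substr(rep(seqs[i], k), pos, pos + len - 1)
  }))
}

#' Simulate three stage-labeled small-RNA FASTQ libraries
#'
#' Draws per-read classes (clean vs artifact) and, for clean reads, entity
#' identities from the stage profile's abundance fractions (multinomial).
#' Inserts get the 3' adapter appended and are truncated to the fixed
#' instrument read length; artifact classes (5' adapter contaminant,
#' missing 3' adapter, null insert, poly(A), short insert) are injected at
#' the configured rates.  Low quality scores (and rare 'N' bases) are
#' injected per base without altering insert identity.  The number of
#' emitted reads per library is `round(target_clean_reads /
#' (1 - sum(artifact_rates)))`.
#'
#' @param bundle a [make_reference()] bundle.
#' @param profiles list of three stage profiles covering stage1..stage3
#'   (see [default_stage_profiles()]).
#' @param seed integer RNG seed; output is byte-identical for identical
#'   `(bundle, profiles, seed)`.
#' @param outdir optional directory; if given, writes `<stage>.fastq`
#'   (Sanger, Phred+33) and `truth.tsv` there.
#' @return list with `reads` (per stage: character vectors `sequence`,
#'   `quality`, `class`, `entity`), `truth` (TruthTable data.frame: per
#'   planted entity the expected and realized per-stage counts, true
#'   log2 fold changes between stages under per-million scaling with the
#'   0 -> 0.01 substitution, and true DE status at |log2FC| >= 1), and
#'   `paths` when `outdir` is given.
#' @export
simulate_libraries <- function(bundle, profiles = default_stage_profiles(),
                               seed = 1, outdir = NULL) {
  stopifnot(inherits(bundle, "ReferenceBundle"))
  stages <- vapply(profiles, function(p) p$stage, character(1))
  if (!setequal(stages, c("stage1", "stage2", "stage3")))
    stop("profiles must cover stage1, stage2 and stage3")
  lapply(profiles, validate_profile)
  profiles <- profiles[order(stages)]

  ad <- default_adapters()
  rl <- bundle$config$read_length
  ent_seq <- entity_sequences(bundle)

  with_seed(seed, {
    reads <- list()
    realized <- list()
    for (p in profiles) {
      n_emit <- round(p$target_clean_reads / (1 - sum(p$artifact_rates)))
      classes <- sample(c(names(p$artifact_rates), "clean"), n_emit,
                        replace = TRUE,
                        prob = c(p$artifact_rates, 1 - sum(p$artifact_rates)))
      n_clean <- sum(classes == "clean")
      ents <- sample(c(names(p$abundance), ".background"), n_clean,
                     replace = TRUE,
                     prob = c(p$abundance, 1 - sum(p$abundance)))
      inserts <- character(n_clean)
      known_ent <- ents %in% names(ent_seq)
      inserts[known_ent] <- ent_seq[ents[known_ent]]
      for (i in seq_len(nrow(bundle$ncrna_catalog))) {
        nm <- bundle$ncrna_catalog$name[i]
        idx <- which(ents == nm)
        if (length(idx))
          inserts[idx] <- sample_ncrna_fragment(
            bundle$ncrna_catalog$sequence[i], length(idx))
      }
      bg <- which(ents == ".background")
      inserts[bg] <- sample_background(bundle, length(bg))

      all_ins <- character(n_emit)
      all_ins[classes == "clean"] <- inserts
      n_art <- sum(classes != "clean")
      if (n_art) {
        a5 <- which(classes == "adapter5_contaminant")
        all_ins[a5] <- paste0(substr(ad$adapter5, 1, 12), random_dna(rep(10, length(a5))))
        nul <- which(classes == "insert_null")
        all_ins[nul] <- ""
        sh <- which(classes == "shorter_18")
        if (length(sh)) {
          s <- sample_background(bundle, length(sh))
          all_ins[sh] <- substr(s, 1, sample(12:17, length(sh), replace = TRUE))
        }
        pa <- which(classes == "polyA")
        all_ins[pa] <- strrep("A", 22)
      }
      seqs <- substr(paste0(all_ins, ad$adapter3, strrep("G", rl)), 1, rl)
      # adapter3_null artifacts carry no adapter at all: raw genomic 36-mers
      a3 <- which(classes == "adapter3_null")
      if (length(a3)) {
        long <- paste0(sample_background(bundle, length(a3)),
                       sample_background(bundle, length(a3)))
        seqs[a3] <- substr(long, 1, rl)
      }

      # qualities: Q40 baseline, low-quality bases at quality_error_rate
      qm <- matrix("I", length(seqs), rl)
      low <- which(matrix(runif(length(seqs) * rl), length(seqs)) <
                     p$quality_error_rate)
      if (length(low))
        qm[low] <- sample(vapply(c(2:9, 10:12), function(q)
          rawToChar(as.raw(q + 33L)), character(1)), length(low), replace = TRUE)
      quals <- do.call(paste0, as.data.frame(qm, stringsAsFactors = FALSE))
      # rare N base injection
      nn <- which(runif(length(seqs)) < p$n_rate)
      if (length(nn)) {
        at <- sample.int(rl, length(nn), replace = TRUE)
        substr(seqs[nn], at, at) <- "N"
      }

      ent_all <- rep(NA_character_, n_emit)
      ent_all[classes == "clean"] <- ents
      reads[[p$stage]] <- list(sequence = seqs, quality = quals,
                               class = classes, entity = ent_all)
      realized[[p$stage]] <- table(factor(ents[ents != ".background"],
                                          levels = names(p$abundance)))
    }

    truth <- build_truth(bundle, profiles, realized)

    paths <- NULL
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      paths <- list()
      for (st in names(reads)) {
        fq <- file.path(outdir, paste0(st, ".fastq"))
        ids <- sprintf("%s_%06d", st, seq_along(reads[[st]]$sequence))
        x <- Biostrings::DNAStringSet(reads[[st]]$sequence)
        names(x) <- ids
        Biostrings::writeXStringSet(
          x, fq, format = "fastq",
          qualities = Biostrings::BStringSet(reads[[st]]$quality))
        paths[[st]] <- fq
      }
      write_tsv(truth, file.path(outdir, "truth.tsv"))
      paths$truth <- file.path(outdir, "truth.tsv")
    }
    list(reads = reads, truth = truth, paths = paths)
  })
}

## TruthTable: expected/realized counts, true log2FCs (per-million scaled,
## 0 -> 0.01 substituted), true DE status at |log2FC| >= 1
build_truth <- function(bundle, profiles, realized) {
  ents <- names(profiles[[1]]$abundance)
  fr <- vapply(profiles, function(p) p$abundance[ents], numeric(length(ents)))
  tg <- vapply(profiles, function(p) p$target_clean_reads, numeric(1))
  exp_counts <- sweep(fr, 2, tg, `*`)
  rpm <- fr * 1e6
  rpm_sub <- ifelse(rpm == 0, 0.01, rpm)
  fc <- function(a, b) log2(rpm_sub[, b] / rpm_sub[, a])
  data.frame(
    name = ents,
    kind = ifelse(ents %in% bundle$mature_catalog$name, "known_miRNA",
           ifelse(grepl("\\.mature$", ents), "novel_mature",
           ifelse(grepl("\\.star$", ents), "novel_star", "ncRNA"))),
    expected_s1 = exp_counts[, 1], expected_s2 = exp_counts[, 2],
    expected_s3 = exp_counts[, 3],
    realized_s1 = as.integer(realized$stage1[ents]),
    realized_s2 = as.integer(realized$stage2[ents]),
    realized_s3 = as.integer(realized$stage3[ents]),
    log2fc_s2_s1 = fc(1, 2), log2fc_s3_s1 = fc(1, 3), log2fc_s3_s2 = fc(2, 3),
    true_de = abs(fc(1, 2)) >= 1 | abs(fc(1, 3)) >= 1 | abs(fc(2, 3)) >= 1,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a reference bundle to disk
#'
#' Writes `contigs.fa`, `ncrna.fa` (headers `name|kind`), `mature.fa`
#' (headers `name|family`) and `planted_loci.tsv` (0-based half-open).
#'
#' @param bundle a [make_reference()] bundle.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_reference <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(bundle$contigs, file.path(dir, "contigs.fa"))
  write_fasta(setNames(bundle$ncrna_catalog$sequence,
                       paste(bundle$ncrna_catalog$name,
                             bundle$ncrna_catalog$kind, sep = "|")),
              file.path(dir, "ncrna.fa"))
  write_fasta(setNames(bundle$mature_catalog$sequence,
                       paste(bundle$mature_catalog$name,
                             bundle$mature_catalog$family, sep = "|")),
              file.path(dir, "mature.fa"))
  write_tsv(bundle$planted_loci, file.path(dir, "planted_loci.tsv"))
  invisible(dir)
}
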