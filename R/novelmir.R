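#' Pinned nearest-neighbor folding energy parameters
#'
#' The constant table behind [fold_rna()]: stacking energies (kcal/mol)
#' for the 36 ordered combinations of Watson-Crick/G:U pairs (outer pair
#' x inner pair), a fixed terminal-loop penalty, bulge and internal-loop
#' penalties, a multiloop closing/branch penalty, the minimum hairpin loop
#' (3 nt) and the interior-loop size cap (30 nt per side).  Stacks are
#' graded by pair strength (G:C > A:U > G:U), giving kcal/mol-scale
#' minimum free energies comparable to thermodynamic folders.  The table
#' is pinned so results are deterministic and shared with the exhaustive
#' enumeration oracle used in validation.
#'
#' @return list of energy constants (`stack` is a 6x6 matrix over pair
#'   types AU, UA, GC, CG, GU, UG).
#' @export
fold_energy_params <- function() {
  strength <- c(AU = 2, UA = 2, GC = 3, CG = 3, GU = 1, UG = 1)
  stack <- -0.5 - 0.45 * outer(strength, strength, `+`)
  list(stack = stack,
       hairpin = 5.0,
       bulge_open = 3.0, bulge_per = 1.0,
       internal_open = 4.0, internal_per = 0.5,
       multi_close = 6.0, multi_branch = 1.0,
       min_loop = 3L, max_interior = 30L)
}

#' Fold an RNA sequence to its minimum-free-energy nested structure
#'
#' Dynamic-programming search over all pseudoknot-free structures
#' (Watson-Crick and G:U pairs, minimum hairpin loop 3 nt) under the
#' pinned loop-based nearest-neighbor model of [fold_energy_params()].
#' Deterministic; invariant under T/U spelling of the input.  A sequence
#' that can form no favorable pair folds to the open chain with MFE 0.
#'
#' @param sequence RNA or DNA string, 10-400 nt (shorter sequences are
#'   accepted for validation work).
#' @param params energy constants, defaulting to [fold_energy_params()].
#' @return `FoldResult` list: `sequence` (as given), `structure`
#'   (dot-bracket, same length), `mfe` (kcal/mol, <= 0), `partner`
#'   (1-based pairing partner per position, 0 = unpaired).
#' @export
fold_rna <- function(sequence, params = fold_energy_params()) {
  if (nchar(sequence) > 400) stop("sequence longer than 400 nt")
  if (grepl("[^ACGUTacgut]", sequence)) stop("non-ACGU(T) characters")
  res <- .fold_cpp(sequence, params)
  list(sequence = sequence, structure = res$structure, mfe = res$mfe,
       partner = res$partner)
}

#' Excise candidate precursor windows around a mapped tag locus
#'
#' Two windows per locus, assuming the mature sits on the 5' or the 3'
#' arm: `[start - flank, end + small)` and `[start - small, end + flank)`,
#' clipped to contig bounds.  Coordinates are 0-based half-open; for '-'
#' strand loci the returned sequence is the reverse complement and the
#' mature position is given within the excised (strand-adjusted) window.
#'
#' @param locus list/row with `contig`, `start`, `end`, `strand`.
#' @param bundle reference bundle (named `contigs`).
#' @param flank long-side extension (nt), default 160.
#' @param small short-side extension (nt), default 15.
#' @return list of two windows, each a list with `contig`, `start`, `end`,
#'   `strand`, `sequence`, `mature_start`, `mature_end` (0-based half-open
#'   within the window sequence).
#' @export
excise_windows <- function(locus, bundle, flank = 160, small = 15) {
  stopifnot(flank >= 0, small >= 0)
  clen <- nchar(bundle$contigs[[locus$contig]])
  if (is.null(clen) || locus$start < 0 || locus$end > clen)
    stop("locus outside contig bounds")
  spans <- list(c(locus$start - flank, locus$end + small),
                c(locus$start - small, locus$end + flank))
  lapply(spans, function(sp) {
    s <- max(0, sp[1]); e <- min(clen, sp[2])
    seq <- substr(bundle$contigs[[locus$contig]], s + 1, e)
    ms <- locus$start - s
    me <- locus$end - s
    if (identical(locus$strand, "-")) {
      seq <- revcomp(seq)
      w <- e - s
      tmp <- w - me
      me <- w - ms
      ms <- tmp
    }
    list(contig = locus$contig, start = s, end = e, strand = locus$strand,
         sequence = seq, mature_start = ms, mature_end = me)
  })
}

## parse geometry of the mature within a fold: which bases pair, where
mature_geometry <- function(fold, ms, me) {
  # ms/me 0-based half-open -> 1-based inclusive positions
  pos <- (ms + 1):me
  part <- fold$partner[pos]
  paired <- part > 0
  list(pos = pos, part = part, paired = paired)
}

#' Evaluate a precursor window as a novel miRNA candidate
#'
#' Folds the window, locates the mature-spanning helix, trims the
#' precursor to the outermost mature pair, refolds, and computes the
#' acceptance flags: `stem_loop` (the mature pairs predominantly with the
#' opposite arm across a single terminal loop), `mature_in_one_arm` (the
#' mature does not span the loop and does not pair with itself),
#' `duplex_mismatches_ok` (at most 4 unpaired mature bases),
#' `bulge_ok` (no asymmetric bulge > 2 nt inside the duplex), `mfe_ok`
#' (precursor MFE at or below `mfe_max` kcal/mol).  A candidate is
#' accepted iff all flags hold.  If a tag table is supplied, a miRNA*
#' search runs: a tag whose mapped span equals the opposite-arm partner
#' region of the mature shifted 2 nt 3' (the canonical Dicer overhang),
#' with <= `star_slack` nt positional slack, is reported as star support.
#'
#' @param window one element of [excise_windows()] output.
#' @param tag_counts optional named counts (sequence -> total reads) used
#'   for star lookup and the star/mature abundance flag.
#' @param mfe_max MFE acceptance threshold, default -18 kcal/mol (the
#'   observed lower edge of plant precursor stability).
#' @param star_slack positional slack for the star span (nt), default 1.
#' @param params folding energy constants.
#' @return `NovelCandidate` list: `precursor` (sequence), `locus`
#'   (contig/start/end/strand of the trimmed precursor), `hairpin_length`,
#'   `mfe`, `structure`, `arm` ("5p"/"3p"), `criteria_flags` (named
#'   logical), `accepted`, `star` (list with `sequence`, `count`,
#'   `more_abundant_than_mature` flag, or NULL).
#' @export
evaluate_candidate <- function(window, tag_counts = NULL, mfe_max = -18,
                               star_slack = 1, params = fold_energy_params()) {
  flags <- c(stem_loop = FALSE, mature_in_one_arm = FALSE,
             duplex_mismatches_ok = FALSE, bulge_ok = FALSE, mfe_ok = FALSE)
  empty <- list(precursor = NA_character_, locus = NULL,
                hairpin_length = NA_integer_, mfe = NA_real_,
                structure = NA_character_, arm = NA_character_,
                criteria_flags = flags, accepted = FALSE, star = NULL)
  ms <- window$mature_start; me <- window$mature_end
  if (me <= ms || ms < 0 || me > nchar(window$sequence))
    stop("mature tag does not map inside window")

  f <- fold_rna(window$sequence, params)
  g <- mature_geometry(f, ms, me)
  if (sum(g$paired) == 0) return(empty)

  # all geometry flags are read off the window fold (coordinates 1-based
  # within the window sequence)
  n_unpaired <- sum(!g$paired)
  flags["duplex_mismatches_ok"] <- n_unpaired <= 4

  ppos <- g$pos[g$paired]; ppart <- g$part[g$paired]
  self_paired <- any(ppart >= ms + 1 & ppart <= me)
  all_right <- all(ppart > me)
  all_left <- all(ppart < ms + 1)
  flags["mature_in_one_arm"] <- !self_paired && (all_right || all_left) &&
    length(ppos) > 0
  arm <- if (all_right) "5p" else if (all_left) "3p" else NA_character_

  if (flags["mature_in_one_arm"]) {
    # single terminal loop: region between the innermost mature pair and
    # its partner holds at most one helix branch
    if (arm == "5p") { im <- max(ppos); ip <- ppart[which.max(ppos)] }
    else { im <- min(ppos); ip <- ppart[which.min(ppos)] }
    inner <- (min(im, ip) + 1):(max(im, ip) - 1)
    branches <- 0L
    k <- 1
    while (k <= length(inner)) {
      p <- f$partner[inner[k]]
      if (p > inner[k] && p %in% inner) { branches <- branches + 1L
        k <- which(inner == p) + 1 } else k <- k + 1
    }
    predominant <- sum(g$paired) >= ceiling((me - ms) / 2)
    flags["stem_loop"] <- branches <= 1L && predominant

    # asymmetric bulges within the duplex
    ok <- TRUE
    ord <- order(ppos)
    for (k in seq_len(length(ord) - 1)) {
      i1 <- ppos[ord[k]]; i2 <- ppos[ord[k + 1]]
      j1 <- ppart[ord[k]]; j2 <- ppart[ord[k + 1]]
      gap_m <- i2 - i1 - 1
      gap_s <- abs(j1 - j2) - 1
      if (abs(gap_m - gap_s) > 2) { ok <- FALSE; break }
    }
    flags["bulge_ok"] <- ok
  }

  # precursor: trimmed to the mature-spanning helix (outermost mature pair
  # and its partner), refolded for the reported structure and MFE
  lo <- min(c(ppos, ppart)); hi <- max(c(ppos, ppart))
  prec <- substr(window$sequence, lo, hi)
  pf <- fold_rna(prec, params)
  flags["mfe_ok"] <- pf$mfe <= mfe_max

  star <- NULL
  if (all(flags[c("mature_in_one_arm", "stem_loop")]) &&
      !is.null(tag_counts) && length(tag_counts)) {
    # expected star span: partner region of the mature shifted 2 nt 3'
    sp_start <- min(ppart) + 2; sp_end <- max(ppart) + 2
    n <- nchar(window$sequence)
    mature_seq <- substr(window$sequence, ms + 1, me)
    mcount <- if (mature_seq %in% names(tag_counts))
      tag_counts[[mature_seq]] else NA_real_
    for (slack in 0:star_slack) {
      for (sh in unique(c(0, slack, -slack))) {
        s1 <- sp_start + sh; s2 <- sp_end + sh
        if (s1 < 1 || s2 > n) next
        cand <- substr(window$sequence, s1, s2)
        if (cand %in% names(tag_counts)) {
          star <- list(sequence = cand, count = tag_counts[[cand]],
                       more_abundant_than_mature =
                         !is.na(mcount) && tag_counts[[cand]] > mcount)
          break
        }
      }
      if (!is.null(star)) break
    }
  }

  locus <- list(contig = window$contig, strand = window$strand)
  if (identical(window$strand, "-")) {
    locus$start <- window$end - hi
    locus$end <- window$end - (lo - 1)
  } else {
    locus$start <- window$start + lo - 1
    locus$end <- window$start + hi
  }

  list(precursor = prec, locus = locus, hairpin_length = nchar(prec),
       mfe = pf$mfe, structure = pf$structure, arm = arm,
       criteria_flags = flags, accepted = all(flags), star = star)
}

#' Predict novel miRNA candidates from unannotated mapped tags
#'
#' Runs the full discovery pass: eligible tags (unannotated category,
#' mapped to the reference, total count >= `min_count`) are excised into
#' candidate precursor windows at each mapped locus, folded, and
#' evaluated; accepted candidates with overlapping precursor loci collapse
#' to the lowest-MFE one.  Names are assigned `rsa-nmiR<k>-5p/3p` in
#' precursor-locus order.
#'
#' @param annotation annotation data.frame from [classify_tags()] (with
#'   per-stage count columns).
#' @param loci mapped loci data.frame from [classify_tags()]/[map_tags()].
#' @param bundle reference bundle.
#' @param min_count minimum total read count for a mature candidate
#'   (default 5, the lowest abundance observed for accepted plant novel
#'   miRNAs).
#' @param flank,small window extensions, see [excise_windows()].
#' @param mfe_max MFE acceptance threshold (kcal/mol).
#' @return data.frame of accepted candidates: `name`, `mature_sequence`,
#'   `contig`, `start`, `end`, `strand`, `hairpin_length`, `mfe`,
#'   `structure`, per-stage mature counts, `star_sequence`, `star_count`,
#'   `star_flag` (star more abundant than mature).
#' @export
predict_novel <- function(annotation, loci, bundle, min_count = 5,
                          flank = 160, small = 15, mfe_max = -18) {
  count_cols <- setdiff(names(annotation),
                        c("sequence", "length", "category", "matched_mirna",
                          "family", "mismatches", "n_loci", "total"))
  total <- if ("total" %in% names(annotation)) annotation$total
           else rowSums(annotation[, count_cols, drop = FALSE])
  elig <- annotation$category == "unannotated" & annotation$n_loci > 0 &
    total >= min_count
  tag_counts <- setNames(total, annotation$sequence)

  cands <- list()
  for (i in which(elig)) {
    tg <- annotation$sequence[i]
    tl <- loci[loci$sequence == tg, , drop = FALSE]
    for (r in seq_len(nrow(tl))) {
      wins <- excise_windows(as.list(tl[r, ]), bundle, flank, small)
      for (w in wins) {
        cand <- evaluate_candidate(w, tag_counts, mfe_max = mfe_max)
        if (isTRUE(cand$accepted)) {
          cand$mature_sequence <- tg
          cands[[length(cands) + 1]] <- cand
        }
      }
    }
  }
  if (!length(cands)) {
    out <- data.frame(name = character(0), mature_sequence = character(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      hairpin_length = integer(0), mfe = numeric(0),
                      structure = character(0), star_sequence = character(0),
                      star_count = numeric(0), star_flag = logical(0),
                      stringsAsFactors = FALSE)
    return(out)
  }

  df <- data.frame(
    mature_sequence = vapply(cands, `[[`, character(1), "mature_sequence"),
    contig = vapply(cands, function(x) x$locus$contig, character(1)),
    start = vapply(cands, function(x) x$locus$start, numeric(1)),
    end = vapply(cands, function(x) x$locus$end, numeric(1)),
    strand = vapply(cands, function(x) x$locus$strand, character(1)),
    hairpin_length = vapply(cands, `[[`, numeric(1), "hairpin_length"),
    mfe = vapply(cands, `[[`, numeric(1), "mfe"),
    structure = vapply(cands, `[[`, character(1), "structure"),
    arm = vapply(cands, `[[`, character(1), "arm"),
    star_sequence = vapply(cands, function(x)
      if (is.null(x$star)) NA_character_ else x$star$sequence, character(1)),
    star_count = vapply(cands, function(x)
      if (is.null(x$star)) NA_real_ else x$star$count, numeric(1)),
    star_flag = vapply(cands, function(x)
      if (is.null(x$star)) FALSE else x$star$more_abundant_than_mature,
      logical(1)),
    stringsAsFactors = FALSE)
  mat_total <- tag_counts[df$mature_sequence]

  # collapse overlapping accepted precursors: the more abundant arm is
  # called mature (star strands are rapidly degraded), then lowest MFE
  ord <- order(-mat_total, df$mfe)
  df <- df[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    if (!keep[i]) next
    if (i < nrow(df)) for (j in (i + 1):nrow(df)) {
      if (!keep[j]) next
      if (df$contig[j] == df$contig[i] &&
          df$start[j] < df$end[i] && df$end[j] > df$start[i])
        keep[j] <- FALSE
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$contig, df$start), , drop = FALSE]
  df$name <- sprintf("rsa-nmiR%d-%s", seq_len(nrow(df)), df$arm)

  for (cc in count_cols)
    df[[cc]] <- annotation[[cc]][match(df$mature_sequence,
                                       annotation$sequence)]
  rownames(df) <- NULL
  df[, c("name", "mature_sequence", "contig", "start", "end", "strand",
         "hairpin_length", "mfe", "structure", count_cols,
         "star_sequence", "star_count", "star_flag")]
}
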