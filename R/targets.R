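## pairing cost between a miRNA base and a transcript base (antiparallel):
## 0 Watson-Crick, 0.5 G:U wobble, 1 mismatch (N counts as mismatch)
pair_cost <- function(mb, tb) {
  wc <- (mb == "A" & tb == "T") | (mb == "C" & tb == "G") |
        (mb == "G" & tb == "C") | (mb == "T" & tb == "A")
  wob <- (mb == "G" & tb == "T") | (mb == "T" & tb == "G")
  ifelse(wc, 0, ifelse(wob, 0.5, 1))
}

seed_weight <- function(pos, seed_range = c(2, 13)) {
  ifelse(pos >= seed_range[1] & pos <= seed_range[2], 2, 1)
}

#' Score a miRNA / target-site alignment
#'
#' Optimal gapped alignment of a miRNA against a candidate site under the
#' pinned complementarity penalty scheme: mismatch +1, G:U wobble +0.5,
#' gap +2, all doubled at miRNA positions 2-13 (the 5'-anchored seed
#' region).  The site is given 5'->3' as it appears on the transcript; the
#' miRNA pairs antiparallel, so miRNA position 1 aligns at the 3' end of
#' the site.  A perfect reverse-complement site scores 0.
#'
#' @param mirna miRNA sequence 5'->3' (U or T spelling).
#' @param site transcript site 5'->3' (length within miRNA length +/-
#'   `max_gaps`).
#' @param max_gaps maximum number of gap columns (default 1).
#' @param seed_range miRNA positions whose penalties double.
#' @return list with `expectation` (penalty score >= 0), `mode`
#'   (`"translation"` if any penalized column falls at miRNA positions
#'   9-11, else `"cleavage"`), and `alignment` (character length-3:
#'   miRNA 3'->5', match line, site 5'->3'; `|` Watson-Crick, `o` G:U,
#'   space mismatch, `-` gap).
#' @export
score_alignment <- function(mirna, site, max_gaps = 1,
                            seed_range = c(2, 13)) {
  m <- rev(strsplit(toupper(chartr("U", "T", mirna)), "")[[1]])  # 3'->5' read left-right
  s <- strsplit(toupper(chartr("U", "T", site)), "")[[1]]
  M <- length(m); S <- length(s)
  if (abs(S - M) > max_gaps)
    stop("site length outside miRNA length +/- max_gaps")
  # m[i] is miRNA position M - i + 1 (miRNA pos 1 = 3' end of site is at
  # the right); align left-to-right: site 5' end vs miRNA 3' region
  mpos <- M:1  # miRNA position of m[..] reversed... recompute below
  mpos <- rev(seq_len(M))  # position of m[i] in 5'->3' numbering
  INF <- 1e9
  # dp[i+1, j+1, g+1]: first i miRNA chars (3'->5'), first j site chars,
  # g gaps used
  dp <- array(INF, c(M + 1, S + 1, max_gaps + 1))
  bt <- array(0L, c(M + 1, S + 1, max_gaps + 1))
  dp[1, 1, 1] <- 0
  for (g in 0:max_gaps) for (i in 0:M) for (j in 0:S) {
    cur <- dp[i + 1, j + 1, g + 1]
    if (cur >= INF) next
    if (i < M && j < S) {
      w <- seed_weight(mpos[i + 1], seed_range)
      v <- cur + w * pair_cost(m[i + 1], s[j + 1])
      if (v < dp[i + 2, j + 2, g + 1]) {
        dp[i + 2, j + 2, g + 1] <- v; bt[i + 2, j + 2, g + 1] <- 1L
      }
    }
    if (g < max_gaps && i < M) {  # gap in site (miRNA base unpaired)
      w <- seed_weight(mpos[i + 1], seed_range)
      v <- cur + w * 2
      if (v < dp[i + 2, j + 1, g + 2]) {
        dp[i + 2, j + 1, g + 2] <- v; bt[i + 2, j + 1, g + 2] <- 2L
      }
    }
    if (g < max_gaps && j < S) {  # gap in miRNA (site base bulged)
      w <- if (i < M) seed_weight(mpos[i + 1], seed_range) else 1
      v <- cur + w * 2
      if (v < dp[i + 1, j + 2, g + 2]) {
        dp[i + 1, j + 2, g + 2] <- v; bt[i + 1, j + 2, g + 2] <- 3L
      }
    }
  }
  gbest <- which.min(dp[M + 1, S + 1, ]) - 1L
  expectation <- dp[M + 1, S + 1, gbest + 1]

  # traceback for the alignment strings and the mode
  i <- M; j <- S; g <- gbest
  top <- character(0); mid <- character(0); bot <- character(0)
  mode_pos <- integer(0)
  while (i > 0 || j > 0) {
    op <- bt[i + 1, j + 1, g + 1]
    if (op == 1L) {
      cost <- pair_cost(m[i], s[j])
      top <- c(m[i], top)
      mid <- c(if (cost == 0) "|" else if (cost == 0.5) "o" else " ", mid)
      bot <- c(s[j], bot)
      if (cost > 0) mode_pos <- c(mode_pos, mpos[i])
      i <- i - 1; j <- j - 1
    } else if (op == 2L) {
      top <- c(m[i], top); mid <- c(" ", mid); bot <- c("-", bot)
      mode_pos <- c(mode_pos, mpos[i])
      i <- i - 1; g <- g - 1
    } else {
      top <- c("-", top); mid <- c(" ", mid); bot <- c(s[j], bot)
      mode_pos <- c(mode_pos, if (i > 0) mpos[i] else 1L)
      j <- j - 1; g <- g - 1
    }
  }
  mode <- if (any(mode_pos >= 9 & mode_pos <= 11)) "translation" else "cleavage"
  list(expectation = expectation, mode = mode,
       alignment = c(paste(top, collapse = ""), paste(mid, collapse = ""),
                     paste(bot, collapse = "")))
}

#' Scan transcripts for miRNA target sites
#'
#' Slides over every window of each transcript whose length is within
#' `max_gaps` of the miRNA length, computes the optimal gapped alignment
#' expectation ([score_alignment()]), and reports windows scoring at or
#' below `cutoff`.  Overlapping windows are deduplicated to the best
#' (lowest-expectation) one, ties to the leftmost.  Window coordinates are
#' 0-based half-open on the transcript.
#'
#' @param mirna miRNA sequence 5'->3'.
#' @param transcripts named character vector of transcript sequences.
#' @param cutoff maximum expectation for a reported hit (default 3.0).
#' @param max_gaps maximum gap columns (default 1).
#' @return `TargetHit` data.frame: `mirna`, `transcript`, `start`, `end`,
#'   `expectation`, `mode`, `align_mirna`, `align_match`,
#'   `align_transcript`.
#' @export
scan_targets <- function(mirna, transcripts, cutoff = 3.0, max_gaps = 1) {
  if (!length(transcripts)) stop("transcripts must be nonempty")
  if (is.null(names(transcripts)))
    names(transcripts) <- paste0("tx", seq_along(transcripts))
  M <- nchar(chartr("U", "T", mirna))
  hits <- list()
  for (tx in names(transcripts)) {
    s <- transcripts[[tx]]
    L <- nchar(s)
    for (wlen in (M - max_gaps):(M + max_gaps)) {
      if (wlen < 1 || wlen > L) next
      for (st in 1:(L - wlen + 1)) {
        site <- substr(s, st, st + wlen - 1)
        sc <- score_alignment(mirna, site, max_gaps)
        if (sc$expectation <= cutoff)
          hits[[length(hits) + 1]] <- data.frame(
            mirna = mirna, transcript = tx, start = st - 1L,
            end = st - 1L + wlen, expectation = sc$expectation,
            mode = sc$mode, align_mirna = sc$alignment[1],
            align_match = sc$alignment[2],
            align_transcript = sc$alignment[3], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), end = integer(0),
               expectation = numeric(0), mode = character(0),
               align_mirna = character(0), align_match = character(0),
               align_transcript = character(0), stringsAsFactors = FALSE)
  if (!nrow(out)) return(out)
  # deduplicate overlapping windows per transcript: best score, leftmost
  out <- out[order(out$transcript, out$expectation, out$start), ]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in (i + 1):nrow(out)) {
      if (!keep[j] || out$transcript[j] != out$transcript[i]) next
      if (out$start[j] < out$end[i] && out$end[j] > out$start[i])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$transcript, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
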