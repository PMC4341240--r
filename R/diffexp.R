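#' Reads-per-million normalization
#'
#' `count / libsize * 1e6`, where the denominator is the library's
#' clean-read total.  No zero substitution happens here: the 0 -> 0.01
#' rule belongs to the fold-change stage ([fold_change()]).
#'
#' @param count raw read count(s), >= 0.
#' @param libsize clean-read total of the library, > 0.
#' @param digits decimal places for the reported value (default 2,
#'   round-half-even); use `NA` for full precision.
#' @return normalized expression (reads per million).
#' @export
normalize_rpm <- function(count, libsize, digits = 2) {
  if (any(libsize <= 0)) stop("libsize must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  x <- count / libsize * 1e6
  if (!is.na(digits)) x <- round(x, digits)
  x
}

#' Pairwise log2 fold change with substitution and skip rules
#'
#' Substitutes 0.01 for a normalized value of exactly zero in either
#' operand; when both (substituted) values are below one the comparison is
#' skipped (too low expression).  Otherwise returns
#' `log2(rpm_b / rpm_a)` with `a` the control (earlier stage) and `b` the
#' treatment (later stage).
#'
#' @param rpm_a,rpm_b normalized expression in control and treatment.
#' @param digits decimal places (default 2, round-half-even); `NA` for
#'   full precision.
#' @return numeric log2 fold change, or `NA` when skipped.
#' @export
fold_change <- function(rpm_a, rpm_b, digits = 2) {
  stopifnot(all(rpm_a >= 0), all(rpm_b >= 0))
  a <- ifelse(rpm_a == 0, 0.01, rpm_a)
  b <- ifelse(rpm_b == 0, 0.01, rpm_b)
  fc <- ifelse(a < 1 & b < 1, NA_real_, log2(b / a))
  if (!is.na(digits)) fc <- round(fc, digits)
  fc
}

## log(sum(exp(lx))) without overflow
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

#' Exact test for a count difference between two unreplicated libraries
#'
#' Audic-Claverie style exact test: given `x` reads in a library of `N1`
#' total and `y` in one of `N2`, the conditional probability of `y` is
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1+N2/N1)^{-(x+y+1)}}
#' and the two-sided p-value doubles the smaller tail
#' (`sum(k <= y)` vs `sum(k >= y)` of `p(k|x)`), capped at 1.  Computed in
#' log space (log-gamma), so counts up to 1e7 pose no overflow.
#'
#' The construction conditions on `x`: the first library plays the
#' reference role, so arguments are not interchangeable (pass the control
#' library as `(x, N1)`, as [diffexp_table()] does with the earlier
#' stage).
#'
#' @param x,y observed counts in the two libraries.
#' @param N1,N2 library totals (clean reads).
#' @return p-value in (0, 1].
#' @export
ac_pvalue <- function(x, N1, y, N2) {
  stopifnot(x >= 0, y >= 0, N1 > 0, N2 > 0)
  # single-log forms: k * lq amplifies any absolute error in lq, so lq
  # must come from one log of the accurately-rounded ratio
  lq <- log(N2 / (N1 + N2))       # log q, q = N2/(N1+N2)
  lp <- log1p(-N2 / (N1 + N2))
  # log C(x+k, k) via lbeta avoids the catastrophic lgamma cancellation
  # at large counts
  logp <- function(k) -log(x + k + 1) - lbeta(x + 1, k + 1) +
    k * lq + (x + 1) * lp
  lk <- logp(0:y)
  lower <- exp(logsumexp(lk))
  # upper tail: by complement when it carries substantial mass (the lower
  # tail is then the smaller one and absolute error is negligible), else
  # by direct summation from y, where terms decay geometrically
  upper <- 1 - lower + exp(lk[y + 1])
  if (upper <= 0.1) {
    lterms <- numeric(4096)
    lterms[1] <- lk[y + 1]
    m <- 1L
    k <- y
    lmax <- lterms[1]
    repeat {
      k <- k + 1
      lt <- logp(k)
      m <- m + 1L
      if (m > length(lterms)) lterms <- c(lterms, numeric(length(lterms)))
      lterms[m] <- lt
      # term ratio p(k+1)/p(k) = (x+k+1)/(k+1) * q, < 1 beyond the mode
      if (lt < lmax - 45 && (x + k + 1) / (k + 1) * exp(lq) < 1) break
      lmax <- max(lmax, lt)
    }
    upper <- exp(logsumexp(lterms[seq_len(m)]))
  }
  min(1, 2 * min(lower, upper))
}

#' Build the per-miRNA expression table across three stages
#'
#' Computes RPM values, the three pairwise log2 fold changes
#' (stage2/stage1, stage3/stage1, stage3/stage2) under the substitution
#' and skip rules of [fold_change()], exact-test p-values on the raw
#' counts ([ac_pvalue()]), the DE flag (at least one non-skipped
#' comparison with `|log2FC| >= fc_threshold` and `p < alpha`), and the
#' expression-pattern cluster label for DE records.
#'
#' @param counts data.frame with `id` and count columns `s1`, `s2`, `s3`
#'   (optionally `family`).
#' @param libsizes numeric length-3: clean-read totals of the three
#'   stage libraries.
#' @param fc_threshold log2 fold-change threshold (default 1.0).
#' @param alpha significance level (default 0.05).
#' @return `ExpressionRecord` data.frame: `id`, (`family`,) raw counts,
#'   `rpm_s1..s3` (2 dp), `log2fc_s2_s1`, `log2fc_s3_s1`, `log2fc_s3_s2`
#'   (2 dp, `NA` = skipped), `p_s2_s1`, `p_s3_s1`, `p_s3_s2`, `de`,
#'   `cluster`.
#' @export
diffexp_table <- function(counts, libsizes, fc_threshold = 1.0,
                          alpha = 0.05) {
  stopifnot(length(libsizes) == 3,
            all(c("id", "s1", "s2", "s3") %in% names(counts)))
  rpm <- vapply(1:3, function(i)
    normalize_rpm(counts[[paste0("s", i)]], libsizes[i], digits = NA),
    numeric(nrow(counts)))
  if (nrow(counts) == 1) rpm <- matrix(rpm, nrow = 1)
  cmp <- list(c(1, 2), c(1, 3), c(2, 3))
  cmp_names <- c("s2_s1", "s3_s1", "s3_s2")
  fc <- sapply(cmp, function(ij) fold_change(rpm[, ij[1]], rpm[, ij[2]]))
  pv <- sapply(cmp, function(ij)
    mapply(ac_pvalue, counts[[paste0("s", ij[1])]], libsizes[ij[1]],
           counts[[paste0("s", ij[2])]], libsizes[ij[2]]))
  if (nrow(counts) == 1) { fc <- matrix(fc, 1); pv <- matrix(pv, 1) }
  colnames(fc) <- paste0("log2fc_", cmp_names)
  colnames(pv) <- paste0("p_", cmp_names)

  de <- screen_de(fc, pv, fc_threshold, alpha)
  cluster <- cluster_patterns(fc[, "log2fc_s2_s1"], fc[, "log2fc_s3_s2"],
                              fc_threshold)
  cluster[!de] <- NA_character_

  out <- counts[, intersect(c("id", "family", "s1", "s2", "s3"),
                            names(counts)), drop = FALSE]
  out$rpm_s1 <- round(rpm[, 1], 2)
  out$rpm_s2 <- round(rpm[, 2], 2)
  out$rpm_s3 <- round(rpm[, 3], 2)
  out <- cbind(out, fc, pv)
  out$de <- de
  out$cluster <- cluster
  rownames(out) <- NULL
  out
}

#' Differential-expression screen
#'
#' A record is differentially expressed iff at least one of its
#' comparisons has `|log2FC| >= fc_threshold`, `p < alpha`, and was not
#' skipped by the low-expression rule.
#'
#' @param fc matrix of log2 fold changes (records x comparisons; `NA` =
#'   skipped).
#' @param pv matrix of p-values, same shape.
#' @param fc_threshold,alpha screening thresholds.
#' @return logical vector, one per record.
#' @export
screen_de <- function(fc, pv, fc_threshold = 1.0, alpha = 0.05) {
  hit <- !is.na(fc) & abs(fc) >= fc_threshold & pv < alpha
  rowSums(hit) > 0
}

#' Expression-pattern cluster labels
#'
#' Deterministic sign-pattern clustering of stage trajectories: each of
#' the two transitions (stage1 -> stage2, stage2 -> stage3) is labeled
#' `down`, `flat` or `up` using `|log2FC| >= threshold` (skipped
#' comparisons count as flat); the cluster is the pair of labels, e.g.
#' `down_down` for a monotone decline.  The all-flat pattern cannot occur
#' among DE records at the same threshold.
#'
#' @param fc12 log2 fold change stage2/stage1 (vector).
#' @param fc23 log2 fold change stage3/stage2 (vector).
#' @param threshold move threshold on the log2 scale.
#' @return character vector of labels `<move1>_<move2>`.
#' @export
cluster_patterns <- function(fc12, fc23, threshold = 1.0) {
  move <- function(fc) ifelse(is.na(fc), "flat",
                       ifelse(fc >= threshold, "up",
                       ifelse(fc <= -threshold, "down", "flat")))
  paste(move(fc12), move(fc23), sep = "_")
}
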