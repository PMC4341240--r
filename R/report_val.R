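#' Relative expression by the 2^-ddCt method
#'
#' Classic relative quantification for RT-qPCR with a reference gene and a
#' calibrator sample, assuming amplification efficiency 2:
#' `2 ^ -((ct_target - ct_reference) - (ct_target_cal - ct_reference_cal))`.
#' Adding a constant to all four Ct values leaves the ratio unchanged.
#'
#' @param ct_target,ct_reference cycle thresholds of the target and the
#'   reference gene (e.g. 5.8S rRNA for miRNAs, Actin for mRNAs) in the
#'   sample of interest.
#' @param ct_target_cal,ct_reference_cal the same two Ct values in the
#'   calibrator sample.
#' @return relative expression (1.0 for the calibrator itself).
#' @export
ddct <- function(ct_target, ct_reference, ct_target_cal, ct_reference_cal) {
  ctv <- c(ct_target, ct_reference, ct_target_cal, ct_reference_cal)
  if (any(!is.finite(ctv)) || any(ctv <= 0))
    stop("Ct values must be finite and > 0")
  dd <- (ct_target - ct_reference) - (ct_target_cal - ct_reference_cal)
  2^-dd
}

#' Relative expression table from a Ct measurement table
#'
#' @param ct data.frame with columns `sample_id`, `ct_target`,
#'   `ct_reference`.
#' @param calibrator `sample_id` of the calibrator row.
#' @return the table with a `relative_expression` column appended.
#' @export
qpcr_relative <- function(ct, calibrator) {
  stopifnot(all(c("sample_id", "ct_target", "ct_reference") %in% names(ct)))
  cal <- ct[ct$sample_id == calibrator, ]
  if (nrow(cal) != 1) stop("calibrator sample not found (or not unique)")
  ct$relative_expression <- ddct(ct$ct_target, ct$ct_reference,
                                 cal$ct_target, cal$ct_reference)
  ct
}

#' miRNA / target expression-tendency summary
#'
#' Spearman correlation of a miRNA's stagewise expression against each
#' putative target's, flagged `anti` (rho <= -0.5), `co` (rho >= 0.5) or
#' `none`; the qualitative anti-correlation check used when contrasting
#' miRNA and target trajectories.
#'
#' @param mirna_expr numeric vector of miRNA expression across samples.
#' @param target_expr numeric vector (same length) of target expression.
#' @return list with `rho` and `flag`.
#' @export
expression_tendency <- function(mirna_expr, target_expr) {
  stopifnot(length(mirna_expr) == length(target_expr),
            length(mirna_expr) >= 3)
  rho <- suppressWarnings(cor(mirna_expr, target_expr, method = "spearman"))
  flag <- if (is.na(rho)) "none" else if (rho <= -0.5) "anti" else
    if (rho >= 0.5) "co" else "none"
  list(rho = rho, flag = flag)
}

#' Write the paper-shaped summary reports
#'
#' Emits the standard artifact set from upstream pipeline outputs, all
#' recomputed from the upstream tables (no report-only arithmetic):
#' `summary_table1.tsv` (per-stage cleaning accounting),
#' `length_dist.tsv` (clean-read counts per insert length 18-30),
#' `annotation_summary.tsv` (six-category tag/read totals),
#' `expression_table2.tsv` (per-miRNA raw counts, RPM, fold changes,
#' p-values, DE flag, cluster), `de_clusters.tsv`, and
#' `novel_candidates.tsv` when novel predictions are present.
#'
#' @param run list with components `summaries` (named per-stage cleaning
#'   summaries), `tags` (named per-stage tag tables), `annotation_summary`,
#'   `expression` (a [diffexp_table()] result), optionally `novel`.
#' @param outdir output directory.
#' @return invisibly, the vector of written paths.
#' @export
build_reports <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need <- c("summaries", "tags", "expression")
  miss <- setdiff(need, names(run))
  if (length(miss))
    stop("missing upstream output(s): ", paste(miss, collapse = ", "),
         "; rerun that stage")
  paths <- character(0)

  t1 <- do.call(rbind, lapply(names(run$summaries), function(st) {
    s <- run$summaries[[st]]
    s$stage <- st
    s
  }))
  p <- file.path(outdir, "summary_table1.tsv")
  write_tsv(t1[, c("stage", "category", "count", "percent")], p)
  paths <- c(paths, p)

  ld <- do.call(rbind, lapply(names(run$tags), function(st) {
    d <- length_distribution(run$tags[[st]])
    d$stage <- st
    d
  }))
  p <- file.path(outdir, "length_dist.tsv")
  write_tsv(ld[, c("stage", "length", "reads")], p)
  paths <- c(paths, p)

  if (!is.null(run$annotation_summary)) {
    p <- file.path(outdir, "annotation_summary.tsv")
    write_tsv(run$annotation_summary, p)
    paths <- c(paths, p)
  }

  p <- file.path(outdir, "expression_table2.tsv")
  write_tsv(run$expression, p)
  paths <- c(paths, p)

  de <- run$expression[run$expression$de, , drop = FALSE]
  p <- file.path(outdir, "de_clusters.tsv")
  write_tsv(de[, intersect(c("id", "family", "log2fc_s2_s1", "log2fc_s3_s1",
                             "log2fc_s3_s2", "cluster"), names(de))], p)
  paths <- c(paths, p)

  if (!is.null(run$novel) && nrow(run$novel)) {
    p <- file.path(outdir, "novel_candidates.tsv")
    write_tsv(run$novel, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
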