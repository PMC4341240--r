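#' Run the full small-RNA analysis pipeline on three stage libraries
#'
#' Convenience wrapper tying the stages together: per-library cleaning and
#' tag collapsing, tag-table merging, hierarchical annotation, known-miRNA
#' member quantification, novel-candidate prediction, and the three-way
#' differential-expression table (known members and accepted novel
#' matures).
#'
#' @param fastqs named list (`stage1`, `stage2`, `stage3`) of FASTQ paths
#'   or in-memory read lists (see [clean_library()]).
#' @param bundle reference bundle ([make_reference()]).
#' @param adapters adapter list.
#' @param min_novel_count minimum total count for a novel mature
#'   candidate.
#' @param fc_threshold,alpha DE screening thresholds.
#' @return list with `summaries`, `tags` (per stage), `merged` (tag-by-
#'   stage counts), `annotation`, `annotation_summary`, `loci`, `novel`,
#'   `known_counts` (per matched mature), `expression`
#'   ([diffexp_table()] over known members and novel matures), and
#'   `libsizes`.
#' @export
run_pipeline <- function(fastqs, bundle, adapters = default_adapters(),
                         min_novel_count = 5, fc_threshold = 1.0,
                         alpha = 0.05) {
  stopifnot(setequal(names(fastqs), c("stage1", "stage2", "stage3")))
  cleaned <- lapply(fastqs[c("stage1", "stage2", "stage3")],
                    clean_library, adapters = adapters)
  summaries <- lapply(cleaned, `[[`, "summary")
  tags <- lapply(cleaned, `[[`, "tags")
  libsizes <- vapply(summaries, function(s)
    s$count[s$category == "clean_reads"], numeric(1))

  merged <- merge_tag_tables(tags)
  cl <- classify_tags(merged, bundle)

  ann <- cl$annotation
  known <- ann[ann$category == "known_miRNA", , drop = FALSE]
  known_counts <- do.call(rbind, lapply(split(known, known$matched_mirna),
    function(d) data.frame(
      id = d$matched_mirna[1], family = d$family[1],
      s1 = sum(d$stage1), s2 = sum(d$stage2), s3 = sum(d$stage3),
      stringsAsFactors = FALSE)))
  rownames(known_counts) <- NULL

  novel <- predict_novel(ann, cl$loci, bundle, min_count = min_novel_count)
  counts <- known_counts
  if (!is.null(novel) && nrow(novel)) {
    nv <- data.frame(id = novel$name, family = sub("-[35]p$", "", novel$name),
                     s1 = novel$stage1, s2 = novel$stage2, s3 = novel$stage3,
                     stringsAsFactors = FALSE)
    counts <- rbind(counts, nv)
  }
  expression <- diffexp_table(counts, libsizes, fc_threshold, alpha)

  list(summaries = summaries, tags = tags, merged = merged,
       annotation = ann, annotation_summary = cl$summary, loci = cl$loci,
       novel = novel, known_counts = known_counts,
       expression = expression, libsizes = libsizes)
}
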