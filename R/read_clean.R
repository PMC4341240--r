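#' Default library-preparation adapter sequences
#'
#' Fixed default 3' and 5' adapters (the standard Illumina small-RNA
#' ligation adapters, the 3' one extended so that every 7-30 nt insert in a
#' 36-nt read is followed by at least 6 adapter bases).
#'
#' @return list with `adapter3` and `adapter5` character strings.
#' @export
default_adapters <- function() {
  list(adapter3 = "TGGAATTCTCGGGTGCCAAGGAACTCCAG",
       adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC")
}

## leftmost 3' adapter match: position p (1-based) such that the read from
## p matches the adapter prefix over the full available overlap
## (>= min_overlap nt, <= max_mm mismatches).  Returns 0 if absent.
find_adapter_start <- function(seq_int, ad_int, min_overlap = 6L, max_mm = 1L) {
  L <- length(seq_int)
  A <- length(ad_int)
  if (L < min_overlap) return(0L)
  for (p in 1:(L - min_overlap + 1L)) {
    ov <- min(A, L - p + 1L)
    if (ov < min_overlap) break
    if (sum(seq_int[p:(p + ov - 1L)] != ad_int[1:ov]) <= max_mm) return(p)
  }
  0L
}

#' Assess a single raw read
#'
#' Applies the fixed-order screening used for published-style library accounting.
#' First failing check wins:
#' quality (any 'N', more than 4 bases with Q < 10, or more than 6 bases
#' with Q < 13 => `low_quality`, i.e. not counted among high-quality reads)
#' -> 3' adapter absent (`adapter3_null`) -> empty insert (`insert_null`)
#' -> insert starts with a >= 8 nt exact 5' adapter prefix
#' (`adapter5_contaminant`) -> insert >= 80% 'A' (`polyA`) -> insert
#' shorter than 18 nt (`shorter_18`) -> longer than 30 nt (`longer_30`).
#' Surviving reads are `clean` and the trimmed insert is returned.
#'
#' The 3' adapter is located at the leftmost position where the remainder
#' of the read matches the adapter prefix over the full available overlap
#' (minimum 6 nt, at most 1 mismatch).
#'
#' @param sequence read sequence (character scalar).
#' @param quality Sanger (Phred+33) quality string, same length.
#' @param adapters list with `adapter3`, `adapter5` (see
#'   [default_adapters()]).
#' @return list with `category` (one of `low_quality`, `adapter3_null`,
#'   `insert_null`, `adapter5_contaminant`, `polyA`, `shorter_18`,
#'   `longer_30`, `clean`) and `insert` (trimmed insert for clean reads,
#'   otherwise `NA`).
#' @export
assess_read <- function(sequence, quality, adapters = default_adapters()) {
  if (nchar(sequence) == 0) stop("empty read")
  if (nchar(quality) != nchar(sequence))
    stop("quality string length differs from sequence length")
  s_int <- utf8ToInt(sequence)
  q <- utf8ToInt(quality) - 33L
  if (any(s_int == 78L) ||            # 'N'
      sum(q < 10) > 4 || sum(q < 13) > 6)
    return(list(category = "low_quality", insert = NA_character_))
  p <- find_adapter_start(s_int, utf8ToInt(adapters$adapter3))
  if (p == 0L) return(list(category = "adapter3_null", insert = NA_character_))
  insert <- substr(sequence, 1, p - 1L)
  n <- nchar(insert)
  if (n == 0L) return(list(category = "insert_null", insert = NA_character_))
  a5 <- adapters$adapter5
  if (n >= 8L && substr(insert, 1, 8) == substr(a5, 1, 8))
    return(list(category = "adapter5_contaminant", insert = NA_character_))
  if (sum(utf8ToInt(insert) == 65L) >= 0.8 * n)
    return(list(category = "polyA", insert = NA_character_))
  if (n < 18L) return(list(category = "shorter_18", insert = NA_character_))
  if (n > 30L) return(list(category = "longer_30", insert = NA_character_))
  list(category = "clean", insert = insert)
}

removal_categories <- c("adapter3_null", "insert_null",
                        "adapter5_contaminant", "shorter_18", "polyA",
                        "longer_30")

#' Recompute a cleaning summary from category counts
#'
#' The pure accounting step behind the per-library summary: clean reads are
#' the high-quality reads minus the five removal categories (plus the
#' longer-than-30 overflow category, reported alongside), and every
#' category percentage is taken against the high-quality total, at two
#' decimal places (round-half-even).
#'
#' @param raw_reads total raw reads.
#' @param high_quality reads passing the quality screen.
#' @param removed named numeric vector of removal-category counts (any
#'   subset of `adapter3_null`, `insert_null`, `adapter5_contaminant`,
#'   `shorter_18`, `polyA`, `longer_30`).
#' @return a `CleaningSummary` data.frame with columns `category`, `count`,
#'   `percent` in standard accounting-table row order (raw reads, high-quality, removal
#'   categories, clean reads).
#' @export
cleaning_summary <- function(raw_reads, high_quality, removed) {
  full <- setNames(numeric(length(removal_categories)), removal_categories)
  full[names(removed)] <- removed
  if (high_quality > raw_reads) stop("high_quality exceeds raw_reads")
  clean <- high_quality - sum(full)
  if (clean < 0) stop("removal counts exceed high-quality total")
  counts <- c(raw_reads = raw_reads, high_quality = high_quality, full,
              clean_reads = clean)
  pct <- if (high_quality > 0) round(100 * counts / high_quality, 2)
         else setNames(rep(0, length(counts)), names(counts))
  pct["raw_reads"] <- NA_real_
  data.frame(category = names(counts), count = as.numeric(counts),
             percent = as.numeric(pct), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Clean a small-RNA library and collapse to unique tags
#'
#' Screens every read with [assess_read()] and collapses the surviving
#' 18-30 nt inserts into unique tags with read counts.
#'
#' @param fastq path to a Sanger FASTQ file, or a list with `sequence` and
#'   `quality` character vectors (as produced by [simulate_libraries()]).
#' @param adapters adapter list (see [default_adapters()]).
#' @return list with `tags` (data.frame `sequence`, `length`, `count`,
#'   ordered by decreasing count) and `summary` (a [cleaning_summary()]
#'   data.frame).
#' @export
clean_library <- function(fastq, adapters = default_adapters()) {
  if (is.character(fastq)) {
    n_lines <- length(readLines(fastq, warn = FALSE))
    if (n_lines %% 4 != 0)
      stop("malformed FASTQ '", fastq, "': ", n_lines,
           " lines (truncated record near record ", n_lines %/% 4 + 1, ")")
    parsed <- withCallingHandlers(
      tryCatch({
        x <- Biostrings::readQualityScaledDNAStringSet(fastq)
        list(seqs = as.character(x),
             quals = as.character(Biostrings::quality(x)))
      }, error = function(e) stop("malformed FASTQ '", fastq, "': ",
                                  conditionMessage(e))),
      # benign container-conversion chatter from Biostrings
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    seqs <- parsed$seqs
    quals <- parsed$quals
  } else {
    seqs <- fastq$sequence
    quals <- fastq$quality
  }
  n <- length(seqs)
  cats <- character(n)
  inserts <- character(n)
  ad3 <- utf8ToInt(adapters$adapter3)
  a5_8 <- substr(adapters$adapter5, 1, 8)
  for (i in seq_len(n)) {
    s_int <- utf8ToInt(seqs[i])
    q <- utf8ToInt(quals[i]) - 33L
    if (length(q) != length(s_int))
      stop("malformed FASTQ record ", i, ": quality length mismatch")
    if (any(s_int == 78L) || sum(q < 10) > 4 || sum(q < 13) > 6) {
      cats[i] <- "low_quality"; next
    }
    p <- find_adapter_start(s_int, ad3)
    if (p == 0L) { cats[i] <- "adapter3_null"; next }
    m <- p - 1L
    if (m == 0L) { cats[i] <- "insert_null"; next }
    ins <- substr(seqs[i], 1L, m)
    if (m >= 8L && substr(ins, 1, 8) == a5_8) {
      cats[i] <- "adapter5_contaminant"; next
    }
    if (sum(s_int[1:m] == 65L) >= 0.8 * m) { cats[i] <- "polyA"; next }
    if (m < 18L) { cats[i] <- "shorter_18"; next }
    if (m > 30L) { cats[i] <- "longer_30"; next }
    cats[i] <- "clean"
    inserts[i] <- ins
  }
  hq <- sum(cats != "low_quality")
  removed <- vapply(removal_categories, function(k) sum(cats == k), numeric(1))
  summary <- cleaning_summary(n, hq, removed)
  tab <- table(inserts[cats == "clean"])
  tags <- data.frame(sequence = as.character(if (length(tab)) names(tab) else character(0)),
                     length = nchar(as.character(if (length(tab)) names(tab) else character(0))),
                     count = as.integer(tab),
                     stringsAsFactors = FALSE)
  tags <- tags[order(-tags$count, tags$sequence), , drop = FALSE]
  rownames(tags) <- NULL
  list(tags = tags, summary = summary)
}

#' Read-count length distribution of a tag table
#'
#' Total clean reads (tag counts, not unique tags) per insert length
#' 18..30 nt; sums to the library's clean-read total.
#'
#' @param tags tag table from [clean_library()].
#' @return data.frame `length` (18..30), `reads`.
#' @export
length_distribution <- function(tags) {
  lens <- 18:30
  reads <- vapply(lens, function(L) sum(tags$count[tags$length == L]),
                  numeric(1))
  data.frame(length = lens, reads = reads)
}

#' Merge per-stage tag tables into one tag-by-stage count table
#'
#' @param tag_list named list of tag tables (names become count columns).
#' @return data.frame with `sequence`, `length`, one count column per
#'   stage, and `total`.
#' @export
merge_tag_tables <- function(tag_list) {
  seqs <- sort(unique(unlist(lapply(tag_list, `[[`, "sequence"))))
  out <- data.frame(sequence = seqs, length = nchar(seqs),
                    stringsAsFactors = FALSE)
  for (nm in names(tag_list)) {
    v <- setNames(tag_list[[nm]]$count, tag_list[[nm]]$sequence)
    out[[nm]] <- as.integer(ifelse(is.na(v[seqs]), 0L, v[seqs]))
  }
  out$total <- rowSums(out[, names(tag_list), drop = FALSE])
  out
}
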