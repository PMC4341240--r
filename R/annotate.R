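## Exact-substring index: every substring of the indexed sequences with
## length in `lengths`, on both strands, hashed to its loci.  Loci are
## 0-based half-open on the forward strand of the indexed sequence.
build_substring_index <- function(seqs, lengths = 18:30) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  add <- function(key, locus) {
    cur <- env[[key]]
    env[[key]] <- if (is.null(cur)) list(locus) else c(cur, list(locus))
  }
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    n <- nchar(s)
    rc <- revcomp(s)
    for (L in lengths) {
      if (n < L) next
      starts <- 1:(n - L + 1)
      subs <- substring(s, starts, starts + L - 1)
      for (i in seq_along(starts))
        add(subs[i], list(contig = nm, start = starts[i] - 1L,
                          end = starts[i] - 1L + L, strand = "+"))
      subs_rc <- substring(rc, starts, starts + L - 1)
      # rc position i (1-based) corresponds to forward [n-L-i+2, n-i+1]
      for (i in seq_along(starts))
        add(subs_rc[i], list(contig = nm, start = n - L - starts[i] + 1L,
                             end = n - starts[i] + 1L, strand = "-"))
    }
  }
  env
}

#' Map tags to the reference by exact matching
#'
#' Reports every exact occurrence of each tag on either strand of the
#' bundle contigs.  Coordinates are 0-based half-open on the forward
#' strand; a '-' strand locus means the tag equals the reverse complement
#' of the forward-strand slice.
#'
#' @param tags character vector of tag sequences, or a tag table with a
#'   `sequence` column.
#' @param bundle a [make_reference()] bundle (or any list with a named
#'   `contigs` character vector).
#' @return data.frame `sequence`, `contig`, `start`, `end`, `strand`; tags
#'   with no occurrence are absent (use `setdiff` on `sequence` to list
#'   unmapped tags).
#' @export
map_tags <- function(tags, bundle) {
  if (is.data.frame(tags)) tags <- tags$sequence
  lens <- sort(unique(nchar(tags)))
  idx <- build_substring_index(as.list(bundle$contigs), lens)
  res <- lapply(tags, function(tg) {
    hits <- idx[[tg]]
    if (is.null(hits)) return(NULL)
    do.call(rbind, lapply(hits, function(h)
      data.frame(sequence = tg, contig = h$contig, start = h$start,
                 end = h$end, strand = h$strand, stringsAsFactors = FALSE)))
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sequence = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Match tags against a mature miRNA catalog
#'
#' A tag matches a catalog mature when, after anchoring the tag 5' end at
#' one of the offsets -2..+2, the bases compared over the mature's length
#' differ at no more than `max_mm` positions (no indels; tag positions
#' falling outside the tag count as mismatches).  For each tag all catalog
#' entries at the minimal mismatch count are returned; per entry the
#' anchoring with the fewest mismatches wins, ties broken by smaller
#' |offset| (negative first), consistent with the "maximum of two
#' mismatches" rule used for known-miRNA identification.
#'
#' @param tags character vector of tag sequences (or tag table).
#' @param mature_catalog data.frame `name`, `family`, `sequence`.
#' @param max_mm maximum mismatches (default 2).
#' @return data.frame `sequence`, `name`, `family`, `mismatches`, `offset`;
#'   only tags with a qualifying match appear.
#' @export
match_known <- function(tags, mature_catalog, max_mm = 2) {
  if (is.data.frame(tags)) tags <- tags$sequence
  if (length(tags) == 0)
    return(data.frame(sequence = character(0), name = character(0),
                      family = character(0), mismatches = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE))
  maxw <- max(nchar(tags), nchar(mature_catalog$sequence)) + 2
  # padded character matrix of tags: row = tag, col = position
  tag_mat <- matrix("", length(tags), maxw)
  for (i in seq_along(tags)) {
    ch <- strsplit(tags[i], "")[[1]]
    tag_mat[i, seq_along(ch)] <- ch
  }
  offsets <- c(0L, -1L, 1L, -2L, 2L)
  best_mm <- matrix(Inf, length(tags), nrow(mature_catalog))
  best_off <- matrix(NA_integer_, length(tags), nrow(mature_catalog))
  for (m in seq_len(nrow(mature_catalog))) {
    mch <- strsplit(mature_catalog$sequence[m], "")[[1]]
    Lm <- length(mch)
    for (o in offsets) {
      # mature position k (1..Lm) compared to tag position k + o
      cols <- (1:Lm) + o
      sub <- matrix("", length(tags), Lm)
      ok <- cols >= 1 & cols <= maxw
      sub[, ok] <- tag_mat[, cols[ok], drop = FALSE]
      mm <- rowSums(sub != matrix(mch, length(tags), Lm, byrow = TRUE))
      upd <- mm < best_mm[, m]
      best_mm[upd, m] <- mm[upd]
      best_off[upd, m] <- o
    }
  }
  res <- lapply(seq_along(tags), function(i) {
    mm <- best_mm[i, ]
    b <- min(mm)
    if (b > max_mm) return(NULL)
    sel <- which(mm == b)
    data.frame(sequence = tags[i], name = mature_catalog$name[sel],
               family = mature_catalog$family[sel],
               mismatches = as.integer(b), offset = best_off[i, sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(sequence = character(0), name = character(0),
                      family = character(0), mismatches = integer(0),
                      offset = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

annotation_categories <- c("rRNA", "tRNA", "snRNA", "snoRNA",
                           "known_miRNA", "unannotated")

#' Hierarchical tag classification
#'
#' Classifies each unique tag into exactly one of rRNA, tRNA, snRNA,
#' snoRNA, known_miRNA or unannotated.  Matching non-coding RNAs are
#' eliminated first: a tag that is an exact substring (either strand) of
#' an ncRNA catalog entry takes that entry's class, with rRNA > tRNA >
#' snRNA > snoRNA priority.  Remaining tags matching a catalog mature
#' miRNA within 2 mismatches ([match_known()]) are known miRNAs (ties
#' resolved to the lexicographically first mature name, with a warning);
#' the rest are unannotated.
#'
#' @param tags tag table (data.frame with `sequence` and count column(s)),
#'   e.g. from [clean_library()] or [merge_tag_tables()].
#' @param bundle reference bundle with `contigs`, `ncrna_catalog`,
#'   `mature_catalog`.
#' @return list with `annotation` (tag table plus `category`,
#'   `matched_mirna`, `family`, `mismatches`, `n_loci`) and `summary`
#'   (per category: unique tag count and total reads).
#' @export
classify_tags <- function(tags, bundle) {
  stopifnot(is.data.frame(tags), "sequence" %in% names(tags))
  count_cols <- setdiff(names(tags), c("sequence", "length", "total"))
  seqs <- tags$sequence
  category <- rep("unannotated", length(seqs))
  matched <- rep(NA_character_, length(seqs))
  family <- rep(NA_character_, length(seqs))
  mism <- rep(NA_integer_, length(seqs))

  # ncRNA elimination first (exact substring, either strand)
  kinds <- c("rRNA", "tRNA", "snRNA", "snoRNA")
  if (length(seqs)) {
    nc_idx <- build_substring_index(
      setNames(as.list(bundle$ncrna_catalog$sequence),
               bundle$ncrna_catalog$name),
      sort(unique(nchar(seqs))))
    nc_kind <- setNames(bundle$ncrna_catalog$kind, bundle$ncrna_catalog$name)
    for (i in seq_along(seqs)) {
      hits <- nc_idx[[seqs[i]]]
      if (is.null(hits)) next
      ks <- unique(nc_kind[vapply(hits, `[[`, character(1), "contig")])
      category[i] <- kinds[min(match(ks, kinds))]
    }
  }

  # known miRNA matching on the remainder
  rest <- which(category == "unannotated")
  if (length(rest)) {
    km <- match_known(seqs[rest], bundle$mature_catalog)
    if (nrow(km)) {
      multi <- unique(km$sequence[duplicated(km$sequence)])
      if (length(multi))
        warning(length(multi), " tag(s) tied between multiple matures; ",
                "assigned to the lexicographically first name")
      km <- km[order(km$sequence, km$name), ]
      km <- km[!duplicated(km$sequence), ]
      hit <- match(seqs[rest], km$sequence)
      has <- !is.na(hit)
      category[rest[has]] <- "known_miRNA"
      matched[rest[has]] <- km$name[hit[has]]
      family[rest[has]] <- km$family[hit[has]]
      mism[rest[has]] <- km$mismatches[hit[has]]
    }
  }

  mapped <- map_tags(seqs, bundle)
  tb <- table(mapped$sequence)
  n_loci <- as.integer(tb[seqs])
  n_loci[is.na(n_loci)] <- 0L

  annotation <- cbind(tags,
                      data.frame(category = category,
                                 matched_mirna = matched, family = family,
                                 mismatches = mism,
                                 n_loci = as.integer(n_loci),
                                 stringsAsFactors = FALSE))
  total <- if (length(count_cols))
    rowSums(annotation[, count_cols, drop = FALSE]) else rep(0, nrow(tags))
  summary <- data.frame(
    category = annotation_categories,
    unique_tags = vapply(annotation_categories, function(k)
      sum(category == k), numeric(1)),
    reads = vapply(annotation_categories, function(k)
      sum(total[category == k]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(annotation = annotation, summary = summary, loci = mapped)
}
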