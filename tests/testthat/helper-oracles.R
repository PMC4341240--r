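## Independent oracles used across the suite.  These deliberately do not
## reuse the package's search code paths: folding is checked against full
## enumeration of nested structures, the exact test against the
## negative-binomial identity via stats::pnbinom, and target scanning
## against per-window alignment enumeration.

pair_names_oracle <- c("AU", "UA", "GC", "CG", "GU", "UG")

pt_name_oracle <- function(a, b) {
  key <- chartr("T", "U", paste0(a, b))
  if (key %in% pair_names_oracle) key else NA_character_
}

## all nested structures (lists of index pairs), min hairpin loop 3
enumerate_structures <- function(chars, min_loop = 3) {
  n <- length(chars)
  memo <- new.env(parent = emptyenv())
  pairable <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (j - i - 1 >= min_loop && !is.na(pt_name_oracle(chars[i], chars[j])))
      pairable[i, j] <- TRUE
  rec <- function(i, j) {
    if (j <= i) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- rec(i, j - 1)
    for (k in i:(j - 1)) {
      if (!pairable[k, j]) next
      left <- rec(i, k - 1)
      right <- rec(k + 1, j - 1)
      for (a in left) for (b in right)
        res[[length(res) + 1]] <- c(a, b, list(c(k, j)))
    }
    memo[[key]] <- res
    res
  }
  rec(1, n)
}

## loop-decomposition energy of one explicit structure
structure_energy <- function(chars, pairs, par = fold_energy_params()) {
  if (!length(pairs)) return(0)
  ii <- vapply(pairs, `[`, numeric(1), 1)
  jj <- vapply(pairs, `[`, numeric(1), 2)
  energy <- 0
  for (p in seq_along(pairs)) {
    i <- ii[p]; j <- jj[p]
    inside <- which(ii > i & jj < j)
    child <- inside[vapply(inside, function(q)
      !any(ii[inside] < ii[q] & jj[inside] > jj[q]), logical(1))]
    b <- length(child)
    pt_out <- pt_name_oracle(chars[i], chars[j])
    if (b == 0) {
      energy <- energy + par$hairpin
    } else if (b == 1) {
      k <- ii[child]; l <- jj[child]
      l1 <- k - i - 1; l2 <- j - l - 1
      if (l1 == 0 && l2 == 0)
        energy <- energy + par$stack[pt_out, pt_name_oracle(chars[k], chars[l])]
      else if (l1 == 0 || l2 == 0)
        energy <- energy + par$bulge_open + par$bulge_per * (l1 + l2)
      else
        energy <- energy + par$internal_open + par$internal_per * (l1 + l2)
    } else {
      energy <- energy + par$multi_close + par$multi_branch * (b + 1)
    }
  }
  energy
}

## brute-force MFE over every nested structure (empty structure = 0)
oracle_mfe <- function(seq) {
  chars <- strsplit(chartr("T", "U", toupper(seq)), "")[[1]]
  structs <- enumerate_structures(chars)
  min(vapply(structs, function(s) structure_energy(chars, s), numeric(1)))
}

## exact-test oracle through the negative-binomial identity
## p(k|x) = C(x+k, k) q^k (1-q)^(x+1), q = N2/(N1+N2)
ac_oracle <- function(x, N1, y, N2) {
  pr <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = pr)
  upper <- if (y == 0) 1 else
    stats::pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

## target-site alignment oracle: enumerate the gapless alignment and every
## single-gap placement directly
target_cost_oracle <- function(mirna, site, seed_range = c(2, 13)) {
  m <- rev(strsplit(toupper(chartr("U", "T", mirna)), "")[[1]])
  s <- strsplit(toupper(chartr("U", "T", site)), "")[[1]]
  M <- length(m); S <- length(s)
  mpos <- rev(seq_len(M))
  w <- function(pos) if (pos >= seed_range[1] && pos <= seed_range[2]) 2 else 1
  cost1 <- function(a, b) {
    wc <- (a == "A" && b == "T") || (a == "C" && b == "G") ||
      (a == "G" && b == "C") || (a == "T" && b == "A")
    wob <- (a == "G" && b == "T") || (a == "T" && b == "G")
    if (wc) 0 else if (wob) 0.5 else 1
  }
  costs <- c()
  if (S == M)
    costs <- c(costs, sum(vapply(1:M, function(i)
      w(mpos[i]) * cost1(m[i], s[i]), numeric(1))))
  if (S == M - 1) {
    # one miRNA base unmatched (gap in site) at position g
    for (g in 1:M) {
      tot <- 2 * w(mpos[g])
      si <- 0
      for (i in 1:M) {
        if (i == g) next
        si <- si + 1
        tot <- tot + w(mpos[i]) * cost1(m[i], s[si])
      }
      costs <- c(costs, tot)
    }
  }
  if (S == M + 1) {
    # one site base bulged (gap in miRNA) after consuming g miRNA bases
    for (g in 0:M) {
      tot <- 2 * (if (g < M) w(mpos[g + 1]) else 1)
      mi <- 0
      for (j in 1:S) {
        if (j == g + 1) next
        mi <- mi + 1
        tot <- tot + w(mpos[mi]) * cost1(m[mi], s[j])
      }
      costs <- c(costs, tot)
    }
  }
  min(costs)
}

## shared tiny fixtures -------------------------------------------------

## hand-built bundle with fully known content for annotate/novelmir tests
toy_bundle <- function() {
  mature <- data.frame(
    name = c("mirA", "mirB"),
    family = c("miR1", "miR2"),
    sequence = c("ACGTACGTACGTACGTACGTA", "TTGCATGCAAGGCTTCAGTCA"),
    stringsAsFactors = FALSE)
  ncrna <- data.frame(
    name = c("rrnX", "trnX"),
    kind = c("rRNA", "tRNA"),
    sequence = c("GGGCCCAAATTTGGGCCCAAATTTGGGCCCAAGACCA",
                 "TCAGGATCCTGAACCTTGGACTGATCCGGATT"),
    stringsAsFactors = FALSE)
  contig <- paste0(
    strrep("GATTACA", 10),          # 70 nt spacer
    mature$sequence[1],             # mirA at [70, 91)
    strrep("CTTAGGC", 10),          # 70 nt spacer
    mature$sequence[2],             # mirB at [161, 182)
    strrep("TGCCATA", 10))
  list(contigs = c(chr1 = contig),
       ncrna_catalog = ncrna,
       mature_catalog = mature)
}

## mutate k positions of a sequence (deterministic given seed state)
mutate_seq <- function(seq, at) {
  for (i in at) {
    old <- substr(seq, i, i)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(seq, i, i) <- new
  }
  seq
}

## wrap inserts back into full-length reads (insert + adapter + fill)
wrap_reads <- function(inserts, read_length = 36,
                       adapters = default_adapters()) {
  seqs <- substr(paste0(inserts, adapters$adapter3, strrep("G", read_length)),
                 1, read_length)
  list(sequence = seqs, quality = strrep("I", nchar(seqs)))
}
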