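# Brute-force scanning oracle, independent of the package implementation:
# naive substring matching + exhaustive enumeration of 4-repeat chains.

oracle_starts <- function(seq, word) {
  w <- nchar(word)
  n <- nchar(seq)
  if (n < w) return(integer(0))
  out <- integer(0)
  for (i in 0:(n - w)) {
    if (substr(seq, i + 1, i + w) == word) out <- c(out, i)
  }
  out
}

oracle_chains <- function(starts, w, min_sp, max_sp, n_rep = 4L) {
  if (length(starts) < n_rep) return(list())
  cmb <- utils::combn(sort(starts), n_rep)
  keep <- list()
  for (c1 in seq_len(ncol(cmb))) {
    ch <- cmb[, c1]
    gaps <- diff(ch) - w
    if (all(gaps >= min_sp) && all(gaps <= max_sp)) {
      keep[[length(keep) + 1L]] <- ch
    }
  }
  keep
}

# leftmost start, shortest end, lexicographically smallest chain;
# non-overlapping (next match starts at or after the previous end)
oracle_minimal <- function(seq, word, min_sp, max_sp, n_rep = 4L) {
  w <- nchar(word)
  chains <- oracle_chains(oracle_starts(seq, word), w, min_sp, max_sp, n_rep)
  out <- list()
  pos <- 0L
  repeat {
    cand <- Filter(function(ch) ch[1] >= pos, chains)
    if (!length(cand)) break
    best <- NULL
    for (ch in cand) {
      if (is.null(best)) { best <- ch; next }
      if (ch[1] < best[1]) { best <- ch; next }
      if (ch[1] > best[1]) next
      e1 <- ch[n_rep] + w; e2 <- best[n_rep] + w
      if (e1 < e2) { best <- ch; next }
      if (e1 > e2) next
      for (k in seq_len(n_rep)) {
        if (ch[k] < best[k]) { best <- ch; break }
        if (ch[k] > best[k]) break
      }
    }
    out[[length(out) + 1L]] <- best
    pos <- best[n_rep] + w
  }
  out
}

random_dna <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

# common fixture sequences
VK34 <- "GCGAGGGAGCGAGGG"
VK34x4 <- paste(rep(VK34, 4), collapse = "A")

chains_from_matches <- function(matches) {
  lapply(strsplit(matches$repeat_starts, ","), as.integer)
}
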