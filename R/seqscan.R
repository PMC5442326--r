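#' @title Consensus motif scanning for AGCGA-quadruplex and G-quadruplex motifs
#' @description
#' AGCGA-quadruplexes are tetrahelical DNA folds built from four 5'-AGCGA-3'
#' tracts; the sequence consensus is four literal AGCGA repeats separated by
#' three spacers of 1-20 nucleotides. The canonical G-quadruplex consensus is
#' four GGG tracts with spacers of 1-7 nucleotides. These scanners report
#' every consensus match in 0-based half-open coordinates.
#' @name seqscan
NULL

.DNA_ALPHABET <- c("A", "C", "G", "T", "N", "I")

#' Validate a DNA sequence over the extended alphabet \{A,C,G,T,N,I\}
#'
#' @param seq character scalar (case-insensitive)
#' @param id label used in error messages
#' @return the validated upper-case sequence (invisibly usable)
#' @export
validate_dna <- function(seq, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!(chars %in% .DNA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("sequence '%s': invalid symbol '%s' at position %d (1-based)",
                 id, chars[bad[1]], bad[1]))
  }
  s
}

#' Reverse complement over \{A,C,G,T,N,I\}
#'
#' Inosine has no canonical complement and maps to N.
#' @param seq character scalar
#' @return reverse-complemented sequence
#' @export
revcomp_dna <- function(seq) {
  s <- validate_dna(seq)
  comp <- chartr("ACGTNI", "TGCANN", s)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

# 0-based starts of (possibly overlapping) exact occurrences of `word`
.word_starts <- function(seq, word) {
  if (nchar(seq) < nchar(word)) return(integer(0))
  m <- gregexpr(paste0("(?=", word, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  as.integer(m) - 1L
}

# chains of exactly n_rep occurrences with spacers in [min_sp, max_sp].
# mode "minimal": leftmost start, then shortest end (lexicographically
# smallest repeat_starts), non-overlapping (resume after previous end).
# mode "all": every valid decomposition.
.find_chains <- function(starts, w, min_sp, max_sp, n_rep = 4L,
                         mode = c("minimal", "all")) {
  mode <- match.arg(mode)
  starts <- sort(unique(as.integer(starts)))
  nexts <- function(p) starts[starts >= p + w + min_sp & starts <= p + w + max_sp]
  chains <- list()
  if (mode == "all") {
    dfs <- function(chain) {
      if (length(chain) == n_rep) {
        chains[[length(chains) + 1L]] <<- chain
        return(invisible())
      }
      for (q in nexts(chain[length(chain)])) dfs(c(chain, q))
    }
    for (p in starts) dfs(p)
    return(chains)
  }
  # minimal: greedy with backtracking (smallest completable next start)
  first_chain <- function(p, k) {
    if (k == n_rep) return(list(p))
    for (q in nexts(p[length(p)])) {
      res <- first_chain(c(p, q), k + 1L)
      if (!is.null(res)) return(res)
    }
    NULL
  }
  pos <- 0L
  repeat {
    cand <- starts[starts >= pos]
    found <- NULL
    for (p in cand) {
      res <- first_chain(p, 1L)
      if (!is.null(res)) { found <- res[[1]]; break }
    }
    if (is.null(found)) break
    chains[[length(chains) + 1L]] <- found
    pos <- found[n_rep] + w
  }
  chains
}

.chains_to_matches <- function(chains, w, seq_id, motif_class, strand, L) {
  if (!length(chains)) {
    return(data.frame(seq_id = character(0), motif_class = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), n_repeats = integer(0),
                      repeat_starts = character(0),
                      spacer_lengths = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(chains, function(ch) {
    if (strand == "-") {
      # map reverse-complement coordinates back to the plus strand
      ch <- sort(L - ch - w)
    }
    sp <- diff(ch) - w
    data.frame(seq_id = seq_id, motif_class = motif_class,
               start = ch[1], end = ch[length(ch)] + w, strand = strand,
               n_repeats = length(ch),
               repeat_starts = paste(ch, collapse = ","),
               spacer_lengths = paste(sp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.scan_word <- function(seqs, word, min_spacer, max_spacer, both_strands,
                       report, motif_class) {
  stopifnot(min_spacer >= 0, max_spacer >= min_spacer)
  if (is.null(names(seqs))) {
    names(seqs) <- if (length(seqs) == 1) "seq" else paste0("seq", seq_along(seqs))
  }
  w <- nchar(word)
  out <- list()
  for (id in names(seqs)) {
    s <- validate_dna(seqs[[id]], id)
    L <- nchar(s)
    ch <- .find_chains(.word_starts(s, word), w, min_spacer, max_spacer,
                       mode = report)
    out[[length(out) + 1L]] <- .chains_to_matches(ch, w, id, motif_class, "+", L)
    if (both_strands) {
      chm <- .find_chains(.word_starts(revcomp_dna(s), word), w,
                          min_spacer, max_spacer, mode = report)
      out[[length(out) + 1L]] <- .chains_to_matches(chm, w, id, motif_class, "-", L)
    }
  }
  res <- do.call(rbind, out) %||% .chains_to_matches(list(), w, "", "", "+", 0)
  res <- res[order(res$seq_id, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan for the AGCGA-quadruplex consensus
#'
#' Finds runs of four literal 5'-AGCGA-3' repeats separated by three spacers
#' whose lengths fall in `[min_spacer, max_spacer]` (consensus default 1-20).
#' In `"minimal"` mode the scanner reports leftmost-shortest non-overlapping
#' matches; `"all"` enumerates every valid decomposition. Minus-strand
#' matches are located on the reverse complement and reported in plus-strand
#' 0-based half-open coordinates.
#'
#' @param seqs character vector of DNA sequences (names used as seq ids)
#' @param min_spacer,max_spacer allowed spacer length range (nt)
#' @param both_strands scan the reverse complement as well
#' @param report `"minimal"` or `"all"`
#' @return data.frame with columns seq_id, motif_class, start, end, strand,
#'   n_repeats, repeat_starts, spacer_lengths (comma-joined, 0-based)
#' @examples
#' scan_agcga(c(x = "AGCGATAGCGATAGCGATAGCGA"))
#' @export
scan_agcga <- function(seqs, min_spacer = 1, max_spacer = 20,
                       both_strands = TRUE, report = c("minimal", "all")) {
  .scan_word(seqs, "AGCGA", min_spacer, max_spacer, both_strands,
             match.arg(report), "AGCGA_QUAD")
}

#' Scan for the G-quadruplex consensus GGG(N1-7)GGG(N1-7)GGG(N1-7)GGG
#'
#' @inheritParams scan_agcga
#' @return data.frame as for [scan_agcga()] with motif_class `"G4"`
#' @export
scan_g4 <- function(seqs, min_spacer = 1, max_spacer = 7,
                    both_strands = TRUE, report = c("minimal", "all")) {
  .scan_word(seqs, "GGG", min_spacer, max_spacer, both_strands,
             match.arg(report), "G4")
}

#' Count occurrences of a word in a sequence
#'
#' Supports the "at least four AGCGA repeats" criterion and merged-repeat
#' (adenine-deletion) variants, where overlapping occurrences matter.
#'
#' @param seq character scalar
#' @param word word to count (default AGCGA)
#' @param allow_overlap count overlapping occurrences
#' @return list with `n` and 0-based `starts`
#' @export
count_repeats <- function(seq, word = "AGCGA", allow_overlap = TRUE) {
  stopifnot(nzchar(word))
  s <- validate_dna(seq)
  if (allow_overlap) {
    st <- .word_starts(s, word)
  } else {
    m <- gregexpr(word, s, fixed = TRUE)[[1]]
    st <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  list(n = length(st), starts = st)
}

#' Summarize the consensus content of one sequence
#'
#' A sequence is flagged `dual_consensus` when it matches both the
#' AGCGA-quadruplex and the G-quadruplex consensus, the situation where
#' alternating AGCGA and GGG repeats could in principle fold either way.
#'
#' @param seq character scalar
#' @param id sequence label
#' @param ... passed to the two scanners
#' @return list(n_agcga_repeats, agcga_matches, g4_matches, dual_consensus)
#' @export
classify_sequence <- function(seq, id = "seq", ...) {
  s <- stats::setNames(validate_dna(seq, id), id)
  ag <- scan_agcga(s, ...)
  g4 <- scan_g4(s)
  list(n_agcga_repeats = count_repeats(seq)$n,
       agcga_matches = ag,
       g4_matches = g4,
       dual_consensus = nrow(ag) >= 1 && nrow(g4) >= 1)
}

.extinction_table <- function() {
  tab <- .pkg_env$extinction_table
  if (is.null(tab)) {
    tab <- utils::read.delim(.extdata("extinction_nn_260.tsv"),
                             comment.char = "#", stringsAsFactors = FALSE)
    .pkg_env$extinction_table <- tab
  }
  tab
}

#' Nearest-neighbour molar extinction coefficient at 260 nm
#'
#' epsilon = sum over dinucleotides of eps(di) minus sum over interior
#' mononucleotides of eps(mono), using the shipped coefficient table
#' (Cantor-Warshaw-Shapiro values; see `extdata/extinction_nn_260.tsv`).
#' For the 15-mer GCGAGGGAGCGAGGG this evaluates to 155200 M^-1 cm^-1.
#'
#' @param seq unmodified DNA sequence over \{A,C,G,T\}
#' @return molar extinction coefficient in M^-1 cm^-1
#' @export
extinction_260 <- function(seq) {
  s <- validate_dna(seq)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (any(chars %in% c("N", "I"))) {
    stop("extinction_260: unsupported residue(s) ",
         paste(unique(chars[chars %in% c("N", "I")]), collapse = ","),
         " (no nearest-neighbour coefficients for N or I)")
  }
  tab <- .extinction_table()
  mono <- stats::setNames(tab$eps[tab$kind == "mono"], tab$seq[tab$kind == "mono"])
  di <- stats::setNames(tab$eps[tab$kind == "di"], tab$seq[tab$kind == "di"])
  n <- length(chars)
  if (n == 1) return(unname(mono[chars]))
  dis <- paste0(chars[-n], chars[-1])
  unname(sum(di[dis]) - sum(mono[chars[-c(1, n)]]))
}

#' Read a DNA FASTA file
#'
#' Multi-record, wrapped or unwrapped, case-insensitive; validated against
#' the \{A,C,G,T,N,I\} alphabet.
#'
#' @param path FASTA file
#' @return named character vector of upper-case sequences
#' @export
read_fasta_dna <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  for (id in names(seqs)) validate_dna(seqs[[id]], id)
  seqs
}

#' Write sequences to FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta_dna <- function(seqs, path) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write motif matches as BED6
#'
#' chrom, start (0-based), end, name = motif class, score = repeat count,
#' strand.
#' @param matches data.frame from the scanners
#' @param path output BED file
#' @export
write_motif_bed <- function(matches, path) {
  if (nrow(matches) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = matches$seq_id,
    ranges = IRanges::IRanges(start = matches$start + 1L, end = matches$end),
    strand = matches$strand,
    name = matches$motif_class,
    score = matches$n_repeats)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write motif matches as TSV
#' @param matches data.frame from the scanners
#' @param path output TSV file
#' @export
write_motif_tsv <- function(matches, path) {
  utils::write.table(matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
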