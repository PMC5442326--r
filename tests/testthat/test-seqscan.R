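test_that("AGCGA scanner reproduces brute-force results on reference sequences", {
  # VK34 has a single AGCGA occurrence and therefore no 4-repeat match
  expect_identical(count_repeats(VK34)$starts, 7L)
  expect_equal(nrow(scan_agcga(c(VK34 = VK34))), 0)

  # four VK34 units joined by single adenines: oracle decides the match
  oc <- oracle_minimal(VK34x4, "AGCGA", 1, 20)
  expect_length(oc, 1)
  m <- scan_agcga(c(x4 = VK34x4))
  expect_equal(nrow(m), 1)
  expect_identical(chains_from_matches(m)[[1]], as.integer(oc[[1]]))
  expect_identical(m$spacer_lengths, paste(diff(oc[[1]]) - 5, collapse = ","))

  # minimal literal construction with unit spacers
  s <- "AGCGATAGCGATAGCGATAGCGA"
  m2 <- scan_agcga(c(t = s))
  expect_equal(m2$start, 0)
  expect_equal(m2$end, 23)
  expect_identical(m2$spacer_lengths, "1,1,1")
})

test_that("G4 scanner finds GGG tracts with spacers 1-7", {
  m <- scan_g4(c(x4 = VK34x4))
  expect_identical(chains_from_matches(m)[[1]], c(4L, 12L, 20L, 28L))
  expect_identical(m$spacer_lengths[1], "5,5,5")
  expect_equal(nrow(scan_g4(c(VK34 = VK34))), 0)  # only two GGG tracts
  m3 <- scan_g4(c(g = "GGGTGGGTGGGTGGG"))
  expect_equal(nrow(m3), 1)
  expect_identical(m3$spacer_lengths, "1,1,1")
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(30:500, 1)
    gc_rich <- i %% 3 == 0
    s <- random_dna(n, prob = if (gc_rich) c(0.15, 0.2, 0.45, 0.2)
                    else c(0.25, 0.25, 0.25, 0.25))
    word <- if (i %% 2 == 0) "AGCGA" else "GGG"
    msp <- sample(0:2, 1); xsp <- sample(3:20, 1)
    got <- if (word == "AGCGA") {
      scan_agcga(c(x = s), msp, xsp, both_strands = FALSE)
    } else {
      scan_g4(c(x = s), msp, xsp, both_strands = FALSE)
    }
    want <- oracle_minimal(s, word, msp, xsp)
    expect_equal(nrow(got), length(want), info = paste("seq", i))
    if (length(want)) {
      expect_identical(chains_from_matches(got),
                       lapply(want, as.integer), info = paste("seq", i))
    }
  }
})

test_that("matches are strand-symmetric under reverse complement", {
  set.seed(7)
  for (i in 1:40) {
    s <- random_dna(300, prob = c(0.3, 0.15, 0.3, 0.25))
    # embed a motif to make matches likely
    s <- paste0(substr(s, 1, 100), "AGCGATTAGCGATTAGCGATTAGCGA",
                substr(s, 101, 300))
    fwd <- scan_agcga(c(x = s), report = "all")
    rc <- scan_agcga(c(x = revcomp_dna(s)), report = "all")
    L <- nchar(s)
    # a plus-strand match on s maps to a minus-strand match on revcomp(s)
    fwd_plus <- fwd[fwd$strand == "+", ]
    rc_minus <- rc[rc$strand == "-", ]
    expect_equal(nrow(fwd_plus), nrow(rc_minus))
    expect_setequal(paste(L - fwd_plus$end, L - fwd_plus$start),
                    paste(rc_minus$start, rc_minus$end))
  }
})

test_that("widening the spacer window never removes an all-mode match", {
  set.seed(11)
  for (i in 1:30) {
    s <- random_dna(400, prob = c(0.2, 0.2, 0.4, 0.2))
    narrow <- scan_g4(c(x = s), 2, 5, both_strands = FALSE, report = "all")
    wide <- scan_g4(c(x = s), 1, 7, both_strands = FALSE, report = "all")
    key <- function(m) paste(m$start, m$end, m$repeat_starts)
    expect_true(all(key(narrow) %in% key(wide)))
  }
})

test_that("count_repeats handles overlap and degenerate inputs", {
  expect_equal(count_repeats("AGCGAGCGA")$n, 2)
  expect_identical(count_repeats("AGCGAGCGA")$starts, c(0L, 4L))
  expect_equal(count_repeats("AGCGAGCGA", allow_overlap = FALSE)$n, 1)
  expect_equal(count_repeats("")$n, 0)
  expect_equal(nrow(scan_agcga(c(x = ""))), 0)
})

test_that("sequence classification flags dual consensus content", {
  cs <- classify_sequence(VK34x4, "x4")
  expect_true(cs$dual_consensus)
  expect_equal(cs$n_agcga_repeats, 7)  # junction adenines create extras
  cs2 <- classify_sequence("AGCGATAGCGATAGCGATAGCGA")
  expect_false(cs2$dual_consensus)
  cs3 <- classify_sequence(strrep("T", 60))
  expect_equal(cs3$n_agcga_repeats, 0)
  expect_equal(nrow(cs3$agcga_matches), 0)
  expect_equal(nrow(cs3$g4_matches), 0)
})

test_that("alphabet violations are rejected with the offending position", {
  expect_error(scan_agcga(c(x = "ACGTX")), "position 5")
  expect_silent(validate_dna("acgtni"))
})

test_that("nearest-neighbour extinction coefficients match hand evaluation", {
  # 15-mer GCGAGGGAGCGAGGG: 2 GC + 2 CG + 3 GA + 3 AG + 4 GG dinucleotides
  # minus interior 2 C + 8 G + 3 A mononucleotides = 308200 - 153000
  expect_equal(extinction_260("GCGAGGGAGCGAGGG"), 155200)
  expect_equal(extinction_260("A"), 15400)
  expect_equal(extinction_260("AT"), 22800)  # single dinucleotide, no interior
  expect_equal(extinction_260("GAT"), 25200 + 22800 - 15400)
  expect_error(extinction_260("GCIN"), "unsupported")
})

test_that("FASTA and BED round trips preserve matches", {
  tf <- tempfile(fileext = ".fa")
  write_fasta_dna(c(a = VK34x4, b = "AGCGATAGCGATAGCGATAGCGA"), tf)
  seqs <- read_fasta_dna(tf)
  expect_identical(unname(seqs["a"]), VK34x4)
  m <- scan_agcga(seqs)
  tb <- tempfile(fileext = ".bed")
  write_motif_bed(m, tb)
  bed <- read.table(tb, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(bed$V2, m$start)   # BED is 0-based half-open
  expect_equal(bed$V3, m$end)
  expect_identical(bed$V6, m$strand)
  tt <- tempfile(fileext = ".tsv")
  write_motif_tsv(m, tt)
  back <- read.delim(tt, stringsAsFactors = FALSE)
  expect_equal(back$start, m$start)
  expect_identical(back$repeat_starts, m$repeat_starts)
})
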