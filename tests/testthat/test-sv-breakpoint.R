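mkrec <- function(pos, end, strand, mapped = TRUE) {
  data.table::data.table(qname = "p", mapped = mapped, strand = strand,
                         pos = pos, end = end)
}

test_that("read pairs classify by orientation and template length", {
  # FR, template 450 within 400 +/- 4*60
  expect_identical(classify_read_pair(mkrec(100L, 250L, "+"),
                                      mkrec(400L, 550L, "-")), "proper")
  # outward-facing: leftmost reverse, rightmost forward
  expect_identical(classify_read_pair(mkrec(1000L, 1150L, "-"),
                                      mkrec(24800L, 24950L, "+")),
                   "everted_dup")
  expect_identical(classify_read_pair(mkrec(100L, 250L, "+"),
                                      mkrec(600L, 750L, "+")),
                   "same_strand_inv")
  expect_identical(classify_read_pair(mkrec(100L, 250L, "+"),
                                      mkrec(2000L, 2150L, "-")),
                   "long_insert_del")
  expect_identical(classify_read_pair(mkrec(100L, 250L, "+"),
                                      mkrec(NA_integer_, NA_integer_, "+",
                                            mapped = FALSE)),
                   "unpaired")
})

test_that("scan_microhomology equals the brute-force oracle", {
  mh <- scan_microhomology("AAACTGTTTTCTGGGG", e = 13, s = 6)
  expect_equal(mh$left, 3L)
  expect_equal(mh$right, 0L)
  expect_equal(mh$total, 3L)
  expect_error(scan_microhomology("ACGTACGT", e = 4, s = 4), "degenerate")

  brute <- function(ref, e, s, cap = 50) {
    l <- 0
    while (l < cap && e - l - 1 >= 0 && s - l - 1 >= 0 &&
           substr(ref, e - l, e - l) == substr(ref, s - l, s - l)) l <- l + 1
    r <- 0
    while (r < cap && e + r + 1 <= nchar(ref) && s + r + 1 <= nchar(ref) &&
           substr(ref, e + r + 1, e + r + 1) ==
           substr(ref, s + r + 1, s + r + 1)) r <- r + 1
    c(l, r)
  }
  set.seed(23)
  for (i in 1:40) {
    ref <- random_dna(120)
    ij <- sort(sample(5:115, 2))
    if (ij[1] == ij[2]) next
    got <- scan_microhomology(ref, e = ij[2], s = ij[1], max_m = 50)
    expect_equal(c(got$left, got$right), brute(ref, ij[2], ij[1]))
  }
})

test_that("assembler reconstructs a tiled junction string exactly", {
  fl <- fixture_locus()
  ref <- fl$locus$sequence
  s <- 10360L; e <- 34360L
  jstring <- paste0(substr0(ref, e - 40L, e), substr0(ref, s, s + 40L))
  # 12 error-free 40-mers with >= 30 bp overlaps covering every k-mer twice
  # (so count-1 pruning keeps the contig ends)
  starts <- c(rep(seq(1, 41, by = 10), 2), 16, 26)
  reads <- substring(jstring, starts, starts + 39)
  jx <- assemble_junction(reads, ref, k = 15)
  expect_identical(jx$status, "ok")
  expect_identical(jx$contig, jstring)
  expect_identical(jx$orientation, "tandem_duplication")
  expect_equal(jx$mh_total, 3L)
  expect_equal(jx$left_break - jx$right_break, 24000L)

  expect_identical(assemble_junction(character(), ref)$status, "no_junction")
  # reference-only reads assemble no junction
  rr <- substring(ref, seq(5001, 5101, by = 10), seq(5040, 5140, by = 10))
  expect_identical(assemble_junction(rr, ref, k = 15)$status, "no_junction")
})

test_that("end-to-end assembly recovers the planted duplication breakpoints", {
  fx <- fixture_idfl()
  truth <- fx$alleles$truth
  cls <- classify_read_pairs(fx$aln)
  expect_gt(sum(cls$label == "everted_dup"), 0)
  cand <- recruit_junction_reads(fx$aln)
  jx <- assemble_junction(cand, fx$locus$sequence)
  expect_identical(jx$status, "ok")
  dup <- Filter(function(j) j$orientation == "tandem_duplication",
                all_junctions(jx))
  expect_length(dup, 1)
  j <- dup[[1]]
  # placement within the planted 3-nt microhomology ambiguity
  expect_lte(abs(j$left_break - truth$duplication[2]), 3)
  expect_lte(abs(j$right_break - truth$duplication[1]), 3)
  expect_equal(j$mh_total, 3L)
  expect_gte(j$support, 3)
  # microhomology consistency: any cut within the ambiguity range yields the
  # identical allele sequence
  ref <- fx$locus$sequence
  seqs <- vapply(0:j$mh_total, function(c) {
    paste0(substr0(ref, 0, j$left_break + c),
           substr0(ref, j$right_break + c, nchar(ref)))
  }, character(1))
  expect_length(unique(seqs), 1)
})

test_that("extended-homology scan finds planted segments and matches brute force", {
  base <- random_dna(800, seed = 61)
  seg <- substr(base, 151, 165)                 # 15-mer inside cut window
  ref <- paste0(substr(base, 1, 560), seg, substr(base, 576, 800))
  hits <- scan_extended_homology(ref, cut_site = 200, e = 600, s = 350,
                                 window = 100, min_len = 10)
  planted <- hits[hits$anchor == "e" & hits$strand == "+" &
                    hits$length >= 15, ]
  expect_gte(nrow(planted), 1)
  # chance neighbours can extend the planted 15-mer by a base or two
  expect_true(any(abs(planted$cut_window_pos - 150) <= 2 &
                    abs(planted$junction_window_pos - 560) <= 2))

  # i.i.d. windows: no >= 10 bp match on ten seeds (confirmed by oracle)
  brute <- function(A, B, min_len) {
    hits <- 0
    for (i in seq_len(nchar(A) - min_len + 1)) {
      for (j in seq_len(nchar(B) - min_len + 1)) {
        if (substr(A, i, i + min_len - 1) == substr(B, j, j + min_len - 1))
          hits <- hits + 1
      }
    }
    hits
  }
  for (sd in 1:10) {
    ref2 <- random_dna(900, seed = 100 + sd)
    got <- scan_extended_homology(ref2, cut_site = 150, e = 700, s = 450,
                                  window = 100, min_len = 10)
    expect_equal(nrow(got), 0)
    A <- substr(ref2, 51, 250)
    for (anchor in c(700, 450)) {
      B <- substr(ref2, anchor - 99, anchor + 100)
      expect_equal(brute(A, B, 10), 0)
      expect_equal(brute(A, revcomp(B), 10), 0)
    }
  }

  # seed-and-extend equals exhaustive enumeration at a permissive min_len
  ref3 <- random_dna(400, seed = 17)
  got <- scan_extended_homology(ref3, cut_site = 100, e = 300, s = 300,
                                window = 50, min_len = 5)
  A <- substr(ref3, 51, 150); B <- substr(ref3, 251, 350)
  cnt_fwd <- 0
  for (i in 1:(nchar(A) - 4)) for (j in 1:(nchar(B) - 4)) {
    if (substr(A, i, i + 4) == substr(B, j, j + 4)) {
      lmax <- (i == 1 || j == 1 ||
                 substr(A, i - 1, i - 1) != substr(B, j - 1, j - 1))
      if (lmax) {
        len <- 5
        while (i + len <= nchar(A) && j + len <= nchar(B) &&
               substr(A, i + len, i + len) == substr(B, j + len, j + len))
          len <- len + 1
        cnt_fwd <- cnt_fwd + 1
      }
    }
  }
  got_fwd <- got[got$strand == "+" & got$anchor == "e", ]
  expect_equal(nrow(got_fwd), cnt_fwd)
})
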