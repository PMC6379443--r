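E2E2_KMER <- "ACCAGCAACTAACTGTGTCT"
E2E3_KMER <- "ACCAGCAACTCCCATGACAA"

test_that("junction k-mer counting follows grep semantics", {
  pad <- function(km) paste0(random_dna(15, seed = nchar(km)), km,
                             random_dna(15, seed = 2))
  reads <- c(pad(E2E2_KMER), pad(E2E3_KMER),
             paste0("AC", pad(E2E3_KMER)), random_dna(50, seed = 3))
  res <- count_junction_kmers(reads, c(E2E2 = E2E2_KMER, E2E3 = E2E3_KMER),
                              ratio_of = c("E2E3", "E2E2"))
  expect_equal(res$counts$count, c(1L, 2L))
  expect_equal(res$counts$normalized, c(0.25, 0.5))
  expect_equal(res$ratio, 2)
  # order invariance
  res2 <- count_junction_kmers(rev(reads), c(E2E2 = E2E2_KMER,
                                             E2E3 = E2E3_KMER))
  expect_equal(res2$counts$count, res$counts$count)
  # reverse complement counted only when flagged
  rcread <- paste0(random_dna(10, seed = 4), revcomp(E2E3_KMER),
                   random_dna(10, seed = 5))
  expect_equal(count_junction_kmers(rcread, c(E2E3 = E2E3_KMER))$counts$count, 0L)
  expect_equal(count_junction_kmers(rcread, c(E2E3 = E2E3_KMER),
                                    count_reverse_complement = TRUE)$counts$count,
               1L)
  expect_error(count_junction_kmers(reads, c(bad = "ACGTX")), "A,C,G,T")
  # a read with the same k-mer twice still counts once
  twice <- paste0(E2E3_KMER, "GG", E2E3_KMER)
  expect_equal(count_junction_kmers(twice, c(E2E3 = E2E3_KMER))$counts$count, 1L)
})

test_that("counting equals a brute-force substring scan", {
  fl <- fixture_locus()
  ctx <- default_junction_contexts(fl$locus)
  sim <- simulate_rnaseq_reads(ctx, c(E2E3 = 0.7, E2E2 = 0.3), 400, seed = 12)
  res <- count_junction_kmers(sim$reads, sim$kmers)
  brute <- vapply(sim$kmers, function(km)
    sum(vapply(sim$reads, function(r) {
      hit <- FALSE
      if (nchar(r) >= nchar(km)) {
        for (i in 1:(nchar(r) - nchar(km) + 1)) {
          if (substr(r, i, i + nchar(km) - 1) == km) { hit <- TRUE; break }
        }
      }
      hit
    }, logical(1))), integer(1))
  expect_equal(res$counts$count, unname(brute))
  # disjoint labels: normalized frequencies sum to <= 1
  expect_lte(sum(res$counts$normalized), 1)
})

toy_gm <- function(e1, e2, e3) {
  gm <- list(exon_seqs = c(E1 = e1, E2 = e2, E3 = e3), cds_start_tx = 0L)
  mrna <- paste0(e1, e2, e3)
  stops <- c("TAA", "TAG", "TGA")
  for (p in seq(0, nchar(mrna) - 3, by = 3)) {
    if (substr(mrna, p + 1, p + 3) %in% stops) { gm$terminal_stop_tx <- p; break }
  }
  gm
}

test_that("isoform enumeration classifies duplicated-exon chains", {
  gm <- toy_gm("ATGAAA", "AAAT", "GACCC")
  calls <- enumerate_isoforms_and_classify(gm, dup_exon = "E2")
  single <- calls[calls$chain == "E1-E2-E3"]
  dup <- calls[calls$chain == "E1-E2-E2-E3"]
  # hand translation: ATG AAA AAA TGA -> stop codon 4 at the annotated stop
  expect_identical(single$classification, "productive")
  expect_equal(single$stop_codon_index, 4L)
  # ATG AAA AAA TAA ... with the transcript continuing -> premature
  expect_identical(dup$classification, "premature_stop")
  expect_equal(dup$stop_codon_index, 4L)

  # frame-preserving duplication of a stop-free exon stays productive
  gm3 <- toy_gm("ATGAAA", "CCCGGG", "TGACCC")
  calls3 <- enumerate_isoforms_and_classify(gm3, dup_exon = "E2")
  expect_identical(unique(calls3$classification), "productive")

  gm_bad <- toy_gm("CTGAAA", "AAAT", "GACCCTAA")
  expect_error(enumerate_isoforms_and_classify(gm_bad), "start codon")
})

test_that("classification agrees with a codon-interpreter oracle", {
  code <- Biostrings::GENETIC_CODE
  set.seed(91)
  for (i in 1:8) {
    # random exons; force an eventual stop by appending TAA to exon 3
    e1 <- paste0("ATG", random_dna(3 * sample(3:6, 1)))
    e2 <- random_dna(sample(4:12, 1))
    e3 <- paste0(random_dna(3 * sample(3:6, 1)), "TAATT")
    gm <- toy_gm(e1, e2, e3)
    if (is.null(gm$terminal_stop_tx)) next
    calls <- enumerate_isoforms_and_classify(gm, dup_exon = "E2")
    for (r in seq_len(nrow(calls))) {
      chain <- strsplit(calls$chain[r], "-")[[1]]
      mrna <- paste(gm$exon_seqs[chain], collapse = "")
      # oracle: translate codon by codon from the start
      found <- NA_integer_
      ncod <- 0L
      p <- 0L
      while (p + 3 <= nchar(mrna)) {
        aa <- code[[substr(mrna, p + 1, p + 3)]]
        ncod <- ncod + 1L
        if (aa == "*") { found <- ncod; break }
        p <- p + 3L
      }
      expect_equal(calls$stop_codon_index[r], found)
    }
  }
})

test_that("in-silico PCR sizes the deletion and detects the junction band", {
  fl <- fixture_locus()
  pr <- locus_primer_pair(fl$locus, "EDEL")
  wt <- insilico_pcr(fl$alleles$wt, pr)
  edel <- insilico_pcr(fl$alleles$edel, pr)
  expect_identical(wt$status, "product")
  expect_equal(wt$product_length - edel$product_length, 360L)

  dupj <- locus_primer_pair(fl$locus, "DUPJ")
  expect_identical(insilico_pcr(fl$alleles$wt, dupj)$status, "no_product")
  expect_identical(insilico_pcr(fl$alleles$idfl, dupj)$status, "product")

  absent <- list(forward = strrep("ACGT", 5), reverse = pr$reverse)
  expect_identical(insilico_pcr(fl$alleles$wt, absent)$status, "no_product")

  # two convergent cassettes within max_product -> ambiguous
  f <- random_dna(20, seed = 71); r <- random_dna(20, seed = 72)
  cassette <- paste0(f, random_dna(60, seed = 73), revcomp(r))
  twice <- paste0(cassette, random_dna(40, seed = 74), cassette)
  expect_identical(insilico_pcr(twice, list(forward = f, reverse = r),
                                max_product = 500)$status, "ambiguous")
  expect_error(insilico_pcr("ACGT", list(forward = "ACGTACGTAC",
                                         reverse = "ACGTACGTAC")),
               ">= 15")
})
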