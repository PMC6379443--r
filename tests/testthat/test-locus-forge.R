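test_that("default locus satisfies its invariants and printed constants", {
  fl <- fixture_locus()
  locus <- fl$locus
  expect_s3_class(locus, "LocusModel")
  expect_equal(diff(locus$enhancer), 360L)
  expect_equal(diff(locus$dup_span), 24000L)
  expect_identical(sort(unique(strsplit(locus$sequence, "")[[1]])),
                   c("A", "C", "G", "T"))
  # enhancer sits in intron 1
  ex <- locus$exons
  expect_true(locus$enhancer[1] >= ex$end[1] && locus$enhancer[2] <= ex$start[2])
  # planted microhomology: ref[e-3, e) == ref[s-3, s), divergent beyond
  s <- locus$dup_span[1]; e <- locus$dup_span[2]
  expect_identical(substr(locus$sequence, e - 2, e), substr(locus$sequence, s - 2, s))
  expect_false(substr(locus$sequence, e - 3, e - 3) ==
                 substr(locus$sequence, s - 3, s - 3))
  expect_false(substr(locus$sequence, e + 1, e + 1) ==
                 substr(locus$sequence, s + 1, s + 1))
  # gene model reproduces the assay junction 20-mers
  gm <- gene_model(locus)
  expect_identical(junction_kmer(gm, "E2", "E2"), "ACCAGCAACTAACTGTGTCT")
  expect_identical(junction_kmer(gm, "E2", "E3"), "ACCAGCAACTCCCATGACAA")
})

test_that("build_locus validates features and plants microhomology on toys", {
  toy <- build_locus(list(name = "toy", length = 100, seed = 3,
                          exons = data.frame(exon = 1, start = 10, end = 20)))
  expect_equal(nrow(toy$exons), 1)
  expect_error(build_locus(list(name = "bad", length = 100, seed = 3,
                                exons = data.frame(exon = 1, start = 90,
                                                   end = 120))),
               "exon 1")
  # planting mL = 3 at s = 6, e = 13: ref[3,6) == ref[10,13)
  pl <- build_locus(list(name = "plant", length = 50, seed = 5,
                         plant = list(s = 6, e = 13, mL = 3, mR = 0)))
  expect_identical(substr(pl$sequence, 4, 6), substr(pl$sequence, 11, 13))
  expect_false(substr(pl$sequence, 3, 3) == substr(pl$sequence, 10, 10))
})

test_that("apply_deletion follows the splice rule and composes liftover", {
  al <- apply_deletion("AACCGGTT", edit_spec("deletion", 2, 6))
  expect_identical(al$sequence, "AATT")
  expect_identical(allele_to_ref(al, 0:3), c(0L, 1L, 6L, 7L))
  id <- apply_deletion("AACCGGTT", edit_spec("deletion", 0, 0))
  expect_identical(id$sequence, "AACCGGTT")
  expect_error(apply_deletion("AACC", edit_spec("deletion", 2, 10)))
  fl <- fixture_locus()
  expect_equal(nchar(fl$locus$sequence) - nchar(fl$alleles$edel$sequence), 360L)
  # margin indels perturb the deleted span
  alm <- idfl_alleles(fl$locus, margin_indel = 4L)
  expect_equal(nchar(fl$locus$sequence) - nchar(alm$edel$sequence), 364L)
})

test_that("apply_tandem_duplication follows the concatenation rule", {
  al <- apply_tandem_duplication("AACCGGTT", edit_spec("tandem_duplication", 2, 6))
  expect_identical(al$sequence, "AACCGGCCGGTT")
  dbl <- apply_tandem_duplication("ACGT", edit_spec("tandem_duplication", 0, 4))
  expect_identical(dbl$sequence, "ACGTACGT")
  fl <- fixture_locus()
  expect_equal(nchar(fl$alleles$idfl$sequence) - nchar(fl$locus$sequence),
               24000L - 360L)
  # junction 20-mer equals in[end-10, end) + in[start, start+10)
  s <- "GATTACAGATTACAGATTACA"
  d <- apply_tandem_duplication(s, edit_spec("tandem_duplication", 3, 15))
  jk <- paste0(substr(s, 6, 15), substr(s, 4, 13))
  expect_true(grepl(jk, d$sequence, fixed = TRUE))
})

test_that("liftover round trip maps allele positions back to themselves", {
  fl <- fixture_locus()
  idfl <- fl$alleles$idfl
  set.seed(11)
  for (p in sample(nchar(idfl$sequence), 50) - 1L) {
    r <- allele_to_ref(idfl, p)
    expect_true(p %in% ref_to_allele(idfl, r))
    # monotone within each mapped segment: neighbours differ by 1 inside runs
    if (p > 0) {
      d <- r - allele_to_ref(idfl, p - 1L)
      expect_true(d == 1L || abs(d) > 1L)
    }
  }
})

test_that("simulate_wgs_readpairs has the stated count, purity and moments", {
  allele <- random_dna(30000, seed = 42)
  rps <- simulate_wgs_readpairs(allele, depth = 30, read_length = 150,
                                error_rate = 0, seed = 9)
  expect_length(rps$read1, 3000L)
  # with zero error every read is an exact substring of allele or its rc
  idx <- sample(3000, 25)
  expect_true(all(vapply(rps$read1[idx], grepl, TRUE, x = allele,
                         fixed = TRUE)))
  expect_true(all(vapply(revcomp(rps$read2[idx]), grepl, TRUE, x = allele,
                         fixed = TRUE)))
  # empirical mean within 3 SE of the stated truncated-normal expectation
  # (truncation at 2 x read length = 300 bp lifts the mean by ~6 bp)
  z <- (300 - 400) / 60
  mu_trunc <- 400 + 60 * stats::dnorm(z) / (1 - stats::pnorm(z))
  se <- 60 / sqrt(length(rps$frag_len))
  expect_lt(abs(mean(rps$frag_len) - mu_trunc), 3 * se + 1)
  # seed determinism
  again <- simulate_wgs_readpairs(allele, depth = 30, read_length = 150,
                                  error_rate = 0, seed = 9)
  expect_identical(rps$read1, again$read1)
  expect_identical(rps$read2, again$read2)
  expect_error(simulate_wgs_readpairs(random_dna(500, seed = 1), depth = 10),
               "too short")
})

test_that("simulate_rnaseq_reads draws labelled junction reads", {
  fl <- fixture_locus()
  ctx <- default_junction_contexts(fl$locus)
  sim <- simulate_rnaseq_reads(ctx, c(E2E3 = 1, E2E2 = 0), n_reads = 100,
                               seed = 4)
  expect_identical(unname(sim$kmers["E2E2"]), "ACCAGCAACTAACTGTGTCT")
  expect_identical(unname(sim$kmers["E2E3"]), "ACCAGCAACTCCCATGACAA")
  expect_true(all(grepl(sim$kmers["E2E3"], sim$reads, fixed = TRUE)))
  expect_false(any(grepl(sim$kmers["E2E2"], sim$reads, fixed = TRUE)))
  # multinomial counts within 3 binomial SD at 10:1
  mix <- simulate_rnaseq_reads(ctx, c(E2E3 = 10 / 11, E2E2 = 1 / 11),
                               n_reads = 11000, seed = 8)
  n2 <- sum(mix$label == "E2E2")
  sd2 <- sqrt(11000 * (1 / 11) * (10 / 11))
  expect_lt(abs(n2 - 1000), 3 * sd2)
  expect_identical(simulate_rnaseq_reads(ctx, c(E2E3 = .5, E2E2 = .5),
                                         n_reads = 50, seed = 2)$reads,
                   simulate_rnaseq_reads(ctx, c(E2E3 = .5, E2E2 = .5),
                                         n_reads = 50, seed = 2)$reads)
  expect_error(simulate_rnaseq_reads(character(), numeric(), 10), "empty")
})

test_that("emit_cohort_vcf serializes 1-based VCF and round-trips", {
  fl <- fixture_locus()
  samples <- c("A", "B", "C")
  out <- emit_cohort_vcf(fl$locus,
                         data.frame(pos = c(99, 500, 700),
                                    category = c("private", "multiallelic",
                                                 "shared")),
                         samples = samples, affected_sample = "B")
  body <- out$vcf[!startsWith(out$vcf, "#")]
  f1 <- strsplit(body[1], "\t")[[1]]
  expect_identical(f1[2], "100")                  # POS is 1-based
  expect_identical(f1[11], paste0("0/1:30"))      # affected het
  expect_identical(f1[10], paste0("0/0:30"))
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_true(grepl(",", f2[5], fixed = TRUE))    # multiallelic ALT
  tmp <- tempfile(fileext = ".vcf")
  write_cohort_vcf(out$table, tmp)
  back <- read_cohort_vcf(tmp, affected = "B")
  cols <- c("chrom", "pos", "ref", "alt", paste0("gt.", samples),
            paste0("dp.", samples))
  expect_equal(as.data.frame(back)[, cols], as.data.frame(out$table)[, cols])
  expect_error(emit_cohort_vcf(fl$locus,
                               data.frame(pos = c(5, 5),
                                          category = c("shared", "shared")),
                               samples, "B"),
               "duplicate")
})
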