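test_that("off-target proximity filter is inclusive over +/- flank", {
  fl <- fixture_locus()
  plan <- data.frame(pos = c(94, 95, 100, 105, 106), category = "private")
  tbl <- emit_cohort_vcf(fl$locus, plan, c("A", "B", "C"), "B")$table
  sites <- data.table::data.table(contig = fl$locus$name, cut_pos = 100L,
                                  gRNA = "g1", rank = 1L)
  sel <- offtarget_proximity_filter(tbl, sites, flank = 5)
  expect_equal(sort(sel$pos), c(95L, 100L, 105L))
  expect_equal(nrow(offtarget_proximity_filter(tbl, sites[0])), 0)
})

test_that("default cohort plants six background variants at off-target sites", {
  fl <- fixture_locus()
  sites <- make_offtarget_sites(fl$locus, seed = 301)
  expect_equal(nrow(sites), 2 * 49)
  cohort <- emit_cohort_vcf(fl$locus, default_cohort_plan(fl$locus, sites),
                            samples = c("GT_05102", "GT_05105", "GT_05111"),
                            affected_sample = "GT_05105")
  sel <- offtarget_proximity_filter(cohort$table, sites, flank = 5,
                                    background = cohort$background)
  expect_equal(nrow(sel), 6)
  expect_true(all(sel$in_background))
})

test_that("six-rule toy table leaves exactly the private exonic variant", {
  fl <- fixture_locus()
  ex3 <- fl$locus$exons[3, ]
  plan <- data.frame(
    pos = c(1000, 2000, 3000, 4000, 5000, ex3$start + 10),
    category = c("multiallelic", "missing", "low_depth", "shared",
                 "background", "private"))
  cohort <- emit_cohort_vcf(fl$locus, plan, c("A", "B", "C"), "B")
  res <- cohort_inheritance_filter(cohort$table, affected = "B",
                                   background = cohort$background,
                                   exonic = fl$locus$exons)
  expect_equal(unname(res$trace), c(6L, 5L, 4L, 3L, 2L, 1L, 1L))
  expect_equal(res$variants$pos, ex3$start + 10L)
  expect_identical(res$variants$category, "private")
  expect_error(cohort_inheritance_filter(cohort$table, affected = "Z"),
               "not in cohort")
})

test_that("depth and excess rules behave at their boundaries", {
  fl <- fixture_locus()
  plan <- data.frame(pos = c(fl$locus$exons$start[1] + 5,
                             fl$locus$exons$start[1] + 50),
                     category = "private",
                     gt_affected = c("0/1", "1/1"))
  cohort <- emit_cohort_vcf(fl$locus, plan, c("A", "B", "C"), "B")
  tbl <- cohort$table
  # mean depth just under 10 removes the first variant at stage 3
  tbl$dp.A[1] <- 10L; tbl$dp.B[1] <- 10L; tbl$dp.C[1] <- 9L
  res <- cohort_inheritance_filter(tbl, affected = "B",
                                   exonic = fl$locus$exons)
  expect_equal(unname(res$trace[["after_coverage"]]), 1L)
  # affected 1/1 vs others 0/1 (2 > 1) passes the excess rule
  tbl2 <- cohort$table
  tbl2$gt.A[2] <- "0/1"; tbl2$gt.C[2] <- "0/1"
  res2 <- cohort_inheritance_filter(tbl2, affected = "B",
                                    exonic = fl$locus$exons)
  expect_true((fl$locus$exons$start[1] + 50) %in% res2$variants$pos)
  # affected 0/1 vs another 0/1 fails it
  tbl3 <- cohort$table
  tbl3$gt.A[1] <- "0/1"
  res3 <- cohort_inheritance_filter(tbl3, affected = "B",
                                    exonic = fl$locus$exons)
  expect_false(tbl3$pos[1] %in% res3$variants$pos)
})

test_that("filter equals the one-pass predicate oracle on random cohorts", {
  fl <- fixture_locus()
  cats <- c("private", "shared", "background", "low_depth", "multiallelic",
            "missing", "non_exonic")
  for (sd in 1:6) {
    set.seed(400 + sd)
    n <- 12
    plan <- data.frame(pos = sort(sample(99000, n)),
                       category = sample(cats, n, replace = TRUE),
                       gt_affected = sample(c("0/1", "1/1"), n, TRUE))
    cohort <- emit_cohort_vcf(fl$locus, plan, c("A", "B", "C"), "B")
    res <- cohort_inheritance_filter(cohort$table, affected = "B",
                                     background = cohort$background,
                                     exonic = fl$locus$exons)
    keep <- oracle_filter_predicate(cohort$table, "B", cohort$background,
                                    fl$locus$exons)
    expect_equal(res$variants$pos, cohort$table$pos[keep])
    expect_true(all(diff(unname(res$trace)) <= 0))
  }
})

test_that("BED round trip preserves exon intervals", {
  fl <- fixture_locus()
  tmp <- tempfile(fileext = ".bed")
  write_bed(fl$locus$exons, tmp, chrom = fl$locus$name)
  back <- read_bed(tmp)
  expect_equal(back$start, fl$locus$exons$start)
  expect_equal(back$end, fl$locus$exons$end)
})
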