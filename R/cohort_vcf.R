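#' Cohort variant tables
#'
#' A `CohortVariantTable` is a data.table with one row per record and columns
#' `chrom`, `pos` (0-based), `ref`, `alt` (comma-joined for multiallelic
#' records), a truth `category`, and per-sample `gt.<id>` / `dp.<id>`
#' columns. Attributes `samples` (ordered ids) and `affected` (sample id)
#' ride along. Positions are serialized 1-based at the VCF boundary only.
#'
#' @name CohortVariantTable
NULL

new_cohort_table <- function(dt, samples, affected) {
  dt <- data.table::as.data.table(dt)
  data.table::setorder(dt, pos)
  if (anyDuplicated(dt$pos)) stop("duplicate variant positions in cohort table")
  gts <- unlist(dt[, paste0("gt.", samples), with = FALSE])
  if (!all(gts %in% c("0/0", "0/1", "1/1", "1/2", "./."))) {
    stop("invalid genotype value in cohort table")
  }
  data.table::setattr(dt, "samples", samples)
  data.table::setattr(dt, "affected", affected)
  data.table::setattr(dt, "class", c("CohortVariantTable", class(dt)))
  dt
}

#' Emit a cohort VCF from a planted-variant plan
#'
#' Each plan row assigns a 0-based position and a truth category; genotypes
#' and depths are filled per category:
#' \describe{
#'   \item{private}{affected 0/1, others 0/0 (the candidate bystander class)}
#'   \item{shared}{all samples 0/1 (fails the affected-excess rule)}
#'   \item{background}{affected 0/1, others 0/0, and the variant is placed in
#'     the returned strain-background panel}
#'   \item{low_depth}{affected 0/1, others 0/0, DP 8 (fails the >=10 mean
#'     coverage rule)}
#'   \item{multiallelic}{two ALT alleles (fails the biallelic rule)}
#'   \item{missing}{one sample genotype ./. (fails the all-genotyped rule)}
#'   \item{non_exonic}{affected 0/1, others 0/0, at a non-exonic position}
#' }
#'
#' @param locus a `LocusModel` providing the reference bases.
#' @param plan data.frame with columns `pos` (0-based) and `category`;
#'   optional `gt_affected` (e.g. "1/1" for homozygous private variants).
#' @param samples ordered sample ids.
#' @param affected_sample the affected sample id (must be in `samples`).
#' @param depth default per-sample DP (default 30).
#' @return list with `table` (a `CohortVariantTable`), `background`
#'   (data.table pos/ref/alt of the strain panel) and `vcf` (VCF 4.2 text
#'   lines).
#' @export
emit_cohort_vcf <- function(locus, plan, samples, affected_sample,
                            depth = 30L) {
  stopifnot(affected_sample %in% samples)
  plan <- data.table::as.data.table(plan)
  if (anyDuplicated(plan$pos)) stop("duplicate positions in variant plan")
  L <- nchar(locus$sequence)
  stopifnot(all(plan$pos >= 0 & plan$pos < L))
  refb <- substring(locus$sequence, plan$pos + 1L, plan$pos + 1L)
  altb <- vapply(refb, function(b) setdiff(DNA_BASES, b)[1L], character(1))
  alt2 <- vapply(refb, function(b) setdiff(DNA_BASES, b)[2L], character(1))
  n <- nrow(plan)
  dt <- data.table::data.table(chrom = locus$name, pos = as.integer(plan$pos),
                               ref = unname(refb), alt = unname(altb),
                               category = plan$category)
  for (s in samples) {
    dt[[paste0("gt.", s)]] <- "0/0"
    dt[[paste0("dp.", s)]] <- as.integer(depth)
  }
  ga <- paste0("gt.", affected_sample)
  others <- setdiff(samples, affected_sample)
  aff_gt <- if ("gt_affected" %in% names(plan)) plan$gt_affected else
    rep("0/1", n)
  for (i in seq_len(n)) {
    cat_i <- plan$category[i]
    data.table::set(dt, i, ga, aff_gt[i])
    if (cat_i == "shared") {
      for (s in others) data.table::set(dt, i, paste0("gt.", s), "0/1")
    } else if (cat_i == "low_depth") {
      for (s in samples) data.table::set(dt, i, paste0("dp.", s), 8L)
    } else if (cat_i == "multiallelic") {
      data.table::set(dt, i, "alt", paste0(dt$alt[i], ",", alt2[i]))
    } else if (cat_i == "missing") {
      data.table::set(dt, i, paste0("gt.", others[1]), "./.")
    }
  }
  tbl <- new_cohort_table(dt, samples, affected_sample)
  bg <- tbl[tbl$category == "background", c("pos", "ref", "alt")]
  list(table = tbl, background = bg,
       vcf = format_vcf(tbl))
}

format_vcf <- function(tbl) {
  samples <- attr(tbl, "samples")
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", tbl$chrom[1]),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(tbl)), function(i) {
    cells <- vapply(samples, function(s)
      paste0(tbl[[paste0("gt.", s)]][i], ":", tbl[[paste0("dp.", s)]][i]),
      character(1))
    paste(c(tbl$chrom[i], tbl$pos[i] + 1L, ".", tbl$ref[i], tbl$alt[i], ".",
            "PASS", ".", "GT:DP", cells), collapse = "\t")
  }, character(1))
  c(hdr, body)
}

#' Write / read a cohort VCF
#'
#' `write_cohort_vcf` serializes a `CohortVariantTable` as VCF 4.2 text
#' (0-based internal positions become 1-based POS). `read_cohort_vcf` parses
#' it back, via `VariantAnnotation::readVcf` when that package is installed
#' and an internal parser otherwise; both yield the same table.
#'
#' @param tbl a `CohortVariantTable`.
#' @param path file path.
#' @param affected affected sample id to re-attach on read.
#' @return `write_cohort_vcf`: `path` invisibly; `read_cohort_vcf`: a
#'   `CohortVariantTable` (the truth `category` column is not recoverable
#'   from VCF and is set to NA).
#' @export
write_cohort_vcf <- function(tbl, path) {
  writeLines(format_vcf(tbl), path)
  invisible(path)
}

#' @rdname write_cohort_vcf
#' @export
read_cohort_vcf <- function(path, affected = NULL) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(v)
    gt <- VariantAnnotation::geno(v)$GT
    dp <- VariantAnnotation::geno(v)$DP
    samples <- colnames(gt)
    alt <- vapply(VariantAnnotation::alt(v), function(a)
      paste(as.character(a), collapse = ","), character(1))
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = BiocGenerics::start(rr) - 1L,
      ref = as.character(VariantAnnotation::ref(v)),
      alt = unname(alt), category = NA_character_)
    gt[gt == "0|0"] <- "0/0"; gt[gt == "0|1"] <- "0/1"; gt[gt == "1|1"] <- "1/1"
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines, value = TRUE)
    samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
    body <- lines[!startsWith(lines, "#")]
    f <- data.table::tstrsplit(body, "\t")
    dt <- data.table::data.table(chrom = f[[1]],
                                 pos = as.integer(f[[2]]) - 1L,
                                 ref = f[[4]], alt = f[[5]],
                                 category = NA_character_)
    cells <- lapply(seq_along(samples), function(j) f[[9 + j]])
    gt <- do.call(cbind, lapply(cells, function(x)
      vapply(strsplit(x, ":"), `[`, character(1), 1L)))
    dp <- do.call(cbind, lapply(cells, function(x)
      as.integer(vapply(strsplit(x, ":"), `[`, character(1), 2L))))
    colnames(gt) <- colnames(dp) <- samples
  }
  for (j in seq_along(samples)) {
    dt[[paste0("gt.", samples[j])]] <- unname(gt[, j])
    dt[[paste0("dp.", samples[j])]] <- as.integer(dp[, j])
  }
  new_cohort_table(dt, samples, affected %||% samples[1])
}

#' Default three-sample cohort plan
#'
#' Plants one private exonic candidate (the linked-bystander stand-in, in
#' exon 3), plus shared, strain-background, low-depth, multiallelic, missing-
#' genotype and private non-exonic decoys, and six background-panel variants
#' placed within 5 bp of predicted off-target cut sites.
#'
#' @param locus a `LocusModel` (default configuration).
#' @param sites off-target site table from [make_offtarget_sites()]; the
#'   first six sites receive an adjacent background variant.
#' @return data.frame plan for [emit_cohort_vcf()].
#' @export
default_cohort_plan <- function(locus, sites = NULL) {
  ex3 <- locus$exons[locus$exons$exon == 3, ]
  plan <- data.frame(
    pos = c(ex3$start + 57L,    # private exonic survivor
            15000L,             # shared intronic
            45000L,             # background panel, not near a site
            55000L,             # low depth
            65000L,             # multiallelic
            75000L,             # missing genotype
            85000L),            # private non-exonic
    category = c("private", "shared", "background", "low_depth",
                 "multiallelic", "missing", "non_exonic"))
  if (!is.null(sites) && nrow(sites) >= 6) {
    near <- data.frame(pos = sites$cut_pos[1:6] + c(-5L, -3L, 0L, 2L, 4L, 5L),
                       category = "background")
    plan <- rbind(plan, near)
  }
  plan[order(plan$pos), , drop = FALSE]
}

#' Synthetic predicted off-target site list
#'
#' Emulates the consumed input of an off-target predictor: the top `n` ranked
#' predicted cut sites per guide RNA, as a tab-separated table (contig,
#' position, gRNA, rank). Site prediction itself is out of scope; positions
#' are drawn uniformly over the locus away from the on-target cuts.
#'
#' @param locus a `LocusModel`.
#' @param n_per_grna sites per guide (default 49).
#' @param seed integer seed.
#' @return data.table with columns `contig`, `cut_pos` (0-based), `gRNA`,
#'   `rank`.
#' @export
make_offtarget_sites <- function(locus, n_per_grna = 49L, seed = 1L) {
  L <- nchar(locus$sequence)
  guides <- names(locus$cut_sites)
  if (!length(guides)) guides <- c("gRNA_left", "gRNA_right")
  with_seed(seed, {
    out <- data.table::rbindlist(lapply(guides, function(g) {
      pos <- sort(sample(setdiff(seq(1000L, L - 1000L, by = 7L),
                                 locus$cut_sites), n_per_grna))
      data.table::data.table(contig = locus$name, cut_pos = as.integer(pos),
                             gRNA = g, rank = seq_len(n_per_grna))
    }))
    out
  })
}

#' Write / read an off-target site table (TSV)
#'
#' @param sites table from [make_offtarget_sites()].
#' @param path file path.
#' @export
write_offtarget_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_offtarget_sites
#' @export
read_offtarget_sites <- function(path) {
  data.table::fread(path, sep = "\t")
}
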