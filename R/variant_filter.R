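#' Off-target proximity filter
#'
#' Selects cohort variants lying within `flank` bp (inclusive, both sides) of
#' any predicted off-target cut site, and flags each selected variant for
#' membership in the strain background panel.
#'
#' @param variants a `CohortVariantTable`.
#' @param sites off-target site table (columns `contig`, `cut_pos`, `gRNA`,
#'   `rank`); see [make_offtarget_sites()].
#' @param flank proximity window in bp (default 5).
#' @param background background panel (data.table with `pos`, `ref`, `alt`),
#'   matched on position + ref + alt.
#' @return data.table of the selected variant rows with an added logical
#'   column `in_background`.
#' @export
offtarget_proximity_filter <- function(variants, sites, flank = 5L,
                                       background = NULL) {
  v <- data.table::as.data.table(variants)
  if (is.null(sites) || nrow(sites) == 0 || nrow(v) == 0) {
    out <- v[0]
    out[, in_background := logical(0)]
    return(out)
  }
  near <- vapply(v$pos, function(p)
    any(v$chrom[1] == sites$contig & abs(p - sites$cut_pos) <= flank),
    logical(1))
  sel <- v[near]
  sel[, in_background := in_panel(sel, background)]
  sel[]
}

in_panel <- function(v, background) {
  if (is.null(background) || nrow(background) == 0 || nrow(v) == 0) {
    return(rep(FALSE, nrow(v)))
  }
  paste(v$pos, v$ref, v$alt) %in%
    paste(background$pos, background$ref, background$alt)
}

gt_alt_count <- function(gt) {
  c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L, "1/2" = 2L, "./." = NA_integer_)[gt]
}

#' Inheritance-model cohort filter
#'
#' The unbiased candidate search: starting from the full cohort table, keep
#' (1) biallelic SNVs/INDELs only; (2) records where every sample has a
#' genotype call; (3) records with sufficient coverage (cohort-mean DP >=
#' `min_avg_depth` by default, or every sample >= it when
#' `per_sample = TRUE`); (4) records where the affected sample's alternate-
#' allele count strictly exceeds every unaffected sample's ("unique or in
#' excess"); (5) records absent from the strain background panel (matched on
#' pos + ref + alt); (6) records overlapping exonic intervals. A
#' `FilterTrace` records the count surviving each stage.
#'
#' @param variants a `CohortVariantTable`.
#' @param affected affected sample id.
#' @param background background panel (data.table `pos`, `ref`, `alt`).
#' @param exonic exon intervals: data.frame with 0-based half-open `start`,
#'   `end` (e.g. `locus$exons`).
#' @param min_avg_depth depth threshold (default 10).
#' @param per_sample if TRUE, apply the depth rule per sample instead of to
#'   the cohort mean.
#' @return list with `variants` (surviving rows) and `trace` (named integer
#'   vector: input, after_biallelic, after_genotyped, after_coverage,
#'   after_affected_excess, after_background_subtraction, after_exonic).
#' @export
cohort_inheritance_filter <- function(variants, affected, background = NULL,
                                      exonic = NULL, min_avg_depth = 10,
                                      per_sample = FALSE) {
  v <- data.table::as.data.table(variants)
  samples <- attr(variants, "samples")
  if (is.null(samples)) {
    samples <- sub("^gt\\.", "", grep("^gt\\.", names(v), value = TRUE))
  }
  if (!affected %in% samples) stop("affected sample '", affected,
                                   "' not in cohort samples")
  trace <- c(input = nrow(v))

  v <- v[!grepl(",", alt, fixed = TRUE)]
  trace["after_biallelic"] <- nrow(v)

  gtm <- as.matrix(v[, paste0("gt.", samples), with = FALSE])
  v <- v[rowSums(gtm == "./.") == 0L]
  trace["after_genotyped"] <- nrow(v)

  dpm <- as.matrix(v[, paste0("dp.", samples), with = FALSE])
  keep <- if (per_sample) rowSums(dpm < min_avg_depth) == 0L
          else rowMeans(dpm) >= min_avg_depth
  v <- v[keep]
  trace["after_coverage"] <- nrow(v)

  acm <- apply(as.matrix(v[, paste0("gt.", samples), with = FALSE]), 2,
               gt_alt_count)
  if (nrow(v) == 1L) acm <- matrix(acm, nrow = 1L,
                                   dimnames = list(NULL, paste0("gt.", samples)))
  aff_ac <- acm[, paste0("gt.", affected)]
  oth_ac <- acm[, paste0("gt.", setdiff(samples, affected)), drop = FALSE]
  v <- v[aff_ac > apply(oth_ac, 1, max)]
  trace["after_affected_excess"] <- nrow(v)

  v <- v[!in_panel(v, background)]
  trace["after_background_subtraction"] <- nrow(v)

  if (!is.null(exonic) && nrow(exonic) > 0 && nrow(v) > 0) {
    span_end <- v$pos + nchar(v$ref)
    hit <- vapply(seq_len(nrow(v)), function(i)
      any(v$pos[i] < exonic$end & span_end[i] > exonic$start), logical(1))
    v <- v[hit]
  } else if (!is.null(exonic)) {
    v <- v[0]
  }
  trace["after_exonic"] <- nrow(v)

  stopifnot(!is.unsorted(rev(trace)))
  list(variants = v[], trace = trace)
}

#' Read / write BED exon intervals
#'
#' Three-column BED (0-based half-open), the serialization of the exon/
#' feature intervals used by the exonic-overlap stage.
#'
#' @param intervals data.frame with `start`, `end` and optional `name`.
#' @param path file path.
#' @param chrom contig name for writing.
#' @export
write_bed <- function(intervals, path, chrom = "locus") {
  nm <- if ("name" %in% names(intervals)) intervals$name
        else if ("exon" %in% names(intervals)) paste0("exon", intervals$exon)
        else "."
  utils::write.table(
    data.frame(chrom, intervals$start, intervals$end, nm),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  data.table::setnames(dt, seq_len(min(4L, ncol(dt))),
                       c("chrom", "start", "end", "name")[seq_len(min(4L, ncol(dt)))])
  dt[]
}
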