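#' Default run configuration
#'
#' Every random stage carries an explicit seed; unknown keys are rejected by
#' [run_pipeline()]. Stage toggles allow partial runs.
#'
#' @param seed master seed; stage seeds derive from it deterministically.
#' @return a `RunConfig` list.
#' @export
default_run_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    stages = c(simulate = TRUE, align = TRUE, depth = TRUE, sv = TRUE,
               filter = TRUE, isoform = TRUE, pcr = TRUE),
    allele = "idfl",                 # wt | edel | idfl
    zygosity = "hom",                # hom | het (het: half wt reads)
    locus_seed = seed,
    wgs = list(depth = 30, read_length = 150L, fragment_mean = 400,
               fragment_sd = 60, error_rate = 0.001, seed = seed + 100L),
    rna = list(n_reads = 11000L, prop_e2e3 = 10 / 11, read_length = 50L,
               seed = seed + 200L),
    depth = list(window = 500L, threshold = 1.4, min_windows = 5L,
                 max_gap = 1L),
    sv = list(k = 31L, min_support = 3L, min_clip = 20L,
              homology_window = 200L, homology_min_len = 10L),
    filter = list(min_avg_depth = 10, flank = 5L, sites_seed = seed + 300L),
    out_dir = NULL,
    write_intermediates = FALSE)
}

#' Run the discovery pipeline end to end
#'
#' simulate -> align -> depth -> SV -> microhomology -> filter -> isoform ->
#' PCR, on the packaged synthetic locus. Produces a `RunReport` holding each
#' stage's outputs plus a truth-comparison section (boundary error in
#' windows, breakpoint error in bp) since the simulation truth is known.
#'
#' @param config a `RunConfig`; see [default_run_config()].
#' @return a `RunReport` list.
#' @export
run_pipeline <- function(config = default_run_config()) {
  known <- names(default_run_config())
  extra <- setdiff(names(config), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  cfg <- utils::modifyList(default_run_config(), config)
  st <- cfg$stages
  report <- list(package_version = as.character(utils::packageVersion("bystanderscan")),
                 config = cfg, stages_run = names(st)[st],
                 blocks = NULL, junction = NULL, all_junctions = NULL,
                 microhomology = NULL,
                 extended_homology = NULL, pair_classes = NULL,
                 library = NULL, filter_trace = NULL, surviving_variants = NULL,
                 offtarget_hits = NULL, isoform_counts = NULL,
                 isoform_calls = NULL, pcr = NULL, truth_comparison = NULL)
  class(report) <- "RunReport"
  if (!any(st)) return(report)

  locus <- build_locus(default_locus_config(cfg$locus_seed))
  alleles <- idfl_alleles(locus)
  allele <- alleles[[cfg$allele]]
  truth <- alleles$truth
  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  aln <- NULL
  if (st[["simulate"]] && st[["align"]]) {
    rps <- if (cfg$zygosity == "het" && cfg$allele != "wt") {
      half <- cfg$wgs$depth / 2
      combine_readpairs(
        simulate_wgs_readpairs(allele, depth = half,
                               read_length = cfg$wgs$read_length,
                               fragment_mean = cfg$wgs$fragment_mean,
                               fragment_sd = cfg$wgs$fragment_sd,
                               error_rate = cfg$wgs$error_rate,
                               seed = cfg$wgs$seed),
        simulate_wgs_readpairs(alleles$wt, depth = half,
                               read_length = cfg$wgs$read_length,
                               fragment_mean = cfg$wgs$fragment_mean,
                               fragment_sd = cfg$wgs$fragment_sd,
                               error_rate = cfg$wgs$error_rate,
                               seed = cfg$wgs$seed + 1L))
    } else {
      simulate_wgs_readpairs(allele, depth = cfg$wgs$depth,
                             read_length = cfg$wgs$read_length,
                             fragment_mean = cfg$wgs$fragment_mean,
                             fragment_sd = cfg$wgs$fragment_sd,
                             error_rate = cfg$wgs$error_rate,
                             seed = cfg$wgs$seed)
    }
    idx <- reference_index(locus)
    aln <- align_readpair_set(rps, idx)
    report$library <- library_stats(aln, nchar(locus$sequence))
    if (isTRUE(cfg$write_intermediates) && !is.null(out_dir)) {
      write_sam(aln, file.path(out_dir, "alignments.sam"),
                rname = locus$name, rlen = nchar(locus$sequence))
      write_fastq_pair(rps, file.path(out_dir, "wgs"))
      write_fasta(c(ref = locus$sequence), file.path(out_dir, "reference.fasta"))
      write_bed(locus$exons, file.path(out_dir, "exons.bed"),
                chrom = locus$name)
    }
  }

  if (st[["depth"]] && !is.null(aln)) {
    prof <- compute_coverage_profile(aln, nchar(locus$sequence),
                                     window_size = cfg$depth$window)
    blocks <- detect_elevated_blocks(prof, threshold = cfg$depth$threshold,
                                     min_windows = cfg$depth$min_windows,
                                     max_gap = cfg$depth$max_gap)
    report$blocks <- blocks
    if (nrow(blocks)) {
      werr <- c(abs(blocks$start[1] - truth$duplication[1]),
                abs(blocks$end[nrow(blocks)] - truth$duplication[2])) /
        cfg$depth$window
      report$truth_comparison$boundary_error_windows <- max(werr)
    }
  }

  if (st[["sv"]] && !is.null(aln)) {
    cls <- classify_read_pairs(aln, cfg$wgs$fragment_mean, cfg$wgs$fragment_sd)
    report$pair_classes <- as.list(table(cls$label))
    cand <- recruit_junction_reads(aln, min_clip = cfg$sv$min_clip,
                                   fragment_mean = cfg$wgs$fragment_mean,
                                   fragment_sd = cfg$wgs$fragment_sd)
    jx <- assemble_junction(cand, locus$sequence, k = cfg$sv$k,
                            min_support = cfg$sv$min_support)
    jall <- all_junctions(jx)
    # the discovery target is the junction explaining the copy-number gain:
    # prefer a tandem-duplication junction consistent with the elevated
    # block boundaries (within one window), then any tandem duplication,
    # then the best-supported junction of any class
    if (length(jall) > 1) {
      dup <- Filter(function(j) j$orientation == "tandem_duplication", jall)
      if (length(dup) && !is.null(report$blocks) && nrow(report$blocks)) {
        w <- cfg$depth$window
        ok <- Filter(function(j)
          abs(j$right_break - report$blocks$start[1]) <= w &&
          abs(j$left_break - report$blocks$end[nrow(report$blocks)]) <= w,
          dup)
        if (length(ok)) jx <- ok[[1]] else if (length(dup)) jx <- dup[[1]]
      } else if (length(dup)) jx <- dup[[1]]
    }
    report$junction <- jx
    report$all_junctions <- lapply(jall, unclass)
    if (jx$status == "ok") {
      report$microhomology <- list(left = jx$microhomology_left,
                                   right = jx$microhomology_right,
                                   total = jx$mh_total)
      eh <- scan_extended_homology(locus$sequence,
                                   locus$cut_sites[["gRNA_right"]],
                                   jx$left_break, jx$right_break,
                                   window = cfg$sv$homology_window,
                                   min_len = cfg$sv$homology_min_len)
      report$extended_homology <- eh
      report$truth_comparison$breakpoint_error_bp <-
        max(abs(jx$left_break - truth$duplication[2]),
            abs(jx$right_break - truth$duplication[1]))
    }
  }

  if (st[["filter"]]) {
    sites <- make_offtarget_sites(locus, seed = cfg$filter$sites_seed)
    cohort <- emit_cohort_vcf(locus, default_cohort_plan(locus, sites),
                              samples = c("GT_05102", "GT_05105", "GT_05111"),
                              affected_sample = "GT_05105")
    ot <- offtarget_proximity_filter(cohort$table, sites,
                                     flank = cfg$filter$flank,
                                     background = cohort$background)
    fl <- cohort_inheritance_filter(cohort$table, affected = "GT_05105",
                                    background = cohort$background,
                                    exonic = locus$exons,
                                    min_avg_depth = cfg$filter$min_avg_depth)
    report$offtarget_hits <- ot
    report$filter_trace <- as.list(fl$trace)
    report$surviving_variants <- fl$variants
    if (isTRUE(cfg$write_intermediates) && !is.null(out_dir)) {
      write_cohort_vcf(cohort$table, file.path(out_dir, "cohort.vcf"))
      write_offtarget_sites(sites, file.path(out_dir, "offtarget_sites.tsv"))
    }
  }

  if (st[["isoform"]]) {
    ctx <- default_junction_contexts(locus)
    sim <- simulate_rnaseq_reads(ctx,
                                 c(E2E3 = cfg$rna$prop_e2e3,
                                   E2E2 = 1 - cfg$rna$prop_e2e3),
                                 n_reads = cfg$rna$n_reads,
                                 read_length = cfg$rna$read_length,
                                 seed = cfg$rna$seed)
    ct <- count_junction_kmers(sim$reads, sim$kmers,
                               ratio_of = c("E2E3", "E2E2"))
    report$isoform_counts <- list(counts = ct$counts,
                                  e2e3_to_e2e2_ratio = ct$ratio)
    report$isoform_calls <- enumerate_isoforms_and_classify(gene_model(locus))
  }

  if (st[["pcr"]]) {
    edel_assay <- genotype_by_pcr(
      list(wt = alleles$wt, edel = alleles$edel, idfl = alleles$idfl),
      locus_primer_pair(locus, "EDEL"))
    dupj_assay <- genotype_by_pcr(
      list(wt = alleles$wt, idfl = alleles$idfl),
      locus_primer_pair(locus, "DUPJ"))
    report$pcr <- list(
      edel = edel_assay, dupj = dupj_assay,
      deletion_size_bp = edel_assay$product_length[1] -
        edel_assay$product_length[2])
  }

  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"), format = "json")
  }
  report
}

#' Serialize a run report
#'
#' JSON (machine-readable, written atomically via a temp file rename) or a
#' short text summary. Timestamps are deliberately excluded so identical
#' config + seeds give byte-identical reports.
#'
#' @param report a `RunReport`.
#' @param path output path; `NULL` returns the serialized text.
#' @param format `"json"` or `"text"`.
#' @return the serialized lines invisibly (or visibly when `path` is NULL).
#' @export
write_report <- function(report, path = NULL, format = c("json", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    clean <- unclass(report)
    clean$config <- NULL
    clean$junction <- if (!is.null(report$junction))
      unclass(report$junction) else NULL
    txt <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                            na = "null", null = "null", pretty = TRUE)
    lines <- strsplit(as.character(txt), "\n")[[1]]
  } else {
    lines <- c("bystanderscan run report",
               paste0("stages: ", paste(report$stages_run, collapse = ", ")),
               if (!is.null(report$blocks))
                 sprintf("elevated blocks: %d (first: [%s, %s), %s windows)",
                         nrow(report$blocks),
                         report$blocks$start[1] %||% "-",
                         report$blocks$end[1] %||% "-",
                         report$blocks$n_windows[1] %||% "-"),
               if (!is.null(report$junction))
                 sprintf("junction: %s", report$junction$status),
               if (!is.null(report$microhomology))
                 sprintf("microhomology: %d+%d = %d nt",
                         report$microhomology$left, report$microhomology$right,
                         report$microhomology$total),
               if (!is.null(report$filter_trace))
                 sprintf("filter trace: %s",
                         paste(unlist(report$filter_trace), collapse = " -> ")),
               if (!is.null(report$isoform_counts))
                 sprintf("E2E3:E2E2 ratio: %.3f",
                         report$isoform_counts$e2e3_to_e2e2_ratio),
               if (!is.null(report$pcr))
                 sprintf("deletion size by PCR: %d bp",
                         report$pcr$deletion_size_bp))
  }
  if (!is.null(path)) {
    tmp <- paste0(path, ".tmp")
    writeLines(lines, tmp)
    file.rename(tmp, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.RunReport <- function(x, ...) {
  cat(write_report(x, format = "text"), sep = "\n")
  invisible(x)
}
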