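#' Count junction k-mers in reads
#'
#' Exact-substring junction counting: a read counts once per label when it
#' contains the label's k-mer anywhere (grep semantics on raw reads; no
#' alignment). Reverse-complement matching is off by default, matching a
#' forward text search of raw FASTQ; enable it for libraries of unknown
#' strandedness. Counts are normalized to the total number of reads.
#'
#' @param reads character vector of read sequences, or a FASTQ file path.
#' @param kmers named character vector of junction k-mers (uppercase DNA).
#' @param count_reverse_complement also match each k-mer's reverse
#'   complement (default FALSE).
#' @param ratio_of optional character pair `c(label1, label2)`: report
#'   `count(label1) / count(label2)`.
#' @return list with `counts` (data.table: label, kmer, count, total,
#'   normalized) and `ratio` (numeric, `NA` with a warning when the
#'   denominator count is zero; `NULL` when `ratio_of` is not given).
#' @export
count_junction_kmers <- function(reads, kmers,
                                 count_reverse_complement = FALSE,
                                 ratio_of = NULL) {
  if (length(reads) == 1 && file.exists(reads)) reads <- read_fastq(reads)
  if (length(kmers) == 0) stop("empty k-mer set")
  check_dna(kmers, "junction k-mer")
  if (is.null(names(kmers))) names(kmers) <- paste0("kmer", seq_along(kmers))
  total <- length(reads)
  count <- vapply(kmers, function(km) {
    hit <- grepl(km, reads, fixed = TRUE)
    if (count_reverse_complement) hit <- hit | grepl(revcomp(km), reads,
                                                     fixed = TRUE)
    sum(hit)
  }, integer(1))
  counts <- data.table::data.table(label = names(kmers), kmer = unname(kmers),
                                   count = unname(count), total = total,
                                   normalized = unname(count) / total)
  ratio <- NULL
  if (!is.null(ratio_of)) {
    stopifnot(length(ratio_of) == 2, all(ratio_of %in% names(kmers)))
    den <- count[[ratio_of[2]]]
    if (den == 0) {
      warning("ratio undefined: zero reads contain ", ratio_of[2])
      ratio <- NA_real_
    } else ratio <- count[[ratio_of[1]]] / den
  }
  list(counts = counts, ratio = ratio)
}

#' Enumerate splice isoforms of a duplicated-exon allele and classify them
#'
#' For a gene model whose edited allele carries exon `dup_exon` twice,
#' enumerates the exon chain containing both copies and the single-copy
#' chain, splices each, translates in-frame from the start codon, and
#' classifies each isoform as `productive` or `premature_stop`. The
#' annotated terminal stop is anchored from the transcript 3' end (shared
#' terminal exons), so it is well defined on chains whose length differs
#' from the reference chain.
#'
#' @param gm gene model from [gene_model()].
#' @param dup_exon duplicated exon label (default `"E2"`).
#' @param ptc_nmd_bp annotation threshold: a premature stop more than this
#'   many bp upstream of the last exon-exon junction is flagged
#'   `nmd_candidate` (50-nt rule; reported as an annotation only).
#' @return data.table of `IsoformCall`s: `chain`, `n_exons`, `mrna_length`,
#'   `classification`, `stop_codon_index` (1-based codon of the first stop),
#'   `protein_length`, `nmd_candidate`.
#' @export
enumerate_isoforms_and_classify <- function(gm, dup_exon = "E2",
                                            ptc_nmd_bp = 50L) {
  labels <- names(gm$exon_seqs)
  stopifnot(dup_exon %in% labels)
  i <- match(dup_exon, labels)
  chains <- list(
    single = labels,
    duplicated = c(labels[seq_len(i)], labels[i:length(labels)]))
  ref_mrna <- paste(gm$exon_seqs, collapse = "")
  stop_from_3p <- nchar(ref_mrna) - gm$terminal_stop_tx

  rows <- lapply(names(chains), function(nm) {
    chain <- chains[[nm]]
    mrna <- paste(gm$exon_seqs[chain], collapse = "")
    cds_tx <- gm$cds_start_tx  # upstream exons identical across both chains
    if (substr(mrna, cds_tx + 1L, cds_tx + 3L) != "ATG") {
      stop("start codon absent at annotated CDS start")
    }
    annotated_stop <- nchar(mrna) - stop_from_3p
    first_stop <- NA_integer_
    for (p in seq(cds_tx, nchar(mrna) - 3L, by = 3L)) {
      if (substr(mrna, p + 1L, p + 3L) %in% STOP_CODONS) { first_stop <- p; break }
    }
    classification <- if (!is.na(first_stop) && first_stop < annotated_stop)
      "premature_stop" else "productive"
    last_junction <- nchar(mrna) - nchar(gm$exon_seqs[[chain[length(chain)]]])
    nmd <- classification == "premature_stop" && !is.na(first_stop) &&
      (last_junction - (first_stop + 3L)) > ptc_nmd_bp
    data.table::data.table(
      chain = paste(chain, collapse = "-"), n_exons = length(chain),
      mrna_length = nchar(mrna), classification = classification,
      stop_codon_index = if (is.na(first_stop)) NA_integer_ else
        as.integer((first_stop - cds_tx) / 3L + 1L),
      protein_length = if (is.na(first_stop)) NA_integer_ else
        as.integer((first_stop - cds_tx) / 3L),
      nmd_candidate = nmd)
  })
  data.table::rbindlist(rows)
}

#' In-silico PCR
#'
#' Finds exact matches of the forward primer and of the reverse complement
#' of the reverse primer on an allele; a product exists when exactly one
#' convergent pair (forward match upstream of reverse-site match) lies
#' within `max_product` bp. The product length runs from the forward
#' primer's 5' end to the reverse primer's 5' end.
#'
#' @param allele an `AlleleSequence`, `LocusModel`, or DNA string.
#' @param primers list with `forward` and `reverse` primer sequences (both
#'   given 5'->3'; the reverse primer anneals to the plus strand).
#' @param max_product maximum product length in bp (default 1000).
#' @return an `AmpliconCall`: list with `product_length` (NA when no
#'   product), `status` ("product", "no_product", "ambiguous"), `forward_pos`
#'   and `reverse_end` (0-based allele coords of the product span).
#' @export
insilico_pcr <- function(allele, primers, max_product = 1000L) {
  al <- as_allele(allele)
  fwd <- toupper(primers$forward); rev <- toupper(primers$reverse)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primers must be >= 15 nt")
  find_all <- function(pat) {
    g <- gregexpr(pat, al$sequence, fixed = TRUE)[[1]]
    if (g[1] == -1L) integer() else as.integer(g) - 1L
  }
  fpos <- find_all(fwd)
  rpos <- find_all(revcomp(rev))  # plus-strand site of the reverse primer
  cand <- list()
  for (f in fpos) for (r in rpos) {
    len <- (r + nchar(rev)) - f
    if (r >= f + nchar(fwd) && len <= max_product) {
      cand[[length(cand) + 1L]] <- c(f, r + nchar(rev), len)
    }
  }
  if (length(cand) == 0) {
    return(structure(list(status = "no_product", product_length = NA_integer_,
                          forward_pos = NA_integer_, reverse_end = NA_integer_),
                     class = "AmpliconCall"))
  }
  if (length(cand) > 1) {
    return(structure(list(status = "ambiguous", product_length = NA_integer_,
                          forward_pos = NA_integer_, reverse_end = NA_integer_),
                     class = "AmpliconCall"))
  }
  structure(list(status = "product", product_length = cand[[1]][3],
                 forward_pos = cand[[1]][1], reverse_end = cand[[1]][2]),
            class = "AmpliconCall")
}

#' @export
print.AmpliconCall <- function(x, ...) {
  if (x$status == "product") {
    cat(sprintf("AmpliconCall: %d bp product [%d,%d)\n", x$product_length,
                x$forward_pos, x$reverse_end))
  } else cat("AmpliconCall:", x$status, "\n")
  invisible(x)
}

#' Genotype alleles by in-silico PCR product lengths
#'
#' Runs one primer pair across a set of alleles and labels each by its
#' product: the reference product length is the `WT` band, a shorter product
#' the deletion band, and junction-assay primers that amplify only on the
#' duplication allele yield a duplication-specific band.
#'
#' @param alleles named list of alleles.
#' @param primers primer pair (see [insilico_pcr()]).
#' @param max_product maximum product length.
#' @return data.table with `allele`, `status`, `product_length`, `genotype`
#'   (relative to the first allele, taken as reference: "ref_band",
#'   "shorter_band", "longer_band", "no_product", "ambiguous").
#' @export
genotype_by_pcr <- function(alleles, primers, max_product = 1000L) {
  calls <- lapply(alleles, insilico_pcr, primers = primers,
                  max_product = max_product)
  len <- vapply(calls, `[[`, integer(1) + NA, "product_length")
  status <- vapply(calls, `[[`, character(1), "status")
  ref_len <- len[1]
  genotype <- ifelse(status == "ambiguous", "ambiguous",
              ifelse(status == "no_product", "no_product",
              ifelse(is.na(ref_len), "new_band",
              ifelse(len == ref_len, "ref_band",
              ifelse(len < ref_len, "shorter_band", "longer_band")))))
  data.table::data.table(allele = names(alleles), status = status,
                         product_length = len, genotype = genotype)
}
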