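#' Locus models
#'
#' A `LocusModel` bundles a reference sequence with its annotated features:
#' an intronic enhancer, an ordered exon set, the genomic CDS start, named
#' primer sites and blunt Cas9 cut positions. All coordinates are 0-based
#' half-open; 1-based coordinates appear only at VCF/SAM serialization
#' boundaries.
#'
#' @param config a list; see [default_locus_config()] for the full field set.
#'   Minimal fields: `name`, `length`, `seed`. Optional: `enhancer` (c(start,
#'   end)), `exons` (data.frame with columns exon, start, end), `cds_start`,
#'   `strand`, `primer_sites` (named list of c(start, end)), `cut_sites`
#'   (named integer vector), `sequence_patches` (list of list(start, seq)
#'   overwrites applied after background generation), `plant`
#'   (list(s, e, mL, mR): plant `mL` bp of microhomology ending at `s` and
#'   `e`, and `mR` bp starting there, with enforced divergence just outside
#'   the planted span so junction placement is unambiguous).
#'
#' @return an object of class `LocusModel`.
#' @export
build_locus <- function(config = default_locus_config()) {
  L <- as.integer(config$length)
  stopifnot(L > 0)
  seq <- random_dna(L, seed = config$seed %||% 1L)
  chars <- strsplit(seq, "")[[1]]

  for (p in config$sequence_patches %||% list()) {
    check_dna(p$seq, "sequence patch")
    s <- as.integer(p$start)
    check_interval(s, s + nchar(p$seq), L, "sequence patch")
    chars[(s + 1L):(s + nchar(p$seq))] <- strsplit(p$seq, "")[[1]]
  }

  if (!is.null(config$plant)) {
    pl <- config$plant
    s <- as.integer(pl$s); e <- as.integer(pl$e)
    mL <- as.integer(pl$mL %||% 0L); mR <- as.integer(pl$mR %||% 0L)
    check_interval(s, e, L, "microhomology plant span")
    if (mL > 0) chars[(e - mL + 1L):e] <- chars[(s - mL + 1L):s]
    if (mR > 0) chars[(e + 1L):(e + mR)] <- chars[(s + 1L):(s + mR)]
    # divergence immediately outside the planted homology: guarantees the
    # truth microhomology is exactly (mL, mR) and junction placement is
    # unambiguous (a 3-mer recurs in any random 50-bp window, so a
    # recurrence scan cannot be the guard).
    div <- function(i, j) {
      if (chars[i] == chars[j]) {
        chars[j] <<- setdiff(DNA_BASES, c(chars[i]))[1L]
      }
    }
    if (s - mL >= 1L && e - mL >= 1L) div(s - mL, e - mL)
    if (s + mR + 1L <= L && e + mR + 1L <= L) div(s + mR + 1L, e + mR + 1L)
  }

  locus <- structure(list(
    name = config$name %||% "locus",
    sequence = paste(chars, collapse = ""),
    enhancer = config$enhancer,
    exons = config$exons,
    cds_start = config$cds_start,
    strand = config$strand %||% "+",
    primer_sites = config$primer_sites %||% list(),
    cut_sites = config$cut_sites %||% integer(),
    dup_span = config$dup_span,
    mh_planted = if (is.null(config$plant)) c(0L, 0L) else
      c(as.integer(config$plant$mL %||% 0L), as.integer(config$plant$mR %||% 0L))
  ), class = "LocusModel")
  validate_locus(locus)
  locus
}

#' @export
print.LocusModel <- function(x, ...) {
  cat(sprintf("LocusModel '%s': %d bp, %d exons, enhancer [%d,%d), strand %s\n",
              x$name, nchar(x$sequence),
              if (is.null(x$exons)) 0L else nrow(x$exons),
              x$enhancer[1] %||% NA, x$enhancer[2] %||% NA, x$strand))
  invisible(x)
}

#' Validate a LocusModel against its type invariants
#'
#' Checks the sequence alphabet, that all feature intervals fall inside
#' `[0, length)`, that exon intervals are disjoint and ascending, and that
#' the enhancer lies in an intron (strictly between two exons, overlapping
#' none).
#'
#' @param locus a `LocusModel`.
#' @return `locus`, invisibly; stops with an error naming the offending
#'   feature otherwise.
#' @export
validate_locus <- function(locus) {
  L <- nchar(locus$sequence)
  check_dna(locus$sequence, "locus sequence")
  if (!is.null(locus$exons) && nrow(locus$exons) > 0) {
    ex <- locus$exons
    for (i in seq_len(nrow(ex))) {
      check_interval(ex$start[i], ex$end[i], L, paste0("exon ", ex$exon[i]))
    }
    if (is.unsorted(ex$start, strictly = TRUE) ||
        any(ex$start[-1] < ex$end[-nrow(ex)])) {
      stop("exon intervals must be disjoint and ascending", call. = FALSE)
    }
  }
  if (!is.null(locus$enhancer)) {
    check_interval(locus$enhancer[1], locus$enhancer[2], L, "enhancer")
    if (!is.null(locus$exons) && nrow(locus$exons) > 1) {
      ex <- locus$exons
      olap <- locus$enhancer[1] < ex$end & locus$enhancer[2] > ex$start
      if (any(olap)) stop("enhancer overlaps an exon", call. = FALSE)
      if (locus$enhancer[1] < min(ex$end) || locus$enhancer[2] > max(ex$start)) {
        stop("enhancer must lie within an intron", call. = FALSE)
      }
    }
  }
  for (nm in names(locus$primer_sites)) {
    iv <- locus$primer_sites[[nm]]
    check_interval(iv[1], iv[2], L, paste0("primer site ", nm))
  }
  if (any(locus$cut_sites < 0 | locus$cut_sites > L)) {
    stop("cut site out of range", call. = FALSE)
  }
  invisible(locus)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Craft the default CDS so that: the wild-type reading frame is open from ATG
# to the terminal stop; exon 2 starts AACTGTGTCT and ends ACCAGCAACT; exon 3
# starts CCCATGACAA (so exon-junction 20-mers match the assay k-mers); and a
# stop codon sits in the frame adopted by a *second* copy of exon 2, making
# the duplicated-exon transcript carry a premature termination codon.
craft_default_cds <- function(seed = 20L) {
  lens <- c(e1 = 100L, e2 = 134L, e3 = 150L, e4 = 150L, e5 = 150L,
            e6 = 150L, e7 = 150L, e8 = 123L)  # CDS portions; e8 includes stop
  total <- sum(lens)
  stopifnot(total %% 3 == 0)
  codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste,
                  collapse = "")
  sense <- setdiff(codons, STOP_CODONS)
  cds <- with_seed(seed, paste(sample(sense, total / 3, replace = TRUE),
                               collapse = ""))
  ch <- strsplit(cds, "")[[1]]
  put <- function(off0, s) ch[(off0 + 1L):(off0 + nchar(s))] <<-
    strsplit(s, "")[[1]]
  planted <- rep(FALSE, total)
  mark <- function(off0, n) planted[(off0 + 1L):(off0 + n)] <<- TRUE

  put(0L, "ATG"); mark(0L, 3L)
  c2 <- lens[["e1"]]                      # exon 2 CDS offset (== 100, frame 1)
  put(c2, "AACTGTGTCT"); mark(c2, 10L)
  put(c2 + 124L, "ACCAGCAACT"); mark(c2 + 124L, 10L)
  c3 <- c2 + lens[["e2"]]                 # exon 3 offset (== 234, frame 0)
  put(c3, "CCCATGACAA"); mark(c3, 10L)
  # premature stop seen only in the frame of a duplicated exon 2: exon-2
  # offset 12 is codon-aligned at chain offset 234 + 12 but mid-codon in the
  # wild-type frame.
  put(c2 + 12L, "TAA"); mark(c2 + 12L, 3L)
  put(total - 3L, "TAA"); mark(total - 3L, 3L)

  # open the wild-type frame: demote any non-terminal in-frame stop by
  # rewriting one unplanted base of that codon
  for (i in seq(1L, total - 3L, by = 3L)) {
    if (i == total - 2L) next
    cod <- paste(ch[i:(i + 2L)], collapse = "")
    if (cod %in% STOP_CODONS) {
      free <- which(!planted[i:(i + 2L)])
      if (length(free) == 0) stop("cannot open reading frame at codon ", i)
      ch[i + free[1L] - 1L] <- "C"
    }
  }
  split_at <- cumsum(c(0L, unname(lens)))
  list(cds = paste(ch, collapse = ""),
       cds_parts = setNames(
         mapply(function(a, b) paste(ch[(a + 1L):b], collapse = ""),
                split_at[-length(split_at)], split_at[-1L]),
         names(lens)),
       lens = lens)
}

#' Default ("IDFL-like") locus configuration
#'
#' A ~100-kb locus that mirrors the structure of an edited *Il2ra*-like
#' locus: an 8-exon gene on the plus strand, a 360-bp intronic enhancer in
#' intron 1 flanked by two Cas9 cut sites, a 24,000-bp span starting
#' immediately downstream of the enhancer that the duplication allele
#' repeats head-to-tail, 3 nt of planted left-side junction microhomology,
#' primer pairs spanning the enhancer and the duplication junction, and a
#' crafted coding sequence whose exon-junction 20-mers equal the RNA assay
#' k-mers.
#'
#' @param seed integer seed for the background sequence.
#' @return a config list accepted by [build_locus()].
#' @export
default_locus_config <- function(seed = 1L) {
  cds <- craft_default_cds(seed + 19L)
  exons <- data.frame(
    exon  = 1:8,
    start = c(5000L, 20000L, 40000L, 50000L, 60000L, 70000L, 80000L, 88000L),
    end   = c(5200L, 20134L, 40150L, 50150L, 60150L, 70150L, 80150L, 88600L)
  )
  cds_start <- 5100L
  patches <- list(
    list(start = cds_start, seq = cds$cds_parts[["e1"]]),
    list(start = 20000L,    seq = cds$cds_parts[["e2"]]),
    list(start = 40000L,    seq = cds$cds_parts[["e3"]]),
    list(start = 50000L,    seq = cds$cds_parts[["e4"]]),
    list(start = 60000L,    seq = cds$cds_parts[["e5"]]),
    list(start = 70000L,    seq = cds$cds_parts[["e6"]]),
    list(start = 80000L,    seq = cds$cds_parts[["e7"]]),
    list(start = 88000L,    seq = cds$cds_parts[["e8"]])
  )
  list(
    name = "synthLocus",
    length = 100000L,
    seed = seed,
    enhancer = c(10000L, 10360L),
    exons = exons,
    cds_start = cds_start,
    strand = "+",
    primer_sites = list(
      EDEL_F = c(9700L, 9720L),
      EDEL_R = c(10600L, 10620L),
      DUPJ_F = c(34200L, 34220L),
      DUPJ_R = c(10500L, 10520L)
    ),
    cut_sites = c(gRNA_left = 10000L, gRNA_right = 10360L),
    dup_span = c(10360L, 34360L),
    plant = list(s = 10360L, e = 34360L, mL = 3L, mR = 0L),
    sequence_patches = patches
  )
}

#' Extract a primer pair from a LocusModel
#'
#' @param locus a `LocusModel`.
#' @param assay `"EDEL"` (primers spanning the enhancer deletion site) or
#'   `"DUPJ"` (primers convergent only across the duplication junction).
#' @return list with `forward` and `reverse` primer sequences (reverse primer
#'   reported 5'->3' on the opposite strand, i.e. the reverse complement of
#'   its plus-strand site).
#' @export
locus_primer_pair <- function(locus, assay = c("EDEL", "DUPJ")) {
  assay <- match.arg(assay)
  f <- locus$primer_sites[[paste0(assay, "_F")]]
  r <- locus$primer_sites[[paste0(assay, "_R")]]
  if (is.null(f) || is.null(r)) stop("locus lacks primer sites for ", assay)
  list(forward = substr0(locus$sequence, f[1], f[2]),
       reverse = revcomp(substr0(locus$sequence, r[1], r[2])))
}

#' Gene model (exon sequences and CDS anchors) from a LocusModel
#'
#' Projects the genomic annotation into transcript space: per-exon sequences,
#' the transcript offset of the start codon, and the transcript offset of the
#' annotated terminal stop.
#'
#' @param locus a `LocusModel`.
#' @return list with `exon_seqs` (named `E1`..`En`), `cds_start_tx` (0-based
#'   offset of the A of ATG in the spliced transcript) and
#'   `terminal_stop_tx` (0-based transcript offset of the first base of the
#'   annotated stop codon).
#' @export
gene_model <- function(locus) {
  ex <- locus$exons
  seqs <- setNames(
    mapply(function(s, e) substr0(locus$sequence, s, e), ex$start, ex$end),
    paste0("E", ex$exon))
  cum <- cumsum(c(0L, nchar(seqs)))
  i1 <- which(ex$start <= locus$cds_start & locus$cds_start < ex$end)
  if (length(i1) != 1) stop("cds_start does not fall in an exon")
  cds_tx <- cum[i1] + (locus$cds_start - ex$start[i1])
  mrna <- paste(seqs, collapse = "")
  # walk the open frame to the annotated stop
  stop_tx <- NA_integer_
  for (p in seq(cds_tx, nchar(mrna) - 3L, by = 3L)) {
    if (substr(mrna, p + 1L, p + 3L) %in% STOP_CODONS) { stop_tx <- p; break }
  }
  if (is.na(stop_tx)) stop("no in-frame stop codon in reference transcript")
  list(exon_seqs = seqs, cds_start_tx = cds_tx, terminal_stop_tx = stop_tx)
}

#' Exon-junction k-mer for a pair of exons
#'
#' The `2k`-mer spanning an exon-exon splice junction: the last `k` bases of
#' the upstream exon followed by the first `k` bases of the downstream exon.
#'
#' @param gm a gene model from [gene_model()].
#' @param from,to exon labels, e.g. `"E2"`, `"E3"`.
#' @param k flank length on each side (default 10, giving a 20-mer).
#' @return the junction k-mer string.
#' @export
junction_kmer <- function(gm, from, to, k = 10L) {
  a <- gm$exon_seqs[[from]]; b <- gm$exon_seqs[[to]]
  if (is.null(a) || is.null(b)) stop("unknown exon label")
  paste0(substr(a, nchar(a) - k + 1L, nchar(a)), substr(b, 1L, k))
}
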