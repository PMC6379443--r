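#' Simulate whole-genome paired-end reads from an allele
#'
#' Draws `round(depth * L / (2 * read_length))` FR-oriented fragment pairs:
#' fragment lengths are normal(`fragment_mean`, `fragment_sd`) truncated to
#' `[2 * read_length, L]`, fragment starts uniform over valid positions,
#' read 1 is the fragment 5' end and read 2 the reverse complement of its 3'
#' end. Sequencing error is substitution-only at `error_rate` per base.
#'
#' @param allele an `AlleleSequence`, `LocusModel`, or DNA string.
#' @param depth target mean coverage (x).
#' @param read_length read length in bp (default 150).
#' @param fragment_mean,fragment_sd insert-size distribution (default 400/60,
#'   the library target used for 150-bp paired-end sequencing at 30x).
#' @param error_rate per-base substitution probability (default 0.001).
#' @param seed integer seed; identical seeds give identical read sets.
#' @return a `ReadPairSet`: list with `read1`, `read2` (character vectors),
#'   `frag_start` (0-based truth starts), `frag_len`, `source` (allele id),
#'   and the simulation parameters.
#' @export
simulate_wgs_readpairs <- function(allele, depth = 30, read_length = 150L,
                                   fragment_mean = 400, fragment_sd = 60,
                                   error_rate = 0.001, seed = 1L) {
  al <- as_allele(allele)
  L <- nchar(al$sequence)
  stopifnot(depth > 0, fragment_mean >= 2 * read_length)
  if (L < fragment_mean + 4 * fragment_sd) {
    stop("allele too short for the requested fragment-length distribution")
  }
  n <- as.integer(round(depth * L / (2 * read_length)))
  with_seed(seed, {
    flen <- integer(n)
    need <- seq_len(n)
    while (length(need)) {  # truncated-normal rejection
      draw <- as.integer(round(rnorm(length(need), fragment_mean, fragment_sd)))
      ok <- draw >= 2L * read_length & draw <= L
      flen[need[ok]] <- draw[ok]
      need <- need[!ok]
    }
    fstart <- as.integer(floor(runif(n) * (L - flen + 1L)))  # 0-based
    r1 <- substring(al$sequence, fstart + 1L, fstart + read_length)
    r2 <- revcomp(substring(al$sequence, fstart + flen - read_length + 1L,
                            fstart + flen))
    if (error_rate > 0) {
      r1 <- add_substitution_errors(r1, error_rate)
      r2 <- add_substitution_errors(r2, error_rate)
    }
    structure(list(read1 = r1, read2 = r2, frag_start = fstart,
                   frag_len = flen, source = rep(al$id, n),
                   read_length = as.integer(read_length),
                   fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                   error_rate = error_rate, seed = as.integer(seed)),
              class = "ReadPairSet")
  })
}

# vectorized iid substitutions over a character vector of reads
add_substitution_errors <- function(reads, rate) {
  n <- length(reads)
  if (n == 0) return(reads)
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) <= 1)
  total <- sum(rl)
  hit <- which(runif(total) < rate)
  if (!length(hit)) return(reads)
  w <- rl[1]
  ri <- (hit - 1L) %/% w + 1L
  pos <- (hit - 1L) %% w + 1L
  for (k in seq_along(hit)) {
    old <- substr(reads[ri[k]], pos[k], pos[k])
    new <- sample(setdiff(DNA_BASES, old), 1L)
    substr(reads[ri[k]], pos[k], pos[k]) <- new
  }
  reads
}

#' @export
print.ReadPairSet <- function(x, ...) {
  cat(sprintf("ReadPairSet: %d pairs x %d bp from '%s' (insert %g+/-%g)\n",
              length(x$read1), x$read_length, x$source[1] %||% "?",
              x$fragment_mean, x$fragment_sd))
  invisible(x)
}

#' Concatenate read-pair sets (e.g. two haplotypes of a diploid sample)
#'
#' @param ... `ReadPairSet` objects with identical read lengths.
#' @return a combined `ReadPairSet`.
#' @export
combine_readpairs <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  rl <- unique(vapply(sets, `[[`, integer(1), "read_length"))
  stopifnot(length(rl) == 1)
  out <- sets[[1]]
  for (f in c("read1", "read2", "frag_start", "frag_len", "source")) {
    out[[f]] <- unlist(lapply(sets, `[[`, f), use.names = FALSE)
  }
  out
}

#' Simulate junction-spanning RNA-seq reads
#'
#' Draws single-end reads multinomially across labelled junction contexts at
#' the given proportions; every read fully contains its label's junction
#' k-mer. Used to emulate splice-isoform mixtures such as a 10:1 wild-type
#' (E2-E3) to aberrant (E2-E2) junction read ratio.
#'
#' @param junctions named character vector of junction context sequences; the
#'   junction itself must sit at the centre (the `2k`-mer spanning the
#'   midpoint is the junction k-mer).
#' @param proportions named numeric vector summing to 1 (names matching
#'   `junctions`).
#' @param n_reads total reads to draw.
#' @param read_length read length (default 50; must be at least the junction
#'   k-mer length and at most the context length).
#' @param k junction flank size (default 10: 20-mer junctions).
#' @param seed integer seed.
#' @return list with `reads` (character), `label` (factor of junction labels)
#'   and `kmers` (the per-label junction 2k-mers).
#' @export
simulate_rnaseq_reads <- function(junctions, proportions, n_reads,
                                  read_length = 50L, k = 10L, seed = 1L) {
  if (length(junctions) == 0) stop("empty junction label set")
  stopifnot(!is.null(names(junctions)),
            setequal(names(junctions), names(proportions)),
            abs(sum(proportions) - 1) < 1e-8)
  proportions <- proportions[names(junctions)]
  clen <- nchar(junctions)
  if (any(clen < read_length)) stop("junction context shorter than read length")
  mid <- clen %/% 2L
  kmers <- setNames(substring(junctions, mid - k + 1L, mid + k), names(junctions))
  with_seed(seed, {
    lab <- sample(names(junctions), n_reads, replace = TRUE, prob = proportions)
    # read must cover [mid-k, mid+k): start in [mid+k-read_length, mid-k]
    lo <- setNames(mid + k - read_length, names(junctions))
    hi <- setNames(mid - k, names(junctions))
    lo <- pmax(lo, 0L)
    start <- floor(runif(n_reads) * (hi[lab] - lo[lab] + 1L)) + lo[lab]
    reads <- substring(junctions[lab], start + 1L, start + read_length)
    list(reads = unname(reads), label = factor(lab, levels = names(junctions)),
         kmers = kmers)
  })
}

#' Default junction contexts for the duplicated-exon assay
#'
#' Builds the wild-type E2-E3 and aberrant E2-E2 junction contexts from a
#' locus gene model, each 50 bp of exon sequence on either side of the splice
#' junction. Their central 20-mers are the assay k-mers.
#'
#' @param locus a `LocusModel` with the default gene model.
#' @param flank context flank per side (default 50).
#' @return named character vector with elements `E2E3` and `E2E2`.
#' @export
default_junction_contexts <- function(locus, flank = 50L) {
  gm <- gene_model(locus)
  e2 <- gm$exon_seqs[["E2"]]; e3 <- gm$exon_seqs[["E3"]]
  c(E2E3 = paste0(substr(e2, nchar(e2) - flank + 1L, nchar(e2)),
                  substr(e3, 1L, flank)),
    E2E2 = paste0(substr(e2, nchar(e2) - flank + 1L, nchar(e2)),
                  substr(e2, 1L, flank)))
}

#' Write sequences to FASTA / reads to FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @param reads character vector of read sequences.
#' @param ids read names; default `read1..readN`.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  ids <- ids %||% sprintf("read%06d", seq_along(reads))
  x <- Biostrings::DNAStringSet(setNames(reads, ids))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a character vector of reads
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write paired FASTQ files for a ReadPairSet
#'
#' @param rps a `ReadPairSet`.
#' @param prefix output path prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written.
#' @return character vector of the two paths, invisibly.
#' @export
write_fastq_pair <- function(rps, prefix) {
  ids <- sprintf("pair%06d", seq_along(rps$read1))
  p1 <- paste0(prefix, "_1.fastq"); p2 <- paste0(prefix, "_2.fastq")
  write_fastq(rps$read1, p1, ids = ids)
  write_fastq(rps$read2, p2, ids = ids)
  invisible(c(p1, p2))
}
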