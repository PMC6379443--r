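#' Build an exact-seed reference index
#'
#' Hashes every k-mer of a locus-scale reference for seed lookup. Seeds vote
#' for (diagonal, strand) candidates; a local affine-gap extension places the
#' read, soft-clipping bases that do not extend (e.g. across a novel
#' junction).
#'
#' @param ref reference DNA string (or `LocusModel`).
#' @param k seed length (default 21).
#' @return a `RefIndex` object.
#' @export
reference_index <- function(ref, k = 21L) {
  if (inherits(ref, "LocusModel")) {
    nm <- ref$name; ref <- ref$sequence
  } else nm <- "ref"
  n <- nchar(ref) - k + 1L
  stopifnot(n > 0)
  dt <- data.table::data.table(kmer = substring(ref, 1:n, k:(n + k - 1L)),
                               pos = 0:(n - 1L))
  data.table::setkey(dt, kmer)
  structure(list(table = dt, ref = ref, k = as.integer(k), name = nm),
            class = "RefIndex")
}

#' @export
print.RefIndex <- function(x, ...) {
  cat(sprintf("RefIndex '%s': %d bp, k=%d\n", x$name, nchar(x$ref), x$k))
  invisible(x)
}

seed_candidates <- function(reads, index, max_candidates = 2L) {
  k <- index$k
  rl <- nchar(reads)
  stopifnot(length(unique(rl)) == 1)
  rl <- rl[1]
  if (rl < k) return(data.table::data.table())
  n_off <- min(5L, rl - k + 1L)
  offs <- unique(as.integer(round(seq(1L, rl - k + 1L, length.out = n_off))))
  rc <- revcomp(reads)
  mk <- function(seqs, strand) {
    data.table::data.table(
      read = rep(seq_along(seqs), times = length(offs)),
      strand = strand,
      kmer = as.vector(vapply(offs, function(o)
        substring(seqs, o, o + k - 1L), character(length(seqs)))),
      off = rep(offs, each = length(seqs)))
  }
  seeds <- rbind(mk(reads, "+"), mk(rc, "-"))
  hits <- index$table[seeds, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(hits)
  hits[, diag := pos - (off - 1L)]
  votes <- hits[, .N, by = .(read, strand, diag)]
  data.table::setorder(votes, read, -N, strand, diag)
  votes[, rank := seq_len(.N), by = read]
  votes[rank <= max_candidates]
}

#' Align reads to an indexed reference
#'
#' Seed-and-extend: exact seeds of length `k` vote for candidate
#' (diagonal, strand) placements; the top candidates are scored by local
#' affine-gap alignment (match +1, mismatch -4, gap open -6, gap extend -1)
#' over a padded window, and the best-scoring placement wins (ties: lowest
#' reference position, then forward strand). Reads with no seed hit are
#' reported unmapped.
#'
#' @param reads character vector of reads (equal length, A/C/G/T/N).
#' @param index a `RefIndex` from [reference_index()].
#' @param qname read names (default `read<i>`).
#' @param pad extension window padding beyond the read span (default 16).
#' @return data.table with one row per read: `qname`, `mapped`, `strand`,
#'   `pos`/`end` (0-based half-open reference span), `read_start`/`read_end`
#'   (aligned read span), `cigar` (S/M/I/D), `score`, `seq` (read oriented to
#'   the forward reference strand), `read_len`.
#' @export
align_reads <- function(reads, index, qname = NULL, pad = 16L) {
  stopifnot(inherits(index, "RefIndex"))
  n <- length(reads)
  qname <- qname %||% sprintf("read%06d", seq_len(n))
  rl <- nchar(reads[1])
  out <- data.table::data.table(
    qname = qname, mapped = FALSE, strand = "+",
    pos = NA_integer_, end = NA_integer_,
    read_start = NA_integer_, read_end = NA_integer_,
    cigar = NA_character_, score = 0L, seq = reads,
    read_len = nchar(reads))
  cand <- seed_candidates(reads, index)
  if (nrow(cand) == 0) return(out)
  oriented <- ifelse(cand$strand == "+", reads[cand$read],
                     revcomp(reads[cand$read]))
  res <- cpp_align_batch(oriented, index$ref,
                         as.integer(cand$diag - 1L - pad),
                         as.integer(cand$diag - 1L + rl + pad))
  cand[, `:=`(score = res$score, ref_start = res$ref_start,
              ref_end = res$ref_end, read_start = res$read_start,
              read_end = res$read_end, cigar = res$cigar, oseq = oriented)]
  cand <- cand[!is.na(ref_start)]
  if (nrow(cand) == 0) return(out)
  data.table::setorder(cand, read, -score, ref_start, strand)
  best <- cand[, .SD[1L], by = read]
  idx <- best$read
  out[idx, `:=`(mapped = TRUE, strand = best$strand, pos = best$ref_start,
                end = best$ref_end, read_start = best$read_start,
                read_end = best$read_end, cigar = best$cigar,
                score = best$score, seq = best$oseq)]
  out[]
}

#' Align one read pair
#'
#' @param index a `RefIndex`.
#' @param read1,read2 the two mate sequences (read 2 as sequenced, i.e.
#'   reverse-complement of the fragment 3' end).
#' @param fragment_mean,fragment_sd expected insert-size distribution used
#'   for the proper-pair flag (within mean +/- 4 sd, FR orientation).
#' @return a two-row alignment data.table (see [align_reads()]) with added
#'   pairing columns `first`, `mate_pos`, `tlen`, `proper`.
#' @export
align_read_pair <- function(index, read1, read2,
                            fragment_mean = 400, fragment_sd = 60) {
  a1 <- align_reads(read1, index, qname = "pair000001")
  a2 <- align_reads(read2, index, qname = "pair000001")
  pair_up(a1, a2, fragment_mean, fragment_sd)
}

pair_up <- function(a1, a2, fragment_mean, fragment_sd) {
  a1[, first := TRUE]; a2[, first := FALSE]
  a1[, `:=`(mate_pos = a2$pos, mate_strand = a2$strand, mate_mapped = a2$mapped)]
  a2[, `:=`(mate_pos = a1$pos, mate_strand = a1$strand, mate_mapped = a1$mapped)]
  both <- a1$mapped & a2$mapped
  lo <- pmin(a1$pos, a2$pos)
  hi <- pmax(a1$end, a2$end)
  mag <- hi - lo
  fr <- both & (a1$strand != a2$strand) &
    ifelse(a1$pos <= a2$pos, a1$strand == "+", a2$strand == "+")
  proper <- fr & mag >= fragment_mean - 4 * fragment_sd &
    mag <= fragment_mean + 4 * fragment_sd
  proper[is.na(proper)] <- FALSE
  t1 <- ifelse(both, ifelse(a1$pos <= a2$pos, mag, -mag), 0L)
  a1[, `:=`(tlen = as.integer(t1), proper = proper)]
  a2[, `:=`(tlen = as.integer(-t1), proper = proper)]
  rbind(a1, a2)
}

#' Align a simulated read-pair set
#'
#' Vectorized pairing wrapper around [align_reads()] for a `ReadPairSet`.
#'
#' @param rps a `ReadPairSet`.
#' @param index a `RefIndex` (or reference string / `LocusModel`, indexed on
#'   the fly).
#' @param fragment_mean,fragment_sd insert-size distribution for proper-pair
#'   flags; defaults taken from the read set.
#' @return alignment data.table with two rows per pair.
#' @export
align_readpair_set <- function(rps, index, fragment_mean = NULL,
                               fragment_sd = NULL) {
  if (!inherits(index, "RefIndex")) index <- reference_index(index)
  fragment_mean <- fragment_mean %||% rps$fragment_mean
  fragment_sd <- fragment_sd %||% rps$fragment_sd
  qn <- sprintf("pair%06d", seq_along(rps$read1))
  a1 <- align_reads(rps$read1, index, qname = qn)
  a2 <- align_reads(rps$read2, index, qname = qn)
  pair_up(a1, a2, fragment_mean, fragment_sd)
}

cigar_ref_span <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDS]", cg))[[1]]
    sum(lens[ops %in% c("M", "D")])
  }, integer(1), USE.NAMES = FALSE)
}

cigar_clips <- function(cigar) {
  left <- integer(length(cigar)); right <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    cg <- cigar[i]
    if (is.na(cg)) { left[i] <- NA_integer_; right[i] <- NA_integer_; next }
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDS]", cg))[[1]]
    left[i] <- if (ops[1] == "S") lens[1] else 0L
    right[i] <- if (ops[length(ops)] == "S") lens[length(lens)] else 0L
  }
  data.table::data.table(left = left, right = right)
}

#' Write / read SAM text
#'
#' Minimal SAM 1.6 serialization of an alignment table: header with one @SQ
#' line, records with flags, 1-based POS, CIGAR, TLEN and the oriented
#' sequence. Only the columns this pipeline uses are preserved.
#'
#' @param aln alignment data.table from [align_readpair_set()].
#' @param path output file.
#' @param rname,rlen reference name and length for the @SQ line.
#' @return `path` invisibly (`write_sam`); an alignment data.table
#'   (`read_sam`).
#' @export
write_sam <- function(aln, path, rname = "ref", rlen = 0L) {
  flag <- 1L +
    ifelse(aln$proper %||% FALSE, 2L, 0L) +
    ifelse(!aln$mapped, 4L, 0L) +
    ifelse(!(aln$mate_mapped %||% TRUE), 8L, 0L) +
    ifelse(aln$mapped & aln$strand == "-", 16L, 0L) +
    ifelse((aln$mate_mapped %||% FALSE) & aln$mate_strand == "-", 32L, 0L) +
    ifelse(aln$first, 64L, 128L)
  lines <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", rname, rlen),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t*",
            aln$qname, flag,
            ifelse(aln$mapped, rname, "*"),
            ifelse(aln$mapped, aln$pos + 1L, 0L),
            ifelse(aln$mapped, 60L, 0L),
            ifelse(aln$mapped, aln$cigar, "*"),
            ifelse(aln$mate_mapped %||% FALSE, "=", "*"),
            ifelse(aln$mate_mapped %||% FALSE, aln$mate_pos + 1L, 0L),
            aln$tlen %||% 0L, aln$seq))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  f <- data.table::tstrsplit(body, "\t")
  flag <- as.integer(f[[2]])
  mapped <- bitwAnd(flag, 4L) == 0L
  cigar <- ifelse(mapped, f[[6]], NA_character_)
  pos <- ifelse(mapped, as.integer(f[[4]]) - 1L, NA_integer_)
  clips <- cigar_clips(cigar)
  rl <- nchar(f[[10]])
  aln <- data.table::data.table(
    qname = f[[1]], mapped = mapped,
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    pos = pos, end = pos + cigar_ref_span(cigar),
    read_start = clips$left, read_end = rl - clips$right,
    cigar = cigar, score = NA_integer_, seq = f[[10]], read_len = rl,
    first = bitwAnd(flag, 64L) > 0L,
    mate_pos = ifelse(bitwAnd(flag, 8L) == 0L, as.integer(f[[8]]) - 1L,
                      NA_integer_),
    mate_strand = ifelse(bitwAnd(flag, 32L) > 0L, "-", "+"),
    mate_mapped = bitwAnd(flag, 8L) == 0L,
    tlen = as.integer(f[[9]]),
    proper = bitwAnd(flag, 2L) > 0L)
  aln
}
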