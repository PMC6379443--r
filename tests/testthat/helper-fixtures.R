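# Shared end-to-end fixtures, computed once per test run. The IDFL-like
# fixture is the packaged stated world: default locus (seed 1), homozygous
# deletion+duplication allele, 30x 150-bp PE reads (insert 400 +/- 60,
# error 0.1%), aligned with the built-in aligner.
.fx <- new.env(parent = emptyenv())

fixture_locus <- function() {
  if (is.null(.fx$locus)) {
    .fx$locus <- build_locus(default_locus_config(1))
    .fx$alleles <- idfl_alleles(.fx$locus)
    .fx$idx <- reference_index(.fx$locus)
  }
  list(locus = .fx$locus, alleles = .fx$alleles, idx = .fx$idx)
}

fixture_idfl <- function() {
  fl <- fixture_locus()
  if (is.null(.fx$aln_idfl)) {
    rps <- simulate_wgs_readpairs(fl$alleles$idfl, depth = 30, seed = 101)
    .fx$rps_idfl <- rps
    .fx$aln_idfl <- align_readpair_set(rps, fl$idx)
  }
  c(fl, list(rps = .fx$rps_idfl, aln = .fx$aln_idfl))
}

fixture_wt <- function() {
  fl <- fixture_locus()
  if (is.null(.fx$aln_wt)) {
    rps <- simulate_wgs_readpairs(fl$alleles$wt, depth = 30, seed = 101)
    .fx$rps_wt <- rps
    .fx$aln_wt <- align_readpair_set(rps, fl$idx)
  }
  c(fl, list(rps = .fx$rps_wt, aln = .fx$aln_wt))
}

# mock coverage profile from a ratio vector
mock_profile <- function(ratio, window_size = 500L) {
  n <- length(ratio)
  structure(list(window_size = window_size,
                 start = (seq_len(n) - 1L) * window_size,
                 end = seq_len(n) * window_size,
                 depth = ratio, ratio = ratio,
                 normalizer_value = 1, flagged = FALSE),
            class = "CoverageProfile")
}

# brute-force elevated-block oracle: maximal [i,j] with elevated endpoints,
# all internal sub-threshold runs <= max_gap, spanning >= min_windows
oracle_blocks <- function(ratio, threshold, min_windows, max_gap) {
  el <- !is.na(ratio) & ratio >= threshold
  n <- length(el)
  ok <- function(i, j) {
    if (!el[i] || !el[j]) return(FALSE)
    r <- rle(el[i:j])
    all(r$lengths[!r$values] <= max_gap)
  }
  blocks <- list()
  for (i in seq_len(n)) for (j in i:n) {
    if (!ok(i, j)) next
    maximal <- (i == 1 || !ok(i - 1, j)) && (j == n || !ok(i, j + 1))
    # extension candidates may skip over gaps: check any larger valid span
    if (maximal) {
      wider <- FALSE
      for (a in seq_len(i)) for (b in j:n) {
        if ((a < i || b > j) && ok(a, b)) wider <- TRUE
      }
      if (!wider && j - i + 1L >= min_windows) {
        blocks[[length(blocks) + 1L]] <- c(i, j)
      }
    }
  }
  blocks
}

# local ungapped alignment oracle: best Kadane segment score at every offset
# and strand; valid as a Smith-Waterman-scored scan for substitution-only
# reads (gap moves cost >= 7 and never improve these instances)
oracle_best_position <- function(read, ref, match = 1, mismatch = -4) {
  rl <- nchar(read)
  L <- nchar(ref)
  refc <- strsplit(ref, "")[[1]]
  best <- -Inf; best_pos <- NA_integer_; best_strand <- NA_character_
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") read else revcomp(read)
    rc <- strsplit(rd, "")[[1]]
    for (o in 0:(L - rl)) {
      x <- ifelse(rc == refc[(o + 1):(o + rl)], match, mismatch)
      s <- cumsum(x)
      sc <- max(s - cummin(c(0, s[-rl])))
      if (sc > best) { best <- sc; best_pos <- o; best_strand <- strand }
    }
  }
  list(score = best, pos = best_pos, strand = best_strand)
}

# one-pass inheritance-filter predicate oracle
oracle_filter_predicate <- function(tbl, affected, background, exonic,
                                    min_avg_depth = 10) {
  samples <- attr(tbl, "samples")
  ac <- function(g) c("0/0" = 0, "0/1" = 1, "1/1" = 2, "1/2" = 2,
                      "./." = NA)[g]
  keep <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    gts <- vapply(samples, function(s) tbl[[paste0("gt.", s)]][i], "")
    dps <- vapply(samples, function(s) tbl[[paste0("dp.", s)]][i], 0L)
    aff <- ac(gts[affected]); oth <- ac(gts[setdiff(samples, affected)])
    in_bg <- !is.null(background) && nrow(background) > 0 &&
      paste(tbl$pos[i], tbl$ref[i], tbl$alt[i]) %in%
      paste(background$pos, background$ref, background$alt)
    span_end <- tbl$pos[i] + nchar(tbl$ref[i])
    exonic_hit <- !is.null(exonic) &&
      any(tbl$pos[i] < exonic$end & span_end > exonic$start)
    keep[i] <- !grepl(",", tbl$alt[i], fixed = TRUE) &&
      !anyNA(c(aff, oth)) && mean(dps) >= min_avg_depth &&
      aff > max(oth) && !in_bg && exonic_hit
  }
  keep
}
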