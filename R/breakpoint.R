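#' Classify read pairs by structural-variant signature
#'
#' In an FR library: a pair within the expected insert range is `proper`;
#' an outward-facing pair (leftmost mate reverse, rightmost forward) is the
#' tandem-duplication signature `everted_dup`; an FR pair with template
#' longer than mean + 4 sd suggests a deletion (`long_insert_del`); mates on
#' the same strand suggest an inversion (`same_strand_inv`); pairs with an
#' unmapped mate are `unpaired`.
#'
#' @param aln alignment data.table with two rows per pair (columns `qname`,
#'   `mapped`, `strand`, `pos`, `end`, `first`).
#' @param fragment_mean,fragment_sd insert-size distribution.
#' @return data.table with one row per pair: `qname`, `label`.
#' @export
classify_read_pairs <- function(aln, fragment_mean = 400, fragment_sd = 60) {
  a1 <- aln[aln$first == TRUE, ]
  a2 <- aln[aln$first == FALSE, ]
  data.table::setkey(a1, qname); data.table::setkey(a2, qname)
  a2 <- a2[a1$qname]
  lab <- rep("unpaired", nrow(a1))
  both <- a1$mapped & a2$mapped
  lo_pos <- pmin(a1$pos, a2$pos)
  hi_end <- pmax(a1$end, a2$end)
  mag <- hi_end - lo_pos
  left_strand <- ifelse(a1$pos <= a2$pos, a1$strand, a2$strand)
  right_strand <- ifelse(a1$pos <= a2$pos, a2$strand, a1$strand)
  same <- both & a1$strand == a2$strand
  everted <- both & !same & left_strand == "-" & right_strand == "+"
  fr <- both & !same & left_strand == "+" & right_strand == "-"
  hi_t <- fragment_mean + 4 * fragment_sd
  lab[same] <- "same_strand_inv"
  lab[everted] <- "everted_dup"
  lab[fr & mag > hi_t] <- "long_insert_del"
  lab[fr & mag <= hi_t] <- "proper"
  data.table::data.table(qname = a1$qname, label = lab)
}

#' Classify one read pair
#'
#' @param rec1,rec2 single-row alignment records of the two mates.
#' @inheritParams classify_read_pairs
#' @return the pair label as a character scalar.
#' @export
classify_read_pair <- function(rec1, rec2, fragment_mean = 400,
                               fragment_sd = 60) {
  rec1 <- data.table::as.data.table(rec1); rec1[, first := TRUE]
  rec2 <- data.table::as.data.table(rec2); rec2[, first := FALSE]
  rec1[, qname := "p"]; rec2[, qname := "p"]
  classify_read_pairs(rbind(rec1, rec2, fill = TRUE),
                      fragment_mean, fragment_sd)$label
}

#' Recruit breakpoint candidate reads
#'
#' Alignments with >= `min_clip` soft-clipped bases, plus both mates of
#' everted pairs; sequences are returned oriented to the forward reference
#' strand (as aligned), so a single-strand assembly suffices.
#'
#' @param aln alignment data.table.
#' @param min_clip minimum soft-clip length (default 20).
#' @param fragment_mean,fragment_sd insert-size distribution for pair
#'   classification.
#' @return character vector of candidate read sequences.
#' @export
recruit_junction_reads <- function(aln, min_clip = 20L,
                                   fragment_mean = 400, fragment_sd = 60) {
  m <- aln[aln$mapped, ]
  clips <- cigar_clips(m$cigar)
  clipped <- m[clips$left >= min_clip | clips$right >= min_clip, ]
  cls <- classify_read_pairs(aln, fragment_mean, fragment_sd)
  ev <- cls[cls$label == "everted_dup", qname]
  everted <- m[m$qname %in% ev, ]
  unique(c(clipped$seq, everted$seq))
}

#' Assemble the breakpoint junction contig
#'
#' Minimal de Bruijn assembly of candidate reads: k-mers with count 1 are
#' dropped when >= 10 reads are available (error pruning); the maximal
#' unambiguous path (unitig) through the most frequent k-mer is extracted,
#' then its two flanks are anchored on the reference by maximal exact
#' prefix/suffix matches to place the breakpoints. The reported breakpoint
#' pair is the left-aligned (smallest `e`) representative within the
#' microhomology ambiguity range.
#'
#' @param cand_reads character vector of candidate read sequences (oriented;
#'   see [recruit_junction_reads()]).
#' @param ref reference sequence string.
#' @param k odd k-mer size (default 31; reduced automatically for short read
#'   sets).
#' @param min_support minimum number of candidate reads (default 3).
#' @return a `BreakpointJunction`: list with `status` ("ok", "no_junction" or
#'   "ambiguous"), and for "ok": `contig`, `left_break` (e), `right_break`
#'   (s), `orientation`, `microhomology_left`, `microhomology_right`,
#'   `mh_total`, `inserted_sequence`, `support`.
#' @export
assemble_junction <- function(cand_reads, ref, k = 31L, min_support = 3L) {
  fail <- function(status) structure(list(status = status),
                                     class = "BreakpointJunction")
  if (length(cand_reads) < min_support) return(fail("no_junction"))
  k <- as.integer(min(k, min(nchar(cand_reads)) - 4L))
  if (k %% 2L == 0L) k <- k - 1L
  if (k < 11L) return(fail("no_junction"))

  kmers <- unlist(lapply(cand_reads, function(s) {
    n <- nchar(s) - k + 1L
    if (n < 1) return(character())
    substring(s, 1:n, k:(n + k - 1L))
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  tab <- table(kmers)
  if (length(cand_reads) >= 10L) tab <- tab[tab > 1L]
  if (length(tab) == 0) return(fail("no_junction"))
  kset <- new.env(hash = TRUE, parent = emptyenv())
  for (km in names(tab)) assign(km, tab[[km]], envir = kset)

  succ <- function(km) {
    nxt <- paste0(substr(km, 2L, k), DNA_BASES)
    nxt[vapply(nxt, exists, logical(1), envir = kset)]
  }
  pred <- function(km) {
    prv <- paste0(DNA_BASES, substr(km, 1L, k - 1L))
    prv[vapply(prv, exists, logical(1), envir = kset)]
  }
  # junction-crossing k-mers are novel: absent from the reference. Each
  # novel-k-mer graph component seeds one unitig (an edited locus can carry
  # several junctions, e.g. the on-target deletion plus a bystander
  # duplication).
  nr <- nchar(ref) - k + 1L
  ref_kmers <- new.env(hash = TRUE, parent = emptyenv())
  for (km in substring(ref, 1:nr, k:(nr + k - 1L))) assign(km, TRUE, ref_kmers)
  cnts <- as.integer(tab)
  novel <- names(tab)[!vapply(names(tab), exists, logical(1),
                              envir = ref_kmers)]
  if (!length(novel)) return(fail("no_junction"))
  novel <- novel[order(-cnts[match(novel, names(tab))], novel)]

  used <- new.env(hash = TRUE, parent = emptyenv())
  junctions <- list()
  any_branch <- FALSE
  for (start in novel) {
    if (exists(start, envir = used)) next
    contig <- start
    cur <- start
    branched <- FALSE
    for (step in seq_len(100000L)) {
      nx <- succ(cur)
      if (length(nx) != 1L) { branched <- branched || length(nx) > 1L; break }
      if (length(pred(nx)) != 1L) { branched <- TRUE; break }
      contig <- paste0(contig, substr(nx, k, k))
      cur <- nx
    }
    cur <- start
    for (step in seq_len(100000L)) {
      pv <- pred(cur)
      if (length(pv) != 1L) { branched <- branched || length(pv) > 1L; break }
      if (length(succ(pv)) != 1L) { branched <- TRUE; break }
      contig <- paste0(substr(pv, 1L, 1L), contig)
      cur <- pv
    }
    nc <- nchar(contig) - k + 1L
    for (km in substring(contig, 1:nc, k:(nc + k - 1L))) {
      assign(km, TRUE, envir = used)
    }
    any_branch <- any_branch || branched
    placed <- place_junction(contig, ref, anchor_k = min(21L, k))
    if (is.null(placed) || placed$whole) next
    e <- placed$e; s <- placed$s
    if (s == e) next
    orientation <- if (s < e) "tandem_duplication" else "deletion"
    mh <- scan_microhomology(ref, e, s, orientation)
    jk <- paste0(substr0(ref, e - 10L, e), substr0(ref, s, s + 10L))
    support <- sum(vapply(cand_reads, function(r)
      grepl(jk, r, fixed = TRUE) || grepl(jk, revcomp(r), fixed = TRUE),
      logical(1)))
    junctions[[length(junctions) + 1L]] <- structure(
      list(status = "ok", contig = contig,
           left_break = e, right_break = s, orientation = orientation,
           microhomology_left = mh$left, microhomology_right = mh$right,
           mh_total = mh$total, mh_range = placed$mh_range,
           inserted_sequence = placed$inserted, support = support),
      class = "BreakpointJunction")
  }
  if (!length(junctions)) {
    return(fail(if (any_branch) "ambiguous" else "no_junction"))
  }
  # drop duplicate placements, keep the best-supported representative
  key <- vapply(junctions, function(j)
    paste(j$left_break, j$right_break, j$orientation), character(1))
  junctions <- junctions[!duplicated(key)]
  ord <- order(-vapply(junctions, function(j) as.numeric(j$support), 0),
               vapply(junctions, function(j) as.numeric(j$left_break), 0))
  junctions <- junctions[ord]
  primary <- junctions[[1L]]
  attr(primary, "all_junctions") <- junctions
  primary
}

#' All junctions assembled from a candidate read set
#'
#' @param junction result of [assemble_junction()].
#' @return list of `BreakpointJunction`s (the primary first), or an empty
#'   list when assembly failed.
#' @export
all_junctions <- function(junction) {
  if (junction$status != "ok") return(list())
  attr(junction, "all_junctions") %||% list(junction)
}

#' @export
print.BreakpointJunction <- function(x, ...) {
  if (x$status != "ok") {
    cat("BreakpointJunction:", x$status, "\n")
  } else {
    cat(sprintf(
      "BreakpointJunction: %s e=%d s=%d mh=%d+%d support=%d contig=%d bp\n",
      x$orientation, x$left_break, x$right_break, x$microhomology_left,
      x$microhomology_right, x$support, nchar(x$contig)))
  }
  invisible(x)
}

# anchor the contig flanks on the reference by maximal exact prefix/suffix
# extension from a seed k-mer hit; left-aligned breakpoint representative.
place_junction <- function(contig, ref, anchor_k = 21L) {
  anchor_k <- as.integer(anchor_k)
  clen <- nchar(contig)
  if (clen < 2L * anchor_k) return(NULL)
  find_all <- function(pat) {
    g <- gregexpr(pat, ref, fixed = TRUE)[[1]]
    if (g[1] == -1L) integer() else as.integer(g) - 1L  # 0-based
  }
  # longest prefix of contig matching ref
  occ <- find_all(substr(contig, 1L, anchor_k))
  if (!length(occ)) return(NULL)
  best_p <- 0L; best_end <- NA_integer_
  for (o in occ) {
    p <- anchor_k
    while (p < clen && o + p < nchar(ref) &&
           substr(contig, p + 1L, p + 1L) == substr(ref, o + p + 1L, o + p + 1L))
      p <- p + 1L
    if (p > best_p) { best_p <- p; best_end <- o + p }
  }
  if (best_p == clen) {
    return(list(whole = TRUE))
  }
  occ2 <- find_all(substr(contig, clen - anchor_k + 1L, clen))
  if (!length(occ2)) return(NULL)
  best_q <- 0L; best_start <- NA_integer_
  for (o in occ2) {
    rs <- o + anchor_k  # ref end (exclusive) of the anchored suffix seed
    q <- anchor_k
    while (q < clen && (rs - q) > 0L &&
           substr(contig, clen - q, clen - q) == substr(ref, rs - q, rs - q))
      q <- q + 1L
    if (q > best_q) { best_q <- q; best_start <- rs - q }
  }
  p <- best_p                    # contig[0, p) maps to ref ending at best_end
  qpos <- clen - best_q          # contig[qpos, clen) maps to ref from best_start
  if (p >= qpos) {               # overlap = microhomology ambiguity
    m <- p - qpos
    list(whole = FALSE, e = best_end - m, s = best_start, mh_range = m,
         inserted = "")
  } else {
    list(whole = FALSE, e = best_end, s = best_start + (qpos - p), mh_range = 0L,
         inserted = substr(contig, p + 1L, qpos))
  }
}

#' Scan breakpoint microhomology
#'
#' For a junction that joins reference position `e` (sequence ends here) to
#' position `s` (sequence resumes here): the left microhomology is the
#' largest m with `ref[e-m, e) == ref[s-m, s)` and the right microhomology
#' the largest m with `ref[e, e+m) == ref[s, s+m)`. The total (left + right)
#' is the breakpoint ambiguity range.
#'
#' @param ref reference string.
#' @param e,s 0-based breakpoint coordinates (for a tandem duplication,
#'   `s < e`).
#' @param orientation junction orientation (annotation only).
#' @param max_m scan cap (default 200).
#' @return list with `left`, `right`, `total`.
#' @export
scan_microhomology <- function(ref, e, s, orientation = "tandem_duplication",
                               max_m = 200L) {
  L <- nchar(ref)
  if (s == e) stop("degenerate junction: s == e")
  if (s < 0 || e < 0 || s > L || e > L) stop("breakpoint out of range")
  left <- 0L
  while (left < max_m && e - left - 1L >= 0L && s - left - 1L >= 0L &&
         substr(ref, e - left, e - left) == substr(ref, s - left, s - left))
    left <- left + 1L
  right <- 0L
  while (right < max_m && e + right + 1L <= L && s + right + 1L <= L &&
         substr(ref, e + right + 1L, e + right + 1L) ==
         substr(ref, s + right + 1L, s + right + 1L))
    right <- right + 1L
  list(left = left, right = right, total = left + right)
}

#' Scan for extended homology between cut site and junction
#'
#' Reports all maximal exact matches of length >= `min_len` between the
#' window around the Cas9 cut site and the windows around each junction
#' breakpoint, on both strands. An empty result is the "no extended
#' homology" outcome. When the cut-site and breakpoint windows overlap on
#' the reference, identical-coordinate self-matches are excluded.
#'
#' @param ref reference string.
#' @param cut_site 0-based blunt-cut coordinate.
#' @param e,s junction breakpoints.
#' @param window half-window size in bp (default 200).
#' @param min_len minimum match length (default 10).
#' @return data.table with columns `anchor` ("e" or "s"), `strand`,
#'   `cut_window_pos`, `junction_window_pos` (0-based reference coords of
#'   match starts; for "-" strand the junction coordinate refers to the plus
#'   strand of the matched segment), `length`.
#' @export
scan_extended_homology <- function(ref, cut_site, e, s, window = 200L,
                                   min_len = 10L) {
  L <- nchar(ref)
  clip <- function(a, b) {
    if (a < 0 || b > L) warning("homology window truncated to sequence bounds")
    c(max(0L, a), min(L, b))
  }
  aw <- clip(cut_site - window, cut_site + window)
  A <- substr0(ref, aw[1], aw[2])
  out <- list()
  for (anchor in c("e", "s")) {
    pos0 <- if (anchor == "e") e else s
    bw <- clip(pos0 - window, pos0 + window)
    B <- substr0(ref, bw[1], bw[2])
    for (strand in c("+", "-")) {
      Bs <- if (strand == "+") B else revcomp(B)
      mm <- maximal_exact_matches(A, Bs, min_len)
      if (nrow(mm)) {
        bpos <- if (strand == "+") bw[1] + mm$b else
          bw[1] + (nchar(B) - (mm$b + mm$len))
        hits <- data.table::data.table(
          anchor = anchor, strand = strand,
          cut_window_pos = aw[1] + mm$a,
          junction_window_pos = bpos, length = mm$len)
        if (strand == "+") {
          hits <- hits[cut_window_pos != junction_window_pos]
        }
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) {
    return(data.table::data.table(anchor = character(), strand = character(),
                                  cut_window_pos = integer(),
                                  junction_window_pos = integer(),
                                  length = integer()))
  }
  res <- unique(data.table::rbindlist(out))
  data.table::setorder(res, anchor, strand, cut_window_pos)
  res[]
}

# all maximal exact matches of length >= min_len between strings A and B
# (0-based offsets a, b). Seeded on min_len-mers of B, extended to maximal,
# deduplicated by diagonal extent.
maximal_exact_matches <- function(A, B, min_len) {
  na <- nchar(A); nb <- nchar(B)
  empty <- data.table::data.table(a = integer(), b = integer(), len = integer())
  if (na < min_len || nb < min_len) return(empty)
  bk <- substring(B, 1:(nb - min_len + 1L), min_len:nb)
  bdt <- data.table::data.table(kmer = bk, b = 0:(nb - min_len))
  ak <- substring(A, 1:(na - min_len + 1L), min_len:na)
  adt <- data.table::data.table(kmer = ak, a = 0:(na - min_len))
  hits <- bdt[adt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(empty)
  # keep one seed per diagonal run: extend each to its maximal match
  hits[, diag := a - b]
  res <- hits[, {
    keep <- list()
    seen_end <- -1L
    for (i in order(a)) {
      ai <- a[i]; bi <- b[i]
      if (ai < seen_end) next  # inside the previous maximal match
      s0 <- ai; t0 <- bi
      while (s0 > 0L && t0 > 0L &&
             substr(A, s0, s0) == substr(B, t0, t0)) { s0 <- s0 - 1L; t0 <- t0 - 1L }
      len <- min_len
      while (ai + len < na && bi + len < nb &&
             substr(A, ai + len + 1L, ai + len + 1L) ==
             substr(B, bi + len + 1L, bi + len + 1L)) len <- len + 1L
      seen_end <- ai + len
      keep[[length(keep) + 1L]] <- data.table::data.table(
        a = s0, b = t0, len = len + (ai - s0))
    }
    data.table::rbindlist(keep)
  }, by = diag][, diag := NULL]
  unique(res[len >= min_len])
}
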