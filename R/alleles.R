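#' Edit specifications
#'
#' @param kind `"deletion"` or `"tandem_duplication"`.
#' @param start,end 0-based half-open span of the edit, in the coordinates of
#'   the sequence the edit is applied to.
#' @param margin_indel signed bp adjustment at the deletion margin (shifts the
#'   deleted span's end), emulating founder lines that differ by a few
#'   nucleotides at the margins of the deletion. Deletions only.
#' @param planted_microhomology c(left, right) bp of microhomology expected at
#'   a duplication junction (annotation only; planting is done on the locus).
#' @return an `EditSpec` object.
#' @export
edit_spec <- function(kind = c("deletion", "tandem_duplication"),
                      start, end, margin_indel = 0L,
                      planted_microhomology = c(0L, 0L)) {
  kind <- match.arg(kind)
  start <- as.integer(start); end <- as.integer(end)
  if (!(start >= 0 && start <= end)) stop("need 0 <= start <= end")
  if (margin_indel != 0L && kind != "deletion") {
    stop("margin_indel applies only to deletions")
  }
  structure(list(kind = kind, start = start, end = end,
                 margin_indel = as.integer(margin_indel),
                 planted_microhomology = as.integer(planted_microhomology)),
            class = "EditSpec")
}

as_allele <- function(x) {
  if (inherits(x, "AlleleSequence")) return(x)
  if (inherits(x, "LocusModel")) {
    n <- nchar(x$sequence)
    return(structure(list(id = paste0(x$name, ":ref"), sequence = x$sequence,
                          edits = list(),
                          liftover = if (n) 0:(n - 1L) else integer()),
                     class = "AlleleSequence"))
  }
  if (is.character(x) && length(x) == 1) {
    check_dna(x)
    n <- nchar(x)
    return(structure(list(id = "allele", sequence = x, edits = list(),
                          liftover = if (n) 0:(n - 1L) else integer()),
                     class = "AlleleSequence"))
  }
  stop("cannot coerce to AlleleSequence")
}

#' @export
print.AlleleSequence <- function(x, ...) {
  cat(sprintf("AlleleSequence '%s': %d bp, %d edit(s)\n",
              x$id, nchar(x$sequence), length(x$edits)))
  invisible(x)
}

#' Apply a deletion to a locus or allele
#'
#' Removes `[start, end + margin_indel)` from the input sequence. The
#' liftover of the result maps every retained base to its reference
#' coordinate (composing with any existing liftover).
#'
#' @param x a `LocusModel`, `AlleleSequence`, or DNA string.
#' @param edit an `EditSpec` with `kind == "deletion"`.
#' @return an `AlleleSequence`.
#' @export
apply_deletion <- function(x, edit) {
  stopifnot(inherits(edit, "EditSpec"), edit$kind == "deletion")
  al <- as_allele(x)
  L <- nchar(al$sequence)
  start <- edit$start
  end <- edit$end + edit$margin_indel
  if (end < start) end <- start
  if (start == end) {
    out <- al
  } else {
    check_interval(start, end, L, "deletion")
    keep <- c(seq_len(start), if (end < L) (end + 1L):L)
    out <- al
    out$sequence <- paste0(substr0(al$sequence, 0L, start),
                           substr0(al$sequence, end, L))
    out$liftover <- al$liftover[keep]
  }
  out$edits <- c(al$edits, list(edit))
  out$id <- paste0(al$id, "+del")
  out
}

#' Apply a tandem duplication to a locus or allele
#'
#' Repeats `[start, end)` head-to-tail: the result is
#' `in[0, end) + in[start, L)`. The novel junction joins position `end` back
#' to position `start`; the 20-mer centred on the junction is
#' `in[end-10, end) + in[start, start+10)`.
#'
#' @inheritParams apply_deletion
#' @param edit an `EditSpec` with `kind == "tandem_duplication"`, in the
#'   coordinates of the input sequence.
#' @return an `AlleleSequence`.
#' @export
apply_tandem_duplication <- function(x, edit) {
  stopifnot(inherits(edit, "EditSpec"), edit$kind == "tandem_duplication")
  al <- as_allele(x)
  L <- nchar(al$sequence)
  start <- edit$start; end <- edit$end
  check_interval(start, end, L, "duplication")
  out <- al
  out$sequence <- paste0(substr0(al$sequence, 0L, end),
                         substr0(al$sequence, start, L))
  idx <- c(seq_len(end), (start + 1L):L)
  out$liftover <- al$liftover[idx]
  out$edits <- c(al$edits, list(edit))
  out$id <- paste0(al$id, "+dup")
  out
}

#' Reference positions mapping to an allele position, and back
#'
#' `allele_to_ref` returns the reference coordinate of an allele position
#' (`NA` for novel bases); `ref_to_allele` returns every allele position
#' whose liftover equals the given reference position (two for positions
#' inside a duplicated span).
#'
#' @param allele an `AlleleSequence`.
#' @param pos 0-based position(s).
#' @return integer vector of 0-based positions.
#' @export
allele_to_ref <- function(allele, pos) allele$liftover[pos + 1L]

#' @rdname allele_to_ref
#' @export
ref_to_allele <- function(allele, pos) which(allele$liftover == pos) - 1L

#' Construct the default edited alleles
#'
#' Builds the wild-type, enhancer-deletion (EDEL) and deletion-plus-linked-
#' duplication (IDFL-like) haplotypes of a locus. The duplication span is the
#' locus annotation `dup_span` expressed in deletion-allele coordinates, i.e.
#' the duplicated segment starts immediately downstream of the deleted
#' enhancer and spans 24 kb by default.
#'
#' @param locus a `LocusModel` (default configuration expected to carry
#'   `enhancer` and `dup_span`).
#' @param margin_indel optional signed bp perturbation of the deletion margin.
#' @return list with elements `wt`, `edel`, `idfl` (AlleleSequence) and
#'   `truth` (reference-coordinate truth: deletion span, duplication span,
#'   planted microhomology).
#' @export
idfl_alleles <- function(locus, margin_indel = 0L) {
  stopifnot(inherits(locus, "LocusModel"),
            !is.null(locus$enhancer), !is.null(locus$dup_span))
  del <- edit_spec("deletion", locus$enhancer[1], locus$enhancer[2],
                   margin_indel = margin_indel)
  wt <- as_allele(locus); wt$id <- "wt"
  edel <- apply_deletion(locus, del); edel$id <- "edel"
  del_len <- (locus$enhancer[2] + margin_indel) - locus$enhancer[1]
  dup_start_on_edel <- locus$dup_span[1] - del_len
  dup_end_on_edel <- locus$dup_span[2] - del_len
  dup <- edit_spec("tandem_duplication", dup_start_on_edel, dup_end_on_edel,
                   planted_microhomology = locus$mh_planted)
  idfl <- apply_tandem_duplication(edel, dup); idfl$id <- "idfl"
  list(wt = wt, edel = edel, idfl = idfl,
       truth = list(
         deletion = c(locus$enhancer[1], locus$enhancer[2] + margin_indel),
         duplication = locus$dup_span,
         microhomology = locus$mh_planted,
         cut_sites = locus$cut_sites))
}
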