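#' Windowed coverage profile
#'
#' Per-window depth = aligned (non-clipped) reference bases overlapping the
#' window divided by the window size; the ratio track divides depth by a
#' normalizer, by default the sample's own median window depth (robust when
#' the copy-gain event occupies a minority of the locus), optionally a
#' matched control profile to mirror a case-vs-control comparison.
#'
#' @param aln alignment data.table (mapped rows are used).
#' @param ref_length reference length in bp.
#' @param window_size window width in bp (default 500).
#' @param normalizer `"median"` or `"control"`.
#' @param control a `CoverageProfile` of a control sample (same windows)
#'   when `normalizer = "control"`.
#' @return a `CoverageProfile`: list with `window_size`, `start`, `end`,
#'   `depth`, `ratio`, `normalizer_value`, `flagged` (TRUE when no aligned
#'   reads).
#' @export
compute_coverage_profile <- function(aln, ref_length, window_size = 500L,
                                     normalizer = c("median", "control"),
                                     control = NULL) {
  normalizer <- match.arg(normalizer)
  stopifnot(window_size >= 1)
  ws <- as.integer(window_size)
  starts <- seq(0L, ref_length - 1L, by = ws)
  ends <- pmin(starts + ws, ref_length)
  m <- aln[aln$mapped & !is.na(aln$pos), ]
  if (nrow(m) == 0) {
    prof <- list(window_size = ws, start = starts, end = ends,
                 depth = rep(0, length(starts)),
                 ratio = rep(NA_real_, length(starts)),
                 normalizer_value = NA_real_, flagged = TRUE)
    class(prof) <- "CoverageProfile"
    return(prof)
  }
  cov <- IRanges::coverage(IRanges::IRanges(start = m$pos + 1L, end = m$end),
                           width = ref_length)
  sums <- IRanges::viewSums(IRanges::Views(cov, start = starts + 1L,
                                           end = ends))
  depth <- as.numeric(sums) / ws
  norm <- switch(normalizer,
                 median = stats::median(depth),
                 control = {
                   stopifnot(inherits(control, "CoverageProfile"),
                             length(control$depth) == length(depth))
                   NA_real_  # per-window control normalization below
                 })
  ratio <- if (normalizer == "median") {
    if (isTRUE(norm > 0)) depth / norm else rep(NA_real_, length(depth))
  } else {
    ifelse(control$depth > 0, depth / control$depth, NA_real_)
  }
  prof <- list(window_size = ws, start = starts, end = ends, depth = depth,
               ratio = ratio, normalizer_value = norm,
               flagged = !any(depth > 0))
  class(prof) <- "CoverageProfile"
  prof
}

#' @export
print.CoverageProfile <- function(x, ...) {
  cat(sprintf("CoverageProfile: %d windows x %d bp, mean depth %.2f\n",
              length(x$depth), x$window_size, mean(x$depth)))
  invisible(x)
}

#' Segment elevated-coverage blocks
#'
#' Maximal runs of windows with ratio >= `threshold`, bridging internal gaps
#' of at most `max_gap` consecutive sub-threshold windows, reported when the
#' run spans at least `min_windows` windows. Defaults (ratio >= 1.4, 5
#' windows, gap 1) detect heterozygous ~1.5x copy gains while rejecting
#' single-window noise.
#'
#' @param profile a `CoverageProfile`.
#' @param threshold ratio threshold (> 1).
#' @param min_windows minimum run length in windows.
#' @param max_gap maximum bridged sub-threshold windows inside a run.
#' @return data.table of `ElevatedBlock`s: `start`, `end` (bp, window
#'   aligned), `n_windows`, `mean_ratio`; zero rows when nothing is elevated.
#' @export
detect_elevated_blocks <- function(profile, threshold = 1.4,
                                   min_windows = 5L, max_gap = 1L) {
  stopifnot(threshold > 1)
  el <- !is.na(profile$ratio) & profile$ratio >= threshold
  empty <- data.table::data.table(start = integer(), end = integer(),
                                  n_windows = integer(), mean_ratio = numeric())
  if (!any(el)) return(empty)
  r <- rle(el)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  runs <- data.table::data.table(start = idx_start, end = idx_end,
                                 val = r$values)[val == TRUE]
  # merge elevated runs separated by <= max_gap sub-threshold windows
  merged <- list()
  cur <- c(runs$start[1], runs$end[1])
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    gap <- runs$start[i] - cur[2] - 1L
    if (gap <= max_gap) cur[2] <- runs$end[i]
    else { merged[[length(merged) + 1L]] <- cur; cur <- c(runs$start[i], runs$end[i]) }
  }
  merged[[length(merged) + 1L]] <- cur
  blocks <- data.table::rbindlist(lapply(merged, function(b) {
    nw <- b[2] - b[1] + 1L
    data.table::data.table(
      start = profile$start[b[1]], end = profile$end[b[2]],
      n_windows = nw,
      mean_ratio = mean(profile$ratio[b[1]:b[2]], na.rm = TRUE))
  }))
  blocks <- blocks[n_windows >= min_windows]
  data.table::setorder(blocks, start)
  blocks[]
}

#' Library statistics from alignments
#'
#' @param aln alignment data.table.
#' @param ref_length reference length in bp.
#' @return list with `median_template` (median absolute template length over
#'   proper pairs) and `mean_depth` (total aligned reference bases divided by
#'   reference length). Errors when no proper pairs exist.
#' @export
library_stats <- function(aln, ref_length) {
  pp <- aln[aln$proper & aln$first, ]
  if (nrow(pp) == 0) stop("no proper pairs: median template length undefined")
  m <- aln[aln$mapped & !is.na(aln$pos), ]
  list(median_template = stats::median(abs(pp$tlen)),
       mean_depth = sum(m$end - m$pos) / ref_length)
}
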