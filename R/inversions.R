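#' Detect inverted marker blocks within a segment
#'
#' Within one translocation segment, the shared markers form a sequence of
#' reference ranks in query-map order. After compressing these ranks to
#' `1..n` (and flipping the whole sequence when the segment as a whole lies
#' reversed relative to the reference), the sequence is decomposed into
#' maximal strictly monotone runs. Each maximal strictly *decreasing* run
#' whose rank set is contiguous is one candidate inversion:
#' two-marker runs are reported with confidence `"uncertain"` (a two-marker
#' flip is indistinguishable from local mapping error), runs of
#' `min_block_confident` (default 3) or more markers with confidence
#' `"high"`. If reversing the detected runs does not restore the reference
#' order, the residual scrambled span is emitted as a single event carrying
#' the lower-bound annotation `min_count = max(1, ceiling(b/2))`, where `b`
#' is the number of residual breakpoints (adjacent marker pairs that are not
#' reference-consecutive, chromosome ends included); nested or overlapping
#' inversions are deliberately not resolved into a minimal reversal
#' scenario.
#'
#' Breakpoint regions are reported on the reference axis as open intervals
#' between the shared markers flanking the block, in global gap indices (see
#' [partition_segments()]).
#'
#' @param seg a `segmentation` object from [partition_segments()]
#' @param segment_id one of `seg$segments$segment_id`
#' @param min_block_confident block size needed for a `"high"` confidence
#'   call (default 3); two-marker blocks are always flagged uncertain
#' @return data.frame of class `inversion_events`, one row per event:
#'   `segment_id`, `ref_chromosome`, `block_first`, `block_last` (reference
#'   marker ids at the block's reference-order extremes), `block_lo`,
#'   `block_hi` (global reference ranks), `bp1_lo`, `bp1_hi`, `bp2_lo`,
#'   `bp2_hi` (gap-index intervals of the two breakpoints), `n_markers`,
#'   `min_count`, `at_least` (TRUE when `min_count` is a lower bound),
#'   `confidence`, `uninformative`. Block marker ids are in
#'   `attr(, "blocks")`.
#' @export
detect_inversions <- function(seg, segment_id, min_block_confident = 3) {
  segs <- seg$segments
  row <- segs[segs$segment_id == segment_id, ]
  if (nrow(row) != 1) stop("unknown segment: ", segment_id)
  rk <- seg$ranks[[segment_id]]
  mk <- seg$markers[[segment_id]]
  rc <- row$ref_chromosome
  empty <- inversion_frame()
  if (length(rk) < 3) {
    attr(empty, "uninformative") <- TRUE
    return(empty)
  }
  # genome-wide occupancy of this reference chromosome by this species:
  # the outward flank of a block at the segment edge extends to the nearest
  # shared marker beyond the segment (or the chromosome end)
  occ <- sort(unique(unlist(seg$ranks[names(seg$ranks)[
    vapply(names(seg$ranks), function(s)
      segs$ref_chromosome[segs$segment_id == s] == rc, TRUE)]])))
  n_ref <- length(seg$ref_order[[rc]])

  # compress to 1..n in reference order; a segment's reading direction on an
  # unsigned genetic map is arbitrary, and one physical inversion has two
  # complementary descriptions (invert block B, or flip the segment and
  # invert its complement) — decompose both orientations and keep the more
  # parsimonious one (ties favour the unflipped reading)
  comp <- match(rk, sort(rk))
  sorted_rk <- sort(rk)
  fwd <- decompose_orientation(comp, mk, flipped = FALSE)
  rev_ <- decompose_orientation(rev(comp), rev(mk), flipped = TRUE)
  cost <- function(d) sum(vapply(d$events, `[[`, 1L, "min_count"))
  chosen <- if (cost(rev_) < cost(fwd)) rev_ else fwd
  events <- chosen$events; blocks <- chosen$blocks
  if (!length(events)) return(empty)
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    lo_rank <- sorted_rk[min(ev$vals)]; hi_rank <- sorted_rk[max(ev$vals)]
    bp <- block_breakpoints(lo_rank, hi_rank, occ, n_ref)
    data.frame(segment_id = segment_id, ref_chromosome = rc,
               block_first = seg$ref_order[[rc]][lo_rank],
               block_last = seg$ref_order[[rc]][hi_rank],
               block_lo = lo_rank, block_hi = hi_rank,
               bp1_lo = bp$bp1[1], bp1_hi = bp$bp1[2],
               bp2_lo = bp$bp2[1], bp2_hi = bp$bp2[2],
               n_markers = ev$n, min_count = ev$min_count,
               at_least = ev$at_least,
               confidence = if (ev$n >= min_block_confident) "high" else "uncertain",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("inversion_events", "data.frame")
  attr(out, "blocks") <- blocks
  attr(out, "uninformative") <- FALSE
  out
}

# greedy monotone-run decomposition of one reading direction; when the
# reading is flipped, the whole-segment reversal is itself one event
decompose_orientation <- function(comp, mk_eval, flipped) {
  events <- list(); blocks <- list()
  runs <- monotone_runs(comp)
  applied <- comp
  for (r in runs) {
    if (r$dir != "dec" || r$len < 2) next
    vals <- comp[r$from:r$to]
    if (max(vals) - min(vals) + 1L != length(vals)) next  # not rank-contiguous
    applied[r$from:r$to] <- rev(applied[r$from:r$to])
    events[[length(events) + 1L]] <- list(vals = vals, n = r$len,
                                          at_least = FALSE, min_count = 1L)
    blocks[[length(blocks) + 1L]] <- mk_eval[r$from:r$to]
  }
  if (!identical(applied, sort(comp))) {
    # residual scramble: one event with a lower-bound count
    bad <- which(applied != seq_along(applied))
    span <- range(bad)
    sub <- applied[span[1]:span[2]]
    padded <- c(span[1] - 1L, sub, span[2] + 1L)
    b <- sum(diff(padded) != 1L)
    events[[length(events) + 1L]] <- list(vals = sub, n = length(sub),
                                          at_least = TRUE,
                                          min_count = max(1L, as.integer(ceiling(b / 2))))
    blocks[[length(blocks) + 1L]] <- mk_eval[span[1]:span[2]]
  }
  if (flipped && length(comp) >= 3) {
    events[[length(events) + 1L]] <- list(vals = seq_along(comp),
                                          n = length(comp),
                                          at_least = FALSE, min_count = 1L)
    blocks[[length(blocks) + 1L]] <- mk_eval
  }
  list(events = events, blocks = blocks)
}

inversion_frame <- function() {
  out <- data.frame(segment_id = character(0), ref_chromosome = character(0),
                    block_first = character(0), block_last = character(0),
                    block_lo = integer(0), block_hi = integer(0),
                    bp1_lo = integer(0), bp1_hi = integer(0),
                    bp2_lo = integer(0), bp2_hi = integer(0),
                    n_markers = integer(0), min_count = integer(0),
                    at_least = logical(0), confidence = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("inversion_events", "data.frame")
  attr(out, "blocks") <- list()
  attr(out, "uninformative") <- FALSE
  out
}

# breakpoint gap intervals flanking a block [lo_rank, hi_rank]:
# from the nearest occupied rank below lo (or chromosome start) up to lo,
# and from hi up to the nearest occupied rank above (or chromosome end)
block_breakpoints <- function(lo_rank, hi_rank, occ, n_ref) {
  below <- occ[occ < lo_rank]
  above <- occ[occ > hi_rank]
  bp1 <- c(if (length(below)) max(below) else 0L, lo_rank - 1L)
  bp2 <- c(hi_rank, if (length(above)) min(above) - 1L else n_ref)
  list(bp1 = as.integer(bp1), bp2 = as.integer(bp2))
}

# maximal strictly monotone runs of a numeric sequence; descending steps
# claim their endpoints so that a local maximum starts the decreasing run
monotone_runs <- function(v) {
  n <- length(v)
  if (n < 2) return(list(list(from = 1L, to = n, len = n, dir = "inc")))
  step <- ifelse(diff(v) < 0, "dec", "inc")
  runs <- list()
  i <- 1L
  while (i <= n - 1L) {
    d <- step[i]
    j <- i
    while (j <= n - 1L && step[j] == d) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(from = i, to = j, len = j - i + 1L, dir = d)
    i <- j
  }
  runs
}

#' Detect inversions for every segment of a species
#'
#' @param seg a `segmentation` object
#' @param min_block_confident see [detect_inversions()]
#' @return an `inversion_events` data.frame over all segments (with a
#'   `blocks` attribute aligned to rows)
#' @export
detect_inversions_all <- function(seg, min_block_confident = 3) {
  res <- inversion_frame()
  blocks <- list()
  for (sid in seg$segments$segment_id) {
    ev <- detect_inversions(seg, sid, min_block_confident)
    if (nrow(ev)) {
      res <- rbind(res, ev)
      blocks <- c(blocks, attr(ev, "blocks"))
    }
  }
  class(res) <- c("inversion_events", "data.frame")
  attr(res, "blocks") <- blocks
  res
}

#' Classify an inversion as pericentric or paracentric
#'
#' Pericentric inversions span the centromere; paracentric ones lie within
#' one arm. The call is rank-based: an event is pericentric iff its block's
#' reference rank interval contains the centromere's flanking-marker
#' interval.
#'
#' @param event one row of an `inversion_events` data.frame
#' @param centromeres a `centromere_table`
#' @param ref the reference [genetic_map()] (to resolve flanking ranks)
#' @return `"pericentric"`, `"paracentric"`, or `"unclassified"` when the
#'   centromere of that chromosome is unknown
#' @export
classify_pericentric <- function(event, centromeres, ref) {
  rc <- event$ref_chromosome
  row <- centromeres[centromeres$chromosome == rc, ]
  if (nrow(row) != 1) return("unclassified")
  mk <- chromosome_markers(ref, rc)
  lf <- match(row$left_marker, mk); rt <- match(row$right_marker, mk)
  if (is.na(lf) || is.na(rt)) return("unclassified")
  if (event$block_lo <= lf && event$block_hi >= rt) "pericentric" else "paracentric"
}
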