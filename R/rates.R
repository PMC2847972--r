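#' Round half away from zero
#'
#' Printed one-decimal rates use commercial rounding (0.05 -> 0.1), not
#' banker's rounding.
#' @param x numeric
#' @param digits decimal places (default 1)
#' @return rounded numeric
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-branch rearrangement rates
#'
#' Divides per-branch event counts (from [count_events_by_branch()]) by the
#' branch durations of the dated phylogeny. Undetermined events propagate
#' into `[rate_min, rate_max]` ranges. Rates are reported raw and rounded to
#' one decimal (half away from zero), together with the per-chromosome
#' normalisation (dividing by the family's constant chromosome number).
#'
#' @param counts data.frame from [count_events_by_branch()]
#' @param phy a [dated_phylogeny()]
#' @param chromosome_number basic chromosome number used for the
#'   per-chromosome rate (default 12)
#' @return data.frame of class `rate_estimates`: `branch`, `kind`,
#'   `count_min`, `count_max`, `duration_MY`, `rate_min`, `rate_max`,
#'   `rate_min_rounded`, `rate_max_rounded`, `per_chromosome_min`,
#'   `per_chromosome_max`
#' @export
estimate_rates <- function(counts, phy, chromosome_number = 12) {
  dur <- vapply(counts$branch, function(b) branch_duration(phy, b), 1.0)
  if (any(dur <= 0)) stop("zero-duration branch")
  out <- counts[, c("branch", "kind", "count_min", "count_max")]
  out$duration_MY <- as.numeric(dur)
  out$rate_min <- out$count_min / out$duration_MY
  out$rate_max <- out$count_max / out$duration_MY
  out$rate_min_rounded <- round_half_away(out$rate_min, 1)
  out$rate_max_rounded <- round_half_away(out$rate_max, 1)
  out$per_chromosome_min <- out$rate_min / chromosome_number
  out$per_chromosome_max <- out$rate_max / chromosome_number
  rownames(out) <- NULL
  class(out) <- c("rate_estimates", "data.frame")
  out
}

#' Detect reuse of translocation breakpoints
#'
#' Groups *independent* translocation events whose breakpoint regions on the
#' same reference chromosome intersect: within a chromosome, events are
#' nodes and pairwise gap-interval intersection defines edges; connected
#' components with members from at least two distinct lineages are reuse
#' groups. The shared region narrows to the intersection of all member
#' intervals (or, if that is empty in a chain, the range of pairwise
#' intersections). Each group is tested for centromere proximity: the
#' narrowed interval must intersect the centromere's flanking gap interval
#' widened by `proximity_window` marker gaps on each side.
#'
#' @param events data.frame with one row per translocation breakpoint:
#'   columns `event_id`, `lineage`, `ref_chromosome`, `gap_lo`, `gap_hi`
#'   (gap-index interval on the reference, see [partition_segments()])
#' @param centromeres a `centromere_table`
#' @param ref reference [genetic_map()] used to resolve centromere flanking
#'   ranks
#' @param proximity_window number of marker gaps by which the centromere
#'   interval is widened (default 1)
#' @return data.frame of class `reuse_groups`: `ref_chromosome`, `members`
#'   (comma-joined event ids), `lineages`, `n_members`, `narrowed_lo`,
#'   `narrowed_hi`, `centromere_proximal`
#' @export
detect_breakpoint_reuse <- function(events, centromeres, ref,
                                    proximity_window = 1) {
  need <- c("event_id", "lineage", "ref_chromosome", "gap_lo", "gap_hi")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  rows <- list()
  for (rc in sort(unique(events$ref_chromosome))) {
    ev <- events[events$ref_chromosome == rc, , drop = FALSE]
    ev <- ev[order(ev$event_id), , drop = FALSE]  # input-order independence
    n <- nrow(ev)
    if (n < 2) next
    # union-find over pairwise interval intersection
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (ev$gap_lo[i] <= ev$gap_hi[j] && ev$gap_lo[j] <= ev$gap_hi[i]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
    comp <- vapply(seq_len(n), find, 1L)
    for (cid in unique(comp)) {
      idx <- which(comp == cid)
      if (length(idx) < 2) next
      lins <- unique(ev$lineage[idx])
      if (length(lins) < 2) next
      lo <- max(ev$gap_lo[idx]); hi <- min(ev$gap_hi[idx])
      if (lo > hi) { # chained overlap without a common core
        lo <- min(ev$gap_lo[idx]); hi <- max(ev$gap_hi[idx])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ref_chromosome = rc,
        members = paste(sort(ev$event_id[idx]), collapse = ","),
        lineages = paste(sort(lins), collapse = ","),
        n_members = length(idx),
        narrowed_lo = lo, narrowed_hi = hi,
        centromere_proximal = centromere_proximal(
          rc, lo, hi, centromeres, ref, proximity_window),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(ref_chromosome = character(0), members = character(0),
               lineages = character(0), n_members = integer(0),
               narrowed_lo = integer(0), narrowed_hi = integer(0),
               centromere_proximal = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("reuse_groups", "data.frame")
  out
}

centromere_proximal <- function(rc, lo, hi, centromeres, ref, window) {
  row <- centromeres[centromeres$chromosome == rc, ]
  if (nrow(row) != 1) return(NA)
  mk <- chromosome_markers(ref, rc)
  lf <- match(row$left_marker, mk); rt <- match(row$right_marker, mk)
  if (is.na(lf) || is.na(rt)) return(NA)
  # centromere occupies gaps lf .. rt-1; widen by `window` gaps per side
  c_lo <- lf - window; c_hi <- (rt - 1) + window
  lo <= c_hi && c_lo <= hi
}
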