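#' Partition projected chromosomes into translocation segments
#'
#' Each query chromosome is painted by the reference chromosome of its
#' shared markers and split into maximal runs of at least `min_run`
#' consecutive markers sharing one reference chromosome. Runs shorter than
#' `min_run` are flagged stray (potential mapping noise) and excluded from
#' segments and events. Junctions between consecutive segments are
#' translocation breakpoint regions, recorded both on the query map (the
#' adjacent shared marker pair spanning the junction) and on the reference
#' axis of each flanking segment (the open gap interval between the last
#' marker known inside the segment and the nearest marker of the same
#' reference chromosome known elsewhere in the query genome, or the
#' chromosome end).
#'
#' Reference-side intervals are expressed as *gap indices*: gap `g` of a
#' reference chromosome is the interval between its markers of global rank
#' `g` and `g + 1`; gap `0` and gap `n` are the chromosome ends.
#'
#' @param projection a [project_onto_reference()] result
#' @param min_run minimum markers per segment (default 2)
#' @return object of class `segmentation`: list with `species`, `segments`
#'   (data.frame: segment_id, query_chromosome, ref_chromosome, n_markers,
#'   first_marker, last_marker, rank_lo, rank_hi, embedded), `junctions`
#'   (data.frame, one row per junction with query flanks and reference-side
#'   gap intervals for both sides), `events` (data.frame of translocation
#'   events after embedded/reciprocal collapsing), `strays` (data.frame of
#'   excluded markers) and `markers` (named list segment_id -> marker ids).
#' @export
partition_segments <- function(projection, min_run = 2) {
  sp <- projection$species
  seg_rows <- list(); jn_rows <- list(); stray_rows <- list()
  seg_markers <- list(); seg_ranks <- list()
  for (ch in names(projection$chromosomes)) {
    df <- projection$chromosomes[[ch]]
    if (nrow(df) == 0) next
    r <- rle(df$ref_chromosome)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$lengths >= min_run
    # strays
    for (i in which(!keep)) {
      stray_rows[[length(stray_rows) + 1L]] <-
        data.frame(query_chromosome = ch,
                   marker = df$marker[starts[i]:ends[i]],
                   ref_chromosome = r$values[i], stringsAsFactors = FALSE)
    }
    if (!any(keep)) {
      warning("chromosome ", ch, " of ", sp, " has only stray runs (< ",
              min_run, " markers); no segments formed")
      next
    }
    # merge adjacent kept runs with identical reference chromosome
    # (possible once strays in between are removed)
    kept <- data.frame(start = starts[keep], end = ends[keep],
                       ref = r$values[keep], stringsAsFactors = FALSE)
    merged <- kept[1, , drop = FALSE]
    if (nrow(kept) > 1) {
      for (i in 2:nrow(kept)) {
        if (kept$ref[i] == merged$ref[nrow(merged)]) {
          merged$end[nrow(merged)] <- kept$end[i]
        } else merged <- rbind(merged, kept[i, ])
      }
    }
    nseg <- nrow(merged)
    ids <- if (nseg == 1) ch else paste0(ch, letters[seq_len(nseg)])
    for (i in seq_len(nseg)) {
      idx <- merged$start[i]:merged$end[i]
      idx <- idx[!df$marker[idx] %in% unlist(lapply(stray_rows, `[[`, "marker"))]
      mk <- df$marker[idx]; rk <- df$ref_rank[idx]
      seg_markers[[ids[i]]] <- mk
      seg_ranks[[ids[i]]] <- rk
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        segment_id = ids[i], query_chromosome = ch,
        ref_chromosome = merged$ref[i], n_markers = length(mk),
        first_marker = mk[1], last_marker = mk[length(mk)],
        rank_lo = min(rk), rank_hi = max(rk),
        embedded = FALSE, stringsAsFactors = FALSE)
    }
    if (nseg > 1) {
      for (i in seq_len(nseg - 1)) {
        left_id <- ids[i]; right_id <- ids[i + 1]
        lmk <- seg_markers[[left_id]]; rmk <- seg_markers[[right_id]]
        jn_rows[[length(jn_rows) + 1L]] <- data.frame(
          query_chromosome = ch,
          left_segment = left_id, right_segment = right_id,
          left_marker = lmk[length(lmk)], right_marker = rmk[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  segments <- if (length(seg_rows)) do.call(rbind, seg_rows) else
    data.frame(segment_id = character(0), query_chromosome = character(0),
               ref_chromosome = character(0), n_markers = integer(0),
               first_marker = character(0), last_marker = character(0),
               rank_lo = integer(0), rank_hi = integer(0),
               embedded = logical(0), stringsAsFactors = FALSE)
  junctions <- if (length(jn_rows)) do.call(rbind, jn_rows) else
    data.frame(query_chromosome = character(0), left_segment = character(0),
               right_segment = character(0), left_marker = character(0),
               right_marker = character(0), stringsAsFactors = FALSE)
  rownames(segments) <- NULL; rownames(junctions) <- NULL
  res <- structure(list(species = sp, reference = projection$reference,
                        segments = segments, junctions = junctions,
                        strays = if (length(stray_rows)) do.call(rbind, stray_rows)
                                 else NULL,
                        markers = seg_markers, ranks = seg_ranks,
                        ref_order = projection$ref_order),
                   class = "segmentation")
  res <- add_reference_breakpoints(res)
  res$segments <- detect_embedded_insertion(res)
  res$events <- translocation_events(res)
  res
}

# For each junction, compute the reference-side breakpoint gap interval of
# both flanking segments. The interval runs from the junction-end marker of
# the segment outward to the nearest rank of the same reference chromosome
# occupied elsewhere in this species' genome (exclusive), or to the
# chromosome end.
add_reference_breakpoints <- function(seg) {
  jn <- seg$junctions
  if (nrow(jn) == 0) {
    for (col in c("left_ref_chromosome", "right_ref_chromosome"))
      jn[[col]] <- character(0)
    for (col in c("left_gap_lo", "left_gap_hi", "right_gap_lo", "right_gap_hi"))
      jn[[col]] <- integer(0)
    seg$junctions <- jn
    return(seg)
  }
  segs <- seg$segments
  # ranks occupied per reference chromosome across the whole genome
  occ <- list()
  for (sid in names(seg$ranks)) {
    rc <- segs$ref_chromosome[segs$segment_id == sid]
    occ[[rc]] <- sort(unique(c(occ[[rc]], seg$ranks[[sid]])))
  }
  side_interval <- function(sid, junction_side) {
    rc <- segs$ref_chromosome[segs$segment_id == sid]
    rk <- seg$ranks[[sid]]
    n_ref <- length(seg$ref_order[[rc]])
    # junction-adjacent marker: last in query order for the left segment,
    # first for the right segment
    end_rank <- if (junction_side == "left") rk[length(rk)] else rk[1]
    lo <- min(rk); hi <- max(rk)
    # outward direction: the break detaches the segment end nearest the
    # junction; decide by whether the junction-adjacent marker sits at the
    # low or high extreme of the segment's reference span
    outward_high <- abs(end_rank - hi) <= abs(end_rank - lo)
    other <- setdiff(occ[[rc]], rk)
    if (outward_high) {
      nxt <- other[other > hi]
      gap_lo <- hi
      gap_hi <- if (length(nxt)) min(nxt) - 1L else n_ref
    } else {
      prv <- other[other < lo]
      gap_hi <- lo - 1L
      gap_lo <- if (length(prv)) max(prv) else 0L
    }
    list(rc = rc, lo = as.integer(gap_lo), hi = as.integer(gap_hi))
  }
  L <- lapply(jn$left_segment, side_interval, junction_side = "left")
  R <- lapply(jn$right_segment, side_interval, junction_side = "right")
  jn$left_ref_chromosome <- vapply(L, `[[`, "", "rc")
  jn$left_gap_lo <- vapply(L, `[[`, 1L, "lo")
  jn$left_gap_hi <- vapply(L, `[[`, 1L, "hi")
  jn$right_ref_chromosome <- vapply(R, `[[`, "", "rc")
  jn$right_gap_lo <- vapply(R, `[[`, 1L, "lo")
  jn$right_gap_hi <- vapply(R, `[[`, 1L, "hi")
  seg$junctions <- jn
  seg
}

#' Flag embedded (insertional) segments
#'
#' A query chromosome showing the painting pattern X / Y / X, where the two
#' X segments are rank-contiguous on the reference (no other segment of this
#' species occupies ranks between them), records an insertional
#' translocation: the Y segment was excised elsewhere and inserted, while
#' the X flanks stayed together. The middle segment is flagged `embedded`
#' and its two junctions are counted as a single event.
#'
#' @param seg a `segmentation` object
#' @return the `segments` data.frame with the `embedded` column filled
#' @export
detect_embedded_insertion <- function(seg) {
  segs <- seg$segments
  segs$embedded <- FALSE
  for (ch in unique(segs$query_chromosome)) {
    idx <- which(segs$query_chromosome == ch)
    if (length(idx) < 3) next
    for (k in 2:(length(idx) - 1)) {
      a <- idx[k - 1]; b <- idx[k]; c <- idx[k + 1]
      if (segs$ref_chromosome[a] != segs$ref_chromosome[c]) next
      if (segs$ref_chromosome[b] == segs$ref_chromosome[a]) next
      rc <- segs$ref_chromosome[a]
      lo <- min(segs$rank_lo[a], segs$rank_lo[c])
      hi <- max(segs$rank_hi[a], segs$rank_hi[c])
      inner_lo <- min(segs$rank_hi[a], segs$rank_hi[c])
      inner_hi <- max(segs$rank_lo[a], segs$rank_lo[c])
      # contiguous iff no other segment of this species on rc occupies a rank
      # strictly between the two flank segments
      others <- setdiff(which(segs$ref_chromosome == rc), c(a, c))
      blocked <- FALSE
      for (o in others) {
        rk <- seg$ranks[[segs$segment_id[o]]]
        if (any(rk > inner_lo & rk < inner_hi)) { blocked <- TRUE; break }
      }
      if (!blocked) segs$embedded[b] <- TRUE
    }
  }
  segs
}

# Collapse junctions into translocation events.
# - the two junctions flanking an embedded segment -> one insertional event
# - pairs of junctions on different chromosomes exchanging the same two
#   reference chromosomes with complementary rank spans -> one reciprocal
#   event
# - every remaining junction -> one unclassified event
translocation_events <- function(seg) {
  jn <- seg$junctions
  segs <- seg$segments
  empty <- data.frame(event_id = character(0), kind = character(0),
                      query_chromosomes = character(0),
                      segments = character(0), junction_rows = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(jn) == 0) return(empty)
  used <- rep(FALSE, nrow(jn))
  rows <- list()
  eid <- 0L
  new_event <- function(kind, chroms, segids, jrows) {
    eid <<- eid + 1L
    data.frame(event_id = sprintf("%s_tr%02d", seg$species, eid), kind = kind,
               query_chromosomes = paste(unique(chroms), collapse = ","),
               segments = paste(segids, collapse = ","),
               junction_rows = paste(jrows, collapse = ","),
               stringsAsFactors = FALSE)
  }
  # embedded insertions
  emb <- segs$segment_id[segs$embedded]
  for (sid in emb) {
    j1 <- which(jn$right_segment == sid)
    j2 <- which(jn$left_segment == sid)
    if (length(j1) == 1 && length(j2) == 1 && !used[j1] && !used[j2]) {
      used[c(j1, j2)] <- TRUE
      rows[[length(rows) + 1L]] <- new_event(
        "insertional", jn$query_chromosome[c(j1, j2)],
        c(jn$left_segment[j1], sid, jn$right_segment[j2]), c(j1, j2))
    }
  }
  # reciprocal: two junctions on different query chromosomes with the same
  # unordered reference-chromosome pair and non-overlapping spans per
  # reference chromosome
  ref_of <- stats::setNames(segs$ref_chromosome, segs$segment_id)
  span_of <- function(sid) c(segs$rank_lo[segs$segment_id == sid],
                             segs$rank_hi[segs$segment_id == sid])
  pair_key <- function(j) paste(sort(c(ref_of[jn$left_segment[j]],
                                       ref_of[jn$right_segment[j]])), collapse = "|")
  for (j in seq_len(nrow(jn))) {
    if (used[j]) next
    for (k in seq_len(nrow(jn))) {
      if (k <= j || used[k] || used[j]) next
      if (jn$query_chromosome[j] == jn$query_chromosome[k]) next
      if (pair_key(j) != pair_key(k)) next
      ok <- TRUE
      for (rc in unique(c(ref_of[jn$left_segment[j]], ref_of[jn$right_segment[j]]))) {
        sj <- c(jn$left_segment[j], jn$right_segment[j])
        sk <- c(jn$left_segment[k], jn$right_segment[k])
        sj <- sj[ref_of[sj] == rc]; sk <- sk[ref_of[sk] == rc]
        if (length(sj) != 1 || length(sk) != 1) { ok <- FALSE; break }
        a <- span_of(sj); b <- span_of(sk)
        if (!(a[2] < b[1] || b[2] < a[1])) { ok <- FALSE; break }
      }
      if (ok) {
        used[c(j, k)] <- TRUE
        rows[[length(rows) + 1L]] <- new_event(
          "reciprocal", jn$query_chromosome[c(j, k)],
          unique(c(jn$left_segment[j], jn$right_segment[j],
                   jn$left_segment[k], jn$right_segment[k])), c(j, k))
      }
    }
  }
  for (j in which(!used)) {
    rows[[length(rows) + 1L]] <- new_event(
      "unclassified", jn$query_chromosome[j],
      c(jn$left_segment[j], jn$right_segment[j]), j)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat("Segmentation of", x$species, "vs", x$reference, "-",
      nrow(x$segments), "segments,", nrow(x$junctions), "junctions,",
      nrow(x$events), "translocation events\n")
  invisible(x)
}
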