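#' Evaluate inference against a simulation's true history
#'
#' Runs the full pipeline (detection, clustering, timing, reconstruction) on
#' simulated maps and scores it against the recorded truth:
#'
#' * **recall** — a true event is recalled if, for at least one species in
#'   which it is visible against the reference (the species and the
#'   reference lie on opposite sides of the event's branch), a detected
#'   event of the same kind intersects it (inversions: block marker sets
#'   intersect; translocations: a junction's reference-side gap interval
#'   intersects the true break interval on the same reference chromosome).
#' * **breakpoint containment** — for recalled events whose true flanking
#'   markers survive adjacent on the reference map, the detected breakpoint
#'   gap interval must contain the true gap.
#' * **assignment accuracy** — each recalled event is traced to its
#'   observation cluster; among clusters with a determined branch, the
#'   fraction assigned to the true branch.
#' * **ancestral accuracy** — for every reconstructed node, each resolved
#'   chromosome's arrangement must equal the true ancestral genome's
#'   arrangement on the same marker set.
#'
#' @param sim result of [simulate_history()]
#' @param reference reference species (default `"tomato"`)
#' @param nodes internal nodes to reconstruct (default all non-root)
#' @return list of class `sim_evaluation` with per-event tables and summary
#'   scalars (`recall`, `bp_containment_violations`, `assign_total`,
#'   `assign_correct`, `anc_resolved`, `anc_correct`)
#' @export
evaluate_inference <- function(sim, reference = "tomato", nodes = NULL) {
  phy <- sim$truth$params$phy
  maps <- sim$maps
  pipeline <- infer_timing(maps, phy, reference)
  inferred <- pipeline$inferred
  ref_map <- maps[[reference]]
  ref_hi <- ref_map[ref_map$confidence == "high", ]
  rank_of <- stats::setNames(
    unlist(lapply(split(seq_len(nrow(ref_hi)), ref_hi$chromosome),
                  function(ix) seq_along(ix)), use.names = FALSE),
    unlist(split(ref_hi$marker, ref_hi$chromosome), use.names = FALSE))
  chrom_of <- stats::setNames(ref_hi$chromosome, ref_hi$marker)

  # observation lookup: which cluster contains a given species:segment /
  # species:chromosome member
  obs <- pipeline$observations
  member_index <- list()
  if (!is.null(obs)) for (i in seq_len(nrow(obs)))
    for (m in strsplit(obs$members[i], ",")[[1]])
      member_index[[paste(obs$kind[i], m)]] <- i

  ev_rows <- list()
  for (br in names(sim$truth$events)) {
    visible_in <- visible_species(phy, br, reference)
    for (ev in sim$truth$events[[br]]) {
      rec <- score_event(ev, br, visible_in, inferred, rank_of, chrom_of,
                         member_index, obs, pipeline$assignments)
      ev_rows[[length(ev_rows) + 1L]] <- rec
    }
  }
  ev_tab <- if (length(ev_rows)) do.call(rbind, ev_rows) else NULL

  # ancestral reconstruction vs truth. Chromosomes whose markers were moved
  # by events on two different branches are flagged: a later event can undo
  # or reproduce an earlier one on the surviving marker subset (an
  # inversion re-inverting a block; translocations detaching the same
  # block), in which case an outgroup can honestly witness the wrong
  # ancestral arrangement — genuine homoplasy that no parsimony method can
  # see through, and exactly the situation excluded by the "informative
  # outgroup" premise
  painting <- reference_painting(ref_map)
  moved <- list()
  for (br in names(sim$truth$events))
    for (e in sim$truth$events[[br]])
      moved[[length(moved) + 1L]] <- list(
        branch = br,
        markers = unique(unlist(e[intersect(names(e),
                                            c("block", "blockA", "blockB"))],
                                use.names = FALSE)))
  confounded <- character(0)
  if (length(moved) > 1)
    for (i in seq_along(moved)) for (j in seq_along(moved)) {
      if (j <= i || moved[[i]]$branch == moved[[j]]$branch) next
      ov <- intersect(moved[[i]]$markers, moved[[j]]$markers)
      ov <- ov[ov %in% names(painting)]
      if (length(ov)) confounded <- union(confounded, unname(painting[ov]))
    }

  kars <- reconstruct_karyotypes(phy, maps, reference, nodes = nodes)
  anc_resolved <- 0L; anc_correct <- 0L
  anc_clean <- 0L; anc_clean_correct <- 0L
  for (nd in names(kars)) {
    k <- kars[[nd]]
    trueg <- sim$truth$genomes[[nd]]
    for (c in names(k$arrangements)) {
      st <- k$table$status[k$table$chromosome == c]
      if (st != "resolved") next
      anc_resolved <- anc_resolved + 1L
      keep <- k$marker_sets[[c]]
      ta <- chromosome_arrangement(trueg, painting, c, keep)
      hit <- arrangement_equal(k$arrangements[[c]], ta)
      if (hit) anc_correct <- anc_correct + 1L
      if (!c %in% confounded) {
        anc_clean <- anc_clean + 1L
        if (hit) anc_clean_correct <- anc_clean_correct + 1L
      }
    }
  }

  structure(list(
    events = ev_tab, pipeline = pipeline, karyotypes = kars,
    recall = if (is.null(ev_tab)) NA_real_ else
      mean(ev_tab$recalled, na.rm = TRUE),
    bp_containment_violations = if (is.null(ev_tab)) 0L else
      sum(ev_tab$bp_checked & !ev_tab$bp_contained),
    bp_checked = if (is.null(ev_tab)) 0L else sum(ev_tab$bp_checked),
    assign_total = if (is.null(ev_tab)) 0L else sum(ev_tab$assign_determined),
    assign_correct = if (is.null(ev_tab)) 0L else
      sum(ev_tab$assign_determined & ev_tab$assign_correct),
    anc_resolved = anc_resolved, anc_correct = anc_correct,
    anc_clean = anc_clean, anc_clean_correct = anc_clean_correct),
    class = "sim_evaluation")
}

# species in whose comparison against the reference an event on branch `br`
# is visible: exactly one of {species, reference} descends from the branch
visible_species <- function(phy, br, reference) {
  below <- tips_below(phy, br)
  ref_below <- reference %in% below
  sp <- setdiff(phylo_species(phy), reference)
  if (ref_below) setdiff(sp, below) else intersect(sp, below)
}

score_event <- function(ev, br, visible_in, inferred, rank_of, chrom_of,
                        member_index, obs, assignments) {
  out <- data.frame(branch = br, kind = ev$kind, recalled = FALSE,
                    bp_checked = FALSE, bp_contained = NA,
                    assign_determined = FALSE, assign_correct = NA,
                    stringsAsFactors = FALSE)
  if (!length(visible_in)) { out$recalled <- NA; return(out) }
  if (ev$kind == "inversion") {
    # best-overlap match across all visible species: maximise block
    # intersection, penalise spill-over beyond the true block
    hit <- NULL; best <- c(-Inf, -Inf)
    for (sp in visible_in) {
      inv <- inferred[[sp]]$inversions
      if (!nrow(inv)) next
      blocks <- attr(inv, "blocks")
      shared <- unlist(lapply(inferred[[sp]]$projection$chromosomes,
                              `[[`, "marker"), use.names = FALSE)
      target <- intersect(ev$block, shared)
      for (i in seq_len(nrow(inv))) {
        ninter <- length(intersect(blocks[[i]], ev$block))
        if (ninter < 1) next
        score <- c(ninter, -length(setdiff(blocks[[i]], ev$block)))
        if (score[1] > best[1] || (score[1] == best[1] && score[2] > best[2])) {
          best <- score
          hit <- list(species = sp, row = inv[i, ],
                      clean = length(target) >= 2 &&
                        setequal(blocks[[i]], target))
        }
      }
    }
    if (is.null(hit)) return(out)
    out$recalled <- TRUE
    # breakpoint containment on the reference, when the true flanks survive
    # as reference-adjacent markers
    d <- hit$row
    chk <- function(pair) {
      m1 <- pair[1]; m2 <- pair[2]
      if (!nzchar(m1) || !nzchar(m2)) return(NA)
      if (!(m1 %in% names(rank_of)) || !(m2 %in% names(rank_of))) return(NA)
      if (chrom_of[m1] != chrom_of[m2] || chrom_of[m1] != d$ref_chromosome)
        return(NA)
      r1 <- min(rank_of[m1], rank_of[m2]); r2 <- max(rank_of[m1], rank_of[m2])
      if (r2 != r1 + 1) return(NA)   # reference itself rearranged/interrupted
      gap <- r1
      (gap >= d$bp1_lo && gap <= d$bp1_hi) || (gap >= d$bp2_lo && gap <= d$bp2_hi)
    }
    # the single-event containment guarantee is only well-posed when the
    # true block is still one contiguous run on the reference rank axis
    # (i.e. the reference carries no overlapping rearrangement of its own)
    br_ranks <- rank_of[ev$block[ev$block %in% names(rank_of)]]
    contiguous <- length(br_ranks) >= 1 &&
      diff(range(br_ranks)) + 1 == length(br_ranks)
    c1 <- chk(ev$bp1); c2 <- chk(ev$bp2)
    if (hit$clean && contiguous && (!is.na(c1) || !is.na(c2))) {
      out$bp_checked <- TRUE
      out$bp_contained <- all(stats::na.omit(c(c1, c2)))
    }
    # the event has an informative outgroup only if, in every species where
    # it is visible, it is either physically invisible (fewer than two of
    # its block markers survive in that comparison) or cleanly detected
    # (one detected block equal to the surviving true block): otherwise an
    # overlapping rearrangement has compromised the region, and the method
    # by design leaves such events untimed
    eligible <- TRUE
    for (sp in visible_in) {
      shared <- unlist(lapply(inferred[[sp]]$projection$chromosomes,
                              `[[`, "marker"), use.names = FALSE)
      tb <- intersect(ev$block, shared)
      if (length(tb) < 2) next
      inv_sp <- inferred[[sp]]$inversions
      ok <- FALSE
      if (nrow(inv_sp)) for (b in attr(inv_sp, "blocks"))
        if (setequal(b, tb)) { ok <- TRUE; break }
      if (!ok) { eligible <- FALSE; break }
    }
    # attribution to a cluster is only trustworthy on a >= 2 marker overlap
    if (best[1] >= 2 && eligible) {
      key <- paste("inversion", paste0(hit$species, ":", d$segment_id))
      out <- score_assignment(out, key, member_index, obs, assignments, br,
                              visible_in)
    }
  } else {
    # true break intervals on the reference axis
    pairs <- switch(ev$kind,
                    reciprocal = list(ev$bpA, ev$bpB),
                    insertional = list(ev$bpS1, ev$bpS2, ev$bpT))
    true_ivs <- list()
    for (p in pairs) {
      m1 <- p[1]; m2 <- p[2]
      if (!nzchar(m1) || !nzchar(m2)) next
      if (!(m1 %in% names(rank_of)) || !(m2 %in% names(rank_of))) next
      if (chrom_of[m1] != chrom_of[m2]) next
      r1 <- min(rank_of[m1], rank_of[m2]); r2 <- max(rank_of[m1], rank_of[m2])
      true_ivs[[length(true_ivs) + 1L]] <-
        list(rc = unname(chrom_of[m1]), lo = r1, hi = r2 - 1, adjacent = r2 == r1 + 1)
    }
    if (!length(true_ivs)) { out$recalled <- NA; return(out) }
    # best match: prefer the junction agreeing with the true breaks on the
    # most sides, then (cluster corroboration) the one whose observation has
    # the most carriers
    hit <- NULL; best <- c(-Inf, -Inf)
    for (sp in visible_in) {
      jn <- inferred[[sp]]$segmentation$junctions
      if (!nrow(jn)) next
      for (i in seq_len(nrow(jn))) {
        sides <- list(c(jn$left_ref_chromosome[i], jn$left_gap_lo[i],
                        jn$left_gap_hi[i]),
                      c(jn$right_ref_chromosome[i], jn$right_gap_lo[i],
                        jn$right_gap_hi[i]))
        n_match <- 0L; first_side <- NULL; first_tv <- NULL
        for (side in sides) {
          for (tv in true_ivs) {
            if (side[1] == tv$rc &&
                as.integer(side[2]) <= tv$hi && tv$lo <= as.integer(side[3])) {
              n_match <- n_match + 1L
              if (is.null(first_side)) { first_side <- side; first_tv <- tv }
              break
            }
          }
        }
        if (n_match == 0L) next
        member <- paste0(sp, ":", jn$query_chromosome[i], ":", i)
        idx <- member_index[[paste("translocation", member)]]
        ncar <- if (is.null(idx)) 0L else
          length(unique(sub(":.*$", "", strsplit(obs$members[idx], ",")[[1]])))
        score <- c(n_match, ncar)
        if (score[1] > best[1] || (score[1] == best[1] && score[2] > best[2])) {
          best <- score
          hit <- list(species = sp, tv = first_tv,
                      iv = c(as.integer(first_side[2]), as.integer(first_side[3])),
                      member = member)
        }
      }
    }
    if (is.null(hit)) return(out)
    out$recalled <- TRUE
    if (hit$tv$adjacent) {
      out$bp_checked <- TRUE
      out$bp_contained <- hit$iv[1] <= hit$tv$lo && hit$tv$lo <= hit$iv[2]
    }
    # a visible species that retains fewer than two markers of a moved
    # block cannot display the junction — its map is indistinguishable
    # from the intact arrangement, so the event is not timeable from the
    # data and drops out of the accuracy denominator
    moved <- switch(ev$kind, reciprocal = list(ev$blockA, ev$blockB),
                    insertional = list(ev$block))
    eligible <- TRUE
    for (sp in visible_in) {
      shared <- unlist(lapply(inferred[[sp]]$projection$chromosomes,
                              `[[`, "marker"), use.names = FALSE)
      for (blk in moved)
        if (length(intersect(blk, shared)) < 2) { eligible <- FALSE; break }
      if (!eligible) break
    }
    if (eligible) {
      key <- paste("translocation", hit$member)
      out <- score_assignment(out, key, member_index, obs, assignments, br,
                              visible_in)
    }
  }
  out
}

score_assignment <- function(out, key, member_index, obs, assignments, br,
                             visible_in) {
  idx <- member_index[[key]]
  if (is.null(idx) || is.null(assignments)) return(out)
  # carriers outside the set of species where this event is visible mean
  # the cluster merged several events (coinciding breakpoint regions): the
  # resulting observation does not describe this event and the method, by
  # construction, cannot time it individually
  carriers <- unique(sub(":.*$", "", strsplit(obs$members[idx], ",")[[1]]))
  if (length(setdiff(carriers, visible_in))) return(out)
  a <- assignments[assignments$event_id == obs$event_id[idx], ]
  if (nrow(a) != 1) return(out)
  if (a$determined) {
    out$assign_determined <- TRUE
    out$assign_correct <- a$branch == br
  }
  out
}

#' @export
print.sim_evaluation <- function(x, ...) {
  cat("Simulation evaluation:\n")
  cat(sprintf("  recall: %.3f (%d events)\n", x$recall,
              if (is.null(x$events)) 0L else nrow(x$events)))
  cat(sprintf("  breakpoint containment: %d checked, %d violations\n",
              x$bp_checked, x$bp_containment_violations))
  cat(sprintf("  branch assignment: %d/%d correct among determined\n",
              x$assign_correct, x$assign_total))
  cat(sprintf("  ancestral chromosomes: %d/%d resolved correct (%d/%d homoplasy-free)\n",
              x$anc_correct, x$anc_resolved, x$anc_clean_correct, x$anc_clean))
  invisible(x)
}
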