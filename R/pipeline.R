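#' Detect rearrangements of every species against the reference
#'
#' Runs projection, segmentation and inversion detection for each
#' non-reference species.
#'
#' @param maps named list of [genetic_map()]s (one must be the reference)
#' @param reference reference species name
#' @param orthology an [orthology_table()]; defaults to
#'   [shared_name_orthology()] over the maps
#' @param min_run see [partition_segments()]
#' @param min_block_confident see [detect_inversions()]
#' @return named list (per non-reference species) of lists with
#'   `projection`, `segmentation`, `inversions`; plus attributes
#'   `reference`, `ref_map`
#' @export
infer_species_events <- function(maps, reference = "tomato", orthology = NULL,
                                 min_run = 2, min_block_confident = 3) {
  if (!reference %in% names(maps)) stop("reference map missing: ", reference)
  if (is.null(orthology)) orthology <- shared_name_orthology(maps)
  out <- list()
  for (sp in setdiff(names(maps), reference)) {
    proj <- suppressMessages(
      project_onto_reference(maps[[sp]], maps[[reference]], orthology))
    seg <- suppressWarnings(partition_segments(proj, min_run = min_run))
    inv <- detect_inversions_all(seg, min_block_confident = min_block_confident)
    out[[sp]] <- list(projection = proj, segmentation = seg, inversions = inv)
  }
  attr(out, "reference") <- reference
  attr(out, "ref_map") <- maps[[reference]]
  out
}

# union-find used by the clustering steps
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in edges) {
    ri <- find(e[1]); rj <- find(e[2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, 1L)
}

#' Cluster per-species detections into cross-species event observations
#'
#' Inversions detected in different species are the same event iff both
#' breakpoint gap intervals intersect ([compare_via_reference()]);
#' translocation junctions are shared iff both reference-side intervals
#' intersect chromosome-wise. Clusters become [event_observation()] rows:
#' cluster members are carriers; a non-carrier species is scored `ref_order`
#' when it demonstrably shows the reference arrangement in the event region
#' (for inversions: at least two shared markers inside the block interval,
#' all in one intact segment, with no detected inversion of its own
#' overlapping the region; for translocations: a single segment spanning the
#' breakpoint interval), and `uninformative` otherwise. The reference
#' species itself is scored `ref_order` — timing is still unbiased because
#' the parsimony step does not privilege the reference.
#'
#' @param inferred result of [infer_species_events()]
#' @param species all species in the analysis (default: reference + names of
#'   `inferred`)
#' @return an `event_observations` data.frame with extra columns `block_lo`,
#'   `block_hi`, `members` (comma-joined `species:segment` ids)
#' @export
build_observations <- function(inferred, species = NULL) {
  reference <- attr(inferred, "reference")
  if (is.null(species)) species <- c(reference, names(inferred))
  obs <- list()

  # ---- inversions ----
  items <- list()
  for (sp in names(inferred)) {
    inv <- inferred[[sp]]$inversions
    for (i in seq_len(nrow(inv)))
      items[[length(items) + 1L]] <- list(
        species = sp, rc = inv$ref_chromosome[i],
        bp1 = c(inv$bp1_lo[i], inv$bp1_hi[i]),
        bp2 = c(inv$bp2_lo[i], inv$bp2_hi[i]),
        block = c(inv$block_lo[i], inv$block_hi[i]),
        markers = attr(inv, "blocks")[[i]],
        min_count = inv$min_count[i], segment = inv$segment_id[i])
  }
  if (length(items)) {
    edges <- list()
    for (i in seq_along(items)) for (j in seq_along(items)) {
      if (j <= i) next
      a <- items[[i]]; b <- items[[j]]
      if (a$rc != b$rc || a$species == b$species) next
      v <- compare_via_reference(
        list(kind = "inversion", ref_chromosome = a$rc, bp1 = a$bp1, bp2 = a$bp2),
        list(kind = "inversion", ref_chromosome = b$rc, bp1 = b$bp1, bp2 = b$bp2))
      if (v$verdict == "shared_event") edges[[length(edges) + 1L]] <- c(i, j)
    }
    comp <- uf_components(length(items), edges)
    for (cid in unique(comp)) {
      mem <- items[comp == cid]
      carriers <- unique(vapply(mem, `[[`, "", "species"))
      rc <- mem[[1]]$rc
      lo <- min(vapply(mem, function(m) m$block[1], 1L))
      hi <- max(vapply(mem, function(m) m$block[2], 1L))
      cl_markers <- unique(unlist(lapply(mem, `[[`, "markers")))
      states <- stats::setNames(rep("uninformative", length(species)), species)
      states[carriers] <- "carrier"
      states[reference] <- "ref_order"
      for (sp in setdiff(species, c(carriers, reference)))
        if (informative_for_inversion(inferred[[sp]], rc, cl_markers))
          states[sp] <- "ref_order"
      obs[[length(obs) + 1L]] <- local({
        o <- event_observation(
          sprintf("inv_%s_%03d", rc, length(obs) + 1L), "inversion", rc,
          states, n_min = max(1L, max(vapply(mem, `[[`, 1L, "min_count"))))
        o$block_lo <- lo; o$block_hi <- hi
        o$members <- paste(vapply(mem, function(m)
          paste0(m$species, ":", m$segment), ""), collapse = ",")
        o
      })
    }
  }

  # ---- translocations ----
  jitems <- list()
  for (sp in names(inferred)) {
    jn <- inferred[[sp]]$segmentation$junctions
    for (i in seq_len(nrow(jn))) {
      sides <- list(
        list(rc = jn$left_ref_chromosome[i],
             iv = c(jn$left_gap_lo[i], jn$left_gap_hi[i])),
        list(rc = jn$right_ref_chromosome[i],
             iv = c(jn$right_gap_lo[i], jn$right_gap_hi[i])))
      ord <- order(vapply(sides, `[[`, "", "rc"))
      jitems[[length(jitems) + 1L]] <- list(
        species = sp, sideA = sides[[ord[1]]], sideB = sides[[ord[2]]],
        member = paste0(sp, ":", jn$query_chromosome[i], ":", i))
    }
  }
  if (length(jitems)) {
    edges <- list()
    ints <- function(a, b) a$rc == b$rc && a$iv[1] <= b$iv[2] && b$iv[1] <= a$iv[2]
    for (i in seq_along(jitems)) for (j in seq_along(jitems)) {
      if (j <= i) next
      a <- jitems[[i]]; b <- jitems[[j]]
      if (a$species == b$species) next
      if (ints(a$sideA, b$sideA) && ints(a$sideB, b$sideB))
        edges[[length(edges) + 1L]] <- c(i, j)
    }
    comp <- uf_components(length(jitems), edges)
    for (cid in unique(comp)) {
      mem <- jitems[comp == cid]
      carriers <- unique(vapply(mem, `[[`, "", "species"))
      sideA <- mem[[1]]$sideA; sideB <- mem[[1]]$sideB
      states <- stats::setNames(rep("uninformative", length(species)), species)
      states[carriers] <- "carrier"
      states[reference] <- "ref_order"
      for (sp in setdiff(species, c(carriers, reference)))
        if (informative_for_translocation(inferred[[sp]], sideA) ||
            informative_for_translocation(inferred[[sp]], sideB))
          states[sp] <- "ref_order"
      obs[[length(obs) + 1L]] <- local({
        o <- event_observation(
          sprintf("tr_%s_%s_%03d", sideA$rc, sideB$rc, length(obs) + 1L),
          "translocation", sideA$rc, states)
        o$block_lo <- sideA$iv[1]; o$block_hi <- sideA$iv[2]
        o$members <- paste(vapply(mem, `[[`, "", "member"), collapse = ",")
        o
      })
    }
  }
  if (!length(obs)) return(NULL)
  out <- do.call(rbind, obs)
  class(out) <- c("event_observations", "data.frame")
  out
}

# does this species attest the reference order of the event's own markers?
# witnesses are the cluster's block markers as mapped in this species: at
# least two of them, inside one segment on the right reference chromosome,
# outside any of the species' own detected inversion blocks, standing in
# the segment's reference direction. Flanking or interleaved markers that
# the event did not move are deliberately not counted: they are collinear
# whether or not the species carries the event.
informative_for_inversion <- function(sp_data, rc, cl_markers) {
  seg <- sp_data$segmentation
  inv <- sp_data$inversions
  own <- if (nrow(inv))
    inv[inv$ref_chromosome == rc, c("block_lo", "block_hi"), drop = FALSE]
  else NULL
  for (sid in names(seg$ranks)) {
    if (seg$segments$ref_chromosome[seg$segments$segment_id == sid] != rc) next
    full <- seg$ranks[[sid]]
    sel <- seg$markers[[sid]] %in% cl_markers
    rk <- full[sel]
    if (!is.null(own) && nrow(own)) {
      masked <- rep(FALSE, length(rk))
      for (k in seq_len(nrow(own)))
        masked <- masked | (rk >= own$block_lo[k] & rk <= own$block_hi[k])
      rk <- rk[!masked]
    }
    if (length(rk) < 2) next
    # the witnesses must actually stand in the reference direction of the
    # segment: a reversed or interleaved remainder attests nothing
    dir <- if (length(full) >= 3)
      sign(stats::cor(full, seq_along(full), method = "kendall")) else 1
    if (is.na(dir) || dir == 0) dir <- 1
    if (all(diff(rk) * dir > 0)) return(TRUE)
  }
  FALSE
}

# does this species attest intactness across the gap interval `side`?
informative_for_translocation <- function(sp_data, side) {
  segs <- sp_data$segmentation$segments
  sel <- segs$ref_chromosome == side$rc &
    segs$rank_lo <= side$iv[1] & segs$rank_hi >= side$iv[2] + 1
  any(sel)
}

#' Full timing pipeline from maps to per-branch counts
#'
#' Detection, cross-species clustering, observation building, lineage
#' assignment and per-branch counting in one call.
#'
#' @param maps named list of [genetic_map()]s
#' @param phy a [dated_phylogeny()]
#' @param reference reference species
#' @param orthology optional [orthology_table()]
#' @return list with `inferred`, `observations`, `assignments`, `counts`
#' @export
infer_timing <- function(maps, phy, reference = "tomato", orthology = NULL) {
  inferred <- infer_species_events(maps, reference, orthology)
  observations <- build_observations(inferred, species = phylo_species(phy))
  if (is.null(observations))
    return(list(inferred = inferred, observations = NULL,
                assignments = NULL,
                counts = count_events_by_branch(
                  structure(data.frame(), class = c("lineage_assignments",
                                                    "data.frame")), phy)))
  assignments <- assign_lineages(observations, phy, reference)
  counts <- count_events_by_branch(assignments, phy)
  list(inferred = inferred, observations = observations,
       assignments = assignments, counts = counts)
}
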