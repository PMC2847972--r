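#' Compare two rearrangement events seen against the common reference
#'
#' Implements the reference-mediated comparison rules. Both events must lie
#' on the same reference chromosome and are described by breakpoint regions
#' expressed as gap-index intervals on the reference (see
#' [partition_segments()] for the gap convention).
#'
#' For **inversions** the two events are the *same* event only if both
#' breakpoint regions coincide: each of the two flanking intervals must
#' intersect its counterpart. Overlapping inverted spans whose breakpoints
#' differ are two independent events. For **translocations** a single
#' intersecting breakpoint interval makes the events possibly shared, and
#' the breakpoint region narrows to the intersection.
#'
#' @param evA,evB lists with elements `kind` (`"inversion"` or
#'   `"translocation"`), `ref_chromosome`, and gap intervals: inversions
#'   carry `bp1` and `bp2` (each `c(lo, hi)`), translocations carry `bp`
#' @return a list with `verdict` (one of `"shared_event"`,
#'   `"independent_events"`, `"possibly_shared"`) and, for possibly shared
#'   translocations, `narrowed` — the intersected gap interval
#' @export
compare_via_reference <- function(evA, evB) {
  if (evA$kind != evB$kind) stop("events of different kinds are not comparable")
  if (evA$ref_chromosome != evB$ref_chromosome)
    stop("not comparable: events on different reference chromosomes")
  isect <- function(a, b) c(max(a[1], b[1]), min(a[2], b[2]))
  nonempty <- function(iv) iv[1] <= iv[2]
  if (evA$kind == "inversion") {
    ok1 <- nonempty(isect(evA$bp1, evB$bp1))
    ok2 <- nonempty(isect(evA$bp2, evB$bp2))
    if (ok1 && ok2) list(verdict = "shared_event")
    else list(verdict = "independent_events")
  } else {
    iv <- isect(evA$bp, evB$bp)
    if (nonempty(iv)) list(verdict = "possibly_shared", narrowed = iv)
    else list(verdict = "independent_events")
  }
}

#' All minimal sets of branches explaining a two-state pattern
#'
#' A rearrangement is a two-state character (ancestral order vs derived
#' order) on the fixed tree; a set of branches "explains" the observed tip
#' states if flipping the state once on each branch of the set, starting
#' from either root state, reproduces every *informative* tip (tips with
#' state `NA` are unconstrained). This enumerates branch subsets of
#' increasing size and returns all subsets of the minimal size, which is
#' exactly the set of most-parsimonious placements.
#'
#' @param phy a [dated_phylogeny()]
#' @param states named character vector over the tips, values `"A"`, `"B"`
#'   or `NA`
#' @param max_changes largest set size tried (default 4)
#' @return list with `score` (minimal number of changes, `Inf` if nothing
#'   up to `max_changes` works) and `sets` (list of character vectors of
#'   branch names)
#' @export
minimal_change_edge_sets <- function(phy, states, max_changes = 4) {
  tips <- phylo_species(phy)
  stopifnot(all(names(states) %in% tips))
  states <- states[tips[tips %in% names(states)]]
  obs <- !is.na(states)
  M <- branch_path_matrix(phy)[names(states), , drop = FALSE]
  brs <- colnames(M)
  consistent <- function(set) {
    parity <- if (length(set)) rowSums(M[, set, drop = FALSE]) %% 2 else
      rep(0, nrow(M))
    s0 <- unique(states[obs & parity == 0])
    s1 <- unique(states[obs & parity == 1])
    length(s0) <= 1 && length(s1) <= 1 &&
      (length(s0) == 0 || length(s1) == 0 || s0 != s1)
  }
  for (k in 0:max_changes) {
    sets <- if (k == 0) list(character(0)) else
      utils::combn(brs, k, simplify = FALSE)
    hits <- Filter(consistent, sets)
    if (length(hits)) return(list(score = k, sets = lapply(hits, sort)))
  }
  list(score = Inf, sets = list())
}

#' Construct an event observation
#'
#' The per-species presence pattern of one rearrangement event, as used for
#' timing. `states` gives one of `"carrier"` (the species' order differs
#' from the comparison order by this event), `"ref_order"` (the species
#' demonstrably shows the non-event order) or `"uninformative"` (the region
#' is translocated, scrambled or too sparsely mapped in that species) for
#' every species of the analysis.
#'
#' @param event_id identifier
#' @param kind `"inversion"` or `"translocation"`
#' @param ref_chromosome reference chromosome of the event region
#' @param states named character vector over all species
#' @param n_min,n_max number of events this observation stands for (a range
#'   when the narrative count is ambiguous); default 1
#' @param note free-text description
#' @return one-row data.frame of class `event_observation`
#' @export
event_observation <- function(event_id, kind, ref_chromosome, states,
                              n_min = 1L, n_max = n_min, note = "") {
  stopifnot(kind %in% c("inversion", "translocation"),
            all(states %in% c("carrier", "ref_order", "uninformative")))
  if (!any(states == "carrier")) stop("at least one species must carry the event")
  df <- data.frame(event_id = event_id, kind = kind,
                   ref_chromosome = ref_chromosome,
                   n_min = as.integer(n_min), n_max = as.integer(n_max),
                   note = note, stringsAsFactors = FALSE)
  for (sp in names(states)) df[[paste0("state_", sp)]] <- unname(states[sp])
  class(df) <- c("event_observation", "data.frame")
  df
}

obs_states <- function(obs_row) {
  cols <- grep("^state_", names(obs_row), value = TRUE)
  stats::setNames(as.character(obs_row[1, cols]), sub("^state_", "", cols))
}

#' Assign a rearrangement event to a branch of the dated phylogeny
#'
#' Two-state parsimony with the reference species not privileged: an event
#' recorded "relative to the reference" that is carried by every informative
#' non-reference species is assigned to the reference's own terminal branch
#' (the reference has the derived order). Carriers map to one character
#' state, species sharing the comparison order to the other, uninformative
#' species to `NA`; the most-parsimonious single-branch placements are
#' computed by [minimal_change_edge_sets()].
#'
#' Outcomes: a unique single branch (`rationale` `"shared_derived"`, or
#' `"reference_derived"` when it is the reference's terminal branch); a
#' candidate set of equally parsimonious branches (`"outgroup_uninformative"`,
#' no tie-breaking); or, when no single branch explains the pattern, the
#' minimal multi-branch placements (`"independent"`), meaning the pattern
#' requires that many independent events.
#'
#' @param obs an [event_observation()] row
#' @param phy a [dated_phylogeny()]
#' @param reference reference species name (default `"tomato"`)
#' @return list of class `lineage_assignment`: `event_id`, `kind`, `n_min`,
#'   `n_max`, `determined` (logical), `branch` (single branch or `NA`),
#'   `candidate_set` (character vector), `rationale`, `score`, `sets`
#' @export
assign_lineage <- function(obs, phy, reference = "tomato") {
  states <- obs_states(obs)
  sp <- phylo_species(phy)
  missing_sp <- setdiff(sp, names(states))
  if (length(missing_sp))
    stop("observation lacks states for: ", paste(missing_sp, collapse = ", "))
  chr_states <- ifelse(states[sp] == "carrier", "B",
                       ifelse(states[sp] == "ref_order", "A", NA))
  names(chr_states) <- sp
  res <- minimal_change_edge_sets(phy, chr_states)
  if (res$score == 0 || !length(res$sets))
    stop("degenerate pattern for event ", obs$event_id)
  out <- list(event_id = obs$event_id, kind = obs$kind,
              n_min = obs$n_min, n_max = obs$n_max,
              score = res$score, sets = res$sets)
  if (res$score == 1) {
    cands <- sort(vapply(res$sets, `[`, "", 1))
    if (length(cands) == 1) {
      out$determined <- TRUE
      out$branch <- cands
      out$candidate_set <- cands
      out$rationale <- if (cands == reference) "reference_derived" else "shared_derived"
    } else {
      out$determined <- FALSE
      out$branch <- NA_character_
      out$candidate_set <- cands
      out$rationale <- "outgroup_uninformative"
    }
  } else {
    out$determined <- FALSE
    out$branch <- NA_character_
    out$candidate_set <- sort(unique(unlist(res$sets)))
    out$rationale <- "independent"
  }
  class(out) <- "lineage_assignment"
  out
}

#' @export
print.lineage_assignment <- function(x, ...) {
  cat(x$event_id, "(", x$kind, "):",
      if (x$determined) paste("branch", x$branch)
      else paste0("{", paste(x$candidate_set, collapse = ", "), "}"),
      "-", x$rationale, "\n")
  invisible(x)
}

#' Assign every observation in a table
#'
#' @param observations a data.frame of stacked [event_observation()] rows
#'   (e.g. from [read_observations()])
#' @param phy a [dated_phylogeny()]
#' @param reference reference species name
#' @return data.frame of class `lineage_assignments`: one row per event with
#'   `event_id`, `kind`, `ref_chromosome`, `n_min`, `n_max`, `determined`,
#'   `branch`, `candidate_set` (comma-joined), `rationale`
#' @export
assign_lineages <- function(observations, phy, reference = "tomato") {
  rows <- lapply(seq_len(nrow(observations)), function(i) {
    a <- assign_lineage(observations[i, ], phy, reference)
    data.frame(event_id = a$event_id, kind = a$kind,
               ref_chromosome = observations$ref_chromosome[i],
               n_min = a$n_min, n_max = a$n_max,
               determined = a$determined,
               branch = if (a$determined) a$branch else NA_character_,
               candidate_set = paste(a$candidate_set, collapse = ","),
               rationale = a$rationale, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("lineage_assignments", "data.frame")
  out
}

#' Per-branch event counts
#'
#' Determined events add their count to their branch. Undetermined events
#' are never dropped: they add to the *maximum* count of every branch in
#' their candidate set and to the minimum of none, giving per-branch
#' `[count_min, count_max]` ranges. Inversions and translocations are
#' tabulated separately.
#'
#' @param assignments a `lineage_assignments` data.frame
#' @param phy a [dated_phylogeny()]
#' @return data.frame: `branch`, `kind`, `count_min`, `count_max`,
#'   `n_undetermined` (events whose candidate set contains the branch)
#' @export
count_events_by_branch <- function(assignments, phy) {
  brs <- phylo_branches(phy)
  kinds <- c("inversion", "translocation")
  out <- expand.grid(branch = brs, kind = kinds, stringsAsFactors = FALSE)
  out$count_min <- 0L; out$count_max <- 0L; out$n_undetermined <- 0L
  for (i in seq_len(nrow(assignments))) {
    a <- assignments[i, ]
    if (a$determined) {
      j <- which(out$branch == a$branch & out$kind == a$kind)
      out$count_min[j] <- out$count_min[j] + a$n_min
      out$count_max[j] <- out$count_max[j] + a$n_max
    } else {
      for (b in strsplit(a$candidate_set, ",")[[1]]) {
        j <- which(out$branch == b & out$kind == a$kind)
        if (!length(j)) next
        out$count_max[j] <- out$count_max[j] + a$n_max
        out$n_undetermined[j] <- out$n_undetermined[j] + 1L
      }
    }
  }
  out
}

#' Number of undetermined events for a candidate branch set
#'
#' @param assignments a `lineage_assignments` data.frame
#' @param branches character vector; events whose candidate set equals this
#'   set (in any order) are counted
#' @param kind `"inversion"` or `"translocation"`
#' @return total event count (summing `n_min`)
#' @export
undetermined_between <- function(assignments, branches, kind = "inversion") {
  key <- paste(sort(branches), collapse = ",")
  sel <- !assignments$determined & assignments$kind == kind &
    vapply(strsplit(assignments$candidate_set, ","),
           function(s) paste(sort(s), collapse = ",") == key, TRUE)
  sum(assignments$n_min[sel])
}

#' Pairwise map difference implied by per-branch counts
#'
#' The rearrangements separating two extant species are those on the
#' branches of the tip-to-tip path, so determined per-branch counts must sum
#' to the directly observed pairwise difference.
#'
#' @param assignments a `lineage_assignments` data.frame
#' @param phy a [dated_phylogeny()]
#' @param sp1,sp2 species names
#' @param kind `"inversion"` or `"translocation"`
#' @return list with `min` and `max` event counts on the path
#' @export
pairwise_difference <- function(assignments, phy, sp1, sp2, kind = "inversion") {
  path <- path_branches(phy, sp1, sp2)
  counts <- count_events_by_branch(assignments, phy)
  sel <- counts$branch %in% path & counts$kind == kind
  # undetermined events with their whole candidate set on the path are
  # certainly on the path, whatever the branch: add n to min as well
  extra_min <- 0L
  und <- assignments[!assignments$determined & assignments$kind == kind, ]
  for (i in seq_len(nrow(und))) {
    cs <- strsplit(und$candidate_set[i], ",")[[1]]
    if (all(cs %in% path)) extra_min <- extra_min + und$n_min[i]
  }
  list(min = sum(counts$count_min[sel]) + extra_min,
       max = sum(counts$count_max[sel]))
}

#' Read an observation table
#'
#' Tab-delimited with columns `event_id`, `kind`, `ref_chromosome`, `n_min`,
#' `n_max`, `note` and one `state_<species>` column per species, each entry
#' `carrier` / `ref_order` / `uninformative`.
#'
#' @param path file path
#' @return data.frame of class `event_observations`
#' @export
read_observations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("event_id", "kind", "ref_chromosome", "n_min", "n_max")
  if (!all(need %in% names(df)))
    stop("observation table needs columns: ", paste(need, collapse = ", "))
  st <- grep("^state_", names(df), value = TRUE)
  if (length(st) < 2) stop("observation table needs state_<species> columns")
  bad <- !unlist(df[st]) %in% c("carrier", "ref_order", "uninformative")
  if (any(bad)) stop("invalid state value(s) in ", path)
  class(df) <- c("event_observations", "data.frame")
  df
}
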