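phy5 <- solanaceae_phylogeny()
SPECIES <- phylo_species(phy5)

make_obs <- function(states, kind = "inversion", id = "ev1", rc = "T1",
                     n = 1L) {
  event_observation(id, kind, rc, stats::setNames(states, SPECIES), n_min = n)
}

test_that("reference-mediated comparison follows the breakpoint rules", {
  # markers a..j at ranks 1..10; gap k = between ranks k and k+1
  inv <- function(bp1, bp2) list(kind = "inversion", ref_chromosome = "T2",
                                 bp1 = bp1, bp2 = bp2)
  # identical flanking pairs (b,c) and (e,f): shared
  expect_equal(compare_via_reference(inv(c(2, 2), c(5, 5)),
                                     inv(c(2, 2), c(5, 5)))$verdict,
               "shared_event")
  # lower breakpoints (g,h) vs (e,g) differ: independent despite overlap
  expect_equal(compare_via_reference(inv(c(2, 2), c(7, 7)),
                                     inv(c(2, 2), c(5, 6)))$verdict,
               "independent_events")
  # translocations (g,i) vs (h,i): possibly shared, narrowed to (h,i)
  tr <- function(bp) list(kind = "translocation", ref_chromosome = "T2", bp = bp)
  res <- compare_via_reference(tr(c(7, 8)), tr(c(8, 8)))
  expect_equal(res$verdict, "possibly_shared")
  expect_equal(res$narrowed, c(8, 8))
  expect_equal(compare_via_reference(tr(c(2, 3)), tr(c(7, 8)))$verdict,
               "independent_events")
  expect_error(compare_via_reference(
    inv(c(1, 1), c(2, 2)),
    list(kind = "inversion", ref_chromosome = "T3", bp1 = c(1, 1), bp2 = c(2, 2))),
    "not comparable")
})

test_that("lineage assignment reproduces the narrative patterns", {
  # shared by potato and eggplant, region unscored in pepper and the
  # distant species: derived in tomato
  a <- assign_lineage(make_obs(c("ref_order", "carrier", "carrier",
                                 "uninformative", "uninformative")), phy5)
  expect_true(a$determined)
  expect_equal(a$branch, "tomato")
  expect_equal(a$rationale, "reference_derived")

  # shared by eggplant and pepper: derived on the ATPt branch
  a <- assign_lineage(make_obs(c("ref_order", "ref_order", "carrier",
                                 "carrier", "uninformative")), phy5)
  expect_equal(a$branch, "ATPt")

  # pepper-only with distant species uninformative: ATE or pepper
  a <- assign_lineage(make_obs(c("ref_order", "ref_order", "ref_order",
                                 "carrier", "uninformative")), phy5)
  expect_false(a$determined)
  expect_equal(a$candidate_set, c("ATE", "pepper"))
  expect_equal(a$rationale, "outgroup_uninformative")

  # single-species event with everything else in reference order
  a <- assign_lineage(make_obs(c("ref_order", "ref_order", "carrier",
                                 "ref_order", "ref_order")), phy5)
  expect_equal(a$branch, "eggplant")
  expect_equal(a$rationale, "shared_derived")

  # carriers not connected: two independent events required
  a <- assign_lineage(make_obs(c("ref_order", "carrier", "ref_order",
                                 "carrier", "ref_order")), phy5)
  expect_false(a$determined)
  expect_equal(a$rationale, "independent")
  expect_equal(a$score, 2)
})

test_that("counting keeps determined and undetermined events separate", {
  obs <- rbind(
    make_obs(c("ref_order", "ref_order", "carrier", "ref_order", "ref_order"),
             id = "e1"),
    make_obs(c("ref_order", "ref_order", "carrier", "ref_order", "ref_order"),
             id = "e2", n = 3L),
    make_obs(c("ref_order", "ref_order", "ref_order", "carrier",
               "uninformative"), id = "e3", n = 2L))
  asg <- assign_lineages(obs, phy5)
  counts <- count_events_by_branch(asg, phy5)
  inv <- counts[counts$kind == "inversion", ]
  expect_equal(inv$count_min[inv$branch == "eggplant"], 4L)
  expect_equal(inv$count_max[inv$branch == "eggplant"], 4L)
  expect_equal(inv$count_min[inv$branch == "pepper"], 0L)
  expect_equal(inv$count_max[inv$branch == "pepper"], 2L)
  expect_equal(inv$count_max[inv$branch == "ATE"], 2L)
  # conservation: determined plus undetermined equals the total
  expect_equal(sum(inv$count_min) + undetermined_between(asg, c("ATE", "pepper")),
               sum(obs$n_min))

  empty <- count_events_by_branch(asg[0, ], phy5)
  expect_true(all(empty$count_max == 0))
})

# exhaustive minimal-change oracle: enumerate internal-node labellings
oracle_edge_sets <- function(phy, states) {
  tree <- phy$tree
  labels <- c(tree$tip.label, tree$node.label)
  internals <- tree$node.label
  best <- Inf; sets <- list()
  grid <- expand.grid(rep(list(c("A", "B")), length(internals)),
                      stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    lab <- stats::setNames(as.character(grid[g, ]), internals)
    full <- c(states, lab)
    changes <- character(0)
    for (e in seq_len(nrow(tree$edge))) {
      par <- labels[tree$edge[e, 1]]; chd <- labels[tree$edge[e, 2]]
      if (chd %in% names(states) && is.na(states[chd])) next
      if (full[par] != full[chd]) changes <- c(changes, chd)
    }
    k <- length(changes)
    if (k < best) { best <- k; sets <- list(sort(changes)) }
    else if (k == best) sets <- unique(c(sets, list(sort(changes))))
  }
  list(score = best, sets = sets)
}

test_that("assign_lineage matches exhaustive minimal-change placement on all patterns", {
  # complete enumeration over {A, B, NA}^5, skipping all-missing and
  # change-free patterns
  vals <- c("A", "B", NA)
  grid <- expand.grid(rep(list(vals), 5), stringsAsFactors = FALSE)
  checked <- 0L
  for (g in seq_len(nrow(grid))) {
    states <- stats::setNames(as.character(grid[g, ]), SPECIES)
    obs_states <- states[!is.na(states)]
    if (length(unique(obs_states)) < 2) next
    mine <- minimal_change_edge_sets(phy5, states)
    oracle <- oracle_edge_sets(phy5, states)
    expect_equal(mine$score, oracle$score, info = paste(states, collapse = ","))
    expect_setequal(vapply(mine$sets, paste, "", collapse = "|"),
                    vapply(oracle$sets, paste, "", collapse = "|"))
    checked <- checked + 1L
  }
  expect_gt(checked, 100)
})

test_that("adding an uninformative species never changes a determined assignment", {
  pats <- list(
    c("ref_order", "carrier", "carrier", "carrier", "carrier"),
    c("ref_order", "ref_order", "carrier", "ref_order", "ref_order"),
    c("ref_order", "ref_order", "carrier", "carrier", "uninformative"))
  for (p in pats) {
    a1 <- assign_lineage(make_obs(p), phy5)
    stopifnot(a1$determined)
    for (i in which(p == "ref_order")[-1]) {
      p2 <- p; p2[i] <- "uninformative"
      a2 <- assign_lineage(make_obs(p2), phy5)
      if (a2$determined) expect_equal(a2$branch, a1$branch)
      else expect_true(a1$branch %in% a2$candidate_set)
    }
  }
})

test_that("observation tables validate their states", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("event_id\tkind\tref_chromosome\tn_min\tn_max\tstate_a\tstate_b",
               "e1\tinversion\tT1\t1\t1\tcarrier\twrong"), f)
  expect_error(read_observations(f), "invalid state")
})
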