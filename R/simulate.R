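#' Parameters for a marker-map evolution simulation
#'
#' The stated world of the simulator: a dated phylogeny, a root genome of
#' `chromosomes` chromosomes with `markers_per_chromosome` markers each, and
#' per-lineage Poisson processes of inversions and translocations (events
#' per million years, genome-wide). Translocations are a mix of reciprocal
#' exchanges of terminal segments and insertional events (an internal block
#' excised, the flanks rejoined, the block inserted into another chromosome,
#' inverted with probability `inverted_insertion_prop`). Inversion blocks
#' are uniform over rank intervals with a minimum of 2 markers. After
#' evolution, each species independently loses each marker with probability
#' `dropout` (different marker subsets mapped per species); cM positions are
#' cumulative uniform gaps. Chromosome number never changes.
#'
#' @param phy a [dated_phylogeny()] (default [solanaceae_phylogeny()])
#' @param chromosomes number of chromosomes (default 12)
#' @param markers_per_chromosome markers per root chromosome (>= 4)
#' @param inversion_rate inversions / MY / lineage (default 0.5)
#' @param translocation_rate translocations / MY / lineage (default 0.3)
#' @param reciprocal_prop proportion of translocations that are reciprocal
#'   (default 0.5); the rest are insertional
#' @param inverted_insertion_prop probability an inserted block is reversed
#'   (default 0.5)
#' @param dropout per-species marker dropout fraction in `[0, 1)`; scalar or
#'   named vector over species (default 0.2)
#' @param breakpoint_model `"uniform"` or `"hotspot"`
#' @param hotspot_gaps,hotspot_weight for the hotspot model: gap indices
#'   (recycled positionally on every chromosome) whose sampling weight is
#'   multiplied by `hotspot_weight`
#' @return a list of class `simulation_params`
#' @export
simulation_params <- function(phy = solanaceae_phylogeny(),
                              chromosomes = 12,
                              markers_per_chromosome = 40,
                              inversion_rate = 0.5,
                              translocation_rate = 0.3,
                              reciprocal_prop = 0.5,
                              inverted_insertion_prop = 0.5,
                              dropout = 0.2,
                              breakpoint_model = c("uniform", "hotspot"),
                              hotspot_gaps = NULL,
                              hotspot_weight = 20) {
  breakpoint_model <- match.arg(breakpoint_model)
  stopifnot(inversion_rate >= 0, translocation_rate >= 0,
            markers_per_chromosome >= 4, chromosomes >= 2,
            all(dropout >= 0), all(dropout < 1),
            reciprocal_prop >= 0, reciprocal_prop <= 1)
  sp <- phylo_species(phy)
  if (length(dropout) == 1) dropout <- stats::setNames(rep(dropout, length(sp)), sp)
  stopifnot(all(sp %in% names(dropout)))
  structure(list(phy = phy, chromosomes = chromosomes,
                 markers_per_chromosome = markers_per_chromosome,
                 inversion_rate = inversion_rate,
                 translocation_rate = translocation_rate,
                 reciprocal_prop = reciprocal_prop,
                 inverted_insertion_prop = inverted_insertion_prop,
                 dropout = dropout[sp],
                 breakpoint_model = breakpoint_model,
                 hotspot_gaps = hotspot_gaps,
                 hotspot_weight = hotspot_weight),
            class = "simulation_params")
}

root_genome <- function(params) {
  g <- lapply(seq_len(params$chromosomes), function(c)
    sprintf("C%02d.m%03d", c, seq_len(params$markers_per_chromosome)))
  names(g) <- sprintf("C%02d", seq_len(params$chromosomes))
  g
}

# gap weights for one chromosome of length n (gaps 0..n); hotspot gaps get
# an inflated weight, recycled by position
gap_weights <- function(params, n) {
  w <- rep(1, n + 1)
  if (params$breakpoint_model == "hotspot" && length(params$hotspot_gaps)) {
    hs <- params$hotspot_gaps[params$hotspot_gaps <= n]
    w[hs + 1] <- params$hotspot_weight
  }
  w
}

sample_gap <- function(params, n, lo = 0, hi = n) {
  idx <- lo:hi
  w <- gap_weights(params, n)[idx + 1]
  idx[sample.int(length(idx), 1, prob = w)]
}

#' Rearrangement primitives on genomes
#'
#' A genome is a named list chromosome -> ordered marker vector. These are
#' the three event operators of the simulator, exported so that evolutionary
#' scenarios can be constructed by hand (e.g. in tests or examples):
#' `apply_inversion` reverses markers `i+1 .. j` of chromosome `ch`;
#' `apply_reciprocal` exchanges the tails of two chromosomes after cut
#' positions `a` and `b`; `apply_insertional` excises markers `i+1 .. j`
#' from `chS` (the flanks rejoin) and inserts them, optionally reversed,
#' into `chT` after position `t`. `apply_event` dispatches a recorded event
#' from a `true_history`.
#'
#' @param genome named list of marker vectors
#' @param ch,chA,chB,chS,chT chromosome names
#' @param i,j,a,b,t 0-based cut positions (markers `k` and `k+1` flank cut `k`)
#' @param inverted logical: insert the block reversed?
#' @param ev a recorded event (list with `kind` and position fields)
#' @return the modified genome
#' @name rearrangement_ops
NULL

#' @rdname rearrangement_ops
#' @export
apply_inversion <- function(genome, ch, i, j) {
  v <- genome[[ch]]
  genome[[ch]] <- c(v[seq_len(i)], rev(v[(i + 1):j]),
                    if (j < length(v)) v[(j + 1):length(v)])
  genome
}

#' @rdname rearrangement_ops
#' @export
apply_reciprocal <- function(genome, chA, a, chB, b) {
  A <- genome[[chA]]; B <- genome[[chB]]
  genome[[chA]] <- c(A[seq_len(a)], B[(b + 1):length(B)])
  genome[[chB]] <- c(B[seq_len(b)], A[(a + 1):length(A)])
  genome
}

#' @rdname rearrangement_ops
#' @export
apply_insertional <- function(genome, chS, i, j, chT, t, inverted) {
  S <- genome[[chS]]
  block <- S[(i + 1):j]
  if (inverted) block <- rev(block)
  genome[[chS]] <- c(S[seq_len(i)], if (j < length(S)) S[(j + 1):length(S)])
  T_ <- genome[[chT]]
  genome[[chT]] <- append(T_, block, after = t)
  genome
}

flank_or_end <- function(v, idx) if (idx >= 1 && idx <= length(v)) v[idx] else ""

draw_inversion <- function(params, genome) {
  lens <- lengths(genome)
  ok <- lens >= 2
  ch <- names(genome)[sample.int(length(genome), 1, prob = ifelse(ok, lens, 0))]
  n <- length(genome[[ch]])
  for (try in 1:50) {
    g1 <- sample_gap(params, n); g2 <- sample_gap(params, n)
    i <- min(g1, g2); j <- max(g1, g2)
    if (j - i >= 2) break
  }
  if (j - i < 2) { i <- 0; j <- 2 }
  v <- genome[[ch]]
  list(kind = "inversion", chrom = ch, i = i, j = j,
       block = v[(i + 1):j],
       bp1 = c(flank_or_end(v, i), v[i + 1]),
       bp2 = c(v[j], flank_or_end(v, j + 1)))
}

draw_translocation <- function(params, genome) {
  lens <- lengths(genome)
  reciprocal <- stats::runif(1) < params$reciprocal_prop
  for (try in 1:50) {
    if (reciprocal) {
      chs <- sample(names(genome)[lens >= 2], 2)
      nA <- lens[[chs[1]]]; nB <- lens[[chs[2]]]
      a <- sample_gap(params, nA, 1, nA - 1)
      b <- sample_gap(params, nB, 1, nB - 1)
      if (a + (nB - b) >= 2 && b + (nA - a) >= 2) {
        A <- genome[[chs[1]]]; B <- genome[[chs[2]]]
        return(list(kind = "reciprocal", chromA = chs[1], a = a,
                    chromB = chs[2], b = b,
                    blockA = A[(a + 1):nA], blockB = B[(b + 1):nB],
                    bpA = c(A[a], A[a + 1]), bpB = c(B[b], B[b + 1])))
      }
    } else {
      src_ok <- lens >= 4  # block >= 2 and remainder >= 2
      if (!any(src_ok)) { reciprocal <- TRUE; next }
      chS <- names(genome)[sample.int(length(genome), 1,
                                      prob = ifelse(src_ok, lens, 0))]
      n <- length(genome[[chS]])
      g1 <- sample_gap(params, n, 1, n - 1); g2 <- sample_gap(params, n, 1, n - 1)
      i <- min(g1, g2); j <- max(g1, g2)
      if (j - i >= 2 && (n - (j - i)) >= 2) {
        chT <- sample(setdiff(names(genome), chS), 1)
        t <- sample_gap(params, length(genome[[chT]]))
        S <- genome[[chS]]
        return(list(kind = "insertional", chromS = chS, i = i, j = j,
                    chromT = chT, t = t,
                    inverted = stats::runif(1) < params$inverted_insertion_prop,
                    block = S[(i + 1):j],
                    bpS1 = c(flank_or_end(S, i), S[i + 1]),
                    bpS2 = c(S[j], flank_or_end(S, j + 1)),
                    bpT = c(flank_or_end(genome[[chT]], t),
                            flank_or_end(genome[[chT]], t + 1))))
      }
    }
  }
  NULL  # give up; caller skips the event
}

#' @rdname rearrangement_ops
#' @export
apply_event <- function(genome, ev) {
  switch(ev$kind,
         inversion = apply_inversion(genome, ev$chrom, ev$i, ev$j),
         reciprocal = apply_reciprocal(genome, ev$chromA, ev$a, ev$chromB, ev$b),
         insertional = apply_insertional(genome, ev$chromS, ev$i, ev$j,
                                         ev$chromT, ev$t, ev$inverted))
}

#' Simulate marker-map evolution along a dated phylogeny
#'
#' Evolves the root genome along every branch with
#' `Poisson(rate x duration)` inversions and translocations (interleaved in
#' random order), applies per-species marker dropout, assigns cM positions
#' by cumulative uniform gaps, and returns the tip maps together with the
#' complete true history: every event with its breakpoints, the genome at
#' every node, and the per-species retained marker sets. Deterministic under
#' a fixed seed.
#'
#' @param params a [simulation_params()]
#' @param seed integer seed (optional; uses the current RNG state if `NULL`)
#' @return list with `maps` (named list of [genetic_map()], one per tip),
#'   `orthology` (an [orthology_table()]) and `truth` (class `true_history`:
#'   `events` — list of per-branch event lists, `genomes` — named list of
#'   node/tip genomes (chromosome -> marker vector, before dropout),
#'   `retained` — named list of retained marker vectors, `params`)
#' @export
simulate_history <- function(params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phy <- params$phy
  tree <- phy$tree
  labels <- c(tree$tip.label, tree$node.label)
  root_label <- tree$node.label[1]
  genomes <- list()
  genomes[[root_label]] <- root_genome(params)
  events <- stats::setNames(vector("list", nrow(phy$branches)),
                            phy$branches$branch)
  # preorder: parents before children (ape trees are rooted; walk edges from
  # the root down)
  order_edges <- function() {
    done <- root_label
    out <- character(0)
    pending <- phy$branches$branch
    while (length(pending)) {
      ready <- pending[phy$branches[pending, "parent"] %in% done]
      out <- c(out, ready)
      done <- c(done, ready)
      pending <- setdiff(pending, ready)
    }
    out
  }
  for (br in order_edges()) {
    g <- genomes[[phy$branches[br, "parent"]]]
    dur <- phy$branches[br, "duration"]
    n_inv <- stats::rpois(1, params$inversion_rate * dur)
    n_tr <- stats::rpois(1, params$translocation_rate * dur)
    kinds <- sample(c(rep("inv", n_inv), rep("tr", n_tr)))
    evs <- list()
    for (k in kinds) {
      ev <- if (k == "inv") draw_inversion(params, g) else
        draw_translocation(params, g)
      if (is.null(ev)) next
      g <- apply_event(g, ev)
      evs[[length(evs) + 1L]] <- ev
    }
    events[[br]] <- evs
    genomes[[br]] <- g
  }
  # dropout + maps
  tips <- phylo_species(phy)
  retained <- list(); maps <- list()
  for (sp in tips) {
    g <- genomes[[sp]]
    all_mk <- unlist(g, use.names = FALSE)
    keep <- all_mk[stats::runif(length(all_mk)) >= params$dropout[[sp]]]
    retained[[sp]] <- keep
    rows <- list()
    for (ch in names(g)) {
      mk <- g[[ch]][g[[ch]] %in% keep]
      if (!length(mk)) next
      pos <- cumsum(c(0, stats::runif(length(mk) - 1, 1, 5)))
      rows[[ch]] <- data.frame(chromosome = paste0(substr(sp, 1, 2), "_", ch),
                               marker = mk, position_cM = pos,
                               stringsAsFactors = FALSE)
    }
    maps[[sp]] <- genetic_map(do.call(rbind, rows), sp)
  }
  truth <- structure(list(events = events, genomes = genomes,
                          retained = retained, params = params),
                     class = "true_history")
  list(maps = maps, orthology = shared_name_orthology(maps), truth = truth)
}

#' Replay a true history from the root
#'
#' Reapplies every recorded event branch by branch from the root genome and
#' checks that each node and tip genome is reproduced exactly — the
#' bookkeeping invariant of the simulator.
#'
#' @param truth a `true_history`
#' @return TRUE (invisibly); errors on any mismatch
#' @export
replay_history <- function(truth) {
  phy <- truth$params$phy
  root_label <- phy$tree$node.label[1]
  replayed <- list()
  replayed[[root_label]] <- truth$genomes[[root_label]]
  pending <- phy$branches$branch
  done <- root_label
  while (length(pending)) {
    ready <- pending[phy$branches[pending, "parent"] %in% done]
    for (br in ready) {
      g <- replayed[[phy$branches[br, "parent"]]]
      for (ev in truth$events[[br]]) g <- apply_event(g, ev)
      if (!identical(g, truth$genomes[[br]]))
        stop("replay mismatch at ", br)
      replayed[[br]] <- g
    }
    done <- c(done, ready)
    pending <- setdiff(pending, ready)
  }
  invisible(TRUE)
}

#' Count events per branch in a true history
#' @param truth a `true_history`
#' @return data.frame: branch, inversions, translocations
#' @export
true_event_counts <- function(truth) {
  brs <- names(truth$events)
  data.frame(
    branch = brs,
    inversions = vapply(truth$events, function(e)
      sum(vapply(e, function(x) x$kind == "inversion", TRUE)), 1L),
    translocations = vapply(truth$events, function(e)
      sum(vapply(e, function(x) x$kind != "inversion", TRUE)), 1L),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Write simulated maps, orthology and truth to a directory
#' @param sim result of [simulate_history()]
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$maps))
    write_genetic_map(sim$maps[[sp]], file.path(dir, paste0("map_", sp, ".tsv")))
  utils::write.table(as.data.frame(sim$orthology),
                     file.path(dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(events = lapply(sim$truth$events, function(evs)
      lapply(evs, function(e) e[setdiff(names(e), "")])),
      retained = sim$truth$retained),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
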