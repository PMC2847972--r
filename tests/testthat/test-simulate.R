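test_that("zero rates give identical tips and an empty history", {
  p <- simulation_params(inversion_rate = 0, translocation_rate = 0,
                         dropout = 0, markers_per_chromosome = 8)
  sim <- simulate_history(p, seed = 1)
  root <- sim$truth$genomes$ATN
  for (sp in names(sim$maps)) {
    g <- genome_from_map(sim$maps[[sp]])
    expect_equal(unname(lapply(g, c)), unname(root))
  }
  expect_true(all(lengths(sim$truth$events) == 0))
})

test_that("one seed reproduces the whole dataset exactly", {
  p <- simulation_params(markers_per_chromosome = 12)
  s1 <- simulate_history(p, seed = 33)
  s2 <- simulate_history(p, seed = 33)
  expect_equal(s1$maps, s2$maps)
  expect_equal(s1$truth$events, s2$truth$events)
})

test_that("replaying the recorded events reproduces every genome", {
  for (s in c(2, 14, 77)) {
    sim <- simulate_history(simulation_params(markers_per_chromosome = 15),
                            seed = s)
    expect_true(replay_history(sim$truth))
  }
})

test_that("per-branch event counts are Poisson(rate x duration)", {
  # scaled-down genomes keep 10,000 replicates affordable; the count layer
  # being tested is genome-size independent
  p <- tiny_params()
  set.seed(4)
  n <- 10000L
  counts <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    tc <- true_event_counts(simulate_history(p)$truth)
    counts[i, 1] <- tc$inversions[tc$branch == "c"]
    counts[i, 2] <- tc$translocations[tc$branch == "c"]
  }
  for (j in 1:2) {
    lambda <- c(0.3, 0.2)[j] * 4   # branch c spans the full root age
    obs <- table(factor(pmin(counts[, j], 6L), levels = 0:6))
    pr <- stats::dpois(0:5, lambda)
    pr <- c(pr, 1 - sum(pr))
    keep <- pr * n >= 5
    chi <- sum((obs[keep] - n * pr[keep])^2 / (n * pr[keep]))
    pval <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
    expect_gt(pval, 0.01)
  }
  # closed-form mean check on a second branch
  expect_lt(abs(mean(counts[, 1]) - 1.2), 4 * stats::sd(counts[, 1]) / sqrt(n))
})

test_that("dropout retains the expected marker fraction", {
  p <- simulation_params(inversion_rate = 0, translocation_rate = 0,
                         dropout = 0.2, markers_per_chromosome = 40)
  sim <- simulate_history(p, seed = 8)
  n_total <- 12 * 40
  for (sp in names(sim$truth$retained)) {
    frac <- length(sim$truth$retained[[sp]]) / n_total
    ci <- stats::binom.test(length(sim$truth$retained[[sp]]), n_total)$conf.int
    expect_true(ci[1] <= 0.8 && 0.8 <= ci[2])
    expect_true(frac > 0.7 && frac < 0.9)
  }
})

test_that("hotspot breakage produces more positional reuse than uniform", {
  breaks_of <- function(sim) {
    # (chromosome, gap index, branch) of every translocation cut
    out <- list()
    for (br in names(sim$truth$events)) for (e in sim$truth$events[[br]]) {
      if (e$kind == "reciprocal")
        out[[length(out) + 1L]] <- data.frame(
          key = c(paste(e$chromA, e$a), paste(e$chromB, e$b)), branch = br)
      else if (e$kind == "insertional")
        out[[length(out) + 1L]] <- data.frame(
          key = c(paste(e$chromS, e$i), paste(e$chromS, e$j),
                  paste(e$chromT, e$t)), branch = br)
    }
    if (!length(out)) return(0L)
    df <- do.call(rbind, out)
    # reuse multiplicity: extra cuts at positions struck from more than one
    # branch (a plain group count saturates once hotspots soak up all cuts)
    sum(unlist(tapply(df$branch, df$key, function(b)
      if (length(unique(b)) >= 2) length(b) - 1L else 0L)))
  }
  phy <- dated_phylogeny("((a,b)AB,c)R;", c(AB = 3, R = 6))
  base <- list(phy = phy, chromosomes = 2, markers_per_chromosome = 10,
               inversion_rate = 0, translocation_rate = 0.6, dropout = 0)
  p_uni <- do.call(simulation_params, base)
  p_hot <- do.call(simulation_params, c(base, list(
    breakpoint_model = "hotspot", hotspot_gaps = c(3L, 7L),
    hotspot_weight = 40)))
  set.seed(12)
  n <- 1000L
  tot_uni <- sum(vapply(seq_len(n), function(i)
    breaks_of(simulate_history(p_uni)), 1L))
  tot_hot <- sum(vapply(seq_len(n), function(i)
    breaks_of(simulate_history(p_hot)), 1L))
  expect_gt(tot_hot, tot_uni)
})

test_that("parameter validation rejects impossible worlds", {
  expect_error(simulation_params(markers_per_chromosome = 3))
  expect_error(simulation_params(dropout = 1))
  expect_error(simulation_params(inversion_rate = -1))
})

test_that("simulations round-trip through the file interface", {
  dir <- withr::local_tempdir()
  sim <- simulate_history(simulation_params(markers_per_chromosome = 8),
                          seed = 3)
  write_simulation(sim, dir)
  m <- read_genetic_map(file.path(dir, "map_tomato.tsv"))
  expect_equal(m, sim$maps$tomato)
  expect_true(file.exists(file.path(dir, "truth.json")))
})
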