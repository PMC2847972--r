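test_that("rounding is half away from zero", {
  expect_equal(round_half_away(0.05), 0.1)
  expect_equal(round_half_away(-0.05), -0.1)
  expect_equal(round_half_away(0.25), 0.3)
  expect_equal(round_half_away(1.04), 1.0)
  expect_equal(round_half_away(0.548), 0.5)
})

test_that("rates divide counts by branch durations with ranges", {
  phy <- solanaceae_phylogeny()
  counts <- data.frame(
    branch = c("tomato", "potato", "eggplant", "pepper", "ATPt"),
    kind = "inversion",
    count_min = c(4L, 2L, 16L, 1L, 0L),
    count_max = c(4L, 2L, 16L, 12L, 0L), stringsAsFactors = FALSE)
  r <- estimate_rates(counts, phy)
  get <- function(b, col) r[[col]][r$branch == b]
  expect_equal(get("tomato", "rate_min_rounded"), 0.5)
  expect_equal(get("potato", "rate_min_rounded"), 0.3)
  expect_equal(get("eggplant", "rate_min_rounded"), 1.0)
  expect_equal(get("pepper", "rate_min_rounded"), 0.1)
  expect_equal(get("pepper", "rate_max_rounded"), 0.6)
  expect_equal(get("ATPt", "rate_min"), 0)
  # rates times durations recover the counts exactly
  expect_equal(r$rate_min * r$duration_MY, as.numeric(r$count_min))
  expect_equal(r$rate_max * r$duration_MY, as.numeric(r$count_max))
  # per-chromosome normalisation divides by 12
  expect_equal(r$per_chromosome_min, r$rate_min / 12)
})

test_that("zero-duration branches are rejected at construction", {
  expect_error(dated_phylogeny("((a,b)AB,c)R;", c(AB = 0, R = 5)),
               "strictly less")
})

test_that("disjoint breakpoint intervals never group", {
  ev <- data.frame(event_id = c("e1", "e2"), lineage = c("x", "y"),
                   ref_chromosome = "T1", gap_lo = c(2L, 8L),
                   gap_hi = c(3L, 9L), stringsAsFactors = FALSE)
  g <- detect_breakpoint_reuse(ev, solanaceae_centromeres(),
                               solanaceae_reference_map())
  expect_equal(nrow(g), 0)
})

test_that("same-lineage overlaps do not count as reuse", {
  ev <- data.frame(event_id = c("e1", "e2"), lineage = "x",
                   ref_chromosome = "T1", gap_lo = c(2L, 3L),
                   gap_hi = c(4L, 5L), stringsAsFactors = FALSE)
  g <- detect_breakpoint_reuse(ev, solanaceae_centromeres(),
                               solanaceae_reference_map())
  expect_equal(nrow(g), 0)
})

test_that("reuse grouping is independent of event input order", {
  bp <- solanaceae_breakpoints()
  g1 <- detect_breakpoint_reuse(bp, solanaceae_centromeres(),
                                solanaceae_reference_map())
  set.seed(5)
  g2 <- detect_breakpoint_reuse(bp[sample(nrow(bp)), ],
                                solanaceae_centromeres(),
                                solanaceae_reference_map())
  expect_equal(g1[order(g1$ref_chromosome), ], g2[order(g2$ref_chromosome), ],
               ignore_attr = TRUE)
})

test_that("chained overlaps group by transitive closure", {
  ev <- data.frame(event_id = c("e1", "e2", "e3"),
                   lineage = c("x", "y", "z"), ref_chromosome = "T1",
                   gap_lo = c(2L, 4L, 6L), gap_hi = c(4L, 6L, 8L),
                   stringsAsFactors = FALSE)
  g <- detect_breakpoint_reuse(ev, solanaceae_centromeres(),
                               solanaceae_reference_map())
  expect_equal(nrow(g), 1)
  expect_equal(g$n_members, 3L)
})

test_that("expected reuse-group count matches the exhaustive birthday oracle", {
  # k events, each breaking a single uniform gap of m, all lineages
  # distinct: a group is a gap chosen at least twice
  m <- 4L; k <- 3L
  combos <- expand.grid(rep(list(seq_len(m)), k))
  exact <- mean(apply(combos, 1, function(gaps)
    sum(table(gaps) >= 2)))
  set.seed(17)
  nrep <- 3000L
  sim_groups <- vapply(seq_len(nrep), function(i) {
    gaps <- sample.int(m, k, replace = TRUE)
    ev <- data.frame(event_id = paste0("e", 1:k),
                     lineage = paste0("L", 1:k), ref_chromosome = "T1",
                     gap_lo = gaps, gap_hi = gaps, stringsAsFactors = FALSE)
    nrow(detect_breakpoint_reuse(ev, solanaceae_centromeres(),
                                 solanaceae_reference_map()))
  }, 1L)
  mc <- mean(sim_groups)
  se <- stats::sd(sim_groups) / sqrt(nrep)
  expect_lt(abs(mc - exact), 4 * se)
})

test_that("the packaged observations yield six reuse groups, five near centromeres", {
  g <- detect_breakpoint_reuse(solanaceae_breakpoints(),
                               solanaceae_centromeres(),
                               solanaceae_reference_map())
  expect_setequal(g$ref_chromosome, c("T3", "T4", "T5", "T9", "T11", "T12"))
  expect_equal(sum(g$centromere_proximal), 5L)
  expect_false(g$centromere_proximal[g$ref_chromosome == "T3"])
})
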