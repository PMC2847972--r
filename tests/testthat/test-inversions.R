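# build a one-chromosome segmentation whose query shows `order` (a
# permutation of 1..n) relative to a collinear reference
seg_for_order <- function(order, prefix = "m") {
  n <- length(order)
  ref <- mini_map("ref", "R1", paste0(prefix, 1:n))
  qry <- mini_map("qry", "Q1", paste0(prefix, order))
  orth <- shared_name_orthology(list(ref, qry))
  partition_segments(project_onto_reference(qry, ref, orth))
}

# oracle: all single reversals of the identity that produce `perm`
single_reversal_solutions <- function(perm) {
  n <- length(perm)
  out <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- 1:n
    v[i:j] <- rev(v[i:j])
    if (all(v == perm)) out[[length(out) + 1L]] <- c(i, j)
  }
  out
}

test_that("identity order yields no inversions", {
  seg <- seg_for_order(1:6)
  expect_equal(nrow(detect_inversions(seg, "Q1")), 0)
})

test_that("a single inverted block is found with the oracle's unique reversal", {
  perm <- c(1, 2, 5, 4, 3, 6)
  sols <- single_reversal_solutions(perm)
  expect_equal(sols, list(c(3, 5)))   # brute force: unique single reversal
  seg <- seg_for_order(perm)
  ev <- detect_inversions(seg, "Q1")
  expect_equal(nrow(ev), 1)
  expect_equal(c(ev$block_lo, ev$block_hi), c(3, 5))
  expect_equal(ev$block_first, "m3")
  expect_equal(ev$block_last, "m5")
  # breakpoints: the gaps flanked by (m2,m3) and (m5,m6)
  expect_equal(c(ev$bp1_lo, ev$bp1_hi), c(2, 2))
  expect_equal(c(ev$bp2_lo, ev$bp2_hi), c(5, 5))
  expect_equal(ev$min_count, 1L)
  expect_false(ev$at_least)
  expect_equal(ev$confidence, "high")
})

test_that("two disjoint decreasing runs give two events (two-reversal oracle)", {
  perm <- c(3, 2, 1, 6, 5, 4)
  # oracle: no single reversal works, one two-reversal solution set
  expect_length(single_reversal_solutions(perm), 0)
  two_rev <- function(perm) {
    n <- length(perm); sols <- list()
    combs <- utils::combn(n, 2)
    for (a in seq_len(ncol(combs))) for (b in seq_len(ncol(combs))) {
      v <- 1:n
      v[combs[1, a]:combs[2, a]] <- rev(v[combs[1, a]:combs[2, a]])
      v[combs[1, b]:combs[2, b]] <- rev(v[combs[1, b]:combs[2, b]])
      if (all(v == perm))
        sols[[length(sols) + 1L]] <- list(sort(c(combs[1, a], combs[2, a])),
                                          sort(c(combs[1, b], combs[2, b])))
    }
    sols
  }
  sols <- two_rev(perm)
  expect_true(length(sols) >= 1)
  seg <- seg_for_order(perm)
  ev <- detect_inversions(seg, "Q1")
  expect_equal(nrow(ev), 2)
  expect_setequal(paste(ev$block_lo, ev$block_hi), c("1 3", "4 6"))
  expect_true(all(!ev$at_least))
})

test_that("irreducible scrambles carry an at-least lower bound", {
  seg <- seg_for_order(c(2, 4, 1, 3))   # no clean contiguous decreasing run
  ev <- detect_inversions(seg, "Q1")
  expect_true(any(ev$at_least))
  expect_true(all(ev$min_count[ev$at_least] >= 2))
})

test_that("two-marker flips are reported but flagged uncertain", {
  ev <- detect_inversions(seg_for_order(c(1, 3, 2, 4)), "Q1")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$confidence, "uncertain")
  expect_equal(ev$n_markers, 2L)
})

test_that("segments with fewer than three shared markers are uninformative", {
  seg <- seg_for_order(1:2)
  ev <- detect_inversions(seg, "Q1")
  expect_equal(nrow(ev), 0)
  expect_true(attr(ev, "uninformative"))
})

test_that("detected flips replay to the observed order when exact", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(6:12, 1)
    perm <- 1:n
    # apply one or two random non-overlapping reversals
    i <- sample(1:(n - 2), 1); j <- sample((i + 1):min(n, i + 4), 1)
    perm[i:j] <- rev(perm[i:j])
    seg <- seg_for_order(perm)
    ev <- detect_inversions(seg, "Q1")
    if (any(ev$at_least)) next
    v <- 1:n
    for (k in seq_len(nrow(ev))) {
      lo <- ev$block_lo[k]; hi <- ev$block_hi[k]
      idx <- which(v %in% lo:hi)
      expect_equal(idx, seq(min(idx), max(idx)))  # contiguous in current order
      v[idx] <- rev(v[idx])
    }
    expect_equal(v, perm)
  }
})

test_that("detection is invariant to uniform cM rescaling", {
  perm <- c(1, 2, 6, 5, 4, 3, 7, 8)
  seg1 <- seg_for_order(perm)
  ref <- mini_map("ref", "R1", paste0("m", 1:8))
  qry <- mini_map("qry", "Q1", paste0("m", perm))
  qry$position_cM <- qry$position_cM * 3.7
  seg2 <- partition_segments(project_onto_reference(
    qry, ref, shared_name_orthology(list(ref, qry))))
  e1 <- detect_inversions(seg1, "Q1"); e2 <- detect_inversions(seg2, "Q1")
  cols <- c("block_lo", "block_hi", "bp1_lo", "bp1_hi", "bp2_lo", "bp2_hi",
            "min_count", "confidence")
  expect_equal(e1[, cols], e2[, cols], ignore_attr = TRUE)
})

test_that("single simulated inversions are recovered with containing breakpoints", {
  set.seed(31)
  hits <- 0L; total <- 0L
  for (rep in 1:40) {
    n <- 20
    i <- sample(0:(n - 3), 1); j <- sample((i + 2):n, 1)
    perm <- 1:n
    perm[(i + 1):j] <- rev(perm[(i + 1):j])
    # dropout <= 20% applied to the query side
    keep <- sort(sample(n, size = ceiling(n * 0.85)))
    markers <- paste0("m", perm)[paste0("m", perm) %in% paste0("m", keep)]
    ref <- mini_map("ref", "R1", paste0("m", 1:n))
    qry <- mini_map("qry", "Q1", markers)
    seg <- partition_segments(project_onto_reference(
      qry, ref, shared_name_orthology(list(ref, qry))))
    truth_block <- (i + 1):j
    visible <- sum(keep %in% truth_block) >= 2
    if (!visible) next
    total <- total + 1L
    ev <- detect_inversions(seg, "Q1")
    match <- which(ev$block_lo <= max(intersect(keep, truth_block)) &
                   ev$block_hi >= min(intersect(keep, truth_block)))
    if (length(match)) {
      hits <- hits + 1L
      k <- match[1]
      # breakpoint gap intervals contain the true gaps i and j
      expect_true(ev$bp1_lo[k] <= i && i <= ev$bp1_hi[k])
      expect_true(ev$bp2_lo[k] <= j && j <= ev$bp2_hi[k])
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("pericentric classification is by centromere containment", {
  cen <- solanaceae_centromeres()
  ref <- solanaceae_reference_map()
  ev_peri <- data.frame(ref_chromosome = "T1", block_lo = 8, block_hi = 13)
  ev_para <- data.frame(ref_chromosome = "T1", block_lo = 2, block_hi = 5)
  ev_unkn <- data.frame(ref_chromosome = "T99", block_lo = 2, block_hi = 5)
  expect_equal(classify_pericentric(ev_peri, cen, ref), "pericentric")
  expect_equal(classify_pericentric(ev_para, cen, ref), "paracentric")
  expect_equal(classify_pericentric(ev_unkn, cen, ref), "unclassified")
})

test_that("the packaged chromosome-1 pepper inversions split 2 pericentric / 2 paracentric", {
  obs <- solanaceae_observations()
  p1 <- obs[grepl("inv_T1_P1b", obs$event_id), ]
  expect_equal(nrow(p1), 4)
  cls <- vapply(seq_len(nrow(p1)), function(i)
    classify_pericentric(data.frame(ref_chromosome = p1$ref_chromosome[i],
                                    block_lo = p1$block_lo[i],
                                    block_hi = p1$block_hi[i]),
                         solanaceae_centromeres(),
                         solanaceae_reference_map()), "")
  expect_equal(sum(cls == "pericentric"), 2)
  expect_equal(sum(cls == "paracentric"), 2)
})
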