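proj_of <- function(maps, sp = NULL, ref = NULL) {
  if (is.null(sp)) sp <- names(maps)[2]
  if (is.null(ref)) ref <- names(maps)[1]
  orth <- shared_name_orthology(maps)
  suppressMessages(project_onto_reference(maps[[sp]], maps[[ref]], orth))
}

test_that("a translocated chromosome splits into lettered segments with a named breakpoint", {
  tom <- read_genetic_map(example_file("example_tomato.tsv"))
  egg <- read_genetic_map(example_file("example_eggplant.tsv"))
  orth <- read_orthology_table(example_file("example_orthology.tsv"))
  seg <- partition_segments(suppressMessages(
    project_onto_reference(egg, tom, orth)))
  expect_equal(seg$segments$segment_id, c("E4a", "E4b"))
  expect_equal(seg$segments$ref_chromosome, c("T10", "T4"))
  jn <- seg$junctions
  expect_equal(nrow(jn), 1)
  expect_equal(jn$left_marker, "TG386")
  expect_equal(jn$right_marker, "T677")
  expect_equal(nrow(seg$events), 1)
})

test_that("a collinear chromosome yields one segment and no events", {
  maps <- list(ref = mini_map("ref", "R1", paste0("m", 1:8)),
               qry = mini_map("qry", "Q1", paste0("m", 1:8)))
  seg <- partition_segments(proj_of(maps))
  expect_equal(nrow(seg$segments), 1)
  expect_equal(seg$segments$segment_id, "Q1")
  expect_equal(nrow(seg$junctions), 0)
  expect_equal(nrow(seg$events), 0)
})

test_that("a simulated reciprocal translocation is recovered segment for segment", {
  root <- list(C1 = paste0("a", 1:10), C2 = paste0("b", 1:10))
  derived <- apply_reciprocal(root, "C1", 6, "C2", 4)
  maps <- list(ref = genome_map("ref", root), qry = genome_map("qry", derived))
  seg <- partition_segments(proj_of(maps))
  expect_equal(nrow(seg$segments), 4)
  expect_equal(nrow(seg$junctions), 2)
  # composition matches the truth
  got <- lapply(seg$markers, sort)
  expect_true(any(vapply(got, identical, TRUE, sort(paste0("a", 1:6)))))
  expect_true(any(vapply(got, identical, TRUE, sort(paste0("b", 5:10)))))
  expect_equal(seg$events$kind, "reciprocal")
  expect_equal(nrow(seg$events), 1)
})

test_that("junction count equals segments minus chromosomes", {
  set.seed(3)
  sim <- simulate_history(simulation_params(
    inversion_rate = 0, translocation_rate = 0.2, dropout = 0,
    markers_per_chromosome = 20), seed = 5)
  orth <- sim$orthology
  for (sp in c("eggplant", "pepper")) {
    proj <- suppressMessages(
      project_onto_reference(sim$maps[[sp]], sim$maps$tomato, orth))
    seg <- suppressWarnings(partition_segments(proj))
    n_chrom_with_segments <- length(unique(seg$segments$query_chromosome))
    expect_equal(nrow(seg$junctions),
                 nrow(seg$segments) - n_chrom_with_segments)
    # segments partition the non-stray shared markers
    all_markers <- unlist(seg$markers, use.names = FALSE)
    expect_equal(anyDuplicated(all_markers), 0L)
    shared <- unlist(lapply(proj$chromosomes, `[[`, "marker"),
                     use.names = FALSE)
    strays <- if (is.null(seg$strays)) character(0) else seg$strays$marker
    expect_setequal(all_markers, setdiff(shared, strays))
  }
})

test_that("an embedded segment is flagged and counted as one insertional event", {
  root <- list(C1 = paste0("a", 1:10), C2 = paste0("b", 1:10))
  derived <- apply_insertional(root, "C2", 3, 7, "C1", 5, inverted = FALSE)
  maps <- list(ref = genome_map("ref", root), qry = genome_map("qry", derived))
  seg <- partition_segments(proj_of(maps))
  segs <- seg$segments
  emb <- segs[segs$embedded, ]
  expect_equal(nrow(emb), 1)
  expect_equal(emb$ref_chromosome, "C2")
  expect_equal(sum(seg$events$kind == "insertional"), 1)

  # two plain segments carry no embedded flag
  derived2 <- apply_reciprocal(root, "C1", 5, "C2", 5)
  seg2 <- partition_segments(proj_of(list(ref = genome_map("ref", root),
                                          qry = genome_map("qry", derived2))))
  expect_false(any(seg2$segments$embedded))
})

test_that("simulated insertional translocations match the embedded truth", {
  set.seed(9)
  ok <- 0L; total <- 0L
  for (s in 1:10) {
    root <- list(C1 = paste0("a", 1:12), C2 = paste0("b", 1:12))
    i <- sample(2:8, 1); j <- i + sample(2:3, 1)
    t <- sample(2:10, 1)
    derived <- apply_insertional(root, "C2", i, j, "C1", t, inverted = FALSE)
    seg <- partition_segments(proj_of(list(ref = genome_map("ref", root),
                                           qry = genome_map("qry", derived))))
    total <- total + 1L
    truth_block <- root$C2[(i + 1):j]
    emb <- seg$segments[seg$segments$embedded, ]
    if (nrow(emb) == 1 &&
        setequal(seg$markers[[emb$segment_id]], truth_block)) ok <- ok + 1L
  }
  expect_equal(ok, total)
})

test_that("single stray markers are excluded from segments and events", {
  ref <- genome_map("ref", list(R1 = paste0("m", 1:8), R2 = paste0("x", 1:4)))
  qry <- genome_map("qry", list(Q1 = c("m1", "m2", "m3", "x2", "m4", "m5")))
  seg <- partition_segments(proj_of(list(ref = ref, qry = qry)))
  expect_equal(nrow(seg$segments), 1)   # the two m-runs merge across the stray
  expect_equal(seg$strays$marker, "x2")
  expect_equal(nrow(seg$events), 0)
})
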