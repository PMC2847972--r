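#' Packaged Solanaceae observations
#'
#' The transcription of the per-chromosome multi-species comparisons for
#' tomato, potato, eggplant, pepper and Nicotiana: one row per rearrangement
#' event (or narrated group of events, `n_min`..`n_max`), with each species
#' scored as `carrier`, `ref_order` or `uninformative` for that event's
#' region. Feeding this table to [assign_lineages()] on
#' [solanaceae_phylogeny()] reproduces the per-branch counts: 4 inversions
#' on the tomato branch, 2 on potato, 4 on the ATPt branch, 16 on eggplant,
#' 1 on ATE, 1 on pepper and 11 of undetermined timing between the ATE and
#' pepper branches.
#'
#' @return an `event_observations` data.frame
#' @export
solanaceae_observations <- function() {
  read_observations(system.file("extdata", "solanaceae_observations.tsv",
                                package = "synkaryo", mustWork = TRUE))
}

#' Packaged Solanaceae translocation breakpoint intervals
#'
#' Reference-axis breakpoint regions (gap-index intervals) of the
#' translocation events, one row per event side, for breakpoint-reuse
#' screening. The underlying figures are not machine-readable, so ranks are
#' synthetic: they are constructed on the 20-marker reference scaffold to
#' satisfy every overlap and centromere-proximity relation the observations
#' state (overlapping independent breakpoints on chromosomes 3, 4, 5, 9, 11
#' and 12, all but the chromosome-3 case near the centromere).
#'
#' @return data.frame: event_id, lineage, ref_chromosome, gap_lo, gap_hi, note
#' @export
solanaceae_breakpoints <- function() {
  utils::read.table(system.file("extdata", "solanaceae_breakpoints.tsv",
                                package = "synkaryo", mustWork = TRUE),
                    sep = "\t", header = TRUE, quote = "", stringsAsFactors = FALSE,
                    comment.char = "#")
}

#' Packaged Solanaceae centromere table
#'
#' Approximate centromere positions of the 12 reference chromosomes on the
#' synthetic reference scaffold (between the markers of rank 10 and 11).
#' @return a `centromere_table`
#' @export
solanaceae_centromeres <- function() {
  read_centromere_table(system.file("extdata", "solanaceae_centromeres.tsv",
                                    package = "synkaryo", mustWork = TRUE))
}

#' Synthetic reference marker scaffold
#'
#' A deterministic stand-in for the reference (tomato) genetic map: 12
#' chromosomes `T1`..`T12`, 20 markers each (`T1_M01`..`T1_M20`, ...) at a
#' uniform 5 cM spacing. The packaged breakpoint and centromere tables are
#' expressed on this scaffold.
#' @param markers_per_chromosome default 20
#' @return a [genetic_map()] for species `"tomato"`
#' @export
solanaceae_reference_map <- function(markers_per_chromosome = 20) {
  m <- markers_per_chromosome
  loci <- do.call(rbind, lapply(1:12, function(c) data.frame(
    chromosome = paste0("T", c),
    marker = sprintf("T%d_M%02d", c, seq_len(m)),
    position_cM = 5 * (seq_len(m) - 1),
    stringsAsFactors = FALSE)))
  genetic_map(loci, "tomato")
}

#' Write the packaged fixture files to a directory
#'
#' Copies the observation, breakpoint, centromere, tree and config files and
#' writes the synthetic reference scaffold map, so that the whole fixture can
#' be inspected or fed back through the file-based interfaces.
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_solanaceae_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("solanaceae_observations.tsv", "solanaceae_breakpoints.tsv",
              "solanaceae_centromeres.tsv", "solanaceae_tree.nwk",
              "solanaceae_config.json"))
    file.copy(system.file("extdata", f, package = "synkaryo", mustWork = TRUE),
              file.path(dir, f), overwrite = TRUE)
  write_genetic_map(solanaceae_reference_map(),
                    file.path(dir, "solanaceae_reference_scaffold.tsv"))
  invisible(dir)
}
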