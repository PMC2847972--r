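#' Project a species map onto a reference map
#'
#' The central coordinate change of the whole analysis: every marker of the
#' query species that has a high-confidence ortholog on the reference map is
#' annotated with its reference chromosome and its *reference rank* — the
#' 1-based order index of the orthologous marker among all high-confidence
#' markers of that reference chromosome. All downstream interval logic
#' (segments, breakpoints, inversions) operates on these ranks: cM scales of
#' different species are not comparable, marker order is.
#'
#' Low-confidence markers (on either map) are excluded from the projection
#' and counted in the `excluded_low_confidence` attribute. A query
#' chromosome sharing no markers with the reference is kept with zero rows
#' and flagged uninformative rather than erroring.
#'
#' @param map query [genetic_map()]
#' @param ref reference [genetic_map()]
#' @param orth an [orthology_table()] covering both species
#' @return object of class `reference_projection`: list with `species`,
#'   `reference`, `chromosomes` (named list of data.frames with columns
#'   `marker`, `position_cM`, `ref_marker`, `ref_chromosome`, `ref_rank`, in
#'   query-map order), `uninformative` (character vector of query chromosomes
#'   with no shared markers) and `ref_order` (named list: reference
#'   chromosome -> its full high-confidence marker vector in map order).
#' @export
project_onto_reference <- function(map, ref, orth) {
  qsp <- map$species[1]; rsp <- ref$species[1]
  o_q <- orth[orth$species == qsp, ]
  o_r <- orth[orth$species == rsp, ]
  if (nrow(o_q) == 0 || nrow(o_r) == 0)
    stop("orthology table does not cover both species ", qsp, " and ", rsp)
  # group -> reference marker
  ref_of_group <- stats::setNames(o_r$marker, o_r$group_id)
  group_of_qmarker <- stats::setNames(o_q$group_id, o_q$marker)

  ref_hi <- ref[ref$confidence == "high", ]
  ref_chrom_of <- stats::setNames(ref_hi$chromosome, ref_hi$marker)
  ref_order <- split(ref_hi$marker, ref_hi$chromosome)
  ref_rank_of <- stats::setNames(
    unlist(lapply(ref_order, seq_along), use.names = FALSE),
    unlist(ref_order, use.names = FALSE))

  n_low <- 0L
  chroms <- list()
  uninformative <- character(0)
  for (ch in unique(map$chromosome)) {
    loci <- map[map$chromosome == ch, ]
    n_low <- n_low + sum(loci$confidence == "low")
    loci <- loci[loci$confidence == "high", ]
    grp <- group_of_qmarker[loci$marker]
    rmk <- ref_of_group[grp]
    keep <- !is.na(rmk) & rmk %in% names(ref_rank_of)
    df <- data.frame(marker = loci$marker[keep],
                     position_cM = loci$position_cM[keep],
                     ref_marker = unname(rmk[keep]),
                     ref_chromosome = unname(ref_chrom_of[rmk[keep]]),
                     ref_rank = unname(ref_rank_of[rmk[keep]]),
                     stringsAsFactors = FALSE)
    rownames(df) <- NULL
    chroms[[ch]] <- df
    if (nrow(df) == 0) uninformative <- c(uninformative, ch)
  }
  if (n_low > 0)
    message(n_low, " low-confidence marker(s) excluded from projection of ", qsp)
  structure(list(species = qsp, reference = rsp, chromosomes = chroms,
                 uninformative = uninformative, ref_order = ref_order),
            class = "reference_projection",
            excluded_low_confidence = n_low)
}

#' @export
print.reference_projection <- function(x, ...) {
  n <- sum(vapply(x$chromosomes, nrow, 1L))
  cat("Projection of", x$species, "onto", x$reference, "-",
      length(x$chromosomes), "chromosomes,", n, "shared markers")
  if (length(x$uninformative))
    cat(" (uninformative:", paste(x$uninformative, collapse = ", "), ")")
  cat("\n")
  invisible(x)
}

# Named vector marker -> reference gap index helper.
# Gap g on a reference chromosome is the interval between the markers of
# global rank g and g+1 (1 .. n-1); gap 0 and gap n are the chromosome ends.
ref_gap_interval <- function(left_rank, right_rank) {
  # open rank interval (left, right) expressed as the set of gap indices
  stopifnot(right_rank > left_rank)
  seq.int(left_rank, right_rank - 1L)
}
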