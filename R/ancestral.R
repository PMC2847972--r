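#' Genome view of a genetic map
#'
#' Chromosome -> ordered marker vector (high-confidence loci, position
#' order). The unit on which karyotype arrangements are compared.
#' @param map a [genetic_map()]
#' @return named list of character vectors
#' @export
genome_from_map <- function(map) {
  hi <- map[map$confidence == "high", ]
  split(hi$marker, hi$chromosome)
}

#' Reference painting of markers
#'
#' Named vector marker -> reference chromosome, from the reference map's
#' high-confidence loci. "Painting" a genome by this vector assigns every
#' shared marker the colour of its reference chromosome.
#' @param ref reference [genetic_map()]
#' @return named character vector
#' @export
reference_painting <- function(ref) {
  hi <- ref[ref$confidence == "high", ]
  stats::setNames(hi$chromosome, hi$marker)
}

#' Arrangement of one painted chromosome within a genome
#'
#' The comparison unit of ancestral reconstruction: the markers painted `c`
#' within a genome, restricted to the marker set `keep`, grouped into
#' maximal runs (other painted keep-markers act as separators; markers
#' outside `keep` or unpainted are invisible). Each run is reported in
#' canonical orientation (marker order on a genetic map is unsigned)
#' together with the identity of its neighbouring keep-markers. Two genomes
#' "agree" on chromosome `c` iff these structures are identical
#' ([arrangement_equal()]).
#'
#' @param genome named list chromosome -> marker vector
#' @param painting marker -> reference chromosome ([reference_painting()])
#' @param c reference chromosome id
#' @param keep marker subset on which the arrangement is asserted
#' @return list of blocks, each `list(markers, left, right)`
#' @export
chromosome_arrangement <- function(genome, painting, c, keep) {
  blocks <- list()
  for (ch in names(genome)) {
    v <- genome[[ch]]
    v <- v[v %in% keep & v %in% names(painting)]
    if (!length(v)) next
    paint <- unname(painting[v])
    if (!any(paint == c)) next
    r <- rle(paint == c)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      seqm <- v[starts[k]:ends[k]]
      # neighbours are recorded by marker identity: paint-level annotation
      # lets two independent insertions of different foreign markers at the
      # same spot masquerade as the same arrangement
      left <- if (starts[k] > 1) v[starts[k] - 1L] else "END"
      right <- if (ends[k] < length(v)) v[ends[k] + 1L] else "END"
      # canonical orientation: marker order is unsigned, flip to the
      # lexicographically smaller reading
      fwd <- paste(seqm, collapse = "|"); rev_ <- paste(rev(seqm), collapse = "|")
      if (rev_ < fwd) { seqm <- rev(seqm); tmp <- left; left <- right; right <- tmp }
      blocks[[length(blocks) + 1L]] <-
        list(markers = seqm, left = left, right = right)
    }
  }
  keys <- vapply(blocks, function(b) paste(b$markers, collapse = "|"), "")
  blocks[order(keys)]
}

#' Compare two chromosome arrangements
#' @param a1,a2 results of [chromosome_arrangement()] on a common marker set
#' @param organization when `FALSE`, compare block marker content and order
#'   only, ignoring the junction structure
#' @return logical
#' @export
arrangement_equal <- function(a1, a2, organization = TRUE) {
  if (length(a1) != length(a2)) return(FALSE)
  if (organization) return(identical(a1, a2))
  identical(lapply(a1, `[[`, "markers"), lapply(a2, `[[`, "markers"))
}

#' Reconstruct the karyotype of one ancestral node
#'
#' Chromosome-by-chromosome parsimony, reference-painted: for each reference
#' chromosome, the arrangements of the node's two daughter lineages are
#' compared on their common markers. If they agree, both preserve the
#' ancestral arrangement (`resolved`). If they differ, the daughter agreeing
#' with at least one more-distant species preserves it (`resolved`, with the
#' other daughter recorded as derived). If no outgroup is decisive, the
#' chromosome is `partially_resolved` when the daughters still agree on
#' marker order within segments (translocation organization undecidable), or
#' `unknown` otherwise. A daughter that is itself an ancestral node is
#' represented by the extant arrangement chosen when that node was
#' reconstructed, so nodes must be processed tip-ward to root-ward (see
#' [reconstruct_karyotypes()]).
#'
#' A node with no species outside it on the tree (the root) is refused:
#' polarity would require a more distant species.
#'
#' @param phy a [dated_phylogeny()]
#' @param node internal node label
#' @param genomes named list of tip genomes (see [genome_from_map()])
#' @param painting marker -> reference chromosome ([reference_painting()])
#' @param representatives named list from already-reconstructed child nodes:
#'   `representatives[[node]][[chromosome]]` = tip label standing in for
#'   that node's arrangement (or `NA` if unknown)
#' @return object of class `ancestral_karyotype`: list with `node`, `table`
#'   (data.frame: chromosome, status, representative, derived_lineage,
#'   n_markers) and `arrangements` (named list of block structures for
#'   non-unknown chromosomes)
#' @export
reconstruct_node <- function(phy, node, genomes, painting,
                             representatives = list()) {
  kids <- node_children(phy, node)
  if (length(kids) != 2) stop("node must be binary: ", node)
  outgroup_tips <- setdiff(phylo_species(phy), tips_below(phy, node))
  if (!length(outgroup_tips))
    stop("cannot reconstruct ", node, ": requires a more distant species")
  # order outgroups by increasing divergence (age of the MRCA with the node)
  og_age <- vapply(outgroup_tips, function(o) {
    anc <- c(node, ancestor_chain(phy, node))
    anc_o <- c(o, ancestor_chain(phy, o))
    phy$ages[anc[anc %in% anc_o][1]]
  }, 1.0)
  outgroup_tips <- outgroup_tips[order(og_age)]

  rep_of <- function(kid, c) {
    if (kid %in% names(genomes)) return(kid)
    r <- representatives[[kid]][[c]]
    if (is.null(r) || is.na(r)) NA_character_ else r
  }
  chroms <- sort(unique(unname(painting)))
  rows <- list(); arrs <- list(); keeps <- list()
  for (c in chroms) {
    r1 <- rep_of(kids[1], c); r2 <- rep_of(kids[2], c)
    if (is.na(r1) || is.na(r2)) {
      rows[[c]] <- data.frame(chromosome = c, status = "unknown",
                              representative = NA_character_,
                              derived_lineage = NA_character_, n_markers = 0L,
                              stringsAsFactors = FALSE)
      next
    }
    g1 <- genomes[[r1]]; g2 <- genomes[[r2]]
    keep <- intersect(unlist(g1, use.names = FALSE), unlist(g2, use.names = FALSE))
    keep <- keep[keep %in% names(painting)]
    a1 <- chromosome_arrangement(g1, painting, c, keep)
    a2 <- chromosome_arrangement(g2, painting, c, keep)
    nm <- sum(unname(painting[keep]) == c)
    keeps[[c]] <- keep
    if (arrangement_equal(a1, a2)) {
      rows[[c]] <- data.frame(chromosome = c, status = "resolved",
                              representative = r1,
                              derived_lineage = NA_character_, n_markers = nm,
                              stringsAsFactors = FALSE)
      arrs[[c]] <- a1
      next
    }
    decided <- NA_integer_; dec_keep <- NULL; dec_arr <- NULL
    for (o in outgroup_tips) {
      keep3 <- intersect(keep, unlist(genomes[[o]], use.names = FALSE))
      b1 <- chromosome_arrangement(g1, painting, c, keep3)
      b2 <- chromosome_arrangement(g2, painting, c, keep3)
      bo <- chromosome_arrangement(genomes[[o]], painting, c, keep3)
      e1 <- arrangement_equal(b1, bo); e2 <- arrangement_equal(b2, bo)
      if (xor(e1, e2)) {
        decided <- if (e1) 1L else 2L
        # the outgroup corroborates the winner only on the markers it
        # shares: the resolved claim must not extend beyond them
        dec_keep <- keep3
        dec_arr <- if (e1) b1 else b2
        break
      }
    }
    if (!is.na(decided)) {
      anc_rep <- if (decided == 1L) r1 else r2
      der <- if (decided == 1L) kids[2] else kids[1]
      rows[[c]] <- data.frame(chromosome = c, status = "resolved",
                              representative = anc_rep, derived_lineage = der,
                              n_markers = sum(unname(painting[dec_keep]) == c),
                              stringsAsFactors = FALSE)
      arrs[[c]] <- dec_arr
      keeps[[c]] <- dec_keep
    } else if (arrangement_equal(a1, a2, organization = FALSE)) {
      rows[[c]] <- data.frame(chromosome = c, status = "partially_resolved",
                              representative = r1,
                              derived_lineage = NA_character_, n_markers = nm,
                              stringsAsFactors = FALSE)
    } else {
      rows[[c]] <- data.frame(chromosome = c, status = "unknown",
                              representative = NA_character_,
                              derived_lineage = NA_character_, n_markers = nm,
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows); rownames(tab) <- NULL
  structure(list(node = node, table = tab, arrangements = arrs,
                 marker_sets = keeps),
            class = "ancestral_karyotype")
}

#' Reconstruct all requested ancestral karyotypes, tip-ward to root-ward
#'
#' @param phy a [dated_phylogeny()]
#' @param maps named list of tip [genetic_map()]s (names = species)
#' @param reference reference species name (must be in `maps`)
#' @param orthology optional [orthology_table()]; when supplied, non-reference
#'   markers are first translated to their reference ortholog names so that
#'   genomes share the reference namespace
#' @param nodes internal nodes to reconstruct (default: all except the root)
#' @return named list of `ancestral_karyotype` objects
#' @export
reconstruct_karyotypes <- function(phy, maps, reference = "tomato",
                                   orthology = NULL, nodes = NULL) {
  tree <- phy$tree
  root_label <- tree$node.label[1]
  if (is.null(nodes)) nodes <- setdiff(tree$node.label, root_label)
  nodes <- nodes[order(phy$ages[nodes])]  # tip-ward first
  genomes <- lapply(maps, genome_from_map)
  if (!is.null(orthology)) {
    ref_of_group <- stats::setNames(
      orthology$marker[orthology$species == reference],
      orthology$group_id[orthology$species == reference])
    for (sp in setdiff(names(genomes), reference)) {
      o_sp <- orthology[orthology$species == sp, ]
      to_ref <- stats::setNames(unname(ref_of_group[o_sp$group_id]), o_sp$marker)
      genomes[[sp]] <- lapply(genomes[[sp]], function(v) {
        out <- unname(to_ref[v]); out[!is.na(out)]
      })
    }
  }
  painting <- reference_painting(maps[[reference]])
  reps <- list(); out <- list()
  for (nd in nodes) {
    k <- reconstruct_node(phy, nd, genomes, painting, reps)
    out[[nd]] <- k
    reps[[nd]] <- stats::setNames(as.list(k$table$representative),
                                  k$table$chromosome)
  }
  out
}

#' Text rendering of an ancestral karyotype
#'
#' One line per chromosome: status, representative extant arrangement, and
#' the painted segment structure; unknown chromosomes are drawn broken
#' (`~~//~~`).
#' @param kary an `ancestral_karyotype`
#' @return character vector of lines, invisibly (also printed)
#' @export
render_karyotype <- function(kary) {
  lines <- sprintf("Karyotype of %s", kary$node)
  for (i in seq_len(nrow(kary$table))) {
    r <- kary$table[i, ]
    body <- if (r$status == "unknown") "~~//~~ (organization undetermined)"
    else {
      a <- kary$arrangements[[r$chromosome]]
      if (is.null(a)) sprintf("order as in %s (organization undetermined)",
                              r$representative)
      else paste(vapply(a, function(b)
        sprintf("[%d markers|%s..%s]", length(b$markers), b$left, b$right), ""),
        collapse = " ")
    }
    lines <- c(lines, sprintf("  %-6s %-18s rep=%-10s %s", r$chromosome,
                              r$status, ifelse(is.na(r$representative), "-",
                                               r$representative), body))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.ancestral_karyotype <- function(x, ...) {
  cat("Ancestral karyotype", x$node, "-",
      sum(x$table$status == "resolved"), "resolved /",
      sum(x$table$status == "partially_resolved"), "partial /",
      sum(x$table$status == "unknown"), "unknown of",
      nrow(x$table), "chromosomes\n")
  invisible(x)
}
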