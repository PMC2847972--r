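#' Construct a genetic map
#'
#' A genetic map is the raw observable of this package: for one species, an
#' ordered set of marker loci with centimorgan (cM) positions per chromosome
#' and a per-marker mapping-confidence flag. Only marker *order* is treated
#' as a reliable signal downstream; all interval logic is rank-based because
#' cM scales are not comparable between species.
#'
#' Co-segregating markers (identical cM position) are ordered by marker id
#' (lexicographic), a deterministic convention: their true order is
#' unknowable from a genetic map.
#'
#' @param loci data.frame with columns `chromosome`, `marker`, `position_cM`
#'   and optionally `confidence` (`"high"`/`"low"`, default high)
#' @param species species identifier (free string)
#' @return a `genetic_map`: data.frame (species, chromosome, marker,
#'   position_cM, confidence) sorted by chromosome then position then marker
#' @export
genetic_map <- function(loci, species) {
  stopifnot(is.data.frame(loci))
  need <- c("chromosome", "marker", "position_cM")
  if (!all(need %in% names(loci)))
    stop("loci need columns: ", paste(need, collapse = ", "))
  if (!"confidence" %in% names(loci)) loci$confidence <- "high"
  if (nrow(loci) == 0) stop("no loci")
  loci$chromosome <- as.character(loci$chromosome)
  loci$marker <- as.character(loci$marker)
  loci$position_cM <- as.numeric(loci$position_cM)
  loci$confidence <- as.character(loci$confidence)
  if (any(is.na(loci$position_cM))) stop("non-numeric position_cM")
  if (any(loci$position_cM < 0)) stop("negative position_cM")
  if (!all(loci$confidence %in% c("high", "low")))
    stop("confidence must be 'high' or 'low'")
  if (anyDuplicated(loci$marker)) {
    dup <- unique(loci$marker[duplicated(loci$marker)])
    stop("duplicate marker id(s) within species map: ", paste(dup, collapse = ", "))
  }
  out <- data.frame(species = species,
                    chromosome = loci$chromosome,
                    marker = loci$marker,
                    position_cM = loci$position_cM,
                    confidence = loci$confidence,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$position_cM, out$marker), ]
  rownames(out) <- NULL
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("Genetic map of", x$species[1], "-", length(unique(x$chromosome)),
      "chromosomes,", nrow(x), "loci (",
      sum(x$confidence == "low"), "low-confidence )\n")
  invisible(x)
}

#' Read a genetic map from a tab-delimited file
#'
#' Expected columns (header required): `species`, `chromosome`, `marker`,
#' `position_cM`, `confidence`. One file holds the map of one species.
#' Malformed rows are reported with their line number.
#'
#' @param path file path
#' @return a [genetic_map()]
#' @export
read_genetic_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (length(lines) < 1) stop("empty map file: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("species", "chromosome", "marker", "position_cM", "confidence")
  if (!all(need %in% header))
    stop("map file must have header columns: ", paste(need, collapse = ", "))
  if (length(lines) == 1) stop("no loci in map file: ", path)
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1] + 1L
    stop("malformed row at line ", bad, " of ", path,
         " (expected ", length(header), " fields, got ", nf[bad - 1L], ")")
  }
  m <- do.call(rbind, body)
  colnames(m) <- header
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  pos <- suppressWarnings(as.numeric(df$position_cM))
  if (any(is.na(pos))) {
    bad <- which(is.na(pos))[1] + 1L
    stop("non-numeric position_cM at line ", bad, " of ", path)
  }
  if (any(pos < 0)) {
    bad <- which(pos < 0)[1] + 1L
    stop("negative position_cM at line ", bad, " of ", path)
  }
  sp <- unique(df$species)
  if (length(sp) != 1) stop("map file mixes species: ", paste(sp, collapse = ", "))
  if (anyDuplicated(df[, c("chromosome", "marker")]))
    stop("duplicate (chromosome, marker) row(s) in ", path)
  genetic_map(data.frame(chromosome = df$chromosome, marker = df$marker,
                         position_cM = pos, confidence = df$confidence,
                         stringsAsFactors = FALSE), species = sp)
}

#' Write a genetic map to a tab-delimited file
#' @param map a [genetic_map()]
#' @param path file path
#' @return `path`, invisibly
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an orthology table
#'
#' Tab-delimited with columns `group_id`, `species`, `marker`: each group is
#' a 1:1 single-copy equivalence class linking at most one marker per
#' species. Groups observed in fewer than two species carry no comparative
#' signal and are dropped (a message reports how many).
#'
#' @param path file path
#' @return data.frame (group_id, species, marker) of class `orthology_table`
#' @export
read_orthology_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  orthology_table(df)
}

#' Construct an orthology table
#' @param df data.frame with columns `group_id`, `species`, `marker`
#' @return data.frame of class `orthology_table`
#' @export
orthology_table <- function(df) {
  need <- c("group_id", "species", "marker")
  if (!all(need %in% names(df)))
    stop("orthology table needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  df[] <- lapply(df, as.character)
  key <- paste(df$species, df$marker)
  if (anyDuplicated(key))
    stop("a (species, marker) pair appears in two orthology groups")
  if (anyDuplicated(paste(df$group_id, df$species)))
    stop("an orthology group lists two markers for one species (not 1:1)")
  n_by_group <- table(df$group_id)
  small <- names(n_by_group)[n_by_group < 2]
  if (length(small)) {
    message(length(small), " orthology group(s) with <2 species dropped")
    df <- df[!df$group_id %in% small, ]
  }
  rownames(df) <- NULL
  class(df) <- c("orthology_table", "data.frame")
  df
}

#' Identity orthology for maps sharing marker names
#'
#' When species maps already use common marker ids (as simulated maps do),
#' the orthology table is simply one group per marker id.
#' @param maps list of [genetic_map()] objects
#' @return an `orthology_table`
#' @export
shared_name_orthology <- function(maps) {
  rows <- do.call(rbind, lapply(maps, function(m)
    data.frame(group_id = m$marker, species = m$species,
               marker = m$marker, stringsAsFactors = FALSE)))
  suppressMessages(orthology_table(rows))
}

#' Read a centromere table
#'
#' Tab-delimited with columns `chromosome`, `position_cM`, `left_marker`,
#' `right_marker`: the approximate centromere location on each reference
#' chromosome and the marker pair flanking it. Downstream logic uses the
#' flanking-marker rank interval, not the cM value.
#'
#' @param path file path
#' @return data.frame of class `centromere_table`
#' @export
read_centromere_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chromosome", "position_cM", "left_marker", "right_marker")
  if (!all(need %in% names(df)))
    stop("centromere table needs columns: ", paste(need, collapse = ", "))
  df$chromosome <- as.character(df$chromosome)
  if (anyDuplicated(df$chromosome)) stop("duplicate chromosome in centromere table")
  class(df) <- c("centromere_table", "data.frame")
  df
}

#' Validate centromere positions against a reference map
#'
#' Checks that each centromere lies within the cM span of its chromosome's
#' markers and that the flanking markers exist on that chromosome.
#' @param centromeres a `centromere_table`
#' @param ref a reference [genetic_map()]
#' @return `centromeres`, invisibly; errors on violation
#' @export
validate_centromeres <- function(centromeres, ref) {
  for (i in seq_len(nrow(centromeres))) {
    ch <- centromeres$chromosome[i]
    loci <- ref[ref$chromosome == ch, ]
    if (nrow(loci) == 0) stop("centromere on unknown reference chromosome ", ch)
    pos <- centromeres$position_cM[i]
    if (pos < min(loci$position_cM) || pos > max(loci$position_cM))
      stop("centromere position outside marker span on ", ch)
    fl <- c(centromeres$left_marker[i], centromeres$right_marker[i])
    if (!all(fl %in% loci$marker))
      stop("centromere flanking markers missing from reference chromosome ", ch)
  }
  invisible(centromeres)
}

#' Markers of one chromosome in map order
#' @param map a [genetic_map()]
#' @param chromosome chromosome id
#' @param high_confidence_only drop low-confidence loci (default TRUE)
#' @return character vector of marker ids in position order
#' @export
chromosome_markers <- function(map, chromosome, high_confidence_only = TRUE) {
  loci <- map[map$chromosome == chromosome, ]
  if (high_confidence_only) loci <- loci[loci$confidence == "high", ]
  loci$marker
}
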