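# shared builders for the test suite -------------------------------------

# a map with one chromosome whose markers sit at 10 cM spacing
mini_map <- function(species, chromosome, markers, confidence = NULL) {
  loci <- data.frame(chromosome = chromosome, marker = markers,
                     position_cM = 10 * (seq_along(markers) - 1),
                     stringsAsFactors = FALSE)
  if (!is.null(confidence)) loci$confidence <- confidence
  genetic_map(loci, species)
}

# a multi-chromosome map from a genome (list chromosome -> marker vector)
genome_map <- function(species, genome) {
  rows <- do.call(rbind, lapply(names(genome), function(ch)
    data.frame(chromosome = ch, marker = genome[[ch]],
               position_cM = 10 * (seq_along(genome[[ch]]) - 1),
               stringsAsFactors = FALSE)))
  genetic_map(rows, species)
}

# five Solanaceae-shaped maps derived from one root order, with optional
# per-species genome overrides
solanaceae_maps <- function(root, overrides = list()) {
  sp <- c("tomato", "potato", "eggplant", "pepper", "Nicotiana")
  maps <- lapply(sp, function(s)
    genome_map(s, if (s %in% names(overrides)) overrides[[s]] else root))
  stats::setNames(maps, sp)
}

# reverse markers i..j of a chromosome
rev_block <- function(genome, ch, i, j) {
  v <- genome[[ch]]
  genome[[ch]] <- c(v[seq_len(i - 1)], rev(v[i:j]),
                    if (j < length(v)) v[(j + 1):length(v)])
  genome
}

# small parameter set for fast simulator tests
tiny_params <- function(...) {
  simulation_params(
    phy = dated_phylogeny("((a,b)AB,c)R;", c(AB = 2, R = 4)),
    chromosomes = 2, markers_per_chromosome = 6,
    inversion_rate = 0.3, translocation_rate = 0.2, dropout = 0, ...)
}

example_file <- function(name)
  system.file("extdata", name, package = "synkaryo", mustWork = TRUE)
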