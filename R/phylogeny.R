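#' Dated phylogeny with node ages
#'
#' Wraps an [ape::phylo] rooted binary tree together with ages (in million
#' years, MY) for every internal node. Tips are extant species (age 0).
#' Every branch is named after its child node: terminal branches carry the
#' species name, internal branches the label of the ancestral node they lead
#' to. Branch durations are differences of node ages and must be positive.
#'
#' @param tree an [ape::phylo] object or a Newick string with internal node
#'   labels (e.g. `"(((a,b)AB,c)ABC,d)R;"`).
#' @param node_ages named numeric vector of ages (MY) for the internal node
#'   labels. All internal nodes must be covered.
#' @return an object of class `dated_phylogeny`: a list with elements
#'   `tree` (phylo), `ages` (named numeric over all node labels, tips = 0),
#'   and `branches` (data.frame: branch, parent, duration, is_tip).
#' @examples
#' phy <- dated_phylogeny("((a,b)AB,c)R;", c(AB = 2, R = 5))
#' branch_duration(phy, "a")   # 2
#' branch_duration(phy, "AB")  # 3
#' @export
dated_phylogeny <- function(tree, node_ages) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo object or Newick string")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    stop("all internal nodes must be labelled")
  if (anyDuplicated(c(tree$tip.label, tree$node.label)))
    stop("tip and node labels must be unique")
  node_ages <- unlist(node_ages)
  missing_ages <- setdiff(tree$node.label, names(node_ages))
  if (length(missing_ages))
    stop("no age supplied for internal node(s): ", paste(missing_ages, collapse = ", "))
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  ages <- c(rep(0, ntip), as.numeric(node_ages[tree$node.label]))
  names(ages) <- labels
  child <- labels[tree$edge[, 2]]
  parent <- labels[tree$edge[, 1]]
  duration <- ages[parent] - ages[child]
  if (any(duration <= 0))
    stop("child age must be strictly less than parent age (branch ",
         paste(child[duration <= 0], collapse = ", "), ")")
  branches <- data.frame(
    branch = child, parent = parent, duration = as.numeric(duration),
    is_tip = tree$edge[, 2] <= ntip, stringsAsFactors = FALSE)
  rownames(branches) <- branches$branch
  structure(list(tree = tree, ages = ages, branches = branches),
            class = "dated_phylogeny")
}

#' @export
print.dated_phylogeny <- function(x, ...) {
  cat("Dated phylogeny:", length(x$tree$tip.label), "tips,",
      x$tree$Nnode, "internal nodes, root age",
      max(x$ages), "MY\n")
  cat("  tips:", paste(x$tree$tip.label, collapse = ", "), "\n")
  inner <- x$ages[x$tree$node.label]
  cat("  node ages:", paste(sprintf("%s=%.4g", names(inner), inner), collapse = ", "), "\n")
  invisible(x)
}

#' Species (tip) names of a dated phylogeny
#' @param phy a `dated_phylogeny`
#' @return character vector of tip labels
#' @export
phylo_species <- function(phy) phy$tree$tip.label

#' Branch names of a dated phylogeny
#'
#' Every branch is identified by its child node label; the root itself has no
#' branch.
#' @param phy a `dated_phylogeny`
#' @return character vector of branch names
#' @export
phylo_branches <- function(phy) phy$branches$branch

#' Duration of a branch in million years
#' @param phy a `dated_phylogeny`
#' @param branch branch name (child-node label)
#' @return numeric duration in MY
#' @export
branch_duration <- function(phy, branch) {
  if (!branch %in% phy$branches$branch) stop("unknown branch: ", branch)
  phy$branches[branch, "duration"]
}

#' Tips descending from a branch
#'
#' The set of extant species below the given branch (for a terminal branch,
#' the species itself). A rearrangement event on a branch is carried by
#' exactly these tips.
#' @param phy a `dated_phylogeny`
#' @param branch branch name (child-node label)
#' @return character vector of tip labels
#' @export
tips_below <- function(phy, branch) {
  tree <- phy$tree
  ntip <- length(tree$tip.label)
  labels <- c(tree$tip.label, tree$node.label)
  node <- match(branch, labels)
  if (is.na(node)) stop("unknown branch: ", branch)
  if (node <= ntip) return(tree$tip.label[node])
  # iterative descent
  acc <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    acc <- c(acc, kids[kids <= ntip])
    stack <- c(stack, kids[kids > ntip])
  }
  tree$tip.label[sort(acc)]
}

#' Children of an internal node
#' @param phy a `dated_phylogeny`
#' @param node node label
#' @return character vector of child node/tip labels
#' @export
node_children <- function(phy, node) {
  tree <- phy$tree
  labels <- c(tree$tip.label, tree$node.label)
  v <- match(node, labels)
  if (is.na(v)) stop("unknown node: ", node)
  labels[tree$edge[tree$edge[, 1] == v, 2]]
}

#' Branches on the path between two tips
#'
#' Rearrangement events that differentiate two extant species are exactly the
#' events on the branches of the tip-to-tip path, so summed per-branch counts
#' along this path reproduce pairwise map differences.
#' @param phy a `dated_phylogeny`
#' @param tip1,tip2 tip labels
#' @return character vector of branch names on the path
#' @export
path_branches <- function(phy, tip1, tip2) {
  anc1 <- c(tip1, ancestor_chain(phy, tip1))
  anc2 <- c(tip2, ancestor_chain(phy, tip2))
  mrca <- anc1[anc1 %in% anc2][1]
  c(anc1[seq_len(match(mrca, anc1) - 1)], anc2[seq_len(match(mrca, anc2) - 1)])
}

ancestor_chain <- function(phy, label) {
  chain <- character(0)
  cur <- label
  repeat {
    row <- phy$branches[phy$branches$branch == cur, ]
    if (nrow(row) == 0) break
    chain <- c(chain, row$parent)
    cur <- row$parent
  }
  chain
}

#' The fixed Solanaceae phylogeny
#'
#' The five-species dated tree used throughout the packaged observations:
#' `((((tomato,potato)ATPt,eggplant)ATE,pepper)ATP,Nicotiana)ATN` with
#' ancestor ages ATPt = 7.3, ATE = 15.5, ATP = 19.6 and ATN = 23.7 million
#' years. ATPt/ATE/ATP/ATN name the most recent common ancestors of
#' progressively larger species sets.
#' @return a `dated_phylogeny`
#' @export
solanaceae_phylogeny <- function() {
  dated_phylogeny(
    "((((tomato,potato)ATPt,eggplant)ATE,pepper)ATP,Nicotiana)ATN;",
    c(ATPt = 7.3, ATE = 15.5, ATP = 19.6, ATN = 23.7))
}

#' Read a dated phylogeny from Newick plus a JSON config of node ages
#'
#' @param newick_path path to a Newick file with internal node labels
#' @param config_path path to a JSON file with a top-level `node_ages`
#'   object, e.g. `{"node_ages": {"ATPt": 7.3, "ATE": 15.5}}`
#' @return a `dated_phylogeny`
#' @export
read_phylogeny <- function(newick_path, config_path) {
  tree <- ape::read.tree(newick_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = TRUE)
  if (is.null(cfg$node_ages)) stop("config has no `node_ages` entry")
  dated_phylogeny(tree, cfg$node_ages)
}

# logical matrix: is branch b on the root-to-tip path of tip t?
# rows = tips, cols = branches
branch_path_matrix <- function(phy) {
  tips <- phylo_species(phy)
  brs <- phylo_branches(phy)
  m <- matrix(FALSE, length(tips), length(brs), dimnames = list(tips, brs))
  for (b in brs) m[tips_below(phy, b), b] <- TRUE
  m
}
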