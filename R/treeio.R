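#' @useDynLib rjtraits, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile rexp runif rlnorm acf var sd setNames
#' @importFrom utils read.delim write.table combn
NULL

#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()].  The analysis is
#' conditional on rooted trees with branch lengths, so unrooted trees,
#' missing or negative branch lengths, and duplicate leaf labels are
#' rejected rather than repaired.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an object of class `phylo`.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("malformed Newick string: ", substr(text, 1, 60))
  validate_tree(tr)
  tr
}

#' Serialize a tree to Newick
#' @param tree a `phylo` object.
#' @return a Newick string.
#' @export
serialize_newick <- function(tree) {
  ape::write.tree(tree, digits = 15)
}

validate_tree <- function(tr, require_lengths = TRUE) {
  if (!inherits(tr, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (require_lengths) {
    if (is.null(tr$edge.length))
      stop("tree has no branch lengths")
    if (any(tr$edge.length < 0))
      stop("negative branch length on edge ",
           which(tr$edge.length < 0)[1])
  }
  if (ape::Ntip(tr) >= 3L && !ape::is.rooted(tr))
    stop("tree is unrooted; the analysis requires rooted trees")
  invisible(tr)
}

#' Read a posterior sample of trees
#'
#' Accepts a NEXUS TREES block (translate tables are resolved by ape) or a
#' plain file with one Newick string per line.  All trees must share the
#' same leaf-label set.
#'
#' @param path path to the tree file.
#' @param format `"auto"` (default; NEXUS is detected from the `#NEXUS`
#'   header), `"nexus"`, or `"newick"`.
#' @return a `multiPhylo` list of rooted trees.
#' @export
read_tree_sample <- function(path, format = c("auto", "nexus", "newick")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "newick"
  }
  trees <- if (format == "nexus") ape::read.nexus(path) else ape::read.tree(path)
  if (is.null(trees)) stop("no trees found in ", path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("no trees found in ", path)
  as_tree_sample(trees)
}

#' Assemble and validate a tree sample
#'
#' @param trees a `multiPhylo` object or list of `phylo` trees.
#' @return a validated `multiPhylo` sharing one taxon set.
#' @export
as_tree_sample <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0L) stop("empty tree sample")
  class(trees) <- "multiPhylo"
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_tree(trees[[i]])
    lab <- sort(trees[[i]]$tip.label)
    if (!identical(lab, ref)) {
      diffs <- union(setdiff(lab, ref), setdiff(ref, lab))
      stop("tree ", i, " has a different taxon set; symmetric difference: ",
           paste(diffs, collapse = ", "))
    }
  }
  trees
}

#' Write a tree sample as one Newick string per line
#' @param trees a `multiPhylo` object.
#' @param path output path.
#' @export
write_tree_sample <- function(trees, path) {
  writeLines(vapply(trees, serialize_newick, ""), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Character matrices
# ---------------------------------------------------------------------------

#' Read a binary character matrix
#'
#' The canonical dialect is a UTF-8 TSV with a header row, a taxon column
#' followed by one column per character, and cells `0`, `1` or `0/1`
#' (polymorphic/ambiguous).  A NEXUS CHARACTERS/DATA block is also
#' accepted, with `{01}`-style ambiguities and `?` mapped to `0/1`.
#'
#' @param path path to the matrix file.
#' @param format `"auto"`, `"tsv"` or `"nexus"`.
#' @return a character matrix (taxa in rows, characters in columns) with
#'   cells in `c("0", "1", "0/1")`.
#' @export
read_character_matrix <- function(path, format = c("auto", "tsv", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty file: ", path)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus" else "tsv"
  }
  if (format == "tsv") {
    df <- read.delim(path, colClasses = "character", check.names = FALSE)
    if (nrow(df) == 0L || ncol(df) < 2L) stop("empty character matrix in ", path)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    dat <- ape::read.nexus.data(path)
    m <- t(vapply(dat, function(x) {
      vapply(x, function(cell) paste(sort(unique(cell)), collapse = "/"), "")
    }, character(length(dat[[1]]))))
    colnames(m) <- paste0("Ch", seq_len(ncol(m)))
    m[m %in% c("?", "-")] <- "0/1"
  }
  as_character_matrix(m)
}

#' Validate a character matrix
#'
#' @param m a character matrix with taxon rownames; cells `0`, `1`,
#'   `0/1` (or `1/0`, normalised).
#' @return the validated, normalised matrix.
#' @export
as_character_matrix <- function(m) {
  m <- as.matrix(m)
  mode(m) <- "character"
  if (is.null(rownames(m))) stop("character matrix needs taxon rownames")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon names in matrix")
  if (is.null(colnames(m))) colnames(m) <- paste0("Ch", seq_len(ncol(m)))
  m[m == "1/0"] <- "0/1"
  bad <- matrix(!(m %in% c("0", "1", "0/1")), nrow(m), ncol(m))
  if (any(bad)) {
    ij <- which(bad, arr.ind = TRUE)[1, ]
    stop("unknown character code '", m[bad][1], "' at taxon '",
         rownames(m)[ij[1]], "', character '", colnames(m)[ij[2]], "'")
  }
  m
}

#' Write a character matrix as TSV
#' @param m a character matrix (see [as_character_matrix()]).
#' @param path output path.
#' @export
write_character_matrix <- function(m, path) {
  m <- as_character_matrix(m)
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Codebook for the 11 wing-pattern characters
#'
#' The binary characters describe nymphalid-ground-plan (NGP) elements of
#' the fore- and hindwing; state 1 is the leaf-masquerade (dead-leaf)
#' condition, state 0 collapses every other condition.
#'
#' @return a data.frame with columns `id`, `wing`, `elements`, `state1`.
#' @export
character_codebook <- function() {
  data.frame(
    id = paste0("Ch", 1:11),
    wing = c(rep("fore", 6), rep("hind", 5)),
    elements = c("DS,B", "DS,Cp", "Cd", "BOp", "BOp", "ESs",
                 "B", "Cp", "DS", "Cd", "ESs"),
    state1 = c("DS and B parallel",
               "DS attached to Cp",
               "Cd a single broken line",
               "BOp bends distally",
               "upper side of BOp straight",
               "ESs vestigial",
               "B vestigial",
               "Cp fragmented",
               "DS vestigial",
               "Cd straight",
               "ESs vestigial"),
    stringsAsFactors = FALSE
  )
}

# ---------------------------------------------------------------------------
# Clades and subsampling
# ---------------------------------------------------------------------------

#' Most recent common ancestor of a taxon set
#'
#' Returns the deepest node whose leaf descendants contain all of `taxa`
#' (the MRCA approach): when the exact clade does not occur in the tree
#' this node subtends one or more extra taxa.
#'
#' @param tree a `phylo` object.
#' @param taxa nonempty character vector of leaf labels.
#' @return the ape node id (a tip index when `taxa` has one element).
#' @export
find_mrca <- function(tree, taxa) {
  if (length(taxa) == 0L) stop("empty taxon set")
  miss <- setdiff(taxa, tree$tip.label)
  if (length(miss) > 0L)
    stop("taxa absent from tree: ", paste(miss, collapse = ", "))
  if (length(unique(taxa)) == 1L)
    return(match(taxa[1], tree$tip.label))
  ape::getMRCA(tree, unique(taxa))
}

#' Does the exact clade occur in the tree?
#'
#' TRUE when the MRCA of `taxa` subtends exactly `taxa` and nothing else;
#' used to report per-tree clade coverage of the MRCA fallback.
#'
#' @inheritParams find_mrca
#' @export
clade_is_exact <- function(tree, taxa) {
  node <- find_mrca(tree, taxa)
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(length(unique(taxa)) == 1L)
  desc <- tree$tip.label[phangorn_free_descendants(tree, node)]
  setequal(desc, taxa)
}

# tip descendants of a node, without a phangorn dependency
phangorn_free_descendants <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  todo <- node
  tips <- integer(0)
  while (length(todo) > 0L) {
    ch <- tree$edge[tree$edge[, 1] %in% todo, 2]
    tips <- c(tips, ch[ch <= ntip])
    todo <- ch[ch > ntip]
  }
  tips
}

#' Uniform without-replacement subsample of a tree sample
#'
#' @param trees a `multiPhylo` object.
#' @param n number of trees to keep (`n <= length(trees)`).
#' @param seed optional integer seed for reproducibility.
#' @return a `multiPhylo` of size `n`.
#' @export
subsample_trees <- function(trees, n, seed = NULL) {
  trees <- as_tree_sample(trees)
  if (n > length(trees))
    stop("requested ", n, " trees from a sample of ", length(trees))
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(length(trees), n, replace = FALSE)
  out <- trees[idx]
  class(out) <- "multiPhylo"
  out
}

#' Rescale branch lengths to a target mean
#'
#' Optional global rescaling (off by default in every pipeline stage):
#' multiplies all branch lengths so their mean equals `target_mean`.
#'
#' @param trees a `multiPhylo` or `phylo`.
#' @param target_mean target mean branch length (default 0.1).
#' @export
rescale_tree_sample <- function(trees, target_mean = 0.1) {
  single <- inherits(trees, "phylo")
  if (single) trees <- c(trees)
  out <- lapply(trees, function(tr) {
    tr$edge.length <- tr$edge.length * target_mean / mean(tr$edge.length)
    tr
  })
  if (single) return(out[[1]])
  class(out) <- "multiPhylo"
  out
}
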