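# Exhaustive enumeration of rooted binary leaf-labeled topologies, used to
# assess how the arrangement of the A8, A9, A12 and MRP126 clades affects
# reconstructed ancestors. The number of rooted topologies on n leaves is the
# double factorial (2n-3)!!; for the four calgranulin clades that is 15.

#' Double factorial (2n - 3)!!
#'
#' Number of rooted binary leaf-labeled tree topologies on `n` leaves.
#'
#' @param n Number of leaves (>= 2).
#' @return The count as a double.
#' @export
n_rooted_topologies <- function(n) {
  if (n < 2) stop("n must be >= 2")
  prod(seq(1, 2 * n - 3, by = 2))
}

# recursive generation over unordered bipartitions; fixing the first label
# into the left part visits each unordered split exactly once
enumerate_newick <- function(labels) {
  if (length(labels) == 1) return(labels)
  rest <- labels[-1]
  out <- character(0)
  for (k in 0:(length(rest) - 1)) {
    picks <- if (k == 0) list(integer(0)) else
      combn(seq_along(rest), k, simplify = FALSE)
    for (idx in picks) {
      left <- c(labels[1], rest[idx])
      right <- if (k == 0) rest else rest[-idx]
      for (a in enumerate_newick(left))
        for (b in enumerate_newick(right))
          out <- c(out, join_canonical(a, b))
    }
  }
  out
}

# canonical node: children ordered by their smallest descendant leaf label
min_leaf <- function(nwk) {
  toks <- strsplit(gsub("[(),;]", " ", nwk), " +")[[1]]
  min(toks[nzchar(toks)])
}

join_canonical <- function(a, b) {
  if (min_leaf(a) <= min_leaf(b)) paste0("(", a, ",", b, ")")
  else paste0("(", b, ",", a, ")")
}

#' Enumerate all rooted binary topologies over a set of clades
#'
#' Generates every distinct rooted, binary, leaf-labeled topology whose
#' leaves are the given clade names, in a canonical Newick form (at every
#' node, the child subtree containing the alphabetically smallest leaf comes
#' first). The count equals `(2n - 3)!!`; for the four calgranulin clades
#' (A8, A9, A12, MRP126) there are 15.
#'
#' @param clade_names Character vector of >= 2 distinct names.
#' @return Character vector of canonical Newick strings (with terminating
#'   semicolons), sorted and de-duplicated.
#' @export
enumerate_clade_topologies <- function(clade_names) {
  if (length(clade_names) < 2) stop("need at least 2 clade names")
  if (anyDuplicated(clade_names))
    stop("duplicate clade names: ",
         paste(unique(clade_names[duplicated(clade_names)]), collapse = ", "))
  nwk <- unique(enumerate_newick(sort(clade_names)))
  sort(paste0(nwk, ";"))
}

#' Canonical form of a rooted topology
#'
#' Strips branch lengths and internal labels and rewrites the Newick string
#' with children at every node ordered by smallest descendant leaf, so that
#' topologically identical trees map to identical strings.
#'
#' @param tree An ape `phylo` object or a Newick string.
#' @return Canonical Newick string.
#' @export
canonical_topology <- function(tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  rec <- function(v, ntip, children) {
    if (v <= ntip) return(tree$tip.label[v])
    ch <- children[[v]]
    parts <- vapply(ch, rec, character(1), ntip = ntip, children = children)
    Reduce(join_canonical, parts[order(vapply(parts, min_leaf, character(1)))])
  }
  ntip <- length(tree$tip.label)
  children <- lapply(seq_len(ntip + tree$Nnode),
                     function(v) tree$edge[tree$edge[, 1] == v, 2])
  paste0(rec(ntip + 1L, ntip, children), ";")
}
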