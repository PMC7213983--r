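# Fitch parsimony for a binary trait (e.g. proteolytically resistant vs
# susceptible) on a rooted tree: bottom-up set intersection/union, counting
# the minimum number of state changes required to explain the tip states.

#' Fitch parsimony for a discrete trait
#'
#' Runs the Fitch bottom-up pass on a rooted binary tree: at each internal
#' node the state set is the intersection of the children's sets when
#' non-empty, otherwise their union (adding one change). Returns the state
#' set at every node and the minimum number of changes.
#'
#' A single leaf (degenerate tree) may be given as a character scalar naming
#' the leaf; its state is returned with zero changes.
#'
#' @param tree Rooted binary `phylo` tree, or a single leaf name.
#' @param traits Named character vector mapping every tip label to its state.
#' @return List with `node_sets` (named list of state sets: tips then
#'   internal nodes), `root_set` and `changes` (minimum change count).
#' @export
fitch_parsimony <- function(tree, traits) {
  if (is.character(tree) && length(tree) == 1) {
    if (!tree %in% names(traits)) stop("no trait state for leaf '", tree, "'")
    st <- unname(traits[[tree]])
    return(list(node_sets = setNames(list(st), tree),
                root_set = st, changes = 0L))
  }
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree))
    stop("tree must be rooted and binary")
  missing_tips <- setdiff(tree$tip.label, names(traits))
  if (length(missing_tips))
    stop("unassigned leaf state(s): ", paste(missing_tips, collapse = ", "))

  ntip <- length(tree$tip.label)
  ntot <- ntip + tree$Nnode
  sets <- vector("list", ntot)
  for (i in seq_len(ntip)) sets[[i]] <- unname(traits[[tree$tip.label[i]]])

  po <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  for (v in unique(po[, 1])) {
    ch <- po[po[, 1] == v, 2]
    inter <- intersect(sets[[ch[1]]], sets[[ch[2]]])
    if (length(inter)) {
      sets[[v]] <- inter
    } else {
      sets[[v]] <- union(sets[[ch[1]]], sets[[ch[2]]])
      changes <- changes + 1L
    }
  }
  names(sets) <- c(tree$tip.label, internal_node_labels(tree))
  list(node_sets = sets,
       root_set = sets[[ntip + 1L]],
       changes = changes)
}
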