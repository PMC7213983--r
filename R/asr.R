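# Marginal ancestral sequence reconstruction on small rooted trees under the
# equal-rates (Poisson-type) 20-state amino-acid model with uniform
# equilibrium frequencies, optionally mixed over discrete-gamma rate
# categories. The pruning (inside) pass is combined with an outside pass so
# that posteriors at every internal node integrate over all other nodes.

#' Transition probability matrix of the equal-rates amino-acid model
#'
#' All 20 amino acids exchange at the same rate and the equilibrium
#' distribution is uniform. Branch lengths are expected substitutions per
#' site, so the off-diagonal rate is scaled by 1/19:
#' \eqn{P_{ii}(t) = 1/20 + (19/20) e^{-20t/19}} and
#' \eqn{P_{ij}(t) = (1/20)(1 - e^{-20t/19})}.
#'
#' @param t Branch length (expected substitutions/site, >= 0).
#' @param rate Rate multiplier (used for gamma rate categories).
#' @return 20 x 20 transition probability matrix.
#' @export
poisson_transition_matrix <- function(t, rate = 1) {
  if (!is.finite(t) || t < 0) stop("branch length must be finite and >= 0")
  e <- exp(-20 * rate * t / 19)
  off <- (1 - e) / 20
  P <- matrix(off, 20, 20, dimnames = list(AA_STATES, AA_STATES))
  diag(P) <- 1 / 20 + 19 * e / 20
  P
}

# mean-of-bin discretization of a gamma(shape, rate = shape) distribution
# into k equal-probability categories (Yang-style discrete gamma)
discrete_gamma_rates <- function(shape, k) {
  if (k == 1) return(1)
  b <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  k * (pgamma(b[-1] * shape, shape + 1, rate = 1) -
       pgamma(b[-(k + 1)] * shape, shape + 1, rate = 1))
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  # the tree is used as rooted at its root node; a basal polytomy is allowed
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  invisible(tree)
}

internal_node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs) || any(is.na(labs)) || any(labs == ""))
    labs <- paste0("node", seq_len(tree$Nnode) + ntip)
  labs
}

#' Marginal ancestral state reconstruction by the pruning algorithm
#'
#' Computes, at every internal node and alignment site, the marginal
#' posterior probability of each of the 20 amino acids under the equal-rates
#' model, integrating over states at all other nodes (inside/outside
#' recursion). The maximum-likelihood ancestral sequence per node takes the
#' highest-posterior state at each site (alphabetically first on ties).
#'
#' Sites at which any tip of the tree carries a gap are skipped with a
#' warning: their posterior rows are `NA` and ancestral sequences carry the
#' gap symbol there.
#'
#' @param tree Rooted `phylo` tree (binary or multifurcating) with branch
#'   lengths in expected substitutions/site.
#' @param alignment Named character vector of aligned amino-acid sequences
#'   covering (at least) all tree tips.
#' @param gamma_shape Optional shape parameter of a discrete-gamma
#'   rate-heterogeneity model; `NULL` (default) means a single rate.
#' @param n_rate_categories Number of discrete gamma categories (ignored when
#'   `gamma_shape` is `NULL`).
#' @return An object of class `asr_result`: a list with `posteriors` (named
#'   list of L x 20 matrices, one per internal node), `ml` (named character
#'   vector of ML ancestral sequences), `skipped_sites` (1-based indices of
#'   gap-containing sites) and `tree`.
#' @export
marginal_asr <- function(tree, alignment, gamma_shape = NULL,
                         n_rate_categories = 4) {
  check_tree(tree)
  validate_alignment(alignment)
  missing_tips <- setdiff(tree$tip.label, names(alignment))
  if (length(missing_tips))
    stop("missing sequence data for tip(s): ",
         paste(missing_tips, collapse = ", "))

  tipmat <- alignment_matrix(alignment[tree$tip.label])
  L <- ncol(tipmat)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L

  rates <- if (is.null(gamma_shape)) 1 else
    discrete_gamma_rates(gamma_shape, n_rate_categories)
  nr <- length(rates)

  # per-edge transition matrices, indexed by child node, per rate category
  edge <- tree$edge
  Pmats <- vector("list", nr)
  for (r in seq_len(nr)) {
    Pmats[[r]] <- vector("list", ntot)
    for (i in seq_len(nrow(edge)))
      Pmats[[r]][[edge[i, 2]]] <-
        poisson_transition_matrix(tree$edge.length[i], rates[r])
  }

  po <- ape::reorder.phylo(tree, "postorder")
  po_edge <- po$edge
  parent_of <- integer(ntot)
  parent_of[po_edge[, 2]] <- po_edge[, 1]
  children <- lapply(seq_len(ntot), function(v) po_edge[po_edge[, 1] == v, 2])

  skipped <- which(apply(tipmat == GAP, 2, any))
  labs <- internal_node_labels(tree)

  posts <- lapply(seq_len(nnode), function(i) {
    m <- matrix(NA_real_, L, 20, dimnames = list(NULL, AA_STATES))
    m
  })
  names(posts) <- labs

  pi0 <- rep(1 / 20, 20)
  for (s in setdiff(seq_len(L), skipped)) {
    joint <- matrix(0, nnode, 20)   # sum over categories of w * up * down
    for (r in seq_len(nr)) {
      P <- Pmats[[r]]
      down <- matrix(0, ntot, 20)
      for (tip in seq_len(ntip))
        down[tip, match(tipmat[tip, s], AA_STATES)] <- 1
      # inside pass: postorder guarantees children before parents
      for (v in unique(po_edge[, 1])) {
        msgs <- lapply(children[[v]],
                       function(c) as.vector(P[[c]] %*% down[c, ]))
        down[v, ] <- Reduce(`*`, msgs)
      }
      # outside pass: preorder (reverse postorder of parents)
      up <- matrix(0, ntot, 20)
      up[root, ] <- pi0
      for (i in rev(seq_len(nrow(po_edge)))) {
        v <- po_edge[i, 2]
        if (v <= ntip) next
        u <- po_edge[i, 1]
        sibs <- setdiff(children[[u]], v)
        sibmsg <- Reduce(`*`, lapply(sibs, function(s)
          as.vector(P[[s]] %*% down[s, ])), rep(1, 20))
        up[v, ] <- P[[v]] %*% (up[u, ] * sibmsg)
      }
      idx <- (root:ntot)
      joint <- joint + (up[idx, , drop = FALSE] * down[idx, , drop = FALSE]) / nr
    }
    norm <- rowSums(joint)
    for (i in seq_len(nnode)) posts[[i]][s, ] <- joint[i, ] / norm[i]
  }

  if (length(skipped))
    warning(length(skipped), " site(s) with gaps skipped: ",
            paste(skipped, collapse = ", "))

  ml <- vapply(posts, function(m) {
    ch <- rep(GAP, L)
    ok <- setdiff(seq_len(L), skipped)
    ch[ok] <- AA_STATES[apply(m[ok, , drop = FALSE], 1, which.max)]
    paste(ch, collapse = "")
  }, character(1))

  structure(list(posteriors = posts, ml = ml, skipped_sites = skipped,
                 tree = tree),
            class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  L <- nchar(x$ml[[1]])
  cat("Marginal ASR result:", length(x$ml), "internal node(s),",
      L, "sites,", length(x$skipped_sites), "gap site(s) skipped\n")
  invisible(x)
}

#' Write per-node posterior tables to CSV
#'
#' Long format with columns `node`, `site` (1-based) and one column per
#' amino-acid state. Gap-skipped sites are written with empty probabilities.
#'
#' @param asr An `asr_result` from [marginal_asr()], or a named list of
#'   L x 20 posterior matrices.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_posterior_csv <- function(asr, path) {
  posts <- if (inherits(asr, "asr_result")) asr$posteriors else asr
  rows <- do.call(rbind, lapply(names(posts), function(nm) {
    m <- posts[[nm]]
    data.frame(node = nm, site = seq_len(nrow(m)), m, check.names = FALSE)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read per-node posterior tables from CSV
#'
#' @param path CSV written by [write_posterior_csv()] (columns `node`,
#'   `site`, then the 20 state probabilities).
#' @return Named list of L x 20 posterior matrices.
#' @export
read_posterior_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  need <- c("node", "site", AA_STATES)
  if (!all(need %in% names(d)))
    stop("posterior CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$node), function(g) {
    g <- g[order(g$site), ]
    m <- as.matrix(g[, AA_STATES])
    rownames(m) <- NULL
    m
  })
}
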