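# altAll alternative-ancestor construction: at every site where the second-
# best reconstructed state has posterior probability strictly above a
# threshold (default 0.20), the alternate state replaces the ML state. The
# result is a "worst case" ancestor used to test robustness of downstream
# conclusions to reconstruction uncertainty.

#' Validate a per-site posterior probability matrix
#'
#' @param posterior L x 20 numeric matrix with columns named by the
#'   amino-acid states; rows that are all `NA` mark gap-skipped sites.
#' @param tol Tolerance on row sums.
#' @return The matrix, invisibly.
#' @export
validate_posterior <- function(posterior, tol = 1e-6) {
  if (!is.matrix(posterior) || ncol(posterior) != 20)
    stop("posterior must be an L x 20 matrix")
  if (!identical(colnames(posterior), AA_STATES))
    stop("posterior columns must be the amino-acid states in order: ",
         paste(AA_STATES, collapse = ""))
  live <- !apply(is.na(posterior), 1, all)
  p <- posterior[live, , drop = FALSE]
  if (any(p < -tol | p > 1 + tol, na.rm = TRUE))
    stop("posterior entries must lie in [0, 1]")
  bad <- which(abs(rowSums(p) - 1) > tol)
  if (length(bad))
    stop("posterior row(s) not normalized at site(s): ",
         paste(which(live)[bad], collapse = ", "))
  invisible(posterior)
}

#' Construct the altAll alternative ancestor
#'
#' At each site, the second-most-probable (runner-up) state is substituted
#' into the maximum-likelihood sequence when its posterior probability is
#' strictly greater than `threshold`; otherwise the ML state is kept. The
#' comparison is strict, so a runner-up at exactly the threshold is not
#' substituted. If two non-ML states tie for runner-up, the alphabetically
#' first is used.
#'
#' @param posterior L x 20 posterior matrix (columns named by state);
#'   all-`NA` rows mark gap sites, which propagate the gap symbol.
#' @param ml_sequence Optional ML sequence (character scalar). Defaults to
#'   the per-site argmax of `posterior`.
#' @param threshold Posterior-probability threshold in (0, 1); default 0.20.
#' @return An object of class `ancestor_reconstruction`: list with
#'   `ml_sequence`, `altall_sequence`, `site_pp` (posterior of the ML state
#'   per site), `average_pp` (mean of `site_pp` over non-gap sites),
#'   `substituted_sites` (1-based) and `threshold`.
#' @export
build_altall <- function(posterior, ml_sequence = NULL, threshold = 0.20) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly between 0 and 1")
  validate_posterior(posterior)
  L <- nrow(posterior)
  gap_sites <- which(apply(is.na(posterior), 1, all))

  if (is.null(ml_sequence)) {
    ml <- rep(GAP, L)
    for (s in setdiff(seq_len(L), gap_sites))
      ml[s] <- AA_STATES[which.max(posterior[s, ])]
  } else {
    ml <- strsplit(ml_sequence, "")[[1]]
    if (length(ml) != L)
      stop("ml_sequence length (", length(ml),
           ") does not match posterior rows (", L, ")")
  }

  alt <- ml
  site_pp <- rep(NA_real_, L)
  subs <- integer(0)
  for (s in setdiff(seq_len(L), gap_sites)) {
    p <- posterior[s, ]
    site_pp[s] <- p[[ml[s]]]
    p_alt <- p[setdiff(AA_STATES, ml[s])]
    runner <- names(p_alt)[which.max(p_alt)]  # alphabetically first on ties
    if (p_alt[[runner]] > threshold) {
      alt[s] <- runner
      subs <- c(subs, s)
    }
  }

  structure(list(ml_sequence = paste(ml, collapse = ""),
                 altall_sequence = paste(alt, collapse = ""),
                 site_pp = site_pp,
                 average_pp = mean(site_pp, na.rm = TRUE),
                 substituted_sites = subs,
                 threshold = threshold),
            class = "ancestor_reconstruction")
}

#' @export
print.ancestor_reconstruction <- function(x, ...) {
  cat("Ancestor reconstruction (", nchar(x$ml_sequence), " sites)\n",
      "  average posterior probability of ML states: ",
      sprintf("%.3f", x$average_pp), "\n",
      "  altAll substitutions (PP > ", x$threshold, "): ",
      length(x$substituted_sites), " site(s)\n", sep = "")
  invisible(x)
}

#' Compare ancestors reconstructed on alternative topologies to a reference
#'
#' For each topology's reconstructed ancestor, counts sequence differences to
#' the reference ML ancestor, and reports the mean count, the union of
#' differing sites and whether that union is contained in the reference's
#' ML-vs-altAll substituted sites (if it is, the altAll ancestor already
#' bounds the sequence uncertainty contributed by topology).
#'
#' @param reconstructions Named list: topology id -> ancestral sequence
#'   (character scalar) or `ancestor_reconstruction` (its ML sequence is
#'   used).
#' @param reference An `ancestor_reconstruction` (reference ML + altAll).
#' @return List with `counts` (named integer vector), `mean_differences`,
#'   `differing_sites` (union, 1-based) and `within_altall_set` (logical).
#' @export
compare_across_topologies <- function(reconstructions, reference) {
  if (!inherits(reference, "ancestor_reconstruction"))
    stop("reference must be an ancestor_reconstruction")
  ref <- strsplit(reference$ml_sequence, "")[[1]]
  seqs <- lapply(reconstructions, function(r)
    if (inherits(r, "ancestor_reconstruction")) r$ml_sequence else r)
  counts <- integer(length(seqs))
  names(counts) <- names(seqs)
  union_sites <- integer(0)
  for (i in seq_along(seqs)) {
    s <- strsplit(seqs[[i]], "")[[1]]
    if (length(s) != length(ref))
      stop("sequence length mismatch for topology '", names(seqs)[i], "'")
    d <- which(s != ref)
    counts[i] <- length(d)
    union_sites <- union(union_sites, d)
  }
  union_sites <- sort(union_sites)
  list(counts = counts,
       mean_differences = mean(counts),
       differing_sites = union_sites,
       within_altall_set = all(union_sites %in% reference$substituted_sites))
}
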