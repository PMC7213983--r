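# Synthetic-data generators. Every generator takes an explicit seed, returns
# its ground truth alongside the data, and is deterministic: the same
# arguments (including seed) reproduce the output bit-for-bit. Noise models
# are chosen for testability: multiplicative Gaussian for gel band areas and
# luciferase counts, additive Gaussian for CD and OD600 readings.
#
# Named presets mirror the magnitudes of the study system: a fast-degrading
# "hA9-like" protein (k = 0.3/min) vs a "complex-like" protease-resistant
# heterocomplex (k = 3e-4/min, three orders of magnitude slower), and a
# stabilizing point mutation modeled as ddG = 4 kcal/mol at shared m-value.

#' Decay-rate presets (1/min)
#' @export
DECAY_PRESETS <- c("hA9-like" = 0.3, "complex-like" = 3e-4)

with_seed <- function(seed, code) {
  if (!is.numeric(seed)) stop("seed is mandatory")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate sequence evolution on a tree
#'
#' Draws a root sequence uniformly over the 20 amino acids and evolves it
#' down the tree under the equal-rates model, using each branch's length in
#' expected substitutions/site. Returns the tip alignment together with the
#' true sequence at every internal node, so reconstruction accuracy can be
#' scored against known ancestors.
#'
#' @param tree Rooted binary `phylo` tree with branch lengths.
#' @param L Number of sites (>= 1).
#' @param seed Random seed (mandatory).
#' @return List with `alignment` (named character vector, tips),
#'   `ancestors` (named character vector, internal nodes; the root is the
#'   first) and `tree`.
#' @export
simulate_msa <- function(tree, L, seed) {
  check_tree(tree)
  if (L < 1) stop("L must be >= 1")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    ntot <- ntip + tree$Nnode
    root <- ntip + 1L
    seqs <- matrix(NA_integer_, ntot, L)
    seqs[root, ] <- sample.int(20, L, replace = TRUE)
    # preorder: parents before children
    po <- ape::reorder.phylo(tree, "postorder")$edge
    lens <- ape::reorder.phylo(tree, "postorder")$edge.length
    for (i in rev(seq_len(nrow(po)))) {
      P <- poisson_transition_matrix(lens[i])
      parent_states <- seqs[po[i, 1], ]
      child <- integer(L)
      for (a in unique(parent_states)) {
        idx <- which(parent_states == a)
        child[idx] <- sample.int(20, length(idx), replace = TRUE,
                                 prob = P[a, ])
      }
      seqs[po[i, 2], ] <- child
    }
    to_str <- function(v) paste(AA_STATES[v], collapse = "")
    tips <- apply(seqs[seq_len(ntip), , drop = FALSE], 1, to_str)
    names(tips) <- tree$tip.label
    anc <- apply(seqs[root:ntot, , drop = FALSE], 1, to_str)
    names(anc) <- internal_node_labels(tree)
    list(alignment = tips, ancestors = anc, tree = tree)
  })
}

#' Simulate a gel digestion time course as an image
#'
#' Renders one lane per time point: the intact-protein band is a Gaussian in
#' the migration direction whose integrated area is
#' \eqn{A_0 e^{-kt}(1+\epsilon)} with multiplicative Gaussian noise, on top
#' of a linear background gradient shared by the whole image.
#'
#' @param k True decay rate (1/min, > 0).
#' @param times Time points (min, >= 0); the first should be 0 (undigested).
#' @param seed Random seed.
#' @param A0 True initial band area. @param noise_sd Relative area noise
#'   (default 0.03). @param lane_width Lane width in pixels.
#' @param n_rows Image height (migration positions). @param band_center,
#'   band_sd Band position and width (rows). @param bg_base,bg_slope Linear
#'   background per pixel.
#' @return List with `image` (matrix), `times`, and `truth` (list: `k`,
#'   `A0`, `areas` actually rendered, `band_window` c(first,last) rows).
#' @export
simulate_gel_timecourse <- function(k, times, seed, A0 = 1000,
                                    noise_sd = 0.03, lane_width = 20,
                                    n_rows = 120, band_center = 60,
                                    band_sd = 4, bg_base = 2,
                                    bg_slope = 0.02) {
  if (k <= 0) stop("k must be > 0")
  if (any(times < 0)) stop("times must be >= 0")
  with_seed(seed, {
    eps <- rnorm(length(times), 0, noise_sd)
    areas <- A0 * exp(-k * times) * (1 + eps)
    prof0 <- dnorm(seq_len(n_rows), band_center, band_sd)
    prof0 <- prof0 / sum(prof0)
    img <- matrix(rep(bg_base + bg_slope * seq_len(n_rows),
                      length(times) * lane_width),
                  nrow = n_rows)
    for (i in seq_along(times)) {
      cols <- ((i - 1) * lane_width + 1):(i * lane_width)
      img[, cols] <- img[, cols] + areas[i] * prof0 / lane_width
    }
    list(image = img, times = times,
         truth = list(k = k, A0 = A0, areas = areas,
                      band_window = c(max(1, round(band_center - 4 * band_sd)),
                                      min(n_rows,
                                          round(band_center + 4 * band_sd)))))
  })
}

#' Simulate replicate decay time courses (tabular)
#'
#' Fraction-intact values \eqn{A_0 e^{-kt}(1+\epsilon)} with multiplicative
#' Gaussian noise, for several biological replicates on a shared time grid.
#'
#' @param k True rate (1/min). @param times Time grid (min).
#' @param seed Random seed. @param n_replicates Number of replicates.
#' @param A0 True amplitude. @param noise_sd Relative noise (default 0.05).
#' @return Data frame (`replicate`, `time_min`, `fraction_intact`) with the
#'   truth attached as attribute `truth`.
#' @export
simulate_decay_data <- function(k, times, seed, n_replicates = 3, A0 = 1,
                                noise_sd = 0.05) {
  if (k <= 0) stop("k must be > 0")
  with_seed(seed, {
    d <- expand.grid(time_min = times, replicate = seq_len(n_replicates))
    d$fraction_intact <- A0 * exp(-k * d$time_min) *
      (1 + rnorm(nrow(d), 0, noise_sd))
    attr(d, "truth") <- list(k = k, A0 = A0, noise_sd = noise_sd)
    d[, c("replicate", "time_min", "fraction_intact")]
  })
}

#' Simulate an equilibrium denaturation curve
#'
#' Samples the two-state unfolding signal on a denaturant grid and adds
#' Gaussian noise.
#'
#' @param dG,m True free energy (kcal/mol) and m-value (kcal/mol/M).
#' @param seed Random seed.
#' @param b_f,m_f,b_u,m_u Baseline parameters.
#' @param x Denaturant grid (M). @param noise_sd Additive signal noise.
#' @param T,R Temperature and gas constant.
#' @return Data frame (`x_molar`, `signal_mdeg`) with attribute `truth`.
#' @export
simulate_denaturation <- function(dG, m, seed, b_f = -20, m_f = 0.1,
                                  b_u = -2, m_u = 0.05,
                                  x = seq(0, 9, by = 0.375), noise_sd = 0,
                                  T = 298.15, R = R_KCAL) {
  if (m <= 0) stop("m must be > 0")
  with_seed(seed, {
    y <- two_state_signal(x, b_f, m_f, b_u, m_u, dG, m, T, R) +
      rnorm(length(x), 0, noise_sd)
    d <- data.frame(x_molar = x, signal_mdeg = y)
    attr(d, "truth") <- list(b_f = b_f, m_f = m_f, b_u = b_u, m_u = m_u,
                             dG = dG, m = m, Cm = dG / m, T = T, R = R)
    d
  })
}

#' Simulate an unfolding kinetics trace
#'
#' @param k_u True unfolding rate (1/s). @param seed Random seed.
#' @param t Time grid (s). @param y0,y_inf Initial and final signal.
#' @param noise_sd Additive noise.
#' @return Data frame (`t_s`, `signal`) with attribute `truth`.
#' @export
simulate_kinetic_trace <- function(k_u, seed, t = seq(0, 600, by = 2),
                                   y0 = -25, y_inf = -5, noise_sd = 0.1) {
  with_seed(seed, {
    y <- y_inf + (y0 - y_inf) * exp(-k_u * t) + rnorm(length(t), 0, noise_sd)
    d <- data.frame(t_s = t, signal = y)
    attr(d, "truth") <- list(k_u = k_u, y0 = y0, y_inf = y_inf)
    d
  })
}

#' Simulate an antimicrobial growth-curve experiment
#'
#' OD600 follows a logistic curve per treatment,
#' \eqn{OD(t) = blank + K / (1 + e^{-r (t - t_{lag})})} plus additive noise;
#' treatments shift the lag and/or carrying capacity, mirroring delayed
#' growth vs reduced capacity phenotypes. Blank wells stay flat at the blank
#' level. Technical triplicates are generated per treatment and biological
#' replicate.
#'
#' @param treatments Named list of logistic parameter lists
#'   (`K`, `r`, `t_lag`, optional `concentration_uM`); must include
#'   `"untreated"`.
#' @param seed Random seed.
#' @param times Time grid (min), default every 15 min for 13 h.
#' @param blank_od Blank OD level. @param noise_sd Additive OD noise.
#' @param n_tech,n_bio Technical and biological replicate counts.
#' @return Growth-curve set: list with `data`, `map` (see
#'   [growth_inhibition()]) and `truth`.
#' @export
simulate_growth <- function(treatments, seed, times = seq(0, 780, by = 15),
                            blank_od = 0.09, noise_sd = 0.003,
                            n_tech = 3, n_bio = 3) {
  if (!"untreated" %in% names(treatments))
    stop("treatments must include 'untreated'")
  with_seed(seed, {
    map <- NULL; data <- NULL; well <- 0
    add_well <- function(trt, conc, br, od) {
      well <<- well + 1
      id <- sprintf("W%03d", well)
      map <<- rbind(map, data.frame(well = id, treatment = trt,
                                    concentration_uM = conc, bio_rep = br))
      data <<- rbind(data, data.frame(well = id, time_min = times,
                                      od600 = od))
    }
    for (br in seq_len(n_bio)) {
      for (i in seq_len(n_tech))
        add_well("blank", NA_real_, br,
                 blank_od + rnorm(length(times), 0, noise_sd))
      for (nm in names(treatments)) {
        p <- treatments[[nm]]
        mu <- blank_od + p$K / (1 + exp(-p$r * (times - p$t_lag)))
        conc <- if (is.null(p$concentration_uM)) NA_real_
                else p$concentration_uM
        for (i in seq_len(n_tech))
          add_well(nm, conc, br, mu + rnorm(length(times), 0, noise_sd))
      }
    }
    list(data = data, map = map,
         truth = list(treatments = treatments, blank_od = blank_od,
                      noise_sd = noise_sd))
  })
}

#' Simulate a dual-luciferase reporter plate
#'
#' Per well, renilla counts are drawn around a plate scale (multiplicative
#' Gaussian) and firefly counts are
#' renilla x (background + induction x span) x (1 + noise), so the
#' firefly/renilla ratio encodes the treatment's true induction on the
#' LPS / LPS+PB scale: by construction LPS has induction 1 and LPS+PB 0.
#'
#' @param true_inductions Named numeric vector of true inductions for the
#'   non-anchor treatments (e.g. `c(mock = 0, "hA9 5uM" = 0.9)`); the LPS and
#'   LPS+PB anchors are added automatically.
#' @param seed Random seed.
#' @param n_bio,n_tech Biological (plates) and technical replicates.
#' @param renilla_scale Mean renilla counts per plate.
#' @param renilla_cv Relative spread of renilla counts.
#' @param background,span LPS+PB ratio and LPS-minus-LPS+PB ratio span.
#' @param noise_cv Multiplicative firefly noise (0 = exact inversion).
#' @return Data frame (`well`, `firefly`, `renilla`, `treatment`, `bio_rep`)
#'   with attribute `truth`.
#' @export
simulate_reporter_plate <- function(true_inductions, seed, n_bio = 3,
                                    n_tech = 3, renilla_scale = 1e6,
                                    renilla_cv = 0.1, background = 0.2,
                                    span = 2, noise_cv = 0.05) {
  ind <- c("LPS" = 1, "LPS+PB" = 0, true_inductions)
  with_seed(seed, {
    rows <- list(); w <- 0
    for (br in seq_len(n_bio)) {
      for (trt in names(ind)) {
        for (i in seq_len(n_tech)) {
          w <- w + 1
          ren <- renilla_scale * (1 + rnorm(1, 0, renilla_cv))
          ff <- ren * (background + ind[[trt]] * span) *
            (1 + rnorm(1, 0, noise_cv))
          rows[[w]] <- data.frame(well = sprintf("W%03d", w), firefly = ff,
                                  renilla = ren, treatment = trt,
                                  bio_rep = br)
        }
      }
    }
    d <- do.call(rbind, rows)
    attr(d, "truth") <- list(inductions = ind, background = background,
                             span = span)
    d
  })
}
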