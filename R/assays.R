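# Functional assay summaries.
#
# Antimicrobial assay: bacterial growth (OD600 every 15 min) with and without
# S100 protein; growth inhibition is reported as the percent of untreated
# growth at an evaluation time (7 h in the text, 12 h in the figure), after
# subtracting a media blank.
#
# NF-kB reporter assay: per well, firefly (NF-kB promoter) over renilla
# (constitutive) luciferase counts; induction is background-subtracted with
# the LPS + polymyxin-B wells and normalized to the LPS positive control, so
# on every plate LPS maps to 1 and LPS+PB to 0 by construction.

sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_

#' Percent-of-untreated growth at an evaluation time
#'
#' For each biological replicate, technical replicates are averaged at the
#' grid time nearest `t_eval_hr` (within half the 15-min sampling interval),
#' the media blank is subtracted, and each treatment's OD is expressed as a
#' percentage of the untreated control. Replicate percentages are then
#' aggregated as mean +/- SEM over biological replicates.
#'
#' @param curves A growth-curve set: list with `data` (data frame: `well`,
#'   `time_min`, `od600`) and `map` (data frame: `well`, `treatment`,
#'   `concentration_uM`, `bio_rep`). Treatments must include `"blank"` and
#'   `"untreated"` wells in every biological replicate.
#' @param t_eval_hr Evaluation time in hours (default 7; the 12-h endpoint
#'   used for figure summaries is selected by `t_eval_hr = 12`).
#' @param grid_tol_min Maximum distance to the nearest grid time (default
#'   7.5 min, half the sampling interval).
#' @return Data frame (`treatment`, `concentration_uM`,
#'   `percent_of_untreated`, `sem`, `n_bio`) with one row per treatment and
#'   concentration; untreated maps to 100 by construction.
#' @export
growth_inhibition <- function(curves, t_eval_hr = 7, grid_tol_min = 7.5) {
  data <- curves$data; map <- curves$map
  stopifnot(all(c("well", "time_min", "od600") %in% names(data)),
            all(c("well", "treatment", "bio_rep") %in% names(map)))
  if (!"concentration_uM" %in% names(map)) map$concentration_uM <- NA_real_
  t_target <- t_eval_hr * 60
  grid <- sort(unique(data$time_min))
  t_use <- grid[which.min(abs(grid - t_target))]
  if (abs(t_use - t_target) > grid_tol_min)
    stop("no grid time within ", grid_tol_min, " min of ", t_target, " min")

  d <- merge(data[data$time_min == t_use, ], map, by = "well")
  d$grp <- paste(d$treatment, d$concentration_uM, sep = " @ ")
  per_rep <- list()
  for (br in unique(d$bio_rep)) {
    g <- d[d$bio_rep == br, ]
    blank <- mean(g$od600[g$treatment == "blank"])
    untre <- mean(g$od600[g$treatment == "untreated"])
    if (!is.finite(blank) || !is.finite(untre))
      stop("biological replicate ", br, " lacks blank or untreated wells")
    denom <- untre - blank
    if (denom <= 0)
      stop("no growth signal: untreated - blank <= 0 in replicate ", br)
    trt <- g[g$treatment != "blank", ]
    od_bar <- tapply(trt$od600, trt$grp, mean)       # technical means
    per_rep[[as.character(br)]] <-
      data.frame(grp = names(od_bar),
                 percent = 100 * (od_bar - blank) / denom)
  }
  all_reps <- do.call(rbind, per_rep)
  meta <- unique(d[, c("grp", "treatment", "concentration_uM")])
  stats_by <- split(all_reps$percent, all_reps$grp)
  out <- data.frame(grp = names(stats_by),
                    percent_of_untreated = vapply(stats_by, mean, 0),
                    sem = vapply(stats_by, sem, 0),
                    n_bio = vapply(stats_by, length, 0L))
  out <- merge(meta, out, by = "grp")
  out <- out[order(out$treatment, out$concentration_uM), ]
  rownames(out) <- NULL
  cbind(out[, c("treatment", "concentration_uM", "percent_of_untreated",
                "sem", "n_bio")], t_eval_hr = t_eval_hr)
}

#' NF-kB induction from dual-luciferase reporter plates
#'
#' Per well, the ratio r = firefly/renilla is formed; per biological
#' replicate (plate) and treatment, technical replicates are averaged; and
#' each treatment's induction is (r - r_LPS+PB) / (r_LPS - r_LPS+PB), i.e.
#' background-subtracted with the LPS + polymyxin-B wells and normalized to
#' the LPS positive control. Inductions are aggregated as mean +/- SEM over
#' biological replicates. Negative inductions are reported as-is.
#'
#' @param plate Data frame with columns `well`, `firefly`, `renilla`,
#'   `treatment`, `bio_rep`; treatments must include `"LPS"` and `"LPS+PB"`
#'   in every biological replicate, and renilla must be positive.
#' @return Data frame (`treatment`, `induction`, `sem`, `n_bio`).
#' @export
nfkb_induction <- function(plate) {
  need <- c("firefly", "renilla", "treatment", "bio_rep")
  if (!all(need %in% names(plate)))
    stop("plate must have columns: ", paste(need, collapse = ", "))
  if (any(plate$renilla <= 0))
    stop("renilla counts must be > 0 for all retained wells")
  plate$r <- plate$firefly / plate$renilla

  per_rep <- list()
  for (br in unique(plate$bio_rep)) {
    g <- plate[plate$bio_rep == br, ]
    rbar <- tapply(g$r, g$treatment, mean)
    if (!all(c("LPS", "LPS+PB") %in% names(rbar)))
      stop("plate for replicate ", br, " lacks LPS or LPS+PB anchor wells")
    span <- rbar[["LPS"]] - rbar[["LPS+PB"]]
    if (span <= 0)
      stop("failed positive control in replicate ", br,
           ": LPS ratio <= LPS+PB ratio")
    per_rep[[as.character(br)]] <-
      data.frame(treatment = names(rbar),
                 induction = (rbar - rbar[["LPS+PB"]]) / span,
                 bio_rep = br)
  }
  all_reps <- do.call(rbind, per_rep)
  out <- aggregate(induction ~ treatment, all_reps,
                   function(v) c(mean = mean(v), sem = sem(v), n = length(v)))
  data.frame(treatment = out$treatment,
             induction = out$induction[, "mean"],
             sem = out$induction[, "sem"],
             n_bio = out$induction[, "n"])
}

#' Assemble a tidy dose-response table
#'
#' Binds per-concentration assay summaries into one long table sorted by
#' concentration within treatment.
#'
#' @param results List of data frames, each with columns `treatment`,
#'   `response`, `sem` plus a `concentration_uM` column (or the
#'   `percent_of_untreated`/`induction` column of the assay summaries, which
#'   is renamed to `response`), or a single such data frame.
#' @return Data frame (`treatment`, `concentration_uM`, `response`, `sem`)
#'   sorted by treatment then ascending concentration.
#' @export
dose_series <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (length(results) == 0) stop("no results supplied")
  tidy <- lapply(results, function(d) {
    for (col in c("percent_of_untreated", "induction"))
      if (col %in% names(d) && !"response" %in% names(d))
        names(d)[names(d) == col] <- "response"
    if (!all(c("treatment", "concentration_uM", "response") %in% names(d)))
      stop("each result needs treatment, concentration_uM and a response")
    if (!"sem" %in% names(d)) d$sem <- NA_real_
    d[, c("treatment", "concentration_uM", "response", "sem")]
  })
  out <- do.call(rbind, tidy)
  out <- out[!is.na(out$concentration_uM), , drop = FALSE]
  if (nrow(out) < 2) stop("need >= 2 concentrations")
  key <- paste(out$treatment, out$concentration_uM)
  if (anyDuplicated(key))
    stop("duplicate (treatment, concentration) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  out <- out[order(out$treatment, out$concentration_uM), ]
  rownames(out) <- NULL
  out
}
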