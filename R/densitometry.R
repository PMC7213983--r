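# Gel densitometry: lane extraction from a grayscale image, band
# quantification with linear flanking-background subtraction, and
# normalization of a digestion time course to the undigested (t = 0) lane.
# Images are numeric matrices (rows = migration position, columns = pixels
# across the gel width); lanes are vertical strips.

#' Read a grayscale gel image
#'
#' Accepts a 16-bit (or 8-bit) grayscale TIFF or a plain CSV grid of
#' intensities. Multi-channel TIFFs are collapsed by averaging channels.
#'
#' @param path Path to a `.tif`/`.tiff` or `.csv` file.
#' @return Numeric intensity matrix (rows = migration position).
#' @export
read_gel_image <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    return(img)
  }
  as.matrix(read.csv(path, header = FALSE))
}

#' Write a gel image as 16-bit grayscale TIFF
#'
#' Intensities are scaled to the image maximum before writing.
#'
#' @param image Numeric intensity matrix.
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_gel_tiff <- function(image, path) {
  m <- image / max(image, 1e-12)
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

#' Split a gel image into lane intensity profiles
#'
#' Partitions the image into `n_lanes` vertical strips (equal width by
#' default, or at explicit column boundaries) and collapses each strip to a
#' 1-D profile by summing across its width.
#'
#' @param image Numeric intensity matrix; rows are migration positions.
#' @param n_lanes Number of lanes (>= 1, <= image width in pixels).
#' @param boundaries Optional integer vector of n_lanes + 1 column boundaries
#'   (first = 0, last = ncol(image)) overriding the equal-width partition.
#' @param saturation_level Optional intensity at which pixels are considered
#'   saturated; any such pixel triggers a warning (quantification proceeds).
#' @return List of numeric profiles (length = nrow(image)), one per lane.
#' @export
extract_lanes <- function(image, n_lanes, boundaries = NULL,
                          saturation_level = NULL) {
  if (!is.matrix(image) || !all(is.finite(image)))
    stop("image must be a finite numeric matrix")
  if (n_lanes < 1) stop("n_lanes must be >= 1")
  if (n_lanes > ncol(image))
    stop("n_lanes (", n_lanes, ") exceeds image width (", ncol(image), " px)")
  if (!is.null(saturation_level) && any(image >= saturation_level))
    warning(sum(image >= saturation_level),
            " saturated pixel(s) at or above ", saturation_level)
  if (is.null(boundaries))
    boundaries <- round(seq(0, ncol(image), length.out = n_lanes + 1))
  if (length(boundaries) != n_lanes + 1 || any(diff(boundaries) < 1))
    stop("boundaries must be ", n_lanes + 1, " strictly increasing columns")
  lapply(seq_len(n_lanes), function(i)
    rowSums(image[, (boundaries[i] + 1):boundaries[i + 1], drop = FALSE]))
}

#' Quantify a band in a lane profile
#'
#' Background under the band is modeled as the straight line joining the
#' median intensities of small flanking regions on either side of the band
#' window; the band intensity is the sum of (profile - background) over the
#' window, floored at zero. This removes any background that is linear in
#' migration position exactly, including a constant offset.
#'
#' @param profile Numeric lane profile (intensity vs migration position).
#' @param window Integer vector `c(first, last)` of band positions.
#' @param flank Width (positions) of each flanking background region.
#' @return List with `intensity`, the `background` values over the window and
#'   the `window` used.
#' @export
quantify_band <- function(profile, window, flank = 5) {
  if (length(profile) < 10) stop("profile too short (< 10 positions)")
  lo <- window[1]; hi <- window[2]
  if (lo > hi) stop("window must be c(first, last) with first <= last")
  if (lo - flank < 1 || hi + flank > length(profile))
    stop("band window touches the profile edge: no room for ", flank,
         "-point flanks")
  left <- (lo - flank):(lo - 1)
  right <- (hi + 1):(hi + flank)
  x0 <- mean(left); y0 <- median(profile[left])
  x1 <- mean(right); y1 <- median(profile[right])
  xs <- lo:hi
  bg <- y0 + (y1 - y0) * (xs - x0) / (x1 - x0)
  list(intensity = max(0, sum(profile[xs] - bg)),
       background = bg, window = c(lo, hi))
}

#' Normalize a band-intensity time course to the undigested reference
#'
#' Divides every band intensity by the intensity at the reference time
#' (default t = 0, the undigested lane), yielding the fraction of intact
#' protein; the reference lane maps to exactly 1.
#'
#' @param intensities Numeric band intensities, one per time point.
#' @param times Numeric time labels (minutes), same length.
#' @param reference_time Time of the undigested reference lane (default 0).
#' @return Data frame with `time_min`, `intensity` and `fraction_intact`.
#' @export
normalize_timecourse <- function(intensities, times, reference_time = 0) {
  if (length(intensities) != length(times))
    stop("intensities and times must have equal length")
  i <- which(times == reference_time)
  if (length(i) != 1)
    stop("exactly one lane must be at the reference time ", reference_time)
  ref <- intensities[i]
  if (!is.finite(ref) || ref <= 0)
    stop("reference band intensity must be > 0 (got ", ref, ")")
  data.frame(time_min = times, intensity = intensities,
             fraction_intact = intensities / ref)
}

#' Quantify a full gel digestion time course
#'
#' Convenience wrapper: extracts one lane per time point, quantifies the
#' intact-protein band in each lane with a shared window, and normalizes to
#' the t = 0 lane.
#'
#' @param image Gel image matrix, one lane per time point, in time order.
#' @param times Time labels (minutes), one per lane.
#' @param window Band window `c(first, last)` in migration positions, shared
#'   across lanes.
#' @param flank Flanking background width passed to [quantify_band()].
#' @param reference_time Reference (undigested) time, default 0.
#' @return Data frame with `lane`, `time_min`, `intensity`,
#'   `fraction_intact`.
#' @export
quantify_gel_timecourse <- function(image, times, window, flank = 5,
                                    reference_time = 0) {
  lanes <- extract_lanes(image, n_lanes = length(times))
  ints <- vapply(lanes, function(p) quantify_band(p, window, flank)$intensity,
                 numeric(1))
  out <- normalize_timecourse(ints, times, reference_time)
  cbind(lane = seq_along(times), out)
}
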