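#' One-dimensional intensity profile along the A/P axis
#'
#' Positions are micrometres along the anterior/posterior axis with 0 at
#' the A/P compartment border and positive values into the anterior
#' (receiving) compartment; intensities are arbitrary fluorescence units.
#'
#' @param positions Strictly increasing positions, um.
#' @param intensities Non-negative intensities, same length.
#' @param channel_label Channel name (e.g. `"Ptc"`, `"Ci"`).
#' @return Object of class `intensity_profile`.
#' @export
intensity_profile <- function(positions, intensities, channel_label = "") {
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (length(positions) < 2) stop("profile needs at least 2 samples")
  if (any(diff(positions) <= 0))
    stop("positions must be strictly increasing")
  if (any(!is.finite(intensities)) || any(intensities < 0))
    stop("intensities must be finite and >= 0")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 channel_label = as.character(channel_label)),
            class = "intensity_profile")
}

#' Mean of the k longest protrusions
#'
#' The maximum cytoneme extent of a disc is summarised as the average
#' length of its ten longest protrusions, measured from the A/P border to
#' the tip.
#'
#' @param lengths Protrusion lengths, um (non-negative).
#' @param k Number of longest protrusions to average (default 10).
#' @return Mean of the k largest values, um.
#' @export
top_k_mean_extent <- function(lengths, k = 10) {
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths < 0))
    stop("lengths must be finite and >= 0")
  if (length(lengths) < k)
    stop("fewer than k protrusions: need ", k, ", have ", length(lengths),
         " (", k - length(lengths), " missing)")
  mean(sort(lengths, decreasing = TRUE)[seq_len(k)])
}

#' Width of an expression domain from an intensity profile
#'
#' The background is estimated as the median intensity over the 10 percent
#' most-distal positions.  The domain width is the distance from position 0
#' to the farthest position at which the intensity still reaches
#' `background + threshold_fraction * (max - background)`, with the
#' crossing located by linear interpolation between samples.  The result
#' is invariant to affine intensity rescaling (uniform gain and offset).
#'
#' @param profile An [intensity_profile()].
#' @param threshold_fraction Fraction of the above-background peak at which
#'   the domain edge is read (default 0.5).
#' @return Width in um.
#' @export
domain_width <- function(profile, threshold_fraction = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"),
            threshold_fraction > 0, threshold_fraction <= 1)
  pos <- profile$positions
  I <- profile$intensities
  n <- length(pos)
  n_bg <- max(1L, ceiling(0.1 * n))
  bg <- stats::median(I[(n - n_bg + 1L):n])
  peak <- max(I)
  if (peak <= bg + 1e-12 * max(1, abs(bg)))
    stop("no domain: profile of channel '", profile$channel_label,
         "' is flat above background")
  thr <- bg + threshold_fraction * (peak - bg)
  above <- which(I >= thr - 1e-12 * max(1, thr))
  i <- above[length(above)]
  if (i == n) return(pos[n])
  # interpolate the downward crossing between samples i and i+1
  frac <- (I[i] - thr) / (I[i] - I[i + 1L])
  pos[i] + frac * (pos[i + 1L] - pos[i])
}

#' Per-condition mean and SD of domain widths
#'
#' @param groups Named list of numeric width vectors, one per condition.
#' @return Data frame: `condition`, `n`, `mean_um`, `sd_um` (sample SD;
#'   NA for n = 1).
#' @export
compare_domain_widths <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list of width vectors")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    w <- as.numeric(groups[[g]])
    if (length(w) < 1) stop("condition '", g, "' has no widths")
    data.frame(condition = g, n = length(w), mean_um = mean(w),
               sd_um = stats::sd(w), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
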