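# Spatial distribution of labeled cells in the olfactory epithelium.
#
# Raw per-cell measurements are normalized into three relative axes:
# laminar height h_rel (0 = most basal, 1 = most apical), radial position
# r_rel within a lamella (0 = lamellar apex), and section depth z_rel.

#' Normalize raw cell coordinates
#'
#' h_rel = basal_distance / epithelium_thickness;
#' r_rel = radial_distance / radial_extent;
#' z_rel = section_index / n_sections.
#'
#' @param records a \code{\link{spatial_records}} data frame.
#' @return data frame with columns \code{cell_id}, \code{h_rel},
#'   \code{r_rel}, \code{z_rel}, all within [0, 1] (z_rel in (0, 1]).
#' @export
normalize_coordinates <- function(records) {
  stopifnot(inherits(records, "spatial_records"))
  bad <- records$epithelium_thickness <= 0 | records$radial_extent <= 0
  if (any(bad)) {
    stop("zero epithelium thickness or radial extent for cell ",
         records$cell_id[bad][1L])
  }
  data.frame(
    cell_id = records$cell_id,
    h_rel = records$basal_distance / records$epithelium_thickness,
    r_rel = records$radial_distance / records$radial_extent,
    z_rel = records$section_index / records$n_sections
  )
}

#' Histogram of a normalized coordinate
#'
#' Equal-width bins on [0, 1], right-closed, with the first bin including
#' 0.
#'
#' @param values normalized coordinates in [0, 1].
#' @param n_bins number of bins (default 10).
#' @return data frame with \code{bin_lo}, \code{bin_hi}, \code{count},
#'   \code{proportion} (summing to 1).
#' @export
distribution_histogram <- function(values, n_bins = 10L) {
  if (length(values) == 0L) stop("empty input")
  if (any(values < 0 | values > 1)) stop("values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- graphics::hist(values, breaks = breaks, right = TRUE,
                      include.lowest = TRUE, plot = FALSE)
  data.frame(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1L],
    count = h$counts,
    proportion = h$counts / length(values)
  )
}

#' Descriptive summary with a sign test against the uniform midpoint
#'
#' Mean and median of the coordinate plus an exact two-sided binomial sign
#' test of the median against 0.5 (values exactly at 0.5 are dropped).
#' This test is a convenience summary of positional enrichment, not part
#' of the histogram presentation it accompanies.
#'
#' @param values normalized coordinates; n >= 5 for the test (fewer values
#'   yield descriptive statistics only).
#' @return List with \code{n}, \code{mean}, \code{median},
#'   \code{p_sign_test} (NA when omitted or undefined) and \code{note}.
#' @export
enrichment_summary <- function(values) {
  out <- list(n = length(values), mean = mean(values),
              median = stats::median(values), p_sign_test = NA_real_,
              note = "")
  if (length(values) < 5L) {
    out$note <- "n < 5: sign test omitted"
    return(out)
  }
  nz <- values[values != 0.5]
  if (length(nz) == 0L) {
    out$note <- "all values equal 0.5: sign test undefined"
    return(out)
  }
  out$p_sign_test <- stats::binom.test(sum(nz > 0.5), length(nz), p = 0.5)$p.value
  out
}
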