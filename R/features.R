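#' Genome-wide average-speed threshold
#'
#' The threshold captures the average codon speed over all smoothed
#' translational profiles at the reference condition: the mean over the
#' concatenation of every profile's per-position smoothed values
#' (length-weighted, so a long gene contributes proportionally more
#' positions than a short one), on either the time or the speed scale.
#' A single threshold per data set makes drop statistics comparable
#' across conditions; a per-condition variant is obtained by simply
#' recomputing on each condition's own profiles.
#'
#' @param profiles nonempty list of \code{speed_profile}s at the
#'   reference condition.
#' @param scale \code{"speed"} (mean of 1/smoothed time, the default) or
#'   \code{"time"} (mean smoothed time).
#' @return an object of class \code{threshold_value}: list with
#'   \code{value}, \code{scale}, \code{source_condition}.
#' @export
genome_threshold <- function(profiles, scale = c("speed", "time")) {
  scale <- match.arg(scale)
  if (!length(profiles)) stop("empty profile set")
  vals <- unlist(lapply(profiles, function(p)
    if (scale == "speed") p$speed else p$smoothed_times))
  structure(list(value = mean(vals), scale = scale,
                 source_condition = profiles[[1]]$condition),
            class = "threshold_value")
}

# below-threshold indicator: "slower than the genome average"
below_threshold <- function(profile, threshold) {
  if (threshold$scale == "speed") profile$speed < threshold$value
  else profile$smoothed_times > threshold$value
}

#' The four general features of a translational profile
#'
#' (i) average time: arithmetic mean of the smoothed profile; (ii)
#' slowest point: the longest translation time within the smoothed
#' profile; (iii) drop count: the number of maximal contiguous regions
#' slower than the genome threshold, set to 1 when the entire profile
#' lies below it; (iv) maximal drop length: width in codons of the
#' longest such region, excluded (NA) when the entire profile is below
#' the threshold. "Below" is strict: positions exactly at the threshold
#' do not count.
#'
#' @param profile a \code{speed_profile}.
#' @param threshold a \code{\link{genome_threshold}} result.
#' @return an object of class \code{feature_set}: one-row data frame with
#'   columns gene, condition, average_time, slowest_point, drop_count,
#'   max_drop_length, entirely_below.
#' @export
compute_features <- function(profile, threshold) {
  below <- below_threshold(profile, threshold)
  runs <- rle(below)
  drop_lens <- runs$lengths[runs$values]
  all_below <- all(below)
  out <- data.frame(
    gene = profile$gene_id,
    condition = profile$condition,
    average_time = mean(profile$smoothed_times),
    slowest_point = max(profile$smoothed_times),
    drop_count = if (all_below) 1L else length(drop_lens),
    max_drop_length = if (all_below) NA_integer_
                      else if (length(drop_lens)) max(drop_lens) else 0L,
    entirely_below = all_below,
    stringsAsFactors = FALSE)
  class(out) <- c("feature_set", class(out))
  out
}

#' Feature table for many profiles
#'
#' @param profiles list of \code{speed_profile}s.
#' @param threshold a \code{\link{genome_threshold}} result.
#' @return data frame, one row per profile (see
#'   \code{\link{compute_features}}).
#' @export
feature_table <- function(profiles, threshold) {
  out <- do.call(rbind, lapply(profiles, compute_features,
                               threshold = threshold))
  rownames(out) <- NULL
  out
}

#' Genome-wide distributions of the profile features
#'
#' Histogram bins and the median per feature, per condition; the shape of
#' these distributions is what shifts between growth-rate and starvation
#' conditions.
#'
#' @param features a \code{\link{feature_table}} data frame (may span
#'   several conditions).
#' @param breaks passed to \code{\link[graphics]{hist}}-style binning via
#'   \code{\link{cut}}; either a bin count or explicit break points.
#' @return list with \code{medians} (data frame condition x feature) and
#'   \code{histograms} (long data frame: condition, feature, bin_mid,
#'   count). Excluded max-drop-length values (profiles entirely below the
#'   threshold) are dropped from that feature's statistics.
#' @export
feature_distributions <- function(features, breaks = 30) {
  if (!nrow(features)) stop("empty feature table")
  feats <- c("average_time", "slowest_point", "drop_count",
             "max_drop_length")
  meds <- do.call(rbind, lapply(split(features, features$condition),
    function(d) data.frame(
      condition = d$condition[1],
      t(vapply(feats, function(f) stats::median(d[[f]], na.rm = TRUE),
               numeric(1))),
      stringsAsFactors = FALSE)))
  rownames(meds) <- NULL
  hists <- do.call(rbind, lapply(split(features, features$condition),
    function(d) do.call(rbind, lapply(feats, function(f) {
      v <- d[[f]][!is.na(d[[f]])]
      if (!length(v)) return(NULL)
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      data.frame(condition = d$condition[1], feature = f,
                 bin_mid = h$mids, count = h$counts,
                 stringsAsFactors = FALSE)
    }))))
  rownames(hists) <- NULL
  list(medians = meds, histograms = hists)
}
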