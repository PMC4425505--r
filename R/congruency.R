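#' Detect synaptic clusters on the VIAAT channel of a line scan
#'
#' Local maxima of the VIAAT intensity profile above a threshold, at least
#' `min_separation` apart (kept greedily in order of decreasing intensity).
#' The default threshold is the mean plus 3 SD of the lowest-decile pixels
#' (a background estimate). Deterministic.
#'
#' @param scan One scan: tibble with columns `position_um` and `viaat` (plus
#'   any others).
#' @param threshold Intensity threshold; `NULL` (default) uses
#'   background mean + 3 background SD, raised to `rel_height` of the
#'   channel's dynamic range above background when that floor is permissive
#'   (the lowest-decile estimate sits below typical background under noise,
#'   so the floor alone would admit noise bumps).
#' @param min_separation Minimum distance between accepted centres
#'   (micrometres).
#' @param rel_height Minimum peak height as a fraction of
#'   `max(viaat) - background mean` (default 0.2; set 0 for the bare
#'   background-floor threshold).
#' @return Numeric vector of cluster centre positions (micrometres), sorted.
#' @export
detect_clusters <- function(scan, threshold = NULL, min_separation = 1,
                            rel_height = 0.2) {
  v <- scan$viaat
  x <- scan$position_um
  if (sd(v) == 0) {
    warn("flat VIAAT channel; no clusters detectable")
    return(numeric(0))
  }
  if (is.null(threshold)) {
    bg <- v[v <= quantile(v, 0.1)]
    bg_sd <- if (length(bg) > 1) sd(bg) else 0
    threshold <- max(mean(bg) + 3 * bg_sd,
                     mean(bg) + rel_height * (max(v) - mean(bg)))
  }
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n], FALSE) &
    v > threshold
  cand <- which(is_peak)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(-v[cand], x[cand])]
  kept <- numeric(0)
  for (i in cand) {
    if (!length(kept) || all(abs(x[i] - kept) >= min_separation)) {
      kept <- c(kept, x[i])
    }
  }
  sort(kept)
}

#' Per-cluster HA/gephyrin window ratios
#'
#' For each cluster centre, takes the full window (2-3 um, centred on the
#' cluster), locates the HA intensity peak within it, restricts to the peak
#' window (>= 0.66 um, centred on the HA peak), and computes the congruency
#' ratio: mean HA over the peak window divided by mean gephyrin over the same
#' pixels. A ratio of 1 indicates perfect congruency of the HA peak with the
#' local gephyrin signal. Clusters whose windows clip the scan edge are
#' excluded with a reason; clusters with mean gephyrin below `gephyrin_floor`
#' are flagged rather than divided.
#'
#' @param scan One scan: tibble with `position_um`, `ha`, `gephyrin`.
#' @param centers Cluster centres from [detect_clusters()].
#' @param full_len Full window length in micrometres (must lie in
#'   \[2, 3\]; default 2.5).
#' @param peak_len Peak window length in micrometres (>= 0.66; default 0.66).
#' @param gephyrin_floor Minimum mean gephyrin (grey levels) for a defined
#'   ratio (default 1).
#' @return Tibble with one row per cluster: `center`, `ha_peak_pos`,
#'   `ha_peak_mean`, `gephyrin_mean`, `ratio`, `n_pixels`, `flag` (`"ok"`,
#'   `"edge"` or `"no_local_gephyrin"`), and a `profile` list-column holding
#'   the full-window per-pixel ratio profile.
#' @export
window_ratios <- function(scan, centers, full_len = 2.5, peak_len = 0.66,
                          gephyrin_floor = 1) {
  stopifnot(full_len >= 2, full_len <= 3, peak_len >= 0.66,
            peak_len <= full_len)
  x <- scan$position_um
  purrr::map_dfr(centers, function(cen) {
    full <- which(x >= cen - full_len / 2 & x <= cen + full_len / 2)
    clipped <- (cen - full_len / 2) < min(x) - 1e-9 ||
      (cen + full_len / 2) > max(x) + 1e-9
    if (clipped || !length(full)) {
      return(tibble(center = cen, ha_peak_pos = NA_real_,
                    ha_peak_mean = NA_real_, gephyrin_mean = NA_real_,
                    ratio = NA_real_, n_pixels = 0L, flag = "edge",
                    profile = list(NULL)))
    }
    prof <- tibble(position_um = x[full], ha = scan$ha[full],
                   gephyrin = scan$gephyrin[full],
                   ratio = ifelse(scan$gephyrin[full] > 0,
                                  scan$ha[full] / scan$gephyrin[full], NA_real_))
    peak_pos <- x[full][which.max(scan$ha[full])]
    pk <- which(x >= peak_pos - peak_len / 2 & x <= peak_pos + peak_len / 2)
    pk_clipped <- (peak_pos - peak_len / 2) < min(x) - 1e-9 ||
      (peak_pos + peak_len / 2) > max(x) + 1e-9
    if (pk_clipped) {
      return(tibble(center = cen, ha_peak_pos = peak_pos,
                    ha_peak_mean = NA_real_, gephyrin_mean = NA_real_,
                    ratio = NA_real_, n_pixels = 0L, flag = "edge",
                    profile = list(prof)))
    }
    ha_m <- mean(scan$ha[pk])
    ge_m <- mean(scan$gephyrin[pk])
    if (ge_m < gephyrin_floor) {
      return(tibble(center = cen, ha_peak_pos = peak_pos, ha_peak_mean = ha_m,
                    gephyrin_mean = ge_m, ratio = NA_real_,
                    n_pixels = length(pk), flag = "no_local_gephyrin",
                    profile = list(prof)))
    }
    tibble(center = cen, ha_peak_pos = peak_pos, ha_peak_mean = ha_m,
           gephyrin_mean = ge_m, ratio = ha_m / ge_m,
           n_pixels = length(pk), flag = "ok", profile = list(prof))
  })
}

#' Pearson correlation of HA and gephyrin intensities across clusters
#'
#' @param ha,gephyrin Numeric vectors of per-cluster peak-window mean
#'   intensities.
#' @return Pearson R; `NA` (with a warning) if either vector has zero
#'   variance or fewer than 3 clusters are available.
#' @export
correlate_clusters <- function(ha, gephyrin) {
  ok <- is.finite(ha) & is.finite(gephyrin)
  ha <- ha[ok]; gephyrin <- gephyrin[ok]
  if (length(ha) < 3) {
    warn("fewer than 3 clusters; correlation undefined")
    return(NA_real_)
  }
  if (var(ha) == 0 || var(gephyrin) == 0) {
    warn("zero variance in a channel; correlation undefined")
    return(NA_real_)
  }
  cor(ha, gephyrin)
}

#' Histogram of congruency ratios
#'
#' Left-closed right-open bins of fixed width anchored at 0, so a ratio of
#' exactly 1 falls in the bin \[1.0, 1.2) at the default width.
#'
#' @param ratios Numeric vector of congruency ratios (non-finite values are
#'   dropped).
#' @param bin_width Bin width (default 0.2).
#' @return Tibble with `bin_lower`, `bin_upper`, `count`; counts sum to the
#'   number of finite ratios.
#' @export
congruency_histogram <- function(ratios, bin_width = 0.2) {
  r <- ratios[is.finite(ratios)]
  if (!length(r)) {
    return(tibble(bin_lower = numeric(), bin_upper = numeric(),
                  count = integer()))
  }
  bins <- floor(r / bin_width)
  tab <- table(bins)
  tibble(bin_lower = as.numeric(names(tab)) * bin_width,
         bin_upper = (as.numeric(names(tab)) + 1) * bin_width,
         count = as.integer(tab))
}

#' Full line-scan congruency analysis
#'
#' Runs cluster detection, window ratios, the ratio histogram and the
#' cross-cluster Pearson correlation over a set of line scans.
#'
#' @param scans Tibble with columns `scan_id`, `position_um`, `viaat`, `ha`,
#'   `gephyrin` (e.g. from [simulate_line_scans()] or [read_line_scans()]).
#' @param full_len,peak_len,gephyrin_floor See [window_ratios()].
#' @param min_separation,threshold,rel_height See [detect_clusters()].
#' @param bin_width Histogram bin width (default 0.2).
#' @param correlation `"cluster"` (default; Pearson R of per-cluster HA vs
#'   gephyrin peak-window means) or `"pixel"` (Pearson R over all
#'   peak-window pixels pooled).
#' @return A `congruency_result`: per-cluster tibble, excluded clusters with
#'   reasons, histogram, Pearson R and n.
#' @export
congruency_analysis <- function(scans, full_len = 2.5, peak_len = 0.66,
                                gephyrin_floor = 1, min_separation = 1,
                                threshold = NULL, rel_height = 0.2,
                                bin_width = 0.2,
                                correlation = c("cluster", "pixel")) {
  correlation <- match.arg(correlation)
  per_scan <- scans %>%
    dplyr::group_by(.data$scan_id) %>%
    dplyr::group_split()
  clusters <- purrr::map_dfr(per_scan, function(sc) {
    centers <- detect_clusters(sc, threshold = threshold,
                               min_separation = min_separation,
                               rel_height = rel_height)
    if (!length(centers)) return(NULL)
    wr <- window_ratios(sc, centers, full_len = full_len,
                        peak_len = peak_len, gephyrin_floor = gephyrin_floor)
    dplyr::mutate(wr, scan_id = sc$scan_id[1], .before = 1)
  })
  ok <- dplyr::filter(clusters, .data$flag == "ok")
  excluded <- dplyr::filter(clusters, .data$flag != "ok")
  R <- if (correlation == "cluster") {
    correlate_clusters(ok$ha_peak_mean, ok$gephyrin_mean)
  } else {
    px <- dplyr::bind_rows(ok$profile)
    if (nrow(px) >= 3 && var(px$ha) > 0 && var(px$gephyrin) > 0) {
      cor(px$ha, px$gephyrin)
    } else NA_real_
  }
  structure(list(clusters = ok, excluded = excluded,
                 histogram = congruency_histogram(ok$ratio, bin_width),
                 R = R, n = nrow(ok), bin_width = bin_width,
                 correlation = correlation),
            class = "congruency_result")
}

#' @export
print.congruency_result <- function(x, ...) {
  cat("<congruency_result> n =", x$n, "clusters; Pearson R =",
      signif(x$R, 3), paste0("(", x$correlation, "-level)"), "\n")
  if (nrow(x$excluded)) {
    cat("  excluded:", nrow(x$excluded), "cluster(s) —",
        paste(unique(x$excluded$flag), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy a congruency result: one row per retained cluster
#'
#' @param x A `congruency_result`.
#' @param ... Unused.
#' @return The per-cluster tibble (without the profile list-column).
#' @export
tidy.congruency_result <- function(x, ...) {
  dplyr::select(x$clusters, -"profile")
}

#' One-row summary of a congruency analysis
#'
#' @param x A `congruency_result`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `R`, `n_excluded`, `modal_bin_lower`.
#' @export
glance.congruency_result <- function(x, ...) {
  modal <- if (nrow(x$histogram)) {
    x$histogram$bin_lower[which.max(x$histogram$count)]
  } else NA_real_
  tibble(n = x$n, R = x$R, n_excluded = nrow(x$excluded),
         modal_bin_lower = modal)
}

#' Read line scans from CSV
#'
#' Expected columns: `scan_id`, `position_um`, `viaat`, `ha`, `gephyrin`.
#'
#' @param path CSV path.
#' @return A tibble of line scans.
#' @export
read_line_scans <- function(path) {
  d <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("scan_id", "position_um", "viaat", "ha", "gephyrin")
  if (!all(need %in% names(d))) {
    abort(paste0("line-scan CSV must have columns ",
                 paste(need, collapse = ", ")))
  }
  d
}
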