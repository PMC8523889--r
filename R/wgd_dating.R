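#' Bin corrected 4dTv values into a histogram
#'
#' Half-open bins `[i*w, (i+1)*w)`: value `v` goes to bin `floor(v / w)`.
#'
#' @param values Numeric vector of corrected 4dTv values (`status == "ok"`
#'   pairs only), all `>= 0`.
#' @param bin_width Bin width, default 0.01.
#' @return Object of class `fourdtv_histogram`: data frame with `bin_index`,
#'   `bin_lower`, `count`; attributes `bin_width` and `n`.
#' @export
build_histogram <- function(values, bin_width = 0.01) {
  stopifnot(bin_width > 0)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty distribution")
  if (any(values < 0)) stop("negative 4dTv value")
  # tiny epsilon guards against 0.57/0.01 = 56.999... style fp artifacts:
  # a value printed on a bin edge must land in the upper (half-open) bin
  idx <- floor(values / bin_width + 1e-9)
  tab <- table(idx)
  h <- data.frame(
    bin_index = as.integer(names(tab)),
    bin_lower = as.integer(names(tab)) * bin_width,
    count = as.integer(tab)
  )
  h <- h[order(h$bin_index), , drop = FALSE]
  rownames(h) <- NULL
  structure(h, class = c("fourdtv_histogram", "data.frame"),
            bin_width = bin_width, n = length(values))
}

#' Locate the modal peak of a 4dTv histogram
#'
#' The mode is reported as the lower edge of the maximum-count bin, i.e. at
#' bin-width resolution (two decimals at the default width), matching the
#' granularity at which WGD peak values are conventionally quoted. Ties are
#' broken toward the smallest bin index. An optional window `[lo, hi]`
#' restricts the search (bins whose lower edge lies in the window).
#'
#' @param hist A [build_histogram()] result.
#' @param window Optional numeric interval `c(lo, hi)`.
#' @param smooth_sd Optional Gaussian kernel standard deviation (in 4dTv
#'   units) applied to bin counts before the argmax; `NULL` (default) uses
#'   raw counts.
#' @return List with `mode` (bin lower edge), `height` (count of the modal
#'   bin, unsmoothed) and `window`.
#' @export
find_peak <- function(hist, window = NULL, smooth_sd = NULL) {
  stopifnot(inherits(hist, "fourdtv_histogram"))
  w <- attr(hist, "bin_width")
  h <- as.data.frame(hist)
  if (!is.null(window)) {
    h <- h[h$bin_lower >= window[1] & h$bin_lower <= window[2], ,
           drop = FALSE]
  }
  if (nrow(h) == 0L) stop("no data in window")
  score <- h$count
  if (!is.null(smooth_sd) && smooth_sd > 0) {
    # dense count vector over the covered bin range, Gaussian-smoothed
    rng <- range(h$bin_index)
    dense <- numeric(rng[2] - rng[1] + 1L)
    dense[h$bin_index - rng[1] + 1L] <- h$count
    kw <- max(1L, ceiling(3 * smooth_sd / w))
    kern <- stats::dnorm(seq(-kw, kw) * w, sd = smooth_sd)
    kern <- kern / sum(kern)
    sm <- stats::filter(c(numeric(kw), dense, numeric(kw)), kern,
                        sides = 2)
    sm <- as.numeric(sm)[(kw + 1L):(kw + length(dense))]
    score <- sm[h$bin_index - rng[1] + 1L]
  }
  best <- which(score == max(score))[1]  # ties -> smallest bin index
  list(mode = h$bin_lower[best], height = h$count[best], window = window)
}

#' Convert a lineage-specific 4dTv peak to an absolute WGD age
#'
#' Linear calibration against the teleost-specific third-round (3R) genome
#' duplication: `T = (T_3R / v_3R) * v_wgd`. When the calibration peak is an
#' interval, the age range comes from evaluating the two endpoints (the
#' larger calibration peak gives the younger bound) and the point estimate
#' from the interval midpoint.
#'
#' @param v_wgd Lineage-specific 4dTv peak value, `>= 0`.
#' @param T_3R Calibration age of the 3R duplication in Mya (default 320).
#' @param v_3R Calibration 4dTv peak: a point value or an interval
#'   (default `c(0.65, 0.75)`).
#' @return List with `point` (Mya), `range` (`c(lo, hi)` Mya) and
#'   `calibration` (list echoing `T_3R`, `v_3R`).
#' @examples
#' date_wgd(0.04)  # point ~18.29 Mya, range ~[17.07, 19.69]
#' @export
date_wgd <- function(v_wgd, T_3R = 320, v_3R = c(0.65, 0.75)) {
  stopifnot(v_wgd >= 0, T_3R > 0)
  if (any(v_3R <= 0)) stop("invalid calibration: v_3R must be > 0")
  if (length(v_3R) == 1L) {
    point <- T_3R / v_3R * v_wgd
    range <- c(point, point)
  } else {
    range <- sort(T_3R / v_3R * v_wgd)
    point <- T_3R / mean(range(v_3R)) * v_wgd
  }
  list(point = point, range = range,
       calibration = list(T_3R = T_3R, v_3R = v_3R))
}

#' Write a 4dTv histogram as TSV
#'
#' Two columns `bin_lower_edge`, `count`; tab-separated with a header line.
#'
#' @param hist A [build_histogram()] result.
#' @param path Output path.
#' @export
write_histogram_tsv <- function(hist, path) {
  out <- data.frame(bin_lower_edge = sprintf("%.6f", hist$bin_lower),
                    count = hist$count)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' End-to-end WGD dating on a simulated paralogome
#'
#' Simulates a paralog pair set with a duplication burst, computes per-pair
#' corrected 4dTv, bins the `ok` pairs, finds the modal peak and converts it
#' to an absolute age. This is the pipeline the analysis drivers and the
#' acceptance checks run.
#'
#' @param wgd_d Corrected 4dTv of the simulated duplication burst.
#' @param n_pairs Burst pairs.
#' @param n_background Background duplicate pairs.
#' @param background_d_range Background divergence interval.
#' @param n_codons Codons per simulated sequence.
#' @param model An [hky_model()].
#' @param seed Integer seed for the whole run.
#' @param bin_width Histogram bin width.
#' @param peak_window Optional search window for the peak.
#' @param T_3R,v_3R Calibration (see [date_wgd()]).
#' @return List report: `peak`, `peak_height`, `n_pairs`, `n_ok`,
#'   `n_saturated`, `n_no_sites`, `T_point`, `T_range`, `calibration`,
#'   `seed`, plus the `histogram` and per-pair `stats` table.
#' @export
run_wgd_pipeline <- function(wgd_d = 0.04, n_pairs = 1000,
                             n_background = 0,
                             background_d_range = c(0.1, 0.6),
                             n_codons = 500, model = hky_model(),
                             seed = 42, bin_width = 0.01,
                             peak_window = NULL, T_3R = 320,
                             v_3R = c(0.65, 0.75)) {
  sim <- simulate_paralogome(n_pairs, n_background, wgd_d,
                             background_d_range, n_codons, model,
                             seed = seed)
  stats_df <- batch_4dtv(sim$alignments)
  ok <- stats_df$status == "ok"
  hist <- build_histogram(stats_df$d_corrected[ok], bin_width)
  peak <- find_peak(hist, window = peak_window)
  dating <- date_wgd(peak$mode, T_3R = T_3R, v_3R = v_3R)
  list(
    peak = peak$mode, peak_height = peak$height,
    n_pairs = nrow(stats_df), n_ok = sum(ok),
    n_saturated = sum(stats_df$status == "saturated"),
    n_no_sites = sum(stats_df$status == "no_sites"),
    T_point = dating$point, T_range = dating$range,
    calibration = dating$calibration, seed = seed,
    histogram = hist, stats = stats_df
  )
}

#' Write a WGD dating report as JSON
#'
#' @param report A [run_wgd_pipeline()] result (or any list with the same
#'   scalar fields).
#' @param path Output path.
#' @export
write_dating_report <- function(report, path) {
  keep <- c("peak", "n_pairs", "n_ok", "n_saturated", "n_no_sites",
            "T_point", "T_range", "calibration", "seed")
  jsonlite::write_json(report[intersect(keep, names(report))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
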