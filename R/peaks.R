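#' Simulate a peak table from a targeted lipid library
#'
#' Each library entry yields one peak with m/z jittered by at most
#' `ppm_jitter` parts per million and retention time shifted by `drift`
#' (a function of the true retention time, in minutes). Decoy peaks are
#' placed at a fixed ppm offset from randomly chosen entries so tolerance
#' semantics can be exercised. A designated subset of entries acts as
#' retention-time markers, returned as (observed, library) RT pairs.
#'
#' @param library data.frame with columns `name`, `mz`, `adduct`, `rt`.
#' @param drift function mapping true RT (min) to observed RT (min);
#'   default identity.
#' @param ppm_jitter maximum absolute m/z jitter in ppm (uniform).
#' @param n_decoys number of decoy peaks.
#' @param decoy_ppm_offset ppm offset at which decoys are placed.
#' @param marker_idx indices of library entries used as markers; default an
#'   evenly spaced third of the library.
#' @param seed RNG seed.
#' @return list with `peaks` (mz, rt, intensity), `markers` (name,
#'   observed_rt, library_rt) and `truth` (peak row -> library name, NA for
#'   decoys).
#' @export
simulate_peaks <- function(library, drift = identity, ppm_jitter = 2,
                           n_decoys = 0L, decoy_ppm_offset = 20,
                           marker_idx = NULL, seed = 1L) {
  stopifnot(all(c("name", "mz", "rt") %in% names(library)))
  if (any(library$mz <= 0) || any(library$rt < 0))
    stop_config("library m/z must be positive and rt non-negative")
  set.seed(seed)
  n <- nrow(library)
  jitter_ppm <- runif(n, -ppm_jitter, ppm_jitter)
  peaks <- data.frame(
    mz = library$mz * (1 + jitter_ppm * 1e-6),
    rt = vapply(library$rt, drift, numeric(1)),
    intensity = rlnorm(n, log(1e5), 1))
  truth <- library$name
  if (n_decoys > 0) {
    src <- sample.int(n, n_decoys, replace = TRUE)
    decoys <- data.frame(
      mz = library$mz[src] * (1 + decoy_ppm_offset * 1e-6),
      rt = vapply(library$rt[src], drift, numeric(1)),
      intensity = rlnorm(n_decoys, log(1e4), 1))
    peaks <- rbind(peaks, decoys)
    truth <- c(truth, rep(NA_character_, n_decoys))
  }
  marker_idx <- marker_idx %||%
    unique(round(seq(1, n, length.out = max(2, ceiling(n / 3)))))
  markers <- data.frame(name = library$name[marker_idx],
                        observed_rt = peaks$rt[marker_idx],
                        library_rt = library$rt[marker_idx],
                        stringsAsFactors = FALSE)
  list(peaks = peaks, markers = markers, truth = truth)
}

#' Marker-based retention time correction
#'
#' Fits a piecewise-linear mapping from observed to library retention time
#' through the marker pairs and applies it to every peak. Outside the marker
#' range the boundary segments are extended linearly. With fewer than two
#' distinct markers the peaks are returned unchanged with a warning.
#'
#' @param peaks data.frame with at least an `rt` column (minutes).
#' @param markers data.frame with `observed_rt` and `library_rt`.
#' @return `peaks` with corrected `rt`; the original values are kept in
#'   `rt_observed`.
#' @export
rt_correct <- function(peaks, markers) {
  stopifnot(all(c("observed_rt", "library_rt") %in% names(markers)))
  m <- markers[order(markers$observed_rt), , drop = FALSE]
  m <- m[!duplicated(m$observed_rt), , drop = FALSE]
  if (nrow(m) < 2) {
    warning("fewer than 2 distinct markers; retention times left uncorrected")
    peaks$rt_observed <- peaks$rt
    return(peaks)
  }
  x <- m$observed_rt; y <- m$library_rt
  n <- length(x)
  map <- function(t) {
    inner <- approx(x, y, xout = pmin(pmax(t, x[1]), x[n]), ties = "ordered")$y
    lo <- t < x[1]; hi <- t > x[n]
    inner[lo] <- y[1] + (t[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
    inner[hi] <- y[n] + (t[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    inner
  }
  peaks$rt_observed <- peaks$rt
  peaks$rt <- map(peaks$rt)
  peaks
}

#' Match peaks against a targeted lipid library
#'
#' A peak matches a library entry when the relative m/z deviation is at most
#' `ppm_tol` parts per million and the retention time deviation at most
#' `rt_tol` minutes. When several entries qualify, the nearest by ppm wins,
#' ties broken by retention-time deviation. Peaks should be retention-time
#' corrected first (see [rt_correct()]).
#'
#' @param peaks data.frame with `mz` and `rt`.
#' @param library data.frame with `name`, `mz`, `adduct`, `rt`.
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param rt_tol retention time tolerance in minutes (default 0.5).
#' @return list with `matches` (peak index, library name, ppm and rt
#'   deviations), `unmatched_peaks` (indices) and `unmatched_library`
#'   (names).
#' @export
match_library <- function(peaks, library, ppm_tol = 5, rt_tol = 0.5) {
  np <- nrow(peaks); nl <- nrow(library)
  if (np == 0 || nl == 0)
    return(list(matches = data.frame(peak = integer(0),
                                     name = character(0),
                                     ppm = numeric(0), drt = numeric(0)),
                unmatched_peaks = seq_len(np),
                unmatched_library = library$name))
  out <- vector("list", np)
  for (i in seq_len(np)) {
    ppm <- abs(peaks$mz[i] - library$mz) / library$mz * 1e6
    drt <- abs(peaks$rt[i] - library$rt)
    ok <- which(ppm <= ppm_tol & drt <= rt_tol)
    if (!length(ok)) next
    best <- ok[order(ppm[ok], drt[ok])][1]
    out[[i]] <- data.frame(peak = i, name = library$name[best],
                           ppm = ppm[best], drt = drt[best],
                           stringsAsFactors = FALSE)
  }
  matches <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(matches))
    matches <- data.frame(peak = integer(0), name = character(0),
                          ppm = numeric(0), drt = numeric(0))
  list(matches = matches,
       unmatched_peaks = setdiff(seq_len(np), matches$peak),
       unmatched_library = setdiff(library$name, matches$name))
}
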