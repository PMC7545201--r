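# Spectral processing: referencing, 0.02-ppm sum binning, fixed-region and
# RSD-based exclusion, total-area and TSP normalization.

#' One-dimensional NMR spectrum
#'
#' @param ppm strictly monotonic chemical-shift axis (ppm).
#' @param intensity finite intensities, same length as `ppm`.
#' @param sample_id sample identifier.
#' @param matrix `"plasma"` or `"brain"`.
#' @param reference one of `"TSP@0.0"`, `"lactate@1.33"`, `"none"`.
#' @return object of class `nmr_spectrum`; stored with ascending ppm.
#' @export
nmr_spectrum <- function(ppm, intensity, sample_id, matrix,
                         reference = "none") {
  ppm <- as.numeric(ppm); intensity <- as.numeric(intensity)
  if (length(ppm) != length(intensity))
    stop_f("spectrum %s: ppm and intensity lengths differ", sample_id)
  d <- diff(ppm)
  if (!length(d) || !(all(d > 0) || all(d < 0)))
    stop_f("spectrum %s: ppm axis must be strictly monotonic", sample_id)
  if (!all(is.finite(intensity)))
    stop_f("spectrum %s: non-finite intensity values", sample_id)
  if (!all(is.finite(ppm)))
    stop_f("spectrum %s: non-finite ppm values", sample_id)
  if (d[1] < 0) { ppm <- rev(ppm); intensity <- rev(intensity) }
  matrix <- match_matrix_type(matrix)
  if (!reference %in% c("TSP@0.0", "lactate@1.33", "none"))
    stop_f("spectrum %s: unknown reference tag", sample_id)
  structure(list(ppm = ppm, intensity = intensity,
                 sample_id = as.character(sample_id), matrix = matrix,
                 reference = reference, shift_applied = 0),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum %s (%s), %d points, %.3f..%.3f ppm, ref %s>\n",
              x$sample_id, x$matrix, length(x$ppm), min(x$ppm), max(x$ppm),
              x$reference))
  invisible(x)
}

#' Reference a spectrum to a standard peak
#'
#' Shifts the ppm axis so the apex of the tallest peak inside
#' `search_window` lands exactly on `target`. Intensities are untouched; the
#' applied shift is recorded in `$shift_applied`. Defaults follow the sample
#' matrix: TSP to delta 0 for brain extracts, the lactate doublet to delta
#' 1.33 for plasma.
#'
#' @param s an [nmr_spectrum].
#' @param target target chemical shift (ppm).
#' @param search_window length-2 numeric window searched for the apex. The
#'   plasma default is a tight (1.31, 1.35) window: the broad lipid (CH2)n
#'   envelope apex at ~1.27 ppm would otherwise out-compete the lactate
#'   doublet in a wide window.
#' @param min_snr reject if the window maximum does not exceed the spectrum
#'   noise floor (median + `min_snr` * mad) — no detectable reference peak.
#' @return the referenced `nmr_spectrum`.
#' @export
reference_spectrum <- function(s, target = NULL, search_window = NULL,
                               min_snr = 5) {
  stopifnot(inherits(s, "nmr_spectrum"))
  if (is.null(target))
    target <- if (s$matrix == "brain") 0.0 else 1.33
  if (is.null(search_window))
    search_window <- if (s$matrix == "brain") c(-0.2, 0.2) else c(1.31, 1.35)
  stopifnot(length(search_window) == 2L, search_window[1] < search_window[2])
  sel <- s$ppm >= search_window[1] & s$ppm <= search_window[2]
  if (!any(sel))
    stop_f("spectrum %s: search window [%.3f, %.3f] does not overlap axis",
           s$sample_id, search_window[1], search_window[2])
  floor_ <- stats::median(s$intensity) + min_snr * stats::mad(s$intensity)
  apex <- max(s$intensity[sel])
  if (apex <= floor_)
    stop_f(paste0("spectrum %s: no reference peak detected in ",
                  "[%.3f, %.3f] (window max %.4g <= noise floor %.4g)"),
           s$sample_id, search_window[1], search_window[2], apex, floor_)
  at <- s$ppm[sel][which.max(s$intensity[sel])]
  shift <- target - at
  s$ppm <- s$ppm + shift
  s$shift_applied <- s$shift_applied + shift
  s$reference <- if (abs(target) < 1e-9) "TSP@0.0"
                 else if (abs(target - 1.33) < 1e-9) "lactate@1.33"
                 else s$reference
  s
}

bin_label <- function(lo, hi) sprintf("b%.2f_%.2f", lo, hi)

parse_bin_label <- function(label) {
  m <- regmatches(label,
                  regexec("^b(-?[0-9.]+)_(-?[0-9.]+)$", label))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop_f("malformed bin label(s): %s",
                       paste(label[bad], collapse = ", "))
  lo <- vapply(m, function(x) as.numeric(x[2]), numeric(1))
  hi <- vapply(m, function(x) as.numeric(x[3]), numeric(1))
  cbind(lo = lo, hi = hi)
}

#' Sum-bin one spectrum on a fixed ppm grid
#'
#' Bins are half-open `[k*width, (k+1)*width)` intervals anchored at
#' `grid_anchor`; each bin value is the plain sum of the intensity samples
#' whose ppm falls inside, so the bin total equals the intensity total over
#' the covered range exactly (up to floating summation).
#'
#' @param s an [nmr_spectrum] (referenced).
#' @param width bin width in ppm (> 0); 0.02 by convention.
#' @param grid_anchor ppm value on which bin edges are anchored.
#' @return list with `values` (named numeric), `edges` (matrix lo/hi),
#'   `labels`, `k` (integer bin indices).
#' @export
bin_spectrum <- function(s, width = 0.02, grid_anchor = 0.0) {
  stopifnot(inherits(s, "nmr_spectrum"))
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop_f("bin width must be > 0")
  k <- floor((s$ppm - grid_anchor) / width)
  kr <- seq(min(k), max(k))
  values <- vapply(split(s$intensity, factor(k, levels = kr)), sum,
                   numeric(1))
  lo <- grid_anchor + kr * width
  hi <- lo + width
  labels <- bin_label(lo, hi)
  names(values) <- labels
  list(values = values, edges = cbind(lo = lo, hi = hi), labels = labels,
       k = kr)
}

#' Bin a set of spectra into a samples-by-bins matrix
#'
#' All spectra are binned on the same absolute grid; only bin indices common
#' to every spectrum are kept (referencing shifts can move the axis ends by a
#' fraction of a bin).
#'
#' @param spectra list of referenced [nmr_spectrum] objects.
#' @param metadata optional data.frame with `sample_id` and `group` columns,
#'   in the desired row order.
#' @param width,grid_anchor see [bin_spectrum()].
#' @return a `binned_matrix`.
#' @export
bin_cohort <- function(spectra, metadata = NULL, width = 0.02,
                       grid_anchor = 0.0) {
  stopifnot(length(spectra) >= 1L)
  ids <- vapply(spectra, function(s) s$sample_id, character(1))
  if (!is.null(metadata)) {
    if (!all(metadata$sample_id %in% ids))
      stop_f("metadata sample_ids missing from spectra: %s",
             paste(setdiff(metadata$sample_id, ids), collapse = ", "))
    spectra <- spectra[match(metadata$sample_id, ids)]
    ids <- metadata$sample_id
  }
  binned <- lapply(spectra, bin_spectrum, width = width,
                   grid_anchor = grid_anchor)
  klo <- max(vapply(binned, function(b) min(b$k), numeric(1)))
  khi <- min(vapply(binned, function(b) max(b$k), numeric(1)))
  if (khi < klo) stop_f("spectra share no common bins")
  kr <- seq(klo, khi)
  values <- t(vapply(binned, function(b) b$values[match(kr, b$k)],
                     numeric(length(kr))))
  lo <- grid_anchor + kr * width
  labels <- bin_label(lo, lo + width)
  dimnames(values) <- list(ids, labels)
  mt <- unique(vapply(spectra, function(s) s$matrix, character(1)))
  if (length(mt) != 1L) stop_f("spectra mix matrix types")
  new_binned_matrix(values, cbind(lo = lo, hi = lo + width), labels,
                    matrix_type = mt,
                    groups = if (!is.null(metadata)) metadata$group else
                      rep(NA_character_, length(ids)),
                    provenance = list(list(
                      stage = "bin",
                      params = list(width = width,
                                    grid_anchor = grid_anchor))))
}

new_binned_matrix <- function(values, edges, labels, matrix_type, groups,
                              provenance = list()) {
  structure(list(values = values, edges = edges, labels = labels,
                 excluded = rep(FALSE, length(labels)),
                 reason = rep(NA_character_, length(labels)),
                 noise = rep(FALSE, length(labels)),
                 normalization = "raw",
                 sample_ids = rownames(values), groups = groups,
                 matrix_type = matrix_type, provenance = provenance,
                 noise_log = NULL),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf(paste0("<binned_matrix %s: %d samples x %d bins ",
                     "(%d excluded, %d noise), normalization: %s>\n"),
              x$matrix_type, nrow(x$values), length(x$labels),
              sum(x$excluded), sum(x$noise),
              paste(x$normalization, collapse = "+")))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

#' Fixed-region exclusion policy
#'
#' @param regions data.frame with columns `lo`, `hi`, `label` (half-open
#'   `[lo, hi)` ppm intervals); overlapping same-label regions are merged.
#' @param rsd_threshold across-sample RSD above which a bin is a noise
#'   candidate (see [detect_noise_bins()]).
#' @param noise_floor_quantile quantile of the per-bin mean+sd score below
#'   which a high-RSD bin is called noise.
#' @return object of class `exclusion_policy`.
#' @export
exclusion_policy <- function(regions,
                             rsd_threshold = 0.5,
                             noise_floor_quantile = 0.75) {
  regions <- as.data.frame(regions)
  stopifnot(all(c("lo", "hi", "label") %in% names(regions)))
  if (any(regions$hi <= regions$lo))
    stop_f("exclusion regions must have lo < hi")
  assert_number(rsd_threshold, "rsd_threshold")
  if (rsd_threshold <= 0) stop_f("rsd_threshold must be > 0")
  assert_number(noise_floor_quantile, "noise_floor_quantile")
  if (noise_floor_quantile <= 0 || noise_floor_quantile >= 1)
    stop_f("noise_floor_quantile must be in (0, 1)")
  if (nrow(regions) == 0L)
    return(structure(list(regions = regions,
                          rsd_threshold = rsd_threshold,
                          noise_floor_quantile = noise_floor_quantile),
                     class = "exclusion_policy"))
  # merge overlapping regions within a label so each bin maps to one reason
  merged <- do.call(rbind, lapply(split(regions, regions$label), function(r) {
    r <- r[order(r$lo), , drop = FALSE]
    out <- r[1, , drop = FALSE]
    for (i in seq_len(nrow(r))[-1]) {
      j <- nrow(out)
      if (r$lo[i] <= out$hi[j]) out$hi[j] <- max(out$hi[j], r$hi[i])
      else out <- rbind(out, r[i, ])
    }
    out
  }))
  rownames(merged) <- NULL
  structure(list(regions = merged, rsd_threshold = rsd_threshold,
                 noise_floor_quantile = noise_floor_quantile),
            class = "exclusion_policy")
}

#' Default exclusion policy for a sample matrix
#'
#' Masks the low-field tail before 0.7 ppm, everything after 9.38 ppm and
#' the 5.0-6.0 ppm water/noise region; for plasma additionally the EDTA /
#' Ca-EDTA / Mg-EDTA contamination resonances (2.52-2.58, 2.68-2.74,
#' 3.08-3.24, 3.58-3.65 ppm). All bounds are configurable via
#' [exclusion_policy()].
#'
#' @param matrix `"plasma"` or `"brain"`.
#' @param ... overrides passed to [exclusion_policy()].
#' @export
default_exclusion_policy <- function(matrix, ...) {
  matrix <- match_matrix_type(matrix)
  regions <- data.frame(
    lo = c(-Inf, 9.38, 5.0),
    hi = c(0.7, Inf, 6.0),
    label = c("below-0.7", "above-9.38", "water/noise-region"),
    stringsAsFactors = FALSE)
  if (matrix == "plasma")
    regions <- rbind(regions, data.frame(
      lo = c(2.52, 2.68, 3.08, 3.58),
      hi = c(2.58, 2.74, 3.24, 3.65),
      label = "EDTA", stringsAsFactors = FALSE))
  exclusion_policy(regions, ...)
}

#' Flag bins intersecting fixed exclusion regions
#'
#' Flags are additive metadata: bin values are preserved for audit. A bin
#' `[lo, hi)` is flagged when it intersects any policy region `[rlo, rhi)`
#' (i.e. `lo < rhi && hi > rlo`); the first matching region supplies the
#' reason.
#'
#' @param m a `binned_matrix`.
#' @param policy an [exclusion_policy()].
#' @return the flagged `binned_matrix`.
#' @export
apply_exclusions <- function(m, policy) {
  stopifnot(inherits(m, "binned_matrix"), inherits(policy, "exclusion_policy"))
  reg <- policy$regions
  for (i in seq_len(nrow(reg))) {
    hit <- m$edges[, "lo"] < reg$hi[i] & m$edges[, "hi"] > reg$lo[i]
    newly <- hit & !m$excluded
    m$excluded[newly] <- TRUE
    m$reason[newly] <- reg$label[i]
  }
  m$provenance <- c(m$provenance, list(list(
    stage = "fixed_exclusions",
    params = list(regions = reg),
    retained_bins = sum(!m$excluded))))
  m
}

#' Detect noise bins by relative standard deviation
#'
#' For each retained bin, computes the across-sample RSD (`sd / |mean|`) and
#' the signal score `mean + sd`. A bin is flagged `RSD-noise` when its RSD
#' exceeds `policy$rsd_threshold` and its score falls below the
#' `policy$noise_floor_quantile` quantile of all retained bins' scores; a bin
#' whose mean is exactly zero has infinite RSD and is flagged outright.
#' Per-bin decisions are kept in `$noise_log`.
#'
#' @param m a `binned_matrix` with >= 3 samples.
#' @param policy an [exclusion_policy()].
#' @return the `binned_matrix` with `$noise` flags set.
#' @export
detect_noise_bins <- function(m, policy) {
  stopifnot(inherits(m, "binned_matrix"), inherits(policy, "exclusion_policy"))
  if (nrow(m$values) < 3L)
    stop_f("noise detection needs at least 3 samples, got %d", nrow(m$values))
  flags <- noise_flags(m$values[, !m$excluded, drop = FALSE],
                       policy, log = TRUE)
  idx <- which(!m$excluded)
  m$noise[idx] <- flags$flag
  m$noise_log <- data.frame(bin = m$labels[idx], mean = flags$mu,
                            sd = flags$sdv, rsd = flags$rsd,
                            score = flags$score, flagged = flags$flag,
                            stringsAsFactors = FALSE)
  m$provenance <- c(m$provenance, list(list(
    stage = "noise_detection",
    params = list(rsd_threshold = policy$rsd_threshold,
                  noise_floor_quantile = policy$noise_floor_quantile),
    flagged_bins = sum(flags$flag))))
  m
}

# Core RSD rule on a plain matrix (also used per training fold in the CV
# engine). Returns flags parallel to the columns of X.
noise_flags <- function(X, policy, log = FALSE) {
  mu <- colMeans(X)
  sdv <- col_sds(X)
  rsd <- ifelse(mu == 0, Inf, sdv / abs(mu))
  score <- mu + sdv
  floor_ <- stats::quantile(score, policy$noise_floor_quantile, names = FALSE)
  flag <- (rsd > policy$rsd_threshold & score < floor_) | mu == 0
  if (log) list(flag = flag, mu = mu, sdv = sdv, rsd = rsd, score = score)
  else flag
}

#' Normalize a binned matrix
#'
#' `total_area`: divides each row by its sum over retained, non-noise bins
#' and multiplies by 100, so those bins sum to 100 per sample (idempotent,
#' invariant to per-sample global scaling). `tsp`: divides each row by its
#' value in the delta-0-containing bin (brain only); the TSP bin lies inside
#' the below-0.7 exclusion but its value is preserved by flagging, which is
#' what makes this possible.
#'
#' @param m a `binned_matrix`.
#' @param mode `"total_area"` or `"tsp"`.
#' @param constant row total after total-area normalization.
#' @return the normalized `binned_matrix`.
#' @export
normalize_bins <- function(m, mode = c("total_area", "tsp"),
                           constant = 100) {
  stopifnot(inherits(m, "binned_matrix"))
  mode <- match.arg(mode)
  if (mode == "total_area") {
    keep <- !m$excluded & !m$noise
    if (!any(keep)) stop_f("total_area normalization: no retained bins")
    tot <- rowSums(m$values[, keep, drop = FALSE])
    if (any(tot <= 0))
      stop_f("total_area normalization: non-positive row total for %s",
             paste(m$sample_ids[tot <= 0], collapse = ", "))
    m$values <- m$values / tot * constant
  } else {
    if (m$matrix_type != "brain")
      stop_f("TSP normalization is defined for brain extracts only")
    tsp_bin <- which(m$edges[, "lo"] <= 0 & m$edges[, "hi"] > 0)
    if (length(tsp_bin) != 1L)
      stop_f("TSP normalization: delta-0 bin absent from the grid")
    ref <- m$values[, tsp_bin]
    if (any(ref <= 0))
      stop_f("TSP normalization: non-positive TSP-bin value for %s",
             paste(m$sample_ids[ref <= 0], collapse = ", "))
    m$values <- m$values / ref
  }
  m$normalization <- if (identical(m$normalization, "raw")) mode
                     else unique(c(m$normalization, mode))
  m$provenance <- c(m$provenance, list(list(stage = "normalize",
                                            params = list(mode = mode))))
  m
}

#' Extract the modelling matrix from a binned matrix
#'
#' @param m a `binned_matrix`.
#' @param drop_noise drop RSD-noise bins as well as fixed exclusions.
#' @return numeric matrix (samples x retained bins) with dimnames.
#' @export
model_matrix <- function(m, drop_noise = TRUE) {
  stopifnot(inherits(m, "binned_matrix"))
  keep <- !m$excluded & (!drop_noise | !m$noise)
  m$values[, keep, drop = FALSE]
}
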