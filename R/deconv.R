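#' Detect chromatographic peaks on the TIC
#'
#' Local maxima of the smoothed total ion chromatogram above a noise-scaled
#' threshold; each maximum is extended left and right into a retention-time
#' window until the smoothed TIC drops to a fraction of the peak height
#' above the local base. Deterministic for fixed parameters.
#'
#' @param run a `chromatographic_run`.
#' @param smooth_width moving-average width in scans (odd; default 13,
#'   about 0.1 min at 2 spectra/s).
#' @param noise_mult threshold is `median + noise_mult * mad` of the
#'   smoothed TIC.
#' @param rel_height window edges at this fraction of (peak - base) above
#'   the base.
#' @param min_sep maxima closer than this (minutes) are merged into the
#'   higher one; the default merges oxidation-shifted shoulders into one
#'   subunit window while keeping the subunit clusters apart.
#' @return data.frame with `rt_apex`, `rt_min`, `rt_max`, `height`, ordered
#'   by `rt_apex`; zero rows for a flat or empty TIC.
#' @export
detect_chromatographic_peaks <- function(run, smooth_width = 13L,
                                         noise_mult = 8, rel_height = 0.05,
                                         min_sep = 1) {
  tc <- run_tic(run)
  y <- tc$tic
  if (!length(y) || all(y == y[1])) {
    return(data.frame(rt_apex = numeric(), rt_min = numeric(),
                      rt_max = numeric(), height = numeric()))
  }
  k <- max(3L, smooth_width %/% 2L * 2L + 1L)
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- y[is.na(sm)]
  sm <- as.numeric(sm)
  base <- stats::median(sm)
  thr <- base + noise_mult * stats::mad(sm)
  n <- length(sm)
  is_max <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                     sm[2:(n - 1)] >= sm[3:n], FALSE)
  apexes <- which(is_max & sm > thr)
  if (!length(apexes)) {
    return(data.frame(rt_apex = numeric(), rt_min = numeric(),
                      rt_max = numeric(), height = numeric()))
  }
  # merge nearby maxima, keeping the highest
  apexes <- apexes[order(-sm[apexes])]
  kept <- integer()
  for (a in apexes) {
    if (!length(kept) || all(abs(tc$rt[a] - tc$rt[kept]) >= min_sep))
      kept <- c(kept, a)
  }
  kept <- sort(kept)
  out <- lapply(kept, function(a) {
    cut <- base + rel_height * (sm[a] - base)
    lo <- a; while (lo > 1L && sm[lo - 1L] > cut) lo <- lo - 1L
    hi <- a; while (hi < n && sm[hi + 1L] > cut) hi <- hi + 1L
    data.frame(rt_apex = tc$rt[a], rt_min = tc$rt[lo], rt_max = tc$rt[hi],
               height = sm[a])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Average the spectra of a retention-time window
#'
#' Mean intensity on the common m/z grid over all scans in the window;
#' grid points missing from a scan count as zero intensity.
#'
#' @param run a `chromatographic_run`.
#' @param rt_window numeric length-2 `c(rt_min, rt_max)` in minutes.
#' @return list of class `averaged_spectrum` with `mz`, `intensity`,
#'   `n_scans`, `rt_window`.
#' @export
average_spectrum <- function(run, rt_window) {
  rts <- vapply(run$scans, `[[`, numeric(1), "rt")
  sel <- which(rts >= rt_window[1] & rts <= rt_window[2])
  if (!length(sel)) stop("rt_window contains no scans")
  scans <- run$scans[sel]
  first <- scans[[1]]$mz
  same <- all(vapply(scans, function(s)
    length(s$mz) == length(first) && s$mz[1] == first[1] &&
      s$mz[length(s$mz)] == first[length(first)], logical(1)))
  if (same) {
    inten <- rowMeans(vapply(scans, `[[`, numeric(length(first)),
                             "intensity"))
    mz <- first
  } else {
    mzall <- unlist(lapply(scans, `[[`, "mz"))
    iall <- unlist(lapply(scans, `[[`, "intensity"))
    key <- round(mzall * 1e6)
    o <- order(key)
    key <- key[o]; iall <- iall[o]; mzall <- mzall[o]
    grp <- cumsum(c(TRUE, diff(key) != 0))
    mz <- mzall[!duplicated(grp)]
    inten <- as.numeric(rowsum(iall, grp)) / length(scans)
  }
  structure(list(mz = mz, intensity = inten, n_scans = length(sel),
                 rt_window = rt_window), class = "averaged_spectrum")
}

#' Centroid a profile-mode spectrum
#'
#' Local maxima above a threshold become peaks; each centroid is the
#' intensity-weighted mean m/z over the maximum's half-height support
#' (restricted to contiguous grid points).
#'
#' @param spec an `averaged_spectrum` (or any list with `mz`, `intensity`).
#' @param min_rel minimum peak intensity relative to the spectrum maximum.
#' @param min_abs absolute minimum peak intensity.
#' @param gap m/z gap (Th) that breaks grid contiguity.
#' @return data.frame with `mz`, `intensity` (apex height), ordered by mz.
#' @export
centroid_peaks <- function(spec, min_rel = 0.002, min_abs = 1, gap = 0.05) {
  mz <- spec$mz; y <- spec$intensity
  n <- length(mz)
  out <- data.frame(mz = numeric(), intensity = numeric())
  if (n < 3L) return(out)
  thr <- max(min_abs, min_rel * max(y))
  brk <- c(0L, which(diff(mz) > gap), n)
  res <- list()
  for (s in seq_len(length(brk) - 1L)) {
    i0 <- brk[s] + 1L; i1 <- brk[s + 1L]
    if (i1 - i0 < 2L) next
    yy <- y[i0:i1]; mm <- mz[i0:i1]; m <- length(yy)
    loc <- which(yy[2:(m - 1)] > yy[1:(m - 2)] &
                 yy[2:(m - 1)] >= yy[3:m] &
                 yy[2:(m - 1)] >= thr) + 1L
    for (a in loc) {
      half <- yy[a] / 2
      lo <- a; while (lo > 1L && yy[lo - 1L] >= half && yy[lo - 1L] <= yy[lo])
        lo <- lo - 1L
      hi <- a; while (hi < m && yy[hi + 1L] >= half && yy[hi + 1L] <= yy[hi])
        hi <- hi + 1L
      idx <- lo:hi
      res[[length(res) + 1L]] <- c(sum(mm[idx] * yy[idx]) / sum(yy[idx]),
                                   yy[a])
    }
  }
  if (!length(res)) return(out)
  m <- do.call(rbind, res)
  out <- data.frame(mz = m[, 1], intensity = m[, 2])
  out[order(out$mz), , drop = FALSE]
}

#' Charge-series deconvolution of centroided peaks
#'
#' Deterministic replacement for vendor maximum-entropy deconvolution.
#' Every centroid is expanded into candidate zero-charge masses
#' `M = z * (mz - 1.00728)` over the charge range; candidates are clustered
#' on the mass axis (single-linkage, gap above `mass_bin` splits); clusters
#' are processed in decreasing order of total supporting intensity, each
#' consuming its centroids so that harmonic artifacts (M/2, 2M) built from
#' the same centroids are suppressed; surviving clusters supported by at
#' least `min_series` distinct charge states become deconvoluted peaks at
#' the intensity-weighted mean mass.
#'
#' @param centroids data.frame from [centroid_peaks()].
#' @param z_range integer range of charge states considered.
#' @param min_series minimum number of distinct supporting charge states.
#' @param mass_bin mass-axis clustering gap in Da.
#' @return data.frame of peaks sorted by decreasing abundance: `mass`,
#'   `abundance` (summed supporting intensity), `n_charges`, plus a list
#'   column `supporting_charges` of data.frames `(z, mz, intensity)`.
#' @export
deconvolute <- function(centroids, z_range = c(8L, 40L), min_series = 3L,
                        mass_bin = 0.2) {
  empty <- data.frame(mass = numeric(), abundance = numeric(),
                      n_charges = integer())
  empty$supporting_charges <- list()
  if (!nrow(centroids)) return(empty)
  zs <- seq.int(z_range[1], z_range[2])
  cand <- data.frame(
    centroid = rep(seq_len(nrow(centroids)), each = length(zs)),
    z = rep(zs, nrow(centroids)),
    mz = rep(centroids$mz, each = length(zs)),
    intensity = rep(centroids$intensity, each = length(zs)))
  cand$mass <- cand$z * (cand$mz - .proton)
  o <- order(cand$mass)
  cand <- cand[o, , drop = FALSE]
  cl <- cumsum(c(TRUE, diff(cand$mass) > mass_bin))
  members <- split(seq_len(nrow(cand)), cl)
  tot <- vapply(members, function(i) sum(cand$intensity[i]), numeric(1))
  sizes <- lengths(members)
  order_cl <- order(-tot)
  consumed <- logical(nrow(centroids))
  peaks <- list()
  for (ci in order_cl) {
    if (sizes[ci] < min_series) next
    idx <- members[[ci]]
    idx <- idx[!consumed[cand$centroid[idx]]]
    if (length(unique(cand$z[idx])) < min_series) next
    mem <- cand[idx, , drop = FALSE]
    consumed[mem$centroid] <- TRUE
    peaks[[length(peaks) + 1L]] <- list(
      mass = sum(mem$mass * mem$intensity) / sum(mem$intensity),
      abundance = sum(mem$intensity),
      n_charges = length(unique(mem$z)),
      supporting_charges = mem[order(-mem$intensity),
                               c("z", "mz", "intensity")])
  }
  if (!length(peaks)) return(empty)
  out <- data.frame(
    mass = vapply(peaks, `[[`, numeric(1), "mass"),
    abundance = vapply(peaks, `[[`, numeric(1), "abundance"),
    n_charges = vapply(peaks, `[[`, integer(1), "n_charges"))
  out$supporting_charges <- lapply(peaks, `[[`, "supporting_charges")
  out <- out[order(-out$abundance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extracted ion chromatogram of one species
#'
#' Per-scan summed intensity within `mz_center ± tol`; the peak height is
#' the maximum of the trace inside the species' retention-time window.
#'
#' @param run a `chromatographic_run`.
#' @param mz_center m/z of the monitored charge state (Th).
#' @param tol m/z tolerance in Th (default 0.01).
#' @param rt_window optional `c(rt_min, rt_max)`; default is the whole run.
#' @return list of class `eic_trace`: `mz_center`, `tol`, `z` (if supplied),
#'   `rt`, `intensity`, `peak_height`.
#' @export
extract_eic <- function(run, mz_center, tol = 0.01, rt_window = NULL,
                        z = NA_integer_) {
  rng <- run$acq$mz_range
  if (mz_center < rng[1] || mz_center > rng[2])
    stop(sprintf("mz_center %.3f outside acquisition range [%g, %g]",
                 mz_center, rng[1], rng[2]))
  rt <- vapply(run$scans, `[[`, numeric(1), "rt")
  inten <- vapply(run$scans, function(s) {
    sel <- s$mz >= mz_center - tol & s$mz <= mz_center + tol
    if (any(sel)) sum(s$intensity[sel]) else 0
  }, numeric(1))
  if (is.null(rt_window)) rt_window <- range(rt)
  inw <- rt >= rt_window[1] & rt <= rt_window[2]
  structure(list(mz_center = mz_center, tol = tol, z = z,
                 rt = rt, intensity = inten,
                 rt_window = rt_window,
                 peak_height = if (any(inw)) max(inten[inw]) else 0),
            class = "eic_trace")
}
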