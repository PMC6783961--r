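#' Acquisition parameters for the synthetic LC-ESI-QTOF generator
#'
#' Plausible QTOF settings for reversed-phase LC-MS of 23–26 kDa antibody
#' subunits. The m/z range and scan rate follow common practice for subunit
#' work (m/z 600–3200, 2 spectra/s); retention times, peak widths and the
#' charge-envelope shape are generator conventions, all config-exposed. The
#' retention-time axis is compressed to the informative part of a subunit
#' gradient (default 0–16 min) since the generator only places signal at the
#' three subunit clusters.
#'
#' @param mz_range acquisition m/z window (Th).
#' @param rt_span retention-time span in minutes.
#' @param scan_rate spectra per second.
#' @param base_rt named base retention times (min) of the unoxidized
#'   subunits.
#' @param rt_shift_per_ox RT shift per oxidation event in minutes; negative
#'   (oxidized forms are more hydrophilic and elute earlier), magnitude small
#'   enough that oxidation states are only partially separated.
#' @param rt_sigma chromatographic peak width (Gaussian sigma, min).
#' @param sigma_z width (in charge units) of the Gaussian charge-state
#'   envelope; the envelope mean is `round(M / 1200)`.
#' @param mz_fwhm_const isotopically unresolved peak width: FWHM in Th is
#'   `mz_fwhm_const / z`.
#' @param grid_spacing m/z sampling interval of the profile spectra (Th);
#'   points sit on absolute multiples of this spacing.
#' @param base_intensity intensity of a species at fractional abundance 1
#'   (arbitrary counts, per charge-envelope weight).
#' @param baseline_level flat baseline added to every sampled point.
#' @param noise_sd0 additive Gaussian noise sigma.
#' @param noise_prop intensity-proportional noise coefficient.
#' @param species_floor proteoforms below this fractional abundance are not
#'   simulated.
#' @return a list of class `acquisition_params`.
#' @export
acquisition_params <- function(mz_range = c(600, 3200),
                               rt_span = c(0, 16),
                               scan_rate = 2,
                               base_rt = c("Fc/2" = 5, "LC" = 8, "Fd'" = 12),
                               rt_shift_per_ox = -0.15,
                               rt_sigma = 0.08,
                               sigma_z = 2.5,
                               mz_fwhm_const = 6,
                               grid_spacing = 0.01,
                               base_intensity = 1e5,
                               baseline_level = 2,
                               noise_sd0 = 3,
                               noise_prop = 0.01,
                               species_floor = 1e-4) {
  structure(as.list(environment()), class = "acquisition_params")
}

#' Apex charge state of a species
#'
#' The charge-envelope mean used by the generator and, symmetrically, the
#' charge the quantification layer reads the most intense charge state from.
#' @param mass zero-charge mass in Da.
#' @return integer charge.
#' @export
apex_charge <- function(mass) as.integer(round(mass / 1200))

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf("<acquisition_params> m/z %g-%g, rt %g-%g min, %g spectra/s\n",
              x$mz_range[1], x$mz_range[2], x$rt_span[1], x$rt_span[2],
              x$scan_rate))
  invisible(x)
}

# charge-envelope support of a species: charges, normalized weights, centers
.charge_envelope <- function(mass, acq) {
  zc <- apex_charge(mass)
  z <- (zc - 6L):(zc + 6L)
  z <- z[z >= 1L]
  mz <- (mass + z * .proton) / z
  keep <- mz >= acq$mz_range[1] & mz <= acq$mz_range[2]
  z <- z[keep]; mz <- mz[keep]
  if (!length(z)) return(NULL)
  w <- stats::dnorm(z, zc, acq$sigma_z)
  keep <- w >= 0.02 * max(w)
  z <- z[keep]; mz <- mz[keep]; w <- w[keep]
  list(z = z, mz = mz, w = w / sum(w))
}

#' Simulate one chromatographic run
#'
#' Generates seeded profile-mode spectra for one run of the forced-oxidation
#' design. Every proteoform above the abundance floor is placed as a
#' Gaussian chromatographic peak at its subunit's base retention time,
#' shifted per oxidation; its intensity is spread over a Gaussian
#' charge-state envelope, each charge state a Gaussian in m/z (isotopically
#' unresolved); flat baseline plus Gaussian noise with an
#' intensity-proportional term is added. Identical seed and parameters give
#' a bit-identical run.
#'
#' @param mab a [mab_definition()].
#' @param kinetics scenario from [default_scenario()].
#' @param treatment `"oxi"` or `"con"`.
#' @param duration hours.
#' @param replicate replicate number (metadata only; vary the seed for
#'   independent replicates).
#' @param acq an [acquisition_params()].
#' @param seed integer RNG seed for the noise draws.
#' @return object of class `chromatographic_run`: `metadata`, `scans` (list
#'   of `list(rt, mz, intensity)` sorted by rt with strictly increasing mz),
#'   and `ground_truth` (proteoform library with true fractional
#'   abundances summing to 1 per subunit).
#' @examples
#' mab <- synthetic_mab("bevacizumab_synthetic", role = "BS")
#' run <- simulate_run(mab, default_scenario(mab), "oxi", 48, seed = 1)
#' length(run$scans)
#' @export
simulate_run <- function(mab, kinetics, treatment = c("oxi", "con"),
                         duration, replicate = 1L,
                         acq = acquisition_params(), seed = 1L) {
  treatment <- match.arg(treatment)
  gt <- ground_truth_fractions(mab, kinetics, treatment, duration)
  lib <- gt$library
  times <- seq(acq$rt_span[1], acq$rt_span[2], by = 1 / (acq$scan_rate * 60))
  n_scan <- length(times)
  sp <- acq$grid_spacing

  # per-subunit signal blocks
  blocks <- list()
  for (kind in unique(lib$subunit)) {
    sl <- lib[lib$subunit == kind & lib$fraction >= acq$species_floor, ,
              drop = FALSE]
    if (!nrow(sl)) next
    envs <- lapply(sl$avg_mass, .charge_envelope, acq = acq)
    dropped <- vapply(envs, is.null, logical(1))
    if (any(dropped)) {
      warning(sprintf("%d %s species outside the m/z range were dropped",
                      sum(dropped), kind))
      sl <- sl[!dropped, , drop = FALSE]
      envs <- envs[!dropped]
    }
    if (!nrow(sl)) next
    # union m/z grid (absolute indices on the spacing lattice)
    half <- lapply(envs, function(e) 3.5 * (acq$mz_fwhm_const / e$z) / 2.3548)
    idx_list <- lapply(seq_along(envs), function(i) {
      e <- envs[[i]]
      unlist(lapply(seq_along(e$z), function(j)
        seq.int(floor((e$mz[j] - half[[i]][j]) / sp),
                ceiling((e$mz[j] + half[[i]][j]) / sp))))
    })
    uidx <- sort(unique(unlist(idx_list)))
    mzg <- uidx * sp
    P <- matrix(0, length(uidx), nrow(sl))
    for (i in seq_along(envs)) {
      e <- envs[[i]]
      prof <- numeric(length(uidx))
      pos <- match(idx_list[[i]], uidx)
      for (j in seq_along(e$z)) {
        sig <- (acq$mz_fwhm_const / e$z[j]) / 2.3548
        rng <- match(seq.int(floor((e$mz[j] - half[[i]][j]) / sp),
                             ceiling((e$mz[j] + half[[i]][j]) / sp)), uidx)
        prof[rng] <- prof[rng] +
          acq$base_intensity * sl$fraction[i] * e$w[j] *
          exp(-(mzg[rng] - e$mz[j])^2 / (2 * sig^2))
      }
      P[, i] <- prof
    }
    rt_c <- acq$base_rt[[kind]] + sl$n_ox * acq$rt_shift_per_ox
    lo <- min(rt_c) - 4 * acq$rt_sigma
    hi <- max(rt_c) + 4 * acq$rt_sigma
    scan_idx <- which(times >= lo & times <= hi)
    if (!length(scan_idx)) next
    Rm <- vapply(times[scan_idx],
                 function(t) exp(-(t - rt_c)^2 / (2 * acq$rt_sigma^2)),
                 numeric(nrow(sl)))
    if (is.null(dim(Rm))) Rm <- matrix(Rm, nrow = nrow(sl))
    blocks[[length(blocks) + 1L]] <- list(
      idx = uidx, scan_idx = scan_idx, S = P %*% Rm)
  }

  # assemble scans: coarse baseline lattice everywhere + active signal blocks
  base_idx <- unique(round(seq(acq$mz_range[1], acq$mz_range[2],
                               length.out = 64) / sp))
  active <- vector("list", n_scan)
  for (b in seq_along(blocks))
    for (i in blocks[[b]]$scan_idx)
      active[[i]] <- c(active[[i]], b)
  sig <- vapply(active, function(a)
    if (is.null(a)) "g" else paste0("g", paste(a, collapse = ",")), character(1))
  grids <- new.env(parent = emptyenv())
  for (s in unique(sig)) {
    bs <- if (s == "g") integer() else as.integer(strsplit(sub("^g", "", s), ",")[[1]])
    gi <- sort(unique(c(base_idx, unlist(lapply(blocks[bs],
                                                function(b) b$idx)))))
    assign(s, list(idx = gi, mz = gi * sp,
                   maps = lapply(blocks[bs], function(b) match(b$idx, gi)),
                   bs = bs),
           envir = grids)
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  scans <- vector("list", n_scan)
  for (i in seq_len(n_scan)) {
    g <- get(sig[i], envir = grids)
    y <- numeric(length(g$idx))
    for (k in seq_along(g$bs)) {
      b <- blocks[[g$bs[k]]]
      y[g$maps[[k]]] <- y[g$maps[[k]]] + b$S[, match(i, b$scan_idx)]
    }
    noisy <- y + acq$baseline_level +
      stats::rnorm(length(y), 0, acq$noise_sd0 + acq$noise_prop * y)
    noisy[noisy < 0] <- 0
    scans[[i]] <- list(rt = times[i], mz = g$mz, intensity = noisy)
  }

  structure(list(
    metadata = list(mab = mab$name, role = mab$product_role,
                    treatment = treatment, duration = duration,
                    replicate = as.integer(replicate), seed = as.integer(seed)),
    acq = acq,
    scans = scans,
    ground_truth = lib
  ), class = "chromatographic_run")
}

#' @export
print.chromatographic_run <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("<chromatographic_run> %s [%s] %s %gh rep %d, %d scans, seed %d\n",
              m$mab, m$role, m$treatment, m$duration, m$replicate,
              length(x$scans), m$seed))
  invisible(x)
}

#' Total ion chromatogram of a run
#'
#' @param run a `chromatographic_run`.
#' @return data.frame with `rt` (min) and `tic`.
#' @export
run_tic <- function(run) {
  data.frame(rt = vapply(run$scans, `[[`, numeric(1), "rt"),
             tic = vapply(run$scans, function(s) sum(s$intensity), numeric(1)))
}

#' The forced-oxidation experiment design
#'
#' The full run matrix of the study design: two products, RP and BS roles,
#' control and forced-oxidation treatment, durations 0/24/48/72 h (control
#' only at 0 h; both arms at 24–72 h), three independent replicates.
#'
#' @param mabs product names.
#' @param replicates number of replicates.
#' @return data.frame with columns `mab`, `role`, `treatment`, `duration`,
#'   `replicate`.
#' @export
table1_design <- function(mabs = c("bevacizumab_synthetic",
                                   "infliximab_synthetic"),
                          replicates = 3L) {
  arms <- rbind(data.frame(treatment = "con", duration = c(0, 24, 48, 72)),
                data.frame(treatment = "oxi", duration = c(24, 48, 72)))
  out <- expand.grid(replicate = seq_len(replicates),
                     duration_i = seq_len(nrow(arms)),
                     role = c("RP", "BS"), mab = mabs,
                     stringsAsFactors = FALSE)
  out <- data.frame(mab = out$mab, role = out$role,
                    treatment = arms$treatment[out$duration_i],
                    duration = arms$duration[out$duration_i],
                    replicate = out$replicate, stringsAsFactors = FALSE)
  out[order(out$mab, out$role, out$treatment, out$duration, out$replicate), ,
      drop = FALSE]
}

#' Write a simulated run to mzML
#'
#' Profile-mode spectra are written through `mzR`; retention times are stored
#' in seconds per mzML convention.
#'
#' @param run a `chromatographic_run`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$scans)
  pk <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  rt <- vapply(run$scans, `[[`, numeric(1), "rt") * 60
  tic <- vapply(run$scans, function(s) sum(s$intensity), numeric(1))
  bp <- vapply(run$scans, function(s) which.max(s$intensity), integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L,
    peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = tic, retentionTime = rt,
    basePeakMZ = mapply(function(s, i) s$mz[i], run$scans, bp),
    basePeakIntensity = mapply(function(s, i) s$intensity[i], run$scans, bp),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(s) min(s$mz), numeric(1)),
    highMZ = vapply(run$scans, function(s) max(s$mz), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = run$acq$mz_range[1],
    scanWindowUpperLimit = run$acq$mz_range[2])
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read an mzML file back into a run object
#'
#' @param path mzML file.
#' @param acq acquisition parameters to attach (defaults to the package
#'   defaults; metadata beyond scans is not stored in mzML).
#' @return a `chromatographic_run` with `metadata$mab = NA` and no ground
#'   truth.
#' @export
read_mzml <- function(path, acq = acquisition_params()) {
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pk <- mzR::peaks(h)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_along(pk), function(i)
    list(rt = hdr$retentionTime[i] / 60, mz = pk[[i]][, 1],
         intensity = pk[[i]][, 2]))
  structure(list(
    metadata = list(mab = NA_character_, role = NA_character_,
                    treatment = NA_character_, duration = NA_real_,
                    replicate = NA_integer_, seed = NA_integer_),
    acq = acq, scans = scans, ground_truth = NULL
  ), class = "chromatographic_run")
}
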