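#' Build the proteoform library of a mAb
#'
#' Digests the antibody and row-binds the proteoform libraries of its three
#' subunits.
#'
#' @param mab a [mab_definition()].
#' @param unspecific_ox_cap see [enumerate_proteoforms()].
#' @return data.frame library covering LC, Fd' and Fc/2.
#' @export
mab_library <- function(mab, unspecific_ox_cap = 4L) {
  libs <- lapply(ides_digest(mab), enumerate_proteoforms,
                 unspecific_ox_cap = unspecific_ox_cap)
  do.call(rbind, c(libs, list(make.row.names = FALSE)))
}

#' Assign the species of a run
#'
#' For every detected chromatographic peak: average the spectra in its
#' window, centroid, deconvolute to zero-charge masses, and match each mass
#' against the proteoform library at ppm tolerance. Each deconvoluted mass
#' keeps its best match (smallest `|delta_ppm|`); assignments are listed in
#' order of decreasing spectrum intensity, and the peak's subunit call is
#' the subunit of its most abundant assignment. Unmatched masses are
#' reported separately.
#'
#' @param run a `chromatographic_run`.
#' @param library proteoform library from [mab_library()].
#' @param tol_ppm match tolerance (default 70 ppm).
#' @param ... passed to [detect_chromatographic_peaks()].
#' @return list of class `run_annotation`: `windows` (peak table),
#'   `annotations` (one per window: `rt_window`, `assignments` data.frame,
#'   `unmatched` data.frame, `subunit` call), and `assignments` (all
#'   windows row-bound, with a `window` column).
#' @export
assign_run <- function(run, library, tol_ppm = 70, ...) {
  windows <- detect_chromatographic_peaks(run, ...)
  annotations <- vector("list", nrow(windows))
  all_assign <- list()
  for (i in seq_len(nrow(windows))) {
    w <- c(windows$rt_min[i], windows$rt_max[i])
    spec <- average_spectrum(run, w)
    peaks <- deconvolute(centroid_peaks(spec))
    rows <- list(); unmatched <- list()
    for (j in seq_len(nrow(peaks))) {
      m <- match_mass(peaks$mass[j], library, tol_ppm = tol_ppm,
                      abundance = peaks$abundance[j])
      if (nrow(m)) {
        rows[[length(rows) + 1L]] <- m[1L, , drop = FALSE]
      } else {
        unmatched[[length(unmatched) + 1L]] <-
          data.frame(observed_mass = peaks$mass[j],
                     abundance = peaks$abundance[j])
      }
    }
    asn <- if (length(rows)) {
      a <- do.call(rbind, rows)
      a[order(-a$abundance), , drop = FALSE]
    } else {
      match_mass(0, library, tol_ppm = 0)[0, , drop = FALSE]
    }
    rownames(asn) <- NULL
    unm <- if (length(unmatched)) do.call(rbind, unmatched)
           else data.frame(observed_mass = numeric(), abundance = numeric())
    if (!nrow(asn))
      warning(sprintf("window %.2f-%.2f min: no assignable mass", w[1], w[2]))
    annotations[[i]] <- list(
      rt_window = w, rt_apex = windows$rt_apex[i],
      assignments = asn, unmatched = unm,
      subunit = if (nrow(asn)) asn$subunit[1L] else NA_character_)
    if (nrow(asn)) {
      asn$window <- i
      all_assign[[length(all_assign) + 1L]] <- asn
    }
  }
  structure(list(
    windows = windows,
    annotations = annotations,
    assignments = if (length(all_assign)) do.call(rbind, all_assign)
                  else NULL
  ), class = "run_annotation")
}

#' @export
print.run_annotation <- function(x, ...) {
  cat(sprintf("<run_annotation> %d windows\n", nrow(x$windows)))
  for (a in x$annotations) {
    top <- if (nrow(a$assignments))
      paste0(utils::head(a$assignments$display_name, 3), collapse = "; ")
      else "(unassigned)"
    cat(sprintf("  %.2f-%.2f min [%s]: %s\n", a$rt_window[1], a$rt_window[2],
                a$subunit, top))
  }
  invisible(x)
}

#' Most abundant assigned species of a subunit
#'
#' The assignment with maximal abundance among all windows of the run whose
#' species belong to the given subunit. Exact abundance ties are broken
#' toward the lower oxidation state, then lexically by display name.
#'
#' @param annotation a `run_annotation` from [assign_run()].
#' @param subunit `"LC"`, `"Fd'"` or `"Fc/2"`.
#' @return single-row data.frame (the winning assignment).
#' @export
most_abundant_species <- function(annotation, subunit) {
  a <- annotation$assignments
  a <- a[!is.null(a) & a$subunit == subunit, , drop = FALSE]
  if (is.null(a) || !nrow(a))
    stop(sprintf("no assigned species for subunit %s", subunit))
  a <- a[order(-a$abundance, a$n_ox, a$display_name), , drop = FALSE]
  a[1L, , drop = FALSE]
}

#' Relative abundance of an oxidized species
#'
#' `ar = I_nox / (I_0ox + I_nox)`, the fraction the n-fold oxidized form
#' contributes relative to the unoxidized form, computed from EIC peak
#' heights.
#'
#' @param i_0 EIC peak height of the unoxidized species.
#' @param i_n EIC peak height of the n-fold oxidized species.
#' @return `ar` in `[0, 1]`.
#' @export
relative_abundance <- function(i_0, i_n) {
  if (any(c(i_0, i_n) < 0)) stop("intensities must be non-negative")
  if (i_0 + i_n <= 0) stop("undefined: both intensities are zero")
  i_n / (i_0 + i_n)
}

# apex retention time and oxidation count of a subunit's main species.
# The smoothed-TIC apex of a cluster of partially separated oxidation
# states is biased toward the satellites, so the anchor is refined to the
# apex of the top species' own EIC inside the detected window; falls back
# to the acquisition base RT (apex n_ox 0) when no window was called.
.subunit_apex <- function(annotation, run, subunit) {
  if (!is.null(annotation)) {
    calls <- vapply(annotation$annotations, function(a)
      if (is.na(a$subunit)) "" else a$subunit, character(1))
    sel <- which(calls == subunit)
    if (length(sel)) {
      heights <- vapply(sel, function(i) {
        a <- annotation$annotations[[i]]
        if (nrow(a$assignments)) a$assignments$abundance[1L] else 0
      }, numeric(1))
      a <- annotation$annotations[[sel[which.max(heights)]]]
      top_mass <- a$assignments$avg_mass[1L]
      z <- apex_charge(top_mass)
      e <- extract_eic(run, (top_mass + z * .proton) / z,
                       rt_window = a$rt_window)
      inw <- e$rt >= a$rt_window[1] & e$rt <= a$rt_window[2]
      rt_apex <- e$rt[inw][which.max(e$intensity[inw])]
      return(list(rt = rt_apex, n_ox = a$assignments$n_ox[1L]))
    }
  }
  list(rt = run$acq$base_rt[[subunit]], n_ox = 0L)
}

# species-level retention window: the n-ox species elutes (n - n_apex)
# oxidation shifts away from the subunit's main peak; the tight pad keeps
# near-isobaric neighbours (one oxidation shift away) out of the window
.species_rt_window <- function(annotation, run, subunit, n, pad = 0.06) {
  apex <- .subunit_apex(annotation, run, subunit)
  centre <- apex$rt + (n - apex$n_ox) * run$acq$rt_shift_per_ox
  c(centre - pad, centre + pad)
}

#' EIC-based relative-abundance record of one run
#'
#' For each requested `(subunit, n)` pair, extracts EICs of the plain
#' unoxidized and n-fold oxidized proteoforms (no glycan or terminal
#' modifications) at the species' apex charge state, takes each EIC peak
#' height within the species' own retention window (anchored at the
#' subunit's detected apex and shifted per oxidation, so that
#' near-isobaric neighbours eluting one oxidation shift away do not
#' contribute), and computes [relative_abundance()]. When the run carries
#' ground truth, the same statistic computed from true fractions is
#' attached as `ar_truth`.
#'
#' @param run a `chromatographic_run`.
#' @param annotation a `run_annotation` for this run (used for retention
#'   windows); may be NULL to fall back to the acquisition base RTs.
#' @param library proteoform library of the run's mAb.
#' @param levels named integer vector: oxidation level per subunit, e.g.
#'   `c("LC" = 3, "Fd'" = 3)`.
#' @param tol EIC m/z tolerance in Th (default 0.01).
#' @return data.frame with one row per pair: run metadata, `subunit`,
#'   `ox_level`, `z`, `i_0ox`, `i_nox`, `ar`, `ar_truth`.
#' @export
ox_relative_abundance <- function(run, annotation, library, levels,
                                  tol = 0.01) {
  md <- run$metadata
  rows <- lapply(names(levels), function(su) {
    n <- levels[[su]]
    sel0 <- library$subunit == su & library$n_ox == 0L &
      library$glycan == "none" & !library$pyroglu & !library$cterm_lys
    seln <- library$subunit == su & library$n_ox == n &
      library$glycan == "none" & !library$pyroglu & !library$cterm_lys
    if (!any(sel0) || !any(seln))
      stop(sprintf("library lacks %s 0ox/%dox entries", su, n))
    m0 <- library$avg_mass[sel0][1]
    mn <- library$avg_mass[seln][1]
    z <- apex_charge(m0)
    w0 <- .species_rt_window(annotation, run, su, 0L)
    wn <- .species_rt_window(annotation, run, su, n)
    e0 <- extract_eic(run, (m0 + z * .proton) / z, tol = tol, rt_window = w0,
                      z = z)
    en <- extract_eic(run, (mn + z * .proton) / z, tol = tol, rt_window = wn,
                      z = z)
    ar_truth <- NA_real_
    if (!is.null(run$ground_truth)) {
      gt <- run$ground_truth
      f0 <- gt$fraction[gt$subunit == su & gt$n_ox == 0L &
                        gt$glycan == "none" & !gt$pyroglu & !gt$cterm_lys]
      fn <- gt$fraction[gt$subunit == su & gt$n_ox == n &
                        gt$glycan == "none" & !gt$pyroglu & !gt$cterm_lys]
      if (length(f0) && length(fn) && f0 + fn > 0)
        ar_truth <- fn / (f0 + fn)
    }
    data.frame(mab = md$mab, role = md$role, treatment = md$treatment,
               duration = md$duration, replicate = md$replicate,
               subunit = su, ox_level = n, z = z,
               i_0ox = e0$peak_height, i_nox = en$peak_height,
               ar = relative_abundance(e0$peak_height, en$peak_height),
               ar_truth = ar_truth, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Time-course table of relative abundances
#'
#' Arranges relative-abundance records into per-series tables (one series
#' per mab, role, subunit and oxidation level) with individual replicate
#' points, a mean/sd summary per duration, and a monotonicity diagnostic
#' (is the replicate-mean ar non-decreasing with duration).
#'
#' @param records data.frame from [ox_relative_abundance()] (row-bound over
#'   runs); at least two durations per series are expected.
#' @return list of class `time_course` with `points` (the input records),
#'   `summary` (mean/sd per duration) and `monotone` (per-series logical).
#' @export
time_course <- function(records) {
  if (length(unique(records$duration)) < 2L)
    warning("fewer than two durations present")
  key <- interaction(records$mab, records$role, records$treatment,
                     records$subunit, records$ox_level, drop = TRUE)
  summ <- do.call(rbind, lapply(split(records, key), function(d) {
    agg <- stats::aggregate(ar ~ duration, data = d,
                            FUN = function(x) c(mean = mean(x), sd = stats::sd(x),
                                                n = length(x)))
    data.frame(mab = d$mab[1], role = d$role[1], treatment = d$treatment[1],
               subunit = d$subunit[1], ox_level = d$ox_level[1],
               duration = agg$duration,
               ar_mean = agg$ar[, "mean"], ar_sd = agg$ar[, "sd"],
               n = agg$ar[, "n"], stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$mab, summ$role, summ$treatment, summ$subunit,
                     summ$duration), , drop = FALSE]
  mono <- do.call(rbind, lapply(split(summ, interaction(
    summ$mab, summ$role, summ$treatment, summ$subunit, summ$ox_level,
    drop = TRUE)), function(d) {
      d <- d[order(d$duration), , drop = FALSE]
      data.frame(mab = d$mab[1], role = d$role[1], treatment = d$treatment[1],
                 subunit = d$subunit[1], ox_level = d$ox_level[1],
                 monotone = all(diff(d$ar_mean) >= 0),
                 stringsAsFactors = FALSE)
    }))
  rownames(mono) <- NULL
  structure(list(points = records, summary = summ, monotone = mono),
            class = "time_course")
}

#' @export
print.time_course <- function(x, ...) {
  cat("<time_course>\n")
  print(x$summary, digits = 3)
  invisible(x)
}

# split a shared comparison label into the per-mAb local labels
.shared_local <- function(label) {
  if (grepl("/", label, fixed = TRUE)) {
    parts <- strsplit(label, "/", fixed = TRUE)[[1]]
    c(a = parts[1], b = paste0("M", parts[2]))
  } else c(a = label, b = label)
}

#' Attribute oxidation susceptibility to methionine sites
#'
#' Conservative set-difference reasoning over the most-abundant oxidation
#' counts of two antibodies with different methionine layouts. Per subunit:
#' if the most-abundant oxidation count equals the methionine count, all
#' sites are susceptible; if it is zero, all sites are resistant; otherwise
#' sites proven resistant (or susceptible) through the other antibody's
#' shared sites are subtracted, and the remainder is attributed only when
#' the counts force a unique solution — anything else is indeterminate.
#' Evidence strings record the reasoning; conflicting evidence yields
#' `indeterminate` with a conflict note.
#'
#' @param a,b [mab_definition()] objects.
#' @param n_ox_a,n_ox_b named integer vectors: most-abundant oxidation count
#'   per subunit (`LC`, `Fd'`, `Fc/2`) for each antibody, as produced by
#'   [most_abundant_species()].
#' @param equivalences see [compare_methionine_maps()].
#' @return data.frame with `mab`, `subunit`, `site_label`, `verdict`
#'   (`susceptible`/`resistant`/`indeterminate`) and `evidence`; every
#'   methionine site of both antibodies receives exactly one verdict.
#' @export
attribute_sites <- function(a, b, n_ox_a, n_ox_b, equivalences = list()) {
  cmp <- compare_methionine_maps(a, b, equivalences)
  subs <- list(a = ides_digest(a), b = ides_digest(b))
  n_ox <- list(a = n_ox_a, b = n_ox_b)
  mabs <- c(a = a$name, b = b$name)

  verdicts <- list()  # keyed "side|subunit|label"
  set_verdict <- function(side, kind, label, verdict, evidence) {
    key <- paste(side, kind, label, sep = "|")
    prev <- verdicts[[key]]
    if (!is.null(prev) && prev$verdict != verdict &&
        prev$verdict != "indeterminate") {
      verdicts[[key]] <<- list(
        verdict = "indeterminate",
        evidence = paste0("conflict: ", prev$evidence, " vs ", evidence))
    } else if (is.null(prev) || prev$verdict == "indeterminate") {
      verdicts[[key]] <<- list(verdict = verdict, evidence = evidence)
    }
  }

  # pass 1: saturated / null subunits resolve all their sites
  for (side in c("a", "b")) {
    for (kind in names(subs[[side]])) {
      labels <- subs[[side]][[kind]]$site_labels
      if (!length(labels)) next
      n <- n_ox[[side]][[kind]]
      if (n >= length(labels)) {
        for (l in labels)
          set_verdict(side, kind, l, "susceptible",
                      sprintf("%s %s most-abundant %dox covers all %d sites",
                              mabs[[side]], kind, n, length(labels)))
      } else if (n == 0L) {
        for (l in labels)
          set_verdict(side, kind, l, "resistant",
                      sprintf("%s %s most-abundant 0ox", mabs[[side]], kind))
      }
    }
  }

  # pass 2: partial subunits use the other antibody's shared-site verdicts
  for (side in c("a", "b")) {
    other <- if (side == "a") "b" else "a"
    for (kind in names(subs[[side]])) {
      labels <- subs[[side]][[kind]]$site_labels
      if (!length(labels)) next
      n <- n_ox[[side]][[kind]]
      if (n >= length(labels) || n == 0L) next
      known_res <- character(); known_sus <- character()
      evidence <- list()
      for (sh in cmp[[kind]]$shared) {
        loc <- .shared_local(sh)
        v <- verdicts[[paste(other, kind, loc[[other]], sep = "|")]]
        if (is.null(v)) next
        evidence[[loc[[side]]]] <- sprintf(
          "shared site: %s in %s %s %s", loc[[other]], mabs[[other]], kind,
          v$verdict)
        if (v$verdict == "resistant") known_res <- c(known_res, loc[[side]])
        else if (v$verdict == "susceptible")
          known_sus <- c(known_sus, loc[[side]])
      }
      if (length(known_sus) > n) {
        # the transferred evidence oxidizes more sites than observed
        for (l in labels)
          set_verdict(side, kind, l, "indeterminate",
                      sprintf("conflict: %s %s %dox but %d shared sites susceptible",
                              mabs[[side]], kind, n, length(known_sus)))
        next
      }
      for (l in known_res) set_verdict(side, kind, l, "resistant",
                                       evidence[[l]])
      for (l in known_sus) set_verdict(side, kind, l, "susceptible",
                                       evidence[[l]])
      rest <- setdiff(labels, c(known_res, known_sus))
      need <- n - length(known_sus)
      if (need == length(rest) && need >= 0) {
        for (l in rest)
          set_verdict(side, kind, l, "susceptible",
                      sprintf("%s %s %dox minus resistant shared sites leaves {%s}",
                              mabs[[side]], kind, n,
                              paste(rest, collapse = ",")))
      } else if (need == 0L) {
        for (l in rest)
          set_verdict(side, kind, l, "resistant",
                      sprintf("%s %s %dox fully explained by shared susceptible sites",
                              mabs[[side]], kind, n))
      } else {
        for (l in rest)
          set_verdict(side, kind, l, "indeterminate",
                      sprintf("%s %s %dox under-determined over {%s}",
                              mabs[[side]], kind, n,
                              paste(rest, collapse = ",")))
      }
    }
  }

  rows <- lapply(c("a", "b"), function(side) {
    do.call(rbind, lapply(names(subs[[side]]), function(kind) {
      labels <- subs[[side]][[kind]]$site_labels
      if (!length(labels)) return(NULL)
      do.call(rbind, lapply(labels, function(l) {
        v <- verdicts[[paste(side, kind, l, sep = "|")]]
        if (is.null(v)) v <- list(verdict = "indeterminate",
                                  evidence = "no applicable rule")
        data.frame(mab = mabs[[side]], subunit = kind, site_label = l,
                   verdict = v$verdict, evidence = v$evidence,
                   stringsAsFactors = FALSE)
      }))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Side-by-side biosimilarity report
#'
#' Collates reference-product and biosimilar outputs: assigned species
#' tables, a difference list (species observed in only one product above a
#' relative-abundance cutoff, and per-duration deltas of the relative
#' abundance statistic), the time course, and optional site attributions.
#' Regenerating from identical inputs gives an identical report.
#'
#' @param species_rp,species_bs data.frames of assigned species for each
#'   product (columns `display_name`, `subunit`, `abundance`, plus optional
#'   condition columns), e.g. the `assignments` element of [assign_run()].
#' @param records optional combined relative-abundance records (both roles)
#'   from [ox_relative_abundance()].
#' @param attributions optional output of [attribute_sites()].
#' @param min_rel relative-abundance cutoff (fraction of the subunit's
#'   summed assigned abundance) below which a species is ignored in the
#'   difference list.
#' @return list of class `biosimilarity_report` with `species`,
#'   `differences`, `ar_deltas`, `time_course`, `attributions`.
#' @export
biosimilarity_report <- function(species_rp, species_bs, records = NULL,
                                 attributions = NULL, min_rel = 0.005) {
  keep_rel <- function(df) {
    if (is.null(df) || !nrow(df)) return(character())
    tot <- tapply(df$abundance, df$subunit, sum)
    rel <- df$abundance / tot[df$subunit]
    unique(df$display_name[rel >= min_rel])
  }
  rp_names <- keep_rel(species_rp)
  bs_names <- keep_rel(species_bs)
  only_rp <- setdiff(rp_names, bs_names)
  only_bs <- setdiff(bs_names, rp_names)
  differences <- rbind(
    if (length(only_rp)) data.frame(display_name = sort(only_rp),
                                    only_in = "RP", stringsAsFactors = FALSE),
    if (length(only_bs)) data.frame(display_name = sort(only_bs),
                                    only_in = "BS", stringsAsFactors = FALSE))
  if (is.null(differences))
    differences <- data.frame(display_name = character(),
                              only_in = character())
  ar_deltas <- NULL
  tc <- NULL
  if (!is.null(records) && nrow(records)) {
    tc <- time_course(records)
    s <- tc$summary
    rp <- s[s$role == "RP", c("mab", "treatment", "subunit", "ox_level",
                              "duration", "ar_mean")]
    bs <- s[s$role == "BS", c("mab", "treatment", "subunit", "ox_level",
                              "duration", "ar_mean")]
    ar_deltas <- merge(rp, bs,
                       by = c("mab", "treatment", "subunit", "ox_level",
                              "duration"),
                       suffixes = c("_rp", "_bs"))
    ar_deltas$delta <- ar_deltas$ar_mean_bs - ar_deltas$ar_mean_rp
    ar_deltas <- ar_deltas[order(ar_deltas$mab, ar_deltas$subunit,
                                 ar_deltas$duration), , drop = FALSE]
    rownames(ar_deltas) <- NULL
  }
  structure(list(species = list(RP = species_rp, BS = species_bs),
                 differences = differences, ar_deltas = ar_deltas,
                 time_course = tc, attributions = attributions),
            class = "biosimilarity_report")
}

#' @export
print.biosimilarity_report <- function(x, ...) {
  cat("<biosimilarity_report>\n")
  if (nrow(x$differences)) {
    cat("species differences:\n")
    print(x$differences)
  } else cat("no species differences above the cutoff\n")
  if (!is.null(x$ar_deltas)) {
    cat("relative-abundance deltas (BS - RP):\n")
    print(x$ar_deltas[, c("mab", "subunit", "ox_level", "duration", "delta")],
          digits = 3)
  }
  if (!is.null(x$attributions)) {
    cat("site attributions:\n")
    print(x$attributions[, c("mab", "subunit", "site_label", "verdict")])
  }
  invisible(x)
}
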