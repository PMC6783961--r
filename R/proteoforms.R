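#' Modification state of a subunit proteoform
#'
#' @param glycan `"none"`, `"G0F"` or `"G1F"` (glycans only occur on Fc/2).
#' @param n_ox number of oxidation events (each +O).
#' @param pyroglu logical; N-terminal pyroglutamate (chain must start Q or E).
#' @param cterm_lys logical; retained C-terminal lysine (Fc/2 only).
#' @return an object of class `modification_state`.
#' @export
modification_state <- function(glycan = "none", n_ox = 0L, pyroglu = FALSE,
                               cterm_lys = FALSE) {
  stopifnot(glycan %in% c("none", "G0F", "G1F"), n_ox >= 0)
  structure(list(glycan = glycan, n_ox = as.integer(n_ox),
                 pyroglu = isTRUE(pyroglu), cterm_lys = isTRUE(cterm_lys)),
            class = "modification_state")
}

.display_name <- function(kind, glycan, n_ox, pyroglu, cterm_lys) {
  parts <- kind
  if (glycan != "none") parts <- c(parts, glycan)
  if (pyroglu) parts <- c(parts, "pG")
  if (n_ox > 0) parts <- c(parts, paste0(n_ox, "ox"))
  if (cterm_lys) parts <- c(parts, "+K")
  paste(parts, collapse = " ")
}

#' Enumerate the proteoform search library of a subunit
#'
#' Builds the full cross-product of valid modification states for one
#' subunit: glycoforms (Fc/2 only), N-terminal pyroglutamate (only when the
#' chain starts with Q or E), retained C-terminal lysine (Fc/2 only), and
#' 0..(n_met + unspecific_ox_cap) oxidations. The unspecific cap accommodates
#' oxidation states beyond the methionine count, which forced-oxidation runs
#' do produce on other residues.
#'
#' @param subunit a `subunit_chain` (from [ides_digest()]).
#' @param glycans allowed glycans for this subunit (ignored unless Fc/2).
#' @param allow_pyroglu consider the pyroglutamate form (auto-disabled when
#'   the N-terminal residue is neither Q nor E).
#' @param allow_cterm_lys consider the retained-lysine form (Fc/2 only).
#' @param unspecific_ox_cap maximum oxidations beyond the methionine count
#'   (default 4).
#' @return data.frame with one row per proteoform: `subunit`, `glycan`,
#'   `n_ox`, `pyroglu`, `cterm_lys`, `avg_mass`, `mono_mass`, `display_name`,
#'   in deterministic order (glycan, n_ox, flags).
#' @examples
#' mab <- synthetic_mab("bevacizumab_synthetic")
#' lib <- enumerate_proteoforms(ides_digest(mab)[["Fc/2"]])
#' head(lib[, c("display_name", "avg_mass")])
#' @export
enumerate_proteoforms <- function(subunit,
                                  glycans = c("none", "G0F", "G1F"),
                                  allow_pyroglu = TRUE,
                                  allow_cterm_lys = TRUE,
                                  unspecific_ox_cap = 4L) {
  stopifnot(inherits(subunit, "subunit_chain"))
  kind <- subunit$kind
  nterm <- substr(subunit$sequence, 1, 1)
  n_met <- length(subunit$methionine_positions)
  g <- if (kind == "Fc/2") glycans else "none"
  pg <- if (allow_pyroglu && nterm %in% c("Q", "E")) c(FALSE, TRUE) else FALSE
  kk <- if (allow_cterm_lys && kind == "Fc/2") c(FALSE, TRUE) else FALSE
  ox <- 0:(n_met + unspecific_ox_cap)
  grid <- expand.grid(cterm_lys = kk, pyroglu = pg, n_ox = ox, glycan = g,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$glycan, c("none", "G0F", "G1F")), grid$n_ox,
                     grid$pyroglu, grid$cterm_lys), ]
  base_avg <- average_mass(subunit$sequence)
  base_mono <- monoisotopic_mass(subunit$sequence)
  deltas <- function(kind_) {
    vapply(seq_len(nrow(grid)), function(i) {
      .mods_delta(list(glycan = grid$glycan[i], n_ox = grid$n_ox[i],
                       pyroglu = grid$pyroglu[i], cterm_lys = grid$cterm_lys[i]),
                  nterm = nterm, kind = kind_)
    }, numeric(1))
  }
  out <- data.frame(subunit = kind, glycan = grid$glycan, n_ox = grid$n_ox,
                    pyroglu = grid$pyroglu, cterm_lys = grid$cterm_lys,
                    avg_mass = base_avg + deltas("average"),
                    mono_mass = base_mono + deltas("monoisotopic"),
                    stringsAsFactors = FALSE)
  out$display_name <- mapply(.display_name, kind, out$glycan, out$n_ox,
                             out$pyroglu, out$cterm_lys, USE.NAMES = FALSE)
  rownames(out) <- NULL
  out
}

#' Star notation for the absolute mass error of an assignment
#'
#' Matches the annotation convention used on middle-up chromatogram figures:
#' `|delta|` of 0–0.5 Da earns `*`, 0.5–1.5 Da `**`, 1.5–4.0 Da `***`, and
#' anything above 4 Da is flagged for rejection.
#'
#' @param delta_da signed mass error (observed − theoretical) in Da.
#' @return character vector over `"*", "**", "***", "reject"`.
#' @export
annotate_mass_error <- function(delta_da) {
  a <- abs(delta_da)
  out <- character(length(a))
  out[a <= 0.5] <- "*"
  out[a > 0.5 & a <= 1.5] <- "**"
  out[a > 1.5 & a <= 4.0] <- "***"
  out[a > 4.0] <- "reject"
  out
}

#' Match an observed deconvoluted mass against a proteoform library
#'
#' Returns every library entry whose theoretical average mass lies within the
#' ppm tolerance of the observed mass, sorted by increasing `|delta_ppm|`
#' (the top row is the annotation); an empty data.frame if none match.
#'
#' @param observed observed zero-charge mass in Da.
#' @param library proteoform library from [enumerate_proteoforms()] (or
#'   several libraries row-bound together).
#' @param tol_ppm match tolerance in ppm (default 70).
#' @param abundance intensity to attach to the resulting assignments.
#' @return data.frame of assignments: library columns plus `observed_mass`,
#'   `delta_da`, `delta_ppm`, `stars`, `abundance`.
#' @export
match_mass <- function(observed, library, tol_ppm = 70, abundance = NA_real_) {
  stopifnot(nrow(library) > 0)
  delta <- observed - library$avg_mass
  ppm <- delta / library$avg_mass * 1e6
  keep <- which(abs(ppm) <= tol_ppm)
  out <- library[keep, , drop = FALSE]
  out$observed_mass <- rep(observed, length(keep))
  out$delta_da <- delta[keep]
  out$delta_ppm <- ppm[keep]
  out$stars <- annotate_mass_error(out$delta_da)
  out$abundance <- rep(abundance, length(keep))
  out <- out[order(abs(out$delta_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
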