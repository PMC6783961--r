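#' Per-site oxidation kinetics
#'
#' The synthetic-data generator treats forced oxidation as independent
#' pseudo-first-order reactions: methionine site i is oxidized by time t with
#' probability `p_i = 1 - exp(-k_i * t)`. The number of site oxidations on a
#' subunit is then Poisson-binomial over its sites, and an independent
#' "unspecific" count (other residues, e.g. tryptophan, under harsh H2O2)
#' with mean `k_u * t`, truncated at the unspecific cap and renormalized, is
#' convolved on top. Control treatment sets every effective rate to zero.
#'
#' @name oxidation-kinetics
NULL

#' Poisson-binomial distribution
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with individual probabilities `p`, computed by direct convolution.
#'
#' @param p vector of per-trial success probabilities.
#' @return numeric vector of probabilities for counts `0..length(p)`.
#' @keywords internal
.poisson_binomial <- function(p) {
  d <- 1
  for (pi in p) d <- c(d * (1 - pi), 0) + c(0, d * pi)
  d
}

.truncated_poisson <- function(mean, cap) {
  d <- stats::dpois(0:cap, mean)
  d / sum(d)
}

#' Oxidation-state distribution of a subunit
#'
#' @param rate_constants per-site rate constants in 1/h (one per methionine
#'   site of the subunit; may be empty).
#' @param t duration in hours (non-negative).
#' @param treatment `"oxi"` or `"con"`; control forces all effective rates to
#'   zero, so the distribution collapses to the unoxidized state.
#' @param k_u unspecific oxidation rate in 1/h per chain (default 0.01).
#' @param unspecific_ox_cap cap on unspecific oxidations (default 4).
#' @return named numeric vector `P(n_ox = 0..n_met+cap)`, summing to 1.
#' @examples
#' oxidation_state_distribution(c(0.15, 0.15, 0.15), t = 48)
#' @export
oxidation_state_distribution <- function(rate_constants, t,
                                         treatment = c("oxi", "con"),
                                         k_u = 0.01, unspecific_ox_cap = 4L) {
  treatment <- match.arg(treatment)
  if (t < 0) stop("duration t must be non-negative")
  if (any(rate_constants < 0) || k_u < 0) stop("rates must be non-negative")
  if (treatment == "con") {
    rate_constants <- rep(0, length(rate_constants))
    k_u <- 0
  }
  p <- 1 - exp(-rate_constants * t)
  d_sites <- .poisson_binomial(p)
  d_uns <- .truncated_poisson(k_u * t, unspecific_ox_cap)
  d <- numeric(length(d_sites) + length(d_uns) - 1L)
  for (i in seq_along(d_sites)) {
    idx <- i:(i + length(d_uns) - 1L)
    d[idx] <- d[idx] + d_sites[i] * d_uns
  }
  d <- d / sum(d)
  names(d) <- as.character(seq_along(d) - 1L)
  d
}

#' Default forced-oxidation kinetic scenario for an RP/BS mAb pair
#'
#' Encodes the qualitative endpoint behaviour this workflow is designed to
#' detect: all Fc/2 methionines plus the infliximab-like LC M55 and Fd' M18
#' are fast-oxidizing surface-exposed sites, everything else is slow and
#' buried; the biosimilar's slow-class rate is a configurable multiple of the
#' reference product's, emulating a biosimilar that converts faster under
#' stress.
#'
#' @param mab a [mab_definition()] (typically from [synthetic_mab()]).
#' @param fast_k fast-class rate constant, 1/h (default 0.15; >= 97%
#'   site conversion at 24 h).
#' @param slow_k slow-class rate constant for the RP, 1/h (default 0.002,
#'   slow enough that a two-methionine subunit plus the unspecific channel
#'   keeps its unoxidized form most abundant through 48 h for both roles).
#' @param bs_slow_multiplier multiplier applied to `slow_k` when
#'   `mab$product_role == "BS"` (default 2).
#' @param fast_sites character vector of site labels forced to the fast
#'   class in addition to all Fc/2 sites; default covers the infliximab-like
#'   LC M55 and Fd' M18.
#' @param k_u unspecific rate, 1/h per chain (default 0.01).
#' @return list with `sites` (data.frame: subunit, site_label, position,
#'   exposure_class, rate_constant) and `k_u`.
#' @export
default_scenario <- function(mab, fast_k = 0.15, slow_k = 0.002,
                             bs_slow_multiplier = 2,
                             fast_sites = c("M55", "M18"),
                             k_u = 0.01) {
  subunits <- ides_digest(mab)
  slow <- slow_k * if (mab$product_role == "BS") bs_slow_multiplier else 1
  rows <- lapply(subunits, function(s) {
    if (!length(s$site_labels)) return(NULL)
    fast <- s$kind == "Fc/2" | s$site_labels %in% fast_sites
    data.frame(subunit = s$kind, site_label = s$site_labels,
               position = s$methionine_positions,
               exposure_class = ifelse(fast, "fast", "slow"),
               rate_constant = ifelse(fast, fast_k, slow),
               stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites))
    sites <- data.frame(subunit = character(), site_label = character(),
                        position = integer(), exposure_class = character(),
                        rate_constant = numeric())
  rownames(sites) <- NULL
  list(sites = sites, k_u = k_u)
}

#' Ground-truth proteoform fractions of one run condition
#'
#' Combines the subunit oxidation-state distribution under the kinetic model
#' with the mAb's glycoform split, C-terminal lysine retention and
#' pyroglutamate fraction (all modelled as independent) into per-proteoform
#' fractional abundances over the library of [enumerate_proteoforms()].
#'
#' @param mab a [mab_definition()].
#' @param kinetics a scenario from [default_scenario()].
#' @param treatment `"oxi"` or `"con"`.
#' @param duration hours.
#' @param unspecific_ox_cap see [enumerate_proteoforms()].
#' @return list with `library` (row-bound proteoform libraries of the three
#'   subunits with a `fraction` column; fractions sum to 1 per subunit) and
#'   `subunits` (the digested chains).
#' @export
ground_truth_fractions <- function(mab, kinetics,
                                   treatment = c("oxi", "con"), duration,
                                   unspecific_ox_cap = 4L) {
  treatment <- match.arg(treatment)
  subunits <- ides_digest(mab)
  libs <- lapply(subunits, function(s) {
    lib <- enumerate_proteoforms(s, unspecific_ox_cap = unspecific_ox_cap)
    ks <- kinetics$sites$rate_constant[kinetics$sites$subunit == s$kind]
    dox <- oxidation_state_distribution(ks, t = duration,
                                        treatment = treatment,
                                        k_u = kinetics$k_u,
                                        unspecific_ox_cap = unspecific_ox_cap)
    f_g <- c(none = 1)
    if (s$kind == "Fc/2") f_g <- mab$glycan_fractions
    f_k <- c("FALSE" = 1)
    if (s$kind == "Fc/2")
      f_k <- c("FALSE" = 1 - mab$cterm_lys_fraction,
               "TRUE" = mab$cterm_lys_fraction)
    f_p <- c("FALSE" = 1)
    if (any(lib$pyroglu))
      f_p <- c("FALSE" = 1 - mab$pyroglu_fraction,
               "TRUE" = mab$pyroglu_fraction)
    lib$fraction <- unname(
      f_g[lib$glycan] *
      f_k[as.character(lib$cterm_lys)] *
      f_p[as.character(lib$pyroglu)] *
      dox[as.character(lib$n_ox)])
    lib$fraction[is.na(lib$fraction)] <- 0
    lib$fraction <- lib$fraction / sum(lib$fraction)
    lib
  })
  list(library = do.call(rbind, c(libs, list(make.row.names = FALSE))),
       subunits = subunits)
}
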