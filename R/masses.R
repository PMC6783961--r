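#' @title Atomic and residue mass tables
#' @description Frozen IUPAC 2021 standard atomic weights and CODATA-style
#'   monoisotopic masses for the five elements occurring in proteins and
#'   N-glycans, plus elemental compositions of the 20 canonical amino-acid
#'   residues and of the monosaccharide residues used for Fc glycans.
#'   Keeping the tables in the package makes every theoretical mass
#'   bit-reproducible.
#' @name mass-tables
#' @keywords internal
NULL

# element rows: average weight, monoisotopic mass
.elements <- data.frame(
  row.names = c("C", "H", "N", "O", "S"),
  average = c(12.011, 1.008, 14.007, 15.999, 32.06),
  mono    = c(12.000000000, 1.007825032, 14.003074005, 15.994914620, 31.972071174)
)

# canonical residue (dehydrated) compositions, columns C,H,N,O,S
.aa_composition <- matrix(c(
  3,  5, 1, 1, 0,  # A
  6, 12, 4, 1, 0,  # R
  4,  6, 2, 2, 0,  # N
  4,  5, 1, 3, 0,  # D
  3,  5, 1, 1, 1,  # C
  5,  8, 2, 2, 0,  # Q
  5,  7, 1, 3, 0,  # E
  2,  3, 1, 1, 0,  # G
  6,  7, 3, 1, 0,  # H
  6, 11, 1, 1, 0,  # I
  6, 11, 1, 1, 0,  # L
  6, 12, 2, 1, 0,  # K
  5,  9, 1, 1, 1,  # M
  9,  9, 1, 1, 0,  # F
  5,  7, 1, 1, 0,  # P
  3,  5, 1, 2, 0,  # S
  4,  7, 1, 2, 0,  # T
 11, 10, 2, 1, 0,  # W
  9,  9, 1, 2, 0,  # Y
  5,  9, 1, 1, 0   # V
), ncol = 5, byrow = TRUE,
  dimnames = list(c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                    "F","P","S","T","W","Y","V"), c("C","H","N","O","S")))

# monosaccharide residue (anhydro) compositions
.glycan_units <- matrix(c(
  6, 10, 0, 5, 0,   # Hex
  8, 13, 1, 5, 0,   # HexNAc
  6, 10, 0, 4, 0    # Fuc (deoxyhexose)
), ncol = 5, byrow = TRUE,
  dimnames = list(c("Hex", "HexNAc", "Fuc"), c("C","H","N","O","S")))

# glycan compositions (residue counts); G1F = G0F + one galactose
.glycan_compositions <- list(
  G0F = c(HexNAc = 4, Hex = 3, Fuc = 1),
  G1F = c(HexNAc = 4, Hex = 4, Fuc = 1)
)

.canonical_aa <- rownames(.aa_composition)

#' Mass of an elemental composition
#'
#' @param counts named numeric vector of atom counts (names among C,H,N,O,S).
#' @param kind `"average"` or `"monoisotopic"`.
#' @return mass in Da.
#' @keywords internal
.formula_mass <- function(counts, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  w <- if (kind == "average") .elements$average else .elements$mono
  names(w) <- rownames(.elements)
  sum(w[names(counts)] * counts)
}

.water_mass <- function(kind = "average") .formula_mass(c(H = 2, O = 1), kind)
.ammonia_mass <- function(kind = "average") .formula_mass(c(N = 1, H = 3), kind)
.oxygen_mass <- function(kind = "average") .formula_mass(c(O = 1), kind)

# proton mass used to strip charges from m/z (constant per package contract)
.proton <- 1.00728

.residue_masses <- function(kind = "average") {
  w <- if (kind == "average") .elements$average else .elements$mono
  drop(.aa_composition %*% w)
}

.check_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence))
    stop("sequence must be a single character string")
  res <- strsplit(sequence, "")[[1]]
  bad <- which(!res %in% .canonical_aa)
  if (length(bad))
    stop(sprintf("non-canonical residue '%s' at position %d", res[bad[1]], bad[1]))
  res
}

#' Mass delta of a single modification
#'
#' Oxidation adds one oxygen atom; N-terminal pyroglutamate formation loses
#' ammonia from Gln or water from Glu; an unclipped C-terminal lysine adds one
#' lysine residue; glycans are summed from their monosaccharide residue
#' compositions (G0F = HexNAc4 Hex3 Fuc1, G1F = G0F + Hex).
#'
#' @param mod one of `"ox"`, `"pyroglu"`, `"cterm_lys"`, `"G0F"`, `"G1F"`.
#' @param nterm N-terminal residue, required for `"pyroglu"` (must be Q or E).
#' @param kind `"average"` (default) or `"monoisotopic"`.
#' @return signed mass delta in Da.
#' @examples
#' modification_delta("ox")                  # +15.999
#' modification_delta("pyroglu", nterm = "Q")
#' modification_delta("G1F") - modification_delta("G0F")  # one anhydro-hexose
#' @export
modification_delta <- function(mod, nterm = NULL,
                               kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  switch(mod,
    ox = .oxygen_mass(kind),
    pyroglu = {
      if (is.null(nterm) || !nterm %in% c("Q", "E"))
        stop("pyroglutamate requires an N-terminal Q or E residue")
      if (nterm == "Q") -.ammonia_mass(kind) else -.water_mass(kind)
    },
    cterm_lys = unname(.residue_masses(kind)["K"]),
    G0F = ,
    G1F = {
      comp <- .glycan_compositions[[mod]]
      w <- if (kind == "average") .elements$average else .elements$mono
      sum(drop(.glycan_units %*% w)[names(comp)] * comp)
    },
    stop("unknown modification kind: ", mod)
  )
}

.mods_delta <- function(mods, nterm, kind) {
  d <- 0
  if (!is.null(mods$glycan) && mods$glycan != "none")
    d <- d + modification_delta(mods$glycan, kind = kind)
  if (isTRUE(mods$pyroglu))
    d <- d + modification_delta("pyroglu", nterm = nterm, kind = kind)
  if (isTRUE(mods$cterm_lys))
    d <- d + modification_delta("cterm_lys", kind = kind)
  n_ox <- if (is.null(mods$n_ox)) 0L else mods$n_ox
  d + n_ox * modification_delta("ox", kind = kind)
}

#' Average (or monoisotopic) mass of a modified subunit chain
#'
#' Sums residue masses plus one water for the peptide termini, plus the mass
#' deltas of the requested modification state. At subunit size (23–26 kDa) the
#' deconvolved quantity is the isotope-averaged mass, so `"average"` is the
#' matching currency throughout the package; the monoisotopic variant is kept
#' for verification.
#'
#' @param sequence amino-acid sequence (1-letter codes, canonical alphabet).
#' @param mods a [modification_state()] or NULL for the unmodified chain.
#' @param kind `"average"` (default) or `"monoisotopic"`.
#' @return mass in Da.
#' @examples
#' average_mass("GG")   # 132.119 Da
#' average_mass("DIQMK", modification_state(n_ox = 1)) - average_mass("DIQMK")
#' @export
average_mass <- function(sequence, mods = NULL,
                         kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  res <- if (nzchar(sequence)) .check_sequence(sequence) else character()
  rm <- .residue_masses(kind)
  m <- sum(rm[res]) + .water_mass(kind)
  if (!is.null(mods))
    m <- m + .mods_delta(mods, nterm = if (length(res)) res[1] else NULL, kind)
  m
}

#' @rdname average_mass
#' @export
monoisotopic_mass <- function(sequence, mods = NULL) {
  average_mass(sequence, mods, kind = "monoisotopic")
}
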