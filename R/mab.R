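#' Define an IgG1 monoclonal antibody
#'
#' Bundles the heavy- and light-chain sequences of an IgG1 mAb with the
#' metadata the middle-up workflow needs: the product role (reference product
#' or biosimilar), the fraction of heavy chains that retain the C-terminal
#' lysine (lysine clipping is often incomplete in manufacturing), per-subunit
#' label offsets that translate subunit-local methionine indices into the
#' community numbering printed on methionine maps (EU numbering for Fc/2), and
#' the Fc glycoform split.
#'
#' @param name product name.
#' @param heavy_chain,light_chain amino-acid sequences (1-letter codes).
#' @param product_role `"RP"` (reference product) or `"BS"` (biosimilar).
#' @param cterm_lys_fraction fraction in `[0,1]` of heavy chains retaining the
#'   C-terminal K.
#' @param label_offsets named numeric vector with entries `LC`, `Fd'`, `Fc/2`;
#'   a site at subunit-local position `i` is labelled `M(i + offset)`.
#' @param pyroglu_fraction fraction of Fd' chains with N-terminal
#'   pyroglutamate (requires N-terminal Q or E on the heavy chain).
#' @param glycan_fractions named fractions over `G0F`, `G1F`, `none` for the
#'   Fc/2 glycoform split; must sum to 1.
#' @return an object of class `mab_definition`.
#' @seealso [load_mab_fasta()], [ides_digest()], [synthetic_mab()]
#' @export
mab_definition <- function(name, heavy_chain, light_chain,
                           product_role = c("RP", "BS"),
                           cterm_lys_fraction = 0,
                           label_offsets = c("LC" = 0, "Fd'" = 0, "Fc/2" = 0),
                           pyroglu_fraction = 0.05,
                           glycan_fractions = c(G0F = 0.58, G1F = 0.38, none = 0.04)) {
  product_role <- match.arg(product_role)
  .check_sequence(heavy_chain)
  .check_sequence(light_chain)
  if (!is.numeric(cterm_lys_fraction) || cterm_lys_fraction < 0 ||
      cterm_lys_fraction > 1)
    stop("cterm_lys_fraction must lie in [0, 1]")
  if (.count_motif(heavy_chain) != 1L)
    stop("heavy chain must contain exactly one IdeS lower-hinge motif (LLGG)")
  stopifnot(all(c("LC", "Fd'", "Fc/2") %in% names(label_offsets)))
  if (abs(sum(glycan_fractions) - 1) > 1e-9)
    stop("glycan_fractions must sum to 1")
  structure(list(
    name = name,
    heavy_chain = heavy_chain,
    light_chain = light_chain,
    product_role = product_role,
    cterm_lys_fraction = cterm_lys_fraction,
    label_offsets = label_offsets,
    pyroglu_fraction = pyroglu_fraction,
    glycan_fractions = glycan_fractions
  ), class = "mab_definition")
}

#' @export
print.mab_definition <- function(x, ...) {
  cat(sprintf("<mab_definition> %s [%s]\n", x$name, x$product_role))
  cat(sprintf("  HC %d aa, LC %d aa, C-term K fraction %.2f\n",
              nchar(x$heavy_chain), nchar(x$light_chain),
              x$cterm_lys_fraction))
  invisible(x)
}

.ides_motif <- "LLGG"

.count_motif <- function(hc) {
  hits <- gregexpr(.ides_motif, hc, fixed = TRUE)[[1]]
  sum(hits > 0)
}

#' Load a mAb from a two-record FASTA file
#'
#' The file must contain exactly two records whose headers carry an `HC` or
#' `LC` token identifying heavy and light chain.
#'
#' @param path FASTA file.
#' @param role `"RP"` or `"BS"`.
#' @param ... further arguments passed to [mab_definition()] (label offsets,
#'   lysine/pyroglutamate/glycan fractions).
#' @param name product name; defaults to the file stem.
#' @return a [mab_definition()].
#' @export
load_mab_fasta <- function(path, role = c("RP", "BS"), ...,
                           name = sub("\\.[^.]*$", "", basename(path))) {
  role <- match.arg(role)
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) != 2L)
    stop(sprintf("expected exactly 2 FASTA records (HC, LC), found %d",
                 length(seqs)))
  toks <- strsplit(names(seqs), "[ _|]")
  is_hc <- vapply(toks, function(t) "HC" %in% t, logical(1))
  is_lc <- vapply(toks, function(t) "LC" %in% t, logical(1))
  if (sum(is_hc) != 1L || sum(is_lc) != 1L)
    stop("FASTA headers must identify one HC and one LC record")
  mab_definition(name = name,
                 heavy_chain = as.character(seqs[[which(is_hc)]]),
                 light_chain = as.character(seqs[[which(is_lc)]]),
                 product_role = role, ...)
}

#' In-silico IdeS digestion and reduction
#'
#' IdeS cleaves IgG1 below the hinge, between the paired glycines of the
#' lower-hinge motif (...CPAPELLG / GPSV...); with full disulfide reduction
#' this liberates three subunits per antibody: the light chain (LC), the
#' heavy-chain N-terminal fragment (Fd'), and half of the constant fragment
#' (Fc/2), each present in two copies. The cut is implemented as "between the
#' two G of the unique LLGG occurrence"; disulfides are not tracked because
#' the downstream analysis works on fully reduced chains.
#'
#' @param mab a [mab_definition()].
#' @return named list of three `subunit_chain` objects (`LC`, `Fd'`, `Fc/2`),
#'   each with its methionine site map populated from the mAb's label offsets.
#' @examples
#' mab <- synthetic_mab("bevacizumab_synthetic")
#' names(ides_digest(mab))
#' @export
ides_digest <- function(mab) {
  stopifnot(inherits(mab, "mab_definition"))
  hc <- mab$heavy_chain
  hits <- gregexpr(.ides_motif, hc, fixed = TRUE)[[1]]
  hits <- hits[hits > 0]
  if (length(hits) != 1L)
    stop(sprintf("IdeS digestion requires exactly one %s motif, found %d",
                 .ides_motif, length(hits)))
  cut <- hits + 2L  # index of the first motif G; cleave between G|G
  fd <- substr(hc, 1L, cut)
  fc2 <- substr(hc, cut + 1L, nchar(hc))
  subunits <- list(
    "LC"   = .subunit_chain("LC", mab$light_chain),
    "Fd'"  = .subunit_chain("Fd'", fd),
    "Fc/2" = .subunit_chain("Fc/2", fc2)
  )
  lapply(subunits, function(s)
    map_methionines(s, label_offset = mab$label_offsets[[s$kind]]))
}

.subunit_chain <- function(kind, sequence) {
  structure(list(kind = kind, sequence = sequence, copies_per_mab = 2L,
                 methionine_positions = integer(), site_labels = character()),
            class = "subunit_chain")
}

#' @export
print.subunit_chain <- function(x, ...) {
  cat(sprintf("<subunit_chain> %s, %d aa, Met sites: %s\n", x$kind,
              nchar(x$sequence),
              if (length(x$site_labels)) paste(x$site_labels, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Map methionine positions of a subunit
#'
#' Locates every `M` in the subunit sequence and labels it in the community
#' numbering via an additive offset (label = local position + offset). For
#' Fc/2 the offset realises EU numbering without requiring a full-antibody
#' alignment.
#'
#' @param subunit a `subunit_chain`.
#' @param label_offset integer offset added to subunit-local positions.
#' @return the subunit with `methionine_positions` and `site_labels` filled.
#' @export
map_methionines <- function(subunit, label_offset = 0) {
  stopifnot(inherits(subunit, "subunit_chain"))
  pos <- gregexpr("M", subunit$sequence, fixed = TRUE)[[1]]
  pos <- as.integer(pos[pos > 0])
  subunit$methionine_positions <- pos
  subunit$site_labels <- if (length(pos)) paste0("M", pos + label_offset)
                         else character()
  subunit
}

#' Compare methionine maps of two mAbs
#'
#' For each subunit kind, partitions the union of site labels into shared
#' sites, sites unique to the first mAb and sites unique to the second.
#' Homologous positions that carry different labels in the two products
#' (e.g. M83 in one heavy chain corresponding to M85 in the other) can be
#' declared equivalent; such pairs are reported as shared under a combined
#' label ("M83/85").
#'
#' @param a,b [mab_definition()] objects.
#' @param equivalences list of per-subunit equivalences, each a character
#'   vector `c(a = "M83", b = "M85")`, named by subunit kind, e.g.
#'   `list("Fd'" = list(c(a = "M83", b = "M85")))`.
#' @return named list (per subunit kind) of lists with elements `shared`,
#'   `unique_a`, `unique_b`.
#' @export
compare_methionine_maps <- function(a, b, equivalences = list()) {
  sa <- ides_digest(a)
  sb <- ides_digest(b)
  out <- lapply(names(sa), function(kind) {
    la <- sa[[kind]]$site_labels
    lb <- sb[[kind]]$site_labels
    shared <- intersect(la, lb)
    ua <- setdiff(la, lb)
    ub <- setdiff(lb, la)
    for (eq in equivalences[[kind]]) {
      if (eq[["a"]] %in% ua && eq[["b"]] %in% ub) {
        shared <- c(shared, paste0(eq[["a"]], "/", sub("^M", "", eq[["b"]])))
        ua <- setdiff(ua, eq[["a"]])
        ub <- setdiff(ub, eq[["b"]])
      }
    }
    list(shared = shared, unique_a = ua, unique_b = ub)
  })
  names(out) <- names(sa)
  out
}

#' Built-in synthetic mAb pair
#'
#' Returns one of the two synthetic IgG1-like antibodies shipped with the
#' package. The sequences are constructed, not the marketed products'
#' (which are not part of the package); they reproduce the methionine layout
#' used in cross-mAb comparisons of bevacizumab and infliximab: the
#' bevacizumab-like product carries LC M4, Fd' M34/M83 and Fc/2
#' M252/M358/M428 (EU numbering), the infliximab-like product LC M55,
#' Fd' M18/M34/M85 and Fc/2 M255/M431.
#'
#' @param which `"bevacizumab_synthetic"` or `"infliximab_synthetic"`.
#' @param role `"RP"` or `"BS"`.
#' @return a [mab_definition()] with product-appropriate defaults
#'   (C-terminal lysine clipping is complete for the bevacizumab-like pair;
#'   for the infliximab-like product the RP retains 30% C-terminal lysine
#'   and the BS 2%).
#' @export
synthetic_mab <- function(which = c("bevacizumab_synthetic",
                                    "infliximab_synthetic"),
                          role = c("RP", "BS")) {
  which <- match.arg(which)
  role <- match.arg(role)
  path <- system.file("extdata", paste0(which, ".fasta"), package = "forceox",
                      mustWork = TRUE)
  if (which == "bevacizumab_synthetic") {
    load_mab_fasta(path, role = role, name = which,
                   cterm_lys_fraction = 0,
                   label_offsets = c("LC" = 0, "Fd'" = 0, "Fc/2" = 236))
  } else {
    load_mab_fasta(path, role = role, name = which,
                   cterm_lys_fraction = if (role == "RP") 0.30 else 0.02,
                   label_offsets = c("LC" = 0, "Fd'" = 0, "Fc/2" = 239))
  }
}

#' Homologous-site equivalences for the synthetic pair
#'
#' The two synthetic products share the heavy-chain methionine at the
#' homologous Fd' position labelled M83 in the bevacizumab-like and M85 in
#' the infliximab-like sequence.
#' @return equivalence list usable with [compare_methionine_maps()] (first
#'   mAb = bevacizumab-like, second = infliximab-like).
#' @export
synthetic_equivalences <- function() {
  list("Fd'" = list(c(a = "M83", b = "M85")))
}
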