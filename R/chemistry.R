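# Muropeptide structure grammar and monoisotopic mass model.
#
# Muropeptides are written in gm-notation: each disaccharide subunit is
# "gm-<stem>" (g = GlcNAc, m = MurNAc), cross-linked subunits are joined with
# "=", and whole-molecule modifications are appended as " (Anh)"
# (1,6-anhydroMurNAc) and/or " (-Ac)" (sugar deacetylation). Stems are
# sequences of single-letter amino-acid codes plus the multi-character tokens
# "J_NH2" (amidated meso-DAP, alias "Z"). Example: "gm-AEJ_NH2=gm-A (Anh)".

#' Monoisotopic mass constants (Da)
#'
#' Fixed constants used by the mass calculator: water, proton, the
#' modification deltas (amidation, deacetylation, MurNAc reduction) and the
#' sodium / potassium adduct deltas used by satellite cleanup.
#'
#' @format Named numeric vector of masses / mass deltas in Da.
#' @export
mass_constants <- c(
  water            = 18.010565,
  proton           = 1.007276,
  amidation        = -0.984016,
  deacetylation    = -42.010565,
  reduction        = 2.015650,
  adduct_Na        = 21.981944,
  adduct_K         = 37.955882
)

# Residue (dehydrated) monoisotopic masses. J is meso-diaminopimelic acid
# (meso-DAP), the canonical cross-link acceptor at stem position 3; J_NH2 is
# its amidated form (side-chain carboxyl -> amide, -0.984016 Da).
.residue_masses <- c(
  G = 57.02146,  A = 71.03711,  S = 87.03203,  P = 97.05276,
  V = 99.06841,  T = 101.04768, C = 103.00919, I = 113.08406,
  L = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931,
  J = 172.08479
)
.residue_masses <- c(.residue_masses, J_NH2 = unname(.residue_masses["J"] + mass_constants["amidation"]))

.glycan_masses <- c(GlcNAc = 203.07937, MurNAc = 275.10049)

#' Amino-acid residue table
#'
#' Residue (dehydrated) monoisotopic masses for the stem alphabet: the 20
#' standard amino acids plus `J` (meso-diaminopimelic acid) and `J_NH2`
#' (amidated meso-DAP; `Z` is accepted as an input alias).
#'
#' @return A tibble with columns `code`, `mass`.
#' @export
residue_table <- function() {
  tibble::tibble(code = names(.residue_masses), mass = unname(.residue_masses))
}

#' Default amino-acid alphabet for wildcard (X) stem positions
#'
#' The 20 standard amino acids minus leucine: Leu and Ile are mass-identical,
#' so an MS1 search space keeps a single representative.
#'
#' @return Character vector of 19 residue codes.
#' @export
default_x_alphabet <- function() {
  setdiff(c("G", "A", "S", "P", "V", "T", "C", "I", "L", "N", "D", "Q",
            "K", "E", "M", "H", "F", "R", "Y", "W"), "L")
}

# Tokenize a stem string into residue codes; greedy for J_NH2, Z -> J_NH2.
.tokenize_stem <- function(stem, name) {
  out <- character(0)
  i <- 1L
  n <- nchar(stem)
  if (n == 0L) stop("empty peptide stem in '", name, "'", call. = FALSE)
  while (i <= n) {
    if (substr(stem, i, i + 4L) == "J_NH2") {
      out <- c(out, "J_NH2"); i <- i + 5L
    } else {
      ch <- substr(stem, i, i)
      if (ch == "Z") ch <- "J_NH2"
      if (!ch %in% names(.residue_masses)) {
        stop("unknown residue code '", substr(stem, i, n), "' in '", name, "'",
             call. = FALSE)
      }
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

#' Parse a muropeptide written in gm-notation
#'
#' @param name A single muropeptide name, e.g. `"gm-AEJ_NH2=gm-A (Anh)"`.
#' @return An object of class `muropeptide`: a list with `stems` (list of
#'   character vectors of residue codes, acceptor first, donor last), and
#'   logical flags `anh`, `deac`.
#' @examples
#' parse_muropeptide("gm-AEJA")
#' parse_muropeptide("gm-AEJ_NH2=gm-A")
#' @export
parse_muropeptide <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  raw <- name
  s <- trimws(name)
  anh <- FALSE; deac <- FALSE
  repeat {
    if (grepl("\\(Anh\\)\\s*$", s)) {
      if (anh) stop("more than one (Anh) in '", raw, "'", call. = FALSE)
      anh <- TRUE
      s <- trimws(sub("\\(Anh\\)\\s*$", "", s))
    } else if (grepl("\\(-Ac\\)\\s*$", s)) {
      if (deac) stop("more than one (-Ac) in '", raw, "'", call. = FALSE)
      deac <- TRUE
      s <- trimws(sub("\\(-Ac\\)\\s*$", "", s))
    } else break
  }
  parts <- strsplit(s, "=", fixed = TRUE)[[1]]
  if (length(parts) == 0L || !all(nzchar(parts))) {
    stop("malformed muropeptide name '", raw, "'", call. = FALSE)
  }
  if (length(parts) > 3L) {
    stop("more than 3 cross-linked subunits in '", raw, "'", call. = FALSE)
  }
  stems <- lapply(parts, function(p) {
    if (!grepl("^[gG][mM]-", p)) {
      stop("malformed glycan prefix in subunit '", p, "' of '", raw,
           "' (expected 'gm-')", call. = FALSE)
    }
    .tokenize_stem(sub("^[gG][mM]-", "", p), raw)
  })
  structure(list(stems = stems, anh = anh, deac = deac),
            class = "muropeptide")
}

#' Canonical gm-notation name of a parsed muropeptide
#'
#' @param mp A `muropeptide` object.
#' @return A single string; `parse_muropeptide()` round-trips through it.
#' @export
muropeptide_name <- function(mp) {
  stopifnot(inherits(mp, "muropeptide"))
  s <- paste(vapply(mp$stems, function(x) paste0("gm-", paste(x, collapse = "")),
                    character(1)), collapse = "=")
  if (mp$anh) s <- paste0(s, " (Anh)")
  if (mp$deac) s <- paste0(s, " (-Ac)")
  s
}

#' @export
format.muropeptide <- function(x, ...) muropeptide_name(x)

#' @export
print.muropeptide <- function(x, ...) {
  cat("<muropeptide> ", muropeptide_name(x), "\n", sep = "")
  invisible(x)
}

# Mass of one parsed muropeptide. Every subunit carries a borohydride-reduced
# MurNAc (+2.015650) except the one bearing the 1,6-anhydro ring, which is
# neither reduced nor hydrated (net -water - reduction vs a reduced subunit).
.mp_mass <- function(mp) {
  w <- mass_constants[["water"]]
  n <- length(mp$stems)
  stem_mass <- sum(vapply(mp$stems, function(x) sum(.residue_masses[x]), numeric(1)))
  m <- n * (.glycan_masses[["GlcNAc"]] + .glycan_masses[["MurNAc"]] +
              mass_constants[["reduction"]] + w) +
    stem_mass - (n - 1) * w
  if (mp$anh)  m <- m - mass_constants[["reduction"]] - w
  if (mp$deac) m <- m + mass_constants[["deacetylation"]]
  unname(m)
}

#' Neutral monoisotopic mass of muropeptides
#'
#' Computes the neutral (uncharged) monoisotopic mass of borohydride-reduced
#' muropeptides: the sum of glycan and stem residue masses plus one water per
#' molecule, minus one water per cross-link, with modification deltas applied.
#'
#' @param x Muropeptide names (character vector) or a single `muropeptide`.
#' @return Numeric vector of masses in Da.
#' @examples
#' muropeptide_mass("gm-A")                 # 569.2433
#' muropeptide_mass("gm-AEJ_NH2=gm-A")     # 1420.6194
#' @export
muropeptide_mass <- function(x) {
  if (inherits(x, "muropeptide")) return(.mp_mass(x))
  vapply(x, function(nm) .mp_mass(parse_muropeptide(nm)), numeric(1),
         USE.NAMES = FALSE)
}

#' b/y fragment masses of a peptide stem
#'
#' Singly-protonated b and y ion masses for every prefix/suffix of a stem,
#' as used to validate monomer identifications against MS/MS spectra:
#' `b_i = sum(first i residues) + proton`, `y_i = sum(last i residues) +
#' water + proton`, for `1 <= i < length(stem)`.
#'
#' @param stem Character vector of residue codes (e.g. `c("A","E","J","A")`).
#' @return A tibble with columns `ion` ("b"/"y"), `index`, `mass`; empty when
#'   the stem has fewer than 2 residues.
#' @export
stem_fragments <- function(stem) {
  stopifnot(is.character(stem))
  bad <- setdiff(stem, names(.residue_masses))
  if (length(bad)) stop("unknown residue code '", bad[1], "'", call. = FALSE)
  n <- length(stem)
  if (n < 2L) {
    return(tibble::tibble(ion = character(0), index = integer(0),
                          mass = numeric(0)))
  }
  masses <- .residue_masses[stem]
  idx <- seq_len(n - 1L)
  b <- cumsum(masses)[idx] + mass_constants[["proton"]]
  y <- cumsum(rev(masses))[idx] + mass_constants[["water"]] + mass_constants[["proton"]]
  dplyr::bind_rows(
    tibble::tibble(ion = "b", index = idx, mass = unname(b)),
    tibble::tibble(ion = "y", index = idx, mass = unname(y))
  )
}

#' Parts-per-million mass difference
#'
#' @param observed,theoretical Neutral masses in Da; `theoretical` must be > 0.
#' @return Signed ppm difference `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_diff <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  (observed - theoretical) / theoretical * 1e6
}
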