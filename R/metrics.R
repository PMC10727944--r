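# Compositional metrics: relative abundances, cross-linking index, glycan
# chain length and structural classification.

#' Classify muropeptide structures for compositional summaries
#'
#' For each structure: polymerisation level (monomer/dimer/trimer), whether
#' it is a 1-3 cross-linked dimer (a subunit stem is exactly the single
#' residue A), whether a monomer belongs to the disaccharide-dipeptide class
#' (stem length <= 2; `strict_dipeptide` marks stem length exactly 2), and
#' the anhydro / deacetyl / amidated flags. Isobaric-merged names
#' (`"a|b"`) are classified by their first name and flagged `ambiguous`.
#'
#' @param structures Character vector of gm-notation names (possibly
#'   `"|"`-merged).
#' @return A tibble with columns `structure`, `level`, `is_1_3_dimer`,
#'   `dipeptide_monomer`, `strict_dipeptide`, `anhydro`, `deacetyl`,
#'   `amidated`, `ambiguous`.
#' @examples
#' classify_structures(c("gm-AEJ_NH2=gm-A", "gm-AE", "gm-AEJA=gm-AEJA"))
#' @export
classify_structures <- function(structures) {
  first <- vapply(strsplit(structures, "|", fixed = TRUE), `[[`, character(1), 1L)
  parsed <- lapply(first, parse_muropeptide)
  n_sub <- vapply(parsed, function(p) length(p$stems), integer(1))
  stem1_len <- vapply(parsed, function(p) length(p$stems[[1]]), integer(1))
  tibble::tibble(
    structure = structures,
    level = c("monomer", "dimer", "trimer")[n_sub],
    is_1_3_dimer = n_sub == 2L & vapply(parsed, function(p)
      any(vapply(p$stems, function(s) identical(s, "A"), logical(1))),
      logical(1)),
    dipeptide_monomer = n_sub == 1L & stem1_len <= 2L,
    strict_dipeptide = n_sub == 1L & stem1_len == 2L,
    anhydro = vapply(parsed, function(p) p$anh, logical(1)),
    deacetyl = vapply(parsed, function(p) p$deac, logical(1)),
    amidated = vapply(parsed, function(p)
      any(vapply(p$stems, function(s) "J_NH2" %in% s, logical(1))), logical(1)),
    ambiguous = grepl("|", structures, fixed = TRUE)
  )
}

#' Relative abundance of identified structures
#'
#' Intensity of each structure as a percentage of the summed intensity over
#' identified structures only; the unidentified pool is excluded from the
#' denominator.
#'
#' @param consolidated A tibble with columns `structure` and `intensity`
#'   ([consolidate_replicates()] output).
#' @return The input with an `abundance_pct` column appended.
#' @export
relative_abundance <- function(consolidated) {
  stopifnot(nrow(consolidated) >= 1L)
  total <- sum(consolidated$intensity)
  if (!is.finite(total) || total <= 0) {
    stop("total identified intensity is zero; cannot compute abundances",
         call. = FALSE)
  }
  dplyr::mutate(consolidated,
                abundance_pct = .data$intensity / total * 100)
}

#' Cross-linking index
#'
#' `0.5 * (% dimers) + 0.33 * (% trimers)`, a scalar summary of
#' peptidoglycan polymerisation; percentages on the 0-100 scale over
#' identified structures. The factor 0.33 is used as conventionally printed,
#' not 1/3.
#'
#' @param abundances A tibble with columns `abundance_pct` and `level`
#'   (or a `structure` column from which levels are derived).
#' @return The index, in percent.
#' @examples
#' crosslink_index(tibble::tibble(level = c("monomer", "dimer"),
#'                                abundance_pct = c(50, 50)))  # 25
#' @export
crosslink_index <- function(abundances) {
  abundances <- .ensure_levels(abundances)
  pct <- function(lv) sum(abundances$abundance_pct[abundances$level == lv])
  0.5 * pct("dimer") + 0.33 * pct("trimer")
}

#' Average glycan chain length
#'
#' Inferred from the abundance of 1,6-anhydroMurNAc residues, which cap
#' glycan-chain ends: `1 / (f_anh_monomers + 0.5 * f_anh_dimers + 0.33 *
#' f_anh_trimers)` where `f` are fractions (percent / 100). `NA` when no
#' anhydro structure was identified (the chain length is then undefined).
#'
#' @inheritParams crosslink_index
#' @return Average chain length in disaccharide units, or `NA`.
#' @export
glycan_chain_length <- function(abundances) {
  abundances <- .ensure_levels(abundances)
  if (!"anhydro" %in% names(abundances)) {
    abundances$anhydro <- classify_structures(abundances$structure)$anhydro
  }
  f <- function(lv) {
    sum(abundances$abundance_pct[abundances$level == lv & abundances$anhydro]) / 100
  }
  denom <- f("monomer") + 0.5 * f("dimer") + 0.33 * f("trimer")
  if (denom <= 0) return(NA_real_)
  1 / denom
}

.ensure_levels <- function(abundances) {
  stopifnot("abundance_pct" %in% names(abundances))
  if (!"level" %in% names(abundances)) {
    abundances$level <- classify_structures(abundances$structure)$level
  }
  abundances
}

#' Summarise peptidoglycan composition
#'
#' One-row summary of an abundance table: percentage of total assigned
#' intensity per polymerisation level, anhydro content per level,
#' cross-linking index, average glycan chain length, 1-3 dimer content and
#' disaccharide-dipeptide content (both including single-residue gm-A stems,
#' `pct_dipeptide_monomers`, and restricted to true dipeptide stems,
#' `pct_strict_dipeptide_monomers`).
#'
#' @param abundances A tibble with `structure` and `abundance_pct` columns
#'   (e.g. [tidy()] of a [pg_search()] result, or a reference composition
#'   table).
#' @return A one-row tibble of summary metrics (all percentages on the
#'   0-100 scale; `glycan_chain_length` in disaccharide units).
#' @export
summarize_composition <- function(abundances) {
  cls <- classify_structures(abundances$structure)
  d <- dplyr::bind_cols(abundances[, c("structure", "abundance_pct")],
                        cls[, setdiff(names(cls), "structure")])
  pct <- function(cond) sum(d$abundance_pct[cond])
  tibble::tibble(
    pct_monomers = pct(d$level == "monomer"),
    pct_dimers = pct(d$level == "dimer"),
    pct_trimers = pct(d$level == "trimer"),
    pct_anh_monomers = pct(d$level == "monomer" & d$anhydro),
    pct_anh_dimers = pct(d$level == "dimer" & d$anhydro),
    pct_anh_trimers = pct(d$level == "trimer" & d$anhydro),
    crosslink_index = crosslink_index(d),
    glycan_chain_length = glycan_chain_length(d),
    pct_1_3_dimers = pct(d$is_1_3_dimer),
    pct_dipeptide_monomers = pct(d$dipeptide_monomer),
    pct_strict_dipeptide_monomers = pct(d$strict_dipeptide)
  )
}

#' Bundled reference composition of *G. oxydans* B58 peptidoglycan
#'
#' The published high-resolution composition of *Gluconobacter oxydans* B58
#' peptidoglycan: 61 identified muropeptides with relative abundances for
#' wild-type cells in exponential and stationary phase and for two
#' L,D-transpeptidase transposon mutants, plus retention times, theoretical
#' monoisotopic masses and observed ppm errors.
#'
#' @return A tibble with columns `no`, `structure`, `wt_expo_pct`,
#'   `wt_stat_pct`, `ldtgo1_pct`, `ldtgo2_pct`, `rt_min`, `rt_sd`,
#'   `theoretical_mass`, `ppm`. Missing values are structures not detected
#'   in that sample.
#' @export
go_reference_composition <- function() {
  path <- system.file("extdata", "go_muropeptides.csv", package = "muroseek",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Reference composition as an abundance table for one sample
#'
#' @param sample One of `"wt_expo"`, `"wt_stat"`, `"ldtgo1"`, `"ldtgo2"`.
#' @return A tibble with `structure`, `abundance_pct` (undetected structures
#'   dropped, duplicate listings of the same structure summed) and `rt_min`.
#' @export
go_reference_abundances <- function(sample = c("wt_stat", "wt_expo",
                                               "ldtgo1", "ldtgo2")) {
  sample <- match.arg(sample)
  ref <- go_reference_composition()
  col <- paste0(sub("^(wt_)", "wt_", sample), "_pct")
  out <- ref |>
    dplyr::filter(!is.na(.data[[col]])) |>
    dplyr::group_by(.data$structure) |>
    dplyr::summarise(abundance_pct = sum(.data[[col]]),
                     rt_min = dplyr::first(.data$rt_min),
                     .groups = "drop")
  out
}
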