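# Theoretical search-space construction: candidate monomer enumeration,
# curated monomer databases, and dynamic generation of cross-linked
# dimers/trimers.
#
# Cross-link chemistry, all bonds landing on the acceptor's position-3
# meso-DAP side chain:
#   4-3: donor stem position 4 (D-Ala) -> acceptor DAP; donor stem length >= 4
#   3-3: donor stem position 3 (DAP)   -> acceptor DAP; donor length >= 3 with
#        DAP at position 3
#   1-3: donor stem position 1 (Ala)   -> acceptor DAP; donor stem is the
#        single residue A (the gm-A moiety)

.is_dap <- function(code) code %in% c("J", "J_NH2")

.is_acceptor <- function(stem) length(stem) >= 3L && .is_dap(stem[3])

.is_donor <- function(stem, type) {
  switch(type,
    "4-3" = length(stem) >= 4L,
    "3-3" = length(stem) >= 3L && .is_dap(stem[3]),
    "1-3" = identical(stem, "A"),
    stop("unknown cross-link type '", type, "'", call. = FALSE)
  )
}

#' Enumerate a candidate monomer search space
#'
#' Builds all disaccharide-peptide monomers whose stems are consistent with a
#' per-position residue specification, the combinatorial candidate space from
#' which MS/MS-validated monomer databases are curated.
#'
#' @param positions A list of character vectors, one per stem position: the
#'   residues allowed at that position. The wildcard `"X"` expands to
#'   `x_alphabet`. `"Z"` is normalised to `"J_NH2"`.
#' @param lengths Integer vector of stem lengths to emit (default: all lengths
#'   `1..length(positions)`).
#' @param x_alphabet Residues substituted for `"X"` (default
#'   [default_x_alphabet()], 19 residues).
#' @param overrides Optional named list: `overrides[["5"]]` replaces the
#'   position specification for length-5 stems, etc. Used when longer stems
#'   follow a different rule than truncations of the full specification (e.g.
#'   pentapeptides constrained to an A-X dipeptide at the C-terminus).
#' @return A tibble with columns `structure`, `mass`, `stem_length`, ordered
#'   by length then alphabetically; no duplicates.
#' @examples
#' enumerate_monomer_space(list("A", c("E", "Q")))
#' @export
enumerate_monomer_space <- function(positions, lengths = seq_along(positions),
                                    x_alphabet = default_x_alphabet(),
                                    overrides = list()) {
  stopifnot(is.list(positions), length(positions) >= 1L)
  if (length(x_alphabet) == 0L) {
    if (any(vapply(positions, function(p) "X" %in% p, logical(1))) ||
        any(vapply(overrides, function(o)
          any(vapply(o, function(p) "X" %in% p, logical(1))), logical(1)))) {
      stop("empty alphabet for a wildcard (X) position", call. = FALSE)
    }
  }
  expand_pos <- function(p) {
    p <- unique(unlist(lapply(p, function(r) if (r == "X") x_alphabet else r)))
    p[p == "Z"] <- "J_NH2"
    unique(p)
  }
  stems <- unlist(lapply(sort(unique(lengths)), function(len) {
    spec <- overrides[[as.character(len)]]
    if (is.null(spec)) {
      if (len > length(positions)) {
        stop("no position specification for stem length ", len, call. = FALSE)
      }
      spec <- positions[seq_len(len)]
    }
    stopifnot(length(spec) == len)
    grid <- expand.grid(lapply(spec, expand_pos),
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    sort(unique(apply(as.matrix(grid), 1L, paste, collapse = "")))
  }))
  structure_names <- paste0("gm-", stems)
  tibble::tibble(
    structure = structure_names,
    mass = muropeptide_mass(structure_names),
    stem_length = vapply(structure_names,
                         function(s) length(parse_muropeptide(s)$stems[[1]]),
                         integer(1), USE.NAMES = FALSE)
  )
}

#' The candidate stem space used for *G. oxydans*-type peptidoglycan
#'
#' Mono- to pentapeptide stems with Ala in position 1, Glu/Gln in position 2,
#' meso-DAP or amidated meso-DAP in position 3, any amino acid in position 4,
#' and pentapeptides restricted to an A-X dipeptide at the C-terminus.
#'
#' @inheritParams enumerate_monomer_space
#' @return A tibble as [enumerate_monomer_space()] (159 stems with the
#'   default 19-residue alphabet).
#' @export
go_candidate_space <- function(x_alphabet = default_x_alphabet()) {
  pos <- list("A", c("E", "Q"), c("J", "Z"), "X")
  enumerate_monomer_space(pos, lengths = 1:5, x_alphabet = x_alphabet,
                          overrides = list("5" = c(pos[1:3], list("A", "X"))))
}

#' Load a curated monomer database
#'
#' Reads a CSV of muropeptide monomer names (column `Structure`, optionally a
#' precomputed `Mass` column; header required, case-insensitive) and computes
#' each monoisotopic mass. When a supplied mass disagrees with the computed
#' one by more than 1e-3 Da a warning is attached to the row (and raised).
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `structure`, `mass` (computed),
#'   `supplied_mass` (NA when absent), `mass_warning` (logical).
#' @export
read_monomer_db <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L && ncol(df) == 0L) {
    return(tibble::tibble(structure = character(0), mass = numeric(0),
                          supplied_mass = numeric(0), mass_warning = logical(0)))
  }
  names(df) <- tolower(names(df))
  if (!"structure" %in% names(df)) {
    stop("monomer database is missing a 'Structure' column", call. = FALSE)
  }
  supplied <- if ("mass" %in% names(df)) suppressWarnings(as.numeric(df$mass)) else rep(NA_real_, nrow(df))
  computed <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(muropeptide_mass(df$structure[i]),
             error = function(e) {
               stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
             })
  }, numeric(1))
  warn <- !is.na(supplied) & abs(supplied - computed) > 1e-3
  if (any(warn)) {
    warning(sum(warn), " monomer(s) with supplied mass differing from the ",
            "computed mass by > 1e-3 Da (e.g. '", df$structure[which(warn)[1]],
            "')", call. = FALSE)
  }
  tibble::tibble(structure = df$structure, mass = computed,
                 supplied_mass = supplied, mass_warning = warn)
}

#' Bundled curated *G. oxydans* monomer database
#'
#' The 28 MS/MS-validated disaccharide-peptide monomers of *G. oxydans* B58
#' (17 distinct stems plus anhydro and deacetylated variants).
#'
#' @return A tibble as [read_monomer_db()].
#' @export
go_monomer_db <- function() {
  ref <- go_reference_composition()
  mono <- ref$structure[!grepl("=", ref$structure, fixed = TRUE)]
  tibble::tibble(structure = mono, mass = muropeptide_mass(mono),
                 supplied_mass = NA_real_, mass_warning = FALSE)
}

# classification columns for a vector of (unmerged) structure names
.classify_names <- function(structures) {
  parsed <- lapply(structures, parse_muropeptide)
  n_sub <- vapply(parsed, function(p) length(p$stems), integer(1))
  tibble::tibble(
    structure = structures,
    level = c("monomer", "dimer", "trimer")[n_sub],
    anhydro = vapply(parsed, function(p) p$anh, logical(1)),
    deacetyl = vapply(parsed, function(p) p$deac, logical(1)),
    amidated = vapply(parsed, function(p)
      any(vapply(p$stems, function(s) "J_NH2" %in% s, logical(1))), logical(1)),
    has_single_A_donor = vapply(parsed, function(p)
      length(p$stems) > 1L &&
        any(vapply(p$stems, function(s) identical(s, "A"), logical(1))),
      logical(1))
  )
}

# infer the set of cross-link types that could underlie a multimer name,
# given the acceptor/donor rules (bond i connects subunit i to donor i+1)
.crosslink_types_of <- function(stems, enabled) {
  n <- length(stems)
  if (n < 2L) return("")
  types <- character(0)
  for (i in seq_len(n - 1L)) {
    t_i <- enabled[vapply(enabled, function(t) .is_donor(stems[[i + 1L]], t),
                          logical(1))]
    types <- union(types, t_i)
  }
  paste(sort(types), collapse = "+")
}

#' Dynamically generate a theoretical muropeptide database
#'
#' Expands a curated monomer database into the full theoretical search space:
#' the monomers themselves plus every dimer and trimer permitted by the
#' enabled cross-link chemistry, with modification variants, masses by
#' additivity (one water condensed per cross-link), and isobaric entries
#' (masses within `isobaric_tol`) merged into a single entry whose names are
#' joined with `"|"`.
#'
#' Multimers are assembled from the unmodified monomer stems; modification
#' variants (at most one 1,6-anhydro end and one deacetylation per molecule)
#' are then generated at the multimer level. Trimers chain two valid
#' donor-acceptor bonds; every internal acceptor must itself carry a
#' position-3 DAP, so no branched trimers are produced.
#'
#' @param monomers A tibble with a `structure` column ([read_monomer_db()]
#'   output) or a character vector of monomer names.
#' @param crosslinks Character subset of `c("4-3", "3-3", "1-3")`; empty or
#'   `"none"` generates monomers only.
#' @param modifications Character subset of `c("Anh", "DeAc")`: which
#'   multimer modification variants to generate.
#' @param max_level 1 (monomers), 2 (+dimers) or 3 (+trimers).
#' @param restrict_1_3_to_gmA When `TRUE`, 1-3 dimers/trimers are only built
#'   with the canonical unmodified gm-A monomer as donor and no deacetylation
#'   variant is applied to molecules whose only cross-link is 1-3.
#' @param merge_isobaric Merge entries whose masses agree within
#'   `isobaric_tol` (default `TRUE`).
#' @param isobaric_tol Mass tolerance for isobaric grouping, Da.
#' @return A tibble with columns `structure` (possibly `"|"`-merged), `mass`,
#'   `level`, `crosslink_types`, `anhydro`, `deacetyl`, `amidated`,
#'   `has_single_A_donor`, `ambiguous`.
#' @examples
#' build_theoretical_db(c("gm-AEJ_NH2", "gm-AEJA", "gm-A"),
#'                      crosslinks = "1-3", modifications = character(0))
#' @export
build_theoretical_db <- function(monomers,
                                 crosslinks = c("4-3", "3-3", "1-3"),
                                 modifications = c("Anh", "DeAc"),
                                 max_level = 3,
                                 restrict_1_3_to_gmA = FALSE,
                                 merge_isobaric = TRUE,
                                 isobaric_tol = 1e-4) {
  if (is.data.frame(monomers)) monomers <- monomers$structure
  stopifnot(is.character(monomers), max_level %in% 1:3)
  crosslinks <- setdiff(crosslinks, "none")
  stopifnot(all(crosslinks %in% c("4-3", "3-3", "1-3")))
  stopifnot(all(modifications %in% c("Anh", "DeAc")))

  parsed <- lapply(monomers, parse_muropeptide)
  is_mono <- vapply(parsed, function(p) length(p$stems) == 1L, logical(1))
  if (!all(is_mono)) {
    stop("monomer database contains multimers: '",
         monomers[which(!is_mono)[1]], "'", call. = FALSE)
  }

  # unmodified bricks for multimer assembly
  plain <- !vapply(parsed, function(p) p$anh || p$deac, logical(1))
  bricks <- unique(vapply(parsed[plain], function(p)
    paste(p$stems[[1]], collapse = ""), character(1)))
  brick_stems <- lapply(parsed[plain], function(p) p$stems[[1]])
  brick_stems <- brick_stems[!duplicated(bricks)]
  names(brick_stems) <- unique(bricks)

  acceptors <- names(brick_stems)[vapply(brick_stems, .is_acceptor, logical(1))]
  donors <- lapply(crosslinks, function(t) {
    d <- names(brick_stems)[vapply(brick_stems, .is_donor, logical(1), type = t)]
    if (t == "1-3" && restrict_1_3_to_gmA) d <- intersect(d, "A")
    d
  })
  names(donors) <- crosslinks
  donor_union <- unique(unlist(donors))

  multimer_names <- character(0)
  if (max_level >= 2L && length(crosslinks)) {
    pairs <- expand.grid(acc = acceptors, don = donor_union,
                         stringsAsFactors = FALSE)
    if (nrow(pairs)) {
      multimer_names <- paste0("gm-", pairs$acc, "=gm-", pairs$don)
    }
    if (max_level >= 3L) {
      mid <- intersect(acceptors, setdiff(donor_union, "A"))
      if (length(mid) && length(acceptors)) {
        tri <- expand.grid(acc = acceptors, mid = mid, don = donor_union,
                           stringsAsFactors = FALSE)
        multimer_names <- c(multimer_names,
                            paste0("gm-", tri$acc, "=gm-", tri$mid,
                                   "=gm-", tri$don))
      }
    }
  }

  # modification variants at multimer level
  variants <- function(nm) {
    out <- nm
    if ("Anh" %in% modifications) out <- c(out, paste0(nm, " (Anh)"))
    if ("DeAc" %in% modifications) out <- c(out, paste0(out, " (-Ac)"))
    out
  }
  multimer_all <- unlist(lapply(multimer_names, variants))
  if (restrict_1_3_to_gmA && length(multimer_all)) {
    # no deacetyl variants for pure 1-3 products: the donor must stay gm-A
    p <- lapply(multimer_all, parse_muropeptide)
    only_1_3 <- vapply(p, function(m) {
      all(vapply(m$stems[-1], function(s) identical(s, "A"), logical(1)))
    }, logical(1))
    deac <- vapply(p, function(m) m$deac, logical(1))
    multimer_all <- multimer_all[!(only_1_3 & deac)]
  }

  all_names <- unique(c(monomers, multimer_all))
  cls <- .classify_names(all_names)
  parsed_all <- lapply(all_names, parse_muropeptide)
  db <- dplyr::mutate(cls,
    mass = muropeptide_mass(all_names),
    crosslink_types = vapply(parsed_all, function(p)
      .crosslink_types_of(p$stems, crosslinks), character(1)),
    .after = "structure")
  db <- dplyr::arrange(db, .data$mass, .data$structure)

  if (merge_isobaric) db <- merge_isobaric_entries(db, tol = isobaric_tol)
  db
}

#' Merge isobaric database entries
#'
#' Groups entries whose masses agree within `tol` Da into a single entry:
#' names joined with `"|"`, mass averaged, classification taken from the
#' first name and `ambiguous` set when the grouped names differ.
#'
#' @param db A theoretical database tibble ([build_theoretical_db()] layout).
#' @param tol Grouping tolerance in Da.
#' @return A tibble with the same columns plus `ambiguous`.
#' @export
merge_isobaric_entries <- function(db, tol = 1e-4) {
  db <- dplyr::arrange(db, .data$mass, .data$structure)
  grp <- cumsum(c(TRUE, diff(db$mass) > tol))
  db |>
    dplyr::mutate(.grp = grp) |>
    dplyr::group_by(.data$.grp) |>
    dplyr::summarise(
      structure = paste(sort(unique(.data$structure)), collapse = "|"),
      mass = mean(.data$mass),
      level = dplyr::first(.data$level),
      crosslink_types = paste(sort(unique(.data$crosslink_types[nzchar(.data$crosslink_types)])),
                              collapse = "|"),
      anhydro = any(.data$anhydro),
      deacetyl = any(.data$deacetyl),
      amidated = any(.data$amidated),
      has_single_A_donor = any(.data$has_single_A_donor),
      ambiguous = dplyr::n() > 1L,
      .groups = "drop") |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$mass)
}

#' All individual structure names in a (possibly isobaric-merged) database
#'
#' @param db A theoretical database tibble.
#' @return Character vector of unmerged structure names.
#' @export
db_structures <- function(db) {
  unique(unlist(strsplit(db$structure, "|", fixed = TRUE)))
}

#' Write a theoretical database to CSV
#'
#' Columns `Structure,Mass,Level,CrosslinkTypes,Flags`; masses with 4
#' decimals.
#'
#' @param db A theoretical database tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_theoretical_db <- function(db, path) {
  flags <- apply(cbind(ifelse(db$anhydro, "Anh", ""),
                       ifelse(db$deacetyl, "DeAc", ""),
                       ifelse(db$amidated, "Amidated", "")), 1L,
                 function(x) paste(x[nzchar(x)], collapse = "+"))
  out <- tibble::tibble(Structure = db$structure,
                        Mass = sprintf("%.4f", db$mass),
                        Level = db$level,
                        CrosslinkTypes = db$crosslink_types,
                        Flags = flags)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
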