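# Matching observed features against a theoretical database, satellite
# cleanup, and replicate consolidation.

#' Search configuration
#'
#' Defaults mirror the published workflow: 10 ppm mass tolerance and a
#' 0.5 min retention-time cleanup window, with sodium/potassium adducts and
#' in-source GlcNAc / disaccharide losses considered as satellite signals.
#'
#' @param ppm_tolerance Mass-matching tolerance in ppm (inclusive, on
#'   absolute ppm error); must be > 0.
#' @param cleanup_window_min Retention-time window (min) within which a
#'   satellite signal may be merged into its parent match; >= 0.
#' @param adducts Subset of `c("Na", "K")` considered during cleanup.
#' @param insource_losses Subset of `c("GlcNAc", "disaccharide")`: in-source
#'   fragment losses considered during cleanup.
#' @param crosslinks,modifications,restrict_1_3_to_gmA Database-generation
#'   options carried along for [pg_search()] and the command-line driver.
#' @return A list of class `search_config`.
#' @export
search_config <- function(ppm_tolerance = 10,
                          cleanup_window_min = 0.5,
                          adducts = c("Na", "K"),
                          insource_losses = c("GlcNAc", "disaccharide"),
                          crosslinks = c("4-3", "3-3", "1-3"),
                          modifications = c("Anh", "DeAc"),
                          restrict_1_3_to_gmA = FALSE) {
  stopifnot(ppm_tolerance > 0, cleanup_window_min >= 0,
            all(adducts %in% c("Na", "K")),
            all(insource_losses %in% c("GlcNAc", "disaccharide")))
  structure(list(ppm_tolerance = ppm_tolerance,
                 cleanup_window_min = cleanup_window_min,
                 adducts = adducts,
                 insource_losses = insource_losses,
                 crosslinks = setdiff(crosslinks, "none"),
                 modifications = modifications,
                 restrict_1_3_to_gmA = isTRUE(restrict_1_3_to_gmA)),
            class = "search_config")
}

.satellite_deltas <- function(config) {
  deltas <- numeric(0)
  if ("Na" %in% config$adducts) deltas <- c(deltas, adduct_Na = mass_constants[["adduct_Na"]])
  if ("K" %in% config$adducts) deltas <- c(deltas, adduct_K = mass_constants[["adduct_K"]])
  if ("GlcNAc" %in% config$insource_losses) {
    deltas <- c(deltas, loss_GlcNAc = -203.07937)
  }
  if ("disaccharide" %in% config$insource_losses) {
    deltas <- c(deltas, loss_disaccharide = -(203.07937 + 275.10049))
  }
  deltas
}

#' Match features against a theoretical database
#'
#' Every feature is compared to every database entry; a pair within the ppm
#' tolerance (inclusive, absolute value) is a match. A feature matching
#' several entries keeps all matches but only the lowest-|ppm| one is flagged
#' `primary` and receives the feature's intensity, so abundance sums never
#' double-count. Features matching nothing are kept as the "unidentified"
#' pool (structure `NA`), so total intensity is conserved.
#'
#' @param features A feature tibble ([read_features()] layout; a `sample`
#'   column is carried through if present).
#' @param db A theoretical database tibble ([build_theoretical_db()]).
#' @param config A [search_config()].
#' @return A tibble with columns `sample`, `feature_id`, `observed_mass`,
#'   `rt`, `intensity`, `structure`, `theoretical_mass`, `ppm`, `primary`,
#'   `intensity_assigned`, `provenance` (`"direct"` or `"unidentified"`).
#' @export
match_features <- function(features, db, config = search_config()) {
  stopifnot(nrow(db) > 0)
  sample_id <- if ("sample" %in% names(features)) features$sample else rep(NA_character_, nrow(features))
  ord <- order(db$mass)
  dbm <- db$mass[ord]
  dbs <- db$structure[ord]
  tol <- config$ppm_tolerance
  rows <- purrr::map(seq_len(nrow(features)), function(i) {
    m <- features$mass[i]
    # bracket with a slightly widened Da window, then apply the exact
    # (inclusive) ppm criterion, so boundary cases are never lost to
    # floating-point rounding of the bracket itself
    lo <- findInterval(m / (1 + 1.01 * tol * 1e-6), dbm, left.open = TRUE) + 1L
    hi <- findInterval(m * (1 + 1.01 * tol * 1e-6), dbm)
    hits <- if (hi >= lo) lo:hi else integer(0)
    # findInterval brackets by Da window; re-check the ppm criterion exactly
    hits <- hits[abs(ppm_diff(m, dbm[hits])) <= tol]
    if (!length(hits)) {
      return(tibble::tibble(
        sample = sample_id[i], feature_id = features$id[i], observed_mass = m,
        rt = features$rt[i], intensity = features$intensity[i],
        structure = NA_character_, theoretical_mass = NA_real_, ppm = NA_real_,
        primary = FALSE, intensity_assigned = features$intensity[i],
        provenance = "unidentified"))
    }
    ppm <- ppm_diff(m, dbm[hits])
    prim <- which.min(abs(ppm))
    tibble::tibble(
      sample = sample_id[i], feature_id = features$id[i], observed_mass = m,
      rt = features$rt[i], intensity = features$intensity[i],
      structure = dbs[hits], theoretical_mass = dbm[hits], ppm = ppm,
      primary = seq_along(hits) == prim,
      intensity_assigned = ifelse(seq_along(hits) == prim,
                                  features$intensity[i], 0),
      provenance = "direct")
  })
  dplyr::bind_rows(rows)
}

#' Merge adduct and in-source satellite signals into their parent matches
#'
#' An unidentified feature whose mass equals (parent theoretical mass +
#' adduct delta) or (parent theoretical mass - substructure loss) within the
#' ppm tolerance, and whose retention time lies within the cleanup window of
#' a directly-matched feature of that parent, has its intensity added to the
#' parent's primary match and is re-flagged `adduct-merged` /
#' `insource-merged`. Each satellite merges into at most one parent: nearest
#' retention time, ties broken by lowest absolute ppm error. Cleanup never
#' creates identifications without direct evidence, and total intensity is
#' conserved.
#'
#' @param matches Output of [match_features()].
#' @param config A [search_config()].
#' @return The match tibble with merged satellites.
#' @export
cleanup_satellites <- function(matches, config = search_config()) {
  deltas <- .satellite_deltas(config)
  if (!length(deltas) || config$cleanup_window_min < 0) return(matches)
  parents <- matches[matches$provenance == "direct" & matches$primary, ]
  if (!nrow(parents)) return(matches)
  un_idx <- which(matches$provenance == "unidentified")
  tol <- config$ppm_tolerance
  for (i in un_idx) {
    m <- matches$observed_mass[i]
    cand <- purrr::map_dfr(seq_along(deltas), function(d) {
      expected <- parents$theoretical_mass + deltas[d]
      ok <- expected > 0
      ppm <- rep(NA_real_, nrow(parents))
      ppm[ok] <- ppm_diff(m, expected[ok])
      keep <- ok & !is.na(ppm) & abs(ppm) <= tol &
        abs(parents$rt - matches$rt[i]) <= config$cleanup_window_min
      if (!any(keep)) return(NULL)
      tibble::tibble(parent_row = which(keep),
                     kind = names(deltas)[d],
                     ppm = ppm[keep],
                     rt_dist = abs(parents$rt[keep] - matches$rt[i]))
    })
    if (is.null(cand) || !nrow(cand)) next
    best <- cand[order(cand$rt_dist, abs(cand$ppm)), ][1, ]
    p <- parents[best$parent_row, ]
    j <- which(matches$provenance == "direct" & matches$primary &
                 matches$feature_id == p$feature_id &
                 (is.na(matches$sample) | matches$sample == p$sample) &
                 matches$structure == p$structure)[1]
    matches$intensity_assigned[j] <- matches$intensity_assigned[j] +
      matches$intensity[i]
    matches$intensity_assigned[i] <- 0
    matches$structure[i] <- p$structure
    matches$theoretical_mass[i] <- p$theoretical_mass
    matches$provenance[i] <- if (startsWith(best$kind, "adduct")) {
      "adduct-merged"
    } else {
      "insource-merged"
    }
  }
  matches
}

#' Consolidate matches across replicates
#'
#' Per identified structure: mean assigned intensity over the replicates in
#' which it was observed, mean and standard deviation (n-1 denominator) of
#' the retention time, mean observed mass and mean signed ppm error. A
#' structure absent from a replicate contributes nothing to that replicate's
#' totals.
#'
#' @param matches A match tibble (one or more samples in the `sample`
#'   column), from [match_features()] / [cleanup_satellites()].
#' @return A tibble with columns `structure`, `theoretical_mass`,
#'   `intensity`, `rt_mean`, `rt_sd`, `observed_mass`, `ppm_mean`,
#'   `n_replicates`.
#' @export
consolidate_replicates <- function(matches) {
  prim <- matches[matches$provenance == "direct" & matches$primary &
                    !is.na(matches$structure), ]
  per_rep <- prim |>
    dplyr::group_by(.data$sample, .data$structure, .data$theoretical_mass) |>
    dplyr::summarise(
      rt = stats::weighted.mean(.data$rt, .data$intensity_assigned),
      observed_mass = stats::weighted.mean(.data$observed_mass,
                                           .data$intensity_assigned),
      ppm = stats::weighted.mean(.data$ppm, .data$intensity_assigned),
      intensity = sum(.data$intensity_assigned),
      .groups = "drop")
  per_rep |>
    dplyr::group_by(.data$structure, .data$theoretical_mass) |>
    dplyr::summarise(
      intensity = mean(.data$intensity),
      rt_mean = mean(.data$rt),
      rt_sd = stats::sd(.data$rt),
      observed_mass = mean(.data$observed_mass),
      ppm_mean = mean(.data$ppm),
      n_replicates = dplyr::n(),
      .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$intensity))
}

#' Run the full identification pipeline on one or more feature tables
#'
#' Convenience wrapper: match, satellite cleanup, replicate consolidation,
#' relative abundance and composition summary in one call.
#'
#' @param features A feature tibble, or a list of per-replicate feature
#'   tibbles (each gets its `sample` column set from the list names).
#' @param db A theoretical database tibble.
#' @param config A [search_config()].
#' @return An object of class `pg_search_result`: a list with `matches`,
#'   `consolidated` (with `abundance_pct`), `summary` (one-row metrics
#'   tibble), `config`, `db_size`.
#' @export
pg_search <- function(features, db, config = search_config()) {
  if (is.data.frame(features)) features <- list(sample1 = features)
  if (is.null(names(features)) || !all(nzchar(names(features)))) {
    names(features) <- paste0("sample", seq_along(features))
  }
  matches <- purrr::imap(features, function(tbl, nm) {
    tbl$sample <- nm
    cleanup_satellites(match_features(tbl, db, config), config)
  }) |> dplyr::bind_rows()
  consolidated <- consolidate_replicates(matches)
  if (nrow(consolidated)) {
    consolidated <- relative_abundance(consolidated)
    summary <- summarize_composition(consolidated)
  } else {
    consolidated$abundance_pct <- numeric(0)
    summary <- tibble::tibble()
  }
  structure(list(matches = matches, consolidated = consolidated,
                 summary = summary, config = config, db_size = nrow(db)),
            class = "pg_search_result")
}

#' @export
print.pg_search_result <- function(x, ...) {
  n_ident <- nrow(x$consolidated)
  cat("<pg_search_result> ", n_ident, " structures identified against ",
      x$db_size, " theoretical entries\n", sep = "")
  if (nrow(x$summary)) {
    cat("  cross-linking index: ",
        sprintf("%.1f%%", x$summary$crosslink_index), "\n", sep = "")
  }
  invisible(x)
}

#' Turn a search result into a tidy tibble
#'
#' `tidy()` returns the consolidated per-structure table (with relative
#' abundances); `glance()` returns the one-row composition-metrics summary.
#'
#' @param x A `pg_search_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
tidy.pg_search_result <- function(x, ...) x$consolidated

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @rdname tidy
#' @export
glance.pg_search_result <- function(x, ...) x$summary
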