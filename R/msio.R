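# Readers and writers for deconvoluted LC-MS feature lists and result tables.

#' Read a deconvoluted feature list
#'
#' Two dialects are supported: `"csv"` (comma-separated) and `"ftrs"`
#' (tab-separated). Both need columns `mass`, `rt`, `intensity` and accept an
#' optional `id`; column-name matching is case-insensitive. Retention times
#' are normalised to minutes.
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"ftrs"`.
#' @param rt_unit `"min"` (default) or `"sec"`; seconds are divided by 60.
#' @param sample_id Optional sample label stored in the `sample` column;
#'   defaults to the file name without extension.
#' @return A tibble with columns `sample`, `id`, `mass` (Da), `rt` (min),
#'   `intensity`.
#' @export
read_features <- function(path, dialect = c("csv", "ftrs"),
                          rt_unit = c("min", "sec"), sample_id = NULL) {
  dialect <- match.arg(dialect)
  rt_unit <- match.arg(rt_unit)
  if (!file.exists(path)) stop("feature file not found: ", path, call. = FALSE)
  df <- if (dialect == "csv") {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(.default = readr::col_character()))
  }
  names(df) <- tolower(names(df))
  for (col in c("mass", "rt", "intensity")) {
    if (!col %in% names(df)) {
      stop("feature file is missing required column '", col, "'", call. = FALSE)
    }
  }
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !is.na(df[[col]]) & nzchar(df[[col]]))
    if (length(bad)) {
      stop("non-numeric '", col, "' at row ", bad[1], ": '",
           df[[col]][bad[1]], "'", call. = FALSE)
    }
    x
  }
  mass <- num("mass"); rt <- num("rt"); intensity <- num("intensity")
  id <- if ("id" %in% names(df)) {
    ids <- suppressWarnings(as.integer(df$id))
    if (anyDuplicated(ids)) {
      stop("duplicate feature id at row ", which(duplicated(ids))[1],
           call. = FALSE)
    }
    ids
  } else seq_len(nrow(df))
  if (rt_unit == "sec") rt <- rt / 60
  if (any(mass <= 0, na.rm = TRUE)) stop("non-positive mass in feature file", call. = FALSE)
  if (is.null(sample_id)) sample_id <- tools::file_path_sans_ext(basename(path))
  tibble::tibble(sample = sample_id, id = id, mass = mass, rt = rt,
                 intensity = intensity)
}

#' Write a feature table
#'
#' Writes the simple CSV dialect (`id,mass,rt,intensity`) read back by
#' [read_features()]; masses keep full precision.
#'
#' @param features A feature tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features[, c("id", "mass", "rt", "intensity")], path,
                   progress = FALSE)
  invisible(path)
}

#' Write consolidated search results
#'
#' One row per identified theoretical structure: name(s), mean retention time
#' and its standard deviation, theoretical and mean observed mass, mean
#' signed ppm error, mean intensity and relative abundance. Masses are
#' written with 4 decimals and abundances with 3, matching the precision of
#' published composition tables.
#'
#' @param consolidated Output of [consolidate_replicates()] (with an
#'   `abundance_pct` column added by [relative_abundance()], optionally).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(consolidated, path) {
  out <- tibble::tibble(
    Muropeptide = consolidated$structure,
    `RT (min)` = sprintf("%.2f", consolidated$rt_mean),
    `RT sd` = ifelse(is.na(consolidated$rt_sd), "",
                     sprintf("%.2f", consolidated$rt_sd)),
    `Theoretical Mass (Da)` = sprintf("%.4f", consolidated$theoretical_mass),
    `Observed Mass (Da)` = sprintf("%.4f", consolidated$observed_mass),
    `Delta ppm` = sprintf("%.2f", consolidated$ppm_mean),
    Intensity = consolidated$intensity
  )
  if ("abundance_pct" %in% names(consolidated)) {
    out$`Abundance (%)` <- sprintf("%.3f", consolidated$abundance_pct)
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a search configuration file
#'
#' YAML key-value file with any of: `ppm_tolerance`, `cleanup_window_min`,
#' `adducts`, `insource_losses`, `crosslinks`, `modifications`,
#' `restrict_1_3_to_gmA`. Missing keys fall back to [search_config()]
#' defaults.
#'
#' @param path Path to the YAML file.
#' @return A `search_config` list.
#' @export
read_search_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("ppm_tolerance", "cleanup_window_min", "adducts",
             "insource_losses", "crosslinks", "modifications",
             "restrict_1_3_to_gmA")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(search_config, cfg)
}
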