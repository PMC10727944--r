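# Synthetic deconvoluted feature-list generator with known ground truth.

#' Simulate a deconvoluted LC-MS feature table
#'
#' Generates one feature per input structure at its theoretical neutral
#' monoisotopic mass perturbed by multiplicative Gaussian ppm noise, with
#' intensities proportional to the supplied relative abundances. Optionally
#' adds satellite peaks (sodium/potassium adducts and in-source GlcNAc
#' losses) sharing the parent retention time, and decoy features whose
#' masses are rejection-sampled to lie further than `decoy_clearance` times
#' the matching tolerance from every theoretical mass, so they can never be
#' identified by construction.
#'
#' Defaults emulate the published acquisition: total ion intensity around
#' 5e9 counts, mass errors of a few ppm and retention-time jitter of a few
#' hundredths of a minute.
#'
#' @param composition A tibble with columns `structure` and `abundance_pct`
#'   (summing to 100), optionally `rt_min`; or a named numeric vector of
#'   percentages.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param total_intensity Total intensity distributed over true features.
#' @param ppm_noise_sd Standard deviation of the mass error, ppm.
#' @param rt_jitter_sd Retention-time jitter, minutes.
#' @param adduct_rate,insource_rate Per-feature probability of emitting a
#'   Na/K adduct or in-source-loss satellite.
#' @param satellite_intensity_frac Range (length-2) of the satellite/parent
#'   intensity ratio.
#' @param n_decoys Number of decoy features.
#' @param decoy_mass_range Mass range (Da) decoys are drawn from.
#' @param decoy_clearance Minimum distance of a decoy from any theoretical
#'   mass, in multiples of `ppm_tolerance`.
#' @param ppm_tolerance Tolerance used for decoy clearance (match the search
#'   tolerance).
#' @param exclude_masses Optional extra theoretical masses (e.g. the full
#'   search database) decoys must also avoid.
#' @return A list with `features` (tibble `sample`, `id`, `mass`, `rt`,
#'   `intensity`), `truth` (tibble `structure`, `true_abundance_pct`,
#'   `feature_id`) and `satellites` (feature ids of satellite peaks).
#' @examples
#' sim <- simulate_features(c("gm-A" = 100), seed = 1, ppm_noise_sd = 0,
#'                          n_decoys = 0)
#' sim$features$mass  # 569.2433
#' @export
simulate_features <- function(composition,
                              seed,
                              total_intensity = 5e9,
                              ppm_noise_sd = 3,
                              rt_jitter_sd = 0.03,
                              adduct_rate = 0.10,
                              insource_rate = 0.05,
                              satellite_intensity_frac = c(0.02, 0.10),
                              n_decoys = 20,
                              decoy_mass_range = c(500, 2500),
                              decoy_clearance = 3,
                              ppm_tolerance = 10,
                              exclude_masses = NULL) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- tibble::tibble(structure = names(composition),
                                  abundance_pct = unname(composition))
  }
  stopifnot(is.data.frame(composition),
            all(c("structure", "abundance_pct") %in% names(composition)))
  if (abs(sum(composition$abundance_pct) - 100) > 1e-6) {
    stop("composition abundances must sum to 100", call. = FALSE)
  }
  withr::local_seed(as.integer(seed) %% .Machine$integer.max)

  n <- nrow(composition)
  true_mass <- muropeptide_mass(composition$structure)  # errors on bad names
  rt <- if ("rt_min" %in% names(composition) && !anyNA(composition$rt_min)) {
    composition$rt_min
  } else {
    seq(5, 15, length.out = n)
  }
  rt <- rt + stats::rnorm(n, 0, rt_jitter_sd)
  eps <- stats::rnorm(n, 0, ppm_noise_sd) * 1e-6
  features <- tibble::tibble(
    id = seq_len(n),
    mass = true_mass * (1 + eps),
    rt = pmax(rt, 0),
    intensity = composition$abundance_pct / 100 * total_intensity
  )
  truth <- tibble::tibble(structure = composition$structure,
                          true_abundance_pct = composition$abundance_pct,
                          feature_id = features$id)

  # satellite peaks: adducts (+Na/+K) and in-source GlcNAc loss
  sat_rows <- list()
  next_id <- n
  for (i in seq_len(n)) {
    if (stats::runif(1) < adduct_rate) {
      delta <- if (stats::runif(1) < 0.7) mass_constants[["adduct_Na"]] else mass_constants[["adduct_K"]]
      next_id <- next_id + 1L
      sat_rows[[length(sat_rows) + 1L]] <- tibble::tibble(
        id = next_id,
        mass = (true_mass[i] + delta) * (1 + stats::rnorm(1, 0, ppm_noise_sd) * 1e-6),
        rt = features$rt[i] + stats::rnorm(1, 0, rt_jitter_sd / 3),
        intensity = features$intensity[i] *
          stats::runif(1, satellite_intensity_frac[1], satellite_intensity_frac[2]))
    }
    if (stats::runif(1) < insource_rate && true_mass[i] > 300) {
      next_id <- next_id + 1L
      sat_rows[[length(sat_rows) + 1L]] <- tibble::tibble(
        id = next_id,
        mass = (true_mass[i] - 203.07937) * (1 + stats::rnorm(1, 0, ppm_noise_sd) * 1e-6),
        rt = features$rt[i] + stats::rnorm(1, 0, rt_jitter_sd / 3),
        intensity = features$intensity[i] *
          stats::runif(1, satellite_intensity_frac[1], satellite_intensity_frac[2]))
    }
  }
  satellites <- dplyr::bind_rows(sat_rows)

  # decoys: rejection-sampled away from every theoretical (and satellite
  # hypothesis) mass by > decoy_clearance x tolerance
  avoid <- sort(unique(c(true_mass, exclude_masses,
                         true_mass + mass_constants[["adduct_Na"]],
                         true_mass + mass_constants[["adduct_K"]],
                         true_mass - 203.07937)))
  decoys <- list()
  tries <- 0L
  while (length(decoys) < n_decoys && tries < 1000L * max(1L, n_decoys)) {
    tries <- tries + 1L
    m <- stats::runif(1, decoy_mass_range[1], decoy_mass_range[2])
    clear <- decoy_clearance * ppm_tolerance * 1e-6 * m
    if (all(abs(avoid - m) > clear)) {
      next_id <- next_id + 1L
      decoys[[length(decoys) + 1L]] <- tibble::tibble(
        id = next_id, mass = m,
        rt = stats::runif(1, 4, 16),
        intensity = stats::runif(1, 1e4, 1e6))
    }
  }
  if (length(decoys) < n_decoys) {
    stop("could not place ", n_decoys, " decoys clear of theoretical masses",
         call. = FALSE)
  }
  all_features <- dplyr::bind_rows(features, satellites,
                                   dplyr::bind_rows(decoys))
  all_features <- tibble::add_column(all_features,
                                     sample = "simulated", .before = 1L)
  list(features = all_features, truth = truth,
       satellites = if (nrow(satellites)) satellites$id else integer(0))
}

#' Write a simulated run to disk
#'
#' Writes the feature table in the simple CSV dialect and the ground truth
#' as `Structure,TrueAbundance`.
#'
#' @param sim Output of [simulate_features()].
#' @param features_path,truth_path Output paths.
#' @return `features_path`, invisibly.
#' @export
write_simulation <- function(sim, features_path, truth_path) {
  write_features(sim$features, features_path)
  readr::write_csv(
    tibble::tibble(Structure = sim$truth$structure,
                   TrueAbundance = sim$truth$true_abundance_pct),
    truth_path, progress = FALSE)
  invisible(features_path)
}
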