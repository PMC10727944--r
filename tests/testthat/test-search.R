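# ppm matching, satellite cleanup, replicate consolidation.

test_that("ppm differences follow the defining arithmetic", {
  expect_equal(ppm_diff(870.3707, 870.3707), 0)
  expect_equal(ppm_diff(870.3725, 870.3707), 2.068, tolerance = 1e-3)
  expect_equal(ppm_diff(870.3707 * (1 + 10e-6), 870.3707), 10,
               tolerance = 1e-9)
  expect_error(ppm_diff(1, -1))
})

test_that("features match the right structures at the defaults", {
  db <- build_theoretical_db(go_monomer_db())
  ft <- tibble::tibble(sample = "s", id = 1:3,
                       mass = c(569.2433, 600.0000, 1420.6194),
                       rt = c(6.3, 7.0, 8.6), intensity = c(1e6, 1e5, 5e5))
  m <- match_features(ft, db)
  hit1 <- m[m$feature_id == 1 & m$provenance == "direct", ]
  expect_true(any(grepl("gm-A", hit1$structure, fixed = TRUE)))
  expect_lt(abs(hit1$ppm[hit1$primary]), 1)
  expect_equal(m$provenance[m$feature_id == 2], "unidentified")
  hit3 <- m[m$feature_id == 3 & m$primary, ]
  expect_match(hit3$structure, "gm-AEJ_NH2=gm-A", fixed = TRUE)
})

test_that("the tolerance boundary is inclusive and beyond it never matches", {
  # property: against a brute-force all-pairs oracle over random masses
  withr::local_seed(20260926)
  db <- tibble::tibble(structure = sprintf("entry%02d", 1:25),
                       mass = sort(runif(25, 400, 3000)))
  db <- db[!duplicated(round(db$mass, 1)), ]
  for (rep in 1:5) {
    obs <- runif(40, 400, 3000)
    # add exact-boundary cases
    obs <- c(obs, db$mass[3] * (1 + 10e-6), db$mass[7] * (1 - 10e-6),
             db$mass[5] * (1 + 10.5e-6))
    ft <- tibble::tibble(sample = "s", id = seq_along(obs), mass = obs,
                         rt = seq_along(obs), intensity = 1)
    got <- match_features(ft, db, search_config(ppm_tolerance = 10))
    got_pairs <- got[got$provenance == "direct",
                     c("feature_id", "structure")]
    oracle <- do.call(rbind, lapply(seq_along(obs), function(i) {
      hits <- which(abs((obs[i] - db$mass) / db$mass * 1e6) <= 10)
      if (length(hits)) data.frame(feature_id = i, structure = db$structure[hits])
    }))
    expect_equal(nrow(got_pairs), NROW(oracle))
    if (NROW(oracle)) {
      expect_setequal(paste(got_pairs$feature_id, got_pairs$structure),
                      paste(oracle$feature_id, oracle$structure))
    }
  }
})

test_that("multi-match features assign intensity only to the primary match", {
  db <- tibble::tibble(structure = c("a", "b"),
                       mass = c(1000.000, 1000.005))
  ft <- tibble::tibble(sample = "s", id = 1, mass = 1000.001, rt = 5,
                       intensity = 100)
  m <- match_features(ft, db)
  expect_equal(nrow(m), 2)
  expect_equal(sum(m$primary), 1)
  expect_equal(m$structure[m$primary], "a")
  expect_equal(sum(m$intensity_assigned), 100)
})

test_that("satellites merge into the nearest parent within the cleanup window", {
  db <- build_theoretical_db("gm-A", crosslinks = character(0),
                             modifications = character(0))
  gm_a <- muropeptide_mass("gm-A")
  na_delta <- mass_constants[["adduct_Na"]]
  ft <- tibble::tibble(
    sample = "s", id = 1:3,
    mass = c(gm_a, gm_a + na_delta, gm_a + na_delta),
    rt = c(6.0, 6.2, 7.5),  # second satellite is outside the 0.5 min window
    intensity = c(100, 10, 7))
  m <- cleanup_satellites(match_features(ft, db), search_config())
  parent <- m[m$feature_id == 1 & m$primary, ]
  expect_equal(parent$intensity_assigned, 110)
  expect_equal(m$provenance[m$feature_id == 2], "adduct-merged")
  expect_equal(m$intensity_assigned[m$feature_id == 2], 0)
  expect_equal(m$provenance[m$feature_id == 3], "unidentified")

  # in-source GlcNAc loss merges too
  ft2 <- tibble::tibble(sample = "s", id = 1:2,
                        mass = c(gm_a, gm_a - 203.07937),
                        rt = c(6.0, 6.1), intensity = c(100, 5))
  m2 <- cleanup_satellites(match_features(ft2, db), search_config())
  expect_equal(m2$provenance[m2$feature_id == 2], "insource-merged")

  # no satellites: cleanup is the identity
  ft3 <- ft2[1, ]
  m3 <- match_features(ft3, db)
  expect_identical(cleanup_satellites(m3, search_config()), m3)
})

test_that("cleanup never creates matches without direct evidence", {
  db <- build_theoretical_db(c("gm-A", "gm-AE"), crosslinks = character(0),
                             modifications = character(0))
  # only a satellite-mass feature, no direct gm-A match anywhere
  ft <- tibble::tibble(sample = "s", id = 1,
                       mass = muropeptide_mass("gm-A") + mass_constants[["adduct_Na"]],
                       rt = 6, intensity = 10)
  m <- cleanup_satellites(match_features(ft, db), search_config())
  expect_equal(m$provenance, "unidentified")
})

test_that("total intensity is conserved through matching and cleanup", {
  withr::local_seed(7)
  db <- build_theoretical_db(go_monomer_db())
  sim <- simulate_features(sim_composition(), seed = 7,
                           exclude_masses = db$mass)
  total_in <- sum(sim$features$intensity)
  m <- match_features(sim$features, db)
  expect_equal(sum(m$intensity_assigned), total_in)
  m2 <- cleanup_satellites(m, search_config())
  expect_equal(sum(m2$intensity_assigned), total_in)
})

test_that("replicates consolidate to means with n-1 standard deviations", {
  db <- build_theoretical_db("gm-AEJ_NH2", crosslinks = character(0),
                             modifications = character(0))
  mk <- function(rt, intensity, sample) {
    tibble::tibble(sample = sample, id = 1,
                   mass = muropeptide_mass("gm-AEJ_NH2"),
                   rt = rt, intensity = intensity)
  }
  res <- pg_search(list(r1 = mk(5.28, 100, "r1"), r2 = mk(5.36, 300, "r2")),
                   db)
  cons <- tidy(res)
  expect_equal(cons$rt_mean, 5.32)
  expect_equal(cons$rt_sd, sd(c(5.28, 5.36)))
  expect_equal(round(cons$rt_sd, 2), 0.06)
  expect_equal(cons$intensity, 200)
  expect_equal(cons$n_replicates, 2)

  # single replicate: identity, sd undefined
  one <- pg_search(mk(5.28, 100, "r1"), db)
  expect_true(is.na(tidy(one)$rt_sd))
  expect_equal(tidy(one)$intensity, 100)
})

test_that("structures absent from a replicate contribute nothing to it", {
  db <- build_theoretical_db(c("gm-A", "gm-AE"), crosslinks = character(0),
                             modifications = character(0))
  r1 <- tibble::tibble(id = 1:2,
                       mass = muropeptide_mass(c("gm-A", "gm-AE")),
                       rt = c(6.3, 6.8), intensity = c(100, 50))
  r2 <- tibble::tibble(id = 1, mass = muropeptide_mass("gm-A"),
                       rt = 6.3, intensity = 200)
  cons <- tidy(pg_search(list(r1 = r1, r2 = r2), db))
  expect_equal(cons$intensity[grepl("gm-A$", cons$structure)], 150)
  expect_equal(cons$intensity[grepl("gm-AE", cons$structure)], 50)
  expect_equal(cons$n_replicates[grepl("gm-AE", cons$structure)], 1)
})
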