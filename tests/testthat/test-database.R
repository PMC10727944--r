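# Theoretical search-space construction.

test_that("monomer-space enumeration follows the per-position product space", {
  one <- enumerate_monomer_space(list("A"), lengths = 1)
  expect_equal(one$structure, "gm-A")

  two <- enumerate_monomer_space(list("A", c("E", "Q")), lengths = 2)
  expect_setequal(two$structure, c("gm-AE", "gm-AQ"))

  # full candidate space: 1 + 2 + 4 + 4*19 + 4*19 stems
  space <- go_candidate_space()
  expect_equal(nrow(space), 159)
  expect_equal(anyDuplicated(space$structure), 0)
  expect_equal(sum(space$stem_length == 4), 76)
  # pentapeptides end in an A-X dipeptide
  penta <- space$structure[space$stem_length == 5]
  stems <- lapply(penta, function(s) parse_muropeptide(s)$stems[[1]])
  expect_true(all(vapply(stems, function(s) s[4] == "A", logical(1))))
})

test_that("wildcard positions need a non-empty alphabet", {
  expect_error(
    enumerate_monomer_space(list("A", "X"), lengths = 2, x_alphabet = character(0)),
    "empty alphabet")
})

test_that("curated monomer databases load with computed masses", {
  path <- write_temp_csv(c("Structure", paste0(ref_composition()$structure[1:28])))
  db <- read_monomer_db(path)
  expect_equal(nrow(db), 28)
  expect_equal(db$mass, muropeptide_mass(db$structure))

  empty <- write_temp_csv("Structure")
  expect_equal(nrow(read_monomer_db(empty)), 0)

  disagree <- write_temp_csv(c("Structure,Mass", "gm-AE,700.0"))
  expect_warning(db2 <- read_monomer_db(disagree), "differing")
  expect_true(db2$mass_warning)
  expect_equal(db2$mass, 698.2859, tolerance = 1e-3)

  bad <- write_temp_csv(c("Structure", "gm-AB*"))
  expect_error(read_monomer_db(bad), "row 1")
})

test_that("1-3 dimer generation requires a DAP acceptor and a single-A donor", {
  db <- build_theoretical_db(c("gm-AEJ_NH2", "gm-AEJA", "gm-A"),
                             crosslinks = "1-3",
                             modifications = character(0), max_level = 2)
  dimers <- db[db$level == "dimer", ]
  expect_setequal(db_structures(dimers),
                  c("gm-AEJ_NH2=gm-A", "gm-AEJA=gm-A"))
  expect_lt(abs(dimers$mass[grepl("AEJ_NH2", dimers$structure)] - 1420.6194),
            1.5e-3)
  expect_lt(abs(dimers$mass[grepl("AEJA=", dimers$structure)] - 1492.6405),
            1.5e-3)

  none <- build_theoretical_db("gm-A", crosslinks = "1-3",
                               modifications = character(0))
  expect_equal(sum(none$level != "monomer"), 0)
})

test_that("4-3 self-dimers are generated", {
  db <- build_theoretical_db("gm-AEJA", crosslinks = "4-3",
                             modifications = character(0), max_level = 2)
  dimers <- db[db$level == "dimer", ]
  expect_equal(db_structures(dimers), "gm-AEJA=gm-AEJA")
  expect_lt(abs(dimers$mass - 1864.8047), 1.5e-3)
})

test_that("generated masses agree with brute-force monomer additivity", {
  db <- build_theoretical_db(go_monomer_db(), merge_isobaric = FALSE)
  w <- mass_constants[["water"]]
  recomputed <- vapply(db$structure, function(nm) {
    mp <- parse_muropeptide(nm)
    subs <- vapply(mp$stems, function(s)
      paste0("gm-", paste(s, collapse = "")), character(1))
    m <- sum(muropeptide_mass(subs)) - (length(subs) - 1) * w
    if (mp$anh) m <- m - mass_constants[["reduction"]] - w
    if (mp$deac) m <- m + mass_constants[["deacetylation"]]
    m
  }, numeric(1), USE.NAMES = FALSE)
  expect_lt(max(abs(db$mass - recomputed)), 1e-6)
})

test_that("database size is monotone in enabled rules and modifications", {
  mono <- go_monomer_db()
  sizes <- vapply(list(character(0), "1-3", c("1-3", "3-3"),
                       c("1-3", "3-3", "4-3")),
                  function(cl) nrow(build_theoretical_db(
                    mono, crosslinks = cl, modifications = character(0),
                    merge_isobaric = FALSE)),
                  numeric(1))
  expect_true(all(diff(sizes) >= 0))
  no_mods <- nrow(build_theoretical_db(mono, modifications = character(0),
                                       merge_isobaric = FALSE))
  all_mods <- nrow(build_theoretical_db(mono, merge_isobaric = FALSE))
  expect_gte(all_mods, no_mods)
})

test_that("disabling 1-3 removes exactly the single-A-donor entries", {
  mono <- go_monomer_db()
  with_13 <- build_theoretical_db(mono, merge_isobaric = FALSE)
  without_13 <- build_theoretical_db(mono, crosslinks = c("4-3", "3-3"),
                                     merge_isobaric = FALSE)
  removed <- setdiff(with_13$structure, without_13$structure)
  expect_true(all(with_13$has_single_A_donor[match(removed, with_13$structure)]))
  kept_single_A <- without_13$structure[without_13$has_single_A_donor]
  expect_length(kept_single_A, 0)
  # nothing else changes
  expect_setequal(without_13$structure,
                  with_13$structure[!with_13$has_single_A_donor])
})

test_that("restricting 1-3 donors to gm-A keeps the gm-A moiety in every 1-3 dimer", {
  mono <- c("gm-AEJA", "gm-AEJ", "gm-A")
  db <- build_theoretical_db(mono, crosslinks = "1-3",
                             restrict_1_3_to_gmA = TRUE)
  dimers <- db_structures(db[db$level == "dimer", ])
  expect_true(all(grepl("=gm-A( |$)", dimers)))
  expect_false(any(grepl("=gm-A \\(-Ac\\)", dimers)))
})

test_that("isobaric entries are merged with all names retained", {
  # gm-AEJ_NH2=gm-AEJA (4-3) and gm-AEJA=gm-AEJ_NH2 (3-3) are mass-identical
  db <- build_theoretical_db(c("gm-AEJ_NH2", "gm-AEJA"),
                             crosslinks = c("4-3", "3-3"),
                             modifications = character(0), max_level = 2)
  merged <- db[grepl("gm-AEJ_NH2=gm-AEJA", db$structure, fixed = TRUE), ]
  expect_equal(nrow(merged), 1)
  expect_true(merged$ambiguous)
  expect_setequal(strsplit(merged$structure, "|", fixed = TRUE)[[1]],
                  c("gm-AEJ_NH2=gm-AEJA", "gm-AEJA=gm-AEJ_NH2"))
  unmerged <- build_theoretical_db(c("gm-AEJ_NH2", "gm-AEJA"),
                                   crosslinks = c("4-3", "3-3"),
                                   modifications = character(0),
                                   max_level = 2, merge_isobaric = FALSE)
  expect_gt(nrow(unmerged), nrow(db))
})

test_that("database export round-trips through the documented CSV layout", {
  db <- build_theoretical_db(tiny_monomers(), max_level = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_theoretical_db(db, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(names(back),
               c("Structure", "Mass", "Level", "CrosslinkTypes", "Flags"))
  expect_equal(nrow(back), nrow(db))
  expect_equal(as.numeric(back$Mass), db$mass, tolerance = 1e-4)
})
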