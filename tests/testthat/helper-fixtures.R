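# Shared fixtures built in code.

# a minimal monomer set covering 1-3, 3-3 and 4-3 donor/acceptor chemistry
tiny_monomers <- function() c("gm-AEJ_NH2", "gm-AEJA", "gm-AEJ", "gm-A")

ref_composition <- function() go_reference_composition()

# reference abundances renormalised to exactly 100 (simulation input)
sim_composition <- function(sample = "wt_stat") {
  comp <- go_reference_abundances(sample)
  comp$abundance_pct <- comp$abundance_pct / sum(comp$abundance_pct) * 100
  comp
}

# abundance recovered for a truth structure from a possibly isobaric-merged
# consolidated table
recovered_pct <- function(consolidated, structure) {
  hit <- vapply(strsplit(consolidated$structure, "|", fixed = TRUE),
                function(s) structure %in% s, logical(1))
  if (any(hit)) sum(consolidated$abundance_pct[hit]) else 0
}

write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
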