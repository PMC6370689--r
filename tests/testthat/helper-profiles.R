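# hand-built residue profiles for rule-level tests

fake_profile <- function(kinds, positions, residues, role = "class1_alpha") {
  df <- data.frame(site_kind = kinds, instance = 1L, ref_id = "ref",
                   ref_position = seq_along(kinds),
                   ref_residue = residues,
                   query_position = positions, residue = residues,
                   flag = "", stringsAsFactors = FALSE)
  structure(df, query_id = "fake", role = role, unalignable = FALSE,
            class = c("residue_profile", "data.frame"))
}

# beta profile with metal sites 1-8 and an optional tyrosyl-radical residue
fake_beta_profile <- function(metals, tyr = NA_character_) {
  kinds <- paste0("metal_", seq_along(metals))
  pos <- seq(10L, by = 10L, length.out = length(metals))
  pos[is.na(metals)] <- NA_integer_
  if (!is.na(tyr)) {
    kinds <- c("tyr_radical", kinds)
    metals <- c(tyr, metals)
    pos <- c(5L, pos)
  }
  fake_profile(kinds, pos, metals, role = "class1_beta")
}
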