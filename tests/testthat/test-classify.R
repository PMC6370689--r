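test_that("metal-pattern matching reproduces the published examples", {
  pats <- rnr_patterns()
  # the Cyano SP pattern matches only its own row in full mode
  expect_identical(match_metal_pattern(c("E","E","H","E","E","H","D","D"),
                                       pats, "full"), "CyanoSP")
  # first-sphere mode against the five characterized representatives:
  # exactly the Ic and Id rows
  expect_setequal(
    match_metal_pattern(c("E","E","H","E","E","H"),
                        reference_patterns(rnr_references()),
                        "first_sphere"),
    c("Ic", "Id"))
  # the Ia representative's own pattern resolves uniquely to NrdBg
  # (site 7 Ser excludes every other row)
  expect_identical(match_metal_pattern(c("D","E","H","E","E","H","S","D"),
                                       pats, "full"), "NrdBg")
  # missing or masked residues never satisfy a rule
  expect_length(match_metal_pattern(c("E","E","H","E","E","H","D",NA),
                                    pats, "full"), 0L)
  expect_length(match_metal_pattern(c("E","E","H","E","E","H","X","D"),
                                    pats, "full"), 0L)
})

test_that("pattern matching agrees with the brute-force membership oracle", {
  pats <- rnr_patterns()
  pool <- c("D", "E", "H", "S", "M", "I", "V", "Q", "R", "C", "K", "P",
            "A", "W", "Y", "G")
  set.seed(201)
  for (i in 1:1000) {
    res <- sample(pool, 8, replace = TRUE)
    expect_identical(sort(match_metal_pattern(res, pats, "full")),
                     sort(oracle_table4_match(res)),
                     info = paste(res, collapse = ""))
    expect_identical(sort(match_metal_pattern(res, pats, "first_sphere")),
                     sort(oracle_table4_match(res, TRUE)),
                     info = paste(res, collapse = ""))
  }
})

test_that("NrdBz splits on the tyrosyl radical residue", {
  expect_identical(split_nrdbz(fake_beta_profile(rep("E", 8), tyr = "Y")),
                   "NrdBza")
  for (r in c("F", "L", "V")) {
    expect_identical(split_nrdbz(fake_beta_profile(rep("E", 8), tyr = r)),
                     "NrdBzc")
  }
  expect_identical(split_nrdbz(fake_beta_profile(rep("E", 8), tyr = "W")),
                   "unassigned")
  expect_identical(split_nrdbz(fake_beta_profile(rep("E", 8))), "unassigned")
  # generator round trip
  expect_identical(split_nrdbz(extract_profile(
    make_beta("NrdBza", noise = 0, seed = 1)$sequence,
    rnr_references(), "class1_beta")), "NrdBza")
  expect_identical(split_nrdbz(extract_profile(
    make_beta("NrdBzc", noise = 0, seed = 1)$sequence,
    rnr_references(), "class1_beta")), "NrdBzc")
})

test_that("NrdF splits on carboxylate conservation at sites 2, 4, 5", {
  mk <- function(s2, s4, s5) {
    fake_beta_profile(c("D", s2, "H", s4, s5, "H", "M", "D"))
  }
  expect_identical(split_nrdf(mk("E", "E", "E")), "NrdFb")
  expect_identical(split_nrdf(mk("D", "E", "D")), "NrdFb")
  expect_identical(split_nrdf(mk("V", "P", "K")), "NrdFe")
  expect_identical(split_nrdf(mk("E", "P", "K")), "unassigned")
  expect_identical(split_nrdf(mk("V", "E", "K")), "unassigned")
  expect_identical(split_nrdf(fake_beta_profile(
    c("D", NA, "H", "E", "E", "H", "M", "D"))), "unassigned")
  # the two split rules partition every input into exactly one outcome
  set.seed(202)
  for (i in 1:50) {
    p <- fake_beta_profile(sample(c("D","E","V","P","K","M"), 8, TRUE),
                           tyr = sample(c("Y","F","L","V","W","A"), 1))
    expect_length(intersect(split_nrdf(p),
                            c("NrdFb", "NrdFe", "unassigned")), 1L)
    expect_length(intersect(split_nrdbz(p),
                            c("NrdBza", "NrdBzc", "unassigned")), 1L)
  }
})

test_that("class calls follow beta-site and tyrosine-pair evidence", {
  refs <- rnr_references()
  b <- make_beta("NrdBg", noise = 0, seed = 31)
  expect_identical(call_class(extract_profiles(b$sequence, refs)),
                   "class1_beta")
  a <- make_alpha(noise = 0.03, seed = 31)
  expect_identical(call_class(extract_profiles(a$sequence, refs)),
                   "class1_alpha")
  # a single edit to the tyrosine pair flips alpha to Class II
  a2 <- make_alpha(noise = 0.03, seed = 31, radical_pair = FALSE)
  expect_identical(call_class(extract_profiles(a2$sequence, refs)),
                   "class2")
  # unrelated protein: unassigned is a value, not an error
  set.seed(33)
  junk <- stats::setNames(paste(sample(rnrclassify:::AA20, 300, TRUE),
                                collapse = ""), "junk")
  expect_identical(call_class(extract_profiles(junk, refs)), "unassigned")
})

test_that("subclass calls preserve unique, ambiguous, novel and absent cases", {
  pats <- rnr_patterns()
  # unique match, Ia_presumed label preserved
  res <- call_subclass(fake_beta_profile(c("D","E","H","E","E","H","Q","D")),
                       pats)
  expect_identical(res$matched_groups, "NrdBh")
  expect_identical(res$subclass_call, "Ia_presumed")
  # overlapping rows: all reported, call left unassigned
  res2 <- call_subclass(fake_beta_profile(c("D","E","H","E","E","H","E","D")),
                        pats)
  expect_setequal(res2$matched_groups, c("NrdBh", "NrdBn", "NrdBza"))
  expect_identical(res2$subclass_call, "unassigned")
  # complete pattern matching nothing: novel subclass candidate
  res3 <- call_subclass(fake_beta_profile(c("D","E","H","E","E","H","W","D")),
                        pats)
  expect_identical(res3$subclass_call, "novel")
  expect_length(res3$matched_groups, 0L)
  # incomplete profile: unassigned, never "novel"
  res4 <- call_subclass(fake_beta_profile(c("D","E","H","E","E","H","S",NA)),
                        pats)
  expect_identical(res4$subclass_call, "unassigned")
  # determinism: identical profiles give identical results
  p <- fake_beta_profile(c("E","E","H","E","E","H","D","D"))
  expect_identical(call_subclass(p, pats), call_subclass(p, pats))
})

test_that("end-to-end classification recovers each generated group", {
  pats <- rnr_patterns()
  for (g in c("NrdBg", "NrdBzc", "NrdBi", "NrdFe", "CyanoSP")) {
    res <- classify_rnr(make_beta(g, noise = 0, seed = 41)$sequence)
    expect_identical(res$class_call, "class1_beta")
    expect_true(g %in% res$matched_groups, info = g)
    if (length(res$matched_groups) == 1L) {
      expect_identical(res$subclass_call, pats[[g]]$subclass, info = g)
    }
  }
})

test_that("subunit pairing applies the exclusion rule", {
  alphas <- data.frame(alpha_id = c("a1", "a2", "a3"),
                       genome_id = c("g1", "g2", "g3"))
  betas <- data.frame(beta_id = c("b1", "b2a", "b2b"),
                      genome_id = c("g1", "g2", "g2"),
                      subclass_call = c("Ia", "If", "If"))
  p <- pair_subunits(alphas, betas)
  expect_identical(p$status, c("paired", "ambiguous", "unpaired"))
  expect_identical(p$subclass_call[1], "Ia")   # inherits its beta's call
  expect_identical(p$excluded, c(FALSE, TRUE, TRUE))
  expect_identical(p$beta_ids[2], "b2a,b2b")
})
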