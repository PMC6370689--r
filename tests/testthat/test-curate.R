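test_that("dereplication removes duplicates and substrings", {
  expect_identical(names(dereplicate(c(a = "ACDEF", b = "CDE"))), "a")
  expect_length(dereplicate(c(x = "ACDEF", y = "ACDEF")), 1L)
  # brute-force all-pairs oracle on random sets
  set.seed(301)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "D"), sample(3:8, 1), TRUE), collapse = ""),
      character(1))
    names(seqs) <- sprintf("s%02d", seq_len(n))
    got <- dereplicate(seqs)
    # oracle: s is dropped iff it is a substring (or duplicate) of a longer
    # (or lexicographically earlier equal) retained sequence; compute by
    # iterative elimination
    drop <- rep(FALSE, n)
    ord <- order(-nchar(seqs), names(seqs))
    for (i in seq_len(n)) {
      for (j in ord) {
        if (j == i || drop[j]) next
        longer <- nchar(seqs[j]) > nchar(seqs[i]) ||
          (seqs[j] == seqs[i] && names(seqs)[j] < names(seqs)[i])
        if (longer && grepl(seqs[i], seqs[j], fixed = TRUE)) {
          drop[i] <- TRUE
          break
        }
      }
    }
    expect_setequal(names(got), names(seqs)[!drop])
  }
  # no surviving sequence is a substring of another survivor
  out <- dereplicate(c(a = "ACDACD", b = "CDA", c = "DAC", d = "AC"))
  for (i in seq_along(out)) {
    for (j in seq_along(out)) {
      if (i != j) expect_false(grepl(out[i], out[j], fixed = TRUE))
    }
  }
})

test_that("large planted insertions are excised, small ones kept", {
  refs <- rnr_references()
  r <- refs[["NrdB_Ia_syn"]]
  set.seed(302)
  insert <- paste(sample(rnrclassify:::AA20, 120, TRUE), collapse = "")
  # insert between the radical site region and metal_4 (positions 150/151)
  q <- paste0(substr(r$sequence, 1, 150), insert,
              substr(r$sequence, 151, 375))
  out <- remove_inteins(q, r)
  expect_false(out$flagged)
  expect_equal(nrow(out$excised), 1L)
  expect_identical(out$sequence, r$sequence)
  # below-threshold insertion is untouched
  q2 <- paste0(substr(r$sequence, 1, 150), substr(insert, 1, 10),
               substr(r$sequence, 151, 375))
  out2 <- remove_inteins(q2, r)
  expect_identical(out2$sequence, q2)
  expect_equal(nrow(out2$excised), 0L)
})

test_that("excision refuses to cut at an annotated site", {
  refs <- rnr_references()
  r <- refs[["NrdB_Ia_syn"]]
  set.seed(303)
  insert <- paste(sample(rnrclassify:::AA20, 120, TRUE), collapse = "")
  # insertion boundary directly after metal_4 (E205)
  q <- paste0(substr(r$sequence, 1, 205), insert,
              substr(r$sequence, 206, 375))
  out <- remove_inteins(q, r)
  expect_true(out$flagged)
  expect_identical(out$sequence, q)
  expect_equal(nrow(out$excised), 0L)
})

test_that("excision never changes extracted site residues when unflagged", {
  refs <- rnr_references()
  r <- refs[["NrdB_Ia_syn"]]
  set.seed(304)
  for (rep in 1:8) {
    at <- sample(c(20:80, 130:195, 250:330), 1)
    len <- sample(c(55, 90, 140), 1)
    insert <- paste(sample(rnrclassify:::AA20, len, TRUE), collapse = "")
    q <- paste0(substr(r$sequence, 1, at), insert,
                substr(r$sequence, at + 1, 375))
    out <- remove_inteins(q, r)
    if (!out$flagged && nrow(out$excised) > 0) {
      before <- extract_profile(stats::setNames(q, "q"), list(r),
                                "class1_beta")
      after <- extract_profile(stats::setNames(out$sequence, "q"), list(r),
                               "class1_beta")
      present <- !is.na(before$residue)
      expect_identical(after$residue[present], before$residue[present])
    }
  }
})

test_that("functional filtering keeps references and drops knockouts", {
  refs <- rnr_references()
  r <- refs[["NrdB_Ia_syn"]]
  good <- vapply(1:3, function(s)
    unname(make_beta("NrdBg", noise = 0, seed = s)$sequence), character(1))
  names(good) <- paste0("good", 1:3)
  bad <- vapply(1:3, function(s)
    unname(make_beta("NrdBg", noise = 0, seed = s,
                     knockout = "metal_3")$sequence), character(1))
  names(bad) <- paste0("bad", 1:3)
  kept <- filter_functional(c(good, bad, ref = r$sequence))
  expect_setequal(names(kept), c(names(good), "ref"))
  rep_tab <- attr(kept, "report")
  expect_identical(rep_tab$functional[match(names(bad), rep_tab$id)],
                   rep(FALSE, 3))
  # alpha role: catalytic knockout removed, intact alpha kept
  a_ok <- make_alpha(noise = 0, seed = 7)$sequence
  a_ko <- make_alpha(noise = 0, seed = 7, knockout = "catalytic_cys")$sequence
  kept_a <- filter_functional(c(ok = unname(a_ok), ko = unname(a_ko)),
                              role = "class1_alpha")
  expect_identical(names(kept_a), "ok")
})

test_that("region-of-interest trimming follows the anchor intervals", {
  refs <- rnr_references()
  beta_ref <- refs[["NrdB_Ia_syn"]]
  alpha_ref <- refs[["NrdA_Ia_syn"]]
  # inclusive interval arithmetic on the anchors themselves
  expect_equal(nchar(trim_roi(beta_ref$sequence, "beta")), 309L)    # 356-48+1
  expect_equal(nchar(trim_roi(alpha_ref$sequence, "combined")), 189L) # 625-437+1
  expect_equal(nchar(trim_roi(alpha_ref$sequence, "alpha_only")),
               nchar(alpha_ref$sequence) - 224L)
  # idempotence
  for (mode in c("beta", "combined")) {
    seq0 <- if (mode == "beta") make_beta("NrdBg", 0.05, seed = 11)$sequence
            else alpha_ref$sequence
    t1 <- trim_roi(seq0, mode)
    expect_identical(trim_roi(t1, mode), t1)
  }
  # planted N-terminal extension (ATP-cone mimic) removed in alpha-only mode
  set.seed(305)
  ext <- paste(sample(rnrclassify:::AA20, 100, TRUE), collapse = "")
  a <- make_alpha(noise = 0, seed = 12)$sequence
  extended <- paste0(ext, unname(a))
  trimmed <- trim_roi(extended, "alpha_only")
  expect_identical(trimmed, trim_roi(unname(a), "alpha_only"))
  expect_false(startsWith(trimmed, substr(ext, 1, 20)))
  # unalignable-in-ROI signal
  expect_identical(trim_roi("MKL", "beta"), "")
})

test_that("greedy clustering is a deterministic partition", {
  seqs <- c(a = "ACDEFGHIKL", b = "ACDEFGHIKL", c = "ACDEFGHIKL")
  cl <- greedy_cluster(seqs, 0.9, coverage = 1)
  expect_equal(length(unique(cl$representative)), 1L)
  expect_setequal(cl$member, names(seqs))
  # partition property on random sets, plus determinism
  set.seed(306)
  for (rep in 1:5) {
    s <- random_cluster_set(6)
    cl1 <- greedy_cluster(s, 0.75)
    cl2 <- greedy_cluster(s, 0.75)
    expect_identical(cl1, cl2)
    expect_setequal(cl1$member, names(s))
    expect_equal(anyDuplicated(cl1$member), 0L)
    # members meet the threshold against their representative
    for (i in seq_len(nrow(cl1))) {
      if (cl1$member[i] != cl1$representative[i]) {
        expect_gte(cl1$identity[i], 0.75)
      }
    }
  }
  # passthrough mode: singletons, nothing collapsed
  pt <- greedy_cluster(seqs, 0.9, passthrough = TRUE)
  expect_identical(pt$representative, names(seqs))
})

test_that("a 72%-identity pair splits between the 70% and 75% thresholds", {
  set.seed(307)
  base <- sample(rnrclassify:::AA20, 100, TRUE)
  mut <- base
  idx <- sample(100, 28)
  for (i in idx) mut[i] <- sample(setdiff(rnrclassify:::AA20, mut[i]), 1)
  pair <- c(p1 = paste(base, collapse = ""), p2 = paste(mut, collapse = ""))
  expect_equal(percent_identity(pair[[1]], pair[[2]]), 0.72)
  cl70 <- greedy_cluster(pair, 0.70)
  expect_equal(length(unique(cl70$representative)), 1L)
  cl75 <- greedy_cluster(pair, 0.75)
  expect_equal(length(unique(cl75$representative)), 2L)
})

test_that("greedy clustering matches the independent oracle", {
  set.seed(308)
  for (rep in 1:15) {
    seqs <- random_cluster_set(sample(3:8, 1))
    thr <- sample(c(0.7, 0.75, 0.8), 1)
    got <- greedy_cluster(seqs, thr)
    ora <- oracle_greedy_cluster(seqs, thr)
    gmap <- stats::setNames(got$representative, got$member)
    expect_identical(as.character(gmap[names(ora)]), as.character(ora),
                     info = paste("rep", rep))
  }
})
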