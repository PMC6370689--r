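# Seeded synthetic-data generators. Each generator plants the diagnostic
# signal the pipeline keys on (site residues at reference positions,
# consecutive tyrosine pair, genome adjacency) inside mutable background,
# and returns the ground truth alongside, so every downstream stage can be
# tested for exact recovery without external downloads.

# substitute a fraction `rate` of the unprotected positions with a
# different uniformly chosen residue
mutate_background <- function(chars, rate, protected = integer(0)) {
  free <- setdiff(seq_along(chars), protected)
  hit <- free[stats::runif(length(free)) < rate]
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1)
  }
  chars
}

# default tyrosyl-radical-site residue per group: Tyr where the subclass
# carries (or conserves) it, Phe for the Ic split, and a non-aromatic
# placeholder for the Cyano SP clade, which has lost the site
group_tyr_radical <- function(group) {
  switch(group,
         NrdBzc = "F",
         CyanoSP = "A",
         "Y")
}

#' Generate a synthetic Class I beta subunit
#'
#' Starts from the bundled Ia beta scaffold, substitutes background
#' positions at `noise` rate (planted sites are never touched unless
#' `knockout` names them), and writes the metal-site residues of the
#' requested group pattern (sampled uniformly from each allowed set) plus a
#' group-appropriate tyrosyl-radical-site residue at the scaffold's
#' annotated positions.
#'
#' @param group Group pattern name (see [rnr_patterns()]).
#' @param noise Background substitution rate outside planted sites
#'   (default 0.05).
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @param knockout Character vector of site kinds to corrupt (set to a
#'   residue violating the rules) -- separates "divergent" from
#'   "non-functional" in tests.
#' @param id Sequence id for the output.
#' @param refs,patterns Reference set and pattern table (default bundled).
#' @return List with `sequence` (named character), `group`, and `truth`
#'   (data.frame site_kind/position/residue of every planted site).
#' @export
make_beta <- function(group, noise = 0.05, seed = NULL,
                      knockout = character(0), id = paste0(group, "_synth"),
                      refs = rnr_references(), patterns = rnr_patterns()) {
  if (!group %in% names(patterns)) stopf("unknown group '%s'", group)
  scaffold <- refs_by_role(refs, "class1_beta")
  scaffold <- scaffold[[which(vapply(scaffold, `[[`, "", "subclass") == "Ia")]]
  pat <- patterns[[group]]
  with_seed(seed, {
    chars <- strsplit(scaffold$sequence, "", fixed = TRUE)[[1]]
    sitepos <- vapply(c(METAL_SITES, "tyr_radical"), function(k)
      site_position(scaffold, k), integer(1))
    chars <- mutate_background(chars, noise, protected = sitepos)
    for (k in 1:8) {
      chars[sitepos[[paste0("metal_", k)]]] <- sample(pat$allowed[[k]], 1)
    }
    chars[sitepos[["tyr_radical"]]] <- group_tyr_radical(group)
    for (k in knockout) {
      p <- sitepos[[k]]
      if (is.na(p)) stopf("unknown knockout site '%s'", k)
      chars[p] <- "G"  # glycine: allowed at no metal site in any group
    }
    truth <- data.frame(site_kind = names(sitepos),
                        position = unname(sitepos),
                        residue = chars[sitepos],
                        stringsAsFactors = FALSE)
    list(sequence = stats::setNames(paste(chars, collapse = ""), id),
         group = group, truth = truth)
  })
}

#' Generate a synthetic Class I alpha (or Class II-like) subunit
#'
#' Starts from the bundled Ia alpha scaffold, keeps the catalytic sites
#' intact, and plants the consecutive radical-transfer tyrosine pair
#' (`radical_pair = TRUE`) or mutates the second tyrosine to Phe
#' (`radical_pair = FALSE`), turning the sequence into a Class II mimic
#' under the class rules.
#'
#' @param radical_pair Plant the YY pair (default TRUE).
#' @param knockout Site kinds to corrupt (as in [make_beta()]).
#' @inheritParams make_beta
#' @return List with `sequence`, `truth`.
#' @export
make_alpha <- function(noise = 0.05, seed = NULL, radical_pair = TRUE,
                       knockout = character(0), id = "alpha_synth",
                       refs = rnr_references()) {
  scaffold <- refs_by_role(refs, "class1_alpha")
  scaffold <- scaffold[[which(vapply(scaffold, `[[`, "", "subclass") == "Ia")]]
  with_seed(seed, {
    chars <- strsplit(scaffold$sequence, "", fixed = TRUE)[[1]]
    sitepos <- scaffold$sites$position
    names(sitepos) <- paste(scaffold$sites$site_kind,
                            stats::ave(seq_along(sitepos),
                                       scaffold$sites$site_kind,
                                       FUN = seq_along))
    chars <- mutate_background(chars, noise, protected = sitepos)
    if (!radical_pair) {
      p2 <- scaffold$sites$position[
        scaffold$sites$site_kind == "radical_transfer_tyr2"]
      chars[p2] <- "F"
    }
    for (k in knockout) {
      p <- scaffold$sites$position[scaffold$sites$site_kind == k][1]
      if (is.na(p)) stopf("unknown knockout site '%s'", k)
      chars[p] <- "G"
    }
    truth <- data.frame(site_kind = scaffold$sites$site_kind,
                        position = scaffold$sites$position,
                        residue = chars[scaffold$sites$position],
                        stringsAsFactors = FALSE)
    list(sequence = stats::setNames(paste(chars, collapse = ""), id),
         truth = truth)
  })
}

#' Generate sequence families at controlled identities
#'
#' Families descend from a common root: family ancestors diverge from the
#' root so that between-family identity is near `between_identity`, and
#' members diverge from their ancestor so that within-family identity is
#' near `within_identity` (substitution-only evolution; realized
#' identities land within a few percentage points of the targets).
#'
#' @param n_families Number of families.
#' @param members_per Members per family.
#' @param within_identity,between_identity Target pairwise identities.
#' @param length Sequence length in residues.
#' @param seed Integer seed.
#' @return List with `seqs` (named character vector) and `families` (named
#'   character vector of family labels per sequence id).
#' @export
make_family_set <- function(n_families = 3, members_per = 4,
                            within_identity = 0.95,
                            between_identity = 0.40,
                            length = 300, seed = NULL) {
  stopifnot(within_identity > between_identity)
  with_seed(seed, {
    root <- strsplit(random_residues(length), "", fixed = TRUE)[[1]]
    # two lineages each diverging at rate r from a shared ancestor agree at
    # a position with probability (1-r)^2 + r^2/19: both untouched, or both
    # substituted convergently (uniform over the 19 alternatives). Invert
    # for the rate whose expected identity hits the target.
    rate_for <- function(target) {
      u <- (1 + sqrt(1 - 20 * (1 - 19 * target))) / 20
      1 - u
    }
    r_within <- rate_for(within_identity)
    r_between <- rate_for(between_identity)
    seqs <- character(0)
    fams <- character(0)
    for (f in seq_len(n_families)) {
      anc <- mutate_background(root, r_between)
      for (m in seq_len(members_per)) {
        id <- sprintf("fam%d_m%d", f, m)
        seqs[[id]] <- paste(mutate_background(anc, r_within), collapse = "")
        fams[[id]] <- sprintf("fam%d", f)
      }
    }
    list(seqs = seqs, families = fams)
  })
}

#' Generate a toy phage genome with a hidden beta subunit
#'
#' Orders proteins along a genome: annotated filler genes, an annotated
#' alpha-subunit gene, a hidden (hypothetical) beta subunit at a controlled
#' gene offset downstream, and hypothetical decoys inside and outside the
#' discovery length window. Defaults mirror the discovery conditions: the
#' window 200-500 aa contains four hypothetical candidates (three decoys
#' plus the true beta), all on the forward strand with the beta directly
#' downstream of the alpha.
#'
#' @param seed Integer seed.
#' @param beta_group Pattern group of the planted beta.
#' @param beta_offset Gene offset of the beta from the alpha (+1 = directly
#'   downstream).
#' @param n_decoys_in Window-passing hypothetical decoys.
#' @param n_decoys_out Hypothetical decoys outside the length window.
#' @param noise Background substitution rate for planted subunits.
#' @param beta_strand Strand of the planted beta (default same as alpha,
#'   "+").
#' @param beta_length Optional override of the planted beta length
#'   (truncates/pads; used to place the true beta outside the window).
#' @param refs,patterns Reference set and pattern table.
#' @return List with `genome` (a [genome_protein_set()]) and `truth`
#'   (alpha_id, beta_id, beta_group, site table).
#' @export
make_genome <- function(seed = NULL, beta_group = "CyanoSP",
                        beta_offset = 1L, n_decoys_in = 3L,
                        n_decoys_out = 2L, noise = 0.05,
                        beta_strand = "+", beta_length = NULL,
                        refs = rnr_references(), patterns = rnr_patterns()) {
  with_seed(seed, {
    alpha <- make_alpha(noise = noise, id = "alpha_gene", refs = refs)
    beta <- make_beta(beta_group, noise = noise, id = "beta_gene",
                      refs = refs, patterns = patterns)
    bseq <- unname(beta$sequence)
    if (!is.null(beta_length)) {
      bseq <- if (beta_length <= nchar(bseq)) substr(bseq, 1, beta_length)
              else paste0(bseq, random_residues(beta_length - nchar(bseq)))
    }
    decoy_in <- vapply(seq_len(n_decoys_in), function(i)
      random_residues(sample(200:500, 1)), character(1))
    decoy_out <- vapply(seq_len(n_decoys_out), function(i)
      random_residues(sample(c(80:199, 501:650), 1)), character(1))
    filler <- vapply(1:2, function(i)
      random_residues(sample(100:600, 1)), character(1))

    # assemble gene order: filler, alpha, (offset-1 decoys), beta, rest
    ids <- c("gene_a", "alpha_gene")
    seqs <- c(filler[1], unname(alpha$sequence))
    status <- c("annotated", "annotated")
    strand <- c("+", "+")
    pool_ids <- c(paste0("decoy_in_", seq_len(n_decoys_in)),
                  paste0("decoy_out_", seq_len(n_decoys_out)))
    pool_seqs <- c(decoy_in, decoy_out)
    pool_strand <- rep("+", length(pool_seqs))
    k <- 0L
    for (g in seq_len(beta_offset - 1L)) {
      k <- k + 1L
      ids <- c(ids, pool_ids[k]); seqs <- c(seqs, pool_seqs[k])
      status <- c(status, "hypothetical"); strand <- c(strand, pool_strand[k])
    }
    ids <- c(ids, "beta_gene"); seqs <- c(seqs, bseq)
    status <- c(status, "hypothetical"); strand <- c(strand, beta_strand)
    while (k < length(pool_ids)) {
      k <- k + 1L
      ids <- c(ids, pool_ids[k]); seqs <- c(seqs, pool_seqs[k])
      status <- c(status, "hypothetical"); strand <- c(strand, pool_strand[k])
    }
    ids <- c(ids, "gene_z"); seqs <- c(seqs, filler[2])
    status <- c(status, "annotated"); strand <- c(strand, "+")

    len <- nchar(seqs)
    start <- integer(length(seqs))
    pos <- 1L
    for (i in seq_along(seqs)) {
      start[i] <- pos
      pos <- pos + 3L * len[i] + 50L
    }
    genome <- genome_protein_set("synthetic_phage", data.frame(
      protein_id = ids, sequence = seqs, start = start,
      end = start + 3L * len - 1L, strand = strand, status = status,
      stringsAsFactors = FALSE))
    list(genome = genome,
         truth = list(alpha_id = "alpha_gene", beta_id = "beta_gene",
                      beta_group = beta_group, beta_sites = beta$truth))
  })
}
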