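# Class and subclass calls from residue profiles.
#
# Class logic: a query showing the full beta-subunit diagnostic complement
# (first-sphere metal ligands) is a Class I beta; a query showing the shared
# alpha/Class II catalytic complement is a Class I alpha if it also carries
# the consecutive radical-transfer tyrosine pair, otherwise Class II.
# Subclass logic: exact set-membership of the eight metal-site residues
# against the group-level pattern table; NrdBz and NrdF groups are split by
# the tyrosyl-radical-site and carboxylate rules.

CLASS_CALLS <- c("class1_alpha", "class1_beta", "class2", "unassigned")

#' Classification rule configuration
#'
#' @param essential_beta_sites Metal sites a query must display (with a
#'   residue allowed for that site in at least one group pattern) to be
#'   called a Class I beta; default the six first-sphere ligands.
#' @param patterns `subclass_patterns` used for the per-site allowed unions.
#' @return List of class `classify_params`.
#' @export
classify_params <- function(essential_beta_sites = FIRST_SPHERE,
                            patterns = rnr_patterns()) {
  structure(list(essential_beta_sites = essential_beta_sites,
                 patterns = patterns),
            class = "classify_params")
}

# Union of allowed residues per metal site across all group patterns.
allowed_union <- function(patterns) {
  lapply(1:8, function(k)
    sort(unique(unlist(lapply(patterns, function(p) p$allowed[[k]])))))
}

# Does the profile satisfy a beta site: mapped, and residue allowed for
# that site in some group? (X never satisfies a residue rule.)
beta_site_ok <- function(profile, kind, unions) {
  r <- profile_residue(profile, kind)
  k <- as.integer(sub("metal_", "", kind))
  !is.na(r) && r %in% unions[[k]]
}

# Catalytic coverage: every catalytic site instance of the role maps with
# exactly the reference residue.
catalytic_ok <- function(profile) {
  rows <- profile[profile$site_kind %in% c("catalytic_cys", "other_catalytic"), ]
  if (!nrow(rows)) return(FALSE)
  all(!is.na(rows$residue) & rows$residue == rows$ref_residue)
}

#' Call the RNR class of a query
#'
#' @param profiles List with elements `beta`, `alpha`, `class2`: residue
#'   profiles of the query extracted against the three reference roles
#'   (see [extract_profiles()]).
#' @param params [classify_params()] configuration.
#' @return One of `"class1_beta"`, `"class1_alpha"`, `"class2"`,
#'   `"unassigned"` (insufficient coverage is a value, not an error).
#' @export
call_class <- function(profiles, params = classify_params()) {
  unions <- allowed_union(params$patterns)
  beta_cov <- all(vapply(params$essential_beta_sites, function(k)
    beta_site_ok(profiles$beta, k, unions), logical(1)))
  if (beta_cov) return("class1_beta")
  alpha_cat <- catalytic_ok(profiles$alpha)
  class2_cat <- !is.null(profiles$class2) && catalytic_ok(profiles$class2)
  if (alpha_cat || class2_cat) {
    if (has_radical_transfer_pair(profiles$alpha)) return("class1_alpha")
    return("class2")
  }
  "unassigned"
}

#' Extract profiles against all three reference roles
#'
#' @param query Named character scalar (name = query id) or string.
#' @param refs Reference set covering the three roles.
#' @param params [align_params()] configuration.
#' @return List with `residue_profile` elements `beta`, `alpha`, `class2`.
#' @export
extract_profiles <- function(query, refs, params = align_params()) {
  aln <- align_to_profile(query, refs, params)
  list(beta = extract_profile(query, refs, "class1_beta", aln, params),
       alpha = extract_profile(query, refs, "class1_alpha", aln, params),
       class2 = extract_profile(query, refs, "class2", aln, params))
}

#' Match a metal-site profile against subclass patterns
#'
#' A group matches iff at every considered site the profile residue is
#' present and belongs to the group's allowed set; exact set membership, no
#' partial credit. `mode = "first_sphere"` restricts the comparison to
#' sites 1-6 (the direct metal ligands), the mode used when second-sphere
#' columns fail to align.
#'
#' @param profile A `residue_profile` (beta role) or a character vector of
#'   residues for sites 1-8 (names optional).
#' @param patterns `subclass_patterns` to match against.
#' @param mode `"full"` (sites 1-8) or `"first_sphere"` (sites 1-6).
#' @return Character vector of matching group names (possibly empty).
#' @export
match_metal_pattern <- function(profile, patterns = rnr_patterns(),
                                mode = c("full", "first_sphere")) {
  mode <- match.arg(mode)
  res <- if (inherits(profile, "residue_profile")) {
    metal_residues(profile)
  } else {
    r <- as.character(profile)
    if (length(r) > 8) stopf("residue vector longer than 8")
    c(r, rep(NA_character_, 8 - length(r)))
  }
  ks <- if (mode == "full") 1:8 else 1:6
  hits <- vapply(patterns, function(p) {
    all(vapply(ks, function(k)
      !is.na(res[k]) && res[k] != "X" && res[k] %in% p$allowed[[k]],
      logical(1)))
  }, logical(1))
  names(patterns)[hits]
}

#' Split NrdBz beta sequences by the tyrosyl radical site
#'
#' Tyr at the radical site assigns subclass Ia (NrdBza); a Phe, Leu or Val
#' substitution assigns subclass Ic (NrdBzc); anything else, including an
#' unmapped site, is unassigned.
#'
#' @param profile A beta `residue_profile`.
#' @return `"NrdBza"`, `"NrdBzc"` or `"unassigned"`.
#' @export
split_nrdbz <- function(profile) {
  r <- profile_residue(profile, "tyr_radical")
  if (isTRUE(r == "Y")) return("NrdBza")
  if (isTRUE(r %in% c("F", "L", "V"))) return("NrdBzc")
  "unassigned"
}

#' Split NrdF beta sequences by carboxylate conservation
#'
#' Subclass Ib (NrdFb) conserves carboxylate residues (Asp/Glu) at metal
#' sites 2, 4 and 5; subclass Ie (NrdFe) has lost all three. A mixed or
#' incomplete pattern is unassigned (the rule is conjunctive).
#'
#' @param profile A beta `residue_profile`.
#' @return `"NrdFb"`, `"NrdFe"` or `"unassigned"`.
#' @export
split_nrdf <- function(profile) {
  res <- metal_residues(profile, paste0("metal_", c(2, 4, 5)))
  if (anyNA(res)) return("unassigned")
  carbox <- res %in% c("D", "E")
  if (all(carbox)) return("NrdFb")
  if (!any(carbox)) return("NrdFe")
  "unassigned"
}

#' Assign a Class I subclass from the metal-site pattern
#'
#' Full eight-site pattern matching against the group table: a unique match
#' yields that group's subclass (preserving the `"Ia_presumed"`
#' distinction); no match yields `"novel"` (the situation that defines the
#' Cyano SP clade); multiple matches are reported but left unassigned, as
#' overlapping group rows are resolved phylogenetically, a separate
#' evidence channel.
#'
#' @param profile A beta `residue_profile`.
#' @param patterns `subclass_patterns` table.
#' @return Object of class `classification_result`.
#' @export
call_subclass <- function(profile, patterns = rnr_patterns()) {
  res <- metal_residues(profile)
  if (anyNA(res)) {
    # an incomplete pattern is insufficient evidence either way: "novel"
    # is only claimed for a complete eight-site pattern matching no group
    return(classification_result(
      attr(profile, "query_id"), "class1_beta", "unassigned", character(0),
      list(c(rule = "incomplete_profile",
             outcome = paste(names(res)[is.na(res)], collapse = ",")))))
  }
  groups <- match_metal_pattern(profile, patterns, "full")
  evidence <- list(c(rule = "metal_pattern_full",
                     outcome = paste(groups, collapse = ",")))
  if (length(groups) == 1L) {
    subclass <- patterns[[groups]]$subclass
  } else if (!length(groups)) {
    subclass <- "novel"
    evidence <- c(evidence, list(c(rule = "no_group_match",
                                   outcome = "novel_subclass_candidate")))
  } else {
    subclass <- "unassigned"
    evidence <- c(evidence, list(c(rule = "ambiguous_group_match",
                                   outcome = paste(groups, collapse = ","))))
  }
  classification_result(attr(profile, "query_id"), "class1_beta", subclass,
                        groups, evidence)
}

#' @rdname call_subclass
#' @param query_id Query identifier.
#' @param class_call,subclass_call Calls (see spec of values above).
#' @param matched_groups Character vector of matched group names.
#' @param evidence List of named character pairs (rule, outcome).
#' @export
classification_result <- function(query_id, class_call, subclass_call,
                                  matched_groups = character(0),
                                  evidence = list()) {
  class_call <- match.arg(class_call, CLASS_CALLS)
  if (!class_call %in% c("class1_alpha", "class1_beta") &&
      !subclass_call %in% c("unassigned")) {
    stopf("subclass can only be assigned to Class I subunits")
  }
  structure(list(query_id = query_id, class_call = class_call,
                 subclass_call = subclass_call,
                 matched_groups = matched_groups, evidence = evidence),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification> %s: %s / %s%s\n", x$query_id, x$class_call,
              x$subclass_call,
              if (length(x$matched_groups))
                paste0(" [", paste(x$matched_groups, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Classify one query end to end
#'
#' Extracts profiles against all three roles, calls the class, and for
#' Class I beta queries assigns the subclass by pattern matching.
#'
#' @param query Named character scalar or string.
#' @param refs Reference set (default bundled).
#' @param patterns Pattern table (default bundled).
#' @param params [align_params()] configuration.
#' @return A `classification_result`.
#' @export
classify_rnr <- function(query, refs = rnr_references(),
                         patterns = rnr_patterns(),
                         params = align_params()) {
  profiles <- extract_profiles(query, refs, params)
  cls <- call_class(profiles, classify_params(patterns = patterns))
  if (cls == "class1_beta") {
    res <- call_subclass(profiles$beta, patterns)
    res$query_id <- attr(profiles$beta, "query_id")
    return(res)
  }
  evidence <- list(c(rule = "radical_transfer_pair",
                     outcome = as.character(
                       has_radical_transfer_pair(profiles$alpha))))
  classification_result(attr(profiles$beta, "query_id"), cls, "unassigned",
                        character(0), evidence)
}

#' Pair alpha subunits with beta subunits by genome
#'
#' Alpha subunits cannot be subclassed from primary sequence alone; each is
#' assigned the subclass of its corresponding beta subunit. An alpha
#' pairing with exactly one beta in its genome is `"paired"` and inherits
#' that beta's subclass; alphas with no beta are `"unpaired"` and alphas
#' with several are `"ambiguous"`, and both are excluded from further
#' analysis.
#'
#' @param alphas data.frame with columns `alpha_id`, `genome_id`.
#' @param betas data.frame with columns `beta_id`, `genome_id`,
#'   `subclass_call`.
#' @return data.frame with one row per alpha: `alpha_id`, `beta_ids`
#'   (comma-separated), `status`, `subclass_call`, `excluded`.
#' @export
pair_subunits <- function(alphas, betas) {
  stopifnot(all(c("alpha_id", "genome_id") %in% names(alphas)),
            all(c("beta_id", "genome_id", "subclass_call") %in% names(betas)))
  rows <- lapply(seq_len(nrow(alphas)), function(i) {
    b <- betas[betas$genome_id == alphas$genome_id[i], , drop = FALSE]
    status <- if (nrow(b) == 1L) "paired"
              else if (nrow(b) == 0L) "unpaired" else "ambiguous"
    data.frame(alpha_id = alphas$alpha_id[i],
               beta_ids = paste(b$beta_id, collapse = ","),
               status = status,
               subclass_call = if (status == "paired") b$subclass_call[1]
                               else "unassigned",
               excluded = status != "paired",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
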