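#' @importFrom utils read.delim write.table
NULL

# Site vocabulary. Metal sites 1-6 are the first coordination sphere (direct
# metal ligands of the beta subunit), 7-8 the second sphere; the tyrosyl
# radical site and the consecutive radical-transfer tyrosine pair are the
# class-level diagnostics.
SITE_KINDS <- c(
  "tyr_radical", paste0("metal_", 1:8),
  "radical_transfer_tyr1", "radical_transfer_tyr2",
  "catalytic_cys", "other_catalytic"
)
METAL_SITES <- paste0("metal_", 1:8)
FIRST_SPHERE <- paste0("metal_", 1:6)
SECOND_SPHERE <- paste0("metal_", 7:8)

REF_ROLES <- c("class1_alpha", "class1_beta", "class2")

# Beta-only site kinds vs alpha-only site kinds (type invariant).
BETA_ONLY_SITES <- c("tyr_radical", METAL_SITES)
ALPHA_ONLY_SITES <- c("radical_transfer_tyr1", "radical_transfer_tyr2")

PATTERN_GROUPS <- c("NrdBe", "NrdBg", "NrdBh", "NrdBk", "NrdBn", "NrdBza",
                    "NrdFb", "NrdBzc", "NrdBi", "NrdFe", "CyanoSP")

SUBCLASS_LABELS <- c("Ia", "Ia_presumed", "Ib", "Ic", "Id", "Ie", "If")

#' Create an annotated reference sequence
#'
#' An annotated reference is a biochemically characterized representative of
#' an RNR role (Class I alpha, Class I beta, or Class II) together with its
#' curated active-site annotations in 1-based ungapped residue coordinates
#' (the field's "D85"-style numbering).
#'
#' @param id Accession-style identifier (unique within a set).
#' @param label Free-text organism / subclass description.
#' @param role One of `"class1_alpha"`, `"class1_beta"`, `"class2"`.
#' @param sequence Amino-acid string (standard 20 letters plus X).
#' @param sites data.frame with columns `site_kind`, `position`, `residue`.
#' @param subclass Class I subclass label (`"Ia"`..`"Ie"`) or `NA`.
#' @return An object of class `annotated_reference`.
#' @export
annotated_reference <- function(id, label, role, sequence, sites,
                                subclass = NA_character_) {
  ref <- structure(
    list(id = as.character(id), label = as.character(label),
         role = match.arg(role, REF_ROLES),
         subclass = as.character(subclass),
         sequence = toupper(as.character(sequence)),
         sites = as.data.frame(sites)),
    class = "annotated_reference"
  )
  validate_reference(ref)
  ref
}

validate_reference <- function(ref) {
  seq <- ref$sequence
  if (!nzchar(seq) || !aa_ok(seq)) {
    stopf("reference '%s': sequence empty or contains non amino-acid letters",
          ref$id)
  }
  s <- ref$sites
  need <- c("site_kind", "position", "residue")
  if (!all(need %in% names(s))) {
    stopf("reference '%s': sites table must have columns %s",
          ref$id, paste(need, collapse = ", "))
  }
  bad_kind <- setdiff(unique(s$site_kind), SITE_KINDS)
  if (length(bad_kind)) {
    stopf("reference '%s': unknown site_kind '%s'", ref$id, bad_kind[1])
  }
  n <- nchar(seq)
  for (i in seq_len(nrow(s))) {
    p <- s$position[i]
    if (is.na(p) || p < 1L || p > n) {
      stopf("reference '%s': site %s position %s outside [1, %d]",
            ref$id, s$site_kind[i], p, n)
    }
    actual <- substr(seq, p, p)
    if (actual != s$residue[i]) {
      stopf(paste0("reference '%s': integrity error at position %d: ",
                   "annotated residue '%s' but sequence has '%s'"),
            ref$id, p, s$residue[i], actual)
    }
  }
  # role / site-kind compatibility
  if (ref$role != "class1_beta" && any(s$site_kind %in% BETA_ONLY_SITES)) {
    stopf("reference '%s': tyr-radical/metal sites only allowed on class1_beta",
          ref$id)
  }
  if (ref$role != "class1_alpha" && any(s$site_kind %in% ALPHA_ONLY_SITES)) {
    stopf("reference '%s': radical-transfer Tyr pair only allowed on class1_alpha",
          ref$id)
  }
  if (anyDuplicated(s$site_kind[s$site_kind != "other_catalytic"])) {
    stopf("reference '%s': duplicated site_kind", ref$id)
  }
  invisible(ref)
}

#' @export
print.annotated_reference <- function(x, ...) {
  cat(sprintf("<annotated_reference> %s [%s%s] %d aa, %d sites\n  %s\n",
              x$id, x$role,
              if (!is.na(x$subclass)) paste0("/", x$subclass) else "",
              nchar(x$sequence), nrow(x$sites), x$label))
  invisible(x)
}

site_position <- function(ref, kind) {
  p <- ref$sites$position[ref$sites$site_kind == kind]
  if (!length(p)) NA_integer_ else as.integer(p)
}

#' Load annotated references from a sites table and companion FASTA
#'
#' The sites table is a TSV with columns `ref_id`, `role`, `subclass`,
#' `label`, `site_kind`, `position`, `residue`; sequences come from a
#' companion protein FASTA keyed by `ref_id`.
#'
#' @param sites_path Path to the TSV of site annotations.
#' @param fasta_path Path to the protein FASTA.
#' @return Named list of [annotated_reference()] objects.
#' @export
load_references <- function(sites_path, fasta_path) {
  if (!file.exists(sites_path)) stopf("no such file: %s", sites_path)
  if (!file.exists(fasta_path)) stopf("no such file: %s", fasta_path)
  tab <- read.delim(sites_path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("ref_id", "role", "subclass", "label", "site_kind",
            "position", "residue")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("sites table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tab$position <- suppressWarnings(as.integer(tab$position))
  if (anyNA(tab$position)) {
    stopf("sites table row %d: non-integer position",
          which(is.na(tab$position))[1])
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  names(aa) <- sub("\\s.*$", "", names(aa))
  refs <- lapply(split(tab, tab$ref_id), function(rows) {
    id <- rows$ref_id[1]
    if (length(unique(rows$role)) != 1L) {
      stopf("reference '%s' listed with more than one role", id)
    }
    if (!id %in% names(aa)) stopf("no FASTA record for reference '%s'", id)
    annotated_reference(
      id = id, label = rows$label[1], role = rows$role[1],
      subclass = if (nzchar(rows$subclass[1])) rows$subclass[1] else NA,
      sequence = as.character(aa[[id]]),
      sites = data.frame(site_kind = rows$site_kind,
                         position = rows$position,
                         residue = rows$residue,
                         stringsAsFactors = FALSE)
    )
  })
  refs[unique(tab$ref_id)]
}

#' Serialize annotated references back to TSV + FASTA
#'
#' Inverse of [load_references()]; `load(write(x))` reproduces `x`.
#'
#' @param refs Named list of [annotated_reference()] objects.
#' @param sites_path,fasta_path Output paths.
#' @export
write_references <- function(refs, sites_path, fasta_path) {
  rows <- do.call(rbind, lapply(refs, function(r) {
    data.frame(ref_id = r$id, role = r$role,
               subclass = ifelse(is.na(r$subclass), "", r$subclass),
               label = r$label,
               site_kind = r$sites$site_kind,
               position = r$sites$position,
               residue = r$sites$residue,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  seqs <- Biostrings::AAStringSet(vapply(refs, `[[`, "", "sequence"))
  names(seqs) <- vapply(refs, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, fasta_path)
  invisible(NULL)
}

#' Load subclass residue patterns
#'
#' Reads the group-level metal-binding residue pattern table: one row per
#' RNRdb group (plus the Cyano SP clade) with the allowed residues at metal
#' sites 1-8, alternatives separated by "/" (e.g. "M/I/V").
#'
#' @param path TSV with columns `group`, `subclass`, `site1`..`site8`.
#' @return Object of class `subclass_patterns`: a list with one entry per
#'   group carrying `group`, `subclass` and `allowed` (list of 8 character
#'   vectors).
#' @export
load_patterns <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("group", "subclass", paste0("site", 1:8))
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("pattern table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  pats <- lapply(seq_len(nrow(tab)), function(i) {
    g <- tab$group[i]
    if (!g %in% PATTERN_GROUPS) stopf("unknown group name '%s'", g)
    allowed <- lapply(1:8, function(k) {
      set <- strsplit(tab[[paste0("site", k)]][i], "/", fixed = TRUE)[[1]]
      set <- toupper(trimws(set))
      if (!length(set) || any(!nzchar(set))) {
        stopf("group '%s': empty allowed set at site %d", g, k)
      }
      set
    })
    for (k in c(3L, 6L)) {
      if (!identical(allowed[[k]], "H")) {
        stopf("group '%s': site %d must allow only H (histidine metal ligand)",
              g, k)
      }
    }
    list(group = g, subclass = tab$subclass[i], allowed = allowed)
  })
  names(pats) <- tab$group
  if (anyDuplicated(names(pats))) stopf("duplicated group rows")
  structure(pats, class = "subclass_patterns")
}

#' @export
print.subclass_patterns <- function(x, ...) {
  cat(sprintf("<subclass_patterns> %d groups: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Serialize subclass patterns to TSV (inverse of [load_patterns()])
#' @param patterns A `subclass_patterns` object.
#' @param path Output TSV path.
#' @export
write_patterns <- function(patterns, path) {
  tab <- do.call(rbind, lapply(patterns, function(p) {
    row <- data.frame(group = p$group, subclass = p$subclass,
                      stringsAsFactors = FALSE)
    for (k in 1:8) row[[paste0("site", k)]] <- paste(p$allowed[[k]],
                                                     collapse = "/")
    row
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Bundled annotated references
#'
#' The package ships a curated reference set covering one Class I beta and
#' one Class I alpha representative per subclass (Ia-Ie) plus one Class II
#' representative. The sequences are synthetic stand-ins: randomized
#' backgrounds carrying the published diagnostic residues at the published
#' reference positions (e.g. the Ia beta representative carries
#' D85/E116/H119/E205/E239/H242 with S115/D238 in the second sphere and the
#' tyrosyl radical at Y122, in E. coli NrdB numbering). They support every
#' rule and coordinate-mapping contract in the package without requiring
#' database downloads; they are not the biological reference proteins.
#' The alpha/Class II catalytic-site lists are curator-supplied fixture
#' annotations (C225/N437/C439/E441/C462 plus Y730/Y731, E. coli NrdA
#' numbering).
#'
#' @return Named list of [annotated_reference()] objects.
#' @export
rnr_references <- function() {
  if (is.null(.refcache$refs)) {
    .refcache$refs <- load_references(
      system.file("extdata", "rnr_reference_sites.tsv",
                  package = "rnrclassify", mustWork = TRUE),
      system.file("extdata", "rnr_references_synthetic.fasta",
                  package = "rnrclassify", mustWork = TRUE))
    validate_reference_set(.refcache$refs)
  }
  .refcache$refs
}

#' Bundled subclass pattern table
#'
#' Allowed metal-binding residues per RNRdb group (and the Cyano SP clade)
#' at beta-subunit sites 1-8, with each group's Class I subclass membership.
#'
#' @return A `subclass_patterns` object (see [load_patterns()]).
#' @export
rnr_patterns <- function() {
  if (is.null(.refcache$patterns)) {
    .refcache$patterns <- load_patterns(
      system.file("extdata", "subclass_patterns.tsv",
                  package = "rnrclassify", mustWork = TRUE))
  }
  .refcache$patterns
}

.refcache <- new.env(parent = emptyenv())

# Bundled-set completeness: exactly one alpha and one beta per subclass a-e.
validate_reference_set <- function(refs) {
  for (sc in c("Ia", "Ib", "Ic", "Id", "Ie")) {
    for (role in c("class1_alpha", "class1_beta")) {
      n <- sum(vapply(refs, function(r)
        identical(r$subclass, sc) && r$role == role, logical(1)))
      if (n != 1L) {
        stopf("bundled set must have exactly one %s representative for %s (found %d)",
              role, sc, n)
      }
    }
  }
  invisible(refs)
}

#' Select references by role
#' @param refs Named list of references.
#' @param role Reference role to keep.
#' @return Named list of references with that role.
#' @export
refs_by_role <- function(refs, role) {
  role <- match.arg(role, REF_ROLES)
  refs[vapply(refs, function(r) r$role == role, logical(1))]
}

#' Per-representative residue patterns
#'
#' Converts beta-subunit representatives into single-residue
#' `subclass_patterns` (allowed set at each metal site = the
#' representative's own residue), so a query profile can be matched against
#' the characterized representatives themselves rather than group-level
#' residue sets.
#'
#' @param refs List of `class1_beta` [annotated_reference()] objects.
#' @return A `subclass_patterns` object keyed by each reference's subclass.
#' @export
reference_patterns <- function(refs) {
  refs <- refs_by_role(refs, "class1_beta")
  pats <- lapply(refs, function(r) {
    allowed <- lapply(METAL_SITES, function(kind) {
      p <- site_position(r, kind)
      if (is.na(p)) stopf("reference '%s' lacks %s", r$id, kind)
      substr(r$sequence, p, p)
    })
    list(group = r$subclass, subclass = r$subclass, allowed = allowed)
  })
  names(pats) <- vapply(refs, `[[`, "", "subclass")
  class(pats) <- "subclass_patterns"
  pats
}

#' Region-of-interest trim anchors
#'
#' Anchor pairs, in reference coordinates, delimiting the regions used for
#' phylogenetic work: the combined Class I alpha + Class II region of
#' interest (N437-S625), the alpha-only region (from C225 to the sequence
#' end, dropping the mobile N-terminal ATP-cone domain), and the beta region
#' (W48-Y356, excluding ATP-cone-like N-termini and fused glutaredoxin
#' C-termini). Coordinates follow the bundled Ia representatives' numbering.
#'
#' @param refs Reference set used to resolve anchor ids (defaults to the
#'   bundled set).
#' @return Object of class `trim_spec`.
#' @export
trim_spec <- function(refs = rnr_references()) {
  alpha_ref <- refs_by_role(refs, "class1_alpha")
  alpha_ref <- alpha_ref[[which(vapply(alpha_ref, `[[`, "", "subclass") == "Ia")]]
  beta_ref <- refs_by_role(refs, "class1_beta")
  beta_ref <- beta_ref[[which(vapply(beta_ref, `[[`, "", "subclass") == "Ia")]]
  spec <- list(
    combined  = list(ref_id = alpha_ref$id, start = 437L, end = 625L),
    alpha_only = list(ref_id = alpha_ref$id, start = 225L,
                      end = nchar(alpha_ref$sequence)),
    beta      = list(ref_id = beta_ref$id, start = 48L, end = 356L)
  )
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (s$start >= s$end) stopf("trim_spec '%s': start must precede end", nm)
  }
  structure(spec, class = "trim_spec")
}
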