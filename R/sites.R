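# Projection of annotated active-site positions onto query sequences.

PROFILE_COLS <- c("site_kind", "instance", "ref_id", "ref_position",
                  "ref_residue", "query_position", "residue", "flag")

#' Extract a diagnostic residue profile from a query
#'
#' Projects every annotated site of the chosen reference role onto the query
#' through the per-reference position maps of a [align_to_profile()] result.
#' For each site the highest-scoring reference of the role decides the
#' value: the query residue in its site column, or absent
#' (`query_position = NA`) when that column holds a query gap. When a
#' lower-scoring reference of the same role maps the site to a different
#' query position the site is flagged `"conflict"` (the highest-scoring
#' reference still decides). A profile in which every site is absent is
#' flagged unalignable.
#'
#' @param query Named character scalar or plain string (ignored when
#'   `alignment` is supplied).
#' @param refs List of [annotated_reference()] objects (ignored when
#'   `alignment` is supplied).
#' @param role Reference role whose sites are extracted.
#' @param alignment Optional precomputed `profile_alignment`.
#' @param params [align_params()] configuration.
#' @return Object of class `residue_profile`: a data.frame of per-site rows
#'   (site_kind, instance, ref_id, ref_position, query_position, residue,
#'   flag) with attributes `query_id`, `role` and `unalignable`.
#' @export
extract_profile <- function(query, refs, role = "class1_beta",
                            alignment = NULL, params = align_params()) {
  role <- match.arg(role, REF_ROLES)
  if (is.null(alignment)) {
    alignment <- align_to_profile(query, refs, params)
  }
  role_ids <- vapply(alignment$refs, function(r) r$role == role, logical(1))
  if (!any(role_ids)) stopf("no reference of role '%s' in alignment", role)
  rrefs <- alignment$refs[role_ids]
  # order references by decreasing alignment score (deterministic tie-break
  # on id) so "first mapped" = "highest-scoring mapped"
  sc <- alignment$scores[vapply(rrefs, `[[`, "", "id")]
  ord <- order(-sc, names(sc))
  rrefs <- rrefs[ord]

  qlen <- nchar(alignment$query)
  maps <- lapply(rrefs, function(r)
    position_map(alignment$alignments[[r$id]], 1L, 2L))
  names(maps) <- vapply(rrefs, `[[`, "", "id")

  # site instances: i-th occurrence of a site_kind within a reference
  # corresponds across references of the same role
  site_tab <- function(r) {
    s <- r$sites[order(match(r$sites$site_kind, SITE_KINDS), r$sites$position), ]
    s$instance <- stats::ave(seq_len(nrow(s)), s$site_kind,
                             FUN = seq_along)
    s$ref_id <- r$id
    s
  }
  all_sites <- do.call(rbind, lapply(rrefs, site_tab))
  keys <- unique(all_sites[, c("site_kind", "instance")])

  rows <- lapply(seq_len(nrow(keys)), function(i) {
    kind <- keys$site_kind[i]
    inst <- keys$instance[i]
    cand <- all_sites[all_sites$site_kind == kind & all_sites$instance == inst, ]
    qpos <- vapply(seq_len(nrow(cand)), function(j)
      maps[[cand$ref_id[j]]][cand$position[j]], integer(1))
    # the highest-scoring reference carrying the site decides the value
    # (including absence); lower-scoring references can only flag conflict
    best <- 1L  # cand rows inherit the score-sorted reference order
    if (is.na(qpos[best])) {
      return(data.frame(site_kind = kind, instance = inst,
                        ref_id = cand$ref_id[best],
                        ref_position = cand$position[best],
                        ref_residue = cand$residue[best],
                        query_position = NA_integer_,
                        residue = NA_character_, flag = "absent",
                        stringsAsFactors = FALSE))
    }
    others <- qpos[-best]
    flag <- if (any(!is.na(others) & others != qpos[best])) "conflict" else ""
    qp <- qpos[best]
    data.frame(site_kind = kind, instance = inst,
               ref_id = cand$ref_id[best], ref_position = cand$position[best],
               ref_residue = cand$residue[best],
               query_position = qp,
               residue = substr(alignment$query, qp, qp), flag = flag,
               stringsAsFactors = FALSE)
  })
  prof <- do.call(rbind, rows)
  structure(prof,
            query_id = alignment$query_id, role = role,
            unalignable = all(is.na(prof$query_position)),
            class = c("residue_profile", "data.frame"))
}

#' @export
print.residue_profile <- function(x, ...) {
  cat(sprintf("<residue_profile> %s vs %s%s\n", attr(x, "query_id"),
              attr(x, "role"),
              if (isTRUE(attr(x, "unalignable"))) " (unalignable)" else ""))
  print.data.frame(x)
  invisible(x)
}

# Residue at a site kind (first instance), NA if absent.
profile_residue <- function(profile, kind) {
  i <- which(profile$site_kind == kind & profile$instance == 1L)
  if (!length(i)) return(NA_character_)
  profile$residue[i[1]]
}

profile_position <- function(profile, kind) {
  i <- which(profile$site_kind == kind & profile$instance == 1L)
  if (!length(i)) return(NA_integer_)
  profile$query_position[i[1]]
}

#' Metal-site residues of a beta profile
#'
#' @param profile A `residue_profile` extracted against `class1_beta`.
#' @param sites Which metal sites (default all eight).
#' @return Named character vector of residues (`NA` where absent).
#' @export
metal_residues <- function(profile, sites = METAL_SITES) {
  out <- vapply(sites, function(k) profile_residue(profile, k), character(1))
  names(out) <- sites
  out
}

#' Test for the consecutive radical-transfer tyrosine pair
#'
#' Class I alpha subunits carry two consecutive tyrosines near the
#' C-terminus (Y730/Y731 in E. coli numbering) that shuttle the radical
#' between subunits; Class II enzymes lack them. True iff both sites map,
#' both query residues are tyrosine, and the two query positions are
#' consecutive integers (consecutive on the peptide, not merely in
#' alignment columns).
#'
#' @param profile A `residue_profile` extracted against `class1_alpha`.
#' @return Logical scalar.
#' @export
has_radical_transfer_pair <- function(profile) {
  r1 <- profile_residue(profile, "radical_transfer_tyr1")
  r2 <- profile_residue(profile, "radical_transfer_tyr2")
  p1 <- profile_position(profile, "radical_transfer_tyr1")
  p2 <- profile_position(profile, "radical_transfer_tyr2")
  isTRUE(r1 == "Y") && isTRUE(r2 == "Y") && !is.na(p1) && !is.na(p2) &&
    p2 == p1 + 1L
}

#' Write a residue profile report
#'
#' @param profile A `residue_profile`.
#' @param path Output TSV path.
#' @export
write_profile <- function(profile, path) {
  out <- cbind(query_id = attr(profile, "query_id"),
               as.data.frame(profile))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
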