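# Reference-set curation: dereplication, intein excision, functional
# filtering, region-of-interest trimming, and CD-HIT-style greedy identity
# clustering.

#' Remove exact duplicates and substring matches
#'
#' Keeps the longest sequence of each redundant set: a sequence is dropped
#' iff it equals, or is a substring of, another retained sequence. Exact
#' duplicates retain the lexicographically first id. Input order is
#' preserved in the output.
#'
#' @param seqs Named character vector of protein sequences.
#' @return Named character vector (subset of `seqs`).
#' @export
dereplicate <- function(seqs) {
  stopifnot(is.character(seqs))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  kept <- character(0)
  kept_ids <- character(0)
  for (i in ord) {
    s <- seqs[[i]]
    if (!any(vapply(kept, function(k) grepl(s, k, fixed = TRUE), logical(1)))) {
      kept <- c(kept, s)
      kept_ids <- c(kept_ids, names(seqs)[i])
    }
  }
  seqs[names(seqs) %in% kept_ids]
}

#' Excise intein-like insertions relative to a reference
#'
#' Inteins are mobile self-splicing insertions that confound phylogenetic
#' analysis. Relative to the alignment against an annotated reference,
#' contiguous query-only insertions spanning at least `min_insert` columns
#' are excised and the sequence is implicitly realigned by downstream
#' steps. If excision would change any extracted site residue (the
#' automated analogue of cutting into functional sequence), the sequence is
#' returned unmodified and flagged for manual review.
#'
#' @param seq Named character scalar or string.
#' @param ref An [annotated_reference()] guiding the excision.
#' @param min_insert Minimum insertion length in alignment columns
#'   (default 50).
#' @param params [align_params()] configuration.
#' @return List with `sequence` (possibly excised), `excised` (data.frame
#'   of query-coordinate intervals removed), `flagged` (logical) and
#'   `reason`.
#' @export
remove_inteins <- function(seq, ref, min_insert = 50L,
                           params = align_params()) {
  qid <- names(seq) %||% "query"
  qseq <- check_seq(seq[[1]], params, "query")
  qv <- c(qseq); names(qv) <- qid
  aln <- global_align(stats::setNames(ref$sequence, ref$id), qv, params)
  r <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  q <- strsplit(aln$rows[[2]], "", fixed = TRUE)[[1]]
  ins <- r == "-" & q != "-"
  runs <- rle(ins)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  qpos <- cumsum(q != "-")
  cut <- data.frame(start = integer(0), end = integer(0))
  for (j in which(runs$values & runs$lengths >= min_insert)) {
    cut <- rbind(cut, data.frame(start = qpos[starts[j]],
                                 end = qpos[ends[j]]))
  }
  if (!nrow(cut)) {
    return(list(sequence = qseq, excised = cut, flagged = FALSE,
                reason = "no insertion at or above min_insert"))
  }
  # refuse if an excision boundary abuts a mapped annotated site residue:
  # an insertion starting or ending on a diagnostic site is suspicious
  # enough to warrant manual review rather than automated surgery
  site_prof <- function(s) {
    p <- extract_profile(stats::setNames(s, qid), list(ref),
                         role = ref$role, params = params)
    list(residue = stats::setNames(p$residue, paste(p$site_kind, p$instance)),
         position = p$query_position)
  }
  before <- site_prof(qseq)
  for (j in seq_len(nrow(cut))) {
    pos <- before$position[!is.na(before$position)]
    if (any(pos >= cut$start[j] - 1L & pos <= cut$end[j] + 1L)) {
      return(list(sequence = qseq, excised = cut[0, ], flagged = TRUE,
                  reason = "insertion boundary overlaps an annotated site"))
    }
  }
  keep <- rep(TRUE, nchar(qseq))
  for (j in seq_len(nrow(cut))) keep[cut$start[j]:cut$end[j]] <- FALSE
  trimmed <- paste(strsplit(qseq, "", fixed = TRUE)[[1]][keep], collapse = "")
  # second guard: excision must not disturb any extracted site residue
  after <- site_prof(trimmed)
  present <- !is.na(before$residue)
  if (any(is.na(after$residue[present])) ||
      !identical(before$residue[present], after$residue[present])) {
    return(list(sequence = qseq, excised = cut[0, ], flagged = TRUE,
                reason = "excision would alter annotated site residues"))
  }
  cut$length <- cut$end - cut$start + 1L
  list(sequence = trimmed, excised = cut, flagged = FALSE,
       reason = sprintf("excised %d insertion(s)", nrow(cut)))
}

#' Drop sequences lacking essential functional residues
#'
#' Retains only sequences whose residue profile shows every essential site
#' of their role: for Class I beta, the six first-sphere metal ligands with
#' a residue allowed at that site in at least one group pattern; for
#' Class I alpha and Class II, every annotated catalytic site with exactly
#' the reference residue. Sequences failing the check are likely
#' non-functional.
#'
#' @param seqs Named character vector.
#' @param refs Reference set (default bundled).
#' @param role Role the sequences are expected to play.
#' @param patterns Pattern table for the beta allowed-residue unions.
#' @param params [align_params()] configuration.
#' @return Named character vector of retained sequences, with attribute
#'   `report` (data.frame id/functional).
#' @export
filter_functional <- function(seqs, refs = rnr_references(),
                              role = "class1_beta",
                              patterns = rnr_patterns(),
                              params = align_params()) {
  role <- match.arg(role, REF_ROLES)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  unions <- allowed_union(patterns)
  rrefs <- refs_by_role(refs, role)
  ok <- vapply(names(seqs), function(id) {
    prof <- extract_profile(stats::setNames(seqs[[id]], id), rrefs, role,
                            params = params)
    if (role == "class1_beta") {
      all(vapply(FIRST_SPHERE, function(k)
        beta_site_ok(prof, k, unions), logical(1)))
    } else {
      catalytic_ok(prof)
    }
  }, logical(1))
  out <- seqs[ok]
  attr(out, "report") <- data.frame(id = names(seqs), functional = unname(ok),
                                    stringsAsFactors = FALSE)
  out
}

#' Trim a sequence to a region of interest
#'
#' Maps the query onto the anchor reference of the requested mode (see
#' [trim_spec()]) and returns the query residues falling within the anchor
#' interval (inclusive). For `mode = "alpha_only"` only the N-terminus is
#' trimmed (ATP-cone removal); the query C-terminus is kept. A query with
#' no mapped position inside the interval yields an empty string, the
#' "unalignable in ROI" signal. The trim is iterated to a fixed point so
#' the operation is exactly idempotent even when alignment boundaries are
#' ambiguous by a residue.
#'
#' @param seq Named character scalar or string.
#' @param mode One of `"combined"`, `"alpha_only"`, `"beta"`.
#' @param refs Reference set resolving the anchors.
#' @param spec A `trim_spec` (default from `refs`).
#' @param params [align_params()] configuration.
#' @return Trimmed sequence (possibly `""`).
#' @export
trim_roi <- function(seq, mode = c("combined", "alpha_only", "beta"),
                     refs = rnr_references(), spec = trim_spec(refs),
                     params = align_params()) {
  mode <- match.arg(mode)
  s <- spec[[mode]]
  ref <- refs[[s$ref_id]]
  if (is.null(ref)) stopf("trim anchor reference '%s' not in set", s$ref_id)
  qid <- names(seq) %||% "query"
  qseq <- check_seq(seq[[1]], params, "query")
  one_pass <- function(x) {
    aln <- global_align(stats::setNames(ref$sequence, ref$id),
                        stats::setNames(x, qid), params)
    map <- position_map(aln, 1L, 2L)
    mapped <- map[s$start:s$end]
    if (all(is.na(mapped))) return("")
    qs <- mapped[which(!is.na(mapped))[1]]
    qe <- if (mode == "alpha_only") nchar(x)
          else mapped[max(which(!is.na(mapped)))]
    substr(x, qs, qe)
  }
  out <- one_pass(qseq)
  for (i in 1:4) {
    if (!nzchar(out)) return(out)
    nxt <- one_pass(out)
    if (identical(nxt, out)) break
    out <- nxt
  }
  out
}

#' Greedy identity clustering
#'
#' CD-HIT-style greedy clustering: sequences are sorted longest first (ties
#' broken lexicographically by id), each seeds a cluster unless it reaches
#' `threshold` identity (denominator: shorter sequence) with the
#' representative of an earlier cluster while at least `coverage` of the
#' alignment columns pair residues in both sequences. Deterministic.
#'
#' @param seqs Named character vector.
#' @param threshold Identity threshold in `[0, 1]` (the analyses here use
#'   0.70 / 0.75 / 0.80, and 0.90 for network representatives).
#' @param coverage Minimum fraction of alignment columns with residues in
#'   both sequences (0.8 for full-length work, 1.0 for short trimmed
#'   regions).
#' @param passthrough If `TRUE`, skip clustering: every sequence becomes
#'   its own singleton cluster (used for sequence sets that must never be
#'   collapsed).
#' @param params [align_params()] configuration.
#' @return data.frame (`representative`, `member`, `identity`) with
#'   attributes `threshold` and `coverage`; every input id appears exactly
#'   once as a member.
#' @export
greedy_cluster <- function(seqs, threshold, coverage = 0.8,
                           passthrough = FALSE, params = align_params()) {
  stopifnot(is.character(seqs), threshold >= 0, threshold <= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(names(seqs))) stopf("duplicate sequence ids")
  if (passthrough) {
    out <- data.frame(representative = names(seqs), member = names(seqs),
                      identity = 1, stringsAsFactors = FALSE)
    attr(out, "threshold") <- threshold
    attr(out, "coverage") <- coverage
    return(out)
  }
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  rows <- list()
  for (i in ord) {
    id <- names(seqs)[i]
    assigned <- FALSE
    for (rep_id in reps) {
      aln <- global_align(stats::setNames(seqs[[rep_id]], rep_id),
                          stats::setNames(seqs[[i]], id), params)
      x <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
      y <- strsplit(aln$rows[[2]], "", fixed = TRUE)[[1]]
      ident <- sum(x == y & x != "-" & x != "X") /
        min(nchar(seqs[[rep_id]]), nchar(seqs[[i]]))
      cov <- sum(x != "-" & y != "-") / aln$column_count
      if (ident >= threshold && cov >= coverage - 1e-12) {
        rows[[length(rows) + 1L]] <-
          data.frame(representative = rep_id, member = id,
                     identity = ident, stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, id)
      rows[[length(rows) + 1L]] <-
        data.frame(representative = id, member = id, identity = 1,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  attr(out, "coverage") <- coverage
  out
}
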