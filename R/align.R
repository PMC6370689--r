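# Pairwise alignment with an explicit coordinate-mapping contract.
# Alignment itself is delegated to Biostrings::pairwiseAlignment (global and
# local Gotoh under BLOSUM62); everything downstream consumes only the gapped
# row strings and the position maps defined here.

#' Alignment scoring configuration
#'
#' @param matrix Substitution matrix name (only `"BLOSUM62"` is bundled).
#' @param gap_open,gap_extend Affine gap penalties (positive costs); a gap of
#'   length L costs `gap_open + L * gap_extend`. Defaults follow the common
#'   BLOSUM62 half-bit convention (10/1).
#' @param on_illegal What to do with letters outside the 20-residue alphabet
#'   plus X: `"as_x"` recodes them to X, `"error"` rejects the sequence.
#' @param identity_mode Default denominator for [percent_identity()]:
#'   `"over_shorter"` (CD-HIT convention) or `"over_alignment"`.
#' @return A list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 1,
                         on_illegal = c("as_x", "error"),
                         identity_mode = c("over_shorter", "over_alignment")) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 on_illegal = match.arg(on_illegal),
                 identity_mode = match.arg(identity_mode)),
            class = "align_params")
}

# BLOSUM62 with the X row/column zeroed: X is scored as neutral and never
# counts as satisfying a residue rule.
scoring_matrix <- function(params) {
  if (params$matrix != "BLOSUM62") {
    stopf("unsupported substitution matrix '%s'", params$matrix)
  }
  if (is.null(.refcache$blosum62x)) {
    mat <- get(utils::data("BLOSUM62", package = "Biostrings",
                           envir = environment()))
    mat["X", ] <- 0L
    mat[, "X"] <- 0L
    .refcache$blosum62x <- mat
  }
  .refcache$blosum62x
}

check_seq <- function(x, params, what = "sequence") {
  x <- toupper(x)
  if (!nzchar(x)) stopf("empty %s", what)
  if (!aa_ok(x)) {
    if (params$on_illegal == "error") {
      stopf("%s contains letters outside the amino-acid alphabet", what)
    }
    chars <- strsplit(x, "", fixed = TRUE)[[1]]
    chars[!chars %in% c(AA20, "X")] <- "X"
    x <- paste(chars, collapse = "")
  }
  x
}

new_alignment <- function(rows, score, params) {
  stopifnot(length(unique(nchar(rows))) == 1L)
  structure(list(rows = rows, row_ids = names(rows),
                 column_count = nchar(rows[[1]]),
                 score = score, params = params),
            class = "rnr_alignment")
}

#' @export
print.rnr_alignment <- function(x, ...) {
  cat(sprintf("<rnr_alignment> %d rows x %d columns, score %.1f\n",
              length(x$rows), x$column_count, x$score))
  invisible(x)
}

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch/Gotoh global alignment of two protein sequences under
#' BLOSUM62 with affine gap penalties. Deterministic for fixed inputs and
#' parameters.
#'
#' @param a,b Protein sequences (character scalars). Names, if present, are
#'   used as row ids (defaults `"a"`, `"b"`).
#' @param params [align_params()] configuration.
#' @return An `rnr_alignment` with two equal-length gapped rows; removing
#'   the gaps from a row reproduces the input sequence.
#' @export
global_align <- function(a, b, params = align_params()) {
  ids <- c(names(a) %||% "a", names(b) %||% "b")
  a <- check_seq(a[[1]], params, "sequence 'a'")
  b <- check_seq(b[[1]], params, "sequence 'b'")
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = scoring_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  rows <- c(as.character(Biostrings::alignedPattern(pa)),
            as.character(Biostrings::alignedSubject(pa)))
  names(rows) <- ids
  aln <- new_alignment(rows, Biostrings::score(pa), params)
  stopifnot(identical(degap(rows[[1]]), a), identical(degap(rows[[2]]), b))
  aln
}

#' Optimal local pairwise alignment score
#'
#' Smith-Waterman score under the same scoring configuration; used for
#' similarity-network edges.
#'
#' @inheritParams global_align
#' @return Numeric raw alignment score.
#' @export
local_align_score <- function(a, b, params = align_params()) {
  a <- check_seq(a[[1]], params)
  b <- check_seq(b[[1]], params)
  Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = scoring_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Map reference positions onto a query through an alignment
#'
#' For a (reference row, query row) pair of an alignment, returns the
#' partial, strictly increasing map from 1-based ungapped reference
#' positions to 1-based ungapped query positions. Positions whose alignment
#' column holds a query gap map to `NA`.
#'
#' @param alignment An `rnr_alignment`.
#' @param ref_row,query_row Row indices or row ids.
#' @return Integer vector of length `nchar(reference)`; `NA` where undefined.
#' @export
position_map <- function(alignment, ref_row = 1L, query_row = 2L) {
  r <- strsplit(alignment$rows[[ref_row]], "", fixed = TRUE)[[1]]
  q <- strsplit(alignment$rows[[query_row]], "", fixed = TRUE)[[1]]
  rpos <- cumsum(r != "-")
  qpos <- cumsum(q != "-")
  keep <- r != "-"
  map <- ifelse(q[keep] == "-", NA_integer_, qpos[keep])
  as.integer(map)
}

#' Align a query against a set of annotated references
#'
#' Builds a star of pairwise global alignments between the query and each
#' reference, ordered by alignment score. Downstream site extraction
#' projects each reference's annotated positions through its own position
#' map and resolves disagreements between same-role references by alignment
#' score (see [extract_profile()]). A query for which no reference maps any
#' annotated site is reported as unalignable by the extraction step rather
#' than raising an error here.
#'
#' @param query Named character scalar (name = query id) or plain string.
#' @param refs List of [annotated_reference()] objects.
#' @param params [align_params()] configuration.
#' @return Object of class `profile_alignment`: query id/sequence plus one
#'   `rnr_alignment` and score per reference.
#' @export
align_to_profile <- function(query, refs, params = align_params()) {
  qid <- names(query) %||% "query"
  qseq <- check_seq(query[[1]], params, "query")
  if (!length(refs)) stopf("no references supplied")
  ids <- vapply(refs, `[[`, "", "id")
  # one vectorized alignment call for all references
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(vapply(refs, `[[`, "", "sequence")),
    qseq, type = "global", substitutionMatrix = scoring_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  rpat <- as.character(Biostrings::alignedPattern(pa))
  rsub <- as.character(Biostrings::alignedSubject(pa))
  scores <- Biostrings::score(pa)
  alns <- lapply(seq_along(refs), function(i) {
    rows <- c(rpat[i], rsub[i])
    names(rows) <- c(ids[i], qid)
    new_alignment(rows, scores[i], params)
  })
  names(alns) <- ids
  structure(list(query_id = qid, query = qseq, refs = refs,
                 alignments = alns,
                 scores = vapply(alns, `[[`, numeric(1), "score"),
                 params = params),
            class = "profile_alignment")
}

#' Percent identity between two sequences
#'
#' Identity computed from the optimal global alignment. With
#' `mode = "over_shorter"` (the CD-HIT convention, default) the denominator
#' is the shorter input length; with `mode = "over_alignment"` it is the
#' number of alignment columns. Symmetric in its arguments.
#'
#' @inheritParams global_align
#' @param mode Denominator convention.
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b, mode = c("over_shorter", "over_alignment"),
                             params = align_params()) {
  mode <- match.arg(mode, c("over_shorter", "over_alignment"))
  aln <- global_align(a, b, params)
  x <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  y <- strsplit(aln$rows[[2]], "", fixed = TRUE)[[1]]
  matches <- sum(x == y & x != "-" & x != "X")
  denom <- switch(mode,
                  over_shorter = min(nchar(degap(aln$rows[[1]]))
                                     , nchar(degap(aln$rows[[2]]))),
                  over_alignment = aln$column_count)
  matches / denom
}

# Fraction of alignment columns where both rows carry a residue.
alignment_coverage <- function(aln) {
  x <- strsplit(aln$rows[[1]], "", fixed = TRUE)[[1]]
  y <- strsplit(aln$rows[[2]], "", fixed = TRUE)[[1]]
  sum(x != "-" & y != "-") / aln$column_count
}
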