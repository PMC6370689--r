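# Discovery of overlooked Class I beta-subunit genes in phage genomes:
# length window over unannotated proteins, diagnostic-residue screen, and
# adjacency to the alpha-subunit gene.

#' Ordered protein set of one genome
#'
#' @param genome_id Genome identifier.
#' @param proteins data.frame with columns `protein_id`, `sequence`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`), `status` (`"annotated"` or
#'   `"hypothetical"`). Coordinates are 1-based inclusive (GenBank
#'   convention); rows are stored sorted by `start`.
#' @return Object of class `genome_protein_set`.
#' @export
genome_protein_set <- function(genome_id, proteins) {
  need <- c("protein_id", "sequence", "start", "end", "strand", "status")
  miss <- setdiff(need, names(proteins))
  if (length(miss)) stopf("proteins table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(proteins$start < 0 | proteins$end < 0)) {
    stopf("coordinates must be non-negative")
  }
  if (!all(proteins$strand %in% c("+", "-"))) stopf("strand must be + or -")
  if (!all(proteins$status %in% c("annotated", "hypothetical"))) {
    stopf("status must be 'annotated' or 'hypothetical'")
  }
  proteins <- proteins[order(proteins$start), , drop = FALSE]
  rownames(proteins) <- NULL
  structure(list(genome_id = genome_id, proteins = proteins),
            class = "genome_protein_set")
}

#' @export
print.genome_protein_set <- function(x, ...) {
  cat(sprintf("<genome_protein_set> %s: %d proteins (%d hypothetical)\n",
              x$genome_id, nrow(x$proteins),
              sum(x$proteins$status == "hypothetical")))
  invisible(x)
}

#' Length-filter unannotated proteins
#'
#' Class I beta subunits are typically 350-400 aa; the search window is
#' widened to 200-500 aa so divergent subunits are not excluded. Bounds are
#' inclusive; only `"hypothetical"` proteins are considered.
#'
#' @param genome A [genome_protein_set()].
#' @param min_len,max_len Inclusive length window in residues.
#' @return data.frame of candidates (`protein_id`, `length`, `sequence`,
#'   `passed_length`); empty is a valid outcome.
#' @export
length_filter <- function(genome, min_len = 200L, max_len = 500L) {
  p <- genome$proteins
  hyp <- p[p$status == "hypothetical", , drop = FALSE]
  len <- nchar(hyp$sequence)
  keep <- len >= min_len & len <= max_len
  data.frame(protein_id = hyp$protein_id[keep], length = len[keep],
             sequence = hyp$sequence[keep],
             passed_length = rep(TRUE, sum(keep)),
             stringsAsFactors = FALSE)
}

#' Screen candidates for beta-subunit diagnostic residues
#'
#' A candidate passes iff its profile against the Class I beta references
#' shows every essential site (first-sphere metal ligands, residues drawn
#' from the allowed group patterns) -- the residues experimentally required
#' for beta-subunit function.
#'
#' @param candidates data.frame from [length_filter()].
#' @param refs Reference set (default bundled).
#' @param patterns Pattern table (default bundled).
#' @param params [align_params()] configuration.
#' @return `candidates` with a `passed_residues` logical column.
#' @export
residue_screen <- function(candidates, refs = rnr_references(),
                           patterns = rnr_patterns(),
                           params = align_params()) {
  if (!nrow(candidates)) {
    candidates$passed_residues <- logical(0)
    return(candidates)
  }
  unions <- allowed_union(patterns)
  brefs <- refs_by_role(refs, "class1_beta")
  candidates$passed_residues <- vapply(seq_len(nrow(candidates)), function(i) {
    prof <- extract_profile(
      stats::setNames(candidates$sequence[i], candidates$protein_id[i]),
      brefs, "class1_beta", params = params)
    all(vapply(FIRST_SPHERE, function(k)
      beta_site_ok(prof, k, unions), logical(1)))
  }, logical(1))
  candidates
}

# adjacency of a candidate to the alpha gene: "downstream_of_alpha" iff it
# is the next coding gene in genome order on alpha's strand (reading
# direction); otherwise "upstream" or "distant" with a gene-count distance.
candidate_adjacency <- function(genome, alpha_id, protein_id,
                                same_strand = TRUE) {
  p <- genome$proteins
  ai <- match(alpha_id, p$protein_id)
  ci <- match(protein_id, p$protein_id)
  if (is.na(ai) || is.na(ci)) stopf("protein not in genome")
  strand <- p$strand[ai]
  step <- if (strand == "+") 1L else -1L
  if (same_strand && p$strand[ci] != strand) {
    return(list(adjacency = "distant", distance = abs(ci - ai)))
  }
  offset <- (ci - ai) * step
  if (offset > 0) {
    # next same-strand gene downstream?
    between <- if (abs(ci - ai) > 1L) {
      idx <- seq(ai + step, ci - step, by = step)
      if (same_strand) idx[p$strand[idx] == strand] else idx
    } else integer(0)
    adj <- if (length(between) == 0L) "downstream_of_alpha" else "downstream"
    list(adjacency = adj, distance = offset)
  } else {
    list(adjacency = "upstream", distance = -offset)
  }
}

#' Rank beta-subunit candidates
#'
#' Residue-passing candidates rank first; among them, the gene directly
#' downstream of the alpha subunit (next coding gene in reading order on
#' the alpha's strand, the typical operonic arrangement) precedes others,
#' then candidates sort by gene distance from the alpha. Ties break by
#' protein id. Strand awareness is configurable.
#'
#' @param candidates data.frame from [residue_screen()].
#' @param alpha_id Protein id of the alpha subunit gene.
#' @param genome The [genome_protein_set()].
#' @param same_strand Require candidates on the alpha's strand for
#'   downstream adjacency (default TRUE).
#' @return `candidates` with `adjacency`, `gene_distance` and `rank`
#'   columns, sorted by rank.
#' @export
adjacency_rank <- function(candidates, alpha_id, genome, same_strand = TRUE) {
  if (!nrow(candidates)) {
    candidates$adjacency <- character(0)
    candidates$gene_distance <- integer(0)
    candidates$rank <- integer(0)
    return(candidates)
  }
  adj <- lapply(candidates$protein_id, function(id)
    candidate_adjacency(genome, alpha_id, id, same_strand))
  candidates$adjacency <- vapply(adj, `[[`, "", "adjacency")
  candidates$gene_distance <- vapply(adj, function(a)
    as.integer(a$distance), integer(1))
  adj_order <- match(candidates$adjacency,
                     c("downstream_of_alpha", "downstream", "upstream",
                       "distant"))
  ord <- order(!candidates$passed_residues, adj_order,
               candidates$gene_distance, candidates$protein_id)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}

#' Discover the beta subunit of a genome end to end
#'
#' Convenience composition of [length_filter()], [residue_screen()] and
#' [adjacency_rank()].
#'
#' @inheritParams length_filter
#' @inheritParams adjacency_rank
#' @inheritParams residue_screen
#' @return Ranked candidate report (data.frame).
#' @export
discover_beta <- function(genome, alpha_id, min_len = 200L, max_len = 500L,
                          refs = rnr_references(), patterns = rnr_patterns(),
                          same_strand = TRUE, params = align_params()) {
  cand <- length_filter(genome, min_len, max_len)
  cand <- residue_screen(cand, refs, patterns, params)
  adjacency_rank(cand, alpha_id, genome, same_strand)
}
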