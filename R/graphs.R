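# Sequence similarity networks and neighbor-joining clade placement.

# Karlin-Altschul constants for gapped BLOSUM62 (the standard published
# values); used to express a raw Smith-Waterman score as -log10(E), the
# "alignment score" convention of similarity-network tools.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Alignment score for network edges
#'
#' Transforms a raw local-alignment score into the -log10 of its
#' Karlin-Altschul E-value for a search space of `m * n` residues:
#' `S' = (lambda * S - ln K) / ln 2`, `E = m * n * 2^-S'`, and the edge
#' score is `-log10(E)`.
#'
#' @param raw_score Raw Smith-Waterman score under BLOSUM62.
#' @param m,n Lengths of the two sequences.
#' @return Numeric edge score (larger = more significant).
#' @export
ssn_edge_score <- function(raw_score, m, n) {
  bits <- (KA_LAMBDA * raw_score - log(KA_K)) / log(2)
  bits * log10(2) - log10(as.numeric(m) * as.numeric(n))
}

#' Build a protein sequence similarity network
#'
#' Sequences are first collapsed into representative nodes by greedy
#' clustering at `rep_identity` (default 90% identity); every input
#' sequence belongs to exactly one node. For each pair of node
#' representatives the local-alignment significance score
#' ([ssn_edge_score()]) is computed, and an undirected edge is drawn iff it
#' reaches `min_score`. The historical "fraction" parameter of network
#' tools is recorded for provenance only (value 1; it has no functional
#' meaning here).
#'
#' @param seqs Named character vector of protein sequences.
#' @param min_score Minimum alignment score for an edge (default 90).
#' @param rep_identity Identity threshold for representative nodes
#'   (default 0.90).
#' @param coverage Coverage constraint passed to [greedy_cluster()].
#' @param params [align_params()] configuration.
#' @return Object of class `rnr_ssn`: an igraph graph whose vertices carry
#'   `name` (representative id) and `members` (comma-separated member
#'   ids), with `min_score` / `rep_identity` attributes.
#' @export
build_ssn <- function(seqs, min_score = 90, rep_identity = 0.90,
                      coverage = 0.8, params = align_params()) {
  stopifnot(length(seqs) >= 1)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  cl <- greedy_cluster(seqs, rep_identity, coverage, params = params)
  reps <- unique(cl$representative)
  g <- igraph::make_empty_graph(n = length(reps), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = reps)
  members <- vapply(reps, function(r)
    paste(cl$member[cl$representative == r], collapse = ","), character(1))
  g <- igraph::set_vertex_attr(g, "members", value = members)
  if (length(reps) > 1) {
    pairs <- utils::combn(reps, 2)
    scores <- apply(pairs, 2, function(p) {
      raw <- local_align_score(seqs[[p[1]]], seqs[[p[2]]], params)
      ssn_edge_score(raw, nchar(seqs[[p[1]]]), nchar(seqs[[p[2]]]))
    })
    keep <- scores >= min_score
    if (any(keep)) {
      g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]),
                             score = scores[keep])
    }
  }
  structure(list(graph = g, min_score = min_score,
                 rep_identity = rep_identity, clusters = cl),
            class = "rnr_ssn")
}

#' @export
print.rnr_ssn <- function(x, ...) {
  cat(sprintf("<rnr_ssn> %d nodes, %d edges (min score %.0f, reps at %.0f%%)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$min_score, 100 * x$rep_identity))
  invisible(x)
}

#' Connected components of a similarity network
#'
#' @param ssn An `rnr_ssn`.
#' @return List with `components` (list of node-id character vectors,
#'   ordered by smallest member id), `sizes`, and `singleton_count`.
#' @export
ssn_components <- function(ssn) {
  comp <- igraph::components(ssn$graph)
  ids <- igraph::V(ssn$graph)$name
  groups <- split(ids, comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  names(groups) <- NULL
  sizes <- vapply(groups, length, integer(1))
  list(components = groups, sizes = sizes,
       singleton_count = sum(sizes == 1L))
}

#' Write a similarity network as edge-list and membership TSVs
#'
#' @param ssn An `rnr_ssn`.
#' @param edge_path,node_path Output TSV paths.
#' @export
write_ssn <- function(ssn, edge_path, node_path) {
  e <- igraph::as_data_frame(ssn$graph, what = "edges")
  names(e) <- c("node_a", "node_b", "score")[seq_along(names(e))]
  write.table(e, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  v <- igraph::as_data_frame(ssn$graph, what = "vertices")
  write.table(v, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining on a symmetric, zero-diagonal, non-negative
#' distance matrix. When the matrix is additive the output tree's path
#' metric reproduces it exactly (up to numerical tolerance).
#'
#' @param d Symmetric numeric matrix with zero diagonal (or a `dist`).
#' @return An `ape::phylo` tree (unrooted for >= 3 taxa).
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  if (any(d < 0)) stopf("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stopf("diagonal must be zero")
  if (max(abs(d - t(d))) > 1e-9) stopf("matrix must be symmetric")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(nrow(d)))
  }
  ape::nj(stats::as.dist(d))
}

# leaf-id sets on the far side of each internal edge (own traversal,
# shared by clade_query and its tests' brute-force counterpart)
edge_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  # postorder guarantees children resolved before parents
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  lapply(seq_len(nrow(tree$edge)), function(e) sort(desc[[tree$edge[e, 2]]]))
}

#' Query the placement of a focal set of leaves
#'
#' Tests unrooted monophyly: whether some edge of the tree separates
#' exactly the focal leaves from the rest. If so, reports the label
#' composition of the subtrees adjacent to the focal clade (its immediate
#' phylogenetic neighborhood, e.g. the groups for which the focal clade is
#' an outgroup).
#'
#' @param tree An `ape::phylo`.
#' @param focal_ids Character vector of focal tip labels.
#' @param group_labels Named character vector mapping every tip label to a
#'   group label (defaults to the tip labels themselves).
#' @return List with `monophyletic` (logical), `sister_groups` (labels of
#'   the nearest adjacent subtree(s)), and `adjacent` (list of label sets
#'   per adjacent subtree, nearest first).
#' @export
clade_query <- function(tree, focal_ids, group_labels = NULL) {
  tips <- tree$tip.label
  if (!all(focal_ids %in% tips)) stopf("focal ids not all in tree")
  if (is.null(group_labels)) group_labels <- stats::setNames(tips, tips)
  focal <- sort(unique(focal_ids))
  if (length(focal) == length(tips)) {
    return(list(monophyletic = TRUE, sister_groups = character(0),
                adjacent = list()))
  }
  splits <- edge_splits(tree)
  hit <- NA_integer_
  for (e in seq_along(splits)) {
    s <- splits[[e]]
    comp <- sort(setdiff(tips, s))
    if (identical(s, focal) || identical(comp, focal)) { hit <- e; break }
  }
  if (length(focal) == 1L && is.na(hit)) {
    # a single tip is always separated by its pendant edge
    hit <- which(vapply(splits, function(s) identical(s, focal), logical(1)))[1]
  }
  if (is.na(hit)) {
    return(list(monophyletic = FALSE, sister_groups = character(0),
                adjacent = list()))
  }
  # walk outward from the non-focal end of the split edge; each incident
  # edge leads to one adjacent subtree
  a <- tree$edge[hit, 1]; b <- tree$edge[hit, 2]
  focal_end <- if (setequal(splits[[hit]], focal)) b else a
  other_end <- if (focal_end == b) a else b
  inc <- which(tree$edge[, 1] == other_end | tree$edge[, 2] == other_end)
  inc <- setdiff(inc, hit)
  adjacent <- lapply(inc, function(e) {
    far <- splits[[e]]
    if (other_end == tree$edge[e, 1]) {
      sub <- far                      # child side of that edge
    } else {
      sub <- sort(setdiff(tips, far)) # edge points into other_end
    }
    sub <- setdiff(sub, focal)
    sort(unique(unname(group_labels[sub])))
  })
  adjacent <- adjacent[vapply(adjacent, length, integer(1)) > 0]
  sister <- if (length(adjacent)) adjacent[[1]] else character(0)
  list(monophyletic = TRUE, sister_groups = sister, adjacent = adjacent)
}
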