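# Independent oracles used across the suite. These deliberately do not
# share code with the package: the DP oracle is a plain-R Gotoh
# implementation (checked itself against exhaustive enumeration on tiny
# inputs), the pattern oracle hard-codes the group residue sets, and the
# clustering oracle re-implements the greedy loop on oracle alignments.

.oracle_blosum <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  m["X", ] <- 0L
  m[, "X"] <- 0L
  m
})

# Gotoh affine-gap global alignment; a gap of length L costs open + L*ext.
# Returns score and one optimal pair of gapped rows (deterministic
# traceback preference: match > gap-in-b > gap-in-a).
oracle_global <- function(a, b, open = 10, ext = 1, mat = .oracle_blosum) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback
  ra <- rb <- character(0)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  while (i > 0 || j > 0) {
    if (state == 1L && i > 0 && j > 0) {
      s <- mat[av[i], bv[j]]
      prev <- c(M[i, j], X[i, j], Y[i, j])
      state <- which.max(prev)
      ra <- c(av[i], ra); rb <- c(bv[j], rb)
      i <- i - 1; j <- j - 1
    } else if (state == 2L && i > 0) {
      cur <- X[i + 1, j + 1]
      prev <- c(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                Y[i, j + 1] - open - ext)
      state <- which.max(abs(prev - cur) < 1e-9)
      ra <- c(av[i], ra); rb <- c("-", rb)
      i <- i - 1
    } else if (state == 3L && j > 0) {
      cur <- Y[i + 1, j + 1]
      prev <- c(M[i + 1, j] - open - ext, X[i + 1, j] - open - ext,
                Y[i + 1, j] - ext)
      state <- which.max(abs(prev - cur) < 1e-9)
      ra <- c("-", ra); rb <- c(bv[j], rb)
      j <- j - 1
    } else if (i > 0) {       # forced into remaining gaps
      ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1; state <- 2L
    } else {
      ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1; state <- 3L
    }
  }
  list(score = score,
       rows = c(paste(ra, collapse = ""), paste(rb, collapse = "")))
}

# exhaustive enumeration of every global alignment of two short sequences;
# returns the maximum affine-gap score (validates the Gotoh oracle itself)
oracle_enum_score <- function(a, b, open = 10, ext = 1,
                              mat = .oracle_blosum) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  score_cols <- function(ca, cb) {
    s <- 0
    run <- ""  # current gap run: "", "a" (gap in a), "b" (gap in b)
    for (k in seq_along(ca)) {
      if (ca[k] == "-") {
        s <- s - ext - if (run == "a") 0 else open
        run <- "a"
      } else if (cb[k] == "-") {
        s <- s - ext - if (run == "b") 0 else open
        run <- "b"
      } else {
        s <- s + mat[ca[k], cb[k]]
        run <- ""
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, ca, cb) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score_cols(ca, cb))
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, c(ca, av[i]), c(cb, bv[j]))
    }
    if (i <= length(av)) rec(i + 1, j, c(ca, av[i]), c(cb, "-"))
    if (j <= length(bv)) rec(i, j + 1, c(ca, "-"), c(cb, bv[j]))
  }
  rec(1L, 1L, character(0), character(0))
  best
}

# Independent hard-coding of the group-level metal-site residue sets
# (duplicates the bundled table on purpose: a fixture corruption or a
# matcher bug shows up as disagreement).
.oracle_groups <- list(
  NrdBe  = list("D", "E", "H", "E", "E", "H", c("M", "I", "V"), "D"),
  NrdBg  = list("D", "E", "H", "E", "E", "H", "S", "D"),
  NrdBh  = list("D", "E", "H", "E", "E", "H", c("E", "Q"), "D"),
  NrdBk  = list("D", "E", "H", "E", "E", "H", c("M", "R", "I"), c("D", "E")),
  NrdBn  = list("D", "E", "H", "E", "E", "H", "E", "D"),
  NrdBza = list("D", "E", "H", "E", "E", "H", "E", "D"),
  NrdFb  = list("D", "E", "H", "E", "E", "H", "M", "D"),
  NrdBzc = list("E", "E", "H", "E", "E", "H", "E", "D"),
  NrdBi  = list("E", "E", "H", "E", "E", "H", c("C", "S"), c("D", "E")),
  NrdFe  = list("D", c("Q", "V"), "H", c("S", "P"), "K", "H", "M", "D"),
  CyanoSP = list("E", "E", "H", "E", "E", "H", "D", "D")
)

oracle_table4_match <- function(residues, first_sphere_only = FALSE) {
  ks <- if (first_sphere_only) 1:6 else 1:8
  hits <- character(0)
  for (g in names(.oracle_groups)) {
    ok <- TRUE
    for (k in ks) {
      r <- residues[k]
      if (is.na(r) || r == "X" || !(r %in% .oracle_groups[[g]][[k]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, g)
  }
  hits
}

# identity (over shorter) and coverage from an oracle alignment
oracle_identity_cov <- function(a, b) {
  o <- oracle_global(a, b)
  x <- strsplit(o$rows[1], "", fixed = TRUE)[[1]]
  y <- strsplit(o$rows[2], "", fixed = TRUE)[[1]]
  list(identity = sum(x == y & x != "-" & x != "X") /
         min(nchar(a), nchar(b)),
       coverage = sum(x != "-" & y != "-") / length(x))
}

# independent greedy clustering on oracle alignments
oracle_greedy_cluster <- function(seqs, threshold, coverage = 0.8) {
  ord <- order(-nchar(seqs), names(seqs))
  reps <- character(0)
  assign <- character(length(seqs))
  names(assign) <- names(seqs)
  for (i in ord) {
    id <- names(seqs)[i]
    hit <- NA_character_
    for (rep_id in reps) {
      ic <- oracle_identity_cov(seqs[[rep_id]], seqs[[id]])
      if (ic$identity >= threshold && ic$coverage >= coverage - 1e-12) {
        hit <- rep_id
        break
      }
    }
    if (is.na(hit)) {
      reps <- c(reps, id)
      assign[id] <- id
    } else {
      assign[id] <- hit
    }
  }
  assign
}

# random additive distance matrix from a random tree with distinct
# positive edge lengths; returns the matrix and the generating tree
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = NULL)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 2)
  tr <- ape::unroot(tr)
  list(d = ape::cophenetic.phylo(tr), tree = tr)
}

# substitution-only family sets for clustering oracle comparisons;
# lengths vary across families so longest-first ordering is exercised
random_cluster_set <- function(n_seqs, len_range = c(25, 45)) {
  n_fam <- sample(1:3, 1)
  seqs <- character(0)
  k <- 0L
  for (f in seq_len(n_fam)) {
    len <- sample(len_range[1]:len_range[2], 1)
    anc <- strsplit(paste(sample(rnrclassify:::AA20, len, replace = TRUE),
                          collapse = ""), "", fixed = TRUE)[[1]]
    for (m in seq_len(sample(1:3, 1))) {
      k <- k + 1L
      if (k > n_seqs) break
      mut <- anc
      nmut <- sample(0:round(len * 0.3), 1)
      idx <- sample(len, nmut)
      for (i in idx) mut[i] <- sample(setdiff(rnrclassify:::AA20, mut[i]), 1)
      seqs[[sprintf("s%02d", k)]] <- paste(mut, collapse = "")
    }
    if (k > n_seqs) break
  }
  seqs[seq_len(min(k, n_seqs))]
}
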