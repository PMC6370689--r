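# Internal helpers shared across modules.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S","T","V","W","Y")

#' @noRd
aa_ok <- function(x) {
  all(strsplit(x, "", fixed = TRUE)[[1]] %in% c(AA20, "X"))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic operations in the package funnel
# through this so results are reproducible from (arguments, seed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Draw n background residues (uniform over the 20 standard amino acids).
random_residues <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
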