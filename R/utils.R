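# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# x * log(x) with the 0 log 0 = 0 convention; works elementwise on matrices.
xlogx <- function(x, base = exp(1)) {
  out <- x * log(x)
  out[x == 0] <- 0
  if (base != exp(1)) out <- out / log(base)
  out
}

# Derive a per-stage seed from the master seed; stays below 2^31 - 1.
stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

# Small deterministic polynomial hash of an R object (config provenance).
objectHash <- function(x) {
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Canonical "a|b" edge keys (sorted endpoints) for set comparisons.
edgeKeys <- function(graph) {
  if (igraph::ecount(graph) == 0L) return(character())
  e <- igraph::as_edgelist(graph, names = TRUE)
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "|")
}

assertScalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]",
                 name, format(lower), format(upper)), call. = FALSE)
  invisible(x)
}
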