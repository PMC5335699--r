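# Internal helpers: seeding, pair indexing, small numerics.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. If seed is NULL the expression runs under the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # force RNG initialisation so we can save/restore it
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive `n` child seeds from a master seed so that any
# sub-computation (per network, per system, per run) is replayable alone.
# Seeds stay strictly below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Row-major upper-triangle pair order: (1,2),(1,3),...,(1,N),(2,3),...
# This fixed order makes pattern rows comparable across runs and systems.
pair_order <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

n_pairs <- function(n) n * (n - 1L) / 2L

# Unwrap a phase series: remove 2*pi jumps so the phase is continuous.
unwrap_phase <- function(p) {
  if (length(p) < 2L) return(p)
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(p[1L], p[1L] + cumsum(d))
}

# Breadth-first connectivity on a logical/numeric adjacency matrix.
adjacency_connected <- function(adj) {
  n <- nrow(adj)
  if (n == 1L) return(TRUE)
  seen <- logical(n)
  seen[1L] <- TRUE
  frontier <- 1L
  adj <- adj != 0
  while (length(frontier)) {
    nb <- which(matrixStats_any_col(adj, frontier) & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

# any column of adj[frontier, ] TRUE, without dropping dims for length-1 frontier
matrixStats_any_col <- function(adj, rows) {
  if (length(rows) == 1L) adj[rows, ] else colSums(adj[rows, , drop = FALSE]) > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
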