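#' Structural brain networks
#'
#' A `structural_network` couples two symmetric non-negative \eqn{N \times N}
#' matrices over the same node set: `weights`, the coupling strengths
#' (dimensionless, on the scale of generalised fractional anisotropy values of
#' white-matter tracts), and `lengths`, the mean tract lengths in millimetres.
#' An edge exists where the weight is positive, and every edge carries both a
#' strength and a length; the graph induced by the edges must be connected.
#'
#' @param weights symmetric non-negative numeric matrix of coupling strengths,
#'   zero diagonal.
#' @param lengths symmetric non-negative numeric matrix of tract lengths (mm)
#'   with the same support (nonzero pattern) as `weights`.
#' @param labels optional character vector of node identifiers; defaults to
#'   `"n1" ... "nN"`.
#' @param sym_tol relative tolerance for symmetry on input; matrices within
#'   tolerance are exactly symmetrised by averaging with their transpose.
#' @return An object of class `structural_network` with fields `n_nodes`,
#'   `weights`, `lengths`, `labels`.
#' @export
structural_network <- function(weights, lengths, labels = NULL, sym_tol = 1e-8) {
  weights <- as.matrix(weights)
  lengths <- as.matrix(lengths)
  if (nrow(weights) != ncol(weights)) {
    stop("weights matrix is not square: ", nrow(weights), "x", ncol(weights))
  }
  if (!all(dim(weights) == dim(lengths))) {
    stop("dimension mismatch: weights is ", nrow(weights), "x", ncol(weights),
         ", lengths is ", nrow(lengths), "x", ncol(lengths))
  }
  n <- nrow(weights)
  weights <- check_symmetrise(weights, "weights", sym_tol)
  lengths <- check_symmetrise(lengths, "lengths", sym_tol)
  diag(weights) <- 0
  diag(lengths) <- 0
  for (nm in c("weights", "lengths")) {
    m <- get(nm)
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop("negative entries in ", nm, " at [",
           paste(neg[1, ], collapse = ","), "]",
           if (nrow(neg) > 1) paste0(" and ", nrow(neg) - 1, " more") else "")
    }
  }
  mism <- which((weights > 0) != (lengths > 0), arr.ind = TRUE)
  if (nrow(mism)) {
    stop("edge support mismatch (weight>0 xor length>0) at [",
         paste(mism[1, ], collapse = ","), "]",
         if (nrow(mism) > 1) paste0(" and ", nrow(mism) - 1, " more") else "")
  }
  if (!adjacency_connected(weights)) {
    comp <- connected_component(weights)
    stop("network is disconnected; nodes ",
         paste(which(!comp), collapse = ", "),
         " are unreachable from node 1")
  }
  if (is.null(labels)) labels <- paste0("n", seq_len(n))
  if (length(labels) != n) stop("labels length ", length(labels), " != ", n, " nodes")
  labels <- as.character(labels)
  dimnames(weights) <- dimnames(lengths) <- list(labels, labels)
  structure(
    list(n_nodes = n, weights = weights, lengths = lengths, labels = labels),
    class = "structural_network"
  )
}

check_symmetrise <- function(m, name, tol) {
  scale <- max(abs(m), 1e-300)
  asym <- abs(m - t(m)) / scale
  if (max(asym) > tol) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(name, " asymmetric beyond tolerance at [", paste(idx, collapse = ","),
         "]: relative difference ", signif(max(asym), 3))
  }
  (m + t(m)) / 2
}

connected_component <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n); seen[1L] <- TRUE; frontier <- 1L
  adj <- adj != 0
  while (length(frontier)) {
    nb <- which(matrixStats_any_col(adj, frontier) & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  seen
}

#' @export
print.structural_network <- function(x, ...) {
  ut <- upper.tri(x$weights)
  e <- sum(x$weights[ut] > 0)
  cat("structural_network:", x$n_nodes, "nodes,", e, "edges\n")
  cat("  weights: [", signif(min(x$weights[x$weights > 0]), 3), ",",
      signif(max(x$weights), 3), "]  lengths (mm): [",
      signif(min(x$lengths[x$lengths > 0]), 3), ",",
      signif(max(x$lengths), 3), "]\n")
  invisible(x)
}

#' Number of edges of a structural network
#' @param net a `structural_network`.
#' @return integer edge count (unordered pairs with positive weight).
#' @export
edge_count <- function(net) {
  sum(net$weights[upper.tri(net$weights)] > 0)
}

#' Edge list with attributes
#'
#' @param net a `structural_network`.
#' @return data.frame with columns `i`, `j` (`i < j`), `weight`, `length`.
#' @export
edge_list <- function(net) {
  idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])
  idx <- idx[ord, , drop = FALSE]
  data.frame(i = idx[, 1], j = idx[, 2],
             weight = net$weights[idx], length = net$lengths[idx])
}

#' Read a structural network from delimited-text matrix files
#'
#' Both files must hold square numeric matrices of identical dimension,
#' comma- or whitespace-delimited. With `header = TRUE` the first row carries
#' node labels. A JSON sidecar written by [write_network()] can be supplied to
#' restore labels and provenance.
#'
#' @param weights_path,lengths_path paths to the two matrix files.
#' @param header logical; does the first row carry node labels?
#' @param json_path optional JSON sidecar path (labels, provenance).
#' @param sym_tol symmetry tolerance, see [structural_network()].
#' @return a `structural_network`.
#' @export
read_network <- function(weights_path, lengths_path, header = FALSE,
                         json_path = NULL, sym_tol = 1e-8) {
  w <- read_matrix_file(weights_path, header)
  l <- read_matrix_file(lengths_path, header)
  labels <- attr(w, "labels") %||% attr(l, "labels")
  if (!is.null(json_path)) {
    side <- jsonlite::read_json(json_path, simplifyVector = TRUE)
    labels <- side$labels %||% labels
  }
  structural_network(w, l, labels = labels, sym_tol = sym_tol)
}

read_matrix_file <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, header = header, sep = sep,
                          check.names = FALSE, strip.white = TRUE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  labels <- if (header) colnames(df) else NULL
  dimnames(m) <- NULL
  attr(m, "labels") <- labels
  m
}

#' Write a structural network to delimited-text files
#'
#' Matrices are written at full double precision so a write/read cycle
#' round-trips bit-identically. A JSON sidecar records labels and optional
#' provenance (seed, generator parameters).
#'
#' @param net a `structural_network`.
#' @param weights_path,lengths_path output paths.
#' @param json_path optional sidecar path.
#' @param provenance optional named list stored in the sidecar.
#' @param sep field separator, default comma.
#' @return invisibly, `net`.
#' @export
write_network <- function(net, weights_path, lengths_path, json_path = NULL,
                          provenance = NULL, sep = ",") {
  write_matrix_file(net$weights, weights_path, sep)
  write_matrix_file(net$lengths, lengths_path, sep)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(labels = net$labels, n_nodes = net$n_nodes, provenance = provenance),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(net)
}

write_matrix_file <- function(m, path, sep = ",") {
  txt <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = sep))
  writeLines(txt, path)
}

#' Degree-, strength- and length-preserving network randomisation
#'
#' Builds a null-hypothesis network by connected double-edge swaps
#' (Maslov–Sneppen rewiring with a connectivity check, the classical
#' `randmio_und_connected` scheme). Each swap exchanges the endpoints of two
#' edges; the (weight, length) attribute pair travels with its edge, so the
#' rewired network preserves the node count, edge count, per-node degree
#' sequence and the exact multiset of (weight, length) pairs, and remains
#' connected. Identical seed and input give an identical null network.
#'
#' @param net a connected `structural_network` with at least 4 edges.
#' @param swaps_per_edge target number of successful swaps per edge.
#' @param seed integer RNG seed.
#' @return a rewired `structural_network`; the number of successful swaps and
#'   attempts are attached as attributes `n_swaps` and `n_attempts`.
#' @export
randomize_network <- function(net, swaps_per_edge = 10, seed = NULL) {
  el <- edge_list(net)
  ne <- nrow(el)
  if (ne < 4L) stop("need at least 4 edges to rewire, got ", ne)
  n <- net$n_nodes
  adj <- net$weights > 0
  target <- as.integer(round(swaps_per_edge * ne))
  max_attempts <- 30L * target

  res <- with_seed(seed, {
    swaps <- 0L
    attempts <- 0L
    while (swaps < target && attempts < max_attempts) {
      attempts <- attempts + 1L
      picks <- sample.int(ne, 2L)
      e1 <- picks[1L]; e2 <- picks[2L]
      a <- el$i[e1]; b <- el$j[e1]
      c <- el$i[e2]; d <- el$j[e2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # proposed rewiring: (a,b),(c,d) -> (a,d),(c,b)
      if (a == d || c == b || a == c || b == d) next
      if (adj[a, d] || adj[c, b]) next
      adj[a, b] <- adj[b, a] <- FALSE
      adj[c, d] <- adj[d, c] <- FALSE
      adj[a, d] <- adj[d, a] <- TRUE
      adj[c, b] <- adj[b, c] <- TRUE
      if (!adjacency_connected(adj)) { # revert: swap broke connectedness
        adj[a, d] <- adj[d, a] <- FALSE
        adj[c, b] <- adj[b, c] <- FALSE
        adj[a, b] <- adj[b, a] <- TRUE
        adj[c, d] <- adj[d, c] <- TRUE
        next
      }
      el$i[e1] <- min(a, d); el$j[e1] <- max(a, d)
      el$i[e2] <- min(c, b); el$j[e2] <- max(c, b)
      swaps <- swaps + 1L
    }
    list(el = el, swaps = swaps, attempts = attempts)
  })

  if (res$swaps == 0L) {
    warning("no successful swap in ", res$attempts,
            " attempts; topology returned unchanged")
  }
  w <- matrix(0, n, n)
  l <- matrix(0, n, n)
  ij <- cbind(res$el$i, res$el$j)
  w[ij] <- res$el$weight; w[ij[, 2:1]] <- res$el$weight
  l[ij] <- res$el$length; l[ij[, 2:1]] <- res$el$length
  out <- structural_network(w, l, labels = net$labels)
  attr(out, "n_swaps") <- res$swaps
  attr(out, "n_attempts") <- res$attempts
  out
}
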