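#' Specification of a synthetic structural network
#'
#' Parameters of the generator that emulates DSI-derived cortical networks:
#' a modular (planted-partition) topology, log-normal coupling strengths on
#' the GFA scale, and tract lengths obtained from a random spatial embedding
#' so that lengths respect the triangle-inequality-like structure real tracts
#' approximate.
#'
#' @param n_nodes number of nodes.
#' @param n_modules number of planted modules.
#' @param p_within edge probability inside a module (must be >= `p_between`).
#' @param p_between edge probability between modules.
#' @param weight_meanlog,weight_sdlog log-normal parameters of edge weights;
#'   defaults give a median of 0.05 on the GFA scale (~0.02-0.13).
#' @param embedding_dim spatial dimension of the node embedding.
#' @param length_scale mm of tract per unit embedding distance.
#' @param min_length_mm lower floor on tract lengths (mm); mirrors the minimum
#'   fibre length used when tracts are reconstructed from diffusion data.
#' @param module_sd spatial spread of nodes around their module centre.
#' @param between_weight_factor multiplicative attenuation of between-module
#'   edge weights (in (0, 1]); values below 1 emulate the weaker anisotropy
#'   of long-range association tracts relative to dense local connectivity.
#' @param seed integer RNG seed.
#' @return an object of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(n_nodes = 34, n_modules = 4,
                                   p_within = 0.6, p_between = 0.1,
                                   weight_meanlog = log(0.05),
                                   weight_sdlog = 0.5,
                                   embedding_dim = 3, length_scale = 100,
                                   min_length_mm = 20, module_sd = 0.08,
                                   between_weight_factor = 1,
                                   seed = 1L) {
  stopifnot(n_nodes >= 2, n_modules >= 1, n_modules <= n_nodes,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            embedding_dim >= 1, length_scale > 0, min_length_mm >= 0,
            between_weight_factor > 0, between_weight_factor <= 1)
  if (p_within < p_between) {
    stop("p_within (", p_within, ") must be >= p_between (", p_between,
         ") for modular structure")
  }
  structure(as.list(environment()), class = "synthetic_network_spec")
}

#' Generate a synthetic modular structural network
#'
#' Nodes are assigned to modules (balanced), embedded in space around module
#' centres, and wired by a planted-partition rule (`p_within` inside modules,
#' `p_between` across). Edge weights are log-normal; edge lengths are the
#' Euclidean embedding distances times `length_scale`, floored at
#' `min_length_mm`. Generation retries (with deterministic sub-seeds) until
#' the network is connected; identical spec and seed give identical output.
#'
#' @param spec a [synthetic_network_spec()].
#' @param max_retries attempts before giving up on connectedness.
#' @return a `structural_network`; the planted module assignment is attached
#'   as attribute `modules`.
#' @export
generate_network <- function(spec, max_retries = 50L) {
  stopifnot(inherits(spec, "synthetic_network_spec"))
  sub_seeds <- derive_seeds(spec$seed, max_retries)
  for (r in seq_len(max_retries)) {
    net <- try(generate_network_once(spec, sub_seeds[r]), silent = TRUE)
    if (!inherits(net, "try-error")) return(net)
  }
  stop("generated graph disconnected after ", max_retries, " retries; ",
       "raise p_within/p_between or n_nodes")
}

generate_network_once <- function(spec, seed) {
  with_seed(seed, {
    n <- spec$n_nodes
    modules <- sort(rep_len(seq_len(spec$n_modules), n))
    centres <- matrix(stats::runif(spec$n_modules * spec$embedding_dim),
                      spec$n_modules, spec$embedding_dim)
    pos <- centres[modules, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$embedding_dim, sd = spec$module_sd),
             n, spec$embedding_dim)
    po <- pair_order(n)
    same <- modules[po[, "i"]] == modules[po[, "j"]]
    p <- ifelse(same, spec$p_within, spec$p_between)
    on_edge <- stats::runif(nrow(po)) < p
    w <- matrix(0, n, n)
    l <- matrix(0, n, n)
    ij <- po[on_edge, , drop = FALSE]
    wts <- stats::rlnorm(nrow(ij), spec$weight_meanlog, spec$weight_sdlog)
    wts <- wts * ifelse(same[on_edge], 1, spec$between_weight_factor)
    d <- sqrt(rowSums((pos[ij[, 1], , drop = FALSE] -
                         pos[ij[, 2], , drop = FALSE])^2))
    lens <- pmax(d * spec$length_scale, spec$min_length_mm)
    w[ij] <- wts; w[ij[, 2:1]] <- wts
    l[ij] <- lens; l[ij[, 2:1]] <- lens
    net <- structural_network(w, l) # errors if disconnected -> retry upstream
    attr(net, "modules") <- modules
    net
  })
}

#' Split network nodes into random cortical segments
#'
#' Emulates replacing each anatomical landmark node by several smaller random
#' cortical segments while retaining the original white-matter structure.
#' The `n_segments` child nodes are partitioned over the original parents
#' (every parent keeps at least one child; the remainder is spread uniformly
#' at random, giving comparable segment counts). Each original edge (u, v)
#' is inherited by exactly one randomly chosen (child-of-u, child-of-v) pair,
#' carrying its weight and length unchanged; children of the same parent are
#' joined by short, strong edges so the result stays connected.
#'
#' @param net parent `structural_network`.
#' @param n_segments total number of child nodes (>= `net$n_nodes`).
#' @param seed integer RNG seed.
#' @param sibling_length_mm length of intra-parent child edges (mm).
#' @param sibling_weight weight of intra-parent child edges; defaults to the
#'   maximum parent edge weight (a strong local connection).
#' @return a `structural_network` on `n_segments` nodes; the parent of each
#'   child is attached as attribute `parents`.
#' @export
generate_partitioned_variant <- function(net, n_segments, seed = NULL,
                                         sibling_length_mm = 20,
                                         sibling_weight = NULL) {
  n <- net$n_nodes
  if (n_segments < n) {
    stop("n_segments (", n_segments, ") must be >= number of parent nodes (",
         n, ")")
  }
  if (is.null(sibling_weight)) sibling_weight <- max(net$weights)
  with_seed(seed, {
    extra <- n_segments - n
    counts <- rep(1L, n)
    if (extra > 0) {
      add <- sample.int(n, extra, replace = TRUE)
      counts <- counts + tabulate(add, nbins = n)
    }
    parents <- rep(seq_len(n), counts)
    children_of <- split(seq_len(n_segments), parents)
    w <- matrix(0, n_segments, n_segments)
    l <- matrix(0, n_segments, n_segments)
    el <- edge_list(net)
    for (e in seq_len(nrow(el))) {
      cu <- children_of[[el$i[e]]]
      cv <- children_of[[el$j[e]]]
      u <- if (length(cu) == 1L) cu else sample(cu, 1L)
      v <- if (length(cv) == 1L) cv else sample(cv, 1L)
      w[u, v] <- w[v, u] <- el$weight[e]
      l[u, v] <- l[v, u] <- el$length[e]
    }
    for (kids in children_of) {
      if (length(kids) > 1L) {
        for (a in seq_along(kids)[-length(kids)]) {
          for (b in (a + 1L):length(kids)) {
            u <- kids[a]; v <- kids[b]
            w[u, v] <- w[v, u] <- sibling_weight
            l[u, v] <- l[v, u] <- sibling_length_mm
          }
        }
      }
    }
    labels <- paste0(net$labels[parents], ".s",
                     unlist(lapply(counts, seq_len), use.names = FALSE))
    out <- structural_network(w, l, labels = labels)
    attr(out, "parents") <- parents
    out
  })
}
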