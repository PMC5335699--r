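# Fixtures are generated in code; seeds fixed so every run sees the same data.

fixture_net_34 <- function(seed = 3) {
  generate_network(synthetic_network_spec(seed = seed))
}

fixture_net_8 <- function(seed = 3) {
  generate_network(synthetic_network_spec(
    n_nodes = 8, n_modules = 2, p_within = 1.0, p_between = 0.15,
    weight_meanlog = log(0.1), between_weight_factor = 0.3, seed = seed))
}

# simple ring on 4 nodes with distinct edge attributes
net_cycle4 <- function() {
  w <- matrix(0, 4, 4); l <- matrix(0, 4, 4)
  e <- rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))
  w[e] <- c(0.1, 0.2, 0.3, 0.4); l[e] <- c(30, 40, 50, 60)
  w[e[, 2:1]] <- w[e]; l[e[, 2:1]] <- l[e]
  structural_network(w, l)
}

net_k4 <- function() {
  w <- matrix(0.1, 4, 4); diag(w) <- 0
  l <- matrix(50, 4, 4); diag(l) <- 0
  structural_network(w, l)
}

# planted isotropic Gaussian blobs; labels returned for recovery checks
make_blobs <- function(centers, n, sd = 0.3, seed = 42) {
  withr_seed <- seed # plain set.seed is fine inside tests
  set.seed(withr_seed)
  k <- nrow(centers)
  lab <- sample(rep_len(seq_len(k), n))
  x <- centers[lab, , drop = FALSE] +
    matrix(rnorm(n * ncol(centers), sd = sd), n, ncol(centers))
  list(x = x, labels = lab)
}

# multiset of (weight, length) pairs as a canonical sorted string
edge_attr_multiset <- function(net) {
  el <- edge_list(net)
  sort(paste(format(el$weight, digits = 15), format(el$length, digits = 15)))
}

uniform_trajectory <- function(omega, n_steps = 2000, init = c(0, 0),
                               burn_in = 100) {
  ph <- sapply(seq_along(omega), function(k) init[k] + omega[k] * seq_len(n_steps))
  structure(list(phases = ph, dt = 0.001, burn_in = burn_in,
                 n_steps = n_steps), class = "phase_trajectory")
}
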