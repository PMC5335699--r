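test_that("networks are validated, symmetrised and read/written faithfully", {
  tmp <- withr::local_tempdir()
  wp <- file.path(tmp, "w.csv"); lp <- file.path(tmp, "l.csv")

  writeLines(c("0,0.3", "0.3,0"), wp)
  writeLines(c("0,40", "40,0"), lp)
  net <- read_network(wp, lp)
  expect_equal(net$n_nodes, 2)
  expect_equal(edge_count(net), 1)
  expect_equal(net$weights[1, 2], 0.3)
  expect_equal(net$lengths[1, 2], 40)

  # dimension mismatch between the two files
  writeLines(c("0 1 1", "1 0 1", "1 1 0"), wp)
  writeLines(c("0 1 1 1", "1 0 1 1", "1 1 0 1", "1 1 1 0"), lp)
  expect_error(read_network(wp, lp), "mismatch")

  # invalid matrices are rejected with located errors
  expect_error(structural_network(matrix(c(0, 1, 2, 0), 2), matrix(0, 2, 2)),
               "asymmetric")
  w <- matrix(c(0, -1, -1, 0), 2)
  expect_error(structural_network(w, abs(w) * 10), "negative")
  w <- diag(4) * 0; w[1, 2] <- w[2, 1] <- 1; w[3, 4] <- w[4, 3] <- 1
  expect_error(structural_network(w, w * 10), "disconnected")
  w2 <- matrix(c(0, 1, 1, 0), 2)
  l2 <- matrix(0, 2, 2)
  expect_error(structural_network(w2, l2), "support mismatch")

  # 34-node synthetic network round-trips bit-identically
  net34 <- fixture_net_34()
  write_network(net34, wp, lp, json_path = file.path(tmp, "meta.json"))
  back <- read_network(wp, lp, json_path = file.path(tmp, "meta.json"))
  expect_identical(back$weights, net34$weights)
  expect_identical(back$lengths, net34$lengths)
  expect_identical(back$labels, net34$labels)
})

test_that("small asymmetries are averaged away within tolerance", {
  w <- matrix(c(0, 0.3, 0.3 + 1e-12, 0), 2)
  net <- structural_network(w, matrix(c(0, 40, 40, 0), 2))
  expect_identical(net$weights, t(net$weights))
})

test_that("rewiring conserves degrees, edge count and attribute pairing", {
  for (net in list(net_cycle4(), fixture_net_8(), fixture_net_34())) {
    null <- randomize_network(net, swaps_per_edge = 10, seed = 7)
    expect_equal(sort(rowSums(null$weights > 0)), sort(rowSums(net$weights > 0)))
    expect_equal(edge_count(null), edge_count(net))
    expect_identical(edge_attr_multiset(null), edge_attr_multiset(net))
    expect_true(strobosync:::adjacency_connected(null$weights))
  }
})

test_that("rewiring is deterministic given a seed and varies across seeds", {
  net <- fixture_net_34()
  a <- randomize_network(net, seed = 11)
  b <- randomize_network(net, seed = 11)
  c <- randomize_network(net, seed = 12)
  expect_identical(a$weights, b$weights)
  expect_identical(a$lengths, b$lengths)
  expect_false(identical(a$weights, c$weights))
})

test_that("complete graph admits no alternative topology", {
  # the only simple graph with degree sequence (3,3,3,3) is K4 itself
  k4 <- net_k4()
  expect_warning(null <- randomize_network(k4, seed = 5), "no successful swap")
  expect_identical(null$weights > 0, k4$weights > 0)
})

test_that("the null ensemble protocol produces 15 valid independent nulls", {
  net <- fixture_net_34()
  nulls <- lapply(1:15, function(s) randomize_network(net, seed = s))
  for (null in nulls) {
    expect_true(strobosync:::adjacency_connected(null$weights))
    expect_identical(edge_attr_multiset(null), edge_attr_multiset(net))
  }
  topos <- vapply(nulls, function(x) paste(which(x$weights > 0), collapse = ","),
                  "")
  expect_gt(length(unique(topos)), 1)
})
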