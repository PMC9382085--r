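star_net <- function(k) {
  network(edges = data.frame(rep("HUB", k), sprintf("L%02d", seq_len(k))))
}

test_that("seed expansion adds first neighbours with induced edges", {
  star <- star_net(4)
  sub <- expand_subnetwork(star, "L01")
  expect_setequal(sub$nodes, c("L01", "HUB"))
  expect_equal(n_edges(sub), 1)
  sub2 <- expand_subnetwork(star, "HUB")
  expect_equal(n_nodes(sub2), 5)
  expect_equal(n_edges(sub2), 4)
  expect_error(expand_subnetwork(star, "ZZZ"), "no seed")
  part <- expand_subnetwork(star, c("L01", "ZZZ"))
  expect_identical(attr(part, "missing_seeds"), "ZZZ")
})

test_that("seed expansion equals a depth-1 BFS oracle on a large network", {
  cfg <- synthetic_config(seed = 388, interactome = list(n_nodes = 3000L))
  inter <- generate_interactome(cfg)
  set.seed(388)
  seeds <- sample(inter$nodes, 388)
  sub <- expand_subnetwork(inter, seeds)
  # oracle: explicit scan of the raw edge table
  nb <- unique(c(inter$edges$to[inter$edges$from %in% seeds],
                 inter$edges$from[inter$edges$to %in% seeds]))
  want_nodes <- union(seeds, nb)
  keep <- inter$edges$from %in% want_nodes & inter$edges$to %in% want_nodes
  expect_setequal(sub$nodes, want_nodes)
  expect_equal(n_edges(sub), sum(keep))
  expect_equal(n_nodes(expand_subnetwork(inter, seeds, depth = 0)),
               length(intersect(seeds, inter$nodes)))
})

test_that("network intersection is the set intersection of nodes and edges", {
  a <- network(edges = data.frame(c("A", "B", "C"), c("B", "C", "D")))
  expect_equal(n_edges(intersect_networks(a, a)), n_edges(a))
  expect_identical(intersect_networks(a, a)$nodes, a$nodes)
  b <- network(edges = data.frame("X", "Y"))
  expect_equal(n_nodes(intersect_networks(a, b)), 0)

  set.seed(73)
  base <- random_network(60, 0.08)
  n1 <- induced_subgraph(base, sample(base$nodes, 40))
  n2 <- induced_subgraph(base, sample(base$nodes, 40))
  got <- intersect_networks(n1, n2)
  expect_setequal(got$nodes, intersect(n1$nodes, n2$nodes))
  k1 <- paste(n1$edges$from, n1$edges$to)
  k2 <- paste(n2$edges$from, n2$edges$to)
  expect_setequal(paste(got$edges$from, got$edges$to), intersect(k1, k2))
})

test_that("centrality indices reproduce closed-form families", {
  path3 <- network(edges = data.frame(c("A", "B"), c("B", "C")))
  ct <- compute_centralities(path3)
  b <- which(ct$node == "B")
  expect_equal(ct$BC[b], 1)
  expect_equal(ct$BC[-b], c(0, 0))
  expect_equal(ct$CC[b], 1)
  expect_equal(ct$DC[b], 2)
  expect_equal(ct$EC[b], 1 / sqrt(2), tolerance = 1e-10)

  star <- compute_centralities(star_net(4))
  hub <- which(star$node == "HUB")
  expect_equal(star$BC[hub], choose(4, 2))
  expect_equal(star$LAC[hub], 0)
  expect_equal(star$EC[hub], 1 / sqrt(2), tolerance = 1e-10)

  k3 <- compute_centralities(network(edges = data.frame(
    c("A", "A", "B"), c("B", "C", "C"))))
  expect_equal(k3$LAC, rep(1, 3))
  expect_equal(k3$NC, rep(2, 3))
  expect_equal(k3$CC, rep(1, 3))
  expect_equal(k3$EC, rep(1 / sqrt(3), 3), tolerance = 1e-10)

  # complete graph: all indices constant, NC = n - 1
  for (n in c(4, 6)) {
    pairs <- t(utils::combn(sprintf("V%d", 1:n), 2))
    kn <- compute_centralities(network(edges = as.data.frame(pairs)))
    expect_equal(kn$NC, rep(n - 1, n))
    expect_equal(kn$LAC, rep(n - 2, n))
    expect_equal(kn$CC, rep(1, n))
    expect_equal(kn$BC, rep(0, n))
    expect_equal(kn$EC, rep(1 / sqrt(n), n), tolerance = 1e-10)
  }
})

test_that("eigenvector centrality is constant on vertex-transitive graphs", {
  ring <- sprintf("R%02d", 1:12)
  cyc <- network(edges = data.frame(ring, ring[c(2:12, 1)]))
  ct <- compute_centralities(cyc)
  expect_equal(ct$EC, rep(1 / sqrt(12), 12), tolerance = 1e-8)
  expect_equal(ct$NC, rep(0, 12))
})

test_that("betweenness matches exhaustive path enumeration on small graphs", {
  set.seed(79)
  for (rep in 1:8) {
    net <- random_network(sample(5:8, 1), stats::runif(1, 0.3, 0.7))
    got <- compute_centralities(net)
    want <- oracle_bc_enum(net)
    expect_equal(got$BC, want$BC, tolerance = 1e-10)
  }
})

test_that("LAC and NC match the literal-formula oracle", {
  set.seed(83)
  for (rep in 1:10) {
    net <- random_network(sample(8:25, 1), stats::runif(1, 0.1, 0.5))
    got <- compute_centralities(net)
    want <- oracle_lac_nc(net)
    expect_equal(got$LAC, want$LAC, tolerance = 1e-12)
    expect_equal(got$NC, want$NC, tolerance = 1e-12)
  }
})

test_that("median-multiple thresholds follow order statistics", {
  expect_equal(median_multiple_threshold(c(1, 1, 2, 3, 5, 8)), 5)
  expect_equal(median_multiple_threshold(29), 58)
  expect_equal(median_multiple_threshold(rep(7, 10)), 14)
  expect_equal(median_multiple_threshold(c(1, 2, 3), multiplier = 3), 6)
  expect_error(median_multiple_threshold(numeric()), "non-empty")
})

test_that("two-stage screen handles the star and regular-graph extremes", {
  scr <- two_stage_screen(star_net(10))
  expect_equal(scr$stage1_threshold, 2)
  expect_identical(scr$hub_network$nodes, "HUB")
  expect_identical(scr$core_network$nodes, "HUB")
  expect_true(all(scr$stage2_thresholds == 0))

  ring <- sprintf("R%02d", 1:8)
  cyc <- network(edges = data.frame(ring, ring[c(2:8, 1)]))
  expect_error(two_stage_screen(cyc), "stage-1")

  # multiplier 0 keeps everything at both stages
  set.seed(89)
  net <- random_network(30, 0.15)
  scr0 <- two_stage_screen(net, multiplier = 0)
  expect_identical(scr0$hub_network$nodes, net$nodes)
  expect_identical(scr0$core_network$nodes, net$nodes)
})

test_that("screening reports are self-consistent and nested", {
  set.seed(97)
  for (rep in 1:3) {
    cfg <- synthetic_config(seed = 500 + rep,
                            interactome = list(n_nodes = 500L))
    net <- generate_interactome(cfg)
    scr <- two_stage_screen(net)
    expect_equal(scr$stage1_threshold,
                 2 * stats::median(scr$stage1_table$DC))
    for (ix in c("DC", "BC", "EC", "CC", "LAC", "NC")) {
      expect_equal(scr$stage2_thresholds[[ix]],
                   2 * stats::median(scr$stage2_table[[ix]]))
    }
    expect_true(all(scr$core_network$nodes %in% scr$hub_network$nodes))
    expect_true(all(scr$hub_network$nodes %in% net$nodes))
    core_rows <- scr$stage2_table[scr$stage2_table$core, , drop = FALSE]
    for (ix in c("DC", "BC", "EC", "CC", "LAC", "NC")) {
      expect_true(all(core_rows[[ix]] >= scr$stage2_thresholds[[ix]]))
    }
  }
})

test_that("screening is invariant to node relabeling", {
  set.seed(101)
  net <- random_network(40, 0.12)
  relabel <- stats::setNames(sprintf("Z%03d", sample(40)), net$nodes)
  net2 <- network(nodes = unname(relabel[net$nodes]),
                  edges = data.frame(relabel[net$edges$from],
                                     relabel[net$edges$to]))
  s1 <- tryCatch(two_stage_screen(net), error = function(e) NULL)
  s2 <- tryCatch(two_stage_screen(net2), error = function(e) NULL)
  if (is.null(s1)) {
    expect_null(s2)
  } else {
    expect_setequal(unname(relabel[s1$hub_network$nodes]),
                    s2$hub_network$nodes)
    expect_setequal(unname(relabel[s1$core_network$nodes]),
                    s2$core_network$nodes)
  }
})
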