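small_lib <- function() {
  gene_set_library(list(
    T1 = list(description = "hit term", genes = sprintf("Q%02d", 1:5)),
    T2 = list(description = "background", genes = sprintf("B%02d", 1:8))))
}

test_that("hypergeometric tail matches exact enumeration", {
  # M=20, K=5, n=5, k=3 worked example: 1126/15504
  uni <- sprintf("U%02d", 1:20)
  lib <- gene_set_library(list(
    TERM = list(description = "t", genes = uni[1:5])))
  query <- c(uni[1:3], uni[10:11])  # 3 hits of 5
  res <- hypergeom_ora(query, lib, universe = uni)
  expect_equal(res$p, 1126 / 15504, tolerance = 1e-12)
  expect_equal(res$p, oracle_hyper_tail(20, 5, 5, 3), tolerance = 1e-12)
  expect_equal(res$k, 3)

  # k = 0 gives the full tail, p = 1
  res0 <- hypergeom_ora(uni[10:14], lib, universe = uni)
  expect_equal(res0$p, 1)
  # degenerate identity: query = term = universe
  lib2 <- gene_set_library(list(ALL = list(description = "", genes = uni)))
  resall <- hypergeom_ora(uni, lib2, universe = uni)
  expect_equal(resall$p, 1)
})

test_that("hypergeometric p agrees with set-resampling Monte Carlo", {
  set.seed(103)
  for (rep in 1:10) {
    M <- sample(15:40, 1)
    K <- sample(3:(M - 5), 1)
    n <- sample(3:(M - K + 2), 1)
    n <- min(n, M - 1)
    draws <- 20000
    hits <- integer(draws)
    for (d in seq_len(draws)) {
      hits[d] <- sum(sample.int(M, n) <= K)
    }
    k <- min(max(2, round(stats::quantile(hits, 0.8))), min(K, n) - 1)
    k <- max(k, 1)
    p_mc <- mean(hits >= k)
    p_exact <- oracle_hyper_tail(M, K, n, k)
    uni <- sprintf("U%03d", seq_len(M))
    lib <- gene_set_library(list(T = list(description = "", genes = uni[1:K])))
    query <- uni[seq_len(k)]
    if (n > k) query <- c(query, uni[(K + 1):(K + n - k)])
    got <- hypergeom_ora(query, lib, universe = uni)$p
    expect_equal(got, p_exact, tolerance = 1e-12)
    mc_sigma <- sqrt(p_exact * (1 - p_exact) / draws)
    expect_lt(abs(got - p_mc), max(3 * mc_sigma, 1e-3))
  }
})

test_that("query genes outside the universe are dropped with a warning", {
  uni <- sprintf("U%02d", 1:10)
  lib <- gene_set_library(list(T = list(description = "", genes = uni[1:4])))
  expect_warning(res <- hypergeom_ora(c(uni[1:2], "XX"), lib, universe = uni),
                 "outside the universe")
  expect_equal(res$n, 2)
  expect_error(suppressWarnings(hypergeom_ora("XX", lib, universe = uni)),
               "query empty")
})

test_that("p-value corrections match their oracles", {
  terms <- data.frame(term_id = c("a", "b", "c"),
                      p = c(0.01, 0.02, 0.03))
  bon <- correct_pvalues(terms, "bonferroni")
  expect_equal(bon$p_adj, c(0.03, 0.06, 0.09))
  single <- correct_pvalues(terms[1, , drop = FALSE], "holm")
  expect_equal(single$p_adj, single$p)

  set.seed(107)
  many <- data.frame(term_id = sprintf("t%03d", 1:100),
                     p = stats::runif(100))
  bh <- correct_pvalues(many, "bh")
  expect_equal(bh$p_adj, oracle_bh(many$p), tolerance = 1e-12)
  expect_true(all(bh$p_adj >= bh$p))
  holm <- correct_pvalues(many, "holm")
  expect_true(all(holm$p_adj >= holm$p))
  expect_error(correct_pvalues(many, "fdr"), "arg")
})

test_that("kappa agreement reproduces the worked example and bounds", {
  g <- sprintf("g%d", 1:8)
  expect_equal(kappa_score(g[1:5], g[1:5], 20), 1)
  # a=2, b=3, c=3, d=12 over q=20: po=0.7, pe=0.625, kappa=0.2
  expect_equal(kappa_score(g[1:5], g[4:8], 20), 0.2, tolerance = 1e-12)
  # complementary halves of the query disagree maximally
  expect_equal(kappa_score(sprintf("q%d", 1:10), sprintf("q%d", 11:20), 20),
               -1)
  expect_equal(kappa_score(character(), character(), 15), 1)  # pe = 1 rule
  expect_error(kappa_score(sprintf("q%d", 1:9), sprintf("q%d", 5:12), 10),
               "query_size")

  set.seed(109)
  for (rep in 1:20) {
    q <- sample(5:30, 1)
    pool <- sprintf("q%02d", seq_len(q))
    A <- sample(pool, sample(0:q, 1))
    B <- sample(pool, sample(0:q, 1))
    kab <- kappa_score(A, B, q)
    expect_equal(kab, kappa_score(B, A, q), tolerance = 1e-12)
    expect_gte(kab, -1)
    expect_lte(kab, 1)
    expect_equal(kappa_score(A, A, q), 1)
  }
})

test_that("term grouping takes kappa-linked connected components", {
  uni <- sprintf("U%02d", 1:40)
  lib <- gene_set_library(list(
    A = list(description = "", genes = uni[1:6]),
    B = list(description = "", genes = uni[c(1:5, 7)]),
    C = list(description = "", genes = uni[25:30])))
  res <- correct_pvalues(hypergeom_ora(uni[1:10], lib, universe = uni),
                         "bonferroni")
  grp <- group_terms(res, kappa_min = 0.4, p_adj_max = 1)
  gid <- stats::setNames(grp$group, grp$term_id)
  expect_equal(gid[["A"]], gid[["B"]])
  # C has no query hits and kappa-links to nobody
  expect_false(gid[["C"]] %in% gid[c("A", "B")] &&
               sum(grp$group == gid[["C"]]) > 1)
  expect_equal(sum(grp$leading[grp$group == gid[["A"]]]), 1)
})

test_that("grouping matches a union-find oracle on generated terms", {
  set.seed(113)
  q <- 40
  pool <- sprintf("q%02d", seq_len(q))
  terms <- data.frame(
    term_id = sprintf("t%02d", 1:30),
    k = NA_integer_, n = q, p_adj = stats::runif(30, 0, 0.04),
    hit_genes = NA_character_, stringsAsFactors = FALSE)
  # two planted overlap clusters plus scattered terms
  hits <- vector("list", 30)
  for (i in 1:10) hits[[i]] <- c(pool[1:8], sample(pool[30:40], 2))
  for (i in 11:20) hits[[i]] <- c(pool[15:22], sample(pool[30:40], 2))
  for (i in 21:30) hits[[i]] <- sample(pool, 4)
  terms$hit_genes <- vapply(hits, paste, character(1), collapse = ",")
  terms$k <- lengths(hits)
  grp <- group_terms(terms, kappa_min = 0.4, p_adj_max = 0.05)
  # oracle: union-find over all pairs with kappa >= 0.4
  ea <- character(0); eb <- character(0)
  for (i in 1:29) for (j in (i + 1):30) {
    if (kappa_score(hits[[i]], hits[[j]], q) >= 0.4) {
      ea <- c(ea, terms$term_id[i]); eb <- c(eb, terms$term_id[j])
    }
  }
  want <- oracle_components(terms$term_id, ea, eb)
  got <- grp$group[match(terms$term_id, grp$term_id)]
  expect_equal(length(unique(got)), length(unique(want)))
  same_got <- outer(got, got, "==")
  same_want <- outer(want, want, "==")
  expect_identical(same_got, same_want)
  # raising kappa_min only refines the partition
  finer <- group_terms(terms, kappa_min = 0.7, p_adj_max = 0.05)
  fg <- finer$group[match(terms$term_id, finer$term_id)]
  for (g in unique(fg)) {
    expect_equal(length(unique(got[fg == g])), 1)
  }
})

test_that("the planted term is recovered across seeded replicates", {
  ok <- 0L
  top <- 0L
  n_rep <- 100
  for (s in seq_len(n_rep)) {
    cfg <- synthetic_config(seed = 3000 + s)
    uni <- sprintf("G%05d", 1:2000)
    set.seed(6000 + s)
    query <- sample(uni, 50)
    gl <- generate_geneset_library(cfg, universe = uni, query = query)
    enr <- suppressWarnings(hypergeom_ora(query, gl$library, universe = uni))
    enr <- correct_pvalues(enr)
    prow <- enr[enr$term_id == gl$manifest$planted_term, ]
    if (prow$p_adj <= 0.05) ok <- ok + 1L
    if (enr$term_id[1] == gl$manifest$planted_term) top <- top + 1L
  }
  expect_gte(ok / n_rep, 0.95)
  expect_gte(top / n_rep, 0.95)
})
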