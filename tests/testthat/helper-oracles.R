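# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: adjacency-matrix loops, exhaustive
# path enumeration, literal formula transcriptions.

# random Erdos-Renyi network as npm_network (igraph used for sampling only)
random_network <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g)
  sym <- sprintf("N%03d", seq_len(n))
  network(nodes = sym,
          edges = data.frame(from = sym[el[, 1]], to = sym[el[, 2]]))
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

adj_matrix_of <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  A
}

# literal-formula LAC and NC from the adjacency matrix
oracle_lac_nc <- function(net) {
  A <- adj_matrix_of(net)
  n <- nrow(A)
  deg <- rowSums(A)
  lac <- numeric(n)
  nc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] == 1L)
    if (!length(nb)) next
    sub <- A[nb, nb, drop = FALSE]
    lac[v] <- sum(sub) / length(nb)
    for (u in nb) {
      common <- sum(A[u, ] == 1L & A[v, ] == 1L)
      denom <- min(deg[u] - 1, deg[v] - 1)
      if (denom > 0) nc[v] <- nc[v] + common / denom
    }
  }
  data.frame(node = net$nodes, LAC = lac, NC = nc,
             stringsAsFactors = FALSE)
}

# betweenness by exhaustive enumeration of all simple paths (small n only)
oracle_bc_enum <- function(net) {
  A <- adj_matrix_of(net)
  n <- nrow(A)
  all_paths <- function(s, t) {
    paths <- list()
    walk <- function(v, seen) {
      if (v == t) {
        paths[[length(paths) + 1L]] <<- seen
        return(invisible())
      }
      for (w in which(A[v, ] == 1L)) {
        if (!(w %in% seen)) walk(w, c(seen, w))
      }
    }
    walk(s, s)
    paths
  }
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      sigma <- length(shortest)
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
        bc[v] <- bc[v] + through / sigma
      }
    }
  }
  data.frame(node = net$nodes, BC = bc, stringsAsFactors = FALSE)
}

# exact upper-tail hypergeometric by direct combinatorial summation
oracle_hyper_tail <- function(M, K, n, k) {
  upper <- min(K, n)
  if (k > upper) return(0)
  sum(vapply(k:upper, function(i) {
    choose(K, i) * choose(M - K, n - i)
  }, numeric(1))) / choose(M, n)
}

# Benjamini-Hochberg step-up, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# connected components of an explicit edge list via union-find
oracle_components <- function(ids, edge_a, edge_b) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (e in seq_along(edge_a)) {
    ra <- find(edge_a[e])
    rb <- find(edge_b[e])
    if (ra != rb) parent[[rb]] <- ra
  }
  roots <- vapply(ids, find, character(1))
  match(roots, unique(roots))
}

# small fixture: scored compound-target records
make_records <- function(compound, targets, scores, source = "PM") {
  data.frame(compound = compound, target = targets, score = scores,
             source = source, stringsAsFactors = FALSE)
}
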