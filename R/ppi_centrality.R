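#' Expand seed targets into an interactome subnetwork
#'
#' Seed-plus-neighbour expansion: the subnetwork contains the seeds present
#' in the interactome together with their first neighbours (repeated
#' \code{depth} times), and every interactome edge induced on that node
#' set. Seeds absent from the interactome are reported via the
#' \code{missing_seeds} attribute, not included.
#'
#' @param interactome An \code{npm_network}.
#' @param seeds An \code{npm_targetset} or character vector of symbols.
#' @param depth Neighbour expansion depth (default 1; 0 gives the induced
#'   subgraph on the seeds alone).
#' @param name Label for the result.
#' @return An \code{npm_network}; attribute \code{missing_seeds} lists
#'   seeds not found, and the node attribute \code{seed} flags seed nodes.
#' @export
expand_subnetwork <- function(interactome, seeds, depth = 1L,
                              name = "subnetwork") {
  if (inherits(seeds, "npm_targetset")) seeds <- seeds$symbols
  seeds <- unique(normalize_symbols(seeds))
  if (!length(seeds)) stop("seeds must be non-empty")
  if (depth < 0) stop("depth must be >= 0")
  present <- intersect(seeds, interactome$nodes)
  missing <- setdiff(seeds, interactome$nodes)
  if (!length(present)) stop("no seed found in the interactome")
  nodes <- present
  d <- 0L
  while (d < depth) {
    nodes <- union(nodes, neighbors_of(interactome, nodes))
    d <- d + 1L
  }
  sub <- induced_subgraph(interactome, nodes)
  sub$name <- name
  sub$node_attrs <- data.frame(
    node = sub$nodes,
    seed = as.integer(sub$nodes %in% present),
    stringsAsFactors = FALSE)
  attr(sub, "missing_seeds") <- missing
  sub
}

#' Intersect two networks
#'
#' Node set is the intersection of the node sets; edge set the intersection
#' of the edge sets. Nodes isolated in the intersection are retained.
#'
#' @param a,b \code{npm_network} objects.
#' @param name Label for the result.
#' @return An \code{npm_network}.
#' @export
intersect_networks <- function(a, b, name = "intersection") {
  nodes <- intersect(a$nodes, b$nodes)
  ka <- paste0(a$edges$from, "\r", a$edges$to)
  kb <- paste0(b$edges$from, "\r", b$edges$to)
  keep <- a$edges[ka %in% kb, , drop = FALSE]
  network(nodes, keep, name = name, normalize = FALSE)
}

# Brandes betweenness + closeness + component labels in one BFS sweep.
# Returns list(bc, cc, comp). BC counts unordered pairs, unnormalized;
# CC(v) = (n_c - 1) / sum of distances within v's component, 0 if isolated.
bfs_centralities <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    order_v <- integer(n)
    queue <- integer(n)
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    cnt <- 0L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      cnt <- cnt + 1L
      order_v[cnt] <- v
      dv <- dist[v]
      sv <- sigma[v]
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv + 1L) {
          sigma[w] <- sigma[w] + sv
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    if (cnt > 1L) {
      reach <- order_v[seq_len(cnt)]
      cc[s] <- (cnt - 1) / sum(dist[reach])
    }
    delta <- numeric(n)
    for (k in seq(cnt, 1L)) {
      w <- order_v[k]
      coeff <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] * coeff
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  list(bc = bc / 2, cc = cc)
}

# Principal eigenvector per connected component, unit Euclidean norm within
# each component, zeros elsewhere; components without edges get 0.
# Shifted (A + I) power iteration: deterministic uniform start, the shift
# guarantees convergence on bipartite components.
eigenvector_by_component <- function(adj, comp, tol = 1e-12,
                                     max_iter = 10000L) {
  n <- length(adj)
  ec <- numeric(n)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    nc <- length(members)
    if (nc == 1L || all(lengths(adj[members]) == 0L)) next
    pos <- integer(n)
    pos[members] <- seq_len(nc)
    local_adj <- lapply(adj[members], function(v) pos[v])
    x <- rep(1 / sqrt(nc), nc)
    for (it in seq_len(max_iter)) {
      y <- x
      for (i in seq_len(nc)) {
        y[i] <- x[i] + sum(x[local_adj[[i]]])
      }
      y <- y / sqrt(sum(y * y))
      if (max(abs(y - x)) < tol) {
        x <- y
        break
      }
      x <- y
    }
    ec[members] <- x
  }
  ec
}

#' Compute the six topological centrality indices
#'
#' For every node of an undirected simple network: degree (DC), betweenness
#' (BC, unordered-pair counts, unnormalized), closeness (CC, component-size
#' normalized: \eqn{(n_c - 1) / \sum_u d(v, u)} over the node's component,
#' 0 for isolated nodes), eigenvector (EC, nonnegative principal
#' eigenvector of the adjacency matrix computed per connected component
#' with unit Euclidean norm, 0 on edgeless components), local average
#' connectivity (LAC, mean degree of the node's neighbours within the
#' subgraph induced on those neighbours) and network centrality (NC, the
#' sum over incident edges of the edge clustering coefficient
#' \eqn{ECC(u, v) = |N(u) \cap N(v)| / \min(DC(u) - 1, DC(v) - 1)}, with
#' ECC = 0 when the denominator is 0).
#'
#' @param net An \code{npm_network} with at least one node.
#' @return data.frame with columns \code{node}, \code{DC}, \code{BC},
#'   \code{EC}, \code{CC}, \code{LAC}, \code{NC}, one row per node in
#'   node order.
#' @export
compute_centralities <- function(net) {
  stopifnot(is_network(net))
  n <- n_nodes(net)
  if (n < 1) stop("network has no nodes")
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  comp <- component_labels(adj)
  bcc <- bfs_centralities(adj)
  ec <- eigenvector_by_component(adj, comp)
  lac <- numeric(n)
  nc <- numeric(n)
  mark <- logical(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    dv <- deg[v]
    if (dv == 0L) next
    mark[nb] <- TRUE
    within_deg_sum <- 0
    ecc_sum <- 0
    for (u in nb) {
      common <- sum(mark[adj[[u]]])  # counts v's neighbours adjacent to u
      within_deg_sum <- within_deg_sum + common
      denom <- min(deg[u] - 1L, dv - 1L)
      if (denom > 0L) ecc_sum <- ecc_sum + common / denom
    }
    mark[nb] <- FALSE
    lac[v] <- within_deg_sum / dv
    nc[v] <- ecc_sum
  }
  data.frame(node = net$nodes, DC = as.integer(deg), BC = bcc$bc, EC = ec,
             CC = bcc$cc, LAC = lac, NC = nc, stringsAsFactors = FALSE)
}

#' Median-multiple screening threshold
#'
#' \code{multiplier} times the median of the values; the median of an
#' even-length list is the mean of the two central order statistics.
#'
#' @param values Non-empty numeric vector.
#' @param multiplier Multiplier (default 2).
#' @return A single number.
#' @export
median_multiple_threshold <- function(values, multiplier = 2) {
  values <- as.numeric(values)
  if (!length(values)) stop("values must be non-empty")
  multiplier * stats::median(values)
}

#' Two-stage median-multiple core-target screen
#'
#' Stage 1 computes degree (DC) on the input network and keeps nodes with
#' \code{DC >= multiplier x median(DC)}; the induced subgraph is the hub
#' network. Stage 2 recomputes all six indices on the hub network and keeps
#' nodes meeting \code{index >= multiplier x median(index)} for every one
#' of DC, BC, EC, CC, LAC and NC (medians taken over the hub network); the
#' induced subgraph is the core network. Comparisons are inclusive.
#'
#' @param net An \code{npm_network} with at least two nodes.
#' @param multiplier Median multiplier for both stages (default 2).
#' @return A list of class \code{npm_screen} with elements
#'   \code{stage1_threshold}, \code{stage2_thresholds} (named numeric,
#'   six indices), \code{hub_network}, \code{core_network},
#'   \code{stage1_table} (full-network DC), \code{stage2_table}
#'   (hub-network centralities with a \code{core} flag) and
#'   \code{multiplier}.
#' @export
two_stage_screen <- function(net, multiplier = 2) {
  stopifnot(is_network(net))
  if (n_nodes(net) < 2) stop("network needs >= 2 nodes to screen")
  if (!is.finite(multiplier) || multiplier < 0) {
    stop("multiplier must be a non-negative number")
  }
  adj <- adjacency_list(net)
  dc <- as.integer(lengths(adj))
  thr1 <- median_multiple_threshold(dc, multiplier)
  keep1 <- net$nodes[dc >= thr1]
  stage1_table <- data.frame(node = net$nodes, DC = dc,
                             hub = dc >= thr1, stringsAsFactors = FALSE)
  if (!length(keep1)) {
    stop(sprintf(paste0(
      "stage-1 screen kept no node (threshold %.3f; DC range %d-%d, ",
      "median %.1f)"), thr1, min(dc), max(dc), stats::median(dc)))
  }
  hub <- induced_subgraph(net, keep1)
  hub$name <- "hub"
  cent <- compute_centralities(hub)
  indices <- c("DC", "BC", "EC", "CC", "LAC", "NC")
  thr2 <- vapply(indices, function(ix) {
    median_multiple_threshold(cent[[ix]], multiplier)
  }, numeric(1))
  pass <- rep(TRUE, nrow(cent))
  for (ix in indices) pass <- pass & cent[[ix]] >= thr2[[ix]]
  cent$core <- pass
  core <- induced_subgraph(hub, cent$node[pass])
  core$name <- "core"
  structure(list(stage1_threshold = thr1,
                 stage2_thresholds = thr2,
                 hub_network = hub,
                 core_network = core,
                 stage1_table = stage1_table,
                 stage2_table = cent,
                 multiplier = multiplier),
            class = "npm_screen")
}

#' @export
print.npm_screen <- function(x, ...) {
  cat(sprintf(paste0(
    "<npm_screen: stage 1 DC >= %.3f -> %d hub nodes; ",
    "stage 2 (six indices) -> %d core nodes>\n"),
    x$stage1_threshold, n_nodes(x$hub_network), n_nodes(x$core_network)))
  invisible(x)
}
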