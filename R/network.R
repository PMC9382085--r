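#' Normalize gene symbols
#'
#' Trims surrounding whitespace and uppercases, the convention used for
#' human gene symbols throughout the package. Normalization is idempotent.
#'
#' @param x Character vector of symbols.
#' @return Character vector of normalized symbols.
#' @export
normalize_symbols <- function(x) {
  if (!is.character(x)) x <- as.character(x)
  toupper(trimws(x))
}

canonical_edges <- function(from, to) {
  # unordered pairs in canonical (lexicographic) order, deduplicated,
  # self-loops removed; returns a data.frame sorted across rows
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- a != b
  a <- a[keep]
  b <- b[keep]
  if (!length(a)) {
    # early return: paste0/order misbehave on zero-length inputs
    return(data.frame(from = character(), to = character(),
                      stringsAsFactors = FALSE))
  }
  key <- paste0(a, "\r", b)
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]
  o <- order(a, b, method = "radix")
  data.frame(from = a[o], to = b[o], stringsAsFactors = FALSE)
}

#' Construct an undirected simple network of gene symbols
#'
#' The container used for every interactome, subnetwork and tripartite
#' network in the pipeline. Symbols are normalized (trimmed, uppercased),
#' self-loops are dropped, duplicate and reversed-duplicate edges are
#' collapsed, and edges are stored as canonically ordered unordered pairs.
#'
#' @param nodes Character vector of node symbols (may be empty).
#' @param edges Two-column data.frame (or matrix) of endpoint symbols;
#'   endpoints absent from \code{nodes} are added.
#' @param node_attrs Optional data.frame with a \code{node} column plus
#'   attribute columns (e.g. \code{layer}).
#' @param name Network label.
#' @param normalize Normalize symbols (default \code{TRUE}); set to
#'   \code{FALSE} only when symbols are already canonical.
#' @return An object of class \code{npm_network} with elements
#'   \code{nodes} (sorted character), \code{edges} (data.frame
#'   \code{from}/\code{to}), \code{node_attrs} and \code{name}.
#' @export
network <- function(nodes = character(), edges = NULL, node_attrs = NULL,
                    name = "", normalize = TRUE) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) >= 2) {
    from <- as.character(edges[[1]])
    to <- as.character(edges[[2]])
  } else if (nrow(edges) == 0) {
    from <- to <- character()
  } else {
    stop("edges must have two columns")
  }
  nodes <- as.character(nodes)
  if (normalize) {
    nodes <- normalize_symbols(nodes)
    from <- normalize_symbols(from)
    to <- normalize_symbols(to)
  } else {
    nodes <- trimws(nodes)
    from <- trimws(from)
    to <- trimws(to)
  }
  bad <- c(nodes, from, to) == ""
  if (any(bad)) stop("empty symbol in network input")
  edges <- canonical_edges(from, to)
  nodes <- sort(unique(c(nodes, edges$from, edges$to)), method = "radix")
  if (!is.null(node_attrs)) {
    node_attrs <- as.data.frame(node_attrs, stringsAsFactors = FALSE)
    if (!"node" %in% names(node_attrs)) {
      stop("node_attrs requires a 'node' column")
    }
    node_attrs$node <- if (normalize) normalize_symbols(node_attrs$node)
                       else trimws(node_attrs$node)
    if (anyDuplicated(node_attrs$node)) {
      stop("duplicate node in node_attrs")
    }
    unknown <- setdiff(node_attrs$node, nodes)
    if (length(unknown)) {
      stop("node_attrs for nodes absent from network: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
    node_attrs <- node_attrs[order(node_attrs$node, method = "radix"), ,
                             drop = FALSE]
    rownames(node_attrs) <- NULL
  }
  structure(list(nodes = nodes, edges = edges, node_attrs = node_attrs,
                 name = as.character(name)[1]),
            class = "npm_network")
}

is_network <- function(x) inherits(x, "npm_network")

#' Number of nodes in a network
#' @param net An \code{npm_network}.
#' @return Integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Number of edges in a network
#' @param net An \code{npm_network}.
#' @return Integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @export
print.npm_network <- function(x, ...) {
  nm <- if (nzchar(x$name)) paste0(" '", x$name, "'") else ""
  cat(sprintf("<npm_network%s: %d nodes, %d edges>\n",
              nm, n_nodes(x), n_edges(x)))
  invisible(x)
}

# adjacency list as integer indices into net$nodes (sorted neighbours)
adjacency_list <- function(net) {
  n <- length(net$nodes)
  adj <- vector("list", n)
  if (nrow(net$edges)) {
    i <- match(net$edges$from, net$nodes)
    j <- match(net$edges$to, net$nodes)
    adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
    adj <- lapply(adj, function(v) sort(as.integer(v)))
  } else {
    adj <- rep(list(integer()), n)
  }
  names(adj) <- NULL
  adj
}

#' Induced subgraph on a node subset
#'
#' Keeps the requested nodes (those present in \code{net}) and every edge of
#' \code{net} with both endpoints among them; nodes isolated in the subgraph
#' are retained. Node attributes are carried over.
#'
#' @param net An \code{npm_network}.
#' @param nodes Character vector of symbols.
#' @return An \code{npm_network}.
#' @export
induced_subgraph <- function(net, nodes) {
  nodes <- intersect(normalize_symbols(nodes), net$nodes)
  keep <- net$edges$from %in% nodes & net$edges$to %in% nodes
  attrs <- net$node_attrs
  if (!is.null(attrs)) {
    attrs <- attrs[attrs$node %in% nodes, , drop = FALSE]
    if (!nrow(attrs)) attrs <- NULL
  }
  network(nodes, net$edges[keep, , drop = FALSE], node_attrs = attrs,
          name = net$name, normalize = FALSE)
}

neighbors_of <- function(net, nodes) {
  nodes <- intersect(nodes, net$nodes)
  hit <- net$edges$from %in% nodes | net$edges$to %in% nodes
  setdiff(unique(c(net$edges$from[hit], net$edges$to[hit])), nodes)
}

# connected component labels (integer vector along net$nodes)
component_labels <- function(adj) {
  n <- length(adj)
  comp <- integer(n)
  cur <- 0L
  queue <- integer(n)
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    queue[1L] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      for (w in adj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- cur
          tail <- tail + 1L
          queue[tail] <- w
        }
      }
    }
  }
  comp
}
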