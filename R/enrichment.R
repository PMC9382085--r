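#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene set against every term of
#' a gene-set library: with universe size M, term size K, query size n and
#' k query genes in the term, \eqn{p = \sum_{i \ge k} C(K,i) C(M-K,n-i) /
#' C(M,n)}. Query and term genes outside the universe are dropped (with a
#' warning for the query); terms empty after restriction are skipped.
#'
#' @param query An \code{npm_targetset} or character vector of symbols.
#' @param lib An \code{npm_gmt}.
#' @param universe Character vector of background symbols; default, all
#'   genes annotated in the library.
#' @return data.frame with columns \code{term_id}, \code{description},
#'   \code{k}, \code{K}, \code{n}, \code{M}, \code{p}, \code{hit_genes}
#'   (comma-joined), sorted by p then term id.
#' @export
hypergeom_ora <- function(query, lib, universe = NULL) {
  stopifnot(inherits(lib, "npm_gmt"))
  if (inherits(query, "npm_targetset")) query <- query$symbols
  query <- unique(normalize_symbols(query))
  if (is.null(universe)) {
    universe <- unique(unlist(lapply(lib, `[[`, "genes"), use.names = FALSE))
  } else {
    universe <- unique(normalize_symbols(universe))
  }
  if (!length(universe)) stop("universe must be non-empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
  }
  query <- intersect(query, universe)
  if (!length(query)) stop("query empty after restriction to the universe")
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(lib), function(id) {
    genes <- intersect(lib[[id]]$genes, universe)
    K <- length(genes)
    if (K == 0) return(NULL)
    hits <- intersect(query, genes)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term_id = id, description = lib[[id]]$description,
               k = k, K = K, n = n, M = M, p = p,
               hit_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no term overlaps the universe")
  }
  out <- out[order(out$p, out$term_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multiple-testing correction for enrichment results
#'
#' Adds a \code{p_adj} column. Holm (the step-down Bonferroni used by
#' ClueGO-style tools) is the default; Bonferroni and Benjamini-Hochberg
#' are available.
#'
#' @param terms data.frame from \code{\link{hypergeom_ora}}.
#' @param method One of \code{"holm"}, \code{"bonferroni"}, \code{"bh"}.
#' @return The input data.frame with \code{p_adj} added.
#' @export
correct_pvalues <- function(terms, method = c("holm", "bonferroni", "bh")) {
  method <- match.arg(method)
  if (is.null(terms) || !nrow(terms)) stop("terms must be non-empty")
  padj_method <- c(holm = "holm", bonferroni = "bonferroni", bh = "BH")[method]
  terms$p_adj <- stats::p.adjust(terms$p, method = padj_method)
  terms
}

#' Cohen's kappa between two terms' query-gene memberships
#'
#' Agreement between two hit sets over the query of size \code{query_size}:
#' with \eqn{a = |A \cap B|}, \eqn{b = |A \setminus B|},
#' \eqn{c = |B \setminus A|}, \eqn{d = q - a - b - c}, observed agreement
#' \eqn{p_o = (a + d)/q}, chance agreement
#' \eqn{p_e = ((a+b)(a+c) + (c+d)(b+d))/q^2} and
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)}; \eqn{\kappa = 1} when
#' \eqn{p_e = 1} (both sets empty or both the full query).
#'
#' @param hitsA,hitsB Character vectors, subsets of the query.
#' @param query_size Size of the query (>= 1).
#' @return Kappa in \code{[-1, 1]}.
#' @export
kappa_score <- function(hitsA, hitsB, query_size) {
  if (query_size < 1) stop("query_size must be >= 1")
  hitsA <- unique(hitsA)
  hitsB <- unique(hitsB)
  a <- length(intersect(hitsA, hitsB))
  b <- length(setdiff(hitsA, hitsB))
  cc <- length(setdiff(hitsB, hitsA))
  d <- query_size - a - b - cc
  if (d < 0) {
    stop("hit sets exceed query_size: ensure hits are subsets of the query")
  }
  q <- query_size
  po <- (a + d) / q
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / q^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Group significant terms by kappa-statistic agreement
#'
#' Builds a term graph with an edge wherever the kappa score of two terms'
#' hit sets is at least \code{kappa_min}, and takes connected components as
#' groups (single linkage). The leading term of a group has the smallest
#' adjusted p, ties broken by larger \code{k} then lexicographic term id.
#'
#' @param terms data.frame from \code{\link{correct_pvalues}} (columns
#'   \code{term_id}, \code{k}, \code{n}, \code{p_adj}, \code{hit_genes}).
#' @param kappa_min Kappa threshold for linking terms (default 0.4).
#' @param p_adj_max Significance cutoff applied before grouping (default
#'   0.05, inclusive); pass \code{Inf} if \code{terms} is pre-filtered.
#' @return data.frame with columns \code{term_id}, \code{group},
#'   \code{leading} (logical); attribute \code{kappa_edges} holds the
#'   linking pairs and their kappa values.
#' @export
group_terms <- function(terms, kappa_min = 0.4, p_adj_max = 0.05) {
  if (!is.finite(kappa_min) && !is.infinite(kappa_min)) {
    stop("kappa_min must be numeric")
  }
  if (kappa_min < -1 || kappa_min > 1) stop("kappa_min must be in [-1, 1]")
  sig <- terms[terms$p_adj <= p_adj_max, , drop = FALSE]
  m <- nrow(sig)
  if (!m) {
    out <- data.frame(term_id = character(), group = integer(),
                      leading = logical(), stringsAsFactors = FALSE)
    attr(out, "kappa_edges") <- data.frame(term_a = character(),
                                           term_b = character(),
                                           kappa = numeric())
    return(out)
  }
  hits <- lapply(strsplit(sig$hit_genes, ",", fixed = TRUE),
                 function(g) g[nzchar(g)])
  q <- sig$n[1]
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ea <- eb <- integer(0)
  ek <- numeric(0)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq(i + 1, m)) {
        kp <- kappa_score(hits[[i]], hits[[j]], q)
        if (kp >= kappa_min) {
          ea <- c(ea, i)
          eb <- c(eb, j)
          ek <- c(ek, kp)
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  group <- match(roots, unique(roots))
  leading <- logical(m)
  for (g in unique(group)) {
    members <- which(group == g)
    ord <- order(sig$p_adj[members], -sig$k[members], sig$term_id[members],
                 method = "radix")
    leading[members[ord[1]]] <- TRUE
  }
  out <- data.frame(term_id = sig$term_id, group = group, leading = leading,
                    stringsAsFactors = FALSE)
  attr(out, "kappa_edges") <- data.frame(term_a = sig$term_id[ea],
                                         term_b = sig$term_id[eb],
                                         kappa = ek,
                                         stringsAsFactors = FALSE)
  out
}
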