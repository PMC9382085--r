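#' @title Readers and writers for the pipeline's file formats
#' @description Edge lists (SIF / two-column TSV), GMT gene-set libraries,
#'   expression matrices with group labels, and two-column symbol mapping
#'   tables. All readers skip lines whose first non-blank character is
#'   \code{#}.
#' @name graph_io
NULL

read_body_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read an undirected edge list
#'
#' Supports Cytoscape SIF (\code{"A relation B [B2 ...]"}, one edge per
#' listed partner) and plain two-column TSV. Duplicate and reversed
#' duplicate pairs are collapsed; self-loop lines are dropped with a
#' warning; \code{#} comment lines are ignored. An empty file yields an
#' empty network.
#'
#' @param path File path.
#' @param dialect \code{"tsv2col"} (default) or \code{"sif"}.
#' @param name Label for the resulting network (defaults to the file name).
#' @return An \code{npm_network}.
#' @export
read_edge_list <- function(path, dialect = c("tsv2col", "sif"),
                           name = basename(path)) {
  dialect <- match.arg(dialect)
  body <- read_body_lines(path)
  from <- character()
  to <- character()
  for (k in seq_along(body$lines)) {
    fields <- strsplit(body$lines[k], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    if (dialect == "tsv2col") {
      if (length(fields) != 2) {
        stop(sprintf("malformed edge line %d in %s: expected 2 columns, got %d",
                     body$lineno[k], path, length(fields)))
      }
      from <- c(from, fields[1])
      to <- c(to, fields[2])
    } else {
      if (length(fields) == 1) {
        # SIF permits isolated-node lines; tolerated, contributes a node
        from <- c(from, fields[1])
        to <- c(to, fields[1])  # removed below as self-loop; node kept
        next
      }
      if (length(fields) < 3) {
        stop(sprintf("malformed SIF line %d in %s: expected 'A relation B ...'",
                     body$lineno[k], path))
      }
      partners <- fields[-(1:2)]
      from <- c(from, rep(fields[1], length(partners)))
      to <- c(to, partners)
    }
  }
  nf <- normalize_symbols(from)
  nt <- normalize_symbols(to)
  loops <- sum(nf == nt & nzchar(nf))
  if (loops > 0 && dialect == "tsv2col") {
    warning(sprintf("dropped %d self-loop line(s) in %s", loops, path))
  }
  network(nodes = c(nf, nt), edges = data.frame(from = from, to = to),
          name = name)
}

#' Write a network as node and edge tables
#'
#' Emits \code{<prefix>.nodes.tsv} (symbol plus attribute columns, sorted by
#' symbol) and \code{<prefix>.edges.tsv} (two columns, canonically ordered
#' within and across rows). Header lines are written as \code{#} comments so
#' both files can be re-read by \code{\link{read_edge_list}} /
#' \code{\link{read_network}}. Output order is deterministic, so identical
#' networks produce byte-identical files.
#'
#' @param net An \code{npm_network}.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_network <- function(net, prefix) {
  stopifnot(is_network(net))
  nodes_path <- paste0(prefix, ".nodes.tsv")
  edges_path <- paste0(prefix, ".edges.tsv")
  attrs <- net$node_attrs
  if (is.null(attrs)) {
    attrs <- data.frame(node = net$nodes, stringsAsFactors = FALSE)
  } else {
    attrs <- merge(data.frame(node = net$nodes, stringsAsFactors = FALSE),
                   attrs, by = "node", all.x = TRUE, sort = TRUE)
  }
  attrs <- attrs[order(attrs$node, method = "radix"), , drop = FALSE]
  con <- file(nodes_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste0("# ", paste(names(attrs), collapse = "\t")), con)
  if (nrow(attrs)) {
    utils::write.table(attrs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE, na = "")
  }
  con2 <- file(edges_path, "w")
  on.exit(close(con2), add = TRUE)
  writeLines("# from\tto", con2)
  if (nrow(net$edges)) {
    utils::write.table(net$edges, con2, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(nodes = nodes_path, edges = edges_path))
}

#' Read a network written by \code{write_network}
#'
#' Restores nodes (including isolated ones), node attributes and edges.
#'
#' @param prefix Path prefix used by \code{\link{write_network}}.
#' @param name Network label.
#' @return An \code{npm_network}.
#' @export
read_network <- function(prefix, name = basename(prefix)) {
  nodes_path <- paste0(prefix, ".nodes.tsv")
  edges_path <- paste0(prefix, ".edges.tsv")
  header <- readLines(nodes_path, n = 1L)
  cols <- strsplit(sub("^#\\s*", "", header), "\t", fixed = TRUE)[[1]]
  body <- read_body_lines(nodes_path)
  attrs <- NULL
  nodes <- character()
  if (length(body$lines)) {
    parts <- strsplit(body$lines, "\t", fixed = TRUE)
    tab <- as.data.frame(do.call(rbind, lapply(parts, function(p) {
      length(p) <- length(cols)
      p
    })), stringsAsFactors = FALSE)
    names(tab) <- cols
    nodes <- tab$node
    if (ncol(tab) > 1) {
      for (cn in setdiff(names(tab), "node")) {
        v <- tab[[cn]]
        suppressWarnings(num <- as.numeric(v))
        if (!anyNA(num[nzchar(v) & !is.na(v)])) tab[[cn]] <- num
      }
      attrs <- tab
    }
  }
  net <- read_edge_list(edges_path, dialect = "tsv2col", name = name)
  network(nodes = c(nodes, net$nodes), edges = net$edges,
          node_attrs = attrs, name = name)
}

#' Construct a gene-set library
#'
#' @param terms Named list; each element is \code{list(description =, genes =)}.
#' @return An object of class \code{npm_gmt}.
#' @export
gene_set_library <- function(terms) {
  ids <- names(terms)
  if (is.null(ids) || anyDuplicated(ids)) stop("term ids must be unique")
  terms <- lapply(terms, function(t) {
    genes <- unique(normalize_symbols(t$genes))
    if (!length(genes)) stop("empty gene set in library")
    list(description = as.character(t$description)[1], genes = genes)
  })
  structure(terms, class = "npm_gmt")
}

#' @export
print.npm_gmt <- function(x, ...) {
  sizes <- vapply(x, function(t) length(t$genes), integer(1))
  cat(sprintf("<npm_gmt: %d terms, %d distinct genes>\n",
              length(x), length(unique(unlist(lapply(x, `[[`, "genes"))))))
  invisible(x)
}

#' Read a GMT gene-set library
#'
#' Standard GMT: tab-separated \code{term_id}, \code{description}, then one
#' gene per field. Duplicate genes within a term are collapsed.
#'
#' @param path File path.
#' @return An \code{npm_gmt}.
#' @export
read_gmt <- function(path) {
  body <- read_body_lines(path)
  terms <- list()
  for (k in seq_along(body$lines)) {
    fields <- strsplit(body$lines[k], "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3) {
      stop(sprintf("malformed GMT line %d in %s: need >= 3 fields",
                   body$lineno[k], path))
    }
    id <- fields[1]
    if (id %in% names(terms)) stop("duplicate term id: ", id)
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    terms[[id]] <- list(description = fields[2], genes = genes)
  }
  gene_set_library(terms)
}

#' Write a GMT gene-set library
#'
#' @param lib An \code{npm_gmt}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "npm_gmt"))
  lines <- vapply(names(lib), function(id) {
    paste(c(id, lib[[id]]$description, sort(lib[[id]]$genes)),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with group labels
#'
#' The matrix TSV has a header row of sample ids and a first column of gene
#' symbols; the labels TSV maps every sample id to one of exactly two group
#' names. Duplicate gene symbols keep the row with the highest mean (a
#' message reports the drops). Gene symbol case is preserved so that
#' species-specific symbols (e.g. mouse) survive for ortholog mapping.
#'
#' @param path Matrix TSV path.
#' @param labels_path Two-column sample/group TSV path.
#' @param case_label,control_label Group names to treat as case and control;
#'   by default \code{"case"} and \code{"control"}.
#' @return An \code{npm_expr} (see \code{\link{expression_dataset}}).
#' @export
read_expression_matrix <- function(path, labels_path,
                                   case_label = "case",
                                   control_label = "control") {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("expression matrix needs >= 2 sample columns")
  genes <- trimws(as.character(tab[[1]]))
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- genes
  lab <- utils::read.delim(labels_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs two columns (sample, group)")
  groups <- stats::setNames(trimws(lab[[2]]), trimws(lab[[1]]))
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing)) {
    stop("samples missing from labels file: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    means <- rowMeans(values)
    ord <- order(-means)  # keep highest-mean row per symbol
    keep_first <- ord[!duplicated(genes[ord])]
    dropped <- nrow(values) - length(keep_first)
    message(sprintf("dropped %d duplicate gene row(s), kept highest mean",
                    dropped))
    keep_first <- sort(keep_first)
    values <- values[keep_first, , drop = FALSE]
  }
  expression_dataset(values, groups[colnames(values)],
                     case_label = case_label, control_label = control_label,
                     name = basename(path))
}

#' Write an expression matrix and its label sidecar
#'
#' @param ds An \code{npm_expr}.
#' @param path Matrix TSV path.
#' @param labels_path Labels TSV path.
#' @return Invisibly, the two paths.
#' @export
write_expression_matrix <- function(ds, path, labels_path) {
  stopifnot(inherits(ds, "npm_expr"))
  tab <- data.frame(gene = rownames(ds$values), ds$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(names(ds$groups), unname(ds$groups)),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(matrix = path, labels = labels_path))
}

#' Read a two-column symbol mapping table
#'
#' Maps source symbols (case preserved, e.g. mouse) to target symbols
#' (normalized to the human convention). Repeated identical pairs are
#' collapsed; a source mapped to two different targets is an error.
#'
#' @param path File path.
#' @return A named character vector (source -> target) of class
#'   \code{npm_symbolmap}.
#' @export
read_mapping_table <- function(path) {
  body <- read_body_lines(path)
  src <- character()
  dst <- character()
  for (k in seq_along(body$lines)) {
    fields <- trimws(strsplit(body$lines[k], "\t", fixed = TRUE)[[1]])
    fields <- fields[nzchar(fields)]
    if (length(fields) != 2) {
      stop(sprintf("malformed mapping line %d in %s: expected 2 columns",
                   body$lineno[k], path))
    }
    src <- c(src, fields[1])
    dst <- c(dst, fields[2])
  }
  symbol_map(src, dst)
}

#' Construct a symbol map
#'
#' @param source Character vector of source symbols (case preserved).
#' @param target Character vector of target symbols (normalized).
#' @return Named character vector of class \code{npm_symbolmap}.
#' @export
symbol_map <- function(source, target) {
  source <- trimws(source)
  target <- normalize_symbols(target)
  key <- paste0(source, "\r", target)
  keep <- !duplicated(key)
  source <- source[keep]
  target <- target[keep]
  conf <- unique(source[duplicated(source)])
  if (length(conf)) {
    stop("conflicting mapping for source symbol(s): ",
         paste(utils::head(conf, 5), collapse = ", "))
  }
  structure(stats::setNames(target, source), class = "npm_symbolmap")
}
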