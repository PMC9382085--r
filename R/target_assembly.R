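#' Construct a target set with provenance
#'
#' A deduplicated set of gene symbols, each carrying the set of source
#' labels (database names, directions, dataset ids) that contributed it.
#'
#' @param symbols Character vector of symbols.
#' @param provenance Named list (symbol -> character vector of sources), or
#'   a single character vector of sources applied to every symbol.
#' @param normalize Uppercase symbols (default \code{TRUE}). Pass
#'   \code{FALSE} for case-significant symbols (e.g. mouse genes awaiting
#'   ortholog mapping).
#' @return An object of class \code{npm_targetset} with elements
#'   \code{symbols} (sorted character) and \code{provenance}.
#' @export
target_set <- function(symbols = character(), provenance = NULL,
                       normalize = TRUE) {
  symbols <- as.character(symbols)
  norm <- if (normalize) normalize_symbols(symbols) else trimws(symbols)
  if (any(norm == "")) stop("empty symbol in target set")
  if (is.null(provenance)) {
    prov <- stats::setNames(rep(list("unspecified"), length(norm)), norm)
  } else if (is.character(provenance)) {
    prov <- stats::setNames(rep(list(provenance), length(norm)), norm)
  } else {
    names(provenance) <- if (normalize) normalize_symbols(names(provenance))
                         else trimws(names(provenance))
    prov <- provenance
  }
  u <- sort(unique(norm), method = "radix")
  merged <- lapply(u, function(s) {
    src <- unlist(prov[names(prov) == s], use.names = FALSE)
    if (is.null(src) || !length(src)) src <- "unspecified"
    sort(unique(as.character(src)))
  })
  names(merged) <- u
  structure(list(symbols = u, provenance = merged),
            class = "npm_targetset")
}

#' @export
print.npm_targetset <- function(x, ...) {
  src <- sort(unique(unlist(x$provenance, use.names = FALSE)))
  cat(sprintf("<npm_targetset: %d symbols; sources: %s>\n",
              length(x$symbols),
              paste(utils::head(src, 6), collapse = ", ")))
  invisible(x)
}

#' @export
length.npm_targetset <- function(x) length(x$symbols)

#' Write a target set as TSV
#' @param ts An \code{npm_targetset}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_target_set <- function(ts, path) {
  stopifnot(inherits(ts, "npm_targetset"))
  src <- vapply(ts$provenance[ts$symbols],
                function(s) paste(s, collapse = ","), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# target\tsources", con)
  if (length(ts$symbols)) {
    writeLines(paste(ts$symbols, src, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a target set written by \code{write_target_set}
#'
#' Also accepts plain one-column or \code{target<TAB>source} tables such as
#' curated disease-target files.
#'
#' @param path File path.
#' @return An \code{npm_targetset}.
#' @export
read_target_set <- function(path) {
  body <- read_body_lines(path)
  if (!length(body$lines)) return(target_set())
  parts <- strsplit(body$lines, "\t", fixed = TRUE)
  syms <- vapply(parts, `[[`, character(1), 1)
  prov <- lapply(parts, function(p) {
    if (length(p) >= 2) strsplit(p[2], ",", fixed = TRUE)[[1]] else "unspecified"
  })
  names(prov) <- normalize_symbols(syms)
  target_set(syms, provenance = prov)
}

#' Screen compound target predictions by score or rank
#'
#' Per compound, scored predictions are kept when their score strictly
#' exceeds \code{score_min}; when no prediction for a compound clears the
#' score cut, the \code{top_k} highest-scored predictions are kept instead
#' (the two rules act as alternatives). Records without a score are treated
#' as curated database entries and pass unfiltered.
#'
#' @param records data.frame with columns \code{compound}, \code{target},
#'   \code{score} (numeric, \code{NA} for curated records) and
#'   \code{source}.
#' @param score_min Strict score cutoff (default 60).
#' @param top_k Rank fallback size per compound (default 50).
#' @return An \code{npm_targetset}; provenance carries the source labels.
#' @export
filter_predicted_targets <- function(records, score_min = 60, top_k = 50) {
  if (top_k <= 0) stop("top_k must be positive")
  if (is.null(records) || nrow(as.data.frame(records)) == 0) {
    return(target_set())
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  req <- c("compound", "target", "source")
  if (!all(req %in% names(records))) {
    stop("records need columns compound, target, score, source")
  }
  if (!"score" %in% names(records)) records$score <- NA_real_
  records$score <- as.numeric(records$score)
  if (any(!is.finite(records$score) & !is.na(records$score))) {
    stop("non-finite score in records")
  }
  curated <- records[is.na(records$score), , drop = FALSE]
  scored <- records[!is.na(records$score), , drop = FALSE]
  kept <- curated
  for (cmp in unique(scored$compound)) {
    sub <- scored[scored$compound == cmp, , drop = FALSE]
    pass <- sub[sub$score > score_min, , drop = FALSE]
    if (nrow(pass) == 0 && nrow(sub) > 0) {
      ord <- order(-sub$score, sub$target, method = "radix")
      pass <- sub[utils::head(ord, top_k), , drop = FALSE]
    }
    kept <- rbind(kept, pass)
  }
  if (!nrow(kept)) return(target_set())
  prov <- split(kept$source, normalize_symbols(kept$target))
  target_set(kept$target, provenance = prov)
}

#' Merge target sets, removing duplicates
#'
#' Union of symbols with per-symbol union of provenance. Associative and
#' commutative.
#'
#' @param sets List of \code{npm_targetset} objects (or several such objects
#'   passed via \code{...}).
#' @param ... Additional target sets.
#' @return An \code{npm_targetset}.
#' @export
merge_target_sets <- function(sets, ...) {
  if (inherits(sets, "npm_targetset")) sets <- list(sets)
  sets <- c(sets, list(...))
  syms <- unlist(lapply(sets, `[[`, "symbols"), use.names = FALSE)
  prov <- do.call(c, lapply(sets, `[[`, "provenance"))
  if (is.null(prov)) prov <- list()
  target_set(syms, provenance = prov)
}

#' Build a herb-compound-target tripartite network
#'
#' Nodes carry a \code{layer} attribute (\code{herb}, \code{compound} or
#' \code{target}); edges connect herbs to their compounds and compounds to
#' their targets only. A symbol appearing in two layers is an error.
#'
#' @param herb_compound data.frame (herb, compound).
#' @param compound_target data.frame (compound, target).
#' @param name Network label.
#' @return An \code{npm_network} with a \code{layer} node attribute.
#' @export
build_tripartite <- function(herb_compound, compound_target,
                             name = "herb-compound-target") {
  hc <- as.data.frame(herb_compound, stringsAsFactors = FALSE)
  ct <- as.data.frame(compound_target, stringsAsFactors = FALSE)
  if (!nrow(hc) || !nrow(ct)) stop("both pair lists must be non-empty")
  herbs <- unique(normalize_symbols(hc[[1]]))
  compounds <- unique(normalize_symbols(c(hc[[2]], ct[[1]])))
  targets <- unique(normalize_symbols(ct[[2]]))
  clash <- c(intersect(herbs, compounds), intersect(herbs, targets),
             intersect(compounds, targets))
  if (length(clash)) {
    stop("symbol(s) in more than one layer: ",
         paste(unique(clash), collapse = ", "))
  }
  attrs <- data.frame(
    node = c(herbs, compounds, targets),
    layer = c(rep("herb", length(herbs)),
              rep("compound", length(compounds)),
              rep("target", length(targets))),
    stringsAsFactors = FALSE)
  edges <- rbind(stats::setNames(hc[, 1:2], c("from", "to")),
                 stats::setNames(ct[, 1:2], c("from", "to")))
  network(nodes = attrs$node, edges = edges, node_attrs = attrs, name = name)
}

#' Translate a target set through an ortholog / symbol map
#'
#' Sources are matched on trimmed, case-preserved symbols first (mouse
#' symbols are case-significant); symbols without an exact match fall back
#' to a case-insensitive match when that match is unambiguous. Outputs are
#' normalized to the human convention. Provenance is carried over and
#' merged when two sources map to one target.
#'
#' @param genes An \code{npm_targetset}.
#' @param map An \code{npm_symbolmap} (see \code{\link{symbol_map}}).
#' @param policy \code{"drop"} (default) discards unmapped symbols;
#'   \code{"keep"} retains them under their normalized form.
#' @return An \code{npm_targetset}.
#' @export
map_orthologs <- function(genes, map, policy = c("drop", "keep")) {
  policy <- match.arg(policy)
  stopifnot(inherits(genes, "npm_targetset"))
  src <- genes$symbols
  hit <- match(src, names(map))
  fold <- toupper(names(map))
  for (i in which(is.na(hit))) {
    cand <- which(fold == toupper(src[i]))
    if (length(cand) == 1) hit[i] <- cand
  }
  out_sym <- character()
  out_prov <- list()
  for (i in seq_along(src)) {
    if (is.na(hit[i])) {
      if (policy == "drop") next
      tgt <- normalize_symbols(src[i])
    } else {
      tgt <- unname(map[[hit[i]]])
    }
    out_sym <- c(out_sym, tgt)
    out_prov <- c(out_prov, stats::setNames(list(genes$provenance[[src[i]]]),
                                            tgt))
  }
  target_set(out_sym, provenance = out_prov)
}
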