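#' Construct a two-group expression dataset
#'
#' Log2-scale intensities (microarray) or log2(count + 1) (RNA-seq) for
#' genes x samples, with every sample assigned to one of two groups.
#'
#' @param values Numeric matrix, genes in rows (rownames are symbols),
#'   samples in columns (colnames are sample ids).
#' @param groups Named character vector, sample id -> group name; exactly
#'   two group names, each with at least two samples.
#' @param case_label,control_label Which group name is the case and which
#'   the control (log2 fold change is case minus control).
#' @param name Dataset label.
#' @return An object of class \code{npm_expr}.
#' @export
expression_dataset <- function(values, groups, case_label = "case",
                               control_label = "control", name = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs gene rownames and sample colnames")
  }
  if (!all(is.finite(values))) stop("non-finite expression values")
  groups <- stats::setNames(as.character(groups), names(groups))
  if (!all(colnames(values) %in% names(groups))) {
    stop("every sample needs a group label")
  }
  groups <- groups[colnames(values)]
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required, got: ",
                            paste(lv, collapse = ", "))
  if (!all(c(case_label, control_label) %in% lv)) {
    stop(sprintf("groups are {%s}; pass case_label/control_label to match",
                 paste(lv, collapse = ", ")))
  }
  if (min(table(groups)) < 2) stop("each group needs >= 2 samples")
  structure(list(values = values, groups = groups,
                 case_label = case_label, control_label = control_label,
                 name = name),
            class = "npm_expr")
}

#' @export
print.npm_expr <- function(x, ...) {
  cat(sprintf("<npm_expr '%s': %d genes x %d samples (%d %s / %d %s)>\n",
              x$name, nrow(x$values), ncol(x$values),
              sum(x$groups == x$case_label), x$case_label,
              sum(x$groups == x$control_label), x$control_label))
  invisible(x)
}

#' Per-gene two-group differential expression test
#'
#' Two-sided t-test on the (log2) values of every gene, Welch's unequal-
#' variance form by default. The log2 fold change is the case-group mean
#' minus the control-group mean. Degenerate genes follow fixed conventions:
#' both groups at zero variance give p = 1 when the means are equal and
#' p = 0 when they differ.
#'
#' @param ds An \code{npm_expr}.
#' @param test \code{"welch_t"} (default) or \code{"student_t"}.
#' @return data.frame with columns \code{gene}, \code{log2fc}, \code{p}.
#' @export
de_test <- function(ds, test = c("welch_t", "student_t")) {
  test <- match.arg(test)
  stopifnot(inherits(ds, "npm_expr"))
  case <- ds$values[, ds$groups == ds$case_label, drop = FALSE]
  ctrl <- ds$values[, ds$groups == ds$control_label, drop = FALSE]
  n1 <- ncol(case)
  n2 <- ncol(ctrl)
  m1 <- rowMeans(case)
  m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, stats::var)
  v2 <- apply(ctrl, 1, stats::var)
  log2fc <- m1 - m2
  if (test == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(v1))
  }
  tstat <- log2fc / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate & log2fc == 0] <- 1
    zero_unequal <- degenerate & log2fc != 0
    if (any(zero_unequal)) {
      p[zero_unequal] <- 0
      message(sprintf(
        "%d gene(s) with zero within-group variance and unequal means: p = 0",
        sum(zero_unequal)))
    }
  }
  data.frame(gene = rownames(ds$values), log2fc = unname(log2fc),
             p = unname(p), stringsAsFactors = FALSE)
}

#' Threshold a differential-expression result into a DEG set
#'
#' Keeps genes with \code{|log2fc| > fc_min_log2} and \code{p < p_max},
#' both strict. Microarray mode uses \code{fc_min_log2 = 1}; RNA-seq mode
#' uses \code{fc_min_log2 = log2(1.5)} (fold change above 1.5 in either
#' direction). Provenance records the direction (\code{up} / \code{down}).
#'
#' @param res data.frame from \code{\link{de_test}}.
#' @param fc_min_log2 Strict absolute log2-fold-change cutoff.
#' @param p_max Strict p-value cutoff.
#' @param normalize Uppercase the returned symbols (default \code{FALSE},
#'   preserving species-specific case for ortholog mapping).
#' @return An \code{npm_targetset} with \code{up}/\code{down} provenance.
#' @export
threshold_degs <- function(res, fc_min_log2 = 1, p_max = 0.05,
                           normalize = FALSE) {
  if (!is.finite(fc_min_log2) || fc_min_log2 < 0) {
    stop("fc_min_log2 must be a non-negative number")
  }
  if (!is.finite(p_max) || p_max <= 0 || p_max > 1) {
    stop("p_max must be in (0, 1]")
  }
  keep <- abs(res$log2fc) > fc_min_log2 & res$p < p_max
  genes <- res$gene[keep]
  dir <- ifelse(res$log2fc[keep] > 0, "up", "down")
  key <- if (normalize) normalize_symbols(genes) else trimws(genes)
  target_set(genes, provenance = stats::setNames(as.list(dir), key),
             normalize = normalize)
}

#' Intersect DEG sets across datasets with Venn region counts
#'
#' Returns the symbols common to every set together with the size of each
#' of the \code{2^K - 1} Venn regions (exclusive membership patterns),
#' named by the contributing set names joined with \code{"&"}.
#'
#' @param sets Named list of \code{npm_targetset} objects (>= 2). Unnamed
#'   lists get names \code{set1, set2, ...}.
#' @return List with elements \code{common} (an \code{npm_targetset} whose
#'   provenance unions the inputs') and \code{regions} (named integer
#'   vector).
#' @export
intersect_degs <- function(sets) {
  if (length(sets) < 2) stop("need at least two sets to intersect")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  k <- length(sets)
  membership <- lapply(sets, `[[`, "symbols")
  universe <- sort(unique(unlist(membership)), method = "radix")
  inmat <- vapply(membership, function(s) universe %in% s,
                  logical(length(universe)))
  if (length(universe) == 1) inmat <- matrix(inmat, nrow = 1)
  pattern <- apply(inmat, 1, function(r) {
    paste(names(sets)[r], collapse = "&")
  })
  regions <- integer(2^k - 1)
  region_names <- character(2^k - 1)
  idx <- 0
  for (size in seq_len(k)) {
    combos <- utils::combn(names(sets), size, simplify = FALSE)
    for (cb in combos) {
      idx <- idx + 1
      region_names[idx] <- paste(cb, collapse = "&")
    }
  }
  names(regions) <- region_names
  tab <- table(pattern)
  regions[names(tab)] <- as.integer(tab)
  common_syms <- universe[rowSums(inmat) == k]
  prov <- list()
  for (s in common_syms) {
    src <- unlist(lapply(sets, function(ts) ts$provenance[[s]]),
                  use.names = FALSE)
    prov[[s]] <- sort(unique(src))
  }
  common <- target_set(common_syms, provenance = prov, normalize = FALSE)
  list(common = common, regions = regions)
}
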