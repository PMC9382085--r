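#' Configuration for the synthetic-data generators
#'
#' Bundles every knob of the seeded generators with defaults sized to the
#' study conditions the pipeline is built for: a scale-free interactome
#' with planted high-degree hubs, five microarray-like expression datasets
#' sharing 66 planted differential genes, evidence tables for 22 serum
#' compounds over ten herbs, and a pathway library of 41 background terms
#' plus one planted enriched term.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it, so identical configs give identical outputs.
#' @param interactome List: \code{n_nodes}, preferential-attachment
#'   \code{m} (edges per new node).
#' @param hubs List: \code{count} of planted hubs and
#'   \code{degree_fraction}: each hub is degree-boosted until it is
#'   adjacent to this fraction of the network, emulating the
#'   superhub proteins (TP53-class) of curated interactomes whose
#'   neighbourhoods span a large share of all nodes.
#' @param expression List: \code{n_genes}, \code{n_per_group},
#'   \code{planted_deg_count} per dataset, \code{effect_log2fc},
#'   \code{sigma}, \code{n_datasets}, \code{shared_deg_count} (planted
#'   genes common to all datasets), \code{baseline_mean}.
#' @param evidence List: \code{n_compounds}, \code{n_herbs},
#'   \code{targets_per_compound}, \code{score_range} for scored
#'   predictions, \code{curated_fraction} of unscored records,
#'   \code{disease_overlap} (fraction of disease targets drawn from the
#'   drug-target neighbourhood), \code{n_disease_targets}.
#' @param library List: \code{n_terms} background terms,
#'   \code{term_size_range}, \code{planted_term_size},
#'   \code{planted_overlap} (planted-term genes inside the designated
#'   query).
#' @return A list of class \code{npm_synth_config}.
#' @export
synthetic_config <- function(seed = 1L,
                             interactome = list(),
                             hubs = list(),
                             expression = list(),
                             evidence = list(),
                             library = list()) {
  merge_defaults <- function(given, defaults) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) stop("unknown config field(s): ",
                              paste(unknown, collapse = ", "))
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed),
    interactome = merge_defaults(interactome,
                                 list(n_nodes = 2000L, m = 2L)),
    hubs = merge_defaults(hubs, list(count = 20L, degree_fraction = 0.15)),
    expression = merge_defaults(expression, list(
      n_genes = 1000L, n_per_group = 10L, planted_deg_count = 100L,
      effect_log2fc = 2, sigma = 1, n_datasets = 5L,
      shared_deg_count = 66L, baseline_mean = 8)),
    evidence = merge_defaults(evidence, list(
      n_compounds = 22L, n_herbs = 10L, targets_per_compound = 18L,
      score_range = c(40, 100), curated_fraction = 0.5,
      disease_overlap = 0.4, n_disease_targets = 150L)),
    library = merge_defaults(library, list(
      n_terms = 41L, term_size_range = c(10L, 40L),
      planted_term_size = 20L, planted_overlap = 15L)))
  counts <- c(cfg$interactome$n_nodes, cfg$interactome$m, cfg$hubs$count,
              unlist(cfg$expression), cfg$evidence$n_compounds,
              cfg$evidence$n_herbs, cfg$evidence$targets_per_compound,
              cfg$library$n_terms, cfg$library$planted_term_size)
  if (any(counts < 0)) stop("config counts must be non-negative")
  if (cfg$expression$shared_deg_count > cfg$expression$planted_deg_count) {
    stop("shared_deg_count must not exceed planted_deg_count")
  }
  if (cfg$library$planted_overlap > cfg$library$planted_term_size) {
    stop("planted_overlap must not exceed planted_term_size")
  }
  structure(cfg, class = "npm_synth_config")
}

#' Generate a scale-free interactome with planted hubs
#'
#' Preferential attachment (each new node links to \code{m} distinct
#' existing nodes chosen proportionally to degree), followed by degree
#' boosting of \code{hubs$count} randomly chosen nodes until each is
#' adjacent to a fraction \code{hubs$degree_fraction} of all nodes
#' (superhub planting). Node symbols are
#' \code{G00001 ...}; the planted hub symbols are recorded in the
#' \code{manifest} attribute and as a \code{planted_hub} node attribute.
#'
#' @param cfg An \code{npm_synth_config}.
#' @return An \code{npm_network}; \code{attr(net, "manifest")$hub_nodes}
#'   lists the planted hubs.
#' @export
generate_interactome <- function(cfg) {
  stopifnot(inherits(cfg, "npm_synth_config"))
  n <- cfg$interactome$n_nodes
  m <- cfg$interactome$m
  if (n <= m || m < 1) stop("need n_nodes > m >= 1")
  set.seed(cfg$seed)
  # repeated-node preferential attachment: each node appears in `rep_pool`
  # once per unit of degree, so uniform draws from the pool are
  # degree-proportional
  from <- integer(0)
  to <- integer(0)
  rep_pool <- integer(2L * m * n)
  pool_len <- 0L
  push <- function(v) {
    # grow-by-doubling not needed: pool sized for worst case
    pool_len <<- pool_len + length(v)
    rep_pool[(pool_len - length(v) + 1L):pool_len] <<- v
  }
  push(1L)  # seed node gets one phantom unit so node 2 can attach
  for (t in 2:n) {
    k <- min(m, t - 1L)
    targets <- integer(0)
    while (length(targets) < k) {
      cand <- rep_pool[sample.int(pool_len, k - length(targets),
                                  replace = TRUE)]
      targets <- unique(c(targets, cand))
      targets <- targets[targets != t]
    }
    from <- c(from, rep(t, k))
    to <- c(to, targets)
    push(c(rep(t, k), targets))
  }
  deg <- tabulate(c(from, to), nbins = n)
  hub_count <- cfg$hubs$count
  hub_ids <- integer(0)
  if (hub_count > 0) {
    target_deg <- ceiling(cfg$hubs$degree_fraction * n)
    hub_ids <- sort(sample.int(n, hub_count))
    for (h in hub_ids) {
      need <- target_deg - deg[h]
      if (need <= 0) next
      existing <- c(to[from == h], from[to == h])
      pool <- setdiff(seq_len(n), c(h, existing))
      add <- sample(pool, min(need, length(pool)))
      from <- c(from, rep(h, length(add)))
      to <- c(to, add)
      deg[h] <- deg[h] + length(add)
      deg[add] <- deg[add] + 1L
    }
  }
  sym <- sprintf("G%05d", seq_len(n))
  net <- network(nodes = sym,
                 edges = data.frame(from = sym[from], to = sym[to]),
                 name = "synthetic-interactome", normalize = FALSE)
  hubs <- sym[hub_ids]
  net$node_attrs <- data.frame(node = net$nodes,
                               planted_hub = as.integer(net$nodes %in% hubs),
                               stringsAsFactors = FALSE)
  attr(net, "manifest") <- list(hub_nodes = hubs)
  net
}

#' Generate a bundle of two-group expression datasets with planted DEGs
#'
#' Each dataset is genes x (2 x \code{n_per_group}) samples of Gaussian
#' log2 intensities, baseline \code{N(baseline_mean, sigma)}. Per dataset,
#' \code{planted_deg_count} genes are shifted by \code{effect_log2fc}
#' (random sign per gene) in the case group; \code{shared_deg_count} of
#' them are the same genes in every dataset, the rest dataset-private.
#'
#' @param cfg An \code{npm_synth_config}.
#' @param genes Optional character vector to draw gene symbols from
#'   (e.g. interactome nodes); defaults to \code{GENE0001 ...}.
#' @return List with \code{datasets} (named list of \code{npm_expr}) and
#'   \code{manifest} (\code{shared} symbols, \code{per_dataset} planted
#'   symbol lists, \code{directions}).
#' @export
generate_expression_bundle <- function(cfg, genes = NULL) {
  stopifnot(inherits(cfg, "npm_synth_config"))
  ex <- cfg$expression
  set.seed(cfg$seed + 1L)
  if (is.null(genes)) {
    genes <- sprintf("GENE%05d", seq_len(ex$n_genes))
  } else {
    if (length(genes) < ex$n_genes) stop("gene pool smaller than n_genes")
    genes <- sort(sample(genes, ex$n_genes))
  }
  if (ex$planted_deg_count > ex$n_genes) {
    stop("planted_deg_count exceeds n_genes")
  }
  shared <- sort(sample(genes, ex$shared_deg_count))
  datasets <- list()
  per_dataset <- list()
  directions <- list()
  for (d in seq_len(ex$n_datasets)) {
    n_private <- ex$planted_deg_count - ex$shared_deg_count
    private <- sort(sample(setdiff(genes, shared), n_private))
    planted <- c(shared, private)
    dir <- stats::setNames(sample(c(-1, 1), length(planted), replace = TRUE),
                           planted)
    samples <- c(sprintf("case_%02d", seq_len(ex$n_per_group)),
                 sprintf("ctrl_%02d", seq_len(ex$n_per_group)))
    vals <- matrix(stats::rnorm(ex$n_genes * length(samples),
                                mean = ex$baseline_mean, sd = ex$sigma),
                   nrow = ex$n_genes,
                   dimnames = list(genes, samples))
    case_cols <- seq_len(ex$n_per_group)
    vals[planted, case_cols] <- vals[planted, case_cols] +
      dir[planted] * ex$effect_log2fc
    groups <- stats::setNames(rep(c("case", "control"),
                                  each = ex$n_per_group), samples)
    nm <- sprintf("synth_ds%d", d)
    datasets[[nm]] <- expression_dataset(vals, groups, name = nm)
    per_dataset[[nm]] <- planted
    directions[[nm]] <- dir
  }
  list(datasets = datasets,
       manifest = list(shared = shared, per_dataset = per_dataset,
                       directions = directions))
}

#' Generate compound/herb/disease evidence tables
#'
#' Compound targets are drawn from the interactome nodes; a configurable
#' fraction are curated records (no score), the rest carry prediction
#' scores uniform on \code{score_range}. Disease targets are drawn partly
#' from the drug-target pool (fraction \code{disease_overlap}) and partly
#' from the remaining interactome, with multi-database source labels.
#'
#' @param cfg An \code{npm_synth_config}.
#' @param interactome An \code{npm_network}.
#' @return List with \code{compound_target}, \code{herb_compound},
#'   \code{disease_targets} data.frames and a \code{manifest}.
#' @export
generate_evidence_tables <- function(cfg, interactome) {
  stopifnot(inherits(cfg, "npm_synth_config"), is_network(interactome))
  ev <- cfg$evidence
  set.seed(cfg$seed + 2L)
  compounds <- sprintf("CPD%02d", seq_len(ev$n_compounds))
  herbs <- sprintf("HERB%02d", seq_len(ev$n_herbs))
  herb_of <- herbs[(seq_len(ev$n_compounds) - 1L) %% ev$n_herbs + 1L]
  herb_compound <- data.frame(herb = herb_of, compound = compounds,
                              stringsAsFactors = FALSE)
  nodes <- interactome$nodes
  ct <- do.call(rbind, lapply(seq_len(ev$n_compounds), function(i) {
    tg <- sample(nodes, ev$targets_per_compound)
    curated <- stats::runif(length(tg)) < ev$curated_fraction
    score <- ifelse(curated, NA_real_,
                    stats::runif(length(tg), ev$score_range[1],
                                 ev$score_range[2]))
    source <- ifelse(curated,
                     sample(c("TCMSP", "HERB"), length(tg), replace = TRUE),
                     "PM")
    data.frame(compound = compounds[i], target = tg, score = score,
               source = source, stringsAsFactors = FALSE)
  }))
  drug_pool <- unique(ct$target)
  n_from_drug <- round(ev$disease_overlap * ev$n_disease_targets)
  n_from_drug <- min(n_from_drug, length(drug_pool))
  rest_pool <- setdiff(nodes, drug_pool)
  n_rest <- min(ev$n_disease_targets - n_from_drug, length(rest_pool))
  disease <- c(sample(drug_pool, n_from_drug), sample(rest_pool, n_rest))
  db <- c("DrugBank", "TTD", "PharmGkb", "GAD", "OMIM")
  disease_targets <- data.frame(
    target = disease,
    source = sample(db, length(disease), replace = TRUE),
    stringsAsFactors = FALSE)
  list(compound_target = ct,
       herb_compound = herb_compound,
       disease_targets = disease_targets,
       manifest = list(compounds = compounds, herbs = herbs,
                       drug_targets = sort(drug_pool),
                       disease_targets = sort(unique(disease))))
}

#' Generate a gene-set library with one planted enriched term
#'
#' Background terms are uniform draws from the universe; the planted term
#' takes \code{planted_overlap} genes from the designated query and fills
#' the remainder from outside it, so the query is over-represented in the
#' planted term and (on average) not in the background.
#'
#' @param cfg An \code{npm_synth_config}.
#' @param universe Character vector of background symbols.
#' @param query Character vector, the gene set the planted term is
#'   enriched for (subset of \code{universe}).
#' @return List with \code{library} (an \code{npm_gmt}) and
#'   \code{manifest} (\code{planted_term}, \code{planted_genes}).
#' @export
generate_geneset_library <- function(cfg, universe, query) {
  stopifnot(inherits(cfg, "npm_synth_config"))
  lb <- cfg$library
  universe <- unique(normalize_symbols(universe))
  query <- intersect(unique(normalize_symbols(query)), universe)
  if (max(lb$term_size_range) > length(universe)) {
    stop("universe smaller than the largest term size")
  }
  if (lb$planted_overlap > length(query)) {
    stop("planted_overlap exceeds query size")
  }
  set.seed(cfg$seed + 3L)
  planted_id <- "PW000"
  in_query <- sample(query, lb$planted_overlap)
  outside <- setdiff(universe, query)
  filler <- sample(outside, min(lb$planted_term_size - lb$planted_overlap,
                                length(outside)))
  terms <- list()
  terms[[planted_id]] <- list(description = "planted enriched pathway",
                              genes = c(in_query, filler))
  for (i in seq_len(lb$n_terms)) {
    size <- sample(seq(lb$term_size_range[1], lb$term_size_range[2]), 1)
    terms[[sprintf("PW%03d", i)]] <- list(
      description = sprintf("background pathway %d", i),
      genes = sample(universe, size))
  }
  list(library = gene_set_library(terms),
       manifest = list(planted_term = planted_id,
                       planted_genes = sort(normalize_symbols(
                         c(in_query, filler)))))
}

#' Materialize a complete synthetic input bundle on disk
#'
#' Runs every generator and writes the file formats the pipeline consumes:
#' interactome node/edge tables, per-dataset expression matrices with label
#' sidecars, compound/herb/disease evidence TSVs, a GMT library (planted
#' against the interactome's hub neighbourhood) and \code{manifest.json}
#' recording all planted ground truth.
#'
#' @param cfg An \code{npm_synth_config}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of the written paths plus the manifest.
#' @export
write_synthetic_inputs <- function(cfg, dir) {
  stopifnot(inherits(cfg, "npm_synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  net <- generate_interactome(cfg)
  write_network(net, p("interactome"))
  bundle <- generate_expression_bundle(cfg, genes = net$nodes)
  expr_paths <- list()
  for (nm in names(bundle$datasets)) {
    write_expression_matrix(bundle$datasets[[nm]],
                            p(paste0(nm, ".tsv")),
                            p(paste0(nm, ".labels.tsv")))
    expr_paths[[nm]] <- list(matrix = p(paste0(nm, ".tsv")),
                             labels = p(paste0(nm, ".labels.tsv")))
  }
  ev <- generate_evidence_tables(cfg, net)
  utils::write.table(ev$compound_target, p("compound_target.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(ev$herb_compound, p("herb_compound.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ev$disease_targets, p("disease_targets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # designated query for the planted term: the planted hubs plus a seeded
  # sample of their neighbours, capped at 50 genes (a core-target-sized set;
  # the full hub neighbourhood would approach the whole universe and make
  # over-representation undefined)
  hubs <- attr(net, "manifest")$hub_nodes
  set.seed(cfg$seed + 4L)
  nbr <- neighbors_of(net, hubs)
  extra <- sample(nbr, max(0L, min(length(nbr), 50L - length(hubs))))
  designated_query <- sort(union(hubs, extra))
  lib <- generate_geneset_library(cfg, universe = net$nodes,
                                  query = designated_query)
  write_gmt(lib$library, p("library.gmt"))
  lib$manifest$designated_query <- designated_query
  manifest <- list(seed = cfg$seed,
                   hub_nodes = attr(net, "manifest")$hub_nodes,
                   expression = bundle$manifest,
                   evidence = ev$manifest,
                   library = lib$manifest)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    paths = list(interactome = p("interactome"),
                 expression = expr_paths,
                 compound_target = p("compound_target.tsv"),
                 herb_compound = p("herb_compound.tsv"),
                 disease_targets = p("disease_targets.tsv"),
                 gmt = p("library.gmt"),
                 manifest = p("manifest.json")),
    manifest = manifest))
}
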