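#' Build a run configuration
#'
#' Collects the input paths and every screening threshold of an
#' end-to-end run. Defaults follow the pipeline's standard criteria:
#' prediction score > 60 or top 50 per compound, microarray DEG thresholds
#' |log2 FC| > 1 and p < 0.05, median multiplier 2 for both screening
#' stages, enrichment p_adj <= 0.05 with kappa >= 0.4 grouping.
#'
#' @param interactome Path prefix of the interactome node/edge tables (as
#'   written by \code{\link{write_network}}), or a \code{.tsv}/\code{.sif}
#'   edge-list path.
#' @param expression List of \code{list(matrix =, labels =)} path pairs.
#' @param compound_target,herb_compound,disease_targets,gmt Input paths.
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @param score_min,top_k Compound-target screen parameters.
#' @param fc_min_log2,p_max DEG thresholds (microarray mode defaults).
#' @param multiplier Median multiplier for the two-stage screen.
#' @param depth Interactome expansion depth.
#' @param p_adj_max,kappa_min Enrichment cutoffs.
#' @param correction Multiple-testing correction method.
#' @return A list of class \code{npm_run_config}.
#' @export
run_config <- function(interactome, expression, compound_target,
                       herb_compound, disease_targets, gmt, out_dir,
                       seed = 1L, score_min = 60, top_k = 50,
                       fc_min_log2 = 1, p_max = 0.05, multiplier = 2,
                       depth = 1L, p_adj_max = 0.05, kappa_min = 0.4,
                       correction = "holm") {
  structure(list(interactome = interactome, expression = expression,
                 compound_target = compound_target,
                 herb_compound = herb_compound,
                 disease_targets = disease_targets, gmt = gmt,
                 out_dir = out_dir, seed = as.integer(seed),
                 score_min = score_min, top_k = top_k,
                 fc_min_log2 = fc_min_log2, p_max = p_max,
                 multiplier = multiplier, depth = depth,
                 p_adj_max = p_adj_max, kappa_min = kappa_min,
                 correction = correction),
            class = "npm_run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   \code{\link{run_config}}.
#' @return An \code{npm_run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Validate a run configuration
#'
#' @param cfg An \code{npm_run_config}.
#' @return Character vector of diagnostics; empty when the configuration
#'   is runnable.
#' @export
validate_config <- function(cfg) {
  d <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) d <<- c(d, msg)
  inter_ok <- is.character(cfg$interactome) &&
    (file.exists(cfg$interactome) ||
     file.exists(paste0(cfg$interactome, ".edges.tsv")))
  need(inter_ok, "interactome path not found")
  need(length(cfg$expression) >= 1, "no expression datasets configured")
  for (nm in names(cfg$expression)) {
    pair <- cfg$expression[[nm]]
    need(file.exists(pair$matrix %||% ""),
         sprintf("expression matrix missing: %s", nm))
    need(file.exists(pair$labels %||% ""),
         sprintf("expression labels missing: %s", nm))
  }
  for (f in c("compound_target", "herb_compound", "disease_targets", "gmt")) {
    need(is.character(cfg[[f]]) && file.exists(cfg[[f]]),
         paste(f, "path not found"))
  }
  need(cfg$score_min >= 0, "score_min must be >= 0")
  need(cfg$top_k >= 1, "top_k must be >= 1")
  need(cfg$fc_min_log2 >= 0, "fc_min_log2 must be >= 0")
  need(cfg$p_max > 0 && cfg$p_max <= 1, "p_max must be in (0, 1]")
  need(cfg$multiplier >= 0, "multiplier must be >= 0")
  need(cfg$depth >= 0, "depth must be >= 0")
  need(cfg$p_adj_max > 0 && cfg$p_adj_max <= 1,
       "p_adj_max must be in (0, 1]")
  need(cfg$kappa_min >= -1 && cfg$kappa_min <= 1,
       "kappa_min must be in [-1, 1]")
  need(cfg$correction %in% c("holm", "bonferroni", "bh"),
       "correction must be holm, bonferroni or bh")
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic run configuration
#'
#' Materializes the synthetic input bundle under \code{dir/inputs} and
#' returns a run configuration pointing at it, with outputs under
#' \code{dir/out}.
#'
#' @param dir Working directory for inputs and outputs.
#' @param seed Master seed for the synthetic generators.
#' @param synth Optional \code{npm_synth_config} overriding the default
#'   generator settings (its seed is replaced by \code{seed}).
#' @return An \code{npm_run_config}; attribute \code{manifest} carries the
#'   synthetic ground truth.
#' @export
default_run_config <- function(dir, seed = 1L, synth = NULL) {
  if (is.null(synth)) synth <- synthetic_config(seed = seed)
  else synth$seed <- as.integer(seed)
  inputs <- write_synthetic_inputs(synth, file.path(dir, "inputs"))
  cfg <- run_config(
    interactome = inputs$paths$interactome,
    expression = inputs$paths$expression,
    compound_target = inputs$paths$compound_target,
    herb_compound = inputs$paths$herb_compound,
    disease_targets = inputs$paths$disease_targets,
    gmt = inputs$paths$gmt,
    out_dir = file.path(dir, "out"),
    seed = seed)
  attr(cfg, "manifest") <- inputs$manifest
  cfg
}

read_compound_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  tab$score <- suppressWarnings(as.numeric(tab$score))
  tab
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[netpharm] ", fmt), ...))
}

#' Run the full network-pharmacology pipeline
#'
#' Stages, in order: assemble drug-side targets from the compound-target
#' table (score/rank screen); build the herb-compound-target network;
#' per-dataset differential-expression screen and Venn intersection;
#' merge curated disease targets with the shared DEGs; expand both target
#' sets against the interactome (seed plus neighbours); intersect the two
#' subnetworks; two-stage median-multiple centrality screen; hypergeometric
#' enrichment of the core targets with kappa grouping; and the
#' DEG-by-drug-target intersection subnetwork. Every intermediate artifact
#' is written under \code{cfg$out_dir}; identical configuration and inputs
#' give byte-identical artifacts.
#'
#' @param cfg An \code{npm_run_config}.
#' @param quiet Suppress per-stage progress messages.
#' @return The run report (also written as \code{report.json}), a list of
#'   per-stage counts and the thresholds applied.
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  diags <- validate_config(cfg)
  if (length(diags)) {
    stop("invalid configuration:\n  - ", paste(diags, collapse = "\n  - "))
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  stage <- "read_inputs"
  report <- list(seed = cfg$seed,
                 package_version = as.character(utils::packageVersion("netpharm")),
                 thresholds = cfg[c("score_min", "top_k", "fc_min_log2",
                                    "p_max", "multiplier", "depth",
                                    "p_adj_max", "kappa_min", "correction")],
                 stages = character(), counts = list())
  tryCatch({
    interactome <- if (file.exists(paste0(cfg$interactome, ".edges.tsv"))) {
      read_network(cfg$interactome)
    } else {
      dialect <- if (grepl("\\.sif$", cfg$interactome)) "sif" else "tsv2col"
      read_edge_list(cfg$interactome, dialect = dialect)
    }
    report$counts$interactome <- list(nodes = n_nodes(interactome),
                                      edges = n_edges(interactome))
    stage_log(quiet, "interactome: %d nodes, %d edges",
              n_nodes(interactome), n_edges(interactome))

    stage <- "drug_targets"
    ct <- read_compound_table(cfg$compound_target)
    hc <- utils::read.delim(cfg$herb_compound, header = TRUE,
                            comment.char = "#", stringsAsFactors = FALSE)
    drug_targets <- filter_predicted_targets(ct, score_min = cfg$score_min,
                                             top_k = cfg$top_k)
    write_target_set(drug_targets, out("drug_targets.tsv"))
    report$counts$drug_targets <- length(drug_targets)
    stage_log(quiet, "drug targets: %d", length(drug_targets))

    stage <- "tripartite"
    kept <- ct[normalize_symbols(ct$target) %in% drug_targets$symbols,
               c("compound", "target")]
    tripartite <- build_tripartite(hc, kept)
    write_network(tripartite, out("tripartite"))
    report$counts$tripartite <- list(nodes = n_nodes(tripartite),
                                     edges = n_edges(tripartite))

    stage <- "deg_screen"
    deg_sets <- list()
    de_tables <- list()
    for (nm in names(cfg$expression)) {
      ds <- read_expression_matrix(cfg$expression[[nm]]$matrix,
                                   cfg$expression[[nm]]$labels)
      res <- de_test(ds)
      res$pass <- abs(res$log2fc) > cfg$fc_min_log2 & res$p < cfg$p_max
      utils::write.table(res, out(paste0("de_", nm, ".tsv")), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      deg_sets[[nm]] <- threshold_degs(res, fc_min_log2 = cfg$fc_min_log2,
                                       p_max = cfg$p_max)
      de_tables[[nm]] <- res
    }
    report$counts$degs_per_dataset <- lapply(deg_sets, length)
    venn <- intersect_degs(deg_sets)
    jsonlite::write_json(as.list(venn$regions), out("venn_regions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    shared_degs <- target_set(venn$common$symbols,
                              provenance = list())  # re-normalized (human)
    write_target_set(shared_degs, out("shared_degs.tsv"))
    report$counts$shared_degs <- length(shared_degs)
    stage_log(quiet, "shared DEGs across %d datasets: %d",
              length(deg_sets), length(shared_degs))

    stage <- "disease_targets"
    curated <- read_target_set(cfg$disease_targets)
    disease_targets <- merge_target_sets(list(curated, shared_degs))
    write_target_set(disease_targets, out("disease_targets.tsv"))
    report$counts$disease_targets <- length(disease_targets)

    stage <- "expand_subnetworks"
    drug_net <- expand_subnetwork(interactome, drug_targets,
                                  depth = cfg$depth, name = "drug")
    disease_net <- expand_subnetwork(interactome, disease_targets,
                                     depth = cfg$depth, name = "disease")
    write_network(drug_net, out("drug_network"))
    write_network(disease_net, out("disease_network"))
    report$counts$drug_network <- list(nodes = n_nodes(drug_net),
                                       edges = n_edges(drug_net))
    report$counts$disease_network <- list(nodes = n_nodes(disease_net),
                                          edges = n_edges(disease_net))

    stage <- "intersect_networks"
    inter <- intersect_networks(drug_net, disease_net)
    write_network(inter, out("intersection_network"))
    report$counts$intersection <- list(nodes = n_nodes(inter),
                                       edges = n_edges(inter))
    stage_log(quiet, "intersection network: %d nodes, %d edges",
              n_nodes(inter), n_edges(inter))

    stage <- "two_stage_screen"
    screen <- two_stage_screen(inter, multiplier = cfg$multiplier)
    write_network(screen$hub_network, out("hub_network"))
    write_network(screen$core_network, out("core_network"))
    utils::write.table(screen$stage1_table, out("stage1_centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(screen$stage2_table, out("stage2_centrality.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(stage1_DC = screen$stage1_threshold,
           stage2 = as.list(screen$stage2_thresholds)),
      out("screen_thresholds.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    report$counts$hub <- list(nodes = n_nodes(screen$hub_network),
                              edges = n_edges(screen$hub_network))
    report$counts$core <- list(nodes = n_nodes(screen$core_network),
                               edges = n_edges(screen$core_network))
    report$thresholds$stage1_DC <- screen$stage1_threshold
    report$thresholds$stage2 <- as.list(screen$stage2_thresholds)
    stage_log(quiet, "screen: %d hub -> %d core nodes",
              n_nodes(screen$hub_network), n_nodes(screen$core_network))

    stage <- "enrichment"
    lib <- read_gmt(cfg$gmt)
    core_nodes <- screen$core_network$nodes
    if (length(core_nodes)) {
      enr <- hypergeom_ora(core_nodes, lib)
      enr <- correct_pvalues(enr, method = cfg$correction)
      groups <- group_terms(enr, kappa_min = cfg$kappa_min,
                            p_adj_max = cfg$p_adj_max)
      enr$group <- groups$group[match(enr$term_id, groups$term_id)]
      enr$leading <- groups$leading[match(enr$term_id, groups$term_id)]
      utils::write.table(enr, out("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
      report$counts$significant_terms <- sum(enr$p_adj <= cfg$p_adj_max)
      report$counts$term_groups <-
        if (nrow(groups)) length(unique(groups$group)) else 0L
    } else {
      report$counts$significant_terms <- 0L
      report$counts$term_groups <- 0L
    }

    stage <- "deg_drug_intersection"
    overlap <- intersect(shared_degs$symbols, drug_targets$symbols)
    report$counts$deg_drug_overlap <- length(overlap)
    if (length(overlap)) {
      overlap_net <- induced_subgraph(interactome, overlap)
      overlap_net$name <- "deg-drug-intersection"
      write_network(overlap_net, out("deg_drug_network"))
    }
  }, error = function(e) {
    report$failed_stage <<- stage
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  report$stages <- c("read_inputs", "drug_targets", "tripartite",
                     "deg_screen", "disease_targets", "expand_subnetworks",
                     "intersect_networks", "two_stage_screen", "enrichment",
                     "deg_drug_intersection")
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
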