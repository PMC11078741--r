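#' @importFrom utils modifyList
NULL

#' Default pipeline configuration
#'
#' Nested list of every stage parameter with its default. Any subset can be
#' overridden via \code{run_pipeline(..., config = ...)}; unknown keys are
#' rejected so typos fail loudly.
#'
#' @return named nested list
#' @export
default_config <- function() {
  list(
    de = list(p_max = 0.05, lfc_min = 1.0, q_max = 0.20,
              cpm_threshold = 1.0, genomewide_q = FALSE,
              shrink_weight = 0.8,
              comparisons = list(c("LR.Li-", "NR.Li-"),
                                 c("LR.Li+", "NR.Li+")),
              min_seeds = 10L, fallback_n_seeds = 40L),
    gwas = list(window_bp = 0L, sims = c(1e3, 1e4, 1e5),
                lambda = 1.0, neighbor_cap = 50L, fraction = 0.05),
    propagation = list(alpha = 0.5, mode = "row_stochastic",
                       tol = 1e-8, max_iter = 1e4,
                       permutations = 1000L, bins = 10L,
                       k_list = c(500L, 2000L)),
    overlap = list(k_grid = c(100, 250, 500, 1000, 2000, 4000)),
    enrichment = list(q_max = 0.05, resolution = 1.0, restarts = 10L,
                      degree_threshold = 200L, min_overlap = 1L),
    seed = 1L)
}

merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  for (k in names(override)) {
    if (!k %in% names(base)) stop("unknown config key: ", k)
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

# order-insensitive content hash of the (canonicalized) configuration
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else x
  }
  txt <- jsonlite::toJSON(canon(config), auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(txt), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full integration pipeline on a bundle
#'
#' Executes the five analysis stages in order: serial-filter differential
#' expression (seeds), gene-based GWAS scoring with network boosting
#' (prioritized list), seed propagation with degree-matched significance,
#' hypergeometric overlap of the two channels, and Louvain clustering with
#' term/pathway enrichment and hub-gene scoring. When the DE stage yields
#' fewer than \code{de$min_seeds} genes (e.g. a null experiment), the
#' pipeline falls back to the top \code{de$fallback_n_seeds} genes by raw
#' p-value so the downstream stages still run, and flags the run as weak.
#'
#' @param bundle a \code{simulate_bundle} result or \code{read_fixture}
#'   output (interactome, experiment, gwas, gene_models, collection)
#' @param config overrides merged onto \code{default_config()}
#' @param out_dir optional directory for TSV outputs, report.md and
#'   summary.json
#' @return list of class \code{pipeline_report} with per-stage results and
#'   a \code{summary} list of headline numbers
#' @export
run_pipeline <- function(bundle, config = NULL, out_dir = NULL) {
  cfg <- merge_config(default_config(), config)
  seed <- as.integer(cfg$seed)

  ## Stage 1: differential expression -> seed genes
  factors <- tmm_factors(bundle$experiment)
  cpm <- compute_cpm(bundle$experiment, factors)
  kept <- filter_low_expression(cpm, threshold = cfg$de$cpm_threshold,
                                design = bundle$experiment$design)
  de_lists <- list()
  de_tables <- list()
  for (cmp in cfg$de$comparisons) {
    de <- fit_de_model(bundle$experiment, genes = kept,
                       cell_a = cmp[1], cell_b = cmp[2],
                       factors = factors,
                       shrink_weight = cfg$de$shrink_weight)
    sf <- serial_filter(de, p_max = cfg$de$p_max,
                        lfc_min = cfg$de$lfc_min, q_max = cfg$de$q_max,
                        genomewide_q = cfg$de$genomewide_q)
    lab <- paste(cmp, collapse = "_vs_")
    de_lists[[lab]] <- sf$de_genes
    de_tables[[lab]] <- sf$table
  }
  venn <- if (length(de_lists) >= 2) compare_de_lists(de_lists) else NULL
  seeds <- sort(unique(unlist(de_lists)))
  seeds_fallback <- FALSE
  if (length(seeds) < cfg$de$min_seeds) {
    # weak/null expression signal: rank all tested genes by best raw p
    pooled <- do.call(rbind, lapply(de_tables, function(t)
      t[, c("gene", "p")]))
    best <- tapply(pooled$p, pooled$gene, min)
    seeds <- names(sort(best))[seq_len(min(cfg$de$fallback_n_seeds,
                                           length(best)))]
    seeds_fallback <- TRUE
  }

  ## Stage 2: GWAS gene scoring + network boost -> prioritized list
  assoc <- snp_logistic_assoc(bundle$gwas)
  gidx <- map_snps_to_genes(
    data.frame(snp = assoc$snp, chr = assoc$chr, pos = assoc$pos),
    bundle$gene_models, window_bp = cfg$gwas$window_bp)
  gscores <- vegas_scores(assoc, gidx, bundle$gwas,
                          sims = cfg$gwas$sims, seed = seed + 11L)
  s <- setNames(-log10(gscores$p_empirical), gscores$gene)
  boosted <- gwab_boost(s, bundle$interactome, lambda = cfg$gwas$lambda,
                        neighbor_cap = cfg$gwas$neighbor_cap)
  top_gwab <- select_top_fraction(setNames(boosted$B, boosted$gene),
                                  fraction = cfg$gwas$fraction)
  top_vegas <- select_top_fraction(s, fraction = cfg$gwas$fraction)

  ## Stage 3: propagation of the DE seeds
  prop <- propagate_seeds(bundle$interactome, seeds,
                          alpha = cfg$propagation$alpha,
                          mode = cfg$propagation$mode,
                          R = cfg$propagation$permutations,
                          B = cfg$propagation$bins,
                          k_list = cfg$propagation$k_list,
                          seed = seed + 23L,
                          tol = cfg$propagation$tol,
                          max_iter = cfg$propagation$max_iter)
  k_main <- as.character(min(cfg$propagation$k_list))
  main_net <- prop$networks[[k_main]]

  ## Stage 4: overlap of the two evidence channels
  background <- interactome_genes(bundle$interactome)
  types <- label_gene_types(main_net$genes, prop$seeds_used,
                            top_gwab$genes)
  prop$result$gene_type <- NA_character_
  prop$result$gene_type[match(names(types), prop$result$gene)] <- types
  ov <- overlap_test(main_net$genes, top_gwab$genes, background,
                     seeds = prop$seeds_used)
  sweep_tab <- overlap_sweep(main_net$ranking, top_gwab$genes, background,
                             k_grid = cfg$overlap$k_grid)

  ## Stage 5: clustering, enrichment, hubs
  part <- louvain_cluster(main_net$subgraph,
                          gamma = cfg$enrichment$resolution,
                          seed = seed + 31L,
                          restarts = cfg$enrichment$restarts)
  enr_bg <- intersect(background, unique(unlist(bundle$collection$sets)))
  net_enr <- if (length(intersect(main_net$genes, enr_bg)))
    term_enrichment(main_net$genes, bundle$collection, enr_bg,
                    seeds = prop$seeds_used, prioritized = top_gwab$genes,
                    q_max = cfg$enrichment$q_max,
                    min_overlap = cfg$enrichment$min_overlap)
  else NULL
  top_terms <- if (!is.null(net_enr) && any(net_enr$significant))
    net_enr[net_enr$significant, ] else net_enr
  hub_cand <- if (!is.null(top_terms) && nrow(top_terms))
    unique(unlist(strsplit(top_terms$genes, ","))) else character()
  hubs <- if (length(hub_cand))
    hub_genes(main_net$subgraph, hub_cand,
              degree_threshold = cfg$enrichment$degree_threshold)
  else NULL

  type_counts <- table(factor(types,
                              levels = c("DE", "DE/GWAB", "GWAB", "network")))
  summary <- list(
    n_genes_tested = length(kept),
    de_counts = lapply(de_lists, length),
    n_seeds = length(seeds),
    seeds_fallback = seeds_fallback,
    seeds_dropped = length(prop$seeds_dropped),
    gwab_top_size = top_gwab$n_selected,
    gwab_universe = top_gwab$n_universe,
    network_k = as.integer(k_main),
    network_edges = main_net$n_edges,
    gene_type_counts = as.list(type_counts),
    overlap_p = setNames(as.list(ov$p), ov$variant),
    n_clusters = part$n_clusters,
    modularity = part$modularity,
    n_enriched_terms = if (!is.null(net_enr)) sum(net_enr$significant)
    else 0L,
    n_hubs = if (!is.null(hubs)) sum(hubs$hub) else 0L,
    weak_signal = seeds_fallback,
    seed = seed,
    config_hash = config_hash(cfg))
  report <- structure(
    list(config = cfg, factors = factors, de_lists = de_lists,
         de_tables = de_tables, venn = venn, seeds = seeds,
         assoc = assoc, gene_scores = gscores, boosted = boosted,
         top_gwab = top_gwab, top_vegas = top_vegas,
         propagation = prop, gene_types = types, overlap = ov,
         overlap_sweep = sweep_tab, clusters = part,
         enrichment = net_enr, hubs = hubs, summary = summary),
    class = "pipeline_report")
  if (!is.null(out_dir)) write_pipeline_outputs(report, bundle, out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("pipeline_report\n")
  cat(sprintf("  seeds: %d%s (dropped from network: %d)\n", s$n_seeds,
              if (s$seeds_fallback) " [fallback: weak DE signal]" else "",
              s$seeds_dropped))
  cat(sprintf("  prioritized (boosted top fraction): %d of %d\n",
              s$gwab_top_size, s$gwab_universe))
  cat(sprintf("  proximal network: %d genes, %d edges\n",
              s$network_k, s$network_edges))
  cat(sprintf("  gene types: %s\n",
              paste(sprintf("%s=%d", names(s$gene_type_counts),
                            unlist(s$gene_type_counts)), collapse = " ")))
  cat(sprintf("  overlap p (prioritized only): %.3g\n",
              s$overlap_p$prioritized_only))
  cat(sprintf("  clusters: %d (Q = %.3f), enriched terms: %d, hubs: %d\n",
              s$n_clusters, s$modularity, s$n_enriched_terms, s$n_hubs))
  invisible(x)
}

# write stage TSVs, report.md and summary.json under out_dir
write_pipeline_outputs <- function(report, bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  for (lab in names(report$de_tables))
    write.table(report$de_tables[[lab]], fp(paste0("de_", lab, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$venn))
    write.table(report$venn$regions, fp("de_venn.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(report$gene_scores, fp("gene_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$boosted, fp("boosted_scores.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$propagation$result, fp("propagation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$overlap, fp("overlap.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$overlap_sweep, fp("overlap_sweep.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$enrichment))
    write.table(report$enrichment, fp("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(report$hubs))
    write.table(report$hubs, fp("hubs.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  cl <- data.frame(gene = names(report$clusters$membership),
                   cluster = as.integer(report$clusters$membership))
  write.table(cl, fp("clusters.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  prox_col <- paste0("proximal_", report$summary$network_k)
  write_network_tables(report$propagation$result, bundle$interactome,
                       fp("network"), proximal_col = prox_col)
  jsonlite::write_json(report$summary, fp("summary.json"),
                       auto_unbox = TRUE, digits = NA)
  s <- report$summary
  md <- c(
    "# Integration pipeline report", "",
    sprintf("- config hash: `%s`; master seed: %d", s$config_hash, s$seed),
    sprintf("- genes tested after CPM filter: %d", s$n_genes_tested),
    paste0("- DE genes per comparison: ",
           paste(sprintf("%s = %d", names(report$de_lists),
                         vapply(report$de_lists, length, 0L)),
                 collapse = ", ")),
    sprintf("- seeds: %d%s", s$n_seeds,
            if (s$seeds_fallback)
              " (FALLBACK: weak differential-expression signal; seeds are top raw-p genes)"
            else ""),
    sprintf("- prioritized genes (boosted top fraction): %d of %d",
            s$gwab_top_size, s$gwab_universe),
    sprintf("- proximal network: %d genes, %d edges", s$network_k,
            s$network_edges),
    paste0("- gene types: ",
           paste(sprintf("%s = %d", names(s$gene_type_counts),
                         unlist(s$gene_type_counts)), collapse = ", ")),
    sprintf("- hypergeometric overlap p: %.6g (prioritized only), %.6g (prioritized or seed)",
            s$overlap_p$prioritized_only, s$overlap_p$prioritized_or_seed),
    sprintf("- clusters: %d (modularity %.4f)", s$n_clusters, s$modularity),
    sprintf("- significantly enriched terms: %d", s$n_enriched_terms),
    sprintf("- hub genes: %d", s$n_hubs))
  writeLines(md, fp("report.md"))
  invisible(out_dir)
}
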