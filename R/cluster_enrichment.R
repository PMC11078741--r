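NULL

# ---------------------------------------------------------------------------
# Louvain clustering
# ---------------------------------------------------------------------------

#' Louvain community detection on a proximal network
#'
#' Runs weighted Louvain clustering \code{restarts} times with seeds derived
#' deterministically from the master seed and keeps the partition with the
#' highest modularity. Singletons are allowed; an empty graph yields an
#' empty partition.
#'
#' @param subgraph igraph graph (e.g. the induced top-k proximal network)
#' @param gamma resolution parameter
#' @param seed master RNG seed (restart r uses seed + r)
#' @param restarts number of random restarts
#' @return list of class \code{cluster_partition}: membership (named integer
#'   vector), modularity, gamma, seed, restarts, n_clusters
#' @export
louvain_cluster <- function(subgraph, gamma = 1.0, seed = 1L,
                            restarts = 10L) {
  if (igraph::vcount(subgraph) == 0) {
    return(structure(list(membership = setNames(integer(0), character(0)),
                          modularity = NA_real_, gamma = gamma, seed = seed,
                          restarts = restarts, n_clusters = 0L),
                     class = "cluster_partition"))
  }
  w <- igraph::E(subgraph)$weight
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    cl <- igraph::cluster_louvain(subgraph, weights = w,
                                  resolution = gamma)
    q <- modularity_score(igraph::membership(cl), subgraph, gamma = gamma)
    if (q > best_q) { best <- cl; best_q <- q }
  }
  memb <- igraph::membership(best)
  structure(list(membership = setNames(as.integer(memb),
                                       igraph::V(subgraph)$name),
                 modularity = best_q, gamma = gamma, seed = seed,
                 restarts = restarts,
                 n_clusters = length(unique(memb))),
            class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat(sprintf("cluster_partition: %d genes in %d clusters, Q = %.4f\n",
              length(x$membership), x$n_clusters, x$modularity))
  invisible(x)
}

#' Weighted modularity of a partition
#'
#' Standard weighted modularity with resolution gamma:
#' Q = sum_c [ e_c / m - gamma * (d_c / 2m)^2 ], where e_c is the weight
#' inside cluster c, d_c the total weighted degree of its nodes and m the
#' total edge weight.
#'
#' @param membership named (or graph-ordered) cluster assignment
#' @param subgraph igraph graph
#' @param gamma resolution parameter
#' @return modularity Q
#' @export
modularity_score <- function(membership, subgraph, gamma = 1.0) {
  if (igraph::vcount(subgraph) == 0) return(NA_real_)
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(subgraph)$name]
  igraph::modularity(subgraph, membership,
                     weights = igraph::E(subgraph)$weight,
                     resolution = gamma)
}

# ---------------------------------------------------------------------------
# Term enrichment
# ---------------------------------------------------------------------------

#' Hypergeometric term enrichment with B-H control
#'
#' Tests each term of a gene-set collection for over-representation in a
#' query gene set against an explicit background, adjusting across all
#' tested terms by Benjamini-Hochberg. Records carry the participating
#' genes, their evidence-channel types, and the DE gene rich factor
#' (fraction of seed genes among a term's participating genes; a config
#' switch uses the full term size as denominator instead). The optional
#' pathway-style constraint keeps only terms whose participants include at
#' least one seed gene and one prioritized gene.
#'
#' @param query gene set to test (cluster or whole network)
#' @param collection \code{gene_set_collection}
#' @param background explicit gene universe; terms are intersected with it
#'   and terms falling fully outside are skipped (counted in attribute
#'   \code{n_skipped})
#' @param seeds seed genes (for gene types and the rich factor)
#' @param prioritized prioritized genes (for gene types)
#' @param q_max B-H significance threshold for the \code{significant} flag
#' @param min_overlap minimum participating genes for a term to be tested
#' @param require_seed_and_prioritized pathway-style constraint (see above)
#' @param rich_denominator "participants" (default) or "term_size"
#' @return data.frame of enrichment records sorted by q then p then term
#' @export
term_enrichment <- function(query, collection, background,
                            seeds = character(), prioritized = character(),
                            q_max = 0.05, min_overlap = 1L,
                            require_seed_and_prioritized = FALSE,
                            rich_denominator = c("participants",
                                                 "term_size")) {
  rich_denominator <- match.arg(rich_denominator)
  background <- unique(background)
  query <- intersect(unique(query), background)
  if (!length(query)) stop("query is empty after background intersection")
  n_skipped <- 0L
  rows <- list()
  for (id in names(collection$sets)) {
    term <- intersect(collection$sets[[id]], background)
    if (!length(term)) { n_skipped <- n_skipped + 1L; next }
    part <- intersect(query, term)
    if (length(part) < min_overlap) next
    types <- label_gene_types(part, seeds, prioritized)
    if (require_seed_and_prioritized &&
        !(any(types %in% c("DE", "DE/GWAB")) &&
          any(types %in% c("GWAB", "DE/GWAB")))) next
    n_de <- sum(types %in% c("DE", "DE/GWAB"))
    denom <- if (rich_denominator == "participants") length(part)
    else length(term)
    rows[[id]] <- data.frame(
      term = id, source = collection$source[[id]],
      description = collection$description[[id]],
      N_bg = length(background), K_t = length(term),
      n_q = length(query), x_t = length(part),
      p = hypergeom_overlap(length(background), length(term),
                            length(query), length(part)),
      rich_factor = n_de / denom,
      genes = paste(sort(part), collapse = ","),
      gene_types = paste(types[sort(part)], collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(term = character(), source = character(),
                      description = character(), N_bg = integer(),
                      K_t = integer(), n_q = integer(), x_t = integer(),
                      p = numeric(), q = numeric(), rich_factor = numeric(),
                      genes = character(), gene_types = character(),
                      significant = logical())
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$q <= q_max
  out <- out[order(out$q, out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

# ---------------------------------------------------------------------------
# Hub genes
# ---------------------------------------------------------------------------

#' Hub-like genes among top-pathway members
#'
#' Computes the (unweighted) degree of each candidate gene on the induced
#' top-k proximal subgraph and flags as hubs the candidates whose degree
#' exceeds the threshold. Candidates absent from the subgraph are flagged
#' rather than dropped.
#'
#' @param subgraph induced top-k proximal igraph graph
#' @param candidates candidate genes, typically the union of the selected
#'   top pathways' participating genes
#' @param degree_threshold hub iff degree strictly exceeds this
#' @return data.frame: gene, degree, hub, in_subgraph; sorted by descending
#'   degree then symbol
#' @export
hub_genes <- function(subgraph, candidates, degree_threshold = 200L) {
  candidates <- unique(candidates)
  nodes <- igraph::V(subgraph)$name
  deg <- igraph::degree(subgraph)
  in_g <- candidates %in% nodes
  out <- data.frame(gene = candidates,
                    degree = ifelse(in_g, deg[candidates], NA_integer_),
                    in_subgraph = in_g, stringsAsFactors = FALSE)
  out$hub <- !is.na(out$degree) & out$degree > degree_threshold
  out <- out[order(-ifelse(is.na(out$degree), -1, out$degree), out$gene), ]
  rownames(out) <- NULL
  out
}
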