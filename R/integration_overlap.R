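#' @importFrom stats phyper
NULL

# ---------------------------------------------------------------------------
# Gene-type labeling
# ---------------------------------------------------------------------------

#' Label network genes by evidence channel
#'
#' Partitions the genes of a proximal network into four exhaustive,
#' disjoint types: \code{DE} (seed only), \code{DE/GWAB} (seed and
#' prioritized), \code{GWAB} (prioritized only) and \code{network}
#' (neither).
#'
#' @param network_genes gene symbols of the proximal network
#' @param seeds differential-expression seed genes
#' @param prioritized network-boosted top-fraction GWAS genes
#' @return named character vector, gene -> type
#' @export
label_gene_types <- function(network_genes, seeds, prioritized) {
  network_genes <- unique(network_genes)
  in_seed <- network_genes %in% seeds
  in_pri <- network_genes %in% prioritized
  type <- ifelse(in_seed & in_pri, "DE/GWAB",
                 ifelse(in_seed, "DE",
                        ifelse(in_pri, "GWAB", "network")))
  setNames(type, network_genes)
}

# ---------------------------------------------------------------------------
# Hypergeometric overlap
# ---------------------------------------------------------------------------

#' Upper-tail hypergeometric overlap probability
#'
#' P(X >= x) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least x marked genes when n genes are drawn without replacement from a
#' background of N genes of which K are marked. Computed in log space so
#' extreme tails never underflow to an exact zero.
#'
#' @param N background size
#' @param K marked genes in the background
#' @param n drawn genes
#' @param x observed overlap
#' @return upper-tail probability in (0, 1]
#' @export
hypergeom_overlap <- function(N, K, n, x) {
  if (K > N || n > N) stop("K and n cannot exceed N")
  if (x > min(K, n)) stop("x cannot exceed min(K, n)")
  if (x <= 0) return(1)
  lp <- phyper(x - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  max(exp(lp), .Machine$double.xmin)
}

#' Over-representation of a prioritized list in a proximal network
#'
#' Tests whether the proximal network contains more prioritized genes than
#' expected from a uniform draw out of the propagation background. Two
#' framings are reported: \code{prioritized_only} (overlap counts GWAB and
#' DE/GWAB genes) and \code{prioritized_or_seed} (seeds count as marked
#' too).
#'
#' @param network_genes proximal network gene symbols
#' @param prioritized prioritized gene list
#' @param background gene universe the network was drawn from (the
#'   propagation interactome)
#' @param seeds seed genes, used by the second framing
#' @return data.frame with one row per framing: variant, N, K, n, x, p
#' @export
overlap_test <- function(network_genes, prioritized, background,
                         seeds = character()) {
  background <- unique(background)
  net <- intersect(unique(network_genes), background)
  variants <- list(
    prioritized_only = intersect(unique(prioritized), background),
    prioritized_or_seed = intersect(union(prioritized, seeds), background))
  rows <- lapply(names(variants), function(v) {
    marked <- variants[[v]]
    x <- length(intersect(net, marked))
    data.frame(variant = v, N = length(background), K = length(marked),
               n = length(net), x = x,
               p = hypergeom_overlap(length(background), length(marked),
                                     length(net), x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Overlap significance as a function of network size
#'
#' For each k on the grid, tests the top-k genes of the propagation ranking
#' for over-representation of the prioritized list, tracing how overlap
#' significance varies with network size. k = 500 and k = 2000 are always
#' included when the background allows. A grid-Bonferroni companion column
#' accompanies the unadjusted p because the k values are analyst-chosen.
#'
#' @param ranking full propagation-ranked gene vector (best first)
#' @param prioritized prioritized gene list
#' @param background gene universe
#' @param k_grid network sizes to evaluate
#' @return data.frame: k, N, K, n, x, p, p_bonferroni, neg_log10_p
#' @export
overlap_sweep <- function(ranking, prioritized, background,
                          k_grid = c(100, 250, 500, 1000, 2000, 4000)) {
  background <- unique(background)
  k_grid <- sort(unique(c(k_grid, 500, 2000)))
  k_grid <- k_grid[k_grid >= 1 & k_grid <= length(ranking)]
  marked <- intersect(unique(prioritized), background)
  rows <- lapply(k_grid, function(k) {
    net <- intersect(ranking[seq_len(k)], background)
    x <- length(intersect(net, marked))
    p <- hypergeom_overlap(length(background), length(marked),
                           length(net), x)
    data.frame(k = k, N = length(background), K = length(marked),
               n = length(net), x = x, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p * nrow(out), 1)
  out$neg_log10_p <- -log10(out$p)
  out
}
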