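#' @import Matrix
NULL

# ---------------------------------------------------------------------------
# Adjacency normalization
# ---------------------------------------------------------------------------

#' Normalize the interactome adjacency matrix
#'
#' Row-stochastic (W' = D^-1 A; each row sums to 1) or symmetric
#' (W' = D^-1/2 A D^-1/2) normalization of the weighted adjacency matrix.
#' Isolated nodes get a zero row and are flagged; propagation leaves their
#' score at (1 - alpha) * Y.
#'
#' @param interactome \code{interactome}
#' @param mode "row_stochastic" or "symmetric"
#' @return sparse matrix with gene dimnames; attributes \code{mode} and
#'   \code{isolated} (gene symbols with zero degree)
#' @export
normalize_adjacency <- function(interactome,
                                mode = c("row_stochastic", "symmetric")) {
  mode <- match.arg(mode)
  g <- interactome$graph
  A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  d <- Matrix::rowSums(A)
  isolated <- rownames(A)[d == 0]
  dn <- ifelse(d > 0, d, 1)
  W <- if (mode == "row_stochastic") {
    Matrix::Diagonal(x = 1 / dn) %*% A
  } else {
    Dh <- Matrix::Diagonal(x = 1 / sqrt(dn))
    Dh %*% A %*% Dh
  }
  dimnames(W) <- dimnames(A)
  attr(W, "mode") <- mode
  attr(W, "isolated") <- isolated
  W
}

# ---------------------------------------------------------------------------
# Random walk with restart
# ---------------------------------------------------------------------------

# Core iteration; Y may be a matrix with one restart vector per row, so
# permutation walks run batched.
rwr_iterate <- function(W, Y, alpha, tol = 1e-8, max_iter = 1e4) {
  F <- Y
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    Fn <- alpha * (F %*% W) + (1 - alpha) * Y
    delta <- max(abs(Fn - F))
    F <- Fn
    iters <- it
    if (delta < tol) { converged <- TRUE; break }
  }
  list(F = as.matrix(F), converged = converged, iters = iters)
}

#' Random walk with restart from seed genes
#'
#' Iterates F <- alpha * F W' + (1 - alpha) * Y to convergence, where Y puts
#' uniform mass 1 on the seed genes. Seeds absent from the graph are dropped
#' with a named warning; if none remain the call is an error. In
#' row-stochastic mode the stationary scores conserve the restart mass
#' (sum F = 1).
#'
#' @param W normalized adjacency from \code{normalize_adjacency}
#' @param seeds character vector of seed gene symbols
#' @param alpha restart weight in (0, 1)
#' @param tol max-abs-change convergence tolerance
#' @param max_iter iteration cap
#' @return list(F = named score vector, converged, iters, seeds_used,
#'   seeds_dropped)
#' @export
propagate <- function(W, seeds, alpha = 0.5, tol = 1e-8, max_iter = 1e4) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  nodes <- rownames(W)
  seeds <- unique(seeds)
  dropped <- setdiff(seeds, nodes)
  kept <- intersect(seeds, nodes)
  if (length(dropped))
    warning("seed gene(s) absent from the network dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(kept)) stop("no seed gene present in the network")
  Y <- matrix(0, 1, length(nodes), dimnames = list(NULL, nodes))
  Y[1, kept] <- 1 / length(kept)
  res <- rwr_iterate(W, Y, alpha, tol, max_iter)
  list(F = setNames(drop(res$F), nodes), converged = res$converged,
       iters = res$iters, seeds_used = kept, seeds_dropped = dropped)
}

# ---------------------------------------------------------------------------
# Degree-matched permutation significance
# ---------------------------------------------------------------------------

#' Degree-matched permutation z-scores for propagation
#'
#' Bins nodes into \code{B} quantile bins of log(degree + 1); each of the
#' \code{R} permutations draws a random seed set with the same per-bin
#' composition as the true seeds and re-runs the walk (all permutations are
#' propagated as one batched iteration). z_i = (F_i - mean_perm) / sd_perm;
#' genes with zero permutation sd get z = 0 and are flagged. Bins with fewer
#' candidates than required seeds are merged with their lower neighbor.
#'
#' @param W normalized adjacency
#' @param interactome \code{interactome} (degree index)
#' @param seeds seed gene symbols (present in the graph)
#' @param alpha,tol,max_iter walk parameters as in \code{propagate}
#' @param R number of permutations (>= 100)
#' @param B number of degree bins
#' @param seed RNG seed
#' @return data.frame: gene, F, perm_mean, perm_sd, z, sd_zero flag
#' @export
degree_matched_zscores <- function(W, interactome, seeds, alpha = 0.5,
                                   R = 1000L, B = 10L, seed = 1L,
                                   tol = 1e-8, max_iter = 1e4) {
  if (R < 100) stop("R must be >= 100 for stable z-scores")
  nodes <- rownames(W)
  seeds <- intersect(unique(seeds), nodes)
  if (!length(seeds)) stop("no seed gene present in the network")
  deg <- interactome_degree(interactome)[nodes]
  ldeg <- log(deg + 1)
  br <- unique(quantile(ldeg, probs = seq(0, 1, length.out = B + 1)))
  if (length(br) < 2) br <- c(min(ldeg) - 1, max(ldeg) + 1)
  bin <- cut(ldeg, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- nodes
  need <- table(factor(bin[seeds], levels = sort(unique(bin))))
  have <- table(factor(bin, levels = sort(unique(bin))))
  # merge underfilled bins downward
  lev <- as.integer(names(need))
  for (k in rev(seq_along(lev))) {
    if (need[k] > have[k] && k > 1) {
      bin[bin == lev[k]] <- lev[k - 1]
      need[k - 1] <- need[k - 1] + need[k]; need[k] <- 0
      have[k - 1] <- have[k - 1] + have[k]
    }
  }
  observed <- propagate(W, seeds, alpha = alpha, tol = tol,
                        max_iter = max_iter)
  F_obs <- observed$F

  set.seed(seed)
  ns <- length(seeds)
  Y <- matrix(0, R, length(nodes), dimnames = list(NULL, nodes))
  bins_present <- sort(unique(bin[seeds]))
  cand_by_bin <- lapply(bins_present, function(b) which(bin == b))
  need_by_bin <- vapply(bins_present, function(b) sum(bin[seeds] == b), 0L)
  for (r in seq_len(R)) {
    pick <- unlist(mapply(function(cand, k) {
      if (length(cand) == 1) cand else sample(cand, k)
    }, cand_by_bin, need_by_bin, SIMPLIFY = FALSE))
    Y[r, pick] <- 1 / ns
  }
  perm <- rwr_iterate(W, Y, alpha, tol, max_iter)
  mu <- colMeans(perm$F)
  sdv <- apply(perm$F, 2, sd)
  z <- ifelse(sdv > 0, (F_obs - mu) / sdv, 0)
  data.frame(gene = nodes, F = as.numeric(F_obs),
             perm_mean = as.numeric(mu), perm_sd = as.numeric(sdv),
             z = as.numeric(z), sd_zero = sdv == 0,
             stringsAsFactors = FALSE)
}

#' Extract the top-k proximal gene network
#'
#' Ranks genes by permutation z (ties broken by raw propagation score, then
#' symbol) and returns the top-k set with its induced subgraph. Seed genes
#' compete on z like any other node and are expected to rank high.
#'
#' @param ztab data.frame from \code{degree_matched_zscores}
#' @param interactome \code{interactome}
#' @param k network size (k <= number of genes)
#' @param by rank by "z" (default) or raw score "F" (sensitivity analysis)
#' @return list(genes = ranked top-k symbols, subgraph = induced igraph,
#'   n_edges, ranking = full ranked gene vector)
#' @export
top_k_proximal <- function(ztab, interactome, k = 500L, by = c("z", "F")) {
  by <- match.arg(by)
  if (k > nrow(ztab)) stop("k exceeds the number of scored genes")
  ord <- if (by == "z") order(-ztab$z, -ztab$F, ztab$gene)
  else order(-ztab$F, -ztab$z, ztab$gene)
  ranking <- ztab$gene[ord]
  top <- ranking[seq_len(k)]
  keep <- intersect(top, interactome_genes(interactome))
  sub <- igraph::induced_subgraph(interactome$graph, keep)
  list(genes = top, subgraph = sub, n_edges = igraph::ecount(sub),
       ranking = ranking)
}

#' Seed propagation with significance, end to end
#'
#' Convenience wrapper: normalize, propagate the seeds, compute
#' degree-matched permutation z-scores, and flag the top-k proximal sets.
#'
#' @param interactome \code{interactome}
#' @param seeds seed gene symbols
#' @param alpha restart weight
#' @param mode adjacency normalization mode
#' @param R permutations
#' @param B degree bins
#' @param k_list proximal set sizes to flag
#' @param seed RNG seed
#' @param tol,max_iter walk parameters
#' @return list(result = per-gene data.frame with rank and proximal flags,
#'   networks = named list of \code{top_k_proximal} outputs,
#'   seeds_used, seeds_dropped)
#' @export
propagate_seeds <- function(interactome, seeds, alpha = 0.5,
                            mode = "row_stochastic", R = 1000L, B = 10L,
                            k_list = c(500L, 2000L), seed = 1L,
                            tol = 1e-8, max_iter = 1e4) {
  W <- normalize_adjacency(interactome, mode = mode)
  pr <- propagate(W, seeds, alpha = alpha, tol = tol, max_iter = max_iter)
  ztab <- degree_matched_zscores(W, interactome, pr$seeds_used,
                                 alpha = alpha, R = R, B = B, seed = seed,
                                 tol = tol, max_iter = max_iter)
  k_list <- k_list[k_list <= nrow(ztab)]
  nets <- list()
  ord <- order(-ztab$z, -ztab$F, ztab$gene)
  ztab$rank <- NA_integer_
  ztab$rank[ord] <- seq_len(nrow(ztab))
  for (k in k_list) {
    nk <- top_k_proximal(ztab, interactome, k = k)
    ztab[[paste0("proximal_", k)]] <- ztab$gene %in% nk$genes
    nets[[as.character(k)]] <- nk
  }
  list(result = ztab, networks = nets,
       seeds_used = pr$seeds_used, seeds_dropped = pr$seeds_dropped)
}
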