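#' @importFrom stats binomial glm.fit pchisq pnorm qnorm rnorm
NULL

# ---------------------------------------------------------------------------
# Per-SNP association
# ---------------------------------------------------------------------------

#' Per-SNP logistic association
#'
#' Logistic regression of case status on dosage plus covariates (age, sex,
#' population PCs or synthetic equivalents), one fit per SNP; Wald p-value
#' on the dosage coefficient. Missing dosages are mean-imputed; SNPs with a
#' missing rate of 10% or more, monomorphic SNPs, and fits showing complete
#' separation are flagged and carry no usable p.
#'
#' @param data \code{gwas_dataset}
#' @param use_covariates include the covariate matrix in the model
#' @return data.frame: snp, chr, pos, n, beta, se, p, flag ("" when clean)
#' @export
snp_logistic_assoc <- function(data, use_covariates = TRUE) {
  dos <- data$dosage
  y <- data$phenotype
  covars <- if (use_covariates) data$covariates else NULL
  n <- ncol(dos)
  out <- data.frame(snp = data$snp_info$snp, chr = data$snp_info$chr,
                    pos = data$snp_info$pos, n = n,
                    beta = NA_real_, se = NA_real_, p = NA_real_,
                    flag = "", stringsAsFactors = FALSE)
  base_X <- cbind(`(Intercept)` = 1, covars)
  for (i in seq_len(nrow(dos))) {
    g <- dos[i, ]
    miss <- is.na(g)
    if (any(miss)) {
      if (mean(miss) >= 0.10) { out$flag[i] <- "high_missing"; next }
      g[miss] <- mean(g, na.rm = TRUE)
      out$flag[i] <- "imputed"
    }
    if (length(unique(g)) < 2) { out$flag[i] <- "monomorphic"; next }
    X <- cbind(base_X[, 1, drop = FALSE], dosage = g,
               base_X[, -1, drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { out$flag[i] <- "nonconverged"
      out$p[i] <- 1; next }
    mu <- fit$fitted.values
    if (any(mu < 1e-8) || any(mu > 1 - 1e-8)) {
      # quasi-complete separation: Wald statistics are meaningless
      out$flag[i] <- "separation"; out$p[i] <- 1; next
    }
    W <- mu * (1 - mu)
    XtWX <- crossprod(X * sqrt(W))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov)) { out$flag[i] <- "singular"; out$p[i] <- 1; next }
    b <- fit$coefficients["dosage"]
    se <- sqrt(cov["dosage", "dosage"])
    out$beta[i] <- b
    out$se[i] <- se
    out$p[i] <- 2 * pnorm(abs(b / se), lower.tail = FALSE)
  }
  out$p <- pmin(pmax(out$p, .Machine$double.xmin), 1)
  out$p[out$flag %in% c("monomorphic", "high_missing")] <- NA_real_
  out
}

# ---------------------------------------------------------------------------
# SNP -> gene assignment
# ---------------------------------------------------------------------------

#' Map SNPs to genes by position
#'
#' A SNP is assigned to every gene whose window
#' \code{[start - window_bp, end + window_bp)} contains its position
#' (half-open: the left edge is inclusive, the right edge exclusive).
#' Multi-assignment is allowed. SNPs on chromosomes absent from the gene
#' models stay unassigned and are counted.
#'
#' @param snps data.frame with columns snp, chr, pos
#' @param genes gene model data.frame (gene, chr, start, end; 0-based
#'   half-open, see \code{read_gene_models})
#' @param window_bp symmetric window in bp
#' @return named list, gene -> character vector of SNP ids; attribute
#'   \code{n_unassigned} counts SNPs assigned to no gene
#' @export
map_snps_to_genes <- function(snps, genes, window_bp = 0L) {
  idx <- setNames(vector("list", nrow(genes)), genes$gene)
  assigned <- logical(nrow(snps))
  for (j in seq_len(nrow(genes))) {
    lo <- genes$start[j] - window_bp
    hi <- genes$end[j] + window_bp
    hit <- snps$chr == genes$chr[j] & snps$pos >= lo & snps$pos < hi
    idx[[j]] <- snps$snp[hit]
    assigned <- assigned | hit
  }
  idx <- idx[lengths(idx) > 0]
  attr(idx, "n_unassigned") <- sum(!assigned)
  idx
}

# ---------------------------------------------------------------------------
# LD
# ---------------------------------------------------------------------------

#' Dosage LD matrix per gene
#'
#' Pearson correlation of the dosage vectors of a gene's SNPs, followed by a
#' positive-semidefinite repair: eigenvalues clipped at zero and the matrix
#' rescaled to unit diagonal.
#'
#' @param data \code{gwas_dataset}
#' @param snp_ids SNP ids of one gene
#' @return correlation matrix with attribute \code{repaired} (logical)
#' @export
ld_from_genotypes <- function(data, snp_ids) {
  if (!length(snp_ids)) stop("gene has no SNPs")
  rows <- match(snp_ids, rownames(data$dosage))
  if (anyNA(rows)) stop("unknown SNP id(s)")
  D <- data$dosage[rows, , drop = FALSE]
  if (nrow(D) == 1) {
    S <- matrix(1, 1, 1, dimnames = list(snp_ids, snp_ids))
    attr(S, "repaired") <- FALSE
    return(S)
  }
  # mean-impute missing per SNP before correlating
  D <- t(apply(D, 1, function(g) { g[is.na(g)] <- mean(g, na.rm = TRUE); g }))
  sds <- apply(D, 1, sd)
  S <- matrix(0, nrow(D), nrow(D), dimnames = list(snp_ids, snp_ids))
  ok <- sds > 0
  if (any(ok)) S[ok, ok] <- cor(t(D[ok, , drop = FALSE]))
  diag(S) <- 1
  repaired <- FALSE
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    S2 <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(pmax(diag(S2), .Machine$double.eps))
    S <- S2 / tcrossprod(d)
    diag(S) <- 1
    dimnames(S) <- list(snp_ids, snp_ids)
    repaired <- TRUE
  }
  attr(S, "repaired") <- repaired
  S
}

# ---------------------------------------------------------------------------
# Gene-based Monte-Carlo test (VEGAS-style)
# ---------------------------------------------------------------------------

#' LD-aware gene-based association test
#'
#' Sums per-SNP 1-df chi-square statistics, T = sum_j qnorm(p_j/2)^2, and
#' compares against Monte-Carlo draws v ~ MVN(0, Sigma) under the gene's LD
#' structure: empirical p = (1 + #\{sum v^2 >= T\}) / (1 + S). The
#' simulation count escalates adaptively: start at \code{sims[1]}, rerun at
#' \code{sims[2]} when p < 0.1, at \code{sims[3]} when p < 0.01.
#'
#' @param snp_pvalues per-SNP p-values of one gene, all in (0, 1]
#' @param ld SNP x SNP correlation matrix (PSD; see
#'   \code{ld_from_genotypes})
#' @param sims escalation schedule of simulation counts
#' @param seed RNG seed, recorded in the result
#' @return list(p, T_obs, n_snps, sims_used, seed)
#' @export
vegas_gene_test <- function(snp_pvalues, ld,
                            sims = c(1e3, 1e4, 1e5), seed = 1L) {
  p <- snp_pvalues[is.finite(snp_pvalues)]
  if (!length(p)) stop("no usable SNP p-values")
  if (any(p <= 0 | p > 1)) stop("SNP p-values must lie in (0, 1]")
  m <- length(p)
  if (!is.matrix(ld) || nrow(ld) != m)
    stop("LD matrix dimension does not match SNP count")
  T_obs <- sum(qnorm(p / 2)^2)
  ev <- eigen(ld, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("LD matrix not positive semidefinite")
  R <- tryCatch(chol(ld), error = function(e)
    chol(ld + diag(1e-10, m)))
  emp <- NA_real_
  S_used <- NA_real_
  for (k in seq_along(sims)) {
    S <- as.integer(sims[k])
    set.seed(seed + k - 1L)
    exceed <- 0L
    # draw in blocks to bound memory at large S
    block <- 20000L
    done <- 0L
    while (done < S) {
      nb <- min(block, S - done)
      z <- matrix(rnorm(nb * m), nb, m)
      v <- z %*% R
      exceed <- exceed + sum(rowSums(v * v) >= T_obs)
      done <- done + nb
    }
    emp <- (1 + exceed) / (1 + S)
    S_used <- S
    thr <- c(0.1, 0.01, rep(0, max(0, length(sims) - 3)))
    if (k < length(sims) && emp >= thr[k]) break
  }
  list(p = emp, T_obs = T_obs, n_snps = m, sims_used = S_used, seed = seed)
}

#' Gene score table from per-SNP associations
#'
#' Runs the gene-based Monte-Carlo test for every gene with at least one
#' mapped, testable SNP and returns the per-gene evidence table.
#'
#' @param assoc per-SNP association table from \code{snp_logistic_assoc}
#' @param gene_index gene -> SNP ids mapping from \code{map_snps_to_genes}
#' @param data \code{gwas_dataset} (for LD)
#' @param sims escalation schedule passed to \code{vegas_gene_test}
#' @param seed master seed; per-gene seeds are derived deterministically
#' @return data.frame of class \code{gene_score_table}: gene, n_snps, T,
#'   p_empirical, sims_used
#' @export
vegas_scores <- function(assoc, gene_index, data,
                         sims = c(1e3, 1e4, 1e5), seed = 1L) {
  genes <- names(gene_index)
  rows <- vector("list", length(genes))
  usable <- setNames(assoc$p, assoc$snp)
  for (gi in seq_along(genes)) {
    ids <- gene_index[[gi]]
    ids <- ids[is.finite(usable[ids])]
    if (!length(ids)) next
    ld <- ld_from_genotypes(data, ids)
    res <- vegas_gene_test(usable[ids], ld, sims = sims,
                           seed = (seed + gi) %% .Machine$integer.max)
    rows[[gi]] <- data.frame(gene = genes[gi], n_snps = res$n_snps,
                             T = res$T_obs, p_empirical = res$p,
                             sims_used = res$sims_used,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  class(out) <- c("gene_score_table", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Network boosting (GWAB-style)
# ---------------------------------------------------------------------------

#' Network boosting of gene association scores
#'
#' Re-ranks GWAS genes by lifting genes whose network neighbors carry strong
#' association evidence: with s_i = -log10(gene p) (0 for genes without a
#' GWAS score),
#' \deqn{B_i = s_i + \lambda \frac{\sum_{j \in N_c(i)} w_{ij} s_j}
#'   {\sum_{j \in N_c(i)} w_{ij}}}
#' where N_c(i) is the up-to-\code{neighbor_cap} strongest-weight neighbors
#' of i (weight ties broken by symbol). Isolated genes keep B = s.
#'
#' @param scores named numeric vector of gene scores s (e.g.
#'   -log10 p_empirical); genes in the network but absent here enter with 0
#' @param interactome \code{interactome}
#' @param lambda boost weight
#' @param neighbor_cap maximum neighbors contributing to the boost
#' @return data.frame: gene, s, boost, B, rank (descending B, ties by s then
#'   symbol)
#' @export
gwab_boost <- function(scores, interactome, lambda = 1.0, neighbor_cap = 50L) {
  g <- interactome$graph
  if (igraph::ecount(g) == 0 && igraph::vcount(g) == 0) {
    warning("empty network: boost is the identity")
    out <- data.frame(gene = names(scores), s = as.numeric(scores),
                      boost = 0, B = as.numeric(scores),
                      stringsAsFactors = FALSE)
  } else {
    universe <- union(igraph::V(g)$name, names(scores))
    s <- setNames(rep(0, length(universe)), universe)
    s[names(scores)] <- scores
    if (any(!is.finite(s))) stop("scores must be finite")
    boost <- setNames(rep(0, length(universe)), universe)
    in_net <- universe[universe %in% igraph::V(g)$name]
    inc <- igraph::incident_edges(g, in_net)
    for (ii in seq_along(in_net)) {
      es <- inc[[ii]]
      if (!length(es)) next
      ends <- igraph::ends(g, es, names = TRUE)
      nb <- ifelse(ends[, 1] == in_net[ii], ends[, 2], ends[, 1])
      w <- es$weight
      ord <- order(-w, nb)
      if (length(ord) > neighbor_cap) ord <- ord[seq_len(neighbor_cap)]
      boost[in_net[ii]] <- lambda * sum(w[ord] * s[nb[ord]]) / sum(w[ord])
    }
    out <- data.frame(gene = universe, s = as.numeric(s),
                      boost = as.numeric(boost),
                      B = as.numeric(s + boost), stringsAsFactors = FALSE)
  }
  out <- out[order(-out$B, -out$s, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Top-fraction prioritized gene list
#'
#' Selects ceil(fraction x n) genes by descending score; score ties at the
#' cut are broken by symbol so the list size is deterministic.
#'
#' @param scores named numeric vector
#' @param fraction fraction of the scored universe, in (0, 1)
#' @return list(genes, n_selected, n_universe, fraction)
#' @export
select_top_fraction <- function(scores, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  n <- length(scores)
  k <- as.integer(ceiling(fraction * n))
  ord <- order(-scores, names(scores))
  list(genes = names(scores)[ord][seq_len(k)], n_selected = k,
       n_universe = n, fraction = fraction)
}
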