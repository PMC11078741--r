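#' @importFrom stats quantile complete.cases p.adjust pt sd var cor
NULL

# ---------------------------------------------------------------------------
# Normalization
# ---------------------------------------------------------------------------

#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization (reference sample =
#' the one whose 75th-percentile count fraction is closest to the mean of
#' those fractions; M-values trimmed at 30%, A-values at 5%; precision
#' weighting). Factors are rescaled to geometric mean 1, and the effective
#' library size is library size times factor.
#'
#' @param experiment \code{counts_experiment}
#' @param trim_M two-sided trim fraction on M-values
#' @param trim_A two-sided trim fraction on A-values
#' @return data.frame of class \code{normalization_factors} with columns
#'   sample, lib_size, tmm_factor, effective_lib_size
#' @export
tmm_factors <- function(experiment, trim_M = 0.30, trim_A = 0.05) {
  counts <- experiment$counts
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  out <- data.frame(sample = colnames(counts),
                    lib_size = as.numeric(lib),
                    tmm_factor = as.numeric(f),
                    effective_lib_size = as.numeric(lib * f),
                    stringsAsFactors = FALSE)
  class(out) <- c("normalization_factors", "data.frame")
  out
}

#' Counts per million
#'
#' CPM[g,s] = counts[g,s] / effective library size[s] * 1e6, where the
#' effective library size is the raw library size times the TMM factor.
#'
#' @param experiment \code{counts_experiment}
#' @param factors \code{normalization_factors} aligned to the samples; if
#'   NULL, factors of 1 are used (library-size-only CPM)
#' @return gene x sample numeric matrix
#' @export
compute_cpm <- function(experiment, factors = NULL) {
  counts <- experiment$counts
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  if (is.null(factors)) {
    eff <- lib
  } else {
    idx <- match(colnames(counts), factors$sample)
    if (anyNA(idx)) stop("factors not aligned to samples")
    eff <- factors$effective_lib_size[idx]
  }
  sweep(counts, 2, eff, "/") * 1e6
}

#' Low-expression filter
#'
#' A gene is retained iff CPM strictly exceeds \code{threshold} in at least
#' \code{min_samples} samples (quorum rule).
#'
#' @param cpm gene x sample CPM matrix
#' @param threshold CPM threshold (strict >)
#' @param min_samples quorum; defaults to the smallest design-cell size when
#'   a design is supplied, else 1
#' @param design optional design data.frame used to derive the default quorum
#' @return character vector of retained gene symbols
#' @export
filter_low_expression <- function(cpm, threshold = 1.0, min_samples = NULL,
                                  design = NULL) {
  if (is.null(min_samples)) {
    min_samples <- if (!is.null(design))
      min(table(design$group, design$treatment)[table(design$group, design$treatment) > 0])
    else 1L
  }
  if (min_samples > ncol(cpm)) stop("min_samples exceeds sample count")
  keep <- rowSums(cpm > threshold) >= min_samples
  rownames(cpm)[keep]
}

# ---------------------------------------------------------------------------
# Differential expression
# ---------------------------------------------------------------------------

#' Negative-binomial differential-expression fit
#'
#' Fits a per-gene negative-binomial log-linear model with offset
#' log(effective library size) and tests a contrast by likelihood-ratio test.
#' Genewise dispersions are estimated and shrunk toward the common value
#' with fixed weight \code{shrink_weight} (an empirical-Bayes style
#' stabilizer for small n). Two contrast forms are supported:
#'
#' \itemize{
#'   \item \code{cell_a} vs \code{cell_b}: two design cells, each named
#'     "GROUP.TREATMENT" (e.g. "LR.Li-" vs "NR.Li-"); only samples in those
#'     cells enter the fit. Within-group treatment comparisons (same group,
#'     both treatments) add fixed subject effects for the paired design.
#'   \item \code{interaction = TRUE}: all samples of the named groups enter
#'     and the group x treatment interaction term is tested.
#' }
#'
#' @param experiment \code{counts_experiment}
#' @param genes genes to fit (rows of the count matrix), typically the
#'   CPM-retained set
#' @param cell_a,cell_b design cells "GROUP.TREATMENT" for a two-cell
#'   contrast
#' @param interaction if TRUE, test the group x treatment interaction instead
#' @param groups groups entering the interaction test (default all)
#' @param tissue_covariate adjust for tissue of origin when it varies
#' @param factors optional precomputed \code{normalization_factors}
#' @param shrink_weight weight on the common dispersion when shrinking the
#'   genewise estimates
#' @return data.frame of class \code{de_result}: gene, mean CPM per arm,
#'   log2fc, p, plus the comparison label as attribute
#' @export
fit_de_model <- function(experiment, genes = NULL,
                         cell_a = NULL, cell_b = NULL,
                         interaction = FALSE, groups = NULL,
                         tissue_covariate = TRUE,
                         factors = NULL, shrink_weight = 0.8) {
  des <- experiment$design
  des$cell <- paste(des$group, des$treatment, sep = ".")
  if (is.null(factors)) factors <- tmm_factors(experiment)

  if (interaction) {
    if (is.null(groups)) groups <- unique(des$group)
    sel <- des$group %in% groups
    comparison <- paste0("interaction(", paste(groups, collapse = ","), ")")
  } else {
    if (is.null(cell_a) || is.null(cell_b))
      stop("supply cell_a and cell_b, or interaction = TRUE")
    sel <- des$cell %in% c(cell_a, cell_b)
    if (sum(des$cell == cell_a) < 2 || sum(des$cell == cell_b) < 2)
      stop("each design cell in the contrast needs >= 2 samples")
    comparison <- paste(cell_a, "vs", cell_b)
  }
  counts <- experiment$counts[, sel, drop = FALSE]
  sdes <- des[sel, , drop = FALSE]
  if (is.null(genes)) genes <- rownames(counts)
  counts <- counts[genes, , drop = FALSE]
  nz <- rowSums(counts) > 0
  counts <- counts[nz, , drop = FALSE]

  fi <- match(colnames(counts), factors$sample)
  eff_lib <- factors$effective_lib_size[fi]

  # design matrix
  if (interaction) {
    grp <- factor(sdes$group)
    trt <- factor(sdes$treatment)
    mm <- stats::model.matrix(~ grp * trt)
    test_coefs <- grep(":", colnames(mm))
  } else {
    cellf <- factor(sdes$cell, levels = c(cell_b, cell_a))
    paired <- {
      parts_a <- strsplit(cell_a, ".", fixed = TRUE)[[1]]
      parts_b <- strsplit(cell_b, ".", fixed = TRUE)[[1]]
      identical(parts_a[1], parts_b[1])
    }
    if (paired && length(unique(sdes$subject)) > 1 &&
        length(unique(sdes$subject)) < nrow(sdes)) {
      subj <- factor(sdes$subject)
      mm <- stats::model.matrix(~ subj + cellf)
    } else {
      mm <- stats::model.matrix(~ cellf)
    }
    test_coefs <- grep("cellf", colnames(mm))
  }
  if (tissue_covariate && length(unique(sdes$tissue)) > 1) {
    tis <- factor(sdes$tissue)
    tcol <- stats::model.matrix(~ tis)[, -1, drop = FALSE]
    # drop tissue columns confounded with existing design columns
    if (qr(cbind(mm, tcol))$rank > qr(mm)$rank) mm <- cbind(mm, tcol)
  }

  # rescale the subset's factors to geometric mean 1 (a constant rescaling
  # of all offsets; shifts only the intercept)
  nf <- factors$tmm_factor[fi]
  nf <- nf / exp(mean(log(nf)))
  dge <- edgeR::DGEList(counts = counts,
                        lib.size = factors$lib_size[fi],
                        norm.factors = nf)
  dge <- edgeR::estimateGLMCommonDisp(dge, design = mm)
  dge <- edgeR::estimateGLMTagwiseDisp(dge, design = mm)
  disp <- shrink_weight * dge$common.dispersion +
    (1 - shrink_weight) * dge$tagwise.dispersion
  fit <- edgeR::glmFit(dge, design = mm, dispersion = disp)
  lrt <- edgeR::glmLRT(fit, coef = test_coefs)
  tab <- lrt$table

  cpm <- sweep(counts, 2, eff_lib, "/") * 1e6
  if (interaction) {
    mean_a <- rowMeans(cpm)
    mean_b <- rowMeans(cpm)
    lfc <- if (length(test_coefs) == 1)
      fit$coefficients[, test_coefs] / log(2)
    else apply(fit$coefficients[, test_coefs, drop = FALSE] / log(2), 1,
               function(v) v[which.max(abs(v))])
  } else {
    in_a <- sdes$cell == cell_a
    mean_a <- rowMeans(cpm[, in_a, drop = FALSE])
    mean_b <- rowMeans(cpm[, !in_a, drop = FALSE])
    lfc <- fit$coefficients[, test_coefs[length(test_coefs)]] / log(2)
  }

  conv <- if (!is.null(fit$failed)) !fit$failed else rep(TRUE, nrow(counts))
  p <- tab$PValue
  p[!conv] <- 1
  out <- data.frame(gene = rownames(counts),
                    mean_cpm_a = as.numeric(mean_a),
                    mean_cpm_b = as.numeric(mean_b),
                    log2fc = as.numeric(lfc),
                    p = as.numeric(p),
                    converged = conv,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "comparison") <- comparison
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment. Non-finite p-values are excluded from the ranking
#' and propagated as NA.
#'
#' @param pvalues numeric vector of p-values in [0,1]
#' @return q-values, same length and order
#' @export
bh_adjust <- function(pvalues) {
  q <- rep(NA_real_, length(pvalues))
  ok <- is.finite(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Serial DE filter
#'
#' Applies the serial filtering rule: a gene is differentially expressed iff
#' p < \code{p_max} AND |log2FC| >= \code{lfc_min} AND B-H q <= \code{q_max}.
#' By default the q-values are computed over the genes surviving the earlier
#' p and fold-change gates (serial semantics); set
#' \code{genomewide_q = TRUE} for adjustment over all tested genes.
#'
#' @param de \code{de_result} from \code{fit_de_model}
#' @param p_max raw p-value gate (strict <)
#' @param lfc_min absolute log2 fold-change gate (>=)
#' @param q_max B-H q-value gate (<=)
#' @param genomewide_q compute q over all tested genes instead of survivors
#' @return list with \code{de_genes} (ordered by q, p, symbol) and
#'   \code{table} (per-gene q and pass flags); the q denominator used is
#'   recorded in attribute \code{q_universe}
#' @export
serial_filter <- function(de, p_max = 0.05, lfc_min = 1.0, q_max = 0.20,
                          genomewide_q = FALSE) {
  tab <- as.data.frame(de)
  tab$pass_p <- tab$p < p_max
  tab$pass_lfc <- tab$pass_p & abs(tab$log2fc) >= lfc_min
  tab$q <- NA_real_
  if (genomewide_q) {
    tab$q <- bh_adjust(tab$p)
  } else {
    surv <- which(tab$pass_lfc)
    if (length(surv)) tab$q[surv] <- bh_adjust(tab$p[surv])
  }
  tab$pass_q <- tab$pass_lfc & !is.na(tab$q) & tab$q <= q_max
  tab$direction <- ifelse(tab$log2fc >= 0, "up", "down")
  hits <- tab[tab$pass_q, , drop = FALSE]
  hits <- hits[order(hits$q, hits$p, hits$gene), , drop = FALSE]
  structure(list(de_genes = hits$gene, table = tab),
            comparison = attr(de, "comparison"),
            q_universe = if (genomewide_q) "all_tested" else "gate_survivors")
}

#' Venn comparison of DE gene lists
#'
#' Computes the counts of every region of the Venn partition of two or more
#' named gene lists, the identities of the fully shared genes, and pairwise
#' overlap percentages (of each pairwise union, to 2 decimals).
#'
#' @param lists named list of >= 2 character vectors
#' @return list with \code{regions} (data.frame: region, count, genes),
#'   \code{shared} (genes common to all lists), \code{union_size}, and
#'   \code{pairwise} (data.frame: list_a, list_b, shared, union,
#'   pct_of_union)
#' @export
compare_de_lists <- function(lists) {
  if (length(lists) < 2 || is.null(names(lists)))
    stop("need >= 2 named lists")
  lists <- lapply(lists, unique)
  univ <- sort(unique(unlist(lists)))
  memb <- vapply(lists, function(l) univ %in% l, logical(length(univ)))
  if (length(univ) == 1) memb <- matrix(memb, nrow = 1,
                                        dimnames = list(NULL, names(lists)))
  pat <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  regions <- data.frame(region = sort(unique(pat)), stringsAsFactors = FALSE)
  regions$count <- vapply(regions$region, function(rg) sum(pat == rg), 0L)
  regions$genes <- vapply(regions$region, function(rg)
    paste(univ[pat == rg], collapse = ","), "")
  shared <- univ[rowSums(memb) == length(lists)]
  nm <- names(lists)
  pairs <- utils::combn(nm, 2)
  pairwise <- data.frame(
    list_a = pairs[1, ], list_b = pairs[2, ],
    shared = apply(pairs, 2, function(p)
      length(intersect(lists[[p[1]]], lists[[p[2]]]))),
    union = apply(pairs, 2, function(p)
      length(union(lists[[p[1]]], lists[[p[2]]]))),
    stringsAsFactors = FALSE)
  pairwise$pct_of_union <- round(100 * pairwise$shared /
                                   pmax(pairwise$union, 1), 2)
  list(regions = regions, shared = shared, union_size = length(univ),
       pairwise = pairwise)
}

# ---------------------------------------------------------------------------
# qPCR validation utilities
# ---------------------------------------------------------------------------

#' Relative quantification by the 2^-ddCt method
#'
#' dCt = Ct(target) - Ct(reference) per replicate and arm; ddCt = mean
#' dCt(condition) - mean dCt(baseline); fold change = 2^-ddCt. The SEM of
#' the fold change is propagated from the replicate dCt variances by the
#' delta method: SEM(FC) = ln(2) * FC * sqrt(var_c/n_c + var_b/n_b).
#'
#' @param ct_target_cond,ct_ref_cond replicate Ct values for target and
#'   reference gene in the condition arm
#' @param ct_target_base,ct_ref_base replicate Ct values in the baseline arm
#' @return list(fold_change, sem, ddct)
#' @export
ddct_fold_change <- function(ct_target_cond, ct_ref_cond,
                             ct_target_base, ct_ref_base) {
  if (!length(ct_ref_cond) || !length(ct_ref_base))
    stop("missing reference gene Ct values")
  if (length(ct_target_cond) != length(ct_ref_cond) ||
      length(ct_target_base) != length(ct_ref_base))
    stop("target and reference replicates must be paired")
  dct_c <- ct_target_cond - ct_ref_cond
  dct_b <- ct_target_base - ct_ref_base
  ddct <- mean(dct_c) - mean(dct_b)
  fc <- 2^(-ddct)
  n_c <- length(dct_c); n_b <- length(dct_b)
  v <- (if (n_c > 1) var(dct_c) / n_c else 0) +
    (if (n_b > 1) var(dct_b) / n_b else 0)
  sem <- log(2) * fc * sqrt(v)
  list(fold_change = fc, sem = sem, ddct = ddct)
}

#' Concordance of two log2FC vectors
#'
#' Squared Pearson correlation with a two-sided p-value from the t statistic
#' on n-2 degrees of freedom. Direction (sign of r) is reported separately;
#' R^2 itself is sign-blind.
#'
#' @param x,y paired log2 fold-change vectors, n >= 3
#' @return list(r2, p, direction, n); r2 is NA with \code{flag}
#'   "zero_variance" when either vector is constant
#' @export
log2fc_concordance <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need paired vectors of length >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r2 = NA_real_, p = NA_real_, direction = NA_character_,
                n = length(x), flag = "zero_variance"))
  r <- cor(x, y)
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  list(r2 = r^2, p = p,
       direction = if (r >= 0) "positive" else "negative", n = n)
}
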