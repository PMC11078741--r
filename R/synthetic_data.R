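#' @importFrom stats rbinom rlnorm rnbinom runif
NULL

# ---------------------------------------------------------------------------
# Interactome with a planted functional module
# ---------------------------------------------------------------------------

#' Simulate a functional interactome with one planted module
#'
#' Grows a scale-free backbone by preferential attachment and densifies one
#' gene module by adding intra-module edges with probability \code{p_in},
#' emulating a functional interaction network in which one biological
#' process forms a tightly connected neighborhood. All edge weights are 1.
#'
#' @param n_genes number of genes
#' @param m edges attached per new node (preferential attachment)
#' @param module_size size of the planted module
#' @param p_in probability of each extra intra-module edge
#' @param seed RNG seed
#' @return list(interactome, module = module gene symbols)
#' @export
simulate_interactome <- function(n_genes = 5000L, m = 5L,
                                 module_size = 150L, p_in = 0.10,
                                 seed = 1L) {
  if (module_size >= n_genes) stop("module must be smaller than the gene set")
  set.seed(seed)
  g <- igraph::sample_pa(n_genes, m = m, directed = FALSE)
  genes <- sprintf("G%05d", seq_len(n_genes))
  igraph::V(g)$name <- genes
  module <- sort(sample(genes, module_size))
  if (p_in > 0 && length(module) >= 2) {
    pairs <- utils::combn(module, 2)
    pick <- runif(ncol(pairs)) < p_in
    if (any(pick)) {
      g <- igraph::add_edges(g, as.vector(pairs[, pick, drop = FALSE]))
    }
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  ed <- igraph::as_data_frame(g, what = "edges")
  net <- interactome(data.frame(source = ed$from, target = ed$to,
                                weight = 1.0, stringsAsFactors = FALSE))
  list(interactome = net, module = module)
}

# ---------------------------------------------------------------------------
# RNA-seq counts
# ---------------------------------------------------------------------------

#' Simulate an RNA-seq counts experiment with planted DE genes
#'
#' Emulates the design of a three-group iPSC-neuron study: CT / LR / NR
#' subjects, each assayed untreated (Li-) and treated (Li+), negative-
#' binomial counts over lognormal baseline means, lognormal library-size
#' variation, and a shared per-subject expression profile so paired samples
#' of a subject correlate more than samples of different subjects. The
#' planted differential expression acts on the LR vs NR contrast with the
#' same direction under both treatments; a subset of the planted genes sits
#' inside the network module so the expression channel points at it. An
#' optional tissue-of-origin covariate shifts a small fraction of genes for
#' the lymphoblast-derived subjects.
#'
#' @param genes expressed gene universe (symbols)
#' @param module planted network module genes (subset of \code{genes})
#' @param n_ct,n_lr,n_nr subjects per group
#' @param n_de planted DE genes
#' @param n_de_module how many of those lie inside the module
#' @param log2fc planted effect size (half up-, half down-regulated);
#'   0 gives a global-null experiment
#' @param dispersion NB dispersion phi (var = mu + phi mu^2)
#' @param subject_sd sd of the per-subject lognormal expression profile
#'   (log scale)
#' @param lib_sd sd of the lognormal library-size factors (log scale)
#' @param tissue_frac fraction of genes shifted by tissue of origin
#' @param tissue_lfc log2 shift applied to those genes in lymphoblast
#'   subjects
#' @param seed RNG seed
#' @return list(experiment = \code{counts_experiment}, truth = list with
#'   de_genes, log2fc (named, signed), module overlap, parameters)
#' @export
simulate_counts <- function(genes, module = character(),
                            n_ct = 6L, n_lr = 6L, n_nr = 5L,
                            n_de = 40L, n_de_module = 30L, log2fc = 2,
                            dispersion = 0.1, subject_sd = 0.15,
                            lib_sd = 0.2, tissue_frac = 0.05,
                            tissue_lfc = 0.5, seed = 1L) {
  set.seed(seed)
  n_genes <- length(genes)
  module <- intersect(module, genes)
  n_de_module <- min(n_de_module, n_de, length(module))
  de_in <- if (n_de_module > 0) sample(module, n_de_module) else character()
  de_out <- if (n_de - n_de_module > 0)
    sample(setdiff(genes, module), n_de - n_de_module) else character()
  de_genes <- c(de_in, de_out)
  signs <- rep(c(1, -1), length.out = length(de_genes))
  true_lfc <- setNames(rep(0, n_genes), genes)
  if (length(de_genes)) true_lfc[de_genes] <- signs * log2fc

  subjects <- c(sprintf("CT%02d", seq_len(n_ct)),
                sprintf("LR%02d", seq_len(n_lr)),
                sprintf("NR%02d", seq_len(n_nr)))
  group <- c(rep("CT", n_ct), rep("LR", n_lr), rep("NR", n_nr))
  tissue <- rep(c("fibroblast", "lymphoblast"), length.out = length(subjects))
  design <- data.frame(
    sample = paste0(rep(subjects, each = 2), c(".Li-", ".Li+")),
    group = rep(group, each = 2),
    treatment = rep(c("Li-", "Li+"), times = length(subjects)),
    tissue = rep(tissue, each = 2),
    subject = rep(subjects, each = 2),
    clone = paste0(rep(subjects, each = 2), "c1"),
    stringsAsFactors = FALSE)

  base_mu <- rlnorm(n_genes, meanlog = 4, sdlog = 1.3)
  names(base_mu) <- genes
  subj_eff <- matrix(rlnorm(n_genes * length(subjects), 0, subject_sd),
                     n_genes, length(subjects),
                     dimnames = list(genes, subjects))
  lib_fac <- rlnorm(nrow(design), 0, lib_sd)
  tis_genes <- if (tissue_frac > 0)
    sample(genes, round(tissue_frac * n_genes)) else character()

  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(genes, design$sample))
  for (s in seq_len(nrow(design))) {
    mu <- base_mu * subj_eff[, design$subject[s]] * lib_fac[s]
    if (design$group[s] == "LR") mu <- mu * 2^(true_lfc / 2)
    if (design$group[s] == "NR") mu <- mu * 2^(-true_lfc / 2)
    if (design$tissue[s] == "lymphoblast" && length(tis_genes))
      mu[tis_genes] <- mu[tis_genes] * 2^tissue_lfc
    counts[, s] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }
  experiment <- counts_experiment(counts, design)
  truth <- list(de_genes = sort(de_genes),
                log2fc = true_lfc[true_lfc != 0],
                de_in_module = sort(de_in),
                params = list(n_ct = n_ct, n_lr = n_lr, n_nr = n_nr,
                              n_de = n_de, n_de_module = n_de_module,
                              log2fc = log2fc, dispersion = dispersion,
                              subject_sd = subject_sd, lib_sd = lib_sd,
                              tissue_frac = tissue_frac,
                              tissue_lfc = tissue_lfc, seed = seed))
  list(experiment = experiment, truth = truth)
}

# ---------------------------------------------------------------------------
# Case/control GWAS
# ---------------------------------------------------------------------------

#' Simulate a case/control GWAS over a gene universe
#'
#' Lays the genes of the universe along a toy chromosome (10 kb bodies,
#' 10 kb gaps), places \code{snps_per_gene} SNPs evenly inside each body,
#' and draws dosages from latent per-haplotype AR(1) Gaussians thresholded
#' at the allele frequency, giving an LD block per gene. The binary
#' phenotype follows a logistic model over centered causal-SNP dosages
#' (two causal SNPs per causal gene), with the intercept at 0 so prevalence
#' sits near 50%. Covariates (age, sex, three PCs) are generated with null
#' effects.
#'
#' @param genes gene universe (symbols)
#' @param module planted network module genes
#' @param n_subjects cohort size
#' @param snps_per_gene SNPs per gene body
#' @param maf_range allele-frequency range (uniform per SNP)
#' @param rho AR(1) correlation of the latent haplotype Gaussians
#' @param n_causal causal genes
#' @param n_causal_module how many of those lie inside the module
#' @param n_causal_snps causal SNPs per causal gene
#' @param beta per-SNP log-odds effect; 0 gives a null GWAS
#' @param seed RNG seed
#' @return list(gwas = \code{gwas_dataset}, gene_models, truth)
#' @export
simulate_gwas <- function(genes, module = character(),
                          n_subjects = 256L, snps_per_gene = 8L,
                          maf_range = c(0.05, 0.5), rho = 0.8,
                          n_causal = 60L, n_causal_module = 45L,
                          n_causal_snps = 2L, beta = 0.4, seed = 1L) {
  set.seed(seed)
  n_genes <- length(genes)
  module <- intersect(module, genes)
  n_causal <- min(n_causal, length(genes))
  n_causal_module <- min(n_causal_module, n_causal, length(module))
  n_causal <- min(n_causal,
                  n_causal_module + length(setdiff(genes, module)))
  caus_in <- if (n_causal_module > 0) sample(module, n_causal_module)
  else character()
  caus_out <- if (n_causal - n_causal_module > 0)
    sample(setdiff(genes, module), n_causal - n_causal_module) else character()
  causal <- c(caus_in, caus_out)

  gene_models <- data.frame(
    gene = genes, chr = "1",
    start = (seq_len(n_genes) - 1L) * 20000L,
    end = (seq_len(n_genes) - 1L) * 20000L + 10000L,
    stringsAsFactors = FALSE)

  m <- snps_per_gene
  n_snps <- n_genes * m
  pos <- as.vector(vapply(seq_len(n_genes), function(i)
    gene_models$start[i] + round(seq(500, 9500, length.out = m)),
    numeric(m)))
  snp_info <- data.frame(
    snp = sprintf("rs%06d", seq_len(n_snps)), chr = "1", pos = pos,
    gene = rep(genes, each = m), stringsAsFactors = FALSE)
  maf <- runif(n_snps, maf_range[1], maf_range[2])

  # dosages: two haplotypes per subject, latent AR(1) within each gene block
  dosage <- matrix(0L, n_snps, n_subjects)
  ar1_block <- function(n, m, rho) {
    z <- matrix(rnorm(n * m), n, m)
    if (m > 1 && rho != 0)
      for (j in 2:m) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    z
  }
  for (i in seq_len(n_genes)) {
    rows <- ((i - 1) * m + 1):(i * m)
    thr <- qnorm(maf[rows])
    h1 <- ar1_block(n_subjects, m, rho)
    h2 <- ar1_block(n_subjects, m, rho)
    dosage[rows, ] <- t((sweep(h1, 2, thr, "<")) + (sweep(h2, 2, thr, "<")))
  }
  rownames(dosage) <- snp_info$snp
  colnames(dosage) <- sprintf("S%03d", seq_len(n_subjects))

  causal_snps <- unlist(lapply(causal, function(gn) {
    rows <- which(snp_info$gene == gn)
    snp_info$snp[rows[seq_len(min(n_causal_snps, length(rows)))]]
  }))
  eta <- rep(0, n_subjects)
  if (beta != 0 && length(causal_snps)) {
    ci <- match(causal_snps, snp_info$snp)
    centered <- dosage[ci, , drop = FALSE] - 2 * maf[ci]
    eta <- as.vector(beta * colSums(centered))
  }
  phenotype <- rbinom(n_subjects, 1, 1 / (1 + exp(-eta)))
  if (length(unique(phenotype)) < 2) phenotype[1:2] <- c(0L, 1L)

  covariates <- cbind(age = rnorm(n_subjects, 45, 10),
                      sex = rbinom(n_subjects, 1, 0.5),
                      PC1 = rnorm(n_subjects), PC2 = rnorm(n_subjects),
                      PC3 = rnorm(n_subjects))
  gwas <- gwas_dataset(dosage, snp_info[, c("snp", "chr", "pos")],
                       phenotype, covariates)
  truth <- list(causal_genes = sort(causal), causal_snps = causal_snps,
                causal_in_module = sort(caus_in),
                params = list(n_subjects = n_subjects,
                              snps_per_gene = snps_per_gene,
                              maf_range = maf_range, rho = rho,
                              n_causal = n_causal,
                              n_causal_module = n_causal_module,
                              n_causal_snps = n_causal_snps,
                              beta = beta, seed = seed))
  list(gwas = gwas, gene_models = gene_models, truth = truth)
}

# ---------------------------------------------------------------------------
# Gene sets
# ---------------------------------------------------------------------------

#' Simulate a gene-set collection with one planted term
#'
#' Decoy terms are uniform samples from the gene universe; one planted term
#' overlaps the module at a configured Jaccard index (term size fixed at
#' the module size, intersection chosen to hit the target Jaccard; 1 makes
#' the term equal the module).
#'
#' @param genes gene universe
#' @param module planted module
#' @param n_terms total terms including the planted one
#' @param size_range decoy term size bounds (uniform)
#' @param jaccard target Jaccard between the planted term and the module
#' @param seed RNG seed
#' @return list(collection = \code{gene_set_collection},
#'   truth = list(planted_term, jaccard))
#' @export
simulate_gmt <- function(genes, module, n_terms = 100L,
                         size_range = c(20L, 200L), jaccard = 1.0,
                         seed = 1L) {
  set.seed(seed)
  module <- intersect(module, genes)
  msz <- length(module)
  i <- round(2 * jaccard * msz / (1 + jaccard))
  planted <- c(if (i > 0) sample(module, i) else character(),
               sample(setdiff(genes, module), msz - i))
  sets <- list()
  ids <- sprintf("T%03d", seq_len(n_terms))
  planted_id <- ids[1]
  sets[[planted_id]] <- sort(planted)
  sizes <- sample(seq(size_range[1], size_range[2]), n_terms - 1,
                  replace = TRUE)
  for (k in seq_len(n_terms - 1)) {
    sets[[ids[k + 1]]] <- sort(sample(genes, sizes[k]))
  }
  desc <- setNames(c("planted module term",
                     rep("decoy term", n_terms - 1)), ids)
  coll <- gene_set_collection(sets, description = desc)
  list(collection = coll,
       truth = list(planted_term = planted_id, jaccard = jaccard))
}

# ---------------------------------------------------------------------------
# Full bundle + fixture files
# ---------------------------------------------------------------------------

#' Simulate a complete multi-omics bundle
#'
#' Generates the interactome, the counts experiment, the GWAS and the
#' gene-set collection with one shared planted module, mirroring a study in
#' which the expression and association channels converge on the same
#' functional neighborhood. The expression and GWAS gene universes are
#' subsets of the interactome universe (module included) so symbol joins
#' are exact. Presets: \code{"paperlike"} plants the default signal;
#' \code{"null"} sets log2fc = 0 and beta = 0 and removes the planted
#' coupling entirely (both universes become uniform draws from the
#' interactome rather than module-first), giving a matched no-signal
#' fixture in which the two channels are independent.
#'
#' @param seed master seed; stage seeds are derived deterministically
#' @param preset "paperlike" or "null"
#' @param n_interactome,module_size interactome scale
#' @param n_expressed expressed-gene universe size
#' @param n_gwas_genes GWAS gene universe size
#' @param ... overrides forwarded to \code{simulate_counts} /
#'   \code{simulate_gwas} (matched by name)
#' @return list with interactome, module, experiment, gwas, gene_models,
#'   collection, truth (per channel), seed, preset
#' @export
simulate_bundle <- function(seed = 1L, preset = c("paperlike", "null"),
                            n_interactome = 5000L, module_size = 150L,
                            n_expressed = 2000L, n_gwas_genes = 1000L,
                            ...) {
  preset <- match.arg(preset)
  dots <- list(...)
  net <- simulate_interactome(n_genes = n_interactome,
                              module_size = module_size, seed = seed)
  genes_all <- interactome_genes(net$interactome)
  set.seed(seed + 101L)
  if (preset == "null") {
    # no planted coupling at all: both universes are uniform draws, so the
    # dense module does not tie the channels together
    expr_genes <- sort(sample(genes_all, n_expressed))
    gwas_genes <- sort(sample(genes_all, n_gwas_genes))
  } else {
    expr_genes <- sort(union(net$module,
                             sample(setdiff(genes_all, net$module),
                                    n_expressed - length(net$module))))
    gwas_genes <- sort(union(net$module,
                             sample(setdiff(genes_all, net$module),
                                    n_gwas_genes - length(net$module))))
  }
  counts_args <- list(genes = expr_genes, module = net$module,
                      seed = seed + 202L)
  gwas_args <- list(genes = gwas_genes, module = net$module,
                    seed = seed + 303L)
  if (preset == "null") {
    counts_args$log2fc <- 0
    gwas_args$beta <- 0
  }
  cn <- intersect(names(dots), names(formals(simulate_counts)))
  counts_args[cn] <- dots[cn]
  gn <- intersect(names(dots), names(formals(simulate_gwas)))
  gwas_args[gn] <- dots[gn]
  cnt <- do.call(simulate_counts, counts_args)
  gw <- do.call(simulate_gwas, gwas_args)
  gmt <- simulate_gmt(genes_all, net$module, seed = seed + 404L)
  list(interactome = net$interactome, module = net$module,
       experiment = cnt$experiment, gwas = gw$gwas,
       gene_models = gw$gene_models, collection = gmt$collection,
       truth = list(counts = cnt$truth, gwas = gw$truth, gmt = gmt$truth,
                    module = net$module),
       seed = seed, preset = preset)
}

#' Write a simulated bundle to disk as plain-text fixtures
#'
#' Emits every file in the formats the readers consume (counts/design TSV,
#' edge-list TSV, dosage/phenotype/covariate TSVs, gene-model TSV, GMT) plus
#' a YAML manifest recording all generator parameters, seeds and the planted
#' truth.
#'
#' @param bundle output of \code{simulate_bundle}
#' @param out_dir target directory
#' @param force overwrite an existing directory
#' @return invisibly, the manifest path
#' @export
write_fixture <- function(bundle, out_dir, force = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory exists; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_counts(bundle$experiment, fp("counts.tsv"), fp("design.tsv"))
  write_edge_list(bundle$interactome, fp("edges.tsv"))
  dos <- data.frame(bundle$gwas$snp_info,
                    bundle$gwas$dosage, check.names = FALSE)
  write.table(dos, fp("dosage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(subject = colnames(bundle$gwas$dosage),
                         phenotype = bundle$gwas$phenotype),
              fp("phenotype.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(subject = colnames(bundle$gwas$dosage),
                         bundle$gwas$covariates, check.names = FALSE),
              fp("covariates.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(bundle$gene_models, fp("gene_models.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(bundle$collection, fp("sets.gmt"))
  manifest <- list(seed = bundle$seed, preset = bundle$preset,
                   truth = rapply(bundle$truth, unname, how = "replace"))
  yaml::write_yaml(manifest, fp("manifest.yaml"))
  invisible(fp("manifest.yaml"))
}

#' Read a fixture directory back into a bundle
#'
#' Inverse of \code{write_fixture} for the data files; the planted truth is
#' restored from the manifest.
#'
#' @param dir fixture directory
#' @return bundle list (same shape as \code{simulate_bundle})
#' @export
read_fixture <- function(dir) {
  fp <- function(f) file.path(dir, f)
  experiment <- read_counts(fp("counts.tsv"), fp("design.tsv"))
  net <- read_edge_list(fp("edges.tsv"))
  dos <- read.delim(fp("dosage.tsv"), check.names = FALSE,
                    stringsAsFactors = FALSE)
  snp_info <- dos[, c("snp", "chr", "pos")]
  dosage <- as.matrix(dos[, -(1:3), drop = FALSE])
  if ("gene" %in% names(dos)) dosage <- as.matrix(dos[, -(1:4), drop = FALSE])
  phen <- read.delim(fp("phenotype.tsv"))
  cov <- read.delim(fp("covariates.tsv"), check.names = FALSE)
  gwas <- gwas_dataset(dosage, snp_info, phen$phenotype,
                       as.matrix(cov[, -1, drop = FALSE]))
  gene_models <- read.delim(fp("gene_models.tsv"),
                            stringsAsFactors = FALSE)
  gene_models$chr <- as.character(gene_models$chr)
  collection <- read_gmt(fp("sets.gmt"))
  manifest <- yaml::read_yaml(fp("manifest.yaml"))
  list(interactome = net, module = manifest$truth$module,
       experiment = experiment, gwas = gwas, gene_models = gene_models,
       collection = collection, truth = manifest$truth,
       seed = manifest$seed, preset = manifest$preset)
}
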