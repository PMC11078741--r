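test_that("per-SNP logistic association is calibrated and flags degeneracy", {
  genes <- sprintf("G%03d", 1:125)  # 1000 null SNPs
  sim <- simulate_gwas(genes, n_subjects = 256, beta = 0, seed = 21)
  assoc <- snp_logistic_assoc(sim$gwas)
  p <- assoc$p[assoc$flag == ""]
  # uniformity: one-sample Kolmogorov distance against U(0,1)
  D <- max(abs(sort(p) - seq_along(p) / length(p)))
  expect_lt(D, 0.05)

  # planted beta = 0.5 recovery at n = 256, against the Fisher-information
  # oracle for the achievable precision: median |err| = qnorm(.75) * SE,
  # with a 1.3 allowance for sample-median noise and small-sample MLE bias
  set.seed(22)
  errs <- replicate(200, {
    g <- rbinom(256, 2, 0.3)
    y <- rbinom(256, 1, plogis(-0.3 + 0.5 * g))
    ds <- gwas_dataset(matrix(g, 1, dimnames = list("rs1", NULL)),
                       data.frame(snp = "rs1", chr = "1", pos = 100),
                       y, matrix(rnorm(256), ncol = 1,
                                 dimnames = list(NULL, "PC1")))
    abs(snp_logistic_assoc(ds)$beta - 0.5)
  })
  go <- rbinom(2e5, 2, 0.3)
  wo <- {mu <- plogis(-0.3 + 0.5 * go); mu * (1 - mu)}
  Xo <- cbind(1, go, rnorm(2e5))
  se_oracle <- sqrt(solve(crossprod(Xo * sqrt(wo)) / 2e5)[2, 2] / 256)
  expect_lt(median(errs), 1.3 * qnorm(0.75) * se_oracle)

  # monomorphic SNP flagged and excluded from gene tests
  ds2 <- gwas_dataset(matrix(c(rep(1, 256), rbinom(256, 2, 0.3)), 2,
                             byrow = TRUE,
                             dimnames = list(c("rsA", "rsB"), NULL)),
                      data.frame(snp = c("rsA", "rsB"), chr = "1",
                                 pos = c(1, 2)),
                      rep(c(0L, 1L), 128),
                      matrix(rnorm(256), ncol = 1))
  a2 <- snp_logistic_assoc(ds2)
  expect_equal(a2$flag[1], "monomorphic")
  expect_true(is.na(a2$p[1]))
})

test_that("SNP-gene mapping uses half-open windows and matches brute force", {
  gm <- data.frame(gene = c("GA", "GB"), chr = c("1", "1"),
                   start = c(100, 500), end = c(200, 700))
  snps <- data.frame(snp = c("s1", "s2", "s3", "s4"), chr = "1",
                     pos = c(100, 200, 650, 75))
  idx <- map_snps_to_genes(snps, gm)
  expect_true("s1" %in% idx$GA)        # position == start: inclusive
  expect_false("s2" %in% idx$GA)       # position == end: exclusive
  expect_equal(idx$GB, "s3")
  expect_equal(attr(idx, "n_unassigned"), 2)
  # a 25 bp window pulls s4 into GA
  idx2 <- map_snps_to_genes(snps, gm, window_bp = 25)
  expect_true("s4" %in% idx2$GA)

  # random assignment equals a brute-force interval scan
  set.seed(23)
  gm2 <- data.frame(gene = sprintf("g%02d", 1:50), chr = "1",
                    start = st <- sample(1e5, 50))
  gm2$end <- gm2$start + sample(500:5000, 50)
  snps2 <- data.frame(snp = sprintf("s%03d", 1:500), chr = "1",
                      pos = sample(1.1e5, 500))
  idx3 <- map_snps_to_genes(snps2, gm2)
  for (g in names(idx3)) {
    j <- match(g, gm2$gene)
    brute <- snps2$snp[snps2$pos >= gm2$start[j] & snps2$pos < gm2$end[j]]
    expect_setequal(idx3[[g]], brute)
  }
})

test_that("LD matrices are PSD correlation matrices with expected structure", {
  genes <- sprintf("G%03d", 1:10)
  sim <- simulate_gwas(genes, n_subjects = 500, beta = 0, rho = 0.8,
                       seed = 24)
  ids <- rownames(sim$gwas$dosage)[1:8]
  S <- ld_from_genotypes(sim$gwas, ids)
  expect_equal(diag(S), setNames(rep(1, 8), ids))
  expect_gte(min(eigen(S, symmetric = TRUE)$values), -1e-12)

  # duplicated SNP column: off-diagonal 1 stays valid after repair
  d2 <- rbind(sim$gwas$dosage[1, ], sim$gwas$dosage[1, ])
  rownames(d2) <- c("dupA", "dupB")
  ds <- gwas_dataset(d2, data.frame(snp = c("dupA", "dupB"), chr = "1",
                                    pos = c(1, 2)),
                     sim$gwas$phenotype, sim$gwas$covariates)
  S2 <- ld_from_genotypes(ds, c("dupA", "dupB"))
  expect_equal(S2[1, 2], 1)
  expect_gte(min(eigen(S2, symmetric = TRUE)$values), -1e-12)

  # independent SNPs: sampling-noise bound on the mean |off-diagonal|
  set.seed(25)
  n <- 500
  ind <- matrix(rbinom(8 * n, 2, 0.3), 8,
                dimnames = list(sprintf("i%d", 1:8), NULL))
  dsi <- gwas_dataset(ind, data.frame(snp = rownames(ind), chr = "1",
                                      pos = 1:8),
                      rep(c(0L, 1L), n / 2), matrix(rnorm(n), ncol = 1))
  Si <- ld_from_genotypes(dsi, rownames(ind))
  expect_lt(mean(abs(Si[upper.tri(Si)])), 3 / sqrt(n))

  # AR(1) block: adjacent correlations near the attenuated latent target
  adj <- S[cbind(1:7, 2:8)]
  # MC oracle: latent rho = 0.8 thresholded at independent allele freqs
  set.seed(26)
  oracle <- mean(replicate(300, {
    a <- rnorm(2000); b <- 0.8 * a + 0.6 * rnorm(2000)
    cor(a < qnorm(runif(1, 0.05, 0.5)), b < qnorm(runif(1, 0.05, 0.5)))
  }))
  expect_lt(abs(mean(adj) - oracle), 0.1)
})

test_that("gene-based Monte-Carlo test matches closed forms", {
  # single SNP: empirical p equals the SNP p within Monte-Carlo error
  r1 <- vegas_gene_test(0.05, matrix(1, 1, 1), sims = c(1e4), seed = 2)
  expect_lt(abs(r1$p - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))

  # perfectly correlated pair degenerates to the 1-SNP result
  r2 <- vegas_gene_test(c(0.05, 0.05), matrix(1, 2, 2), sims = c(1e4),
                        seed = 4)
  expect_lt(abs(r2$p - 0.05), 3 * sqrt(0.05 * 0.95 / 1e4))

  # bounds: never 0, never above 1; the +1 correction floors at 1/(S+1)
  r3 <- vegas_gene_test(1e-12, matrix(1, 1, 1), sims = c(1e3), seed = 5)
  expect_equal(r3$p, 1 / 1001)
  expect_error(vegas_gene_test(c(0.5, 0), diag(2)), "0, 1")
})

test_that("network boost follows its closed form and preserves isolates", {
  # edgeless graph: identity mapping, input ranking preserved
  lone <- interactome(data.frame(source = "X", target = "Y", weight = 1))
  sc <- c(A = 3, B = 2, C = 1)
  b0 <- suppressWarnings(
    gwab_boost(sc, structure(list(graph = igraph::make_empty_graph(0)),
                             class = "interactome")))
  expect_equal(setNames(b0$B, b0$gene)[names(sc)], sc)
  expect_equal(b0$gene[1:3], c("A", "B", "C"))

  # star: hub s=0, leaves s=3 -> hub B = lambda*3, leaves B = 3; at
  # lambda=1 the hub overtakes an isolated s=2 gene
  star <- interactome(data.frame(source = "H",
                                 target = c("L1", "L2", "L3"), weight = 1))
  ss <- c(H = 0, L1 = 3, L2 = 3, L3 = 3, ISO = 2)
  bs <- gwab_boost(ss, star, lambda = 1)
  bmap <- setNames(bs$B, bs$gene)
  expect_equal(bmap[["H"]], 3)
  expect_equal(bmap[["L1"]], 3)
  expect_lt(bmap[["ISO"]], bmap[["H"]])
  expect_equal(bmap[["ISO"]], 2)  # isolated node score preserved exactly

  # random graph: elementwise brute-force recomputation
  set.seed(27)
  ed <- data.frame(source = sprintf("n%02d", sample(15, 40, TRUE)),
                   target = sprintf("n%02d", sample(15, 40, TRUE)),
                   weight = round(runif(40, 0.2, 2), 2))
  ed <- ed[ed$source != ed$target, ]
  g <- interactome(ed)
  sc2 <- setNames(runif(15, 0, 4), sprintf("n%02d", 1:15))
  bb <- gwab_boost(sc2, g, lambda = 0.7, neighbor_cap = 3)
  el <- igraph::as_data_frame(g$graph)
  for (v in bb$gene) {
    nb <- rbind(el[el$from == v, c("to", "weight")],
                setNames(el[el$to == v, c("from", "weight")],
                         c("to", "weight")))
    s_v <- if (v %in% names(sc2)) sc2[[v]] else 0
    if (!nrow(nb)) { expect_equal(bb$B[bb$gene == v], s_v); next }
    nb <- nb[order(-nb$weight, nb$to), ][seq_len(min(3, nrow(nb))), ]
    sn <- ifelse(nb$to %in% names(sc2), sc2[nb$to], 0)
    expect_equal(bb$B[bb$gene == v],
                 s_v + 0.7 * sum(nb$weight * sn) / sum(nb$weight))
  }
})

test_that("top-fraction selection uses ceil and symbol-ordered ties", {
  sc <- setNames(seq(100, 1), sprintf("g%03d", 1:100))
  expect_length(select_top_fraction(sc, 0.05)$genes, 5)
  sc2 <- setNames(seq(101, 1), sprintf("g%03d", 1:101))
  expect_length(select_top_fraction(sc2, 0.05)$genes, 6)
  # 3-way tie at the cut resolved by symbol, size unchanged
  sc3 <- setNames(c(9, 8, 5, 5, 5, 1), c("f", "e", "d", "c", "b", "a"))
  top <- select_top_fraction(sc3, 0.5)
  expect_equal(top$genes, c("f", "e", "b"))
  expect_equal(top$n_universe, 6)
})
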