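test_that("interactome generator plants a dense module deterministically", {
  # fixed seed: byte-identical edge list on rerun
  a <- simulate_interactome(n_genes = 500, module_size = 50, seed = 71)
  b <- simulate_interactome(n_genes = 500, module_size = 50, seed = 71)
  expect_identical(igraph::as_data_frame(a$interactome$graph),
                   igraph::as_data_frame(b$interactome$graph))
  expect_identical(a$module, b$module)

  # p_in = 0 leaves the backbone untouched
  c0 <- simulate_interactome(n_genes = 500, module_size = 50, p_in = 0,
                             seed = 71)
  expect_equal(igraph::ecount(c0$interactome$graph),
               igraph::ecount(igraph::sample_pa(500, m = 5,
                                                directed = FALSE)))

  # default parameters: the module's mean internal degree exceeds twice the
  # backbone expectation for a random same-size node set
  ratios <- vapply(1:10, function(s) {
    sim <- simulate_interactome(n_genes = 1000, module_size = 80,
                                p_in = 0.10, seed = 80 + s)
    g <- sim$interactome$graph
    sub <- igraph::induced_subgraph(g, sim$module)
    rand_deg <- mean(vapply(1:20, function(r) {
      set.seed(1000 * s + r)
      nodes <- sample(interactome_genes(sim$interactome), 80)
      mean(igraph::degree(igraph::induced_subgraph(g, nodes)))
    }, 0))
    mean(igraph::degree(sub)) / rand_deg
  }, 0)
  expect_true(all(ratios > 2))
})

test_that("counts generator emits NB counts with the requested moments", {
  genes <- sprintf("G%04d", 1:1500)
  sim <- simulate_counts(genes, subject_sd = 0, lib_sd = 0, n_de = 0,
                         tissue_frac = 0, seed = 72)
  x <- sim$experiment$counts
  # moment oracle within one design cell (6 LR.Li- samples): the pooled
  # method-of-moments dispersion should sit near the requested 0.1
  cell <- sim$experiment$design$sample[sim$experiment$design$group == "LR"]
  m <- rowMeans(x[, cell])
  v <- apply(x[, cell], 1, var)
  keep <- m > 20
  disp <- median((v[keep] - m[keep]) / m[keep]^2)
  expect_lt(abs(disp - 0.1), 0.05)

  # paired samples of a subject correlate more than samples across subjects
  sim2 <- simulate_counts(genes, seed = 73)
  d <- sim2$experiment$design
  lx <- log1p(sim2$experiment$counts)
  same <- vapply(unique(d$subject), function(s)
    cor(lx[, d$sample[d$subject == s][1]],
        lx[, d$sample[d$subject == s][2]]), 0)
  set.seed(74)
  others <- replicate(40, {
    s2 <- sample(unique(d$subject), 2)
    cor(lx[, d$sample[d$subject == s2[1]][1]],
        lx[, d$sample[d$subject == s2[2]][2]])
  })
  expect_gt(mean(same), mean(others))

  # design shape: 6 CT / 6 LR / 5 NR, two paired treatments
  tab <- table(sim2$experiment$design$group,
               sim2$experiment$design$treatment)
  expect_equal(as.vector(tab), c(6L, 6L, 5L, 6L, 6L, 5L))
})

test_that("GWAS generator plants detectable causal genes", {
  genes <- sprintf("G%04d", 1:120)
  sim <- simulate_gwas(genes, module = genes[1:60], n_causal = 30,
                       n_causal_module = 22, seed = 75)
  expect_equal(length(sim$truth$causal_genes), 30)
  expect_true(all(sim$gwas$dosage %in% 0:2))
  expect_equal(dim(sim$gwas$dosage), c(120 * 8, 256))
  # both phenotype classes present near balance
  expect_gt(mean(sim$gwas$phenotype), 0.2)
  expect_lt(mean(sim$gwas$phenotype), 0.8)

  # causal genes score better than nulls (rank-sum over pooled seeds)
  pools <- lapply(1:3, function(s) {
    g2 <- simulate_gwas(genes, module = genes[1:60], n_causal = 30,
                        n_causal_module = 22, seed = 90 + s)
    assoc <- snp_logistic_assoc(g2$gwas)
    idx <- map_snps_to_genes(
      data.frame(snp = assoc$snp, chr = assoc$chr, pos = assoc$pos),
      g2$gene_models)
    sc <- vegas_scores(assoc, idx, g2$gwas, sims = c(500), seed = s)
    split(sc$p_empirical, sc$gene %in% g2$truth$causal_genes)
  })
  caus <- unlist(lapply(pools, `[[`, "TRUE"))
  null <- unlist(lapply(pools, `[[`, "FALSE"))
  expect_lt(wilcox.test(caus, null, alternative = "less")$p.value, 0.01)
})

test_that("GMT generator hits the requested planted overlap and sizes", {
  bg <- sprintf("g%03d", 1:400)
  mod <- bg[1:50]
  g1 <- simulate_gmt(bg, mod, jaccard = 1, seed = 76)
  expect_setequal(g1$collection$sets[[g1$truth$planted_term]], mod)
  g0 <- simulate_gmt(bg, mod, jaccard = 0, seed = 76)
  expect_length(intersect(g0$collection$sets[[g0$truth$planted_term]],
                          mod), 0)
  sizes <- lengths(g1$collection$sets)[-1]
  expect_true(all(sizes >= 20 & sizes <= 200))
})

test_that("fixtures are deterministic and round-trip through disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(seed = 77, n_interactome = 400, module_size = 40,
                        n_expressed = 200, n_gwas_genes = 80)
  b2 <- simulate_bundle(seed = 77, n_interactome = 400, module_size = 40,
                        n_expressed = 200, n_gwas_genes = 80)
  write_fixture(b1, d1)
  write_fixture(b2, d2)
  # same master seed: identical manifest (and all files)
  expect_identical(readLines(file.path(d1, "manifest.yaml")),
                   readLines(file.path(d2, "manifest.yaml")))
  expect_identical(tools::md5sum(file.path(d1, "counts.tsv"))[[1]],
                   tools::md5sum(file.path(d2, "counts.tsv"))[[1]])
  # a different seed changes the counts
  b3 <- simulate_bundle(seed = 78, n_interactome = 400, module_size = 40,
                        n_expressed = 200, n_gwas_genes = 80)
  expect_false(identical(b1$experiment$counts, b3$experiment$counts))

  # read-back equality of every component consumed downstream
  rb <- read_fixture(d1)
  expect_identical(rb$experiment$counts, b1$experiment$counts)
  expect_identical(rb$experiment$design, b1$experiment$design)
  expect_equal(sort(interactome_genes(rb$interactome)),
               sort(interactome_genes(b1$interactome)))
  expect_identical(rb$gwas$dosage, b1$gwas$dosage)
  expect_identical(rb$gwas$phenotype, b1$gwas$phenotype)
  expect_identical(rb$collection$sets, b1$collection$sets)
  expect_setequal(rb$module, b1$module)
  # overwrite protection
  expect_error(write_fixture(b1, d1), "force")
})
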