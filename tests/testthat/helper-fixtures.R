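# Shared fixture builders and independent oracles used across test files.

# tiny counts experiment built in code
tiny_experiment <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10L, 20L, 5L, 15L, 0L, 8L), nrow = 3, byrow = TRUE,
                     dimnames = list(c("GA", "GB", "GC"), c("s1", "s2")))
  }
  design <- data.frame(sample = colnames(counts),
                       group = rep(c("LR", "NR"),
                                   length.out = ncol(counts)),
                       treatment = "Li-", tissue = "fibroblast",
                       subject = paste0("sub", seq_len(ncol(counts))),
                       clone = "c1", stringsAsFactors = FALSE)
  counts_experiment(counts, design)
}

# small weighted graph from an explicit edge table
graph_fixture <- function(edges) {
  interactome(edges)
}

# independent hand step-up B-H oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# dense closed-form RWR oracle: F = (1-a) Y (I - a W)^(-1)
rwr_oracle <- function(W, Y, alpha) {
  Wd <- as.matrix(W)
  as.vector(Y %*% solve(diag(ncol(Wd)) - alpha * Wd)) * (1 - alpha)
}

# exhaustive hypergeometric upper-tail oracle by draw enumeration
hyper_enum_oracle <- function(N, K, n, x) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  ov <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(ov >= x)
}

# brute-force weighted modularity double sum
modularity_oracle <- function(graph, membership, gamma = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, attr = "weight"))
  memb <- membership[rownames(A)]
  m2 <- sum(A)                      # 2m
  deg <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(ncol(A))) {
    if (memb[i] == memb[j])
      q <- q + A[i, j] / m2 - gamma * deg[i] * deg[j] / m2^2
  }
  unname(q)
}

# all set partitions of 1..n as membership vectors (restricted growth)
all_partitions <- function(n) {
  res <- list()
  rec <- function(prefix, maxblock) {
    k <- length(prefix)
    if (k == n) { res[[length(res) + 1]] <<- prefix; return(invisible()) }
    for (b in seq_len(maxblock + 1))
      rec(c(prefix, b), max(maxblock, b))
  }
  rec(integer(0), 0L)
  res
}

# adjusted Rand index between two labelings
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- si * sj / comb2(n)
  (sij - expected) / ((si + sj) / 2 - expected)
}
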