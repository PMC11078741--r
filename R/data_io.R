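#' @import igraph
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table
NULL

# ---------------------------------------------------------------------------
# Domain type constructors
# ---------------------------------------------------------------------------

#' Construct a counts experiment
#'
#' Bundles a gene x sample integer count matrix with its sample design
#' (group, treatment, tissue, subject, clone). All downstream expression
#' operations consume this container.
#'
#' @param counts integer matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param design data.frame with one row per sample and columns
#'   \code{sample}, \code{group} (CT/LR/NR), \code{treatment} (Li-/Li+),
#'   \code{tissue}, \code{subject}, \code{clone}.
#' @return object of class \code{counts_experiment}.
#' @export
counts_experiment <- function(counts, design) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts matrix must carry gene rownames and sample colnames")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  }
  storage.mode(counts) <- "integer"
  req <- c("sample", "group", "treatment", "tissue", "subject", "clone")
  miss <- setdiff(req, names(design))
  if (length(miss))
    stop("design is missing column(s): ", paste(miss, collapse = ", "))
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  absent <- setdiff(colnames(counts), design$sample)
  if (length(absent))
    stop("sample(s) in counts missing from design: ",
         paste(absent, collapse = ", "))
  design <- design[match(colnames(counts), design$sample), req, drop = FALSE]
  rownames(design) <- NULL
  if (anyNA(design))
    stop("design has incomplete fields for sample(s): ",
         paste(design$sample[!stats::complete.cases(design)], collapse = ", "))
  bad_grp <- setdiff(unique(design$group), c("CT", "LR", "NR"))
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  bad_trt <- setdiff(unique(design$treatment), c("Li-", "Li+"))
  if (length(bad_trt))
    stop("unknown treatment label(s): ", paste(bad_trt, collapse = ", "))
  ntrt <- tapply(design$treatment, design$subject,
                 function(x) length(unique(x)))
  if (any(ntrt > 2))
    stop("subject appears in more than 2 treatment conditions")
  structure(list(counts = counts, design = design),
            class = "counts_experiment")
}

#' @export
print.counts_experiment <- function(x, ...) {
  cat(sprintf("counts_experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("groups:    ", paste(sprintf("%s=%d", names(table(x$design$group)),
                                   table(x$design$group)), collapse = " "), "\n")
  cat("treatments:", paste(sprintf("%s=%d", names(table(x$design$treatment)),
                                   table(x$design$treatment)), collapse = " "), "\n")
  invisible(x)
}

#' Construct an interactome from an edge table
#'
#' Builds the weighted undirected gene graph used for propagation and
#' boosting. Self-loops are dropped (with a warning count); duplicate
#' gene pairs are collapsed keeping the maximum weight.
#'
#' @param edges data.frame with columns \code{source}, \code{target},
#'   \code{weight}.
#' @param keep_largest_component keep only the largest connected component
#'   (ties broken by node count then by lexicographically smallest member).
#' @return object of class \code{interactome} wrapping an igraph graph.
#' @export
interactome <- function(edges, keep_largest_component = FALSE) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  req <- c("source", "target", "weight")
  if (!all(req %in% names(edges)))
    stop("edge table needs columns source, target, weight")
  edges$weight <- as.numeric(edges$weight)
  if (any(!is.finite(edges$weight) | edges$weight <= 0))
    stop("edge weights must be finite and > 0")
  self <- edges$source == edges$target
  if (any(self)) {
    warning(sum(self), " self-loop row(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  if (!nrow(edges)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g), class = "interactome"))
  }
  # canonical pair ordering, then max-weight collapse
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  key <- paste(a, b, sep = "\r")
  w <- tapply(edges$weight, key, max)
  keys <- strsplit(names(w), "\r", fixed = TRUE)
  ed <- data.frame(source = vapply(keys, `[`, "", 1L),
                   target = vapply(keys, `[`, "", 2L),
                   weight = as.numeric(w), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  if (keep_largest_component && igraph::vcount(g) > 0) {
    comp <- igraph::components(g)
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1) {
      # tie: lexicographically smallest member wins
      firsts <- vapply(best, function(ci)
        min(igraph::V(g)$name[comp$membership == ci]), "")
      best <- best[order(firsts)][1]
    }
    g <- igraph::induced_subgraph(g, which(comp$membership == best))
  }
  structure(list(graph = g), class = "interactome")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d genes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Node symbols of an interactome
#' @param x interactome
#' @return character vector of gene symbols
#' @export
interactome_genes <- function(x) igraph::V(x$graph)$name

#' Degree index of an interactome
#' @param x interactome
#' @param weighted if TRUE return weighted degree (strength)
#' @return named numeric vector
#' @export
interactome_degree <- function(x, weighted = FALSE) {
  if (weighted) igraph::strength(x$graph, weights = igraph::E(x$graph)$weight)
  else igraph::degree(x$graph)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term id -> member symbols).
#' @param description named character vector of term descriptions.
#' @param source named character vector of source category tags.
#' @return object of class \code{gene_set_collection}.
#' @export
gene_set_collection <- function(sets, description = NULL, source = NULL) {
  if (anyDuplicated(names(sets)))
    stop("duplicate term id(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sum(empty), " empty term(s) skipped")
    sets <- sets[!empty]
  }
  ids <- names(sets)
  if (is.null(description)) description <- setNames(rep("", length(ids)), ids)
  if (is.null(source)) {
    src <- ifelse(grepl("^[A-Za-z]+:", ids), sub(":.*$", "", ids), "custom")
    source <- setNames(src, ids)
  }
  structure(list(sets = sets,
                 description = description[ids],
                 source = source[ids]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d terms, sizes %d-%d\n",
              length(x$sets),
              if (length(x$sets)) min(lengths(x$sets)) else 0L,
              if (length(x$sets)) max(lengths(x$sets)) else 0L))
  invisible(x)
}

#' Construct a GWAS dataset
#'
#' @param dosage numeric matrix SNPs x subjects with entries in {0,1,2} or NA.
#' @param snp_info data.frame with columns \code{snp}, \code{chr}, \code{pos}
#'   (strictly positive).
#' @param phenotype binary 0/1 vector per subject.
#' @param covariates numeric matrix subjects x covariates (e.g. age, sex,
#'   PC1-PC3).
#' @return object of class \code{gwas_dataset}.
#' @export
gwas_dataset <- function(dosage, snp_info, phenotype, covariates) {
  dosage <- as.matrix(dosage)
  snp_info <- as.data.frame(snp_info, stringsAsFactors = FALSE)
  if (!all(c("snp", "chr", "pos") %in% names(snp_info)))
    stop("snp_info needs columns snp, chr, pos")
  if (nrow(snp_info) != nrow(dosage))
    stop("dosage rows and snp_info rows differ")
  if (any(snp_info$pos <= 0)) stop("SNP positions must be strictly positive")
  if (length(phenotype) != ncol(dosage))
    stop("phenotype length and dosage columns differ")
  if (length(unique(phenotype[!is.na(phenotype)])) < 2)
    stop("phenotype must contain both classes")
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != ncol(dosage))
    stop("covariate rows and dosage columns differ")
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosage entries must be 0, 1, 2 or missing")
  rownames(dosage) <- snp_info$snp
  structure(list(dosage = dosage, snp_info = snp_info,
                 phenotype = as.integer(phenotype), covariates = covariates),
            class = "gwas_dataset")
}

# ---------------------------------------------------------------------------
# Readers / writers
# ---------------------------------------------------------------------------

#' Read a counts experiment from TSV files
#'
#' @param counts_path TSV with a header row of sample ids and first column of
#'   gene symbols.
#' @param design_path TSV keyed by sample id with group/treatment/tissue/
#'   subject/clone columns.
#' @return \code{counts_experiment}
#' @export
read_counts <- function(counts_path, design_path) {
  tab <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(apply(mat, 2, as.numeric))),
                 arr.ind = TRUE)
    stop(sprintf("non-numeric count at gene '%s', sample '%s'",
                 genes[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  frac <- which(mat != round(mat), arr.ind = TRUE)
  if (nrow(frac))
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 genes[frac[1, 1]], colnames(mat)[frac[1, 2]]))
  rownames(mat) <- genes
  design <- read.delim(design_path, stringsAsFactors = FALSE,
                       colClasses = "character")
  counts_experiment(mat, design)
}

#' Write a counts experiment to TSV files
#' @param x counts_experiment
#' @param counts_path,design_path output TSV paths
#' @export
write_counts <- function(x, counts_path, design_path) {
  tab <- data.frame(gene = rownames(x$counts), x$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$design, design_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(x)
}

#' Read an interactome edge list
#'
#' Expects a 3-column TSV (source, target, weight). Duplicate pairs are
#' collapsed keeping the maximum weight; self-loops dropped with a warning.
#'
#' @param path edge-list TSV
#' @param keep_largest_component retain only the largest connected component
#' @return \code{interactome}
#' @export
read_edge_list <- function(path, keep_largest_component = FALSE) {
  ed <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "numeric"))
  names(ed)[1:3] <- c("source", "target", "weight")
  interactome(ed, keep_largest_component = keep_largest_component)
}

#' Write an interactome edge list
#' @param x interactome
#' @param path output TSV
#' @export
write_edge_list <- function(x, path) {
  ed <- igraph::as_data_frame(x$graph, what = "edges")
  a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
  ed <- data.frame(source = a, target = b, weight = ed$weight,
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$source, ed$target), ]
  write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: term id, description, then member genes, tab-separated.
#' A "SOURCE:" prefix on the term id is parsed as the source category tag.
#'
#' @param path GMT file
#' @return \code{gene_set_collection}
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "))
  ids <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- setNames(vapply(fields, `[`, "", 2L), ids)
  sets <- setNames(lapply(fields, function(f) unique(f[-(1:2)])), ids)
  gene_set_collection(sets, description = desc)
}

#' Write a gene-set collection as GMT
#' @param x gene_set_collection
#' @param path output file
#' @export
write_gmt <- function(x, path) {
  lines <- vapply(names(x$sets), function(id) {
    paste(c(id, x$description[[id]], x$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(x)
}

#' Read gene models (coordinates)
#'
#' Intervals are stored 0-based half-open internally; set
#' \code{one_based = TRUE} when the file uses 1-based inclusive coordinates.
#'
#' @param path TSV with columns gene, chr, start, end
#' @param one_based input uses 1-based inclusive coordinates
#' @return data.frame(gene, chr, start, end), 0-based half-open
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  gm <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "chr", "start", "end") %in% names(gm)))
    stop("gene model table needs columns gene, chr, start, end")
  if (one_based) gm$start <- gm$start - 1L
  if (anyDuplicated(gm$gene))
    stop("duplicate gene model record(s): ",
         paste(unique(gm$gene[duplicated(gm$gene)]), collapse = ", "))
  if (any(gm$start >= gm$end)) stop("gene interval with start >= end")
  gm[, c("gene", "chr", "start", "end")]
}

#' Write Cytoscape-loadable node and edge tables for a proximal network
#'
#' The node table carries gene, propagation score, permutation z, rank and
#' gene type; the edge table is the interactome restricted to the proximal
#' set. Rows are ordered deterministically (rank, then symbol) so runs are
#' byte-comparable.
#'
#' @param result propagation result data.frame (columns gene, F, z, rank,
#'   gene_type, proximal flag named by \code{proximal_col})
#' @param interactome \code{interactome}
#' @param out_prefix path prefix; writes \code{<prefix>_nodes.tsv} and
#'   \code{<prefix>_edges.tsv}
#' @param proximal_col name of the logical proximal-flag column
#' @return invisibly, the two file paths
#' @export
write_network_tables <- function(result, interactome, out_prefix,
                                 proximal_col = "proximal_500") {
  if (!nrow(result)) stop("empty propagation result")
  if (!proximal_col %in% names(result))
    stop("no column '", proximal_col, "' in result")
  prox <- result[result[[proximal_col]], , drop = FALSE]
  prox <- prox[order(prox$rank, prox$gene), , drop = FALSE]
  nodes <- data.frame(gene = prox$gene, score = prox$F, z = prox$z,
                      rank = prox$rank,
                      gene_type = if ("gene_type" %in% names(prox))
                        prox$gene_type else NA_character_)
  node_path <- paste0(out_prefix, "_nodes.tsv")
  edge_path <- paste0(out_prefix, "_edges.tsv")
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  keep <- intersect(prox$gene, interactome_genes(interactome))
  sub <- igraph::induced_subgraph(interactome$graph, keep)
  ed <- igraph::as_data_frame(sub, what = "edges")
  if (nrow(ed)) {
    a <- pmin(ed$from, ed$to); b <- pmax(ed$from, ed$to)
    ed <- data.frame(source = a, target = b, weight = ed$weight)
    ed <- ed[order(ed$source, ed$target), ]
  } else {
    ed <- data.frame(source = character(), target = character(),
                     weight = numeric())
  }
  write.table(ed, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes = node_path, edges = edge_path))
}

#' Read a GWAS summary-statistics table
#' @param path TSV with columns snp, chr, pos, p and optionally beta, se
#' @return data.frame
#' @export
read_gwas_summary <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("snp", "chr", "pos", "p") %in% names(tab)))
    stop("summary table needs columns snp, chr, pos, p")
  if (any(tab$p <= 0 | tab$p > 1, na.rm = TRUE))
    stop("summary p-values must lie in (0, 1]")
  tab
}
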