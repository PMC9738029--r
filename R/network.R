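# minimal union-find for component labeling (path compression, union by size)
uf_new <- function(n) list(parent = seq_len(n), size = rep(1L, n))
uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) { nxt <- uf$parent[i]; uf$parent[i] <- root; i <- nxt }
  list(uf = uf, root = root)
}
uf_union <- function(uf, i, j) {
  fi <- uf_find(uf, i); uf <- fi$uf
  fj <- uf_find(uf, j); uf <- fj$uf
  a <- fi$root; b <- fj$root
  if (a == b) return(uf)
  if (uf$size[a] < uf$size[b]) { tmp <- a; a <- b; b <- tmp }
  uf$parent[b] <- a
  uf$size[a] <- uf$size[a] + uf$size[b]
  uf
}

#' Build the genotypic network of retained SNP sets
#'
#' Nodes are SNP sets; for every unordered pair, the shared-SNP overlap is
#' tested with the upper-tail hypergeometric law over the pooled panel
#' (universe = `panel_size`), and an edge is created when the pair's p falls
#' below `alpha / n_pairs` (Bonferroni over pairs). Edge weight is the
#' SNP-Jaccard; components come from union-find over the edges.
#'
#' @param sets non-empty list of [snp_set()] objects.
#' @param panel_size pooled SNP universe size (193 in the reference design).
#' @param alpha family-wise level over pairs; `alpha = 1` links any pair with
#'   a nonzero overlap.
#' @return object of class `genotypic_network`: `nodes` (data.frame with
#'   `label`, `n_snps`, `n_subjects`, `component`), `edges` (data.frame with
#'   `set_a`, `set_b`, `shared_snps`, `shared_snp_ids`, `p`, `jaccard`),
#'   `threshold`.
#' @export
build_genotypic_network <- function(sets, panel_size, alpha = 0.05) {
  stopifnot(length(sets) >= 1)
  labels <- vapply(sets, `[[`, character(1), "label")
  n <- length(sets)
  pairs <- if (n > 1) utils::combn(n, 2) else matrix(integer(), 2, 0)
  n_pairs <- ncol(pairs)
  thr <- if (n_pairs) bonferroni_threshold(alpha, n_pairs) else alpha
  edges <- list()
  uf <- uf_new(n)
  for (e in seq_len(n_pairs)) {
    i <- pairs[1, e]; j <- pairs[2, e]
    shared <- intersect(sets[[i]]$snp_ids, sets[[j]]$snp_ids)
    if (!length(shared)) next
    hg <- hypergeom_overlap(sets[[i]]$snp_ids, sets[[j]]$snp_ids, panel_size)
    if (hg$p < thr) {
      edges[[length(edges) + 1L]] <- data.frame(
        set_a = labels[i], set_b = labels[j],
        shared_snps = length(shared),
        shared_snp_ids = paste(shared, collapse = ","),
        p = hg$p, jaccard = jaccard(sets[[i]]$snp_ids, sets[[j]]$snp_ids),
        stringsAsFactors = FALSE)
      uf <- uf_union(uf, i, j)
    }
  }
  roots <- vapply(seq_len(n), function(i) { r <- uf_find(uf, i); r$root }, integer(1))
  comp <- match(roots, unique(roots))
  nodes <- data.frame(label = labels,
                      n_snps = vapply(sets, function(s) length(s$snp_ids), integer(1)),
                      n_subjects = vapply(sets, function(s) length(s$subject_ids), integer(1)),
                      component = comp, stringsAsFactors = FALSE)
  edges <- if (length(edges)) do.call(rbind, edges)
           else data.frame(set_a = character(), set_b = character(),
                           shared_snps = integer(), shared_snp_ids = character(),
                           p = numeric(), jaccard = numeric(),
                           stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = thr,
                 n_components = length(unique(comp))),
            class = "genotypic_network")
}

#' @export
print.genotypic_network <- function(x, ...) {
  cat("genotypic_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      x$n_components, "components\n")
  invisible(x)
}

#' Export a genotypic network to GraphML or edge-list TSV
#'
#' GraphML export goes through igraph (node attributes `n_snps`,
#' `n_subjects`, `component`; edge attributes `shared_snps`,
#' `shared_snp_ids`, `p`, `jaccard`) and round-trips losslessly via
#' [import_graphml()]. The TSV form writes one edge per row plus a companion
#' `<path>.nodes.tsv` with the node table, numeric values at full precision.
#'
#' @param net a `genotypic_network`.
#' @param path output file.
#' @param format `"graphml"` or `"edge_tsv"`.
#' @export
export_graph <- function(net, path, format = c("graphml", "edge_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "genotypic_network"))
  if (format == "graphml") {
    ig <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                        vertices = net$nodes)
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    fmt <- net$edges
    utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GraphML export back into a genotypic network
#'
#' @param path file written by [export_graph()] with `format = "graphml"`.
#' @return a `genotypic_network` (threshold is not stored in GraphML and is
#'   returned as `NA`).
#' @export
import_graphml <- function(path) {
  ig <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(ig, what = "vertices")
  ed <- igraph::as_data_frame(ig, what = "edges")
  nodes <- data.frame(label = vd$name, n_snps = as.integer(vd$n_snps),
                      n_subjects = as.integer(vd$n_subjects),
                      component = as.integer(vd$component),
                      stringsAsFactors = FALSE)
  edges <- if (nrow(ed))
    data.frame(set_a = ed$from, set_b = ed$to,
               shared_snps = as.integer(ed$shared_snps),
               shared_snp_ids = ed$shared_snp_ids,
               p = as.numeric(ed$p), jaccard = as.numeric(ed$jaccard),
               stringsAsFactors = FALSE)
  else data.frame(set_a = character(), set_b = character(),
                  shared_snps = integer(), shared_snp_ids = character(),
                  p = numeric(), jaccard = numeric(), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, threshold = NA_real_,
                 n_components = length(unique(nodes$component))),
            class = "genotypic_network")
}
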