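# Ortholog grouping: a k-mer peptide similarity graph stands in for the
# all-vs-all search, Markov clustering (expansion/inflation) partitions it,
# and cluster-level differential expression is aggregated with the
# published retention filters (>10 ORFs, >= 1 significant member,
# mean |log2FC| > 2.5 in either contrast).

#' Peptide k-mer similarity graph
#'
#' Edge weight between two peptides is the number of distinct amino-acid
#' k-mers they share; edges below `min_shared` are dropped. Peptides
#' shorter than `k` become isolated nodes. Pairs are enumerated through an
#' inverted k-mer index, so unrelated sequences are never compared.
#'
#' @param peptides Named character vector of peptide sequences.
#' @param k K-mer length.
#' @param min_shared Minimum shared distinct k-mers to keep an edge.
#' @return List `nodes` (character), `edges` (data.frame `from`, `to`,
#'   `weight`).
#' @export
kmer_similarity_graph <- function(peptides, k = 4L, min_shared = 3L) {
  nodes <- names(peptides)
  kmer_sets <- lapply(peptides, function(p) {
    n <- nchar(p)
    if (n < k) return(character())
    unique(substring(p, 1:(n - k + 1L), k:n))
  })
  kt <- data.table::data.table(
    id = rep(seq_along(kmer_sets), lengths(kmer_sets)),
    kmer = unlist(kmer_sets, use.names = FALSE))
  empty <- data.frame(from = character(), to = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (nrow(kt) == 0L) return(list(nodes = nodes, edges = empty))
  pairs <- merge(kt, kt, by = "kmer", allow.cartesian = TRUE)
  pairs <- pairs[pairs$id.x < pairs$id.y]
  if (nrow(pairs) == 0L) return(list(nodes = nodes, edges = empty))
  w <- pairs[, list(weight = .N), by = c("id.x", "id.y")]
  w <- w[w$weight >= min_shared]
  edges <- data.frame(from = nodes[w$id.x], to = nodes[w$id.y],
                      weight = as.numeric(w$weight),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

#' Markov clustering
#'
#' Canonicalizes node order (lexicographic), adds a self-loop per node with
#' weight equal to its maximum incident edge weight (unit weight for
#' isolated nodes), column-normalizes, then alternates expansion (matrix
#' square) and inflation (entrywise power, renormalize), pruning entries
#' below `prune`, until the maximum entry change drops below `tol` or
#' `max_iter` is reached. Clusters are the weakly connected components of
#' the converged matrix's nonzero structure.
#'
#' @param graph A graph from [kmer_similarity_graph()] or a data.frame edge
#'   list (`from`, `to`, `weight`) — nodes are then inferred from edges.
#' @param inflation Inflation exponent.
#' @param max_iter,tol,prune Iteration controls.
#' @return List `membership` (named integer vector), `clusters` (list of
#'   character vectors, largest first), `converged` (flag), `iterations`.
#' @export
mcl <- function(graph, inflation = 1.5, max_iter = 100L, tol = 1e-6,
                prune = 1e-5) {
  if (is.data.frame(graph)) {
    graph <- list(nodes = sort(unique(c(graph$from, graph$to))),
                  edges = graph)
  }
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  m <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$from, nodes); j <- match(e$to, nodes)
    m[cbind(i, j)] <- e$weight
    m[cbind(j, i)] <- e$weight
  }
  loop <- apply(m, 1, max)
  loop[loop == 0] <- 1
  diag(m) <- loop
  m <- sweep(m, 2, colSums(m), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    prev <- m
    m <- m %*% m                      # expansion
    m <- m^inflation                  # inflation
    m[m < prune] <- 0
    cs <- colSums(m)
    cs[cs == 0] <- 1
    m <- sweep(m, 2, cs, "/")
    if (max(abs(m - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iter, " iterations")
  }
  adj <- (m > 0) | t(m > 0)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  clusters <- split(nodes, comp)
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, `[`, character(1), 1))]
  names(clusters) <- NULL
  membership <- stats::setNames(rep(seq_along(clusters), lengths(clusters)),
                                unlist(clusters))
  membership <- membership[nodes]
  list(membership = membership, clusters = clusters, converged = converged,
       iterations = iter)
}

#' Cluster-level differential expression
#'
#' Aggregates group-wise ORF DE onto clusters: per contrast, the cluster
#' fold change is the arithmetic mean of member log2FCs (members without a
#' tested value are excluded from the mean and counted as untested), and a
#' cluster is retained when it has more than `min_members` ORFs (strictly),
#' at least one significant member in either contrast, and mean `|log2FC|`
#' above `min_abs_lfc` for N or Fe. The cluster's functional label is the
#' modal member annotation (ties concatenated with `/`).
#'
#' @param clusters Cluster list or [mcl()] result.
#' @param de_n,de_fe Group-wise DE tables for the N and Fe contrasts (either
#'   may be `NULL`).
#' @param annotation Optional annotation supplying member labels.
#' @param min_members Strict member-count threshold (default 10: clusters
#'   need > 10 ORFs).
#' @param min_abs_lfc Retention threshold on mean |log2FC|.
#' @param alpha FDR threshold defining a significant member.
#' @return data.frame: `cluster_id`, `n_members`, `n_untested`,
#'   `mean_log2fc_N`, `mean_log2fc_Fe`, `n_significant`, `label`,
#'   `retained`, plus a `members` list-column.
#' @export
cluster_de <- function(clusters, de_n = NULL, de_fe = NULL,
                       annotation = NULL, min_members = 10L,
                       min_abs_lfc = 2.5, alpha = 0.05) {
  if (is.list(clusters) && !is.null(clusters$clusters)) {
    clusters <- clusters$clusters
  }
  summarize_contrast <- function(de, members) {
    if (is.null(de)) return(list(mean = NA_real_, n_sig = 0L, n_tested = 0L))
    m <- de[de$orf_id %in% members, , drop = FALSE]
    list(mean = if (nrow(m)) mean(m$log2fc) else NA_real_,
         n_sig = sum(m$fdr < alpha, na.rm = TRUE), n_tested = nrow(m))
  }
  rows <- lapply(seq_along(clusters), function(i) {
    members <- clusters[[i]]
    sn <- summarize_contrast(de_n, members)
    sf <- summarize_contrast(de_fe, members)
    n_tested <- max(sn$n_tested, sf$n_tested)
    label <- NA_character_
    if (!is.null(annotation)) {
      labs <- annotation$label[match(members, annotation$orf_id)]
      labs <- labs[!is.na(labs)]
      if (length(labs)) {
        tab <- sort(table(labs), decreasing = TRUE)
        label <- paste(names(tab)[tab == max(tab)], collapse = "/")
      }
    }
    big <- length(members) > min_members
    sig <- (sn$n_sig + sf$n_sig) >= 1L
    strong <- (!is.na(sn$mean) && abs(sn$mean) > min_abs_lfc) ||
      (!is.na(sf$mean) && abs(sf$mean) > min_abs_lfc)
    data.frame(cluster_id = i, n_members = length(members),
               n_untested = length(members) - n_tested,
               mean_log2fc_N = sn$mean, mean_log2fc_Fe = sf$mean,
               n_significant = sn$n_sig + sf$n_sig, label = label,
               retained = big && sig && strong && n_tested > 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$members <- clusters
  out
}
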