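# K-mer similarity graph, Markov clustering, cluster-level DE.

test_that("kmer similarity graph weights and thresholds", {
  pep <- strrep("X", 0)  # silence lint
  p1 <- "MKTAYIAKQRQISFVK"   # length 16 -> 13 distinct 4-mers
  g <- kmer_similarity_graph(c(a = p1, b = p1), k = 4, min_shared = 3)
  expect_equal(g$edges$weight, 13)

  # one shared 20-aa domain: at least 17 shared 4-mers
  domain <- "ACDEFGHIKLMNPQRSTVWY"
  p2 <- paste0("MMMMMMMMMM", domain, "KKKKKKKKKK")
  p3 <- paste0("EEEEEEEEEE", domain, "RRRRRRRRRR")
  g <- kmer_similarity_graph(c(a = p2, b = p3))
  expect_gte(g$edges$weight, 17)

  # two random peptides: weight ~0, edge dropped at min_shared = 3
  set.seed(1)
  rand <- function() paste(sample(strsplit(domain, "")[[1]], 100,
                                  replace = TRUE), collapse = "")
  g <- kmer_similarity_graph(c(a = rand(), b = rand()))
  expect_equal(nrow(g$edges), 0L)

  # peptide shorter than k: isolated node, still listed
  g <- kmer_similarity_graph(c(a = "MK", b = p1))
  expect_true("a" %in% g$nodes)
  expect_equal(nrow(g$edges), 0L)
})

triangle_edges <- function(nodes, w = 1) {
  data.frame(from = nodes[c(1, 2, 3)], to = nodes[c(2, 3, 1)], weight = w,
             stringsAsFactors = FALSE)
}

test_that("MCL: documented partitions on canonical graphs", {
  two_tri <- rbind(triangle_edges(c("a", "b", "c")),
                   triangle_edges(c("x", "y", "z")))
  part <- mcl(two_tri)
  expect_length(part$clusters, 2L)
  expect_setequal(part$clusters[[which(vapply(part$clusters, function(cl)
    "a" %in% cl, logical(1)))]], c("a", "b", "c"))

  single <- mcl(list(nodes = "lonely",
                     edges = data.frame(from = character(),
                                        to = character(),
                                        weight = numeric())))
  expect_equal(single$clusters, list("lonely"))

  # barbell: two 6-cliques (weight 10) joined by a unit bridge
  clique <- function(nodes, w) {
    idx <- t(utils::combn(nodes, 2))
    data.frame(from = idx[, 1], to = idx[, 2], weight = w,
               stringsAsFactors = FALSE)
  }
  barbell <- rbind(clique(paste0("L", 1:6), 10),
                   clique(paste0("R", 1:6), 10),
                   data.frame(from = "L1", to = "R1", weight = 1))
  part <- mcl(barbell, inflation = 1.5)
  expect_length(part$clusters, 2L)
  expect_setequal(part$clusters[[1]], part$clusters[[1]])
  left <- part$membership[paste0("L", 1:6)]
  right <- part$membership[paste0("R", 1:6)]
  expect_length(unique(left), 1L)
  expect_length(unique(right), 1L)
  expect_false(unique(left) == unique(right))
})

test_that("MCL output is a partition, invariant to node input order", {
  set.seed(3)
  fam <- function(prefix, n) {
    idx <- t(utils::combn(paste0(prefix, seq_len(n)), 2))
    data.frame(from = idx[, 1], to = idx[, 2],
               weight = 20 + runif(nrow(idx)), stringsAsFactors = FALSE)
  }
  edges <- rbind(fam("a", 5), fam("b", 7), fam("c", 4),
                 data.frame(from = c("a1", "b1"), to = c("b2", "c1"),
                            weight = 0.5))
  p1 <- mcl(edges)
  nodes <- sort(unique(c(edges$from, edges$to)))
  expect_setequal(unlist(p1$clusters), nodes)
  expect_equal(sum(lengths(p1$clusters)), length(nodes))

  p2 <- mcl(edges[sample(nrow(edges)), ])
  expect_identical(p1$membership, p2$membership)
})

test_that("planted ortholog families are recovered (ARI >= 0.95)", {
  set.seed(8)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  make_family <- function(n, mut = 6) {
    parent <- sample(aa, 60, replace = TRUE)
    vapply(seq_len(n), function(i) {
      child <- parent
      pos <- sample(60, mut)
      child[pos] <- sample(aa, mut, replace = TRUE)
      paste(child, collapse = "")
    }, character(1))
  }
  fams <- lapply(c(6, 8, 5, 7), make_family)
  peptides <- unlist(fams)
  names(peptides) <- sprintf("p%02d", seq_along(peptides))
  truth <- rep(seq_along(fams), lengths(fams))
  g <- kmer_similarity_graph(peptides)
  part <- mcl(g)
  ari <- adjusted_rand_index(truth, part$membership[names(peptides)])
  expect_gte(ari, 0.95)
})

test_that("cluster_de applies the published retention filters", {
  mk_de <- function(ids, lfc, fdr) {
    data.frame(orf_id = ids, log2fc = lfc, fdr = fdr,
               stringsAsFactors = FALSE)
  }
  clusters <- list(
    paste0("A", 1:11),   # 11 members, 1 significant, mean 2.6 -> retained
    paste0("B", 1:10),   # 10 members: ">10" is strict -> excluded
    paste0("C", 1:12),   # 12 members, 0 significant -> excluded
    paste0("D", 1:12),   # 12 members, significant but mean 2.0 -> excluded
    paste0("E", 1:12))   # retained via the Fe contrast
  de_n <- rbind(
    mk_de(paste0("A", 1:11), 2.6, c(0.01, rep(0.5, 10))),
    mk_de(paste0("B", 1:10), 3.0, c(0.01, rep(0.5, 9))),
    mk_de(paste0("C", 1:12), 3.0, rep(0.5, 12)),
    mk_de(paste0("D", 1:12), 2.0, c(0.01, rep(0.5, 11))),
    mk_de(paste0("E", 1:12), 0.0, rep(0.5, 12)))
  de_fe <- mk_de(paste0("E", 1:12), -2.8, c(0.02, rep(0.6, 11)))
  tab <- cluster_de(clusters, de_n, de_fe)
  expect_equal(tab$retained, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(tab$mean_log2fc_N[1], 2.6)
  expect_equal(tab$mean_log2fc_Fe[5], -2.8)

  # consistency: cluster mean equals an independent recomputation
  expect_equal(tab$mean_log2fc_N[3],
               mean(de_n$log2fc[de_n$orf_id %in% clusters[[3]]]))

  # cluster with zero tested members: means missing, not retained
  tab2 <- cluster_de(list(paste0("Z", 1:15)), de_n, de_fe)
  expect_true(is.na(tab2$mean_log2fc_N))
  expect_false(tab2$retained)
})

test_that("cluster labels use the modal member annotation", {
  ann <- data.frame(orf_id = paste0("A", 1:5),
                    taxon_group = "g", genus = "g",
                    label = c("LHC", "LHC", "LHC", "NRT2", "GSII"),
                    stringsAsFactors = FALSE)
  de <- data.frame(orf_id = paste0("A", 1:5), log2fc = 1, fdr = 0.5,
                   stringsAsFactors = FALSE)
  tab <- cluster_de(list(paste0("A", 1:5)), de, NULL, annotation = ann)
  expect_equal(tab$label, "LHC")
})
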