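# shared fixtures and independent oracles, all built in code

toy_table <- function(counts = NULL, phyla = NULL, groups = NULL) {
  if (is.null(counts)) {
    counts <- matrix(
      c(5, 0, 3, 2,
        1, 4, 0, 5,
        2, 2, 2, 2),
      nrow = 3, byrow = TRUE,
      dimnames = list(paste0("s", 1:3), paste0("o", 1:4))
    )
  }
  n_s <- nrow(counts)
  n_o <- ncol(counts)
  if (is.null(phyla)) phyla <- rep_len(c("PhyA", "PhyB"), n_o)
  if (is.null(groups)) groups <- rep_len(c("SD", "ND"), n_s)
  otu_table(
    counts,
    taxonomy = data.frame(otu_id = colnames(counts), phylum = phyla),
    metadata = data.frame(sample_id = rownames(counts), group = groups,
                          replicate = seq_len(n_s), kingdom = "bacteria")
  )
}

# independent evaluation of Newman's modularity
# Q = sum_c (e_c / m - (d_c / 2m)^2)
newman_q <- function(edges, membership) {
  m <- nrow(edges)
  mods <- unique(membership)
  deg <- table(factor(c(edges[[1]], edges[[2]]),
                      levels = names(membership)))
  sum(vapply(mods, function(cm) {
    in_c <- names(membership)[membership == cm]
    e_c <- sum(edges[[1]] %in% in_c & edges[[2]] %in% in_c)
    d_c <- sum(deg[in_c])
    e_c / m - (d_c / (2 * m))^2
  }, numeric(1)))
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# wrap an igraph (or edge data frame) as a cooccurrence_network
graph_as_network <- function(g, sign = 1L) {
  ed <- igraph::as_data_frame(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) {
    ids <- as.character(seq_len(igraph::vcount(g)))
    ed$from <- as.character(ed$from)
    ed$to <- as.character(ed$to)
  }
  edges <- tibble::tibble(otu_a = ed$from, otu_b = ed$to,
                          rho = 1, q = 0, sign = sign)
  deg <- table(factor(c(edges$otu_a, edges$otu_b), levels = ids))
  nodes <- tibble::tibble(otu_id = ids, phylum = "PhyA",
                          degree = as.integer(deg[ids]))
  chronet:::new_cooccurrence_network(nodes, edges, 0.7, 0.01)
}

# planted roles of a planted network, usable by
# simulate_attack(strategy = "keystone")
planted_role_table <- function(net) planted_roles(net)

# two-K4 cliques joined by one bridge edge (13 edges, Q = 0.4230769)
two_clique_bridge <- function() {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(4, 5))
  igraph::V(g)$name <- paste0("v", 1:8)
  g
}
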