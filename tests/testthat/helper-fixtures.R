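# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

net_from_edges <- function(...) new_gene_network(rbind(...))

tm_from_edges <- function(...) build_transition_matrix(net_from_edges(...))

# a - b edge: the smallest network with a nontrivial stationary solution
two_node_tm <- function() tm_from_edges(c("a", "b"))

# Random simple graph with minimum degree >= 1 (isolated nodes get one
# random edge), so the closed-form resolvent is the exact stationary
# distribution of the renormalized iteration.
random_tm <- function(n, p = 0.12, seed = 1, model = c("er", "pa")) {
  model <- match.arg(model)
  set.seed(seed)
  g <- if (model == "er") igraph::sample_gnp(n, p)
       else igraph::sample_pa(n, m = 2, directed = FALSE)
  iso <- which(igraph::degree(g) == 0)
  for (v in iso) g <- igraph::add_edges(g, c(v, sample(setdiff(seq_len(n), v), 1)))
  nm <- sprintf("g%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  build_transition_matrix(new_gene_network(cbind(nm[el[, 1]], nm[el[, 2]]),
                                           extra_nodes = nm))
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

sims_from_lines <- function(...) load_similarities(write_tsv_lines(c(...)))

# 2-gene network with two single-gene diseases; the worked weighting example
weighted_fixture <- function() {
  tm <- two_node_tm()
  list(tm = tm,
       map = structure(list(D1 = "a", D2 = "b"), class = "disease_gene_map"),
       sims = sims_from_lines("D1\tD2\t0.5"))
}
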