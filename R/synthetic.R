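#' Configuration for the synthetic data generator
#'
#' Bundles the knobs of the planted-module generator. The defaults describe
#' a small but structured benchmark: a scale-free interactome of 300 genes,
#' 20 diseases of 2-4 genes each grouped into 4 phenotype clusters, strong
#' within-module edge cohesion (0.8), and informative within-cluster
#' phenotype similarities (0.5-0.9) against an uninformative cross-cluster
#' background (0-0.2, below the 0.3 cutoff).
#'
#' @param n_genes number of genes (network nodes).
#' @param graph_model `"pa"` (preferential attachment, scale-free like real
#'   interactomes) or `"er"` (Erdős–Rényi).
#' @param er_p edge probability for the ER model.
#' @param pa_m edges added per node for the PA model.
#' @param n_diseases number of diseases.
#' @param genes_per_disease inclusive range (min, max) of causal genes per
#'   disease; the minimum must be >= 2 so leave-one-out validation is
#'   possible.
#' @param module_cohesion probability of adding each missing edge between a
#'   disease's genes. When 0, disease gene sets are drawn uniformly at
#'   random (no planted modules at all), giving a structure-free null.
#' @param n_phenotype_clusters number of phenotype clusters; diseases in a
#'   cluster are planted in the same network territory and given high
#'   mutual similarity.
#' @param within_cluster_sim,cross_cluster_sim (min, max) uniform similarity
#'   ranges for same-cluster and cross-cluster disease pairs.
#' @param n_chromosomes synthetic chromosomes for the gene-position table.
#' @param seed generator seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 300L, graph_model = c("pa", "er"),
                             er_p = 0.03, pa_m = 2L,
                             n_diseases = 20L, genes_per_disease = c(2L, 4L),
                             module_cohesion = 0.8, n_phenotype_clusters = 4L,
                             within_cluster_sim = c(0.5, 0.9),
                             cross_cluster_sim = c(0, 0.2),
                             n_chromosomes = 4L, seed = 1L) {
  graph_model <- match.arg(graph_model)
  stopifnot(n_genes >= 3L, n_diseases >= 1L,
            length(genes_per_disease) == 2L, genes_per_disease[1L] >= 2L,
            genes_per_disease[1L] <= genes_per_disease[2L],
            module_cohesion >= 0, module_cohesion <= 1,
            er_p >= 0, er_p <= 1, n_phenotype_clusters >= 1L,
            all(within_cluster_sim >= 0), all(within_cluster_sim <= 1),
            all(cross_cluster_sim >= 0), all(cross_cluster_sim <= 1))
  structure(list(n_genes = as.integer(n_genes), graph_model = graph_model,
                 er_p = er_p, pa_m = as.integer(pa_m),
                 n_diseases = as.integer(n_diseases),
                 genes_per_disease = as.integer(genes_per_disease),
                 module_cohesion = module_cohesion,
                 n_phenotype_clusters = as.integer(n_phenotype_clusters),
                 within_cluster_sim = within_cluster_sim,
                 cross_cluster_sim = cross_cluster_sim,
                 n_chromosomes = as.integer(n_chromosomes),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

gene_names <- function(n) sprintf("g%04d", seq_len(n))
disease_names <- function(n) sprintf("D%03d", seq_len(n))

#' Generate a synthetic interactome
#'
#' @param cfg a `synthetic_config`.
#' @return A `gene_network` over `cfg$n_genes` genes; deterministic under
#'   `cfg$seed`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_local_seed(cfg$seed, {
    g <- if (cfg$graph_model == "er")
      igraph::sample_gnp(cfg$n_genes, cfg$er_p)
    else
      igraph::sample_pa(cfg$n_genes, m = cfg$pa_m, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    nm <- gene_names(cfg$n_genes)
    edges <- cbind(nm[el[, 1L]], nm[el[, 2L]])
    new_gene_network(edges, extra_nodes = nm)
  })
}

#' Plant disease modules and phenotype clusters on a network
#'
#' Each phenotype cluster claims a territory of the network (a breadth-first
#' neighbourhood around a cluster seed node); each of its diseases grows its
#' causal gene set by a breadth-first walk inside that territory, and
#' missing edges among a disease's genes are added with probability
#' `module_cohesion`. This encodes the modularity premise that genes of the
#' same (or a phenotypically similar) disease sit close together in the
#' interactome. With `module_cohesion = 0` the gene sets are instead drawn
#' uniformly at random and no edges are added, producing a structure-free
#' null.
#'
#' @param network a `gene_network`.
#' @param cfg a `synthetic_config`.
#' @return A list with `map` (a `disease_gene_map`), `clusters` (named
#'   integer vector disease -> cluster), and `network` (the input network
#'   plus any cohesion edges).
#' @export
plant_diseases <- function(network, cfg) {
  stopifnot(inherits(network, "gene_network"), inherits(cfg, "synthetic_config"))
  nodes <- network$nodes
  dn <- disease_names(cfg$n_diseases)
  clusters <- stats::setNames(rep_len(seq_len(cfg$n_phenotype_clusters), cfg$n_diseases), dn)
  with_local_seed(derive_seed(cfg$seed, 1L), {
    size_range <- seq(cfg$genes_per_disease[1L], cfg$genes_per_disease[2L])
    sizes <- size_range[sample.int(length(size_range), cfg$n_diseases, replace = TRUE)]
    if (cfg$module_cohesion == 0) {
      map <- lapply(sizes, function(k) sort(sample(nodes, k)))
      names(map) <- dn
      list(map = structure(map, class = "disease_gene_map"),
           clusters = clusters, network = network)
    } else plant_modular(network, cfg, nodes, dn, clusters, sizes)
  })
}

plant_modular <- function(network, cfg, nodes, dn, clusters, sizes) {
  g <- igraph::graph_from_edgelist(network$edges, directed = FALSE)
    missing <- setdiff(nodes, igraph::V(g)$name)
    if (length(missing)) g <- igraph::add_vertices(g, length(missing), name = missing)
    territory_size <- max(cfg$genes_per_disease[2L] * 3L, 12L)
    seeds <- sample(nodes, cfg$n_phenotype_clusters)
    territories <- lapply(seeds, function(s) {
      bfs <- igraph::bfs(g, root = s, order = TRUE, dist = FALSE)
      reach <- igraph::V(g)$name[as.integer(bfs$order)]
      reach <- reach[!is.na(reach)]
      utils::head(reach, territory_size)
    })
    map <- vector("list", cfg$n_diseases)
    names(map) <- dn
    extra <- list()
    for (i in seq_len(cfg$n_diseases)) {
      terr <- territories[[clusters[i]]]
      k <- min(sizes[i], length(terr))
      # breadth-first growth inside the territory, from a random territory node
      sub <- igraph::induced_subgraph(g, terr)
      start <- sample(igraph::V(sub)$name, 1L)
      bfs <- igraph::bfs(sub, root = start, order = TRUE)
      reach <- igraph::V(sub)$name[as.integer(bfs$order)]
      reach <- reach[!is.na(reach)]
      genes <- utils::head(reach, k)
      if (length(genes) < k)
        genes <- c(genes, sample(setdiff(terr, genes), k - length(genes)))
      map[[i]] <- sort(genes)
      pairs <- if (k >= 2L) utils::combn(sort(genes), 2L) else matrix(character(), 2L)
      if (ncol(pairs)) {
        add <- stats::runif(ncol(pairs)) < cfg$module_cohesion
        if (any(add)) extra[[length(extra) + 1L]] <- t(pairs[, add, drop = FALSE])
      }
    }
  edges <- rbind(network$edges, do.call(rbind, extra))
  list(map = structure(map, class = "disease_gene_map"),
       clusters = clusters,
       network = new_gene_network(edges, extra_nodes = nodes))
}

#' Generate phenotype similarities from a cluster assignment
#'
#' Same-cluster disease pairs draw their similarity uniformly from
#' `within_cluster_sim`, other pairs from `cross_cluster_sim`; the matrix is
#' symmetric by construction.
#'
#' @param clusters named integer vector disease -> cluster.
#' @param cfg a `synthetic_config`.
#' @return A `phenotype_sim`.
#' @export
generate_similarities <- function(clusters, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dn <- names(clusters)
  if (length(dn) < 2L)
    return(new_phenotype_sim(data.frame(a = character(), b = character(), sim = double())))
  pairs <- utils::combn(dn, 2L)
  with_local_seed(derive_seed(cfg$seed, 2L), {
    same <- clusters[pairs[1L, ]] == clusters[pairs[2L, ]]
    lo <- ifelse(same, cfg$within_cluster_sim[1L], cfg$cross_cluster_sim[1L])
    hi <- ifelse(same, cfg$within_cluster_sim[2L], cfg$cross_cluster_sim[2L])
    sim <- stats::runif(ncol(pairs), lo, hi)
    new_phenotype_sim(data.frame(a = pairs[1L, ], b = pairs[2L, ], sim = sim,
                                 stringsAsFactors = FALSE))
  })
}

#' Generate synthetic gene positions
#'
#' Genes are distributed evenly over synthetic chromosomes in node order and
#' placed at regularly spaced intervals with uniform jitter, enabling
#' artificial-linkage-interval control selection.
#'
#' @param network a `gene_network`.
#' @param cfg a `synthetic_config`.
#' @return A `gene_positions` table.
#' @export
generate_positions <- function(network, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  nodes <- network$nodes
  n <- length(nodes)
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  with_local_seed(derive_seed(cfg$seed, 3L), {
    idx_within <- stats::ave(seq_len(n), chrom_of, FUN = seq_along)
    start <- as.integer(idx_within * 100000L +
                          floor(stats::runif(n, 0, 20000)))
    width <- as.integer(floor(stats::runif(n, 1000, 5000)))
    df <- data.frame(gene = nodes, chrom = paste0("chr", chrom_of),
                     start = start, end = start + width,
                     mid = floor((start + (start + width)) / 2),
                     stringsAsFactors = FALSE)
    class(df) <- c("gene_positions", "data.frame")
    df
  })
}

#' Generate a complete synthetic input bundle
#'
#' Runs the network, disease-module, phenotype-similarity and gene-position
#' generators in sequence (all deterministic under `cfg$seed`).
#'
#' @param cfg a `synthetic_config`.
#' @return A list of class `synthetic_bundle` with elements `network`
#'   (including cohesion edges), `map`, `clusters`, `sims`, `positions`,
#'   `config`.
#' @export
generate_bundle <- function(cfg = synthetic_config()) {
  net <- generate_network(cfg)
  planted <- plant_diseases(net, cfg)
  sims <- generate_similarities(planted$clusters, cfg)
  positions <- generate_positions(planted$network, cfg)
  structure(list(network = planted$network, map = planted$map,
                 clusters = planted$clusters, sims = sims,
                 positions = positions, config = cfg),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("Synthetic bundle:", length(x$network$nodes), "genes,",
      nrow(x$network$edges), "edges,", length(x$map), "diseases,",
      nrow(x$sims), "similarity pairs (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Emits the four plain-text inputs (edge-list TSV, association TSV,
#' similarity TSV, BED4 positions) plus a JSON manifest recording the
#' configuration, so the bundle round-trips losslessly through the package
#' loaders and can be regenerated from the manifest alone.
#'
#' @param bundle a `synthetic_bundle`.
#' @param outdir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_bundle <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(outdir, "network.tsv"),
             associations = file.path(outdir, "associations.tsv"),
             similarities = file.path(outdir, "similarities.tsv"),
             positions = file.path(outdir, "positions.bed"),
             manifest = file.path(outdir, "manifest.json"))
  write_network(bundle$network, paths[["network"]])
  assoc <- data.frame(disease = rep(names(bundle$map), lengths(bundle$map)),
                      gene = unlist(bundle$map, use.names = FALSE))
  utils::write.table(assoc, paths[["associations"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sims <- data.frame(bundle$sims$a, bundle$sims$b,
                     format(bundle$sims$sim, digits = 17, trim = TRUE))
  utils::write.table(sims, paths[["similarities"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pos <- bundle$positions[, c("chrom", "start", "end", "gene")]
  utils::write.table(pos, paths[["positions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(c(bundle$config, list(clusters = as.list(bundle$clusters))),
                       paths[["manifest"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a bundle directory written by [write_bundle()]
#'
#' @param dir directory containing the bundle files.
#' @param quiet passed to the loaders.
#' @return A list with `network`, `map`, `sims`, `positions`, `manifest`.
#' @export
load_bundle <- function(dir, quiet = TRUE) {
  network <- load_network(file.path(dir, "network.tsv"), quiet = quiet)
  list(network = network,
       map = load_associations(file.path(dir, "associations.tsv"), network, quiet = quiet),
       sims = load_similarities(file.path(dir, "similarities.tsv")),
       positions = load_gene_positions(file.path(dir, "positions.bed")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE))
}
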