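#' Construct a gene network from an edge matrix
#'
#' Internal constructor shared by [load_network()] and the synthetic
#' generator. Self-loops are dropped, duplicate and reversed-duplicate
#' edges are collapsed, and nodes are put in lexicographic order so that
#' vector and matrix indices are stable across runs.
#'
#' @param edges two-column character matrix of endpoints (may be empty).
#' @param extra_nodes gene identifiers to include even if they touch no edge.
#' @return An object of class `gene_network` with elements `nodes`
#'   (sorted character vector) and `edges` (two-column character matrix,
#'   each row sorted, rows sorted).
#' @export
new_gene_network <- function(edges, extra_nodes = character()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(character(), ncol = 2L)
  storage.mode(edges) <- "character"
  all_endpoints <- as.character(edges)  # self-loop endpoints stay as nodes
  keep <- edges[, 1L] != edges[, 2L]
  n_self <- sum(!keep)
  edges <- edges[keep, , drop = FALSE]
  # canonical order within each edge, then dedupe
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, c(2L, 1L), drop = FALSE]
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, , drop = FALSE]
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  nodes <- sort(unique(c(all_endpoints, as.character(extra_nodes))))
  structure(
    list(nodes = nodes, edges = edges),
    dropped_self_loops = n_self,
    dropped_duplicates = n_dup,
    class = "gene_network"
  )
}

#' Read a protein-protein interaction network from an edge-list file
#'
#' The file is a TSV with at least two columns (gene_a, gene_b); lines
#' starting with `#` are comments. Self-linked interactions and duplicated
#' (including reversed) interactions are removed, and the counts of removed
#' records are reported.
#'
#' @param path path to the edge-list TSV.
#' @param quiet suppress the message about dropped records.
#' @return A `gene_network` (see [new_gene_network()]).
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("a\tb", "b\ta", "c\tc"), tf)
#' net <- load_network(tf)
#' net$nodes
load_network <- function(path, quiet = FALSE) {
  lines <- read_input_lines(path, "network")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop_data("network file '", path, "': line ", idx[bad[1L]],
              " has fewer than 2 tab-separated fields")
  edges <- if (length(fields)) t(vapply(fields, function(f) f[1:2], character(2L)))
           else matrix(character(), ncol = 2L)
  net <- new_gene_network(edges)
  if (!quiet) {
    ds <- attr(net, "dropped_self_loops"); dd <- attr(net, "dropped_duplicates")
    if (ds + dd > 0)
      message("load_network: dropped ", ds, " self-loop(s) and ", dd, " duplicate edge(s)")
  }
  net
}

#' Write a gene network back to an edge-list TSV
#'
#' @param network a `gene_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.gene_network <- function(x, ...) {
  cat("Gene network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Restrict a network to its largest connected component
#'
#' Optional preprocessing; by default all components are kept.
#'
#' @param network a `gene_network`.
#' @return A `gene_network` over the largest component's nodes.
#' @export
largest_component <- function(network) {
  g <- igraph::graph_from_edgelist(network$edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(network$nodes, igraph::V(g)$name)),
                            name = setdiff(network$nodes, igraph::V(g)$name))
  comp <- igraph::components(g)
  keep <- igraph::V(g)$name[comp$membership == which.max(comp$csize)]
  sub <- network$edges[network$edges[, 1L] %in% keep & network$edges[, 2L] %in% keep, ,
                       drop = FALSE]
  new_gene_network(sub, extra_nodes = keep)
}

#' Build the column-normalized transition matrix of a network
#'
#' Entry (i, j) is 1/degree(j) when genes i and j interact, so that every
#' column over a node of degree >= 1 sums to 1. Columns of isolated nodes
#' are left all-zero; the random-walk engine compensates by renormalizing
#' each iterate.
#'
#' @param network a `gene_network` with at least one node.
#' @return An object of class `transition_matrix`: a list with `matrix`
#'   (a `dgCMatrix`), `nodes` and `node_index`.
#' @export
build_transition_matrix <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  nodes <- network$nodes
  if (length(nodes) == 0L) stop_data("cannot build a transition matrix for an empty network")
  index <- stats::setNames(seq_along(nodes), nodes)
  e <- network$edges
  i <- c(index[e[, 1L]], index[e[, 2L]])
  j <- c(index[e[, 2L]], index[e[, 1L]])
  A <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(length(nodes), length(nodes)),
                            dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  M <- A %*% Matrix::Diagonal(x = scale)
  dimnames(M) <- list(nodes, nodes)
  structure(list(matrix = M, nodes = nodes, node_index = index),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("Column-normalized transition matrix over", length(x$nodes), "genes (",
      Matrix::nnzero(x$matrix), "nonzero entries )\n")
  invisible(x)
}

#' Read disease-gene associations
#'
#' The file is a TSV with columns (disease_id, gene_id). Duplicate pairs are
#' collapsed; associations whose gene is absent from the network are dropped
#' (with a reported count). Optionally diseases left with a single gene are
#' discarded, as required for leave-one-out cross-validation.
#'
#' @param path path to the association TSV.
#' @param network a `gene_network`; genes outside it are dropped.
#' @param drop_single_gene drop diseases with fewer than 2 retained genes.
#' @param quiet suppress the dropped-record message.
#' @return A named list of class `disease_gene_map`: disease id ->
#'   character vector of associated gene ids (sorted).
#' @export
load_associations <- function(path, network, drop_single_gene = FALSE, quiet = FALSE) {
  stopifnot(inherits(network, "gene_network"))
  lines <- read_input_lines(path, "association")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad))
    stop_data("association file '", path, "': line ", idx[bad[1L]],
              " has fewer than 2 tab-separated fields")
  if (!length(fields)) return(structure(stats::setNames(list(), character()),
                                        class = "disease_gene_map"))
  dis <- vapply(fields, `[[`, "", 1L)
  gene <- vapply(fields, `[[`, "", 2L)
  dup <- duplicated(paste(dis, gene, sep = "\r"))
  dis <- dis[!dup]; gene <- gene[!dup]
  in_net <- gene %in% network$nodes
  n_off <- sum(!in_net)
  map <- lapply(split(gene[in_net], dis[in_net]), function(g) sort(unique(g)))
  n_single <- 0L
  if (drop_single_gene) {
    single <- vapply(map, length, 1L) < 2L
    n_single <- sum(single)
    map <- map[!single]
  }
  if (!quiet && (n_off > 0L || n_single > 0L))
    message("load_associations: dropped ", n_off, " association(s) with genes absent ",
            "from the network and ", n_single, " single-gene disease(s)")
  structure(map[order(names(map))], class = "disease_gene_map",
            dropped_off_network = n_off, dropped_single_gene = n_single)
}

#' Read gene genomic positions from a BED4 file
#'
#' Columns: chrom, chromStart (0-based), chromEnd (half-open), gene_id.
#' Used to build artificial-linkage-interval control sets. A gene's point
#' position is the integer midpoint of its interval.
#'
#' @param path path to the BED4 TSV.
#' @return A data frame of class `gene_positions` with columns `gene`,
#'   `chrom`, `start`, `end`, `mid`, one row per gene.
#' @export
load_gene_positions <- function(path) {
  lines <- read_input_lines(path, "position")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4L)
  if (length(bad))
    stop_data("position file '", path, "': line ", idx[bad[1L]],
              " has fewer than 4 tab-separated fields")
  if (!length(fields)) {
    df <- data.frame(gene = character(), chrom = character(),
                     start = integer(), end = integer(), mid = double())
    class(df) <- c("gene_positions", "data.frame")
    return(df)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- as.integer(vapply(fields, `[[`, "", 2L))
  end <- as.integer(vapply(fields, `[[`, "", 3L))
  gene <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop_data("position file '", path, "': line ", idx[bad[1L]],
              " has an invalid interval (start must be <= end)")
  dup <- which(duplicated(gene))
  if (length(dup))
    stop_data("position file '", path, "': duplicate record for gene '", gene[dup[1L]], "'")
  df <- data.frame(gene = gene, chrom = chrom, start = start, end = end,
                   mid = floor((start + end) / 2), stringsAsFactors = FALSE)
  class(df) <- c("gene_positions", "data.frame")
  df
}
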