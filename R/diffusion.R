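#' Indicator start distribution of a single gene
#'
#' @param gene a gene identifier present in the network.
#' @param transition a `transition_matrix`.
#' @return A named numeric vector over the network nodes with unit mass on
#'   `gene`.
#' @export
indicator_distribution <- function(gene, transition) {
  stopifnot(inherits(transition, "transition_matrix"))
  i <- transition$node_index[gene]
  if (length(i) != 1L || is.na(i))
    stop_data("gene '", gene, "' is not a node of the network")
  p <- stats::setNames(numeric(length(transition$nodes)), transition$nodes)
  p[i] <- 1
  p
}

#' Equal-mass start distribution of a disease
#'
#' Each gene currently associated with the disease receives mass 1/k, where
#' k is the number of associated genes present in the network.
#'
#' @param disease a disease identifier.
#' @param map a `disease_gene_map`.
#' @param transition a `transition_matrix`.
#' @return A named numeric vector over the network nodes summing to 1.
#' @export
disease_initial_distribution <- function(disease, map, transition) {
  stopifnot(inherits(transition, "transition_matrix"))
  genes <- intersect(map[[disease]], transition$nodes)
  if (length(genes) == 0L)
    stop_data("disease '", disease, "' has no associated genes in the network")
  p <- stats::setNames(numeric(length(transition$nodes)), transition$nodes)
  p[transition$node_index[genes]] <- 1 / length(genes)
  p
}

new_diffusion_profile <- function(values, restart, iterations, converged, tol) {
  structure(list(values = values, restart = restart, iterations = iterations,
                 converged = converged, tol = tol),
            class = "diffusion_profile")
}

#' @export
print.diffusion_profile <- function(x, ...) {
  cat("Diffusion profile over", length(x$values), "genes (restart =", x$restart,
      if (is.na(x$iterations)) ", closed form" else paste(",", x$iterations, "iterations"),
      if (x$converged) ", converged" else ", NOT converged", ")\n")
  top <- sort(x$values, decreasing = TRUE)[seq_len(min(5L, length(x$values)))]
  cat("Top mass:", paste(sprintf("%s=%.4g", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

check_start_distribution <- function(p0, transition) {
  if (length(p0) != length(transition$nodes))
    stop_data("start distribution length (", length(p0),
              ") does not match the network size (", length(transition$nodes), ")")
  if (any(p0 < 0)) stop_data("start distribution has a negative entry")
  s <- sum(p0)
  if (s <= 0) stop_data("start distribution sums to zero")
  p0 / s
}

#' Random walk with restart
#'
#' Iterates `P_{t+1} = (1 - gamma) * M %*% P_t + gamma * P_0` until the L1
#' difference of successive iterates falls below `tol`. Each iterate is
#' renormalized to sum 1; on networks without isolated nodes this is a
#' no-op, and it keeps the probabilistic interpretation when zero columns
#' would otherwise leak mass.
#'
#' @param transition a `transition_matrix`.
#' @param p0 start distribution aligned to the node order (nonnegative,
#'   positive sum; it is normalized to sum 1).
#' @param gamma restart probability in (0, 1]. Values near 1 keep the walk
#'   local to the start nodes; values near 0 give a global view.
#' @param tol L1 convergence threshold.
#' @param max_iter iteration safety bound.
#' @return A `diffusion_profile` with elements `values` (the stationary
#'   distribution), `restart`, `iterations`, `converged`, `tol`.
#' @export
#' @examples
#' net <- new_gene_network(rbind(c("a", "b")))
#' tm <- build_transition_matrix(net)
#' rwr(tm, indicator_distribution("a", tm), gamma = 0.5)$values  # (2/3, 1/3)
rwr <- function(transition, p0, gamma = 0.25, tol = 1e-6, max_iter = 10000L) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!(gamma > 0 && gamma <= 1)) stop_data("gamma must be in (0, 1]")
  if (tol <= 0) stop_data("tol must be positive")
  p0 <- check_start_distribution(p0, transition)
  M <- transition$matrix
  p <- p0
  iterations <- 0L
  converged <- FALSE
  while (iterations < max_iter) {
    q <- as.numeric((1 - gamma) * (M %*% p) + gamma * p0)
    s <- sum(q)
    if (s > 0) q <- q / s
    iterations <- iterations + 1L
    if (sum(abs(q - p)) < tol) {
      p <- q
      converged <- TRUE
      break
    }
    p <- q
  }
  if (!converged)
    warning("rwr: not converged after ", max_iter, " iterations (gamma = ", gamma, ")")
  new_diffusion_profile(stats::setNames(p, transition$nodes), gamma, iterations,
                        converged, tol)
}

#' Exact stationary distribution of the restarted walk
#'
#' Solves the linear fixed-point system
#' `P = gamma * (I - (1 - gamma) * M)^{-1} %*% P_0` by a dense solve. Used
#' as an independent oracle for the iterative engine and for small runs.
#' The solution coincides with [rwr()] exactly when the network has no
#' isolated nodes (otherwise the iterative renormalization makes the map
#' nonlinear).
#'
#' @inheritParams rwr
#' @param max_nodes guard against accidental dense solves on large networks.
#' @return A `diffusion_profile` (with `iterations = NA`).
#' @export
rwr_closed_form <- function(transition, p0, gamma = 0.25, max_nodes = 2000L) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!(gamma > 0 && gamma <= 1)) stop_data("gamma must be in (0, 1]")
  n <- length(transition$nodes)
  if (n > max_nodes)
    stop_data("closed-form solve guarded to networks of <= ", max_nodes, " nodes")
  p0 <- check_start_distribution(p0, transition)
  A <- diag(n) - (1 - gamma) * as.matrix(transition$matrix)
  x <- solve(A, gamma * p0)
  x <- x / sum(x)
  new_diffusion_profile(stats::setNames(as.numeric(x), transition$nodes),
                        gamma, NA_integer_, TRUE, NA_real_)
}

#' Diffusion profiles of all genes (or a subset)
#'
#' Computes the stationary distribution of the restarted walk started from
#' each gene's indicator vector, batched as one matrix iteration.
#'
#' @inheritParams rwr
#' @param genes genes to profile (default: every network node).
#' @return A numeric matrix with one column per start gene (rows indexed by
#'   the network nodes), each column summing to 1, with attributes `gamma`
#'   and `tol`.
#' @export
all_gene_profiles <- function(transition, gamma = 0.25, tol = 1e-6,
                              max_iter = 10000L, genes = NULL) {
  stopifnot(inherits(transition, "transition_matrix"))
  if (!(gamma > 0 && gamma <= 1)) stop_data("gamma must be in (0, 1]")
  nodes <- transition$nodes
  genes <- genes %||% nodes
  miss <- setdiff(genes, nodes)
  if (length(miss)) stop_data("unknown gene(s): ", paste(miss, collapse = ", "))
  n <- length(nodes)
  P0 <- matrix(0, n, length(genes), dimnames = list(nodes, genes))
  P0[cbind(transition$node_index[genes], seq_along(genes))] <- 1
  M <- transition$matrix
  P <- P0
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    Q <- (1 - gamma) * as.matrix(M %*% P) + gamma * P0
    cs <- colSums(Q)
    pos <- cs > 0
    Q[, pos] <- sweep(Q[, pos, drop = FALSE], 2L, cs[pos], "/")
    if (max(colSums(abs(Q - P))) < tol) {
      P <- Q
      converged <- TRUE
      break
    }
    P <- Q
  }
  if (!converged)
    warning("all_gene_profiles: not converged after ", max_iter, " iterations")
  dimnames(P) <- list(nodes, genes)
  attr(P, "gamma") <- gamma
  attr(P, "tol") <- tol
  P
}

#' Write / read a diffusion-profile cache
#'
#' The cache is a plain-text TSV matrix (rows = start genes, columns =
#' network nodes) plus a JSON sidecar recording the restart probability,
#' tolerance and node order, so a reloaded cache can be validated against
#' the network it was computed on.
#'
#' @param profiles matrix from [all_gene_profiles()].
#' @param path output TSV path; the sidecar is written at `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_profile_cache <- function(profiles, path) {
  m <- t(profiles)  # rows = start genes
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, col.names = NA)
  sidecar <- list(gamma = attr(profiles, "gamma"), tol = attr(profiles, "tol"),
                  nodes = rownames(profiles))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profile_cache
#' @param transition optional `transition_matrix` to validate the cached
#'   node order against.
#' @return For `read_profile_cache`, the profile matrix in
#'   [all_gene_profiles()] orientation.
#' @export
read_profile_cache <- function(path, transition = NULL) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                                   check.names = FALSE))
  profiles <- t(m)
  if (!identical(colnames(m), sidecar$nodes))
    stop_data("profile cache '", path, "': node order does not match its sidecar")
  if (!is.null(transition) && !identical(sidecar$nodes, transition$nodes))
    stop_data("profile cache '", path, "' was computed on a different node order")
  attr(profiles, "gamma") <- sidecar$gamma
  attr(profiles, "tol") <- sidecar$tol
  profiles
}
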