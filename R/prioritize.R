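#' Global similarity measures between diffusion profiles
#'
#' `lcc` is the Pearson linear correlation coefficient of two profiles;
#' `cosine_sim` is the cosine of the angle between them. Both are symmetric
#' and invariant to positive rescaling of either argument, which is why the
#' renormalization of weighted disease start vectors cannot change any
#' ranking. A degenerate input (constant profile for `lcc`, zero profile
#' for `cosine_sim`) has no defined score and yields `NA`; rankers place
#' such candidates last.
#'
#' @param a,b numeric vectors of equal length (profiles over the same node
#'   order).
#' @return A scalar in \[-1, 1\] for `lcc`, in \[0, 1\] for `cosine_sim`
#'   on nonnegative input, or `NA` if undefined.
#' @export
#' @examples
#' lcc(c(1, 2, 3), c(3, 2, 1))        # -1
#' cosine_sim(c(1, 1), c(1, 0))       # 1/sqrt(2)
lcc <- function(a, b) {
  if (length(a) != length(b)) stop_data("profiles have different lengths")
  if (length(a) < 2L) stop_data("profiles must have length >= 2")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' @rdname lcc
#' @export
cosine_sim <- function(a, b) {
  if (length(a) != length(b)) stop_data("profiles have different lengths")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

#' PRINCE-style logistic prior over genes
#'
#' Builds the prior start vector of the PRINCE baseline: each gene receives
#' mass proportional to `L(x) = 1 / (1 + exp(c * x + d))` where `x` is the
#' largest phenotype similarity between the query disease and any disease
#' the gene is known to cause (with similarity 1 for the query disease's
#' own genes, and 0 for genes causing no similar disease). Defaults
#' `c = -15`, `d = log(9999)` give `L(0) = 1e-4` and `L(1)` close to 1.
#' This reproduces the prior construction only; no edge-weight variant or
#' iterative refinement is included, hence "PRINCE-style".
#'
#' @param disease the query disease.
#' @param map a `disease_gene_map` (training associations).
#' @param sims a `phenotype_sim` (may be `NULL`: only the disease's own
#'   genes then rise above the logistic floor).
#' @param transition a `transition_matrix`.
#' @param c,d logistic parameters.
#' @return A named numeric vector over the network nodes summing to 1.
#' @export
prince_prior <- function(disease, map, sims, transition, c = -15, d = log(9999)) {
  stopifnot(inherits(transition, "transition_matrix"))
  nodes <- transition$nodes
  x <- stats::setNames(numeric(length(nodes)), nodes)
  partners <- if (is.null(sims)) numeric() else similar_diseases(sims, disease, threshold = 0)
  partners <- c(stats::setNames(1, disease), partners[names(partners) != disease])
  for (i in seq_along(partners)) {
    genes <- intersect(map[[names(partners)[i]]], nodes)
    if (length(genes)) {
      j <- transition$node_index[genes]
      x[j] <- pmax(x[j], partners[i])
    }
  }
  prior <- 1 / (1 + exp(c * x + d))
  prior / sum(prior)
}

rank_with_ties <- function(scores) {
  # pessimistic (worst-rank) ties; undefined (NA) scores rank last
  ranks <- rep.int(length(scores), length(scores))
  ok <- !is.na(scores)
  ranks[ok] <- rank(-scores[ok], ties.method = "max")
  ranks
}

score_candidates <- function(disease, candidates, method, map, sims, transition,
                             gene_profiles = NULL, gamma = 0.25, lambda = 0.5,
                             threshold = 0.3, tol = 1e-6, max_iter = 10000L,
                             exclude_gene = NULL) {
  method <- match.arg(method, c("dp_lcc", "dp_cos", "rwr", "prince"))
  if (method %in% c("dp_lcc", "dp_cos")) {
    if (is.null(gene_profiles))
      gene_profiles <- all_gene_profiles(transition, gamma = gamma, tol = tol,
                                         max_iter = max_iter, genes = candidates)
    dprof <- disease_diffusion_profile(disease, map, sims, transition,
                                       gamma = gamma, lambda = lambda,
                                       threshold = threshold, tol = tol,
                                       max_iter = max_iter,
                                       exclude_gene = exclude_gene)$values
    gp <- gene_profiles[, candidates, drop = FALSE]
    if (method == "dp_lcc") {
      if (stats::sd(dprof) == 0) return(stats::setNames(rep(NA_real_, length(candidates)),
                                                        candidates))
      s <- suppressWarnings(as.numeric(stats::cor(dprof, gp)))
      s[apply(gp, 2L, stats::sd) == 0] <- NA_real_
    } else {
      nd <- sqrt(sum(dprof^2))
      ng <- sqrt(colSums(gp^2))
      s <- ifelse(nd == 0 | ng == 0, NA_real_, colSums(gp * dprof) / (nd * ng))
    }
    return(stats::setNames(s, candidates))
  }
  p0 <- if (method == "rwr") {
    # classical component-score baseline: unweighted equal-mass start vector
    disease_initial_distribution(disease, map, transition)
  } else {
    prince_prior(disease, map, sims, transition)
  }
  prof <- rwr(transition, p0, gamma = gamma, tol = tol, max_iter = max_iter)$values
  prof[candidates]
}

#' Rank candidate genes for a disease
#'
#' Scores every candidate with the chosen method and ranks them in
#' decreasing score order. Methods:
#' \describe{
#'   \item{`dp_lcc`, `dp_cos`}{global similarity (Pearson correlation /
#'     cosine) between the disease's phenotype-weighted diffusion profile
#'     and each candidate gene's diffusion profile.}
#'   \item{`rwr`}{the candidate's component of the unweighted disease
#'     stationary vector (the classical local score).}
#'   \item{`prince`}{the candidate's component of the stationary vector
#'     started from the PRINCE-style logistic prior.}
#' }
#' Tied scores all receive the worst (largest) rank of their tie group, so
#' evaluation never credits a tie; undefined scores rank last.
#'
#' @param disease the query disease.
#' @param candidates character vector of candidate genes (network nodes).
#' @param method one of `"dp_lcc"`, `"dp_cos"`, `"rwr"`, `"prince"`.
#' @param map a `disease_gene_map` (training associations).
#' @param sims a `phenotype_sim` or `NULL`.
#' @param transition a `transition_matrix`.
#' @param gene_profiles optional precomputed matrix from
#'   [all_gene_profiles()] (must cover `candidates`); avoids recomputation
#'   across many queries at the same `gamma`.
#' @inheritParams disease_diffusion_profile
#' @return An object of class `ranked_result`: a data frame with columns
#'   `gene`, `score`, `rank` (sorted by rank, ties by gene id), with
#'   attributes `disease` and `method`.
#' @export
rank_candidates <- function(disease, candidates, method = c("dp_lcc", "dp_cos", "rwr", "prince"),
                            map, sims = NULL, transition, gene_profiles = NULL,
                            gamma = 0.25, lambda = 0.5, threshold = 0.3,
                            tol = 1e-6, max_iter = 10000L, exclude_gene = NULL) {
  method <- match.arg(method)
  if (length(candidates) == 0L) stop_data("empty candidate list")
  miss <- setdiff(candidates, transition$nodes)
  if (length(miss)) stop_data("candidate gene(s) not in the network: ",
                              paste(miss, collapse = ", "))
  scores <- score_candidates(disease, candidates, method, map, sims, transition,
                             gene_profiles = gene_profiles, gamma = gamma,
                             lambda = lambda, threshold = threshold, tol = tol,
                             max_iter = max_iter, exclude_gene = exclude_gene)
  if (anyNA(scores))
    warning("rank_candidates: ", sum(is.na(scores)),
            " candidate(s) had an undefined score and were ranked last")
  ranks <- rank_with_ties(scores)
  out <- data.frame(gene = candidates, score = as.numeric(scores), rank = ranks,
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, disease = disease, method = method,
            class = c("ranked_result", "data.frame"))
}

#' Rank every non-associated gene in the network
#'
#' Genome-wide prioritization: candidates are all network genes not already
#' associated with the disease in `map`.
#'
#' @inheritParams rank_candidates
#' @param top_k if given, return only the `top_k` best-ranked rows.
#' @return A `ranked_result`.
#' @export
rank_genome_wide <- function(disease, method = c("dp_lcc", "dp_cos", "rwr", "prince"),
                             map, sims = NULL, transition, gene_profiles = NULL,
                             gamma = 0.25, lambda = 0.5, threshold = 0.3,
                             tol = 1e-6, max_iter = 10000L, top_k = NULL) {
  candidates <- setdiff(transition$nodes, map[[disease]])
  res <- rank_candidates(disease, candidates, method, map = map, sims = sims,
                         transition = transition, gene_profiles = gene_profiles,
                         gamma = gamma, lambda = lambda, threshold = threshold,
                         tol = tol, max_iter = max_iter)
  if (!is.null(top_k)) {
    res <- res[seq_len(min(top_k, nrow(res))), , drop = FALSE]
    class(res) <- c("ranked_result", "data.frame")
  }
  res
}

#' @export
print.ranked_result <- function(x, n = 10L, ...) {
  cat("Candidate ranking for disease '", attr(x, "disease"), "' (method: ",
      toupper(attr(x, "method")), ", ", nrow(x), " candidates)\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
summary.ranked_result <- function(object, ...) {
  cat("Ranking of", nrow(object), "candidates for disease '",
      attr(object, "disease"), "' by", toupper(attr(object, "method")), "\n")
  cat("Score range: [", format(min(object$score, na.rm = TRUE), digits = 4), ", ",
      format(max(object$score, na.rm = TRUE), digits = 4), "]; ",
      sum(is.na(object$score)), " undefined score(s)\n", sep = "")
  invisible(object)
}
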