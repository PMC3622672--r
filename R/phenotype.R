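#' Read a sparse phenotype-similarity matrix
#'
#' The file is a TSV with columns (disease_a, disease_b, similarity), each
#' similarity in \[0, 1\]. Entries are symmetrized; a pair reported twice
#' with different values is an error; the diagonal is not stored.
#'
#' @param path path to the similarity TSV.
#' @return An object of class `phenotype_sim`: a data frame with columns
#'   `a`, `b` (canonically ordered, `a < b`) and `sim`.
#' @export
load_similarities <- function(path) {
  lines <- read_input_lines(path, "similarity")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad))
    stop_data("similarity file '", path, "': line ", idx[bad[1L]],
              " has fewer than 3 tab-separated fields")
  if (!length(fields))
    return(new_phenotype_sim(data.frame(a = character(), b = character(), sim = double())))
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  sim <- as.numeric(vapply(fields, `[[`, "", 3L))
  bad <- which(is.na(sim) | sim < 0 | sim > 1)
  if (length(bad))
    stop_data("similarity file '", path, "': line ", idx[bad[1L]],
              " has a similarity outside [0, 1]")
  self <- a == b
  a <- a[!self]; b <- b[!self]; sim <- sim[!self]; idx <- idx[!self]
  flip <- a > b
  tmp <- a[flip]; a[flip] <- b[flip]; b[flip] <- tmp
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    conflict <- which(abs(sim[dup] - sim[first]) > 1e-12)
    if (length(conflict))
      stop_data("similarity file '", path, "': line ", idx[which(dup)[conflict[1L]]],
                " contradicts an earlier entry for the same disease pair")
  }
  new_phenotype_sim(data.frame(a = a[!dup], b = b[!dup], sim = sim[!dup],
                               stringsAsFactors = FALSE))
}

new_phenotype_sim <- function(df) {
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("phenotype_sim", "data.frame")
  df
}

#' @export
print.phenotype_sim <- function(x, ...) {
  cat("Phenotype similarities:", nrow(x), "disease pairs over",
      length(unique(c(x$a, x$b))), "diseases\n")
  invisible(x)
}

#' Diseases similar to a query disease
#'
#' @param sims a `phenotype_sim`.
#' @param disease disease identifier.
#' @param threshold minimum informative similarity (pairs below it are
#'   ignored; the conventional text-mining cutoff is 0.3).
#' @return A named numeric vector: partner disease id -> similarity, for
#'   every partner with similarity >= `threshold`.
#' @export
similar_diseases <- function(sims, disease, threshold = 0.3) {
  stopifnot(inherits(sims, "phenotype_sim"))
  hit <- (sims$a == disease | sims$b == disease) & sims$sim >= threshold
  partner <- ifelse(sims$a[hit] == disease, sims$b[hit], sims$a[hit])
  stats::setNames(sims$sim[hit], partner)
}

#' Phenotype-similarity-weighted start distribution of a disease
#'
#' The equal-mass start vector of the disease is augmented by the start
#' vectors of phenotypically similar diseases: each disease with similarity
#' at or above `threshold` contributes its own equal-mass distribution
#' scaled by `lambda * similarity`. The result is renormalized to sum 1;
#' because the correlation and cosine prioritizers are invariant to positive
#' rescaling, renormalization does not affect rankings.
#'
#' @param disease the query disease.
#' @param map a `disease_gene_map` (the training associations).
#' @param sims a `phenotype_sim`, or `NULL` for no weighting.
#' @param transition a `transition_matrix`.
#' @param lambda nonnegative weight on the similar diseases' contribution
#'   (0 recovers the unweighted start vector; default 0.5).
#' @param threshold similarity cutoff below which pairs are uninformative.
#' @param exclude_gene optional gene removed from every *similar* disease's
#'   gene set before it contributes (strict leakage-free cross-validation);
#'   the query disease's own set is taken from `map` as given.
#' @return A named numeric vector over the network nodes summing to 1.
#' @export
weighted_initial_distribution <- function(disease, map, sims, transition,
                                          lambda = 0.5, threshold = 0.3,
                                          exclude_gene = NULL) {
  if (lambda < 0) stop_data("lambda must be nonnegative")
  if (threshold < 0 || threshold > 1) stop_data("threshold must be in [0, 1]")
  d0 <- disease_initial_distribution(disease, map, transition)
  if (is.null(sims) || lambda == 0) return(d0)
  partners <- similar_diseases(sims, disease, threshold)
  partners <- partners[names(partners) != disease]
  dw <- d0
  skipped <- 0L
  for (i in seq_along(partners)) {
    di <- names(partners)[i]
    genes <- intersect(map[[di]], transition$nodes)
    if (!is.null(exclude_gene)) genes <- setdiff(genes, exclude_gene)
    if (length(genes) == 0L) {
      skipped <- skipped + 1L
      next
    }
    d0i <- stats::setNames(numeric(length(transition$nodes)), transition$nodes)
    d0i[transition$node_index[genes]] <- 1 / length(genes)
    dw <- dw + lambda * partners[i] * d0i
  }
  if (skipped > 0L)
    message("weighted_initial_distribution: ", skipped,
            " similar disease(s) had no in-network genes and contributed nothing")
  dw / sum(dw)
}

#' Diffusion profile of a disease
#'
#' Runs the restarted walk from the (optionally phenotype-weighted) disease
#' start distribution. With `lambda = 0` or `sims = NULL` this is the plain
#' disease walk.
#'
#' @inheritParams weighted_initial_distribution
#' @inheritParams rwr
#' @return A `diffusion_profile`.
#' @export
disease_diffusion_profile <- function(disease, map, sims = NULL, transition,
                                      gamma = 0.25, lambda = 0.5, threshold = 0.3,
                                      tol = 1e-6, max_iter = 10000L,
                                      exclude_gene = NULL) {
  d0 <- weighted_initial_distribution(disease, map, sims, transition,
                                      lambda = lambda, threshold = threshold,
                                      exclude_gene = exclude_gene)
  rwr(transition, d0, gamma = gamma, tol = tol, max_iter = max_iter)
}
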