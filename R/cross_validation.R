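#' Random control genes for one validation case
#'
#' Samples `n` control genes uniformly without replacement from the network,
#' excluding the test gene (and any further excluded genes, e.g. genes
#' already associated with the same disease).
#'
#' @param test_gene the held-out gene.
#' @param nodes character vector of network genes.
#' @param n number of controls (conventionally 99, so the candidate set has
#'   size 100).
#' @param seed reproducibility seed (local to the call).
#' @param exclude further genes barred from the control set.
#' @return Character vector of `n` control genes.
#' @export
select_controls_random <- function(test_gene, nodes, n = 99L, seed = NULL,
                                   exclude = character()) {
  pool <- setdiff(nodes, c(test_gene, exclude))
  if (length(pool) < n)
    stop_data("network has only ", length(pool), " eligible control genes; ", n, " requested")
  with_local_seed(seed, sort(sample(pool, n)))
}

#' Artificial-linkage-interval control genes
#'
#' Selects the `n` in-network genes genomically nearest to the test gene
#' (absolute midpoint distance on the same chromosome), mimicking a mapped
#' candidate interval. Distance ties break by gene id. If the chromosome
#' holds fewer than `n` other genes, the remaining slots are filled by
#' random in-network genes (reported).
#'
#' @inheritParams select_controls_random
#' @param positions a `gene_positions` table covering the test gene.
#' @param quiet suppress the random-fill message.
#' @return Character vector of `n` control genes.
#' @export
select_controls_ali <- function(test_gene, positions, nodes, n = 99L, seed = NULL,
                                exclude = character(), quiet = FALSE) {
  stopifnot(inherits(positions, "gene_positions"))
  row <- positions[positions$gene == test_gene, , drop = FALSE]
  if (nrow(row) == 0L)
    stop_data("test gene '", test_gene, "' has no position record")
  cand <- positions[positions$chrom == row$chrom &
                    positions$gene %in% nodes &
                    !(positions$gene %in% c(test_gene, exclude)), , drop = FALSE]
  cand$dist <- abs(cand$mid - row$mid)
  cand <- cand[order(cand$dist, cand$gene), , drop = FALSE]
  picked <- utils::head(cand$gene, n)
  if (length(picked) < n) {
    short <- n - length(picked)
    if (!quiet)
      message("select_controls_ali: chromosome ", row$chrom, " has only ",
              length(picked), " eligible genes; filling ", short, " slot(s) at random")
    pool <- setdiff(nodes, c(test_gene, exclude, picked))
    if (length(pool) < short)
      stop_data("not enough genes in the network to fill the control set")
    picked <- c(picked, with_local_seed(seed, sort(sample(pool, short))))
  }
  picked
}

#' ROC curve and AUC from rank ratios
#'
#' Sweeps a rank-ratio threshold over a regular grid. At each threshold t,
#' sensitivity is the fraction of held-out disease genes with rank ratio
#' <= t and specificity is the fraction of control genes with rank ratio
#' > t. The AUC is the trapezoidal area under sensitivity versus
#' (1 - specificity), whose endpoints (0, 0) and (1, 1) arise at t = 0 and
#' t = 1.
#'
#' @param case_ratios rank ratios of the held-out disease genes (in (0, 1]).
#' @param control_ratios rank ratios of the control genes.
#' @param step threshold grid spacing (default 0.01).
#' @return A list with `roc` (data frame `threshold`, `sensitivity`,
#'   `specificity`) and `auc`.
#' @export
roc_from_rank_ratios <- function(case_ratios, control_ratios, step = 0.01) {
  if (length(case_ratios) == 0L) stop_data("no validation cases")
  if (!(step > 0 && step <= 1)) stop_data("step must be in (0, 1]")
  thresholds <- seq(0, 1, by = step)
  if (thresholds[length(thresholds)] < 1) thresholds <- c(thresholds, 1)
  sens <- vapply(thresholds, function(t) mean(case_ratios <= t), 0)
  spec <- vapply(thresholds, function(t) mean(control_ratios > t), 0)
  x <- 1 - spec
  o <- order(x, sens)
  auc <- sum(diff(x[o]) * (sens[o][-1] + sens[o][-length(sens)]) / 2)
  list(roc = data.frame(threshold = thresholds, sensitivity = sens, specificity = spec),
       auc = auc)
}

#' Precision-recall curve from scored, labelled candidates
#'
#' Sweeps a decision threshold over the observed scores (descending; tied
#' scores are called together). Precision is the fraction of true disease
#' genes among the called candidates; recall is the fraction of all true
#' disease genes called.
#'
#' @param scores numeric candidate scores (higher = stronger call).
#' @param labels logical, `TRUE` for true disease genes.
#' @return Data frame with columns `score`, `recall`, `precision`, one row
#'   per distinct score threshold.
#' @export
pr_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop_data("scores and labels differ in length")
  labels <- as.logical(labels)
  if (!any(labels)) stop_data("no positive (disease gene) labels")
  if (all(labels)) stop_data("no negative (control) labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l)
  calls <- seq_along(l)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)  # call all tied scores together
  data.frame(score = s[last_of_tie],
             recall = tp[last_of_tie] / sum(labels),
             precision = tp[last_of_tie] / calls[last_of_tie])
}

#' Leave-one-out cross-validation of a prioritization method
#'
#' For every association (d, g) of a disease with at least two genes, the
#' link is removed (the gene stays in the network), the disease's start
#' distribution and profile are rebuilt from the remaining links, and g is
#' ranked against `n_controls` control genes. The held-out gene's rank
#' ratio is rank / (n_controls + 1). Aggregates precision at rank one
#' (PRE), the rank-ratio ROC/AUC, and a pooled precision-recall curve
#' (scoring candidates by negative rank ratio).
#'
#' @inheritParams rank_candidates
#' @param control_mode `"random"` or `"ali"` (artificial linkage interval;
#'   requires `positions`).
#' @param n_controls controls per case (default 99).
#' @param positions a `gene_positions` table (required for ALI controls; a
#'   test gene without a position record is skipped with a warning).
#' @param step rank-ratio threshold grid spacing for the ROC sweep.
#' @param seed base seed; each case derives its own control-sampling seed
#'   from it, so results are reproducible end to end.
#' @param strict also remove the held-out gene from similar diseases' start
#'   vectors (leakage analysis); by default only the (d, g) link is removed.
#' @return An object of class `cv_result`: list with `cases` (data frame
#'   `disease`, `gene`, `rank`, `rank_ratio`), `control_ratios`, `pre_count`,
#'   `pre_prop`, `roc`, `auc`, `pr`, `method`, `params`, `n_skipped`.
#' @export
run_loocv <- function(map, sims = NULL, transition,
                      method = c("dp_lcc", "dp_cos", "rwr", "prince"),
                      control_mode = c("random", "ali"), n_controls = 99L,
                      positions = NULL, gamma = 0.25, lambda = 0.5,
                      threshold = 0.3, tol = 1e-6, max_iter = 10000L,
                      step = 0.01, seed = NULL, strict = FALSE,
                      gene_profiles = NULL) {
  method <- match.arg(method)
  control_mode <- match.arg(control_mode)
  if (control_mode == "ali" && is.null(positions))
    stop_data("ALI control mode requires gene positions")
  if (n_controls < 1L) stop_data("n_controls must be >= 1")
  eligible <- names(map)[vapply(map, function(g) length(intersect(g, transition$nodes)), 1L) >= 2L]
  if (length(eligible) == 0L) stop_data("no disease with >= 2 in-network genes to validate")
  if (method %in% c("dp_lcc", "dp_cos") && is.null(gene_profiles))
    gene_profiles <- all_gene_profiles(transition, gamma = gamma, tol = tol,
                                       max_iter = max_iter)
  rows <- list()
  control_ratio_list <- list()
  pooled_scores <- list()
  pooled_labels <- list()
  n_skipped <- 0L
  case_id <- 0L
  for (d in eligible) {
    genes <- intersect(map[[d]], transition$nodes)
    for (g in genes) {
      case_id <- case_id + 1L
      train <- map
      train[[d]] <- setdiff(genes, g)
      # genes co-associated with d cannot serve as controls; if that leaves
      # too small a pool (tiny fixtures) relax to excluding the test gene only
      pick <- function(exclude) {
        if (control_mode == "random")
          select_controls_random(g, transition$nodes, n = n_controls,
                                 seed = derive_seed(seed, case_id), exclude = exclude)
        else
          select_controls_ali(g, positions, transition$nodes, n = n_controls,
                              seed = derive_seed(seed, case_id), exclude = exclude,
                              quiet = TRUE)
      }
      controls <- tryCatch(pick(setdiff(genes, g)),
                           error = function(e) tryCatch(pick(character()),
                                                        error = function(e2) e2))
      if (inherits(controls, "error")) {
        warning("run_loocv: skipping case (", d, ", ", g, "): ",
                conditionMessage(controls))
        n_skipped <- n_skipped + 1L
        next
      }
      candidates <- c(g, controls)
      res <- suppressMessages(rank_candidates(
        d, candidates, method, map = train, sims = sims, transition = transition,
        gene_profiles = gene_profiles, gamma = gamma, lambda = lambda,
        threshold = threshold, tol = tol, max_iter = max_iter,
        exclude_gene = if (strict) g else NULL))
      size <- length(candidates)
      rk <- res$rank[match(candidates, res$gene)]
      g_rank <- rk[1L]
      rows[[case_id]] <- data.frame(disease = d, gene = g, rank = g_rank,
                                    rank_ratio = g_rank / size,
                                    stringsAsFactors = FALSE)
      control_ratio_list[[case_id]] <- rk[-1L] / size
      pooled_scores[[case_id]] <- -rk / size
      pooled_labels[[case_id]] <- c(TRUE, rep(FALSE, size - 1L))
    }
  }
  cases <- do.call(rbind, rows)
  if (is.null(cases) || nrow(cases) == 0L) stop_data("no evaluable cross-validation cases")
  control_ratios <- unlist(control_ratio_list, use.names = FALSE)
  roc <- roc_from_rank_ratios(cases$rank_ratio, control_ratios, step = step)
  pr <- pr_curve(unlist(pooled_scores, use.names = FALSE),
                 unlist(pooled_labels, use.names = FALSE))
  structure(list(
    cases = cases,
    control_ratios = control_ratios,
    pre_count = sum(cases$rank == 1L),
    pre_prop = mean(cases$rank == 1L),
    roc = roc$roc, auc = roc$auc, pr = pr,
    method = method,
    params = list(control_mode = control_mode, n_controls = n_controls,
                  gamma = gamma, lambda = lambda, threshold = threshold,
                  tol = tol, step = step, seed = seed, strict = strict),
    n_skipped = n_skipped
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("Leave-one-out cross-validation (", toupper(x$method), ", ",
      x$params$control_mode, " controls)\n", sep = "")
  cat("Cases:", nrow(x$cases), if (x$n_skipped) paste0("(", x$n_skipped, " skipped)"), "\n")
  cat(sprintf("PRE: %d/%d (%.4f)   AUC: %.4f\n",
              x$pre_count, nrow(x$cases), x$pre_prop, x$auc))
  invisible(x)
}

#' @export
summary.cv_result <- function(object, ...) {
  print(object)
  cat("Rank-ratio quartiles of held-out genes:\n")
  print(stats::quantile(object$cases$rank_ratio))
  invisible(object)
}

#' @export
plot.cv_result <- function(x, ...) {
  plot(1 - x$roc$specificity, x$roc$sensitivity, type = "l",
       xlab = "1 - specificity", ylab = "sensitivity",
       main = sprintf("ROC (%s), AUC = %.3f", toupper(x$method), x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Sweep restart and phenotype-weight parameters
#'
#' Runs [run_loocv()] on a grid of restart probabilities and phenotype
#' weights for each method, reusing the gene-profile matrix across methods
#' and weights at a fixed restart value. The component-score baselines do
#' not depend on the phenotype weight but are run at every grid point so
#' the table is complete.
#'
#' @inheritParams run_loocv
#' @param gammas,lambdas numeric grids.
#' @param methods methods to evaluate.
#' @return Data frame with columns `method`, `gamma`, `lambda`,
#'   `pre_count`, `pre_prop`, `auc`.
#' @export
parameter_sweep <- function(map, sims = NULL, transition,
                            gammas = c(0.1, 0.25, 0.5), lambdas = c(0, 0.5, 1),
                            methods = c("dp_lcc", "dp_cos", "rwr", "prince"),
                            control_mode = "random", n_controls = 99L,
                            positions = NULL, threshold = 0.3, tol = 1e-6,
                            step = 0.01, seed = NULL) {
  if (!length(gammas) || !length(lambdas) || !length(methods))
    stop_data("empty sweep grid")
  out <- list()
  k <- 0L
  for (gamma in gammas) {
    profiles <- if (any(methods %in% c("dp_lcc", "dp_cos")))
      all_gene_profiles(transition, gamma = gamma, tol = tol) else NULL
    for (lambda in lambdas) {
      for (m in methods) {
        cv <- run_loocv(map, sims, transition, method = m,
                        control_mode = control_mode, n_controls = n_controls,
                        positions = positions, gamma = gamma, lambda = lambda,
                        threshold = threshold, tol = tol, step = step,
                        seed = seed, gene_profiles = profiles)
        k <- k + 1L
        out[[k]] <- data.frame(method = m, gamma = gamma, lambda = lambda,
                               pre_count = cv$pre_count, pre_prop = cv$pre_prop,
                               auc = cv$auc, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
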