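test_that("random control selection is reproducible and never includes the test gene", {
  nodes <- sprintf("g%03d", 1:100)
  forced <- select_controls_random("g001", nodes, n = 99, seed = 1)
  expect_setequal(forced, setdiff(nodes, "g001"))      # forced set, any seed
  expect_identical(forced, select_controls_random("g001", nodes, n = 99, seed = 999))

  a <- select_controls_random("g005", nodes, n = 20, seed = 7)
  expect_identical(a, select_controls_random("g005", nodes, n = 20, seed = 7))
  expect_false("g005" %in% a)
  expect_error(select_controls_random("g001", nodes[1:10], n = 99), "eligible")
})

test_that("linkage-interval controls pick nearest midpoints with documented tie and fill rules", {
  bed <- write_tsv_lines(c(sprintf("chr1\t%d\t%d\tg%d", c(5, 15, 25, 35, 45),
                                   c(15, 25, 35, 45, 55), 1:5),
                           "chr2\t100\t200\tg6"))
  pos <- load_gene_positions(bed)  # midpoints 10, 20, 30, 40, 50 on chr1
  nodes <- sprintf("g%d", 1:6)
  expect_setequal(select_controls_ali("g3", pos, nodes, n = 2), c("g2", "g4"))
  # equidistant pair: lexicographically smaller gene id wins
  expect_identical(select_controls_ali("g3", pos, nodes, n = 1), "g2")
  # short chromosome: positional picks then random fill, reported
  expect_message(filled <- select_controls_ali("g6", pos, nodes, n = 3, seed = 1),
                 "filling")
  expect_length(filled, 3)
  expect_false("g6" %in% filled)
  expect_error(select_controls_ali("gX", pos, nodes, n = 2), "no position")
})

test_that("the rank-ratio ROC sweep matches hand-enumerated curves", {
  # every held-out gene at rank 1 of 100, controls at 2..100
  controls <- (2:100) / 100
  perfect <- roc_from_rank_ratios(rep(0.01, 5), rep(controls, 5), step = 0.01)
  expect_equal(perfect$roc$sensitivity[perfect$roc$threshold == 0.01], 1)
  expect_gte(perfect$auc, 0.99)

  # single case at ratio 0.5: sensitivity steps from 0 to 1 at threshold 0.5
  single <- roc_from_rank_ratios(0.5, (c(1:49, 51:100)) / 100, step = 0.01)
  expect_equal(single$roc$sensitivity[single$roc$threshold < 0.5], rep(0, 50))
  expect_equal(single$roc$sensitivity[single$roc$threshold >= 0.5], rep(1, 51))

  # curve is monotone in both coordinates and anchored at (0,0) and (1,1)
  expect_true(all(diff(perfect$roc$sensitivity) >= 0))
  expect_true(all(diff(1 - perfect$roc$specificity) >= 0))
  expect_equal(perfect$roc$sensitivity[1], 0)
  expect_equal(utils::tail(perfect$roc$specificity, 1), 0)
})

test_that("uniformly random ranks give chance-level AUC", {
  set.seed(123)
  n_cases <- 500
  ranks <- sample(1:100, n_cases, replace = TRUE)
  case_ratios <- ranks / 100
  control_ratios <- unlist(lapply(ranks, function(r) setdiff(1:100, r) / 100))
  out <- roc_from_rank_ratios(case_ratios, control_ratios)
  expect_equal(out$auc, 0.5, tolerance = 0.05)
  expect_equal(mean(case_ratios), 0.5, tolerance = 0.05)
})

test_that("precision-recall sweep matches hand enumeration", {
  # scores 0.9(+), 0.8(-), 0.7(+)
  pr <- pr_curve(c(0.9, 0.8, 0.7), c(TRUE, FALSE, TRUE))
  expect_equal(pr$precision[pr$recall == 1], 2 / 3)
  expect_equal(pr$precision[1], 1)

  # perfect separation: precision 1 up to full recall
  pr2 <- pr_curve(c(5, 4, 1, 0.5), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(pr2$precision[1:2], c(1, 1))
  expect_equal(pr2$recall[2], 1)

  # all scores tied: one call of everything, precision = prevalence
  pr3 <- pr_curve(rep(1, 10), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_identical(nrow(pr3), 1L)
  expect_equal(pr3$precision, 0.3)
  expect_equal(pr3$recall, 1)

  expect_error(pr_curve(1:3, c(FALSE, FALSE, FALSE)), "no positive")
  expect_error(pr_curve(1:3, c(TRUE, TRUE, TRUE)), "no negative")
})

test_that("loocv bookkeeping: rank ratios, PRE identities, and determinism", {
  b <- generate_bundle(synthetic_config(n_genes = 80, n_diseases = 6,
                                        n_phenotype_clusters = 2, seed = 11))
  tm <- build_transition_matrix(b$network)
  cv <- suppressWarnings(run_loocv(b$map, b$sims, tm, method = "dp_lcc",
                                   n_controls = 30, seed = 5))
  expect_equal(cv$cases$rank_ratio, cv$cases$rank / 31)
  expect_true(all(cv$cases$rank_ratio > 0 & cv$cases$rank_ratio <= 1))
  expect_identical(cv$pre_count, sum(cv$cases$rank == 1L))
  expect_equal(cv$pre_prop, cv$pre_count / nrow(cv$cases))
  expect_gte(cv$auc, 0); expect_lte(cv$auc, 1)

  cv2 <- suppressWarnings(run_loocv(b$map, b$sims, tm, method = "dp_lcc",
                                    n_controls = 30, seed = 5))
  expect_identical(cv$cases, cv2$cases)
  expect_identical(cv$auc, cv2$auc)

  # during validation the held-out link is removed but the gene stays a node,
  # so it can still be ranked; candidate sets have size n_controls + 1
  expect_length(cv$control_ratios, 30L * nrow(cv$cases))
})

test_that("loocv works with linkage-interval controls", {
  b <- generate_bundle(synthetic_config(n_genes = 80, n_diseases = 6,
                                        n_phenotype_clusters = 2, seed = 12))
  tm <- build_transition_matrix(b$network)
  cv <- suppressWarnings(run_loocv(b$map, b$sims, tm, method = "rwr",
                                   control_mode = "ali", positions = b$positions,
                                   n_controls = 15, seed = 5))
  expect_gt(nrow(cv$cases), 0)
  expect_true(all(cv$cases$rank >= 1 & cv$cases$rank <= 16))
})

test_that("a perfect and a random scorer bracket the loocv metrics", {
  # two disconnected triangle modules: the walk cannot reach the other
  # module, so the held-out gene always outranks its cross-module controls
  tm <- tm_from_edges(c("a", "b"), c("b", "c"), c("a", "c"),
                      c("d", "e"), c("e", "f"), c("d", "f"))
  map <- structure(list(D1 = c("a", "b", "c"), D2 = c("d", "e", "f")),
                   class = "disease_gene_map")
  cv <- run_loocv(map, NULL, tm, method = "rwr", n_controls = 2,
                  gamma = 0.5, seed = 1)
  expect_equal(cv$pre_prop, 1)
  expect_gte(cv$auc, 0.99)
})

test_that("the parameter sweep emits one row per grid point per method, deterministically", {
  b <- generate_bundle(synthetic_config(n_genes = 60, n_diseases = 4,
                                        n_phenotype_clusters = 2, seed = 13))
  tm <- build_transition_matrix(b$network)
  tab <- suppressWarnings(parameter_sweep(b$map, b$sims, tm,
                                          gammas = c(0.25, 0.5), lambdas = c(0, 0.5),
                                          methods = c("dp_lcc", "rwr"),
                                          n_controls = 20, seed = 3))
  expect_identical(nrow(tab), 8L)
  expect_identical(colnames(tab), c("method", "gamma", "lambda", "pre_count",
                                    "pre_prop", "auc"))
  tab2 <- suppressWarnings(parameter_sweep(b$map, b$sims, tm,
                                           gammas = c(0.25, 0.5), lambdas = c(0, 0.5),
                                           methods = c("dp_lcc", "rwr"),
                                           n_controls = 20, seed = 3))
  expect_identical(tab, tab2)
  # the rwr rows must not react to lambda (component score ignores it)
  rwr_rows <- tab[tab$method == "rwr", ]
  expect_identical(rwr_rows$auc[rwr_rows$lambda == 0], rwr_rows$auc[rwr_rows$lambda == 0.5])
})

test_that("pessimistic tie handling can only lower precision relative to optimistic ties", {
  set.seed(9)
  for (i in 1:20) {
    scores <- sample(round(runif(10), 1), 10, replace = TRUE)  # force ties
    pess <- rep(10L, 10); ok <- !is.na(scores)
    pess[ok] <- rank(-scores[ok], ties.method = "max")
    opt <- rank(-scores, ties.method = "min")
    expect_true(all(pess >= opt))
  }
})
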