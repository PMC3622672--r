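test_that("similarity measures reproduce direct evaluations and handle degeneracy", {
  expect_equal(lcc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(lcc(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(lcc(c(1, 5, 2), 3 * c(1, 5, 2) + 7), 1)  # affine invariance
  expect_true(is.na(lcc(c(1, 1, 1), c(1, 2, 3))))
  expect_error(lcc(1:3, 1:4), "length")

  expect_equal(cosine_sim(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_equal(cosine_sim(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_sim(c(2, 3), c(2, 3)), 1)
  expect_true(is.na(cosine_sim(c(0, 0), c(1, 1))))
})

test_that("similarity measures are symmetric, bounded, and scale-invariant on random profiles", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(20); b <- runif(20)
    expect_equal(lcc(a, b), lcc(b, a))
    expect_equal(cosine_sim(a, b), cosine_sim(b, a))
    expect_lte(abs(lcc(a, b)), 1)
    expect_gte(cosine_sim(a, b), 0)
    expect_lte(cosine_sim(a, b), 1 + 1e-12)
    s <- runif(1, 0.1, 10)
    expect_equal(lcc(s * a, b), lcc(a, b))
    expect_equal(cosine_sim(a, s * b), cosine_sim(a, b))
  }
})

test_that("the PRINCE logistic prior matches its stated parameterization", {
  L <- function(x, c = -15, d = log(9999)) 1 / (1 + exp(c * x + d))
  expect_equal(L(0), 1e-4)
  expect_equal(L(1), 1 / (1 + 9999 * exp(-15)))

  # 4-node fixture, no similar disease: own genes share the prior equally,
  # everyone else sits on the logistic floor
  tm <- tm_from_edges(c("a", "b"), c("b", "c"), c("c", "d"))
  map <- structure(list(D1 = c("a", "b")), class = "disease_gene_map")
  prior <- prince_prior("D1", map, sims = NULL, transition = tm)
  expect_equal(sum(prior), 1)
  expect_equal(prior[["a"]], prior[["b"]])
  expect_equal(prior[["c"]], prior[["d"]])
  expect_equal(prior[["a"]] / prior[["c"]], L(1) / L(0))

  # a similar disease lifts its genes by the logistic of the similarity
  sims <- sims_from_lines("D1\tD2\t0.6")
  map$D2 <- "c"
  prior2 <- prince_prior("D1", map, sims, tm)
  expect_equal(prior2[["c"]] / prior2[["d"]], L(0.6) / L(0))
})

test_that("rwr baseline scores are stationary components of the unweighted disease walk", {
  tm <- random_tm(20, p = 0.2, seed = 4)
  map <- structure(list(D = tm$nodes[c(1, 2)]), class = "disease_gene_map")
  res <- rank_candidates("D", tm$nodes, "rwr", map = map, transition = tm,
                         gamma = 0.5, tol = 1e-10)
  expect_equal(sum(res$score), 1, tolerance = 1e-9)  # conservation
  known <- res$score[match(tm$nodes[c(1, 2)], res$gene)]
  expect_true(all(known > median(res$score)))
  # gamma = 1: the fixed point is the start vector itself
  res1 <- rank_candidates("D", tm$nodes, "rwr", map = map, transition = tm, gamma = 1)
  expect_equal(sort(unique(round(res1$score, 12))), c(0, 0.5))
})

test_that("candidates are ranked descending with pessimistic ties and undefined scores last", {
  tm <- two_node_tm()
  map <- structure(list(D = "a"), class = "disease_gene_map")
  # gamma = 1 RWR: score a = 1, b = 0
  res <- rank_candidates("D", c("a", "b"), "rwr", map = map, transition = tm, gamma = 1)
  expect_identical(res$gene[res$rank == 1], "a")

  # tie group takes the worst rank of the group
  tm3 <- tm_from_edges(c("c", "x"), c("c", "y"), c("c", "z"))
  map3 <- structure(list(D = "c"), class = "disease_gene_map")
  res3 <- rank_candidates("D", c("x", "y", "z"), "rwr", map = map3,
                          transition = tm3, gamma = 0.5, tol = 1e-12)
  expect_identical(res3$rank, rep(3L, 3))

  expect_error(rank_candidates("D", character(), "rwr", map = map, transition = tm),
               "empty")
  expect_error(rank_candidates("D", "nope", "rwr", map = map, transition = tm),
               "not in the network")
})

test_that("profile-similarity rankings are invariant to rescaling the disease profile", {
  tm <- random_tm(30, p = 0.15, seed = 8)
  profs <- all_gene_profiles(tm, gamma = 0.25, tol = 1e-10)
  dprof <- rwr(tm, disease_initial_distribution(
    "D", structure(list(D = tm$nodes[1:3]), class = "disease_gene_map"), tm),
    gamma = 0.25, tol = 1e-10)$values
  cand <- tm$nodes[4:30]
  for (f in list(lcc, cosine_sim)) {
    s1 <- vapply(cand, function(g) f(dprof, profs[, g]), 0)
    s2 <- vapply(cand, function(g) f(dprof * 4.2, profs[, g]), 0)
    expect_equal(order(-s1), order(-s2))
    expect_equal(s1, s2)
  }
})

test_that("genome-wide ranking excludes known genes and honours top-k", {
  b <- generate_bundle(synthetic_config(n_genes = 60, n_diseases = 4,
                                        n_phenotype_clusters = 2, seed = 5))
  tm <- build_transition_matrix(b$network)
  d <- names(b$map)[1]
  res <- rank_genome_wide(d, "dp_lcc", map = b$map, sims = b$sims,
                          transition = tm, top_k = 10)
  expect_identical(nrow(res), 10L)
  expect_length(intersect(res$gene, b$map[[d]]), 0)
  full <- rank_genome_wide(d, "dp_lcc", map = b$map, sims = b$sims, transition = tm)
  expect_identical(nrow(full), length(tm$nodes) - length(b$map[[d]]))
  expect_true(all(diff(full$score[!is.na(full$score)]) <= 1e-12))
})

test_that("a held-out module member ranks highly genome-wide on a planted bundle", {
  b <- generate_bundle(synthetic_config(n_genes = 150, n_diseases = 10,
                                        module_cohesion = 0.9, seed = 21))
  tm <- build_transition_matrix(b$network)
  profs <- all_gene_profiles(tm, gamma = 0.25)
  top_decile <- 0L; total <- 0L
  for (d in names(b$map)[1:5]) {
    genes <- b$map[[d]]
    if (length(genes) < 2) next
    g <- genes[1]
    train <- b$map; train[[d]] <- setdiff(genes, g)
    res <- rank_genome_wide(d, "dp_lcc", map = train, sims = b$sims,
                            transition = tm, gene_profiles = profs)
    total <- total + 1L
    if (res$rank[match(g, res$gene)] <= ceiling(nrow(res) / 10)) top_decile <- top_decile + 1L
  }
  expect_gt(top_decile / total, 0.5)
})
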