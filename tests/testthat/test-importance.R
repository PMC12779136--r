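# Multi-level importance: reaction, pathway, gene/family tiers,
# correlations, clustering, and activity summaries.

simple_fm <- function(vals, labels) {
  structure(
    list(values = vals,
         samples = tibble::tibble(
           sample_id = rownames(vals),
           label = labels, origin = "real"
         ),
         feature_ids = colnames(vals)),
    class = "feature_matrix"
  )
}

test_that("importances are normalized and find a planted feature", {
  set.seed(1)
  n <- 60
  lab <- rep(c("healthy", "cancer"), each = n / 2)
  found <- 0
  for (s in 1:5) {
    set.seed(s)
    vals <- matrix(stats::rnorm(n * 8), n, 8)
    vals[lab == "cancer", 3] <- vals[lab == "cancer", 3] + 4
    colnames(vals) <- paste0("R", 1:8)
    rownames(vals) <- sprintf("s%02d", 1:n)
    fm <- simple_fm(vals, lab)
    fit <- train_rf(fm, rf_config(n_trees = 300, seed = s))
    ri <- reaction_importance(fit)
    expect_equal(sum(ri$importance), 1, tolerance = 1e-9)
    expect_true(all(ri$importance >= 0))
    found <- found + (ri$reaction_id[1] == "R3")
  }
  expect_equal(found, 5)
})

test_that("spearman against the class hits the binary-target maximum", {
  # perfect separation at n = 10: the maximum attainable |rho| for a
  # two-valued target, computed by the ranking oracle
  n1 <- 5
  y <- c(rep("healthy", n1), rep("cancer", n1))
  x_perfect <- c(1:5, 11:15)  # strictly higher in all cancer samples
  vals <- cbind(Rp = x_perfect, Rc = rep(2, 10))
  rownames(vals) <- sprintf("s%02d", 1:10)
  fm <- simple_fm(vals, y)
  rho <- spearman_vs_state(fm, positive_class = "cancer")
  oracle_max <- stats::cor(rank(x_perfect),
                           rank(c(rep(0, n1), rep(1, n1))))
  expect_equal(rho$rho[rho$reaction_id == "Rp"], oracle_max)
  # finite-n maximum for a balanced binary target:
  # sqrt(3 n^2 / (4 (n^2 - 1))), tending to sqrt(3)/2 as n grows
  expect_equal(oracle_max, sqrt(3 * 100 / (4 * 99)), tolerance = 1e-12)
  # constant column: rho 0 with flag
  expect_equal(rho$rho[rho$reaction_id == "Rc"], 0)
  expect_true(rho$constant[rho$reaction_id == "Rc"])

  # label-independent feature stays small at n = 80
  set.seed(2)
  vals2 <- matrix(stats::rnorm(80), 80, 1,
                  dimnames = list(sprintf("t%02d", 1:80), "Rx"))
  fm2 <- simple_fm(vals2, rep(c("healthy", "cancer"), 40))
  rho2 <- spearman_vs_state(fm2, "cancer")
  expect_lt(abs(rho2$rho), 0.4)
})

test_that("pathway shares follow within-pathway averaging", {
  net <- build_toy_network()
  rimp <- tibble::tibble(
    reaction_id = c("HSD1", "HSD2", "HSD3", "FAt"),
    importance = c(0.02, 0.04, 0.03, 0.07)
  )
  pw <- pathway_importance(rimp, net)
  # singleton pathway mean equals the reaction importance
  expect_equal(pw$mean_importance[pw$pathway == "Transport reactions"],
               0.07)
  expect_equal(pw$mean_importance[pw$pathway ==
                                    "Heparan sulfate degradation"], 0.03)
  expect_equal(sum(pw$share_pct), 100, tolerance = 1e-9)
  # two-pathway normalization: means 0.03 and 0.01 -> 75% / 25%
  rimp2 <- tibble::tibble(reaction_id = c("HSD1", "FAt"),
                          importance = c(0.03, 0.01))
  pw2 <- pathway_importance(rimp2, net)
  expect_equal(sort(pw2$share_pct), c(25, 75))
})

test_that("sigmoid gene weighting matches its closed form", {
  net <- build_toy_network()
  rimp <- tibble::tibble(
    reaction_id = net$reactions$id,
    importance = rep(1 / nrow(net$reactions), nrow(net$reactions))
  )
  gi <- gene_importance(rimp, net, sigmoid_k = 1, sigmoid_n0 = 1)
  # every toy gene appears in exactly one reaction: weight at the
  # midpoint is 0.5 + 0.5 * 0.5 = 0.75 exactly
  expect_true(all(gi$genes$n_reactions == 1))
  expect_true(all(gi$genes$weight == 0.75))
  # raw 0 implies score 0 regardless of count
  rimp0 <- rimp
  rimp0$importance <- 0
  gi0 <- gene_importance(rimp0, net, sigmoid_n0 = 1)
  expect_true(all(gi0$genes$score == 0))
  # monotonicity in the reaction count at fixed raw score
  w <- function(n, n0 = 3, k = 1) 0.5 + 0.5 * stats::plogis(k * (n - n0))
  expect_gt(w(20), w(1))
})

test_that("quartile tiers follow the type-7 convention with ties upward", {
  sc <- tibble::tibble(family = paste0("f", 1:15), score = 1:15)
  tiers <- tier_genes(sc, top_k = 15)
  vh <- tiers$family[tiers$tier == "Very High"]
  # Q3 of 1..15 (type 7) = 11.5, so Very High = scores 12..15
  expect_setequal(vh, paste0("f", 12:15))

  # all-equal scores: ties promoted to the top tier
  sc2 <- tibble::tibble(family = paste0("f", 1:6), score = 2)
  expect_true(all(tier_genes(sc2, top_k = 6)$tier == "Very High"))

  # top_k = 4 with scores 4,3,2,1: one family per tier
  sc3 <- tibble::tibble(family = paste0("f", 1:4), score = 4:1)
  t3 <- tier_genes(sc3, top_k = 4)
  expect_equal(as.character(t3$tier),
               c("Very High", "High", "Medium", "Low"))
  expect_error(tier_genes(sc3[1:3, ]), "at least 4")
})

test_that("clustering merges correlated fluxes first, order-invariantly", {
  set.seed(3)
  base <- stats::rnorm(30)
  vals <- cbind(Ra = base + stats::rnorm(30, 0, 0.01),
                Rb = base + stats::rnorm(30, 0, 0.01),
                Rc = stats::rnorm(30))
  rownames(vals) <- sprintf("s%02d", 1:30)
  fm <- simple_fm(vals, rep(c("healthy", "cancer"), 15))
  rimp <- tibble::tibble(reaction_id = c("Ra", "Rb", "Rc"),
                         importance = c(0.5, 0.3, 0.2))
  net <- build_toy_network()
  cl <- cluster_reactions(fm, rimp, net, top_n = 3)
  expect_equal(length(cl$phylo$tip.label), 3)
  expect_match(cl$newick, "Ra")
  # the correlated pair merges before the singleton joins
  first_merge <- cl$hclust$merge[1, ]
  expect_setequal(cl$hclust$labels[-first_merge], c("Ra", "Rb"))
  expect_lt(cl$hclust$height[1], 0.05)

  # column permutation: same tree topology
  fmp <- fm
  fmp$values <- fm$values[, c(3, 1, 2)]
  fmp$feature_ids <- fm$feature_ids[c(3, 1, 2)]
  cl2 <- cluster_reactions(fmp, rimp, net, top_n = 3)
  ids <- c("Ra", "Rb", "Rc")
  expect_equal(as.matrix(stats::cophenetic(cl2$hclust))[ids, ids],
               as.matrix(stats::cophenetic(cl$hclust))[ids, ids],
               tolerance = 1e-12)
})

test_that("rolling windows truncate at the edge as specified", {
  vals <- matrix(c(0, 0, 5, 5, 5), 5, 1,
                 dimnames = list(sprintf("s%d", 1:5), "R"))
  fm <- simple_fm(vals, rep("cancer", 5))
  act <- flux_activity_summary(fm, "R", window = 2)
  expect_equal(act$activity_ratio, c(0, 0, 0.5, 1, 1))
  expect_equal(act$rolling_mean, c(0, 0, 2.5, 5, 5))

  # all-zero and all-active limiting cases
  fm0 <- simple_fm(matrix(0, 5, 1, dimnames = list(rownames(vals), "R")),
                   rep("cancer", 5))
  expect_true(all(flux_activity_summary(fm0, "R",
                                        window = 2)$activity_ratio == 0))
  fm1 <- simple_fm(matrix(3, 5, 1, dimnames = list(rownames(vals), "R")),
                   rep("cancer", 5))
  expect_true(all(flux_activity_summary(fm1, "R",
                                        window = 2)$activity_ratio == 1))
  expect_error(flux_activity_summary(fm, "nope"), "unknown")
})
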