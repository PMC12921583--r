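test_that("mccv result is internally consistent and reproducible", {
  tab <- make_table(10, k = 2, sep = 2, seed = 3)
  r1 <- mccv(tab, n_iter = 25, seed = 11)
  r2 <- mccv(tab, n_iter = 25, seed = 11)
  expect_identical(r1$accuracies, r2$accuracies)
  expect_identical(r1$importances, r2$importances)
  expect_length(r1$accuracies, 25)
  expect_true(all(r1$accuracies >= 0 & r1$accuracies <= 1))
  expect_lte(r1$min_acc, r1$mean_acc)
  expect_lte(r1$mean_acc, r1$max_acc)
  expect_equal(r1$mean_acc, mean(r1$accuracies))
  expect_true(all(abs(rowSums(r1$importances) - 1) < 1e-9))
  expect_true(all(r1$oob_errors >= 0 & r1$oob_errors <= 1))
})

test_that("a fully separated table classifies perfectly", {
  tab <- make_table(10, k = 3, sep = 50, seed = 4)
  r <- mccv(tab, n_iter = 20, seed = 2)
  expect_equal(r$mean_acc, 1.0)
  # the informative feature dominates the importances
  expect_equal(names(which.max(r$mean_importance)), "x1")
})

test_that("label-permuted data classifies at chance", {
  accs <- vapply(1:4, function(s) {
    tab <- make_table(12, k = 2, p = 3, sep = 0, seed = s)
    mccv(tab, n_iter = 25, forest_settings = list(ntree = 100),
         seed = s)$mean_acc
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("degenerate classification requests are rejected", {
  tab <- make_table(10, k = 2)
  expect_error(mccv(tab, test_fraction = 0), "test_fraction")
  expect_error(mccv(tab, test_fraction = 0.7), "test_fraction")
  one <- tab[tab$class == "c1", ]
  one$class <- droplevels(one$class)
  expect_error(mccv(rbind(tab[1, ], tab[1, ])[1, ], n_iter = 2))
  expect_error(mccv(tab, feature_subset = "nope"), "unknown features")
})

test_that("umap embedding is deterministic and separates separable classes", {
  tab <- make_table(15, k = 3, sep = 8, seed = 6)
  suppressWarnings({
    e1 <- embed_umap(tab, seed = 5)
    e2 <- embed_umap(tab, seed = 5)
  })
  expect_identical(e1$coords, e2$coords)
  expect_equal(nrow(e1$coords), nrow(tab))
  # between-class centroid spread exceeds within-class spread
  cent <- apply(e1$coords, 2, tapply, e1$labels, mean)
  within <- mean(sqrt(rowSums((e1$coords - cent[e1$labels, ])^2)))
  between <- mean(dist(cent))
  expect_gt(between, within)
  expect_identical(e1$settings$min_dist, 0)
})

test_that("umap clamps the neighbour count and records it", {
  tab <- make_table(5, k = 2, sep = 4, seed = 2)
  expect_warning(e <- embed_umap(tab, n_neighbors = 50, seed = 1),
                 "n_neighbors reduced")
  expect_equal(e$settings$n_neighbors, nrow(tab) - 1)
})

test_that("supervised embedding requires at least two classes", {
  tab <- make_table(10, k = 1)
  expect_error(suppressWarnings(embed_umap(tab, seed = 1)),
               "at least 2 classes")
})

test_that("duplicated rows land together in the embedding", {
  tab <- make_table(10, k = 2, sep = 6, seed = 9)
  dup <- rbind(tab, tab)
  suppressWarnings(e <- embed_umap(dup, n_neighbors = 10, seed = 3))
  n <- nrow(tab)
  pair_d <- sqrt(rowSums((e$coords[1:n, ] - e$coords[n + 1:n, ])^2))
  scale_d <- median(dist(e$coords[1:n, ]))
  expect_lt(median(pair_d), 0.2 * scale_d)
})

test_that("importance summary ranks pooled importances and lists unused
           features", {
  tab <- make_table(10, k = 2, sep = 30, seed = 5)
  r <- mccv(tab, n_iter = 10, feature_subset = c("x1", "x2"), seed = 1)
  s <- importance_summary(r, all_features = names(tab)[1:4])
  expect_setequal(s$unused, c("x3", "x4"))
  expect_equal(s$ranking$feature[1], "x1")
  # single result: ranking equals that run's mean importances
  expect_equal(s$ranking$mean_importance,
               unname(sort(r$mean_importance, decreasing = TRUE)))
})

test_that("tuning returns the only configuration and breaks ties by
           parsimony", {
  tab <- make_table(8, k = 2, sep = 40, seed = 7)
  one <- tune_mccv(tab, grid = data.frame(ntree = 100), n_iter = 5, seed = 1)
  expect_equal(one$best$settings$ntree, 100)
  expect_equal(nrow(one$report), 1)
  # both subsets reach accuracy 1 on a separable table -> fewest features
  both <- tune_mccv(tab, grid = data.frame(ntree = 100),
                    feature_subsets = list(NULL, "x1"), n_iter = 5, seed = 1)
  expect_equal(both$best$features, "x1")
  expect_error(tune_mccv(tab, grid = data.frame()[0, ], n_iter = 2),
               "empty tuning grid")
})
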