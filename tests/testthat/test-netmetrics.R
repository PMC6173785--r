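test_that("all seven metrics match hand computation on a 2x3 grid fixture", {
  # grid edges: (0,1),(1,2),(3,4),(4,5),(0,3),(1,4),(2,5); labels: cells 0,1
  col <- make_colony(grid6_cells())
  expect_identical(nrow(col$edges), 7L)
  m <- colony_metrics(col, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_identical(names(m), metric_names())
  expect_equal(unname(m["frac_diff"]), 2 / 6)
  expect_equal(unname(m["n_diff_clusters"]), 1)       # 0-1 edge joins them
  expect_equal(unname(m["largest_cluster_share"]), 1)
  # cell0 nbrs {1,3}: 1/2 diff; cell1 nbrs {0,2,4}: 1/3 diff
  expect_equal(unname(m["diff_neighbor_frac"]), (1/2 + 1/3) / 2)
  # centroid (13, 6.5); corner distance sqrt(211.25), mid-edge distance 6.5
  dcorner <- sqrt(13^2 + 6.5^2)
  mean_all <- (4 * dcorner + 2 * 6.5) / 6
  expect_equal(unname(m["radial_locale"]), ((dcorner + 6.5) / 2) / mean_all)
  # degrees (2,3,2,2,3,2): diff mean 2.5, population mean 7/3
  expect_equal(unname(m["degree_excess"]), 2.5 - 7 / 3)
  # 1 of 7 edges joins two differentiated cells; expected 2/6 * 1/5
  expect_equal(unname(m["assortativity_excess"]), 1 / 7 - 1 / 15)
})

test_that("metric defaults for unlabelled and fully labelled colonies", {
  col <- make_colony(grid6_cells())
  m0 <- colony_metrics(col, rep(FALSE, 6))
  expect_equal(unname(m0["frac_diff"]), 0)
  expect_equal(unname(m0["n_diff_clusters"]), 0)
  expect_equal(unname(m0["radial_locale"]), 1)
  m1 <- colony_metrics(col, rep(TRUE, 6))
  expect_equal(unname(m1["frac_diff"]), 1)
  expect_equal(unname(m1["n_diff_clusters"]), 1)
  expect_equal(unname(m1["largest_cluster_share"]), 1)
  expect_equal(unname(m1["diff_neighbor_frac"]), 1)
  expect_equal(unname(m1["radial_locale"]), 1)
  expect_equal(unname(m1["degree_excess"]), 0)
  # labels default to the phenotype column
  cells <- grid6_cells(); cells$phenotype <- c("D", "D", "P", "P", "P", "P")
  expect_equal(colony_metrics(make_colony(cells)),
               colony_metrics(col, c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)))
  expect_error(colony_metrics(make_colony(cells[1, , drop = FALSE])),
               "at least 2")
})

test_that("two separated differentiated cells form two clusters", {
  col <- make_colony(grid6_cells())
  m <- colony_metrics(col, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(m["n_diff_clusters"]), 2)
  expect_equal(unname(m["largest_cluster_share"]), 0.5)
  expect_equal(unname(m["diff_neighbor_frac"]), 0)
})

test_that("metrics are invariant to rigid motion and id permutation", {
  set.seed(44)
  st <- make_structures(1, size_range = c(50, 50))[[1]]
  labels <- label_pattern(st, "random", 0.4)$labels
  cells <- make_cells(st$x, st$y)
  base <- colony_metrics(make_colony(cells), labels)
  # rotate + translate
  a <- 0.83
  rot <- make_cells(cos(a) * st$x - sin(a) * st$y + 40,
                    sin(a) * st$x + cos(a) * st$y - 17)
  expect_equal(colony_metrics(make_colony(rot), labels), base,
               tolerance = 1e-12)
  # permute ids (rows reordered on validation; labels must follow the rows)
  perm <- sample(50)
  cells2 <- cells[perm, ]; cells2$id <- 0:49
  expect_equal(colony_metrics(make_colony(cells2), labels[perm]), base,
               tolerance = 1e-12)
})

test_that("train_pca validates its input table", {
  set.seed(6)
  x <- as.data.frame(matrix(runif(7 * 20), ncol = 7,
                            dimnames = list(NULL, metric_names())))
  expect_error(train_pca(x[1:5, ]), "at least 8")
  expect_error(train_pca(x[, -3]), "lacks")
  bad <- x; bad$radial_locale <- 1
  expect_error(train_pca(bad), "radial_locale")
})

test_that("train_pca returns an orthonormal, variance-ordered decomposition", {
  set.seed(13)
  x <- as.data.frame(matrix(rnorm(7 * 200), ncol = 7,
                            dimnames = list(NULL, metric_names())))
  model <- train_pca(x)
  L <- model$loadings
  expect_equal(t(L) %*% L, diag(7), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(model$explained_var), 1)
  expect_true(all(diff(model$explained_var) <= 1e-12))
  # sign convention: the largest-magnitude loading of each PC is positive
  for (j in 1:7) expect_gt(L[which.max(abs(L[, j])), j], 0)
  # iid noise: no component dominates
  expect_lt(model$explained_var[1], 0.35)
})

test_that("a duplicated (perfectly correlated) metric concentrates variance on PC1", {
  set.seed(14)
  x <- as.data.frame(matrix(rnorm(7 * 300), ncol = 7,
                            dimnames = list(NULL, metric_names())))
  x$n_diff_clusters <- 2 * x$frac_diff + 5    # collinear pair
  model <- train_pca(x)
  expect_gte(model$explained_var[1], 2 / 7 - 0.05)
  expect_gt(model$explained_var[1], max(model$explained_var[-1]))
})

test_that("project_latent applies the frozen transform exactly", {
  set.seed(15)
  x <- as.data.frame(matrix(runif(7 * 50), ncol = 7,
                            dimnames = list(NULL, metric_names())))
  model <- train_pca(x)
  sc <- project_latent(model, x)
  # training mean maps to the origin
  expect_equal(unname(colMeans(sc)), rep(0, 7), tolerance = 1e-12)
  # orthonormal loadings: projection is invertible; reconstruct the data
  rec <- sweep(sweep(sc %*% t(model$loadings), 2, model$scale, `*`),
               2, model$center, `+`)
  expect_equal(unname(rec), unname(as.matrix(x[, metric_names()])),
               tolerance = 1e-10)
  # a single named vector projects like a one-row table
  v <- colMeans(x)
  expect_equal(project_latent(model, v)[1, ], rep(0, 7),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(project_latent(model, x[, -2]), "mismatch")
})

test_that("latent_trajectory averages repeats per time point", {
  sc <- rbind(c(1, 0), c(3, 2), c(5, 6))
  colnames(sc) <- c("PC1", "PC2")
  tr <- latent_trajectory(sc, c(0, 0, 1))
  expect_equal(tr$PC1, c(2, 5))
  expect_equal(tr$PC2, c(1, 6))
  expect_equal(tr$PC1_sd, c(stats::sd(c(1, 3)), 0))
  expect_identical(tr$time, c(0, 1))
  expect_error(latent_trajectory(sc, c(0, 1)), "one value per row")
  expect_error(latent_trajectory(sc[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("the trained latent space organizes the pattern classes", {
  ts <- make_training_set(n_structures = 15, size_range = c(60, 120), seed = 8)
  model <- train_pca(ts$metrics)
  sc <- project_latent(model, ts$metrics)
  # differentiation extent is recoverable from the first three components
  fit <- stats::lm(ts$metrics$frac_diff ~ sc[, 1] + sc[, 2] + sc[, 3])
  expect_gt(summary(fit)$r.squared, 0.6)
  # organization/locale axes separate Random from Outside-In on PC2-PC3:
  # mean silhouette of the two class clouds is positive
  keep <- ts$metrics$class_name %in% c("random", "outside_in")
  pts <- sc[keep, 2:3, drop = FALSE]
  is_oi <- ts$metrics$class_name[keep] == "outside_in"
  d <- as.matrix(stats::dist(pts))
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    own <- is_oi == is_oi[i]; own[i] <- FALSE
    a <- mean(d[i, own]); b <- mean(d[i, !own])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
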