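# Binary decision tree multiclass decomposition.

test_that("the fetal-state plan has the fixed two-node structure", {
  plan <- ctg_plan()
  expect_length(plan$splits, 2L)
  root <- plan$splits[[1]]
  expect_setequal(root$parent, ctg_classes)
  expect_setequal(root$positive, c("pathologic", "suspect"))
  expect_identical(root$negative, "normal")
  second <- plan$splits[[2]]
  expect_setequal(second$parent, c("pathologic", "suspect"))
  expect_identical(second$positive, "pathologic")
  expect_identical(second$negative, "suspect")
})

test_that("generic plans have R - 1 splits and singleton leaves", {
  p2 <- partition_plan(c("a", "b"),
                       list(list(parent = c("a", "b"),
                                 positive = "a", negative = "b")))
  expect_length(p2$splits, 1L)
  chain4 <- partition_plan(letters[1:4], list(
    list(parent = letters[1:4], positive = "a", negative = letters[2:4]),
    list(parent = letters[2:4], positive = "b", negative = c("c", "d")),
    list(parent = c("c", "d"), positive = "c", negative = "d")))
  expect_length(chain4$splits, 3L)
  # balanced shape is equally valid
  bal4 <- partition_plan(letters[1:4], list(
    list(parent = letters[1:4], positive = c("a", "b"),
         negative = c("c", "d")),
    list(parent = c("a", "b"), positive = "a", negative = "b"),
    list(parent = c("c", "d"), positive = "c", negative = "d")))
  expect_length(bal4$splits, 3L)
})

test_that("invalid plans are rejected", {
  expect_error(partition_plan(c("a", "b", "c"), list(
    list(parent = c("a", "b", "c"), positive = c("a", "b"),
         negative = c("b", "c")),
    list(parent = c("b", "c"), positive = "b", negative = "c"))),
    "overlap")
  expect_error(partition_plan(c("a", "b", "c"), list(
    list(parent = c("a", "b", "c"), positive = "a", negative = "b"),
    list(parent = c("b", "c"), positive = "b", negative = "c"))),
    "partition")
  expect_error(partition_plan(c("a", "b", "c"), list(
    list(parent = c("a", "b", "c"), positive = "a",
         negative = c("b", "c")),
    list(parent = c("a", "b"), positive = "a", negative = "b"))),
    "unsplit internal node|not an unsplit")
  # wrong number of splits
  expect_error(partition_plan(c("a", "b", "c"), list(
    list(parent = c("a", "b", "c"), positive = "a",
         negative = c("b", "c")),
    list(parent = c("b", "c"), positive = "b", negative = "c"),
    list(parent = c("b", "c"), positive = "b", negative = "c"))),
    "R - 1")
})

test_that("a 3-class fit trains exactly 2 node models on the right rows", {
  d <- generate_ctg(n_per_class = c(40, 15, 12), seed = 21)
  xy <- lssvmbdt:::split_xy(d)
  tree <- fit_bdt(xy$x, xy$y, tune = FALSE, gamma = 10, sigma2 = 21)
  expect_s3_class(tree, "bdt")
  expect_length(tree$node_models, 2L)
  # node 2 is trained only on suspect + pathologic rows
  expect_equal(length(tree$node_models[[2]]$train_labels), 15 + 12)
  expect_equal(length(tree$node_models[[1]]$train_labels), 67)
})

test_that("tree predictions equal the manually composed cascade", {
  d <- generate_ctg(n_per_class = c(40, 15, 12), seed = 22)
  xy <- lssvmbdt:::split_xy(d)
  tree <- fit_bdt(xy$x, xy$y, tune = FALSE, gamma = 10, sigma2 = 21)
  grid <- as.matrix(generate_ctg(n_per_class = c(20, 20, 20),
                                 seed = 23)[, 1:21])
  p_tree <- as.character(predict(tree, grid))
  root <- predict(tree$node_models[[1]], grid)
  node2 <- predict(tree$node_models[[2]], grid)
  p_manual <- ifelse(root < 0, "normal",
                     ifelse(node2 > 0, "pathologic", "suspect"))
  expect_identical(p_tree, p_manual)
  # batch equals pointwise
  p_point <- vapply(seq_len(nrow(grid)), function(i)
    as.character(predict(tree, grid[i, ])), character(1))
  expect_identical(p_tree, p_point)
})

test_that("routing semantics: root negative is normal regardless of node 2", {
  d <- generate_ctg(n_per_class = c(30, 10, 10), seed = 30)
  xy <- lssvmbdt:::split_xy(d)
  tree <- fit_bdt(xy$x, xy$y, tune = FALSE, gamma = 5, sigma2 = 21)
  # points deep in the normal cluster
  normal_like <- as.matrix(d[d$state == "normal", 1:21][1:5, ])
  expect_true(all(predict(tree, normal_like) == "normal"))
  expect_true(all(predict(tree, xy$x) %in% ctg_classes))
})

test_that("row permutation leaves decision values unchanged", {
  d <- generate_ctg(n_per_class = c(25, 10, 8), seed = 40)
  xy <- lssvmbdt:::split_xy(d)
  set.seed(1)
  perm <- sample(nrow(xy$x))
  t1 <- fit_bdt(xy$x, xy$y, tune = FALSE, gamma = 8, sigma2 = 21)
  t2 <- fit_bdt(xy$x[perm, ], xy$y[perm], tune = FALSE, gamma = 8,
                sigma2 = 21)
  grid <- as.matrix(generate_ctg(n_per_class = c(10, 10, 10),
                                 seed = 41)[, 1:21])
  for (i in 1:2)
    expect_equal(decision_values(t1$node_models[[i]], grid),
                 decision_values(t2$node_models[[i]], grid),
                 tolerance = 1e-8)
  expect_identical(as.character(predict(t1, grid)),
                   as.character(predict(t2, grid)))
})

test_that("a class missing from the data is a named error", {
  d <- generate_ctg(n_per_class = c(20, 10, 5), seed = 50)
  keep <- d$state != "pathologic"
  xy <- lssvmbdt:::split_xy(d[keep, ])
  expect_error(fit_bdt(xy$x, as.character(xy$y), plan = ctg_plan(),
                       tune = FALSE, gamma = 1, sigma2 = 1),
               "pathologic")
})

test_that("PSO tuning runs per node and records traces", {
  d <- generate_ctg(n_per_class = c(30, 12, 10), seed = 60)
  xy <- lssvmbdt:::split_xy(d)
  cfg <- swarm_config(n_particles = 4, max_iterations = 3, seed = 5)
  tree <- fit_bdt(xy$x, xy$y, config = cfg, inner_folds = 3)
  expect_length(tree$node_tuning, 2L)
  for (t in tree$node_tuning) {
    expect_length(t$history, 4L)
    expect_true(all(diff(t$history) >= 0))
    expect_gte(t$inner_cv_accuracy, 0.5)
    expect_true(t$log2_gamma >= -4 && t$log2_gamma <= 12)
  }
  # nodes derive distinct sub-seeds, so tuning is reproducible end to end
  tree2 <- fit_bdt(xy$x, xy$y, config = cfg, inner_folds = 3)
  expect_identical(tree$node_tuning, tree2$node_tuning)
})

test_that("inner CV folds shrink with a tiny minority class", {
  d <- generate_ctg(n_per_class = c(30, 12, 4), seed = 61)
  xy <- lssvmbdt:::split_xy(d)
  cfg <- swarm_config(n_particles = 3, max_iterations = 2, seed = 6)
  tree <- fit_bdt(xy$x, xy$y, config = cfg, inner_folds = 5)
  expect_identical(tree$node_tuning[[2]]$inner_folds, 2L)
})

test_that("tree JSON round trip preserves structure and predictions", {
  d <- generate_ctg(n_per_class = c(25, 10, 8), seed = 70)
  xy <- lssvmbdt:::split_xy(d)
  tree <- fit_bdt(xy$x, xy$y, tune = FALSE, gamma = 10, sigma2 = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_bdt(tree, path)
  tree2 <- read_bdt(path)
  expect_length(tree2$node_models, 2L)
  expect_identical(tree2$classes, ctg_classes)
  grid <- as.matrix(generate_ctg(n_per_class = c(8, 8, 8),
                                 seed = 71)[, 1:21])
  expect_identical(as.character(predict(tree2, grid)),
                   as.character(predict(tree, grid)))
})
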