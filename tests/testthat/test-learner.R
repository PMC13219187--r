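# build a labeled dataset directly (no simulation) for learner-only tests
fake_dataset <- function(features, label, gamma = 0.01) {
  structure(list(features = features, label = as.integer(label),
                 policy_ids = sort(unique(as.integer(label))),
                 n_reps = 1L, seed = 1L, gamma = gamma),
            class = "labeled_dataset")
}

feat_names <- c("n_volunteers", "triage_delay", paste0("resp_", 1:10))

rand_features <- function(n, seed) {
  set.seed(seed)
  m <- cbind(sample(0:8, n, TRUE), runif(n, 0, 10),
             matrix(runif(n * 10, 0, 999), n))
  colnames(m) <- feat_names
  m
}

test_that("a separable two-feature problem is learned exactly and shallow", {
  n <- 120
  set.seed(201)
  m <- rand_features(n, 201)
  lab <- ifelse(m[, "resp_1"] < 300, ifelse(m[, "resp_2"] < 600, 4L, 2L),
                0L)
  ds <- fake_dataset(m, lab)
  tree <- train_tree(ds, min_leaf = 1, cp = 0.01)
  pred <- vapply(seq_len(n), function(i) predict_policy(tree, m[i, ]),
                 integer(1))
  expect_equal(mean(pred == lab), 1.0)
  expect_lte(tree_depth(tree), 2)
})

test_that("a unanimous label collapses to a single-leaf strategy", {
  m <- rand_features(30, 202)
  ds <- fake_dataset(m, rep(7L, 30))
  tree <- train_tree(ds)
  expect_equal(nrow(tree$nodes), 1)
  expect_identical(predict_policy(tree, m[1, ]), 7L)
  expect_identical(predict_policy(tree, m[22, ]), 7L)
})

test_that("training is deterministic under a fixed seed", {
  m <- rand_features(150, 203)
  set.seed(204)
  lab <- sample(c(0L, 3L, 11L), 150, TRUE)
  t1 <- train_tree(fake_dataset(m, lab), seed = 9)
  t2 <- train_tree(fake_dataset(m, lab), seed = 9)
  expect_identical(t1$nodes, t2$nodes)
})

test_that("traversal follows the narrated worked example of the tree", {
  # three splits on volunteer response times; equality goes right
  nodes <- data.frame(
    id = 1:7,
    feature = c("resp_4", NA, "resp_2", "resp_3", NA, NA, NA),
    threshold = c(8.76, NA, 9.67, 9.25, NA, NA, NA),
    left = c(2L, NA, 4L, 6L, NA, NA, NA),
    right = c(3L, NA, 5L, 7L, NA, NA, NA),
    policy_id = c(NA, 6L, NA, NA, 0L, 3L, 1L))
  tree <- tree_strategy(nodes, schema = feat_names)
  inc <- incident(1, 0, 12, c(3, 5, 8, 9, 10))
  # V4 at 9 is not below 8.76 -> right; V2 at 5 below 9.67 -> left;
  # V3 at 8 below 9.25 -> left: "Send 3"
  expect_identical(predict_policy(tree, inc), 3L)
  # a feature exactly at the threshold goes right
  f <- extract_features(inc)
  f["resp_4"] <- 8.76
  f["resp_2"] <- 9.67
  expect_identical(predict_policy(tree, f), 0L)
  expect_error(predict_policy(tree, c(bogus = 1)), "schema")
})

test_that("exported trees predict identically after re-import", {
  m <- rand_features(200, 205)
  lab <- ifelse(m[, "resp_1"] < 200, 1L,
                ifelse(m[, "n_volunteers"] >= 4, 21L, 0L))
  tree <- train_tree(fake_dataset(m, lab), min_leaf = 1, cp = 0.01)
  path <- tempfile(fileext = ".json")
  write_tree_strategy(tree, path)
  back <- read_tree_strategy(path)
  probe <- rand_features(10000, 206)
  p1 <- vapply(seq_len(nrow(probe)),
               function(i) predict_policy(tree, probe[i, ]), integer(1))
  p2 <- vapply(seq_len(nrow(probe)),
               function(i) predict_policy(back, probe[i, ]), integer(1))
  expect_identical(p1, p2)
})

test_that("labels are argmax mean objective with low-id tie-breaking", {
  sam <- response_sampler()
  pols <- build_default_policy_set()
  # with no volunteers every policy acts identically: the tie must break to
  # the lowest policy id (send 0)
  empty <- incident(1, 2, 12, numeric(0))
  ds <- label_instances(list(empty), pols, n_reps = 3, seed = 1, sam)
  expect_identical(ds$label, 0L)
  # labels are reproducible and attain the row maximum
  inc2 <- list(test_incident(c(3, 6)), test_incident(c(2, 4, 8), id = 2L))
  d1 <- label_instances(inc2, pols, n_reps = 30, seed = 3, sam)
  d2 <- label_instances(inc2, pols, n_reps = 30, seed = 3, sam)
  expect_identical(d1$label, d2$label)
  for (i in 1:2) {
    expect_equal(d1$mean_objective[i, match(d1$label[i], d1$policy_ids)],
                 max(d1$mean_objective[i, ]))
  }
})

test_that("strategy evaluation reports accuracy and CRN-consistent means", {
  sam <- response_sampler()
  pols <- build_default_policy_set()
  set.seed(207)
  instances <- lapply(1:10, function(i) {
    test_incident(sort(runif(sample(0:5, 1), 0.5, 9)), id = i)
  })
  ds <- label_instances(instances, pols, n_reps = 40, seed = 11, sam)
  # a constant tree predicting one fixed policy: accuracy is the share of
  # instances labeled with it, and its means equal that policy's means
  pid <- as.integer(names(sort(table(ds$label), decreasing = TRUE))[1])
  const_tree <- tree_strategy(
    data.frame(id = 1L, feature = NA_character_, threshold = NA_real_,
               left = NA_integer_, right = NA_integer_, policy_id = pid),
    schema = feat_names)
  rep <- evaluate_strategy(const_tree, instances, pols, n_reps = 40,
                           seed = 11, sam)
  expect_equal(rep$accuracy, mean(ds$label == pid))
  col <- match(pid, ds$policy_ids)
  expect_equal(rep$tree$mean_objective, mean(ds$mean_objective[, col]),
               tolerance = 1e-12)
  # the per-instance oracle weakly dominates the best static policy
  expect_gte(rep$oracle$mean_objective,
             rep$best_static$mean_objective - 1e-12)
  # if the constant tree happens to be the best static policy, their means
  # coincide exactly under common random numbers
  if (pid == rep$best_static$policy_id) {
    expect_equal(rep$tree$mean_objective, rep$best_static$mean_objective)
  }
})
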