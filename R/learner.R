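#' Label instances with their simulation-best policy
#'
#' Evaluates every policy on every instance with common random numbers
#' ([policy_outcomes()]) and labels each instance with the `policy_id`
#' attaining the highest mean objective. Ties are broken toward the lowest
#' `policy_id`, i.e. toward the fewest-alert policy under the default
#' ordering (ties are exact under CRN when two policies take identical
#' actions on an instance).
#'
#' @param instances List of [incident()] objects.
#' @param policy_set Ordered list of [policy_spec()] objects.
#' @param n_reps Simulation replications per (instance, policy).
#' @param seed Base seed for the CRN draws.
#' @param sampler A `response_sampler`.
#' @param tradeoff,survival Model parameters.
#' @param k_max Number of volunteer response-time features.
#' @return An object of class `labeled_dataset`: `features` (matrix),
#'   `label` (integer policy ids), per-policy mean matrices, and metadata.
#' @export
label_instances <- function(instances, policy_set, n_reps, seed, sampler,
                            tradeoff = tradeoff_params(),
                            survival = survival_params(), k_max = 10) {
  stopifnot(length(policy_set) >= 1, n_reps >= 1)
  out <- policy_outcomes(instances, policy_set, n_reps, seed, sampler,
                         tradeoff, survival)
  ids <- vapply(policy_set, function(p) p$policy_id, integer(1))
  lab <- ids[apply(out$mean_objective, 1, which.max)]  # first max = lowest id
  feats <- t(vapply(instances, extract_features,
                    numeric(k_max + 2), k_max = k_max))
  structure(list(features = feats, label = lab, policy_ids = ids,
                 mean_objective = out$mean_objective,
                 mean_survival = out$mean_survival,
                 mean_redundant = out$mean_redundant,
                 var_mean_objective = out$var_mean_objective,
                 n_reps = n_reps, seed = seed,
                 gamma = tradeoff$gamma),
            class = "labeled_dataset")
}

#' Train a classification-tree dispatch strategy
#'
#' Fits a CART multi-class tree (via [rpart::rpart()], Gini impurity) that
#' predicts the simulation-best policy from the incident features, then
#' converts the fit to a portable [tree_strategy()] (plain split nodes and
#' policy-id leaves). The complexity parameter is selected by the
#' cross-validation built into rpart (smallest cross-validated error) under
#' a fixed seed, unless `cp` is supplied.
#'
#' @param dataset A `labeled_dataset` from [label_instances()].
#' @param max_depth Maximum tree depth (default 30, rpart's ceiling).
#' @param min_leaf Minimum observations in a leaf (default 5).
#' @param cp Optional fixed complexity parameter; if `NULL`, chosen by
#'   cross-validation.
#' @param seed Seed for the internal cross-validation folds.
#' @return A [tree_strategy()].
#' @export
train_tree <- function(dataset, max_depth = 30, min_leaf = 5, cp = NULL,
                       seed = 1) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            nrow(dataset$features) >= 1)
  df <- as.data.frame(dataset$features)
  lev <- as.character(sort(unique(dataset$label)))
  df$.label <- factor(as.character(dataset$label), levels = lev)
  schema <- colnames(dataset$features)
  meta <- list(gamma = dataset$gamma, seed = seed, n_reps = dataset$n_reps,
               max_depth = max_depth, min_leaf = min_leaf)
  if (length(lev) == 1L) {  # unanimous label: a single-leaf strategy
    return(tree_strategy(
      nodes = data.frame(id = 1L, feature = NA_character_,
                         threshold = NA_real_, left = NA_integer_,
                         right = NA_integer_,
                         policy_id = as.integer(lev)),
      schema = schema, metadata = meta))
  }
  set.seed(as.integer(seed))
  fit <- rpart::rpart(
    .label ~ ., data = df, method = "class",
    control = rpart::rpart.control(maxdepth = max_depth,
                                   minbucket = min_leaf, cp = 0,
                                   maxcompete = 0, maxsurrogate = 0,
                                   xval = if (is.null(cp)) 10 else 0))
  if (is.null(cp)) {
    tab <- fit$cptable
    best <- which.min(tab[, "xerror"])
    cp_use <- tab[best, "CP"]
  } else {
    cp_use <- cp
  }
  fit <- rpart::prune(fit, cp = cp_use)
  meta$cp <- cp_use
  as_tree_strategy(fit, schema = schema, metadata = meta)
}

#' Portable classification-tree strategy
#'
#' A binary decision tree over the incident feature schema. Internal nodes
#' carry `(feature, threshold, left, right)`; traversal follows
#' `feature < threshold` to the left child, otherwise (including exact
#' equality) to the right. Leaves carry the `policy_id` to dispatch.
#'
#' @param nodes A `data.frame` with columns `id`, `feature`, `threshold`,
#'   `left`, `right`, `policy_id` (internal nodes have `NA` policy, leaves
#'   have `NA` feature); the root has `id` 1.
#' @param schema Character vector of feature names.
#' @param metadata Free-form training metadata list.
#' @return An object of class `tree_strategy`.
#' @export
tree_strategy <- function(nodes, schema, metadata = list()) {
  stopifnot(all(c("id", "feature", "threshold", "left", "right",
                  "policy_id") %in% names(nodes)),
            1 %in% nodes$id)
  internal <- !is.na(nodes$feature)
  stopifnot(all(nodes$feature[internal] %in% schema),
            all(is.finite(nodes$threshold[internal])),
            all(!is.na(nodes$policy_id[!internal])))
  structure(list(nodes = nodes, schema = schema, metadata = metadata),
            class = "tree_strategy")
}

#' @export
print.tree_strategy <- function(x, ...) {
  n_leaf <- sum(is.na(x$nodes$feature))
  cat(sprintf("<tree_strategy: %d nodes (%d leaves) over %d features>\n",
              nrow(x$nodes), n_leaf, length(x$schema)))
  invisible(x)
}

# Convert a pruned rpart fit (maxcompete = maxsurrogate = 0) into the
# portable structure. rpart's ncat = -1 sends `x < split` left; +1 sends it
# right, in which case the children are swapped so that our "< goes left"
# convention always holds.
as_tree_strategy <- function(fit, schema, metadata = list()) {
  frame <- fit$frame
  node_nums <- as.integer(rownames(frame))
  ylev <- attr(fit, "ylevels")
  is_leaf <- frame$var == "<leaf>"
  splits <- fit$splits
  split_row <- integer(nrow(frame))
  split_row[!is_leaf] <- seq_len(sum(!is_leaf))
  id_of <- stats::setNames(seq_along(node_nums), node_nums)
  rows <- vector("list", nrow(frame))
  for (i in seq_len(nrow(frame))) {
    num <- node_nums[i]
    if (is_leaf[i]) {
      rows[[i]] <- data.frame(
        id = id_of[[as.character(num)]], feature = NA_character_,
        threshold = NA_real_, left = NA_integer_, right = NA_integer_,
        policy_id = as.integer(ylev[frame$yval[i]]))
    } else {
      sp <- splits[split_row[i], , drop = TRUE]
      lo <- id_of[[as.character(2 * num)]]
      hi <- id_of[[as.character(2 * num + 1)]]
      flip <- sp[["ncat"]] > 0
      rows[[i]] <- data.frame(
        id = id_of[[as.character(num)]],
        feature = as.character(frame$var[i]),
        threshold = unname(sp[["index"]]),
        left = if (flip) hi else lo, right = if (flip) lo else hi,
        policy_id = NA_integer_)
    }
  }
  tree_strategy(do.call(rbind, rows), schema = schema, metadata = metadata)
}

#' Predict the dispatch policy for an incident
#'
#' Deterministic root-to-leaf traversal: at each internal node go left when
#' `feature < threshold`, right otherwise (a feature exactly at the
#' threshold goes right).
#'
#' @param tree A [tree_strategy()].
#' @param features A named numeric vector conforming to the tree's schema
#'   (see [extract_features()]), or an [incident()].
#' @return The selected `policy_id` (integer).
#' @export
predict_policy <- function(tree, features) {
  if (inherits(features, "incident")) {
    features <- extract_features(features,
                                 k_max = length(tree$schema) - 2L)
  }
  if (!all(tree$schema %in% names(features))) {
    stop("features do not conform to the tree's schema")
  }
  nodes <- tree$nodes
  row <- which(nodes$id == 1L)
  repeat {
    if (is.na(nodes$feature[row])) return(nodes$policy_id[row])
    go_left <- features[[nodes$feature[row]]] < nodes$threshold[row]
    nxt <- if (go_left) nodes$left[row] else nodes$right[row]
    row <- which(nodes$id == nxt)
  }
}

#' Write / read a tree strategy as JSON
#'
#' @param tree A [tree_strategy()].
#' @param path File path.
#' @return For the reader, a [tree_strategy()] predicting identically to
#'   the exported one.
#' @export
write_tree_strategy <- function(tree, path) {
  jsonlite::write_json(
    list(nodes = tree$nodes, schema = tree$schema,
         metadata = tree$metadata),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_tree_strategy
#' @export
read_tree_strategy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- as.data.frame(x$nodes)
  nodes$id <- as.integer(nodes$id)
  nodes$left <- as.integer(nodes$left)
  nodes$right <- as.integer(nodes$right)
  nodes$policy_id <- as.integer(nodes$policy_id)
  nodes$threshold <- as.numeric(nodes$threshold)
  if (!"feature" %in% names(nodes)) nodes$feature <- NA_character_
  tree_strategy(nodes, schema = x$schema,
                metadata = if (is.null(x$metadata)) list() else x$metadata)
}

#' Human-readable rule listing of a tree strategy
#'
#' @param tree A [tree_strategy()].
#' @param policy_set Optional policy set used to print policy labels.
#' @return Character vector of indented rules, invisibly (also printed).
#' @export
describe_tree <- function(tree, policy_set = NULL) {
  nodes <- tree$nodes
  lab <- function(pid) {
    if (is.null(policy_set)) return(sprintf("policy %d", pid))
    hit <- Filter(function(p) p$policy_id == pid, policy_set)
    if (length(hit)) policy_label(hit[[1]]) else sprintf("policy %d", pid)
  }
  out <- character(0)
  walk <- function(id, depth, prefix) {
    row <- which(nodes$id == id)
    pad <- strrep("  ", depth)
    if (is.na(nodes$feature[row])) {
      out <<- c(out, sprintf("%s%s-> %s", pad, prefix,
                             lab(nodes$policy_id[row])))
    } else {
      out <<- c(out, sprintf("%s%s%s < %.4g?", pad, prefix,
                             nodes$feature[row], nodes$threshold[row]))
      walk(nodes$left[row], depth + 1, "yes: ")
      walk(nodes$right[row], depth + 1, "no:  ")
    }
  }
  walk(1L, 0, "")
  cat(out, sep = "\n")
  invisible(out)
}

#' Evaluate a tree strategy on a test set
#'
#' Labels the test instances by fresh CRN simulation, then reports: the
#' classification accuracy (fraction of instances where the tree picks the
#' simulation-best policy); the mean objective/survival/redundancy of the
#' tree-selected policies; the identity and means of the best static policy
#' (highest mean objective when applied uniformly); the per-instance oracle
#' (best labeled policy per instance); and per-instance percentage
#' improvements of the tree over the best static policy.
#'
#' @param tree A [tree_strategy()].
#' @param test_instances List of [incident()] objects.
#' @param policy_set Ordered list of [policy_spec()] objects.
#' @param n_reps,seed,sampler,tradeoff,survival As in [label_instances()].
#' @return A list report; see Details.
#' @export
evaluate_strategy <- function(tree, test_instances, policy_set, n_reps,
                              seed, sampler,
                              tradeoff = tradeoff_params(),
                              survival = survival_params()) {
  ds <- label_instances(test_instances, policy_set, n_reps, seed, sampler,
                        tradeoff, survival,
                        k_max = length(tree$schema) - 2L)
  ids <- ds$policy_ids
  n <- length(test_instances)
  pred <- vapply(seq_len(n),
                 function(i) predict_policy(tree, ds$features[i, ]),
                 integer(1))
  col_of <- match(pred, ids)
  if (anyNA(col_of)) stop("tree predicts a policy outside the policy set")
  pick <- cbind(seq_len(n), col_of)
  tree_obj <- ds$mean_objective[pick]
  tree_sur <- ds$mean_survival[pick]
  tree_red <- ds$mean_redundant[pick]
  static_means <- colMeans(ds$mean_objective)
  b <- which.max(static_means)
  best_static_obj <- ds$mean_objective[, b]
  best_static_sur <- ds$mean_survival[, b]
  best_static_red <- ds$mean_redundant[, b]
  oracle_col <- match(ds$label, ids)
  opick <- cbind(seq_len(n), oracle_col)
  imp <- data.frame(
    instance = seq_len(n),
    pct_improve_objective = 100 * (tree_obj - best_static_obj) /
      pmax(abs(best_static_obj), 1e-12),
    pct_improve_survival = 100 * (tree_sur - best_static_sur) /
      pmax(abs(best_static_sur), 1e-12),
    predicted = pred, label = ds$label)
  list(accuracy = mean(pred == ds$label),
       tree = list(mean_objective = mean(tree_obj),
                   mean_survival = mean(tree_sur),
                   mean_redundant = mean(tree_red)),
       best_static = list(policy_id = ids[b],
                          mean_objective = mean(best_static_obj),
                          mean_survival = mean(best_static_sur),
                          mean_redundant = mean(best_static_red)),
       oracle = list(mean_objective = mean(ds$mean_objective[opick]),
                     mean_survival = mean(ds$mean_survival[opick]),
                     mean_redundant = mean(ds$mean_redundant[opick])),
       per_instance = imp, labeled = ds)
}
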