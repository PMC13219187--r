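# 31-bit polynomial rolling hash over a deparsed object; stamps outputs with
# a configuration fingerprint so artifact bundles are self-describing.
config_fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' End-to-end run configuration
#'
#' Bundles every knob of the generate -> label -> train -> evaluate ->
#' frontier pipeline, with the study defaults: 12-minute EMS response from
#' the call, fatigue penalty 0.01, the 22-policy set, 10,000 training and
#' 2,000 test instances. Smaller sizes are appropriate for demos and tests.
#'
#' @param scenario Free-text scenario name.
#' @param ems_minutes Ambulance response time from the call, minutes.
#' @param gamma Fatigue penalty.
#' @param accept_boost Optional target acceptance rate (e.g. 0.5); `NULL`
#'   keeps the sampler's native rate.
#' @param n_train,n_test Instance counts.
#' @param n_reps Simulation replications per (instance, policy).
#' @param seed_instances,seed_sim,seed_learner Named seeds for the three
#'   randomness sources.
#' @param region A [region_model()].
#' @param sampler A `response_sampler`.
#' @param policy_set Ordered list of [policy_spec()] objects.
#' @param quiet Suppress progress messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = "default", ems_minutes = 12, gamma = 0.01,
                       accept_boost = NULL, n_train = 10000, n_test = 2000,
                       n_reps = 200, seed_instances = 1, seed_sim = 2,
                       seed_learner = 3, region = toy_region(),
                       sampler = response_sampler(),
                       policy_set = build_default_policy_set(),
                       quiet = FALSE) {
  stopifnot(n_train >= 1, n_test >= 1, n_reps >= 1, ems_minutes > 0)
  structure(list(scenario = scenario, ems_minutes = ems_minutes,
                 gamma = gamma, accept_boost = accept_boost,
                 n_train = n_train, n_test = n_test, n_reps = n_reps,
                 seed_instances = seed_instances, seed_sim = seed_sim,
                 seed_learner = seed_learner, region = region,
                 sampler = sampler, policy_set = policy_set,
                 quiet = quiet),
            class = "run_config")
}

#' Run the full dispatch-strategy pipeline
#'
#' Generates training and test incidents, labels the training set by CRN
#' simulation, trains the classification-tree strategy, evaluates it on the
#' test set, and computes the static Pareto frontier, writing all artifacts
#' (instances, labels, tree JSON, evaluation report, frontier CSV) under
#' `out_dir`. Every CSV/JSON carries the configuration hash and seeds.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory artifacts: `train`, `test`,
#'   `labeled`, `tree`, `report`, `frontier`, `config_hash`, `paths`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("cfr_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!config$quiet) message(sprintf(...))
  t0 <- Sys.time()
  hash <- config_fingerprint(config[setdiff(names(config), "quiet")])
  sampler <- config$sampler
  if (!is.null(config$accept_boost)) {
    sampler <- boost_acceptance_rate(sampler, config$accept_boost)
  }
  tradeoff <- tradeoff_params(config$gamma)

  say("[generate] %d train + %d test instances (seed %s)", config$n_train,
      config$n_test, config$seed_instances)
  train <- make_instances(config$region, config$n_train,
                          config$ems_minutes, config$seed_instances)
  test <- make_instances(config$region, config$n_test, config$ems_minutes,
                         config$seed_instances + 1)
  write_instances(train, file.path(out_dir, "train"))
  write_instances(test, file.path(out_dir, "test"))

  say("[label] %d instances x %d policies x %d reps (seed %s)",
      config$n_train, length(config$policy_set), config$n_reps,
      config$seed_sim)
  labeled <- label_instances(train, config$policy_set, config$n_reps,
                             config$seed_sim, sampler, tradeoff)
  utils::write.csv(
    data.frame(instance_id = seq_along(train), label = labeled$label,
               config_hash = hash),
    file.path(out_dir, "labels.csv"), row.names = FALSE)

  say("[train] classification tree (seed %s)", config$seed_learner)
  tree <- train_tree(labeled, seed = config$seed_learner)
  tree$metadata$config_hash <- hash
  tree$metadata$scenario <- config$scenario
  tree$metadata$ems_minutes <- config$ems_minutes
  write_tree_strategy(tree, file.path(out_dir, "tree.json"))

  say("[evaluate] %d test instances", config$n_test)
  report <- evaluate_strategy(tree, test, config$policy_set, config$n_reps,
                              config$seed_sim + 1, sampler, tradeoff)
  jsonlite::write_json(
    list(config_hash = hash, scenario = config$scenario,
         seeds = list(instances = config$seed_instances,
                      sim = config$seed_sim,
                      learner = config$seed_learner),
         accuracy = report$accuracy, tree = report$tree,
         best_static = c(report$best_static,
                         label = policy_label(config$policy_set[[
                           which(vapply(config$policy_set,
                                        function(p) p$policy_id,
                                        integer(1)) ==
                                   report$best_static$policy_id)]])),
         oracle = report$oracle),
    file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)

  say("[frontier] static Pareto frontier")
  ds <- report$labeled
  static_pts <- data.frame(
    label = vapply(config$policy_set, policy_label, character(1)),
    policy_id = ds$policy_ids,
    mean_survival = colMeans(ds$mean_survival),
    mean_redundant = colMeans(ds$mean_redundant))
  static_pts$objective_at_gamma <- static_pts$mean_survival -
    config$gamma * static_pts$mean_redundant
  tree_pt <- data.frame(label = "tree", policy_id = NA_integer_,
                        mean_survival = report$tree$mean_survival,
                        mean_redundant = report$tree$mean_redundant,
                        objective_at_gamma = report$tree$mean_objective)
  frontier <- static_frontier(static_pts)
  out_front <- rbind(static_pts, tree_pt)
  out_front$on_frontier <- c(rownames(static_pts) %in% rownames(frontier),
                             NA)
  out_front$config_hash <- hash
  utils::write.csv(out_front, file.path(out_dir, "frontier.csv"),
                   row.names = FALSE)

  say("[done] %.1f s elapsed",
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(list(train = train, test = test, labeled = labeled, tree = tree,
                 report = report, frontier = frontier,
                 static_points = static_pts, config_hash = hash,
                 paths = file.path(out_dir,
                                   c("train_incidents.csv",
                                     "train_volunteers.csv",
                                     "test_incidents.csv",
                                     "test_volunteers.csv", "labels.csv",
                                     "tree.json", "evaluation.json",
                                     "frontier.csv"))))
}

#' Write small bundled demo/test fixtures
#'
#' Creates, deterministically for a given seed: a one-unit toy region CSV
#' (volunteer density 1 per km^2, so the mean disc count is pi); a
#' 10-incident instance file whose first incident (triage 2 min, EMS 12
#' min, volunteer travel times 4, 6, 8 min) has hand-checkable event
#' traces; and a 3-policy set JSON (send 0, send 2, keep 2 until 3 min).
#'
#' @param dir Output directory.
#' @param seed RNG seed for the nine random incidents.
#' @return Named character vector of the written paths, invisibly.
#' @export
make_fixtures <- function(dir = tempfile("cfr_fixtures_"), seed = 42) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  region <- toy_region()
  region_path <- file.path(dir, "region.csv")
  utils::write.csv(as.data.frame(unclass(region))[
    , c("unit_id", "population", "area_km2", "incident_weight",
        "cfr_fraction")],
    region_path, row.names = FALSE)

  hand <- incident(1L, triage_delay = 2, ems_response_from_call = 12,
                   volunteer_travel_times = c(4, 6, 8))
  rest <- make_instances(region, 9, 12, seed)
  for (i in seq_along(rest)) rest[[i]]$instance_id <- i + 1L
  write_instances(c(list(hand), rest), file.path(dir, "fixture"))

  pol <- list(policy_spec("send_n", 0, policy_id = 0L),
              policy_spec("send_n", 2, policy_id = 1L),
              policy_spec("keep_n_until_t", 2, t_stop = 3, policy_id = 2L))
  pol_path <- file.path(dir, "policies.json")
  write_policy_set(pol, pol_path)
  invisible(c(region = region_path,
              incidents = file.path(dir, "fixture_incidents.csv"),
              volunteers = file.path(dir, "fixture_volunteers.csv"),
              policies = pol_path))
}
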