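#' Pareto-optimal subset of static policies
#'
#' A point dominates another when it has survival at least as high and
#' redundancy no larger (strictly better in at least one). Returns the
#' non-dominated points ordered by increasing redundancy. The minimum-
#' redundancy policy (e.g. "send 0", which alerts nobody) is always on the
#' frontier.
#'
#' @param points A `data.frame` with columns `label`, `mean_survival`,
#'   `mean_redundant` (extra columns are carried through).
#' @return The Pareto-optimal rows, ordered by `mean_redundant`.
#' @export
static_frontier <- function(points) {
  stopifnot(nrow(points) >= 1,
            all(c("mean_survival", "mean_redundant") %in% names(points)))
  n <- nrow(points)
  keep <- vapply(seq_len(n), function(i) {
    dom <- points$mean_survival >= points$mean_survival[i] &
      points$mean_redundant <= points$mean_redundant[i] &
      (points$mean_survival > points$mean_survival[i] |
         points$mean_redundant < points$mean_redundant[i])
    !any(dom)
  }, logical(1))
  out <- points[keep, , drop = FALSE]
  out[order(out$mean_redundant, out$mean_survival), , drop = FALSE]
}

#' Robustness of a strategy to the fatigue penalty
#'
#' Re-scores fixed (survival, redundancy) pairs under each `gamma` in a
#' grid --- valid without re-simulation because the objective is linear in
#' `gamma` and the simulator output is `gamma`-free. Reports, per `gamma`,
#' the best static policy and whether the candidate strategy beats every
#' static policy, plus the contiguous `gamma`-interval around the winners
#' where it does.
#'
#' @param strategy_point One-row `data.frame` (`mean_survival`,
#'   `mean_redundant`) for the adaptive strategy.
#' @param static_points `data.frame` of static-policy points (`label`,
#'   `mean_survival`, `mean_redundant`).
#' @param gamma_grid Positive, increasing vector of `gamma` values.
#' @return A list: `table` (per-gamma winner data.frame) and
#'   `win_interval` (range of grid gammas where the strategy wins, or
#'   `NULL`).
#' @export
gamma_sweep <- function(strategy_point, static_points, gamma_grid) {
  stopifnot(all(gamma_grid >= 0), !is.unsorted(gamma_grid))
  tab <- do.call(rbind, lapply(gamma_grid, function(g) {
    stat_obj <- static_points$mean_survival -
      g * static_points$mean_redundant
    tree_obj <- strategy_point$mean_survival -
      g * strategy_point$mean_redundant
    b <- which.max(stat_obj)
    data.frame(gamma = g, best_static = static_points$label[b],
               best_static_objective = stat_obj[b],
               strategy_objective = tree_obj,
               strategy_wins = tree_obj > stat_obj[b])
  }))
  win <- tab$gamma[tab$strategy_wins]
  list(table = tab,
       win_interval = if (length(win)) range(win) else NULL)
}

#' MDP survival-vs-fatigue frontier and concavity check
#'
#' Sweeps the fatigue penalty `gamma` over a grid on a fixed instance,
#' solves the MDP at each value, and evaluates the resulting optimal policy
#' with `gamma`-free accounting to obtain (expected redundant, expected
#' survival) pairs. The achieved frontier should be concave: each
#' additional redundant volunteer buys progressively less survival.
#'
#' @param config An [mdp_config()]; its own `gamma` is ignored.
#' @param gamma_grid Vector of `gamma` values to scalarise with.
#' @param tol Slope-violation tolerance (default 1e-9).
#' @return A list: `frontier` (`data.frame` of gamma, expected_survival,
#'   expected_redundant), `concave` (logical) and `max_violation`.
#' @export
mdp_frontier_concavity <- function(config, gamma_grid, tol = 1e-9) {
  pts <- do.call(rbind, lapply(gamma_grid, function(g) {
    cfg <- config
    cfg$tradeoff <- tradeoff_params(g)
    sol <- solve_backward_induction(cfg)
    ev <- evaluate_fixed_policy(cfg, sol)
    data.frame(gamma = g, expected_survival = ev$survival,
               expected_redundant = ev$redundant)
  }))
  uni <- pts[!duplicated(round(cbind(pts$expected_survival,
                                     pts$expected_redundant), 12)), ,
             drop = FALSE]
  uni <- uni[order(uni$expected_redundant, uni$expected_survival), ,
             drop = FALSE]
  max_viol <- 0
  if (nrow(uni) >= 3) {
    dg <- diff(uni$expected_redundant)
    ds <- diff(uni$expected_survival)
    ok <- dg > 1e-15
    slopes <- ds[ok] / dg[ok]
    if (length(slopes) >= 2) {
      max_viol <- max(c(0, diff(slopes)))
    }
  }
  list(frontier = pts, achieved = uni, concave = max_viol <= tol,
       max_violation = max_viol)
}
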