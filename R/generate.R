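#' Region model for synthetic incident generation
#'
#' A region is a table of area units, each with a resident population, an
#' area, a relative OHCA incident weight, and the fraction of residents
#' registered as CFRs (0.1% by default). Volunteer density per km^2 is
#' `population / area_km2 * cfr_fraction`. Incident locations reduce to the
#' centre of a dispatch disc, so geography enters only through these
#' densities and weights.
#'
#' @param unit_id Identifiers of the area units.
#' @param population Residents per unit.
#' @param area_km2 Unit areas in km^2.
#' @param incident_weight Relative OHCA rates; nonnegative, not all zero.
#' @param cfr_fraction Proportion of residents registered as CFRs.
#' @return A `data.frame` of class `region_model` with a `cfr_density`
#'   column (volunteers per km^2).
#' @export
region_model <- function(unit_id, population, area_km2, incident_weight = 1,
                         cfr_fraction = 0.001) {
  stopifnot(all(population >= 0), all(area_km2 > 0),
            all(incident_weight >= 0), any(incident_weight > 0),
            all(cfr_fraction >= 0))
  df <- data.frame(unit_id = unit_id, population = population,
                   area_km2 = area_km2,
                   incident_weight = rep_len(incident_weight,
                                             length(population)),
                   cfr_fraction = rep_len(cfr_fraction, length(population)))
  df$cfr_density <- df$population / df$area_km2 * df$cfr_fraction
  class(df) <- c("region_model", "data.frame")
  df
}

#' A one-unit toy region
#'
#' Volunteer density of exactly 1 per km^2 (population 1000 in 1 km^2 at the
#' default 0.1% registration rate), so the expected volunteer count inside a
#' 1 km dispatch disc is pi.
#'
#' @return A [region_model()] with a single area unit.
#' @export
toy_region <- function() {
  region_model(unit_id = "toy", population = 1000, area_km2 = 1,
               incident_weight = 1)
}

#' Read a region from CSV
#'
#' Expects columns `unit_id`, `population`, `area_km2`, `incident_weight`
#' and optionally `cfr_fraction`.
#'
#' @param path CSV file path.
#' @return A [region_model()].
#' @export
read_region <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  region_model(x$unit_id, x$population, x$area_km2, x$incident_weight,
               if ("cfr_fraction" %in% names(x)) x$cfr_fraction else 0.001)
}

#' Sample a spatial Poisson volunteer field
#'
#' Draws the volunteers present in the dispatch disc around one incident.
#' The incident's area unit is chosen with probability proportional to
#' `incident_weight`; the volunteer count is Poisson with mean
#' `density * pi * radius_km^2`; positions are uniform on the disc (distance
#' proportional to the square root of a uniform), and travel time is the
#' straight-line distance at walking speed.
#'
#' @param region A [region_model()].
#' @param radius_km Dispatch radius (default 1 km).
#' @param speed_kmh Volunteer walking speed (default 6 km/h, so the 1 km
#'   boundary corresponds to 10 minutes of travel).
#' @return Unsorted numeric vector of travel times in minutes.
#' @export
sample_volunteer_field <- function(region, radius_km = 1, speed_kmh = 6) {
  stopifnot(radius_km > 0, speed_kmh > 0)
  i <- if (nrow(region) == 1L) 1L else {
    sample.int(nrow(region), 1L, prob = region$incident_weight)
  }
  lambda <- region$cfr_density[i] * pi * radius_km^2
  n <- stats::rpois(1L, lambda)
  if (n == 0L) return(numeric(0))
  dist_km <- radius_km * sqrt(stats::runif(n))
  dist_km / speed_kmh * 60
}

#' Sample triage delays
#'
#' Time from emergency-call arrival to volunteer-system activation.
#' Lognormal with median `median_min` (2 minutes by default), truncated at
#' `max_min` (10 minutes) by resampling, mirroring the practice of
#' discarding incidents whose triage delay is too long for a volunteer
#' response to matter.
#'
#' @param n Number of draws.
#' @param median_min Median triage delay in minutes.
#' @param sdlog Lognormal shape parameter.
#' @param max_min Truncation point in minutes.
#' @return Numeric vector of delays in (0, `max_min`\].
#' @export
sample_triage_delay <- function(n, median_min = 2, sdlog = 0.9,
                                max_min = 10) {
  stopifnot(n >= 0, median_min > 0, sdlog > 0, max_min > median_min)
  out <- stats::rlnorm(n, log(median_min), sdlog)
  bad <- which(out > max_min)
  while (length(bad)) {
    out[bad] <- stats::rlnorm(length(bad), log(median_min), sdlog)
    bad <- bad[out[bad] > max_min]
  }
  out
}

#' Volunteer response sampler
#'
#' Generates joint (outcome, view delay) draws for alerted volunteers.
#' Outcomes are accept / reject / ignore; ignoring volunteers never respond
#' and carry an infinite view delay. The default parametric sampler is
#' calibrated to the observed alert statistics of an operating CFR system:
#' acceptance 14.24%, rejection 30.02%, and responder view delays with 84%
#' within 5 minutes, 95% within 10 minutes, and a 20--50 s mode. View delays
#' are lognormal; the accepter scale is shrunk by `accept_speedup`
#' relative to rejecters (accepters decide slightly faster), with the
#' responder mixture centred so the two calibration quantiles are preserved.
#'
#' @param p_accept,p_reject Marginal outcome probabilities; the remainder is
#'   the no-response probability.
#' @param q5,q10 Responder view-delay calibration quantiles:
#'   `P(view <= 5 min | responded) = q5`, `P(view <= 10 min) = q10`.
#' @param accept_speedup Multiplicative shrink of the accept-conditional
#'   lognormal scale versus reject-conditional (default 0.9).
#' @return An object of class `response_sampler` with `mode = "parametric"`.
#' @export
response_sampler <- function(p_accept = 0.1424, p_reject = 0.3002,
                             q5 = 0.84, q10 = 0.95, accept_speedup = 0.9) {
  stopifnot(p_accept >= 0, p_reject >= 0, p_accept + p_reject <= 1,
            q5 < q10, q10 < 1, accept_speedup > 0)
  sdlog <- (log(10) - log(5)) / (stats::qnorm(q10) - stats::qnorm(q5))
  mu <- log(5) - stats::qnorm(q5) * sdlog
  w_a <- if (p_accept + p_reject > 0) p_accept / (p_accept + p_reject) else 0
  # split the responder meanlog so the mixture stays centred on mu
  delta <- log(accept_speedup)
  mu_rej <- mu - w_a * delta
  mu_acc <- mu_rej + delta
  structure(list(mode = "parametric", p_accept = p_accept,
                 p_reject = p_reject,
                 meanlog_accept = mu_acc, meanlog_reject = mu_rej,
                 sdlog = sdlog),
            class = "response_sampler")
}

#' Empirical response sampler
#'
#' Bootstraps (outcome, view delay) pairs jointly from a user-supplied table
#' of historical alert outcomes, preserving any dependence between response
#' type and view delay.
#'
#' @param table A `data.frame` with columns `outcome` (one of `"accept"`,
#'   `"reject"`, `"ignore"`) and `view_delay_min` (minutes; ignored rows may
#'   be `Inf` or `NA`).
#' @return An object of class `response_sampler` with `mode = "empirical"`.
#' @export
empirical_response_sampler <- function(table) {
  stopifnot(all(c("outcome", "view_delay_min") %in% names(table)),
            all(table$outcome %in% c("accept", "reject", "ignore")))
  table$view_delay_min[table$outcome == "ignore"] <- Inf
  stopifnot(all(table$view_delay_min[table$outcome != "ignore"] > 0))
  structure(list(mode = "empirical", table = table),
            class = "response_sampler")
}

#' Memoryless (geometric) response sampler
#'
#' The response model underlying the MDP: during every `step_seconds` step
#' after the alert, the volunteer accepts with probability `p_step_accept`
#' and rejects with `p_step_reject`, independently across steps. The view
#' delay equals the (geometric) response step times the step length. Used
#' to compare discrete-event simulation output against exact MDP values.
#'
#' @param p_step_accept,p_step_reject Per-step probabilities.
#' @param step_seconds Step length in seconds (default 5).
#' @return An object of class `response_sampler` with `mode = "memoryless"`.
#' @export
memoryless_response_sampler <- function(p_step_accept, p_step_reject,
                                        step_seconds = 5) {
  stopifnot(p_step_accept >= 0, p_step_reject >= 0,
            p_step_accept + p_step_reject <= 1, p_step_accept +
              p_step_reject > 0)
  structure(list(mode = "memoryless", p_accept = p_step_accept,
                 p_reject = p_step_reject, step_seconds = step_seconds),
            class = "response_sampler")
}

#' Draw volunteer responses
#'
#' @param sampler A `response_sampler`.
#' @param n Number of draws.
#' @return A `data.frame` with columns `outcome` (character) and
#'   `view_delay` (minutes; `Inf` for ignored alerts).
#' @export
sample_response <- function(sampler, n = 1) {
  stopifnot(inherits(sampler, "response_sampler"), n >= 0)
  if (n == 0L) {
    return(data.frame(outcome = character(0), view_delay = numeric(0)))
  }
  if (sampler$mode == "empirical") {
    idx <- sample.int(nrow(sampler$table), n, replace = TRUE)
    return(data.frame(outcome = sampler$table$outcome[idx],
                      view_delay = sampler$table$view_delay_min[idx]))
  }
  if (sampler$mode == "memoryless") {
    p <- sampler$p_accept + sampler$p_reject
    k <- stats::rgeom(n, p) + 1L  # response step, support 1, 2, ...
    acc <- stats::runif(n) < sampler$p_accept / p
    return(data.frame(outcome = ifelse(acc, "accept", "reject"),
                      view_delay = k * sampler$step_seconds / 60))
  }
  u <- stats::runif(n)
  outcome <- ifelse(u < sampler$p_accept, "accept",
                    ifelse(u < sampler$p_accept + sampler$p_reject,
                           "reject", "ignore"))
  view <- rep(Inf, n)
  ia <- outcome == "accept"
  ir <- outcome == "reject"
  view[ia] <- stats::rlnorm(sum(ia), sampler$meanlog_accept, sampler$sdlog)
  view[ir] <- stats::rlnorm(sum(ir), sampler$meanlog_reject, sampler$sdlog)
  data.frame(outcome = outcome, view_delay = view)
}

#' Boost the acceptance rate of a response sampler
#'
#' Reweights the outcome marginals so that acceptance occurs with
#' probability `target_accept`, while leaving the conditional view-delay
#' distribution given each outcome unchanged --- the exact equivalent of
#' first drawing a Bernoulli accept/decline flag and resampling historical
#' responses until they match it. Declines split between rejection and
#' no-response in their original proportions.
#'
#' @param sampler A parametric or empirical `response_sampler`.
#' @param target_accept Target acceptance probability in (0, 1).
#' @return A `response_sampler` with the boosted marginals.
#' @export
boost_acceptance_rate <- function(sampler, target_accept) {
  stopifnot(inherits(sampler, "response_sampler"),
            target_accept > 0, target_accept < 1)
  if (sampler$mode == "memoryless") {
    stop("boosting is defined for parametric/empirical samplers")
  }
  if (sampler$mode == "empirical") {
    tab <- sampler$table
    p_acc <- mean(tab$outcome == "accept")
    if (p_acc == 0 || p_acc == 1) {
      stop("source sampler has no mass on a needed outcome")
    }
    w <- ifelse(tab$outcome == "accept", target_accept / p_acc,
                (1 - target_accept) / (1 - p_acc))
    out <- sampler
    out$table <- tab[sample.int(nrow(tab), 100000L, replace = TRUE,
                                prob = w), , drop = FALSE]
    rownames(out$table) <- NULL
    return(out)
  }
  p_acc <- sampler$p_accept
  if (p_acc == 0 || p_acc == 1) {
    stop("source sampler has no mass on a needed outcome")
  }
  decl <- 1 - p_acc
  out <- sampler
  out$p_accept <- target_accept
  out$p_reject <- sampler$p_reject * (1 - target_accept) / decl
  out
}

#' Incident container
#'
#' One synthetic OHCA with its dispatch-relevant quantities: the triage
#' delay, the (deterministic) ambulance response time from the call, and the
#' sorted travel times of the eligible volunteers. Eligibility requires a
#' volunteer, departing at activation, to be able to reach the patient no
#' later than the ambulance: `triage_delay + travel <= ems_response_from_call`
#' (travel is also bounded by the dispatch radius, 10 minutes at defaults).
#'
#' @param instance_id Identifier.
#' @param triage_delay Minutes from call to activation.
#' @param ems_response_from_call Minutes from call to ambulance arrival.
#' @param volunteer_travel_times Sorted ascending travel times, minutes.
#' @return An object of class `incident`.
#' @export
incident <- function(instance_id, triage_delay, ems_response_from_call,
                     volunteer_travel_times = numeric(0)) {
  stopifnot(triage_delay >= 0, ems_response_from_call > 0)
  v <- as.numeric(volunteer_travel_times)
  stopifnot(!is.unsorted(v),
            all(v + triage_delay <= ems_response_from_call + 1e-9))
  structure(list(instance_id = instance_id, triage_delay = triage_delay,
                 ems_response_from_call = ems_response_from_call,
                 volunteer_travel_times = v),
            class = "incident")
}

#' Generate one synthetic incident
#'
#' Samples a triage delay and a Poisson volunteer field, filters volunteers
#' to those able to beat the ambulance, and sorts travel times ascending.
#'
#' @param region A [region_model()].
#' @param ems_response_from_call Minutes from call to ambulance arrival.
#' @param instance_id Identifier to attach.
#' @param radius_km,speed_kmh Dispatch disc parameters.
#' @param triage_median_min,triage_sdlog,triage_max_min Passed to
#'   [sample_triage_delay()].
#' @return An [incident()].
#' @export
make_instance <- function(region, ems_response_from_call, instance_id = 1L,
                          radius_km = 1, speed_kmh = 6,
                          triage_median_min = 2, triage_sdlog = 0.9,
                          triage_max_min = 10) {
  stopifnot(ems_response_from_call > 0)
  triage <- sample_triage_delay(1L, triage_median_min, triage_sdlog,
                                triage_max_min)
  travel <- sample_volunteer_field(region, radius_km, speed_kmh)
  travel <- sort(travel[travel + triage <= ems_response_from_call])
  incident(instance_id, triage, ems_response_from_call, travel)
}

#' Generate a batch of incidents
#'
#' @inheritParams make_instance
#' @param n Number of incidents.
#' @param seed RNG seed; each call with the same arguments reproduces the
#'   same instances.
#' @return A list of [incident()] objects with ids `1..n`.
#' @export
make_instances <- function(region, n, ems_response_from_call, seed,
                           radius_km = 1, speed_kmh = 6,
                           triage_median_min = 2, triage_sdlog = 0.9,
                           triage_max_min = 10) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  lapply(seq_len(n), function(i) {
    make_instance(region, ems_response_from_call, i, radius_km, speed_kmh,
                  triage_median_min, triage_sdlog, triage_max_min)
  })
}

#' Feature vector for policy selection
#'
#' The classifier's predictors: the volunteer count inside the dispatch
#' radius, the triage delay, and the response time (triage delay + travel
#' time, i.e. minutes from the emergency call until the volunteer could be
#' on scene if they accepted instantly) of each of the `k_max` nearest
#' volunteers. Slots beyond the available volunteers are padded with a
#' large sentinel (999 minutes) so tree learners split cleanly on
#' "volunteer i exists and is near".
#'
#' @param incident An [incident()].
#' @param k_max Number of volunteer response-time features (default 10).
#' @return A named numeric vector: `n_volunteers`, `triage_delay`,
#'   `resp_1` ... `resp_<k_max>`.
#' @export
extract_features <- function(incident, k_max = 10) {
  stopifnot(k_max >= 1)
  v <- incident$volunteer_travel_times
  k <- length(v)
  resp <- rep(999, k_max)
  if (k > 0) {
    kk <- min(k, k_max)
    resp[seq_len(kk)] <- incident$triage_delay + v[seq_len(kk)]
  }
  stats::setNames(c(k, incident$triage_delay, resp),
                  c("n_volunteers", "triage_delay",
                    paste0("resp_", seq_len(k_max))))
}

#' Write / read incident batches as CSV
#'
#' `incidents.csv` holds one row per incident (`instance_id`,
#' `triage_delay_min`, `ems_response_min`); `volunteers.csv` one row per
#' eligible volunteer (`instance_id`, `rank`, `travel_time_min`).
#'
#' @param instances List of [incident()] objects.
#' @param prefix Path prefix; files `<prefix>_incidents.csv` and
#'   `<prefix>_volunteers.csv` are written.
#' @return The two file paths, invisibly.
#' @export
write_instances <- function(instances, prefix) {
  inc <- data.frame(
    instance_id = vapply(instances, function(x) as.integer(x$instance_id),
                         integer(1)),
    triage_delay_min = vapply(instances, function(x) x$triage_delay,
                              numeric(1)),
    ems_response_min = vapply(instances,
                              function(x) x$ems_response_from_call,
                              numeric(1)))
  vol <- do.call(rbind, lapply(instances, function(x) {
    k <- length(x$volunteer_travel_times)
    if (k == 0) return(NULL)
    data.frame(instance_id = as.integer(x$instance_id), rank = seq_len(k),
               travel_time_min = x$volunteer_travel_times)
  }))
  if (is.null(vol)) {
    vol <- data.frame(instance_id = integer(0), rank = integer(0),
                      travel_time_min = numeric(0))
  }
  f1 <- paste0(prefix, "_incidents.csv")
  f2 <- paste0(prefix, "_volunteers.csv")
  utils::write.csv(inc, f1, row.names = FALSE)
  utils::write.csv(vol, f2, row.names = FALSE)
  invisible(c(f1, f2))
}

#' @rdname write_instances
#' @export
read_instances <- function(prefix) {
  inc <- utils::read.csv(paste0(prefix, "_incidents.csv"))
  vol <- utils::read.csv(paste0(prefix, "_volunteers.csv"))
  lapply(seq_len(nrow(inc)), function(i) {
    id <- inc$instance_id[i]
    v <- vol$travel_time_min[vol$instance_id == id]
    incident(id, inc$triage_delay_min[i], inc$ems_response_min[i],
             sort(v))
  })
}
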