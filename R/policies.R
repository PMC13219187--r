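#' Dispatch policy specification
#'
#' A policy is an event-driven rule deciding how many CFRs to alert at
#' system activation and whether to issue further alerts as responses come
#' in. Volunteers are always alerted nearest-first. Four families are
#' supported:
#' \describe{
#'   \item{`send_all`}{alert every eligible volunteer at time 0.}
#'   \item{`send_n`}{alert `n` volunteers at time 0, none thereafter.}
#'   \item{`keep_n_until_t`}{alert `n` at time 0 and replace every incoming
#'     rejection with a fresh alert, up to `t_stop` minutes after activation.}
#'   \item{`phased_batches`}{alert batches of `n` every `batch_interval`
#'     seconds until someone accepts (the batch practice baseline).}
#' }
#' No family ever alerts after the first acceptance or after the 15-minute
#' alert-cancellation horizon.
#'
#' @param kind One of `"send_all"`, `"send_n"`, `"keep_n_until_t"`,
#'   `"phased_batches"`.
#' @param n Batch / maintenance size (ignored for `send_all`).
#' @param t_stop Minutes after activation at which `keep_n_until_t` stops
#'   replacing rejections (default 3).
#' @param batch_interval Seconds between `phased_batches` batches
#'   (default 30).
#' @param policy_id Stable integer id within an enumerated policy set.
#' @return An object of class `policy_spec`.
#' @export
policy_spec <- function(kind, n = NULL, t_stop = 3, batch_interval = 30,
                        policy_id = NA_integer_) {
  kind <- match.arg(kind,
                    c("send_all", "send_n", "keep_n_until_t",
                      "phased_batches"))
  if (kind != "send_all") {
    stopifnot(is.numeric(n), length(n) == 1, n >= 0, n == floor(n))
    n <- as.integer(n)
  } else {
    n <- NA_integer_
  }
  stopifnot(t_stop > 0, batch_interval > 0)
  structure(list(kind = kind, n = n, t_stop = t_stop,
                 batch_interval = batch_interval,
                 policy_id = as.integer(policy_id)),
            class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf("<policy %s: %s>\n",
              ifelse(is.na(x$policy_id), "?", x$policy_id),
              policy_label(x)))
  invisible(x)
}

#' Human-readable policy label
#'
#' @param spec A [policy_spec()].
#' @return A character label such as `"Send 3 at time 0"`.
#' @export
policy_label <- function(spec) {
  switch(spec$kind,
         send_all = "Send all at time 0",
         send_n = sprintf("Send %d at time 0", spec$n),
         keep_n_until_t = sprintf("Keep %d active until time %g", spec$n,
                                  spec$t_stop),
         phased_batches = sprintf("Batches of %d every %gs", spec$n,
                                  spec$batch_interval))
}

#' The default 22-policy dispatch set
#'
#' Enumerates the predefined policy classes used for simulation-based policy
#' selection: "Send n at time 0" for n = 0..10 (11 policies, ids 0..10,
#' including "send 0" for incidents where any alert would mostly generate
#' redundancy), "Keep n active until time 3 min" for n = 1..10 (ids 11..20),
#' and "Send all at time 0" (id 21) --- 22 policies in total, in a fixed
#' order so that ids double as classification labels.
#'
#' @return A list of 22 [policy_spec()] objects with `policy_id` 0..21.
#' @export
build_default_policy_set <- function() {
  set <- c(
    lapply(0:10, function(n) policy_spec("send_n", n = n)),
    lapply(1:10, function(n) policy_spec("keep_n_until_t", n = n, t_stop = 3)),
    list(policy_spec("send_all"))
  )
  for (i in seq_along(set)) set[[i]]$policy_id <- i - 1L
  set
}

#' The phased-batch practice baseline
#'
#' The dispatch rule used operationally by the St John GoodSAM deployment:
#' alert volunteers in batches of 3 and repeat every 30 seconds until at
#' least one person accepts. Supplied as an extra policy (id 22 by default)
#' outside the default 22-class label set.
#'
#' @param policy_id Integer id to assign (default 22).
#' @return A [policy_spec()] of kind `phased_batches`.
#' @export
sjas_policy <- function(policy_id = 22L) {
  policy_spec("phased_batches", n = 3, batch_interval = 30,
              policy_id = policy_id)
}

#' Number of alerts issued at system activation
#'
#' @param spec A [policy_spec()].
#' @param n_available Eligible volunteers within the dispatch radius.
#' @return Integer count, capped at `n_available`.
#' @export
initial_alert_count <- function(spec, n_available) {
  stopifnot(n_available >= 0)
  if (spec$kind == "send_all") return(as.integer(n_available))
  as.integer(min(spec$n, n_available))
}

#' Additional alerts triggered by a simulation event
#'
#' Encodes the event-driven part of each policy family. No alerts are ever
#' added once any volunteer has accepted.
#'
#' @param spec A [policy_spec()].
#' @param event One of `"rejection"`, `"acceptance"`, `"timer"`.
#' @param sim_time Minutes since system activation.
#' @param any_acceptance_so_far Has any volunteer accepted yet?
#' @param n_unalerted Volunteers not yet alerted.
#' @return Integer count of additional alerts to issue now.
#' @export
alerts_on_event <- function(spec, event, sim_time, any_acceptance_so_far,
                            n_unalerted) {
  event <- match.arg(event, c("rejection", "acceptance", "timer"))
  stopifnot(sim_time >= 0, n_unalerted >= 0)
  if (any_acceptance_so_far || event == "acceptance" || n_unalerted == 0L) {
    return(0L)
  }
  switch(spec$kind,
         send_all = 0L,
         send_n = 0L,
         keep_n_until_t =
           if (event == "rejection" && sim_time <= spec$t_stop) 1L else 0L,
         phased_batches =
           if (event == "timer") as.integer(min(spec$n, n_unalerted))
           else 0L)
}

#' Write a policy set to JSON
#'
#' The exported array keeps the `policy_id` to class-label mapping stable
#' across runs.
#'
#' @param set List of [policy_spec()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_policy_set <- function(set, path) {
  rows <- lapply(set, function(p) {
    list(policy_id = p$policy_id, kind = p$kind,
         n = if (is.na(p$n)) NULL else p$n,
         t_stop_min = p$t_stop, batch_interval_s = p$batch_interval)
  })
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a policy set from JSON
#'
#' @param path File written by [write_policy_set()].
#' @return List of [policy_spec()] objects.
#' @export
read_policy_set <- function(path) {
  rows <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(rows, function(r) {
    policy_spec(r$kind, n = r$n,
                t_stop = if (is.null(r$t_stop_min)) 3 else r$t_stop_min,
                batch_interval = if (is.null(r$batch_interval_s)) 30
                                 else r$batch_interval_s,
                policy_id = r$policy_id)
  })
}
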