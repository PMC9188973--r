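#' Generate an event-related task design
#'
#' Builds a pseudorandomized fear/neutral face design: brief events (350 ms by
#' default) separated by jittered inter-trial intervals drawn uniformly from
#' `iti_bounds`. When the drawn jitters do not fit inside the run, they are
#' shrunk linearly toward the lower bound until the run fits, which keeps every
#' ITI inside `iti_bounds` and yields a median ITI close to 5 s for the default
#' 130-volume, TR 2 s run.
#'
#' @param n_fear,n_neutral number of events per condition (defaults 24/24).
#' @param iti_bounds length-2 numeric, inter-trial interval bounds in seconds.
#' @param tr repetition time, seconds.
#' @param n_volumes number of volumes in the run.
#' @param stim_duration event duration, seconds.
#' @param start_offset time of the first event, seconds from run start.
#' @param seed integer seed; identical seeds give identical designs.
#' @return A `task_design` object: list with `events` (tibble with `onset`,
#'   `duration`, `trial_type`, `trial_index` numbered 1..n within condition),
#'   `tr` and `n_volumes`.
#' @export
generate_task_design <- function(n_fear = 24, n_neutral = 24,
                                 iti_bounds = c(3, 10), tr = 2,
                                 n_volumes = 130, stim_duration = 0.35,
                                 start_offset = 2, seed = 1) {
  assert_that(is_count(n_fear) && n_fear >= 1, "`n_fear` must be a positive count")
  assert_that(is_count(n_neutral) && n_neutral >= 1, "`n_neutral` must be a positive count")
  assert_that(length(iti_bounds) == 2 && iti_bounds[1] >= 0 && diff(iti_bounds) >= 0,
              "`iti_bounds` must be an increasing pair of non-negative seconds")
  n <- n_fear + n_neutral
  run_len <- tr * n_volumes
  end_buffer <- 2
  # time available for the n-1 inter-trial intervals
  avail <- run_len - start_offset - n * stim_duration - end_buffer
  min_total <- iti_bounds[1] * (n - 1)
  if (avail < min_total) {
    abort(sprintf(
      "run too short to place %d trials at minimum ITI %.1fs: need %.1fs of jitter, have %.1fs",
      n, iti_bounds[1], min_total, avail))
  }
  with_seed(seed, {
    itis <- runif(n - 1, iti_bounds[1], iti_bounds[2])
    if (sum(itis) > avail) {
      # shrink jitters toward the lower bound so the run fits
      s <- (avail - min_total) / (sum(itis) - min_total)
      itis <- iti_bounds[1] + s * (itis - iti_bounds[1])
    }
    onsets <- start_offset + cumsum(c(0, itis + stim_duration))
    trial_type <- sample(rep(c("fear", "neutral"), c(n_fear, n_neutral)))
    events <- tibble::tibble(
      onset = onsets,
      duration = stim_duration,
      trial_type = trial_type
    )
    events$trial_index <- stats::ave(seq_len(n), events$trial_type,
                                     FUN = seq_along)
    structure(list(events = events, tr = tr, n_volumes = n_volumes),
              class = "task_design")
  })
}

#' @export
print.task_design <- function(x, ...) {
  tab <- table(x$events$trial_type)
  cat(sprintf("<task_design> %d events (%s), %d volumes @ TR %gs\n",
              nrow(x$events),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$n_volumes, x$tr))
  invisible(x)
}

#' Inter-trial intervals of a design
#' @param design a `task_design`.
#' @return numeric vector of gaps between successive event offsets and onsets.
#' @export
design_itis <- function(design) {
  e <- design$events
  diff(e$onset) - e$duration[-nrow(e)]
}

#' Read and write BIDS-dialect event tables
#'
#' Tab-separated files with columns `onset`, `duration`, `trial_type`.
#' `write_events()` drops the internal `trial_index` column; `read_events()`
#' reconstructs it from temporal order within condition.
#'
#' @param design a `task_design` (or an events tibble for `write_events`).
#' @param path file path.
#' @param tr,n_volumes run geometry, required to rebuild a `task_design`.
#' @return `read_events()` returns a `task_design`.
#' @export
write_events <- function(design, path) {
  events <- if (inherits(design, "task_design")) design$events else design
  readr::write_tsv(events[, c("onset", "duration", "trial_type")], path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, tr = 2, n_volumes = 130) {
  events <- readr::read_tsv(path, show_col_types = FALSE)
  assert_that(all(c("onset", "duration", "trial_type") %in% names(events)),
              "events file must have onset, duration, trial_type columns")
  events <- events[order(events$onset), ]
  events$trial_index <- stats::ave(seq_len(nrow(events)), events$trial_type,
                                   FUN = seq_along)
  structure(list(events = tibble::as_tibble(events), tr = tr,
                 n_volumes = n_volumes),
            class = "task_design")
}
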