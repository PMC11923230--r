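# Pollinator-preference statistics on bumblebee choice-trial event logs:
# pooled chi-square goodness-of-fit against a 50:50 null, first-choice
# test, per-bee summaries.

validate_choice_events <- function(events) {
  need <- c("bee_id", "event_order", "morph", "probed", "handling_seconds")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("event log missing columns: ", paste(miss, collapse = ", "))
  if (!all(events$morph %in% c("yellow", "red")))
    stop("'morph' must be 'yellow' or 'red'")
  if (any(!is.finite(events$handling_seconds) | events$handling_seconds < 0))
    stop("handling_seconds must be finite and non-negative")
  invisible(events)
}

#' Pool choice counts across trials
#'
#' Tallies a preference metric per colour morph over all trials of one
#' species pair: `visits` counts every floral visit, `probes` counts visits
#' where the bee entered the corolla tube, `handling_time` sums handling
#' seconds (rounded to whole seconds), and `first_choice` counts one event
#' per bee, its earliest visit.
#'
#' @param events Event-log data.frame with columns `bee_id`, `event_order`,
#'   `morph` (`"yellow"`/`"red"`), `probed` (logical), `handling_seconds`.
#' @param metric One of `"visits"`, `"probes"`, `"handling_time"`,
#'   `"first_choice"`.
#' @return Named numeric vector `c(yellow = , red = )`.
#' @export
#' @examples
#' ev <- synth_choice(seed = 1)$events
#' pool_counts(ev, "visits")
pool_counts <- function(events, metric = c("visits", "probes", "handling_time",
                                           "first_choice")) {
  metric <- match.arg(metric)
  validate_choice_events(events)
  if (!nrow(events)) stop("empty trial set")
  morphs <- factor(events$morph, levels = c("yellow", "red"))
  counts <- switch(metric,
    visits = table(morphs),
    probes = tapply(as.logical(events$probed), morphs, sum, default = 0),
    handling_time = round(tapply(events$handling_seconds, morphs, sum,
                                 default = 0)),
    first_choice = {
      firsts <- do.call(rbind, lapply(split(events, events$bee_id), function(df)
        df[which.min(df$event_order), , drop = FALSE]))
      table(factor(firsts$morph, levels = c("yellow", "red")))
    })
  out <- as.numeric(counts)
  names(out) <- c("yellow", "red")
  out
}

#' Chi-square goodness-of-fit test for a two-morph preference
#'
#' Compares observed visit counts for the two colour morphs to the 50:50
#' expectation under no colour preference, with no continuity correction:
#' \eqn{\chi^2 = \sum (O - E)^2 / E}, E = total / 2, 1 degree of freedom.
#'
#' @param n_yellow,n_red Non-negative counts, not both zero.
#' @return List of class `"preference_result"`: `counts`, `chi_square`,
#'   `df` (= 1), `p`, `proportion_yellow`.
#' @export
#' @examples
#' chisq_gof(59, 30)  # strong preference for yellow
chisq_gof <- function(n_yellow, n_red) {
  if (n_yellow < 0 || n_red < 0) stop("counts must be non-negative")
  total <- n_yellow + n_red
  if (total < 1) stop("at least one choice is required")
  ht <- suppressWarnings(stats::chisq.test(c(n_yellow, n_red),
                                           p = c(0.5, 0.5)))
  structure(list(counts = c(yellow = n_yellow, red = n_red),
                 chi_square = unname(ht$statistic),
                 df = 1L,
                 p = unname(ht$p.value),
                 proportion_yellow = n_yellow / total),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("Choice preference: yellow %d vs red %d (%.1f%% yellow)\n",
              x$counts["yellow"], x$counts["red"],
              100 * x$proportion_yellow))
  cat(sprintf("  chi-square(1) = %.4g, p = %.4g\n", x$chi_square, x$p))
  invisible(x)
}

#' First-choice preference test
#'
#' Applies [chisq_gof()] to the colour of each bee's first (naive) visit.
#'
#' @inheritParams pool_counts
#' @return A `"preference_result"` (see [chisq_gof()]).
#' @export
first_choice_test <- function(events) {
  counts <- pool_counts(events, "first_choice")
  chisq_gof(counts["yellow"], counts["red"])
}

#' Per-bee choice summary
#'
#' One row per bee: visit counts by morph, probes, handling-time totals and
#' proportion of visits to yellow. Column sums reproduce the pooled
#' margins of [pool_counts()].
#'
#' @inheritParams pool_counts
#' @return Data.frame with columns `bee_id`, `n_visits`, `n_yellow`,
#'   `n_red`, `n_probes`, `handling_total`, `proportion_yellow`.
#' @export
per_bee_summary <- function(events) {
  validate_choice_events(events)
  rows <- lapply(split(events, events$bee_id), function(df) {
    data.frame(bee_id = df$bee_id[1],
               n_visits = nrow(df),
               n_yellow = sum(df$morph == "yellow"),
               n_red = sum(df$morph == "red"),
               n_probes = sum(as.logical(df$probed)),
               handling_total = sum(df$handling_seconds),
               proportion_yellow = mean(df$morph == "yellow"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
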