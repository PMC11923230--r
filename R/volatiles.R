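# GC-MS volatile processing: peak-filter cascade, Kovats retention index,
# standard-curve quantification to emission rates, and group summaries.

#' Configuration for the GC-MS peak-filter cascade
#'
#' Bundles the thresholds of the four-stage peak filter: minimum integrated
#' area, maximum retention time, blank-matching window and fold criterion,
#' and contaminant vocabulary.
#'
#' @param min_area Minimum peak area (detector counts). Peaks with smaller
#'   area are discarded; equality is retained (thresholds stated as "under"
#'   are strict).
#' @param max_retention Latest retention time (minutes) kept. Peaks eluting
#'   strictly later are discarded (high-molecular-weight, unlikely to be
#'   airborne attractants).
#' @param blank_rt_window Retention-time window (minutes) within which a
#'   sample peak is compared to blank peaks.
#' @param blank_fold A sample peak matched to a blank peak is kept only if
#'   its area is at least `blank_fold` times the blank peak's area.
#' @param contaminant_terms Character vector of case-insensitive substrings
#'   marking siloxane/silica/phthalate library identifications.
#' @param blank_match `"top"` compares only the top-ranked library hit of
#'   sample and blank peak (the default); `"any"` matches if the two peaks
#'   share any non-empty library hit.
#'
#' @return A list of class `"peak_filter_config"`.
#' @export
#' @examples
#' cfg <- peak_filter_config()
#' cfg$min_area
peak_filter_config <- function(min_area = 1e5,
                               max_retention = 30,
                               blank_rt_window = 0.1,
                               blank_fold = 5,
                               contaminant_terms = c("silox", "silic", "phthal"),
                               blank_match = c("top", "any")) {
  blank_match <- match.arg(blank_match)
  for (nm in c("min_area", "max_retention", "blank_rt_window", "blank_fold")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm))
  }
  structure(list(min_area = min_area, max_retention = max_retention,
                 blank_rt_window = blank_rt_window, blank_fold = blank_fold,
                 contaminant_terms = as.character(contaminant_terms),
                 blank_match = blank_match),
            class = "peak_filter_config")
}

#' Validate a GC-MS peak table
#'
#' A peak table has one row per detected peak with columns `sample_id`,
#' `rt_min` (retention time, minutes), `area` (detector counts) and three
#' tentative library identifications `hit1`, `hit2`, `hit3` ordered by match
#' rank (empty strings allowed).
#'
#' @param peaks A data.frame.
#' @return The validated data.frame, invisibly.
#' @export
validate_peak_table <- function(peaks) {
  need <- c("sample_id", "rt_min", "area", "hit1", "hit2", "hit3")
  miss <- setdiff(need, names(peaks))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(peaks)) {
    if (!is.numeric(peaks$rt_min) || any(!is.finite(peaks$rt_min)) ||
        any(peaks$rt_min < 0))
      stop("'rt_min' must be finite and non-negative")
    if (!is.numeric(peaks$area) || any(!is.finite(peaks$area)) ||
        any(peaks$area < 0))
      stop("'area' must be finite and non-negative")
  }
  invisible(peaks)
}

#' Area filter
#'
#' Removes peaks whose integrated area falls below the configured minimum
#' (very small peaks are artefacts of a sensitive default integrator).
#' Equality with the threshold is retained.
#'
#' @param peaks Peak table (see [validate_peak_table()]).
#' @param config A [peak_filter_config()].
#' @return The retained rows of `peaks`, order preserved.
#' @export
filter_area <- function(peaks, config = peak_filter_config()) {
  validate_peak_table(peaks)
  peaks[peaks$area >= config$min_area, , drop = FALSE]
}

#' Retention-time filter
#'
#' Removes peaks eluting strictly after the configured maximum retention
#' time. Equality is retained.
#'
#' @inheritParams filter_area
#' @return The retained rows of `peaks`, order preserved.
#' @export
filter_retention <- function(peaks, config = peak_filter_config()) {
  validate_peak_table(peaks)
  peaks[peaks$rt_min <= config$max_retention, , drop = FALSE]
}

#' Blank-subtraction filter
#'
#' A sample peak is removed when some blank peak has the same tentative
#' library identification, elutes within `blank_rt_window` minutes, and the
#' sample area is less than `blank_fold` times the blank area: the peak is
#' then attributed to background rather than the flowers. A match against
#' any qualifying blank peak excludes the sample peak; the triggering blank
#' peak is recorded.
#'
#' @param peaks Sample peak table.
#' @param blank_peaks Peak table from the paired blank run. If empty, all
#'   sample peaks are retained with a warning.
#' @param config A [peak_filter_config()]; `blank_match` selects whether
#'   only top-ranked hits are compared (default) or any shared hit counts.
#' @return A list with elements `retained` (sample rows kept) and `removed`
#'   (sample rows excluded, with `blank_rt`, `blank_area` and `blank_hit`
#'   columns identifying the triggering blank peak).
#' @export
filter_blank_matched <- function(peaks, blank_peaks,
                                 config = peak_filter_config()) {
  validate_peak_table(peaks)
  validate_peak_table(blank_peaks)
  n <- nrow(peaks)
  if (nrow(blank_peaks) == 0L) {
    warning("empty blank peak set: all sample peaks retained")
    removed <- cbind(peaks[0, , drop = FALSE],
                     blank_rt = numeric(0), blank_area = numeric(0),
                     blank_hit = character(0))
    return(list(retained = peaks, removed = removed))
  }
  hit_of <- function(df) as.character(df$hit1)
  drop <- logical(n)
  b_rt <- b_area <- rep(NA_real_, n)
  b_hit <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (config$blank_match == "top") {
      id_match <- hit_of(blank_peaks) == peaks$hit1[i] & nzchar(peaks$hit1[i])
    } else {
      s_hits <- setdiff(unlist(peaks[i, c("hit1", "hit2", "hit3")]), "")
      id_match <- vapply(seq_len(nrow(blank_peaks)), function(j) {
        length(intersect(s_hits,
                         setdiff(unlist(blank_peaks[j, c("hit1", "hit2", "hit3")]),
                                 ""))) > 0L
      }, logical(1))
    }
    cand <- which(id_match &
                  abs(blank_peaks$rt_min - peaks$rt_min[i]) <= config$blank_rt_window &
                  peaks$area[i] < config$blank_fold * blank_peaks$area)
    if (length(cand)) {
      drop[i] <- TRUE
      j <- cand[which.min(abs(blank_peaks$rt_min[cand] - peaks$rt_min[i]))]
      b_rt[i] <- blank_peaks$rt_min[j]
      b_area[i] <- blank_peaks$area[j]
      b_hit[i] <- blank_peaks$hit1[j]
    }
  }
  removed <- peaks[drop, , drop = FALSE]
  removed$blank_rt <- b_rt[drop]
  removed$blank_area <- b_area[drop]
  removed$blank_hit <- b_hit[drop]
  list(retained = peaks[!drop, , drop = FALSE], removed = removed)
}

#' Contaminant filter
#'
#' Removes a peak only when all three tentative library identifications
#' contain at least one contaminant term (case-insensitive substring match,
#' targeting siloxane/silica column bleed and phthalate plasticizers). A
#' single clean hit retains the peak.
#'
#' @inheritParams filter_area
#' @return The retained rows of `peaks`, order preserved.
#' @export
filter_contaminants <- function(peaks, config = peak_filter_config()) {
  validate_peak_table(peaks)
  if (!nrow(peaks)) return(peaks)
  dirty <- function(hits) {
    vapply(tolower(hits), function(h) {
      any(vapply(tolower(config$contaminant_terms),
                 function(term) grepl(term, h, fixed = TRUE), logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }
  all3 <- dirty(peaks$hit1) & dirty(peaks$hit2) & dirty(peaks$hit3)
  peaks[!all3, , drop = FALSE]
}

#' Full peak-filter cascade
#'
#' Applies, in order: area filter, retention-time filter, blank subtraction,
#' contaminant filter. Each predicate depends only on the individual peak
#' and the fixed blank table, so the retained set equals the joint
#' conjunction of the four predicates regardless of order.
#'
#' @inheritParams filter_blank_matched
#' @return A list with `peaks` (retained table) and `log` (one row per
#'   excluded peak with the triggering `rule`).
#' @export
#' @examples
#' syn <- synth_gcms(seed = 1, n_per_group = 2)
#' res <- filter_peaks(syn$peaks, syn$blanks)
#' table(res$log$rule)
filter_peaks <- function(peaks, blank_peaks, config = peak_filter_config()) {
  validate_peak_table(peaks)
  log_rows <- list()
  note <- function(df, rule) {
    if (nrow(df)) {
      df$rule <- rule
      log_rows[[length(log_rows) + 1L]] <<- df[, c("sample_id", "rt_min", "area", "rule")]
    }
  }
  kept <- filter_area(peaks, config)
  note(peaks[!rownames(peaks) %in% rownames(kept), , drop = FALSE], "min_area")
  prev <- kept
  kept <- filter_retention(prev, config)
  note(prev[!rownames(prev) %in% rownames(kept), , drop = FALSE], "max_retention")
  bl <- filter_blank_matched(kept, blank_peaks, config)
  note(bl$removed[, c("sample_id", "rt_min", "area"), drop = FALSE], "blank_match")
  prev <- bl$retained
  kept <- filter_contaminants(prev, config)
  note(prev[!rownames(prev) %in% rownames(kept), , drop = FALSE], "contaminant")
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(sample_id = character(0), rt_min = numeric(0),
               area = numeric(0), rule = character(0))
  rownames(log) <- NULL
  list(peaks = kept, log = log)
}

#' Kovats retention index (temperature-programmed convention)
#'
#' Converts retention times to the dimensionless Kovats scale by linear
#' interpolation between the bracketing rungs of an n-alkane ladder
#' (van den Dool–Kratz formula for ramped oven programs):
#' \deqn{RI = 100 n + 100 \frac{t - t_n}{t_{n+1} - t_n}}
#' where \eqn{t_n \le t \le t_{n+1}} are the retention times of the alkanes
#' with \eqn{n} and \eqn{n+1} carbons.
#'
#' @param rt Numeric vector of retention times (minutes).
#' @param ladder Data.frame with columns `carbon` (integer carbon number)
#'   and `rt_min`, both strictly increasing, at least two rungs.
#' @return Numeric vector of retention indices.
#' @export
#' @examples
#' ladder <- data.frame(carbon = 8:12, rt_min = c(4, 7, 10.5, 14, 17.2))
#' kovats_index(c(10.5, 12.25), ladder)  # 1000 at the C10 rung
kovats_index <- function(rt, ladder) {
  if (!all(c("carbon", "rt_min") %in% names(ladder)))
    stop("ladder needs columns 'carbon' and 'rt_min'")
  if (nrow(ladder) < 2L)
    stop("alkane ladder needs at least two rungs")
  if (any(diff(ladder$carbon) <= 0) || any(diff(ladder$rt_min) <= 0))
    stop("ladder must be strictly increasing in carbon number and retention time")
  lo <- min(ladder$rt_min); hi <- max(ladder$rt_min)
  if (any(rt < lo | rt > hi))
    stop(sprintf("retention time outside ladder span [%.4g, %.4g] min", lo, hi))
  # index of the lower bracketing rung; rt exactly at a rung maps to 100*carbon
  k <- findInterval(rt, ladder$rt_min, rightmost.closed = TRUE)
  t_n <- ladder$rt_min[k]
  t_n1 <- ladder$rt_min[k + 1L]
  c_n <- ladder$carbon[k]
  c_n1 <- ladder$carbon[k + 1L]
  100 * c_n + 100 * (c_n1 - c_n) * (rt - t_n) / (t_n1 - t_n)
}

#' Quantify peak areas as emission rates
#'
#' Back-calculates compound mass from peak area with each compound's
#' standard curve (`mass_ng = (area - intercept) / slope`, clipped at zero)
#' and divides by a per-sample scaling factor to give ng per flower per
#' hour. The default scaling of 48 encodes the sampling design: 2 flowers
#' per headspace sample collected over 24 h (an overall calibration factor
#' of 1 absorbs elution/aliquot/injection volumes; adjust `scaling` if your
#' protocol differs). Compounds lacking a curve may be routed to a
#' structurally similar surrogate curve via `surrogates`.
#'
#' @param peaks Peak table (filtered); the compound of each peak is taken
#'   from its top-ranked library hit unless a `compound` column is present.
#' @param curves Data.frame with columns `compound`, `slope` (area per ng,
#'   > 0) and `intercept` (area).
#' @param scaling Positive per-sample factor (flowers x hours x calibration);
#'   default `2 * 24`.
#' @param surrogates Optional named character vector mapping compounds
#'   without their own curve to the name of the surrogate curve compound.
#' @param ladder Optional alkane ladder; if given, a `kovats_ri` column is
#'   added (see [kovats_index()]).
#' @return Data.frame of emission records: `sample_id`, `compound`,
#'   `emission` (ng/flower/hour) and optionally `kovats_ri`.
#' @export
quantify_emissions <- function(peaks, curves, scaling = 2 * 24,
                               surrogates = NULL, ladder = NULL) {
  validate_peak_table(peaks)
  if (!all(c("compound", "slope", "intercept") %in% names(curves)))
    stop("curves needs columns 'compound', 'slope', 'intercept'")
  if (any(curves$slope <= 0)) stop("standard-curve slopes must be positive")
  if (!is.numeric(scaling) || length(scaling) != 1L || scaling <= 0)
    stop("'scaling' must be a single positive number")
  compound <- if ("compound" %in% names(peaks)) peaks$compound else peaks$hit1
  curve_for <- compound
  missing_curve <- !(curve_for %in% curves$compound)
  if (any(missing_curve) && !is.null(surrogates)) {
    sub <- curve_for %in% names(surrogates)
    curve_for[sub] <- unname(surrogates[curve_for[sub]])
    missing_curve <- !(curve_for %in% curves$compound)
  }
  if (any(missing_curve))
    stop("no standard curve or surrogate for compound(s): ",
         paste(unique(compound[missing_curve]), collapse = ", "))
  idx <- match(curve_for, curves$compound)
  mass_ng <- (peaks$area - curves$intercept[idx]) / curves$slope[idx]
  if (any(mass_ng < 0)) {
    warning(sum(mass_ng < 0),
            " peak(s) back-calculated below the curve intercept; clipped to 0")
    mass_ng <- pmax(0, mass_ng)
  }
  out <- data.frame(sample_id = peaks$sample_id, compound = compound,
                    emission = mass_ng / scaling,
                    stringsAsFactors = FALSE)
  if (!is.null(ladder)) out$kovats_ri <- kovats_index(peaks$rt_min, ladder)
  out
}

#' Total emission of one sample
#'
#' Arithmetic sum of per-compound emission rates for a single sample.
#'
#' @param emission Numeric vector of non-negative emission rates
#'   (ng/flower/hour) for one sample.
#' @return The summed emission rate; 0 with a warning for an empty input.
#' @export
total_emission <- function(emission) {
  if (length(emission) == 0L) {
    warning("no emission records: total is 0")
    return(0)
  }
  if (any(emission < 0)) stop("emission rates must be non-negative")
  sum(emission)
}

#' Per-sample total emissions
#'
#' @param records Emission records as returned by [quantify_emissions()].
#' @return Data.frame with one row per `sample_id` and its `total` emission.
#' @export
sample_totals <- function(records) {
  stopifnot(all(c("sample_id", "emission") %in% names(records)))
  agg <- stats::aggregate(emission ~ sample_id, data = records, FUN = sum)
  names(agg)[2] <- "total"
  agg
}

#' Fold change between two groups of totals
#'
#' Ratio of group means, the summary used to compare total scent emission of
#' colour morphs (e.g. yellow vs red).
#'
#' @param group_a,group_b Non-empty numeric vectors (e.g. per-sample total
#'   emissions); the denominator mean must be non-zero.
#' @return `mean(group_a) / mean(group_b)`.
#' @export
#' @examples
#' fold_change(675.830, 291.169)  # ~2.32
fold_change <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  mb <- mean(group_b)
  if (mb == 0) stop("denominator group mean is zero")
  mean(group_a) / mb
}

#' Welch two-sample t test
#'
#' Two-sided Welch test (unequal variances, Welch–Satterthwaite degrees of
#' freedom) for comparing a quantitative trait between two morphs.
#'
#' @param x,y Numeric vectors, each of length >= 2 with non-zero variance in
#'   at least one.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
#' @examples
#' welch_t(c(1, 2, 3), c(4, 5, 6))
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least two observations")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
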