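# Electroantennogram (EAG) normalization. Antennae fatigue over a recording
# session, so a positive-control odorant (phenylacetaldehyde, PAA) is
# presented in anchor blocks at the start, middle and end; test responses
# are corrected by a piecewise-linear baseline through the block means and
# scaled to the initial control response. The first presentation of each
# test stimulus is discarded (solvent blow-off inflates it).

validate_eag_series <- function(series, control_label = "PAA") {
  need <- c("antenna_id", "presentation_index", "stimulus", "amplitude_mV")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("EAG series missing columns: ", paste(miss, collapse = ", "))
  if (any(series$amplitude_mV <= 0)) stop("amplitudes must be positive")
  for (df in split(series, series$antenna_id)) {
    idx <- df$presentation_index[order(df$presentation_index)]
    if (any(duplicated(idx)))
      stop("presentation indices must be strictly increasing within an antenna")
    if (df$stimulus[which.min(df$presentation_index)] != control_label)
      stop("each series must start with the control stimulus '", control_label, "'")
    if (sum(df$stimulus == control_label) < 2L)
      stop("each series needs at least two control presentations")
  }
  invisible(series)
}

#' Remove the first response to each test stimulus
#'
#' The first exposure to a novel scent produces a disproportionately large
#' peak (solvent blow-off), so for every non-control stimulus the earliest
#' presentation within each antenna is dropped. Control presentations are
#' kept.
#'
#' @param series Data.frame with columns `antenna_id`, `presentation_index`
#'   (strictly increasing within antenna), `stimulus`, `amplitude_mV`.
#' @param control_label Stimulus label of the positive control (default
#'   `"PAA"`).
#' @return `series` without first test-stimulus presentations. A stimulus
#'   seen only once disappears entirely, with a warning.
#' @export
drop_first_responses <- function(series, control_label = "PAA") {
  validate_eag_series(series, control_label)
  drop <- rep(FALSE, nrow(series))
  for (ant in unique(series$antenna_id)) {
    sel <- series$antenna_id == ant & series$stimulus != control_label
    for (stim in unique(series$stimulus[sel])) {
      rows <- which(sel & series$stimulus == stim)
      if (length(rows) == 1L)
        warning("stimulus '", stim, "' has a single presentation in antenna '",
                ant, "' and is removed entirely")
      drop[rows[which.min(series$presentation_index[rows])]] <- TRUE
    }
  }
  series[!drop, , drop = FALSE]
}

#' Piecewise-linear control baseline for one antenna
#'
#' Control presentations arrive in consecutive anchor blocks. Each block is
#' summarized by its mean presentation index and mean amplitude; the
#' baseline interpolates linearly between block summaries and extends as a
#' constant before the first and after the last block. It models the
#' multiplicative drift (fatigue) of the antenna over the session.
#'
#' @param series Single-antenna EAG data.frame (see
#'   [drop_first_responses()]).
#' @param control_label Control stimulus label.
#' @return A function mapping presentation index to expected control
#'   amplitude (mV).
#' @export
control_baseline <- function(series, control_label = "PAA") {
  if (length(unique(series$antenna_id)) != 1L)
    stop("control_baseline() expects a single antenna; split the series first")
  ord <- order(series$presentation_index)
  df <- series[ord, , drop = FALSE]
  is_ctrl <- df$stimulus == control_label
  if (sum(is_ctrl) < 2L) stop("need at least two control presentations")
  # anchor blocks = maximal runs of consecutive control presentations
  r <- rle(is_ctrl)
  block_of <- rep.int(cumsum(r$values) * r$values, r$lengths)[is_ctrl]
  anchors_x <- tapply(df$presentation_index[is_ctrl], block_of, mean)
  anchors_y <- tapply(df$amplitude_mV[is_ctrl], block_of, mean)
  if (length(anchors_x) < 2L) {
    # a single block: flat baseline at the block mean
    y0 <- mean(anchors_y)
    return(function(index) rep(y0, length(index)))
  }
  stats::approxfun(as.numeric(anchors_x), as.numeric(anchors_y), rule = 2)
}

#' Normalize EAG responses against the control baseline
#'
#' For each antenna the corrected amplitude is the raw amplitude divided by
#' the control baseline at that presentation index (so control anchors sit
#' at 1 by construction), and the scaled amplitude re-expresses corrected
#' values relative to the initial control response. With the default
#' reference (`"first_block_mean"`) the initial reference equals the first
#' baseline value and scaled coincides with corrected;
#' `"first_presentation"` instead scales by first-block-mean / very first
#' control amplitude.
#'
#' @param series EAG data.frame, ideally after [drop_first_responses()].
#' @param control_label Control stimulus label.
#' @param scale_ref `"first_block_mean"` (default) or
#'   `"first_presentation"`.
#' @return Data.frame `antenna_id`, `presentation_index`, `stimulus`,
#'   `corrected_amplitude`, `scaled_amplitude`.
#' @export
#' @examples
#' syn <- synth_eag(seed = 1, n_antennae = 2)
#' norm <- eag_normalize(drop_first_responses(syn$series))
#' head(norm)
eag_normalize <- function(series, control_label = "PAA",
                          scale_ref = c("first_block_mean", "first_presentation")) {
  scale_ref <- match.arg(scale_ref)
  out <- lapply(split(series, series$antenna_id), function(df) {
    bl <- control_baseline(df, control_label)
    base <- bl(df$presentation_index)
    if (any(base <= 0)) stop("control baseline must be positive")
    corrected <- df$amplitude_mV / base
    first_idx <- min(df$presentation_index[df$stimulus == control_label])
    ref <- switch(scale_ref,
                  first_block_mean = bl(first_idx),
                  first_presentation = df$amplitude_mV[
                    df$presentation_index == first_idx])
    data.frame(antenna_id = df$antenna_id,
               presentation_index = df$presentation_index,
               stimulus = df$stimulus,
               corrected_amplitude = corrected,
               scaled_amplitude = corrected * bl(first_idx) / ref,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
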