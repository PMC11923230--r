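# Genome-wide variant-density profiling: fixed-width windowing of called
# variant sites per chromosome and Savitzky-Golay neighborhood smoothing
# for cross-species overlay of density tracks.

#' Read variant site positions from a VCF
#'
#' Parses a (optionally gzip-compressed) VCF and returns the distinct
#' variant sites. Multi-allelic records count as a single site: the track
#' is a site-count, not an allele-count.
#'
#' @param path Path to a VCF file.
#' @return Data.frame with columns `chrom` and `pos` (1-based).
#' @export
read_variant_positions <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  df <- data.frame(chrom = as.character(fix[, "CHROM"]),
                   pos = as.integer(fix[, "POS"]),
                   stringsAsFactors = FALSE)
  unique(df)
}

#' Read a chromosome-length table (FASTA index)
#'
#' Reads the first two columns of a `.fai`-format file (sequence name and
#' length).
#'
#' @param path Path to a FASTA index file.
#' @return Data.frame with columns `chrom` and `length`.
#' @export
read_fai <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]), length = as.numeric(tab[[2]]),
             stringsAsFactors = FALSE)
}

#' Per-window variant counts along chromosomes
#'
#' Tiles each chromosome with fixed-width windows (0-based half-open
#' `[start, end)`; the last window may be short) and counts the variant
#' sites falling in each. Input positions are 1-based per the VCF
#' convention, so a variant at position p falls in the window containing
#' p - 1. Windowing conserves the total variant count per chromosome.
#'
#' `window_size` has no default: published analyses of this kind have used
#' both 50 kb and 30 kb windows, so the choice is explicit.
#'
#' @param variants Data.frame with columns `chrom` and `pos` (1-based), as
#'   from [read_variant_positions()].
#' @param chrom_lengths Data.frame with columns `chrom` and `length` (bp),
#'   as from [read_fai()].
#' @param window_size Window width in bp (> 0).
#' @return Data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `count`, ordered by chromosome then start.
#' @export
#' @examples
#' v <- data.frame(chrom = "chr1", pos = c(1, 50000, 50001))
#' window_counts(v, data.frame(chrom = "chr1", length = 100000), 50000)
window_counts <- function(variants, chrom_lengths, window_size) {
  if (missing(window_size)) stop("'window_size' must be supplied (e.g. 50000 or 30000)")
  if (!is.numeric(window_size) || window_size <= 0)
    stop("'window_size' must be a positive number of base pairs")
  if (!all(c("chrom", "pos") %in% names(variants)))
    stop("variants needs columns 'chrom' and 'pos'")
  if (!all(c("chrom", "length") %in% names(chrom_lengths)))
    stop("chrom_lengths needs columns 'chrom' and 'length'")
  stray <- setdiff(unique(variants$chrom), chrom_lengths$chrom)
  if (length(stray))
    stop("variants on chromosome(s) absent from the length table: ",
         paste(stray, collapse = ", "))
  out <- lapply(seq_len(nrow(chrom_lengths)), function(i) {
    chrom <- chrom_lengths$chrom[i]
    len <- chrom_lengths$length[i]
    pos <- variants$pos[variants$chrom == chrom]
    bad <- pos < 1 | pos > len
    if (any(bad))
      stop(sprintf("variant position %d outside chromosome %s (length %d)",
                   pos[which(bad)[1]], chrom, as.integer(len)))
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    counts <- tabulate((pos - 1) %/% window_size + 1L, nbins = length(starts))
    data.frame(chrom = chrom, start = starts, end = ends, count = counts,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Savitzky-Golay center-point weights for a symmetric window of half-width h
sg_weights <- function(h, order = 2) {
  A <- outer(-h:h, 0:order, `^`)
  # first row of (A'A)^{-1} A' evaluates the fitted polynomial at the center
  solve(crossprod(A), t(A))[1, ]
}

#' Savitzky-Golay smoothing of a variant-density track
#'
#' Smooths per-window counts with a centred local least-squares quadratic
#' fit over `2 * neighbors + 1` windows, evaluated at the centre
#' (Savitzky-Golay convention). Near the chromosome ends the window
#' shrinks symmetrically, so polynomial signals of degree <= 2 are
#' reproduced exactly everywhere. If a chromosome has fewer than
#' `2 * neighbors + 1` windows, the half-width shrinks accordingly (with a
#' message).
#'
#' @param track Data.frame from [window_counts()] (columns `chrom`,
#'   `start`, `end`, `count`), or a plain numeric vector for a single
#'   chromosome.
#' @param neighbors Windows on each side of the centre (default 50, the
#'   "50 neighbors" convention: a 101-point window).
#' @param order Polynomial order of the local fit (default 2).
#' @return `track` with a `smooth` column (or, for vector input, the
#'   smoothed numeric vector).
#' @export
smooth_track <- function(track, neighbors = 50, order = 2) {
  if (2 * neighbors + 1 <= order)
    stop("window length 2 * neighbors + 1 must exceed the polynomial order")
  smooth_vec <- function(x) {
    n <- length(x)
    if (n == 1L) {
      warning("single-window track returned unchanged")
      return(x)
    }
    nb <- neighbors
    if (n < 2 * nb + 1) {
      nb <- (n - 1) %/% 2
      message("track has ", n, " windows; shrinking neighbors to ", nb)
    }
    out <- numeric(n)
    cache <- list()
    for (i in seq_len(n)) {
      h <- min(nb, i - 1L, n - i)
      if (2 * h + 1 <= order + 1) {
        # too few points for a non-trivial quadratic fit: interpolation is exact
        out[i] <- x[i]
      } else {
        key <- as.character(h)
        if (is.null(cache[[key]])) cache[[key]] <- sg_weights(h, order)
        out[i] <- sum(cache[[key]] * x[(i - h):(i + h)])
      }
    }
    out
  }
  if (is.numeric(track)) return(smooth_vec(track))
  stopifnot(all(c("chrom", "count") %in% names(track)))
  parts <- split(track, factor(track$chrom, levels = unique(track$chrom)))
  res <- do.call(rbind, lapply(parts, function(df) {
    df <- df[order(df$start), , drop = FALSE]
    df$smooth <- smooth_vec(df$count)
    df
  }))
  rownames(res) <- NULL
  res
}

#' Compare two variant-density tracks on a shared grid
#'
#' For two species' smoothed tracks on the same windowing grid, reports
#' per-window differences and, per chromosome, the Spearman rank
#' correlation between the tracks: high rank correlation would indicate
#' convergent regional patterns of variant accumulation, values near zero
#' indicate independent patterns.
#'
#' @param track_a,track_b Data.frames with columns `chrom`, `start`, `end`
#'   and a value column (`smooth` if present, else `count`), on identical
#'   grids.
#' @return List with `windows` (per-window `delta` = a - b) and `summary`
#'   (per chromosome: `n_windows`, `mean_delta`, `mean_abs_delta`,
#'   `spearman_rho`).
#' @export
overlay_summary <- function(track_a, track_b) {
  val <- function(tr) if ("smooth" %in% names(tr)) tr$smooth else tr$count
  grid_cols <- c("chrom", "start", "end")
  same_grid <- nrow(track_a) == nrow(track_b) &&
    all(track_a$chrom == track_b$chrom) &&
    all(track_a$start == track_b$start) &&
    all(track_a$end == track_b$end)
  if (!same_grid) stop("tracks are not on the same windowing grid")
  windows <- track_a[grid_cols]
  windows$value_a <- val(track_a)
  windows$value_b <- val(track_b)
  windows$delta <- windows$value_a - windows$value_b
  summ <- do.call(rbind, lapply(split(windows, windows$chrom), function(df) {
    rho <- if (stats::sd(df$value_a) == 0 || stats::sd(df$value_b) == 0)
      NA_real_
    else
      stats::cor(df$value_a, df$value_b, method = "spearman")
    data.frame(chrom = df$chrom[1], n_windows = nrow(df),
               mean_delta = mean(df$delta),
               mean_abs_delta = mean(abs(df$delta)),
               spearman_rho = rho, stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  list(windows = windows, summary = summ)
}
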