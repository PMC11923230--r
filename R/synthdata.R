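# Seeded synthetic-data generators. Each generator emulates the shape and
# statistical structure of one instrument/assay output so every pipeline
# stage can be exercised and validated by parameter recovery, with ground
# truth stored alongside. Defaults are fixed at the observed study
# magnitudes: ~2.3-fold emission difference between colour morphs, 2:1
# bumblebee preference for yellow, exponential antennal fatigue, spatially
# heterogeneous variant densities.

#' Synthetic GC-MS experiment
#'
#' Generates sample and paired-blank peak tables, an alkane ladder and
#' per-compound standard curves with a known true emission fold-change
#' between a "yellow" and a "red" sample group. Sample peaks carry
#' log-normal area noise; contaminant peaks (all-siloxane/phthalate hit
#' triplets), sub-threshold noise peaks, late-eluting peaks and
#' blank-shared background peaks are injected so every filter stage has
#' work to do.
#'
#' @param seed Integer RNG seed.
#' @param n_per_group Samples per colour group (default 15).
#' @param fold True total-emission fold-change, yellow over red (default
#'   2.3).
#' @param base_emissions Named vector of red-group mean emission rates
#'   (ng/flower/hour) per true compound.
#' @param area_cv Log-normal coefficient of variation of peak areas
#'   (default 0.25).
#' @param scaling Area-to-emission scaling (flowers x hours; default 48).
#' @param contaminant_rate Expected contaminant peaks per sample (default
#'   2).
#' @param blank_shared_rate Expected background (blank-shared) peaks per
#'   sample (default 2).
#' @return List: `peaks`, `blanks` (peak tables), `ladder`, `curves`,
#'   `samples` (sample_id and group), and `truth` (per-compound group
#'   means, `fold`, `scaling`).
#' @export
#' @examples
#' syn <- synth_gcms(seed = 42, n_per_group = 3)
#' head(syn$peaks)
synth_gcms <- function(seed, n_per_group = 15, fold = 2.3,
                       base_emissions = c("alpha-pinene" = 120,
                                          "beta-myrcene" = 45,
                                          "sabinene" = 60,
                                          "limonene" = 25,
                                          "linalool" = 15,
                                          "methyl salicylate" = 8),
                       area_cv = 0.25, scaling = 48,
                       contaminant_rate = 2, blank_shared_rate = 2) {
  set.seed(seed)
  compounds <- names(base_emissions)
  k <- length(compounds)
  rt_mean <- seq(6, 24, length.out = k)
  curves <- data.frame(compound = compounds,
                       slope = stats::runif(k, 1.5e4, 3e4),
                       intercept = stats::runif(k, 5e3, 2e4),
                       stringsAsFactors = FALSE)
  ladder <- data.frame(carbon = 5:25,
                       rt_min = 1.2 + 1.35 * (5:25 - 5) +
                         0.005 * (5:25 - 5)^2)
  sdlog <- sqrt(log(1 + area_cv^2))
  samples <- data.frame(sample_id = sprintf("s%02d", seq_len(2 * n_per_group)),
                        group = rep(c("yellow", "red"), each = n_per_group),
                        stringsAsFactors = FALSE)
  contam_names <- c("hexamethylcyclotrisiloxane", "octamethyltetrasiloxane",
                    "silicic acid derivative", "dibutyl phthalate",
                    "diisooctyl phthalate")
  bg_names <- c("toluene background", "styrene background", "decanal background")
  peak_rows <- list()
  blank_rows <- list()
  add_peak <- function(store, sample_id, rt, area, hits) {
    row <- data.frame(sample_id = sample_id, rt_min = rt, area = area,
                      hit1 = hits[1], hit2 = hits[2], hit3 = hits[3],
                      stringsAsFactors = FALSE)
    if (store == "sample") peak_rows[[length(peak_rows) + 1L]] <<- row
    else blank_rows[[length(blank_rows) + 1L]] <<- row
  }
  for (i in seq_len(nrow(samples))) {
    sid <- samples$sample_id[i]
    gf <- if (samples$group[i] == "yellow") fold else 1
    for (j in seq_len(k)) {
      true_em <- base_emissions[j] * gf *
        stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      area <- true_em * scaling * curves$slope[j] + curves$intercept[j]
      rt <- rt_mean[j] + stats::rnorm(1, 0, 0.02)
      add_peak("sample", sid, rt, area,
               c(compounds[j], paste(compounds[j], "isomer"), "unknown"))
    }
    # sub-threshold integrator noise
    for (r in seq_len(stats::rpois(1, 3)))
      add_peak("sample", sid, stats::runif(1, 3, 28),
               stats::runif(1, 1e3, 9e4),
               c("noise peak", "noise peak b", "noise peak c"))
    # late-eluting heavies
    for (r in seq_len(stats::rpois(1, 1)))
      add_peak("sample", sid, stats::runif(1, 30.5, 38),
               stats::runif(1, 2e5, 8e5),
               c("heavy wax ester", "heavy alkane", "unknown heavy"))
    # contaminants: all three hits dirty
    for (r in seq_len(stats::rpois(1, contaminant_rate)))
      add_peak("sample", sid, stats::runif(1, 5, 28),
               stats::runif(1, 1.5e5, 9e5),
               sample(contam_names, 3))
    # background shared with the blank: sample area < 5x blank area
    for (r in seq_len(stats::rpois(1, blank_shared_rate))) {
      bg <- sample(bg_names, 1)
      rt <- stats::runif(1, 4, 27)
      b_area <- stats::runif(1, 2e5, 6e5)
      add_peak("sample", sid, rt + stats::runif(1, -0.08, 0.08),
               b_area * stats::runif(1, 0.5, 4.5),
               c(bg, "unknown", "unknown"))
      add_peak("blank", paste0(sid, "_blank"), rt, b_area,
               c(bg, "unknown", "unknown"))
    }
  }
  # blank also carries its own contaminants
  for (r in seq_len(stats::rpois(1, 4)))
    add_peak("blank", "blank_run", stats::runif(1, 5, 28),
             stats::runif(1, 1.5e5, 6e5), sample(contam_names, 3))
  truth <- list(
    group_means = rbind(yellow = base_emissions * fold, red = base_emissions),
    fold = fold, scaling = scaling)
  peaks <- do.call(rbind, peak_rows); rownames(peaks) <- NULL
  blanks <- do.call(rbind, blank_rows); rownames(blanks) <- NULL
  list(peaks = peaks, blanks = blanks, ladder = ladder, curves = curves,
       samples = samples, truth = truth)
}

#' Synthetic reflectance spectra
#'
#' Generates long-format reflectance tables for a "red-like" line (low
#' reflectance below 600 nm with a sharp long-wavelength shoulder) and a
#' "yellow-like" line (high plateau above ~520 nm plus a small UV bump, a
#' subtle bullseye), with replicate structure and Gaussian noise, plus a
#' green-leaf background spectrum.
#'
#' @param seed Integer RNG seed.
#' @param n_plants Plants per line (default 5).
#' @param n_flowers Flowers per plant (default 3).
#' @param n_reps Technical replicates per flower (default 3).
#' @param noise_sd Gaussian reflectance noise SD (default 0.01).
#' @param grid Wavelength grid (default 300:700 nm).
#' @return List: `spectra` (long data.frame: line, plant_id, flower_id,
#'   replicate, wavelength_nm, reflectance) and `background` (data.frame:
#'   wavelength_nm, reflectance).
#' @export
synth_spectra <- function(seed, n_plants = 5, n_flowers = 3, n_reps = 3,
                          noise_sd = 0.01, grid = 300:700) {
  set.seed(seed)
  shapes <- list(
    red = function(wl) 0.05 + 0.55 / (1 + exp(-(wl - 620) / 12)),
    yellow = function(wl) 0.05 + 0.60 / (1 + exp(-(wl - 520) / 15)) +
      0.12 * exp(-((wl - 360) / 25)^2))
  rows <- list()
  for (line in names(shapes)) {
    base <- shapes[[line]](grid)
    for (p in seq_len(n_plants)) for (f in seq_len(n_flowers))
      for (r in seq_len(n_reps)) {
        refl <- pmin(pmax(base + stats::rnorm(length(grid), 0, noise_sd), 0), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          line = line, plant_id = sprintf("%s_p%d", line, p),
          flower_id = sprintf("%s_p%d_f%d", line, p, f),
          replicate = r, wavelength_nm = grid, reflectance = refl,
          stringsAsFactors = FALSE)
      }
  }
  spectra <- do.call(rbind, rows); rownames(spectra) <- NULL
  list(spectra = spectra,
       background = data.frame(wavelength_nm = grid,
                               reflectance = green_leaf_background(grid)))
}

#' Synthetic EAG session
#'
#' Builds per-antenna presentation schedules with the control odorant in
#' three four-exposure anchor blocks (first, middle, final) and the test
#' stimuli in between. Amplitudes follow multiplicative exponential
#' fatigue, `A * exp(-k * i) * rho_s * (1 + eps)`, with the first
#' presentation of each test stimulus inflated (solvent blow-off).
#'
#' @param seed Integer RNG seed.
#' @param n_antennae Number of antennae (default 9).
#' @param rho Named vector of true stimulus response ratios relative to the
#'   control.
#' @param k Fatigue decay rate per presentation (default 0.04).
#' @param amplitude0 Initial control amplitude, mV (default 2).
#' @param noise_sd Multiplicative noise SD (default 0.05).
#' @param n_reps Presentations of each test stimulus (default 6).
#' @param first_inflation Multiplier on the first presentation of each test
#'   stimulus (default 1.6).
#' @return List: `series` (data.frame antenna_id, presentation_index,
#'   stimulus, amplitude_mV) and `truth` (`rho`, `k`).
#' @export
synth_eag <- function(seed, n_antennae = 9,
                      rho = c(air = 0.3, solvent = 0.5,
                              MvY = 0.9, MvR = 0.8, McY = 1.0, McR = 0.85),
                      k = 0.04, amplitude0 = 2, noise_sd = 0.05,
                      n_reps = 6, first_inflation = 1.6) {
  set.seed(seed)
  stimuli <- names(rho)
  rows <- list()
  for (a in seq_len(n_antennae)) {
    test_sched <- sample(rep(stimuli, n_reps))
    half <- length(test_sched) %/% 2
    sched <- c(rep("PAA", 4), test_sched[seq_len(half)],
               rep("PAA", 4), test_sched[-seq_len(half)], rep("PAA", 4))
    seen <- character(0)
    amp <- numeric(length(sched))
    for (i in seq_along(sched)) {
      s <- sched[i]
      r <- if (s == "PAA") 1 else unname(rho[s])
      infl <- 1
      if (s != "PAA" && !(s %in% seen)) {
        infl <- first_inflation
        seen <- c(seen, s)
      }
      amp[i] <- amplitude0 * exp(-k * i) * r * infl *
        (1 + stats::rnorm(1, 0, noise_sd))
    }
    rows[[a]] <- data.frame(antenna_id = sprintf("ant%02d", a),
                            presentation_index = seq_along(sched),
                            stimulus = sched, amplitude_mV = pmax(amp, 1e-4),
                            stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, rows); rownames(series) <- NULL
  list(series = series, truth = list(rho = rho, k = k))
}

#' Synthetic bumblebee choice trials
#'
#' Per-bee visit events with morph drawn iid Bernoulli(P(yellow)), visit
#' counts Poisson (truncated at one: a successful trial has at least one
#' visit), probe flags Bernoulli and handling times Gamma. Defaults emulate
#' the study design: 10 successful trials with ~9 visits each and a 2:1
#' preference for yellow.
#'
#' @param seed Integer RNG seed.
#' @param p_yellow True probability a visit goes to yellow (default 2/3).
#' @param n_bees Number of successful trials/bees (default 10).
#' @param visits_lambda Poisson mean of visits per bee (default 9).
#' @param p_probe Probability a visit includes a corolla probe (default
#'   0.5).
#' @param handling_shape,handling_rate Gamma parameters of per-visit
#'   handling seconds (default shape 2, rate 0.4: mean 5 s).
#' @param species_pair Label for the comparison (default `"MvY-MvR"`).
#' @return List: `events` (data.frame bee_id, species_pair, event_order,
#'   morph, probed, handling_seconds) and `truth` (`p_yellow`).
#' @export
synth_choice <- function(seed, p_yellow = 2/3, n_bees = 10,
                         visits_lambda = 9, p_probe = 0.5,
                         handling_shape = 2, handling_rate = 0.4,
                         species_pair = "MvY-MvR") {
  set.seed(seed)
  rows <- list()
  for (b in seq_len(n_bees)) {
    n <- 0
    while (n == 0) n <- stats::rpois(1, visits_lambda)
    morph <- ifelse(stats::runif(n) < p_yellow, "yellow", "red")
    rows[[b]] <- data.frame(bee_id = sprintf("bee%02d", b),
                            species_pair = species_pair,
                            event_order = seq_len(n), morph = morph,
                            probed = stats::runif(n) < p_probe,
                            handling_seconds = stats::rgamma(n, handling_shape,
                                                             handling_rate),
                            stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, rows); rownames(events) <- NULL
  list(events = events, truth = list(p_yellow = p_yellow))
}

#' Synthetic variant calls
#'
#' Draws variant positions from an inhomogeneous Poisson process with
#' piecewise-constant intensity along mock chromosomes, so per-window
#' expected counts are known exactly.
#'
#' @param seed Integer RNG seed.
#' @param chrom_lengths Data.frame `chrom`, `length` (bp); default two mock
#'   chromosomes of 2 Mb and 1.5 Mb.
#' @param segments_per_chrom Number of equal-length intensity segments per
#'   chromosome (default 4).
#' @param intensity_range Range of per-bp variant intensities from which
#'   segment rates are drawn (default 2e-4 to 2e-3).
#' @return List: `variants` (data.frame chrom, pos), `chrom_lengths`, and
#'   `truth` (data.frame chrom, seg_start, seg_end, rate).
#' @export
synth_variants <- function(seed,
                           chrom_lengths = data.frame(
                             chrom = c("chr1", "chr2"),
                             length = c(2e6, 1.5e6),
                             stringsAsFactors = FALSE),
                           segments_per_chrom = 4,
                           intensity_range = c(2e-4, 2e-3)) {
  set.seed(seed)
  var_rows <- list()
  truth_rows <- list()
  for (i in seq_len(nrow(chrom_lengths))) {
    chrom <- chrom_lengths$chrom[i]
    len <- chrom_lengths$length[i]
    bounds <- round(seq(0, len, length.out = segments_per_chrom + 1))
    rates <- stats::runif(segments_per_chrom, intensity_range[1],
                          intensity_range[2])
    for (s in seq_len(segments_per_chrom)) {
      seg_len <- bounds[s + 1] - bounds[s]
      n <- stats::rpois(1, seg_len * rates[s])
      if (n > 0) {
        pos <- sort(sample.int(seg_len, n, replace = TRUE)) + bounds[s]
        var_rows[[length(var_rows) + 1L]] <-
          data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
      }
      truth_rows[[length(truth_rows) + 1L]] <-
        data.frame(chrom = chrom, seg_start = bounds[s], seg_end = bounds[s + 1],
                   rate = rates[s], stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(var_rows)) unique(do.call(rbind, var_rows)) else
    data.frame(chrom = character(0), pos = integer(0), stringsAsFactors = FALSE)
  variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL
  list(variants = variants, chrom_lengths = chrom_lengths,
       truth = do.call(rbind, truth_rows))
}

#' Write variants as a minimal VCF
#'
#' Writes a valid plain-text VCFv4.2 file (with contig headers) holding one
#' biallelic SNP record per variant site, readable by standard VCF parsers
#' and by [read_variant_positions()].
#'
#' @param variants Data.frame `chrom`, `pos`.
#' @param chrom_lengths Data.frame `chrom`, `length`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, chrom_lengths, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=floralshift-synth",
              sprintf("##contig=<ID=%s,length=%d>", chrom_lengths$chrom,
                      as.integer(chrom_lengths$length)),
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\tA\tT\t50\tPASS\t.",
                  variants$chrom, as.integer(variants$pos))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a FASTA-index style chromosome length table
#'
#' @param chrom_lengths Data.frame `chrom`, `length`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fai <- function(chrom_lengths, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%d", chrom_lengths$chrom,
                   as.integer(chrom_lengths$length), 10L, 60L, 61L)
  writeLines(lines, path)
  invisible(path)
}
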