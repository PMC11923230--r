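# Independent brute-force oracles used to validate the vectorized
# implementations, plus small random-fixture builders.

# random peak table drawing hits from a mixed contaminant/clean vocabulary
random_peak_table <- function(n, sample_id = "s1") {
  contam <- c("hexamethylcyclotrisiloxane", "siloxane D4", "silicic ester",
              "dibutyl phthalate")
  clean <- c("alpha-pinene", "beta-myrcene", "linalool", "sabinene",
             "unknown", "")
  vocab <- c(contam, clean)
  data.frame(sample_id = sample_id,
             rt_min = stats::runif(n, 0, 35),
             area = exp(stats::runif(n, log(1e4), log(1e6))),
             hit1 = sample(vocab, n, replace = TRUE),
             hit2 = sample(vocab, n, replace = TRUE),
             hit3 = sample(vocab, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# all-pairs brute-force evaluation of the four filter predicates jointly
oracle_cascade_keep <- function(peaks, blanks, cfg) {
  dirty <- function(h) {
    h <- tolower(h)
    any(vapply(cfg$contaminant_terms, function(tm) grepl(tm, h, fixed = TRUE),
               logical(1)))
  }
  vapply(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    if (p$area < cfg$min_area) return(FALSE)
    if (p$rt_min > cfg$max_retention) return(FALSE)
    for (j in seq_len(nrow(blanks))) {
      b <- blanks[j, ]
      if (nzchar(p$hit1) && p$hit1 == b$hit1 &&
          abs(p$rt_min - b$rt_min) <= cfg$blank_rt_window &&
          p$area < cfg$blank_fold * b$area) return(FALSE)
    }
    if (dirty(p$hit1) && dirty(p$hit2) && dirty(p$hit3)) return(FALSE)
    TRUE
  }, logical(1))
}

# explicit local least-squares quadratic fit over one window slice
oracle_sg_fit <- function(y) {
  h <- (length(y) - 1) / 2
  x <- -h:h
  unname(stats::predict(stats::lm(y ~ x + I(x^2)),
                        newdata = data.frame(x = 0)))
}

# closed-form 2-cell goodness-of-fit statistic against a 50:50 null
oracle_chi2 <- function(y, r) {
  e <- (y + r) / 2
  (y - e)^2 / e + (r - e)^2 / e
}
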