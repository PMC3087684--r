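# Flow-cytometry genome-size estimation against an internal standard, unit
# conversion, clone/species aggregation and ploidy-multiple inference.

#' Picogram / megabase conversion
#'
#' DNA mass and length are interconverted with the standard factor
#' 1 pg = 978 Mbp. Rounding happens only at reporting.
#'
#' @param pg,mbp non-negative DNA amounts.
#' @return the converted amount.
#' @export
#' @examples
#' pgToMbp(1)        # 978
#' mbpToPg(256.3)    # 0.2620...
pgToMbp <- function(pg) {
  stopIfNot(all(pg >= 0), "DNA amount must be non-negative")
  pg * 978
}

#' @rdname pgToMbp
#' @export
mbpToPg <- function(mbp) {
  stopIfNot(all(mbp >= 0), "DNA amount must be non-negative")
  mbp / 978
}

#' Detect fluorescence peaks in a histogram
#'
#' Operational peak extraction from a one-parameter fluorescence histogram
#' (channel, count): the counts are smoothed with a centered moving average;
#' local maxima are kept if their topographic prominence (height above the
#' highest saddle separating them from a higher peak) reaches
#' `minProminenceFraction` of the largest smoothed count AND they rise above
#' the uniform-background expectation (mean + 5 sd of the per-bin Poisson
#' level), which is what separates stained-nuclei peaks from a flat debris
#' floor; each kept peak's mean channel and CV are computed from the raw
#' counts inside a gate of mean +/- 2.5 local standard deviations (the local
#' sd is seeded from the smoothed peak's full width at half maximum and
#' refined once). Peaks are returned sorted by mean channel. Note the gate
#' truncates the Gaussian tails, so the reported CV understates the true peak
#' CV by ~4 percent of its value at the default 2.5-sd gate.
#'
#' @param hist data.frame with strictly increasing integer `channel` and
#'   non-negative `count` columns.
#' @param minProminenceFraction prominence threshold as a fraction of the
#'   largest smoothed count (default 0.10).
#' @param smoothingWindow moving-average window in bins (default 5, odd).
#' @param gateSd half-width of the moment gate in local sd units (default 2.5).
#' @return data.frame with one row per peak: `mean_channel`, `cv` (percent),
#'   `events_in_gate`, `degenerate` (TRUE when the gate holds a single
#'   channel, so cv = 0). Zero rows when no peak qualifies.
#' @export
detectPeaks <- function(hist, minProminenceFraction = 0.10,
                        smoothingWindow = 5L, gateSd = 2.5) {
  stopIfNot(all(c("channel", "count") %in% names(hist)),
            "histogram needs `channel` and `count` columns")
  stopIfNot(all(diff(hist$channel) > 0), "channels must be strictly increasing")
  stopIfNot(all(hist$count >= 0), "counts must be non-negative")
  stopIfNot(sum(hist$count) > 0, "empty histogram: no events")

  ch <- hist$channel
  y <- as.numeric(hist$count)
  w <- max(1L, as.integer(smoothingWindow))
  if (w %% 2L == 0L) w <- w + 1L
  sm <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
  sm[is.na(sm)] <- y[is.na(sm)]

  n <- length(sm)
  ismax <- which(sm > c(-Inf, sm[-n]) & sm >= c(sm[-1], -Inf) & sm > 0)
  if (!length(ismax)) return(emptyPeaks())

  prom <- vapply(ismax, function(i) {
    h <- sm[i]
    saddle <- -Inf
    for (side in c(-1L, 1L)) {
      j <- i
      low <- h
      repeat {
        j <- j + side
        if (j < 1L || j > n) break          # edge: open side, full height
        if (sm[j] > h) { saddle <- max(saddle, low); break }
        low <- min(low, sm[j])
      }
    }
    if (is.infinite(saddle)) h else h - saddle
  }, numeric(1))

  # a genuine peak must also clear the flat-background expectation
  lambda <- sum(y) / n
  floorLevel <- lambda + 5 * sqrt(lambda)
  keep <- ismax[prom >= minProminenceFraction * max(sm) & sm[ismax] >= floorLevel]
  if (!length(keep)) return(emptyPeaks())

  peaks <- lapply(keep, function(i) {
    # FWHM of the smoothed peak seeds the local sd
    half <- sm[i] / 2
    l <- i; while (l > 1L && sm[l] > half) l <- l - 1L
    r <- i; while (r < n && sm[r] > half) r <- r + 1L
    sdLocal <- max((ch[r] - ch[l]) / 2.355, diff(range(ch)) / n)
    mu <- ch[i]
    for (iter in 1:2) {   # refinement passes on the gated raw moments
      g <- which(ch >= mu - gateSd * sdLocal & ch <= mu + gateSd * sdLocal)
      if (sum(y[g]) == 0) break
      mu <- sum(ch[g] * y[g]) / sum(y[g])
      v <- sum(y[g] * (ch[g] - mu)^2) / sum(y[g])
      if (v > 0) sdLocal <- sqrt(v)
    }
    g <- which(ch >= mu - gateSd * sdLocal & ch <= mu + gateSd * sdLocal)
    events <- sum(y[g])
    mu <- if (events > 0) sum(ch[g] * y[g]) / events else ch[i]
    vGate <- if (events > 0) sum(y[g] * (ch[g] - mu)^2) / events else 0
    degenerate <- sum(y[g] > 0) < 2L || vGate == 0
    data.frame(mean_channel = mu,
               cv = if (degenerate || mu <= 0) 0 else 100 * sqrt(vGate) / mu,
               events_in_gate = events,
               degenerate = degenerate)
  })
  out <- do.call(rbind, peaks)
  out <- out[order(out$mean_channel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

emptyPeaks <- function() {
  data.frame(mean_channel = numeric(0), cv = numeric(0),
             events_in_gate = numeric(0), degenerate = logical(0))
}

#' Genome size from sample and internal-standard peaks
#'
#' Fluorescence of stoichiometrically stained nuclei is proportional to DNA
#' content, so the sample genome size is the peak-position ratio times the
#' standard's known DNA content:
#' pg = (sample mean channel / standard mean channel) x standard pg.
#' The default standard is Drosophila melanogaster ISO-1 at 0.35 pg; the
#' calibration assumes sample and standard peaks represent the same C-level
#' (recorded in the `assumption` field).
#'
#' @param samplePeak,standardPeak one-row data.frames as returned by
#'   [detectPeaks()] (or any list with a `mean_channel` element).
#' @param standardPg DNA content of the internal standard in pg
#'   (default 0.35).
#' @return list with `pg`, `mbp` (= pg x 978) and `assumption`.
#' @export
#' @examples
#' genomeSizeFromPeaks(list(mean_channel = 340), list(mean_channel = 1000))
genomeSizeFromPeaks <- function(samplePeak, standardPeak, standardPg = 0.35) {
  if (is.null(standardPeak) || !length(standardPeak$mean_channel))
    stop("internal-standard peak is missing", call. = FALSE)
  s <- samplePeak$mean_channel[1]
  d <- standardPeak$mean_channel[1]
  stopIfNot(is.finite(d) && d > 0, "standard mean channel must be > 0")
  stopIfNot(is.finite(s) && s > 0, "sample mean channel must be > 0")
  stopIfNot(standardPg > 0, "standard genome size must be > 0")
  pg <- s / d * standardPg
  list(pg = pg, mbp = pgToMbp(pg),
       assumption = "sample and standard peaks assumed to be the same C-level")
}

#' Aggregate replicate genome-size estimates for a clone
#'
#' @param values numeric vector of per-replicate estimates (same unit).
#' @return list with `mean`, `sem` (sample sd / sqrt(n); 0 with
#'   `sem_defined = FALSE` when n = 1) and `n`.
#' @export
#' @examples
#' aggregateReplicates(c(110, 112, 114, 116))  # mean 113, sem 1.291
aggregateReplicates <- function(values) {
  stopIfNot(length(values) >= 1L, "no replicate estimates supplied")
  n <- length(values)
  m <- mean(values)
  if (n == 1L)
    return(list(mean = m, sem = 0, n = 1L, sem_defined = FALSE))
  list(mean = m, sem = stats::sd(values) / sqrt(n), n = n, sem_defined = TRUE)
}

#' Species mean from clone means
#'
#' Unweighted mean of the clone means, reported to one decimal with
#' half-away-from-zero rounding (the convention of the summary tables).
#'
#' @param cloneMeans numeric vector of per-clone mean genome sizes.
#' @param digits decimals for reporting (default 1).
#' @return the rounded species mean.
#' @export
#' @examples
#' speciesSummary(c(111.7, 116.7, 114.5, 128.8, 123.0))  # 118.9
speciesSummary <- function(cloneMeans, digits = 1) {
  stopIfNot(length(cloneMeans) >= 1L, "no clone means supplied")
  roundHalfAway(mean(cloneMeans), digits)
}

#' Fit genome sizes as integer multiples of a base size
#'
#' Tests the whole-genome-duplication reading of a set of genome sizes: for
#' a candidate base size beta, each size gets the multiplier
#' m = round(size/beta) clamped at 1, and the candidate is scored by the mean
#' absolute relative residual |size - m beta| / (m beta). With a grid, the
#' best-scoring base is returned; score ties go to the largest base, i.e. the
#' coarsest base consistent with the sizes (a half-size base always fits
#' exact multiples equally well and would be an artifact). With `fixedBase`
#' the search is skipped.
#'
#' @param sizes positive genome sizes (any consistent unit).
#' @param baseGrid numeric `c(low, high, step)` grid of candidate bases, or
#'   NULL when `fixedBase` is given.
#' @param fixedBase optional single base size (skips the grid search).
#' @param labels optional taxon labels for the sizes.
#' @return a [PloidyFit-class] object.
#' @export
#' @examples
#' fitPloidyMultiples(c(100, 200, 300), baseGrid = c(50, 150, 0.5))
fitPloidyMultiples <- function(sizes, baseGrid = NULL, fixedBase = NULL,
                               labels = NULL) {
  stopIfNot(length(sizes) >= 1L, "no sizes supplied")
  stopIfNot(all(sizes > 0), "sizes must be positive")
  if (is.null(labels)) labels <- as.character(seq_along(sizes))
  evalBase <- function(beta) {
    m <- pmax(1, round(sizes / beta))
    res <- (sizes - m * beta) / (m * beta)
    list(m = as.integer(m), res = res, score = mean(abs(res)))
  }
  if (!is.null(fixedBase)) {
    stopIfNot(fixedBase > 0, "fixed base must be positive")
    best <- evalBase(fixedBase)
    base <- fixedBase
  } else {
    stopIfNot(length(baseGrid) == 3L, "baseGrid must be c(low, high, step)")
    grid <- seq(baseGrid[1], baseGrid[2], by = baseGrid[3])
    stopIfNot(length(grid) >= 1L && all(grid > 0), "empty or invalid base grid")
    scores <- vapply(grid, function(b) evalBase(b)$score, numeric(1))
    tied <- which(scores <= min(scores) + 1e-12)
    base <- grid[max(tied)]           # ties: prefer the largest base
    best <- evalBase(base)
  }
  new("PloidyFit", baseSize = base, sizes = as.numeric(sizes),
      multipliers = best$m, relativeResiduals = best$res,
      score = best$score, labels = labels)
}
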