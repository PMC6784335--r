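# Per-locus relocalization quantification and peak calling. Peaks in the
# relocalization-magnitude profile are detected with a continuous wavelet
# transform (Ricker wavelet, widths 1-10 bins) and ridge-line tracking,
# which finds peaks in noisy data by their characteristic shape without
# pre-smoothing.

#' Per-locus relocalization between two aligned structures
#'
#' Displacement is `coords2 - coords1` per locus; magnitude is its Euclidean
#' norm (the relocalization distance, in embedding units). Loci absent from
#' either structure are absent from the profile.
#'
#' @param fit a `joint_mds_fit` or any list with aligned [hic_structure()]
#'   elements `x1` and `x2` over the same loci.
#' @return An object of class `reloc_profile`: list with `loci`,
#'   `displacement` (n x 3), `magnitude`, and `peaks` (`NULL` until
#'   [call_peaks()] is run).
#' @export
relocalization_profile <- function(fit) {
  x1 <- fit$x1; x2 <- fit$x2
  stopifnot(inherits(x1, "hic_structure"), inherits(x2, "hic_structure"))
  if (!same_loci(x1, x2)) stop("aligned pair must share loci")
  p1 <- present_idx(x1); p2 <- present_idx(x2)
  keep <- intersect(p1, p2)
  if (length(keep) == 0) stop("no loci present in both structures")
  disp <- x2$coords[keep, , drop = FALSE] - x1$coords[keep, , drop = FALSE]
  loci <- x1$loci[keep, , drop = FALSE]
  rownames(loci) <- NULL
  structure(list(loci = loci, displacement = disp,
                 magnitude = sqrt(rowSums(disp^2)), peaks = NULL),
            class = "reloc_profile")
}

#' @export
print.reloc_profile <- function(x, ...) {
  cat(sprintf("reloc_profile: %d loci, magnitude median %.4g max %.4g%s\n",
              length(x$magnitude), stats::median(x$magnitude),
              max(x$magnitude),
              if (is.null(x$peaks)) "" else sprintf(", %d peaks", nrow(x$peaks))))
  invisible(x)
}

ricker_wavelet <- function(points, width) {
  a <- 2 / (sqrt(3 * width) * pi^0.25)
  vec <- seq_len(points) - 1 - (points - 1) / 2
  a * (1 - vec^2 / width^2) * exp(-vec^2 / (2 * width^2))
}

conv_same <- function(x, w) {
  n <- length(x); m <- length(w)
  full <- rep(0, n + m - 1)
  for (i in seq_len(m)) {
    idx <- i:(i + n - 1)
    full[idx] <- full[idx] + w[i] * x
  }
  start <- floor((m - 1) / 2) + 1
  full[start:(start + n - 1)]
}

cwt_ricker <- function(x, widths) {
  t(vapply(widths, function(w) {
    conv_same(x, ricker_wavelet(min(10 * w, length(x)), w))
  }, numeric(length(x))))
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v > c(-Inf, v[-n]) & v > c(v[-1], Inf))
}

# Ridge-line tracking across CWT scales: lines are seeded at the local
# maxima of the largest width and followed down to width 1, connecting a
# maximum to the nearest active line if within max_distances of that width;
# lines that skip more than gap_thresh consecutive widths are closed.
identify_ridge_lines <- function(cwt, max_distances, gap_thresh) {
  n_rows <- nrow(cwt)
  active <- list()
  closed <- list()
  for (row in rev(seq_len(n_rows))) {
    cols <- local_maxima(cwt[row, ])
    for (k in seq_along(active)) active[[k]]$gap <- active[[k]]$gap + 1
    for (col in cols) {
      if (length(active)) {
        prev_cols <- vapply(active, function(l) l$cols[length(l$cols)], numeric(1))
        k <- which.min(abs(prev_cols - col))
        if (abs(prev_cols[k] - col) <= max_distances[row]) {
          active[[k]]$rows <- c(active[[k]]$rows, row)
          active[[k]]$cols <- c(active[[k]]$cols, col)
          active[[k]]$gap <- 0
          next
        }
      }
      active[[length(active) + 1]] <- list(rows = row, cols = col, gap = 0)
    }
    stale <- vapply(active, function(l) l$gap > gap_thresh, logical(1))
    closed <- c(closed, active[stale])
    active <- active[!stale]
  }
  c(closed, active)
}

#' Call peaks in a relocalization profile by CWT ridge lines
#'
#' Computes the Ricker-wavelet continuous wavelet transform of the magnitude
#' profile over the given widths, tracks ridge lines across scales, and
#' keeps ridges that persist over at least `min_length` widths and whose
#' signal-to-noise ratio at width 1 exceeds `min_snr` (noise is the
#' `noise_perc` percentile of the absolute width-1 coefficients in a local
#' window). A peak's position is the ridge's locus index at the smallest
#' width it reaches; its width class is the largest width on the ridge.
#'
#' @param profile a `reloc_profile` (or any numeric vector).
#' @param widths integer wavelet widths in bins; default `1:10`. Widths
#'   exceeding the profile length are dropped with a warning.
#' @param gap_thresh maximum number of consecutive scales a ridge may skip;
#'   default 2.
#' @param min_length minimum ridge length in scales; default
#'   `ceiling(length(widths) / 4)`.
#' @param min_snr minimum signal-to-noise ratio; default 1.
#' @param noise_perc percentile (0-100) of absolute width-1 coefficients
#'   used as the noise floor; default 10.
#' @return For a profile input, the profile with a `peaks` data frame
#'   (`index`, `width_class`, `snr`, ordered by position); for a vector
#'   input, the data frame itself.
#' @export
call_peaks <- function(profile, widths = 1:10, gap_thresh = 2,
                       min_length = NULL, min_snr = 1, noise_perc = 10) {
  v <- if (inherits(profile, "reloc_profile")) profile$magnitude else as.numeric(profile)
  n <- length(v)
  widths <- sort(unique(as.integer(widths)))
  if (any(widths > n)) {
    warning("profile shorter than the largest wavelet width; widths truncated")
    widths <- widths[widths <= n]
  }
  if (length(widths) == 0) stop("no usable wavelet widths")
  if (is.null(min_length)) min_length <- ceiling(length(widths) / 4)
  empty <- data.frame(index = integer(0), width_class = integer(0),
                      snr = numeric(0))
  if (stats::sd(v) == 0) {
    # a constant signal has no peaks; skip the transform (whose edge
    # truncation would otherwise manufacture boundary ridges)
    if (inherits(profile, "reloc_profile")) {
      profile$peaks <- empty
      return(profile)
    }
    return(empty)
  }
  cw <- cwt_ricker(v, widths)
  lines <- identify_ridge_lines(cw, max_distances = widths / 4,
                                gap_thresh = gap_thresh)

  window_size <- ceiling(n / 20)
  half <- max(window_size %/% 2, 1)
  noise <- vapply(seq_len(n), function(i) {
    win <- max(1, i - half):min(n, i + half)
    stats::quantile(abs(cw[1, win]), noise_perc / 100, names = FALSE)
  }, numeric(1))
  noise <- pmax(noise, 1e-12)

  keep <- list()
  for (l in lines) {
    if (length(l$rows) < min_length) next
    pos <- l$cols[length(l$cols)]          # locus index at the smallest width
    snr <- abs(cw[1, pos]) / noise[pos]
    if (snr < min_snr) next
    keep[[length(keep) + 1]] <- data.frame(
      index = pos, width_class = widths[max(l$rows)], snr = snr)
  }
  peaks <- if (length(keep)) {
    pk <- do.call(rbind, keep)
    pk <- pk[!duplicated(pk$index), , drop = FALSE]
    # merge ridges landing within 2 bins of a stronger one
    pk <- pk[order(-pk$snr), , drop = FALSE]
    taken <- integer(0)
    sel <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      if (!length(taken) || min(abs(taken - pk$index[i])) > 2) {
        sel[i] <- TRUE
        taken <- c(taken, pk$index[i])
      }
    }
    pk <- pk[sel, , drop = FALSE]
    pk[order(pk$index), , drop = FALSE]
  } else {
    empty
  }
  rownames(peaks) <- NULL
  if (inherits(profile, "reloc_profile")) {
    profile$peaks <- peaks
    profile
  } else {
    peaks
  }
}

#' Filter relocalization peaks by compartment-score difference
#'
#' Retains peaks whose locus has an absolute compartment-score difference
#' strictly below `threshold`, i.e. relocalization not explained by an A/B
#' compartment switch. Peaks without a score difference are dropped with a
#' warning.
#'
#' @param profile a `reloc_profile` with called peaks.
#' @param diff per-locus absolute score differences over the profile's loci
#'   (see [compartment_difference()]).
#' @param threshold strict upper bound; default 0.2 (scores range -1 to 1).
#' @return The profile with its `peaks` subset.
#' @export
filter_peaks_by_compartment <- function(profile, diff, threshold = 0.2) {
  stopifnot(inherits(profile, "reloc_profile"))
  if (is.null(profile$peaks)) stop("call_peaks() first")
  if (length(diff) != length(profile$magnitude))
    stop("diff must cover the profile's loci")
  d <- diff[profile$peaks$index]
  if (any(is.na(d)))
    warning("peaks without a compartment-score difference dropped")
  keep <- !is.na(d) & d < threshold
  profile$peaks <- profile$peaks[keep, , drop = FALSE]
  rownames(profile$peaks) <- NULL
  profile
}

#' Partition peaks by compartment membership in the two conditions
#'
#' @param peaks integer locus indices (e.g. `profile$peaks$index`).
#' @param track_a,track_b oriented `compartment_track` objects.
#' @return A list with integer-vector elements `intra_A` (score > 0 in both
#'   conditions), `intra_B` (score < 0 in both), and `discordant`.
#' @export
split_peaks_by_compartment <- function(peaks, track_a, track_b) {
  stopifnot(inherits(track_a, "compartment_track"),
            inherits(track_b, "compartment_track"))
  sa <- track_a$score[peaks]
  sb <- track_b$score[peaks]
  list(intra_A = peaks[!is.na(sa) & !is.na(sb) & sa > 0 & sb > 0],
       intra_B = peaks[!is.na(sa) & !is.na(sb) & sa < 0 & sb < 0],
       discordant = peaks[is.na(sa) | is.na(sb) |
                            !((sa > 0 & sb > 0) | (sa < 0 & sb < 0))])
}

#' Virtual 4C profile from a viewpoint
#'
#' Mean contact frequency of the viewpoint bin(s) against every other locus;
#' the viewpoint bins themselves are set to `NA`.
#'
#' @param m a [hic_contacts()] object.
#' @param viewpoint either a `"chrom:start-end"` string or a numeric
#'   `c(start, end)` interval (0-based half-open) on the matrix chromosome.
#' @return Numeric per-locus contact profile.
#' @export
virtual_4c <- function(m, viewpoint) {
  stopifnot(inherits(m, "hic_contacts"))
  if (is.character(viewpoint)) {
    reg <- parse_region(viewpoint)
    if (!identical(reg$chrom, m$loci$chrom[1]))
      stop("viewpoint chromosome does not match the matrix")
    viewpoint <- c(reg$start, reg$end)
  }
  vb <- which(m$loci$start < viewpoint[2] & m$loci$end > viewpoint[1])
  if (length(vb) == 0) stop("viewpoint outside the matrix span")
  prof <- colMeans(m$mat[vb, , drop = FALSE])
  prof[vb] <- NA_real_
  prof
}

#' Coverage enrichment of peak intervals over a background
#'
#' Computes, for every peak and background interval, its fractional coverage
#' by the feature intervals (covered bp / interval length, half-open
#' coordinates), and reports the ratio of mean coverages together with a
#' two-sided equal-variance t test comparing the two coverage samples. A
#' zero-coverage background yields an infinite ratio, reported as such.
#'
#' @param peaks,background,features data frames with columns `chrom`,
#'   `start`, `end` on a shared coordinate system.
#' @return A list with `enrichment`, `p_value`, and the per-interval
#'   coverage vectors `peak_coverage` and `background_coverage`.
#' @export
coverage_enrichment <- function(peaks, background, features) {
  if (nrow(peaks) == 0 || nrow(background) == 0)
    stop("peaks and background must be non-empty")
  as_gr <- function(df)
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(start = df$start + 1, end = df$end))
  feat <- GenomicRanges::reduce(as_gr(features))
  cov_frac <- function(df) {
    gr <- as_gr(df)
    hits <- GenomicRanges::findOverlaps(gr, feat)
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    feat[S4Vectors::subjectHits(hits)])
    covered <- rep(0, length(gr))
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- w
    covered / GenomicRanges::width(gr)
  }
  pc <- cov_frac(peaks)
  bc <- cov_frac(background)
  ratio <- mean(pc) / mean(bc)
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  p <- if (sd0(pc) == 0 && sd0(bc) == 0) {
    if (mean(pc) == mean(bc)) 1 else 0
  } else {
    stats::t.test(pc, bc, var.equal = TRUE)$p.value
  }
  list(enrichment = ratio, p_value = p,
       peak_coverage = pc, background_coverage = bc)
}

#' Convert called peaks to genomic intervals
#'
#' @param profile a `reloc_profile` with called peaks.
#' @return BED-like data frame (`chrom`, `start`, `end`, `magnitude`) with
#'   one row per peak bin.
#' @export
peak_intervals <- function(profile) {
  stopifnot(inherits(profile, "reloc_profile"))
  if (is.null(profile$peaks)) stop("call_peaks() first")
  idx <- profile$peaks$index
  data.frame(profile$loci[idx, , drop = FALSE],
             magnitude = profile$magnitude[idx], row.names = NULL)
}
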