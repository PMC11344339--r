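#' Windowed PI_HAT scan around an index variant
#'
#' For each half-width `h` in `step, 2*step, ..., max_flank` (counted in
#' SNPs, not base pairs), estimates pairwise PI_HAT among the carrier
#' samples over the SNPs lying within `h` positions on either side of the
#' index SNP, and averages over carrier pairs. This is the expanding-window
#' scan used to recognize a founder haplotype: carrier pairs sharing an
#' ancestral segment show elevated PI_HAT in small windows, which erodes as
#' the window grows past the shared segment.
#'
#' Windows are truncated symmetrically at chromosome ends; the effective
#' flank actually available is recorded per half-width. The index variant is
#' mapped to the nearest panel SNP (ties to the lower coordinate).
#'
#' @param panel a [genotype_panel()]; frequencies are estimated if absent.
#' @param index_chrom,index_pos genomic location of the index variant.
#' @param carriers sample ids of the carrier set (>= 2).
#' @param max_flank maximum half-width in SNPs (default 500).
#' @param step half-width increment in SNPs (default 50).
#' @param include_baseline also compute a cohort-baseline curve averaged
#'   over *all* sample pairs (slower; default FALSE).
#' @return object of class `scan_curve`: `half_widths`, `mean_pihat`,
#'   `per_pair` (pairs x half-widths matrix), `effective_flank`,
#'   `window_snps`, `window_span_bp`, index bookkeeping, and optionally
#'   `baseline`.
#' @export
windowed_scan <- function(panel, index_chrom, index_pos, carriers,
                          max_flank = 500L, step = 50L,
                          include_baseline = FALSE) {
  if (length(carriers) < 2L) stop("need at least 2 carrier samples")
  if (is.null(panel$freqs)) panel <- estimate_freqs(panel)
  on_chr <- which(panel$snps$chrom == index_chrom)
  if (!length(on_chr))
    stop("chromosome ", index_chrom, " absent from panel")
  pos <- panel$snps$pos[on_chr]
  dist <- abs(pos - index_pos)
  r <- which(dist == min(dist))[1L]  # tie -> lowest coordinate
  n_chr <- length(on_chr)
  hs <- seq.int(step, max_flank, by = step)

  rows <- match(carriers, panel$samples)
  if (anyNA(rows)) stop("unknown carrier id(s): ",
                        paste(carriers[is.na(rows)], collapse = ", "))
  pairs <- utils::combn(length(rows), 2)

  left_max <- min(max_flank, r - 1L)
  right_max <- min(max_flank, n_chr - r)
  wnd <- on_chr[(r - left_max):(r + right_max)]
  offs <- (-left_max):right_max
  f <- panel$freqs[wnd]
  e <- ibd_expectation_terms(f)
  gw <- panel$genotypes[, wnd, drop = FALSE]

  curve_for <- function(ia, ib) {
    ga <- gw[ia, ]; gb <- gw[ib, ]
    ok <- !is.na(ga) & !is.na(gb) & !is.na(f) & f > 0 & f < 1
    d <- abs(ga - gb)
    i0 <- ok & d == 2L; i1 <- ok & d == 1L; i2 <- ok & d == 0L
    vapply(hs, function(h) {
      sel <- abs(offs) <= h
      n <- sum(ok & sel)
      if (n == 0L) return(NA_real_)
      z <- .ibd_solve(sum(i0[sel]), sum(i1[sel]), sum(i2[sel]),
                      sum(e$e00[sel & ok]), sum(e$e10[sel & ok]),
                      sum(e$e11[sel & ok]), sum(e$e20[sel & ok]),
                      sum(e$e21[sel & ok]), n)
      z[3] + z[2] / 2
    }, numeric(1))
  }

  per_pair <- t(apply(pairs, 2, function(pr) curve_for(rows[pr[1]], rows[pr[2]])))
  if (ncol(pairs) == 1L) per_pair <- matrix(per_pair, nrow = 1L)
  rownames(per_pair) <- apply(pairs, 2, function(pr)
    paste(carriers[pr[1]], carriers[pr[2]], sep = ":"))
  colnames(per_pair) <- hs

  eff_left <- pmin(hs, left_max); eff_right <- pmin(hs, right_max)
  window_snps <- eff_left + eff_right + 1L
  span_bp <- vapply(hs, function(h) {
    lo <- r - min(h, left_max); hi <- r + min(h, right_max)
    pos[hi] - pos[lo]
  }, numeric(1))

  baseline <- NULL
  if (include_baseline) {
    all_rows <- seq_along(panel$samples)
    bpairs <- utils::combn(length(all_rows), 2)
    bmat <- apply(bpairs, 2, function(pr) curve_for(pr[1], pr[2]))
    baseline <- rowMeans(matrix(bmat, nrow = length(hs)), na.rm = TRUE)
  }

  structure(list(
    index_chrom = index_chrom, index_pos = panel$snps$pos[on_chr[r]],
    index_rank = r, index_id = panel$snps$id[on_chr[r]],
    carriers = carriers, half_widths = hs,
    mean_pihat = colMeans(per_pair, na.rm = TRUE), per_pair = per_pair,
    effective_flank = pmin(hs, pmax(left_max, right_max)),
    effective_left = eff_left, effective_right = eff_right,
    window_snps = window_snps, window_span_bp = span_bp,
    baseline = baseline, step = step, max_flank = max_flank),
    class = "scan_curve")
}

#' @export
print.scan_curve <- function(x, ...) {
  cat("<scan_curve> index ", x$index_chrom, ":", x$index_pos, ", ",
      length(x$carriers), " carriers (", nrow(x$per_pair), " pairs), h = ",
      x$half_widths[1], "..", max(x$half_widths), " by ", x$step, "\n",
      sep = "")
  print(round(stats::setNames(x$mean_pihat, x$half_widths), 3))
  invisible(x)
}

#' Control curves at randomized genome-wide intervals
#'
#' Repeats the [windowed_scan()] for the same carrier set at randomly chosen
#' index SNPs elsewhere in the genome, giving the null behaviour of the
#' curve. Intervals are drawn uniformly over eligible SNPs (full flank
#' available on both sides, optionally excluding the index chromosome) by
#' rejection sampling under a non-overlap rule: two intervals on the same
#' chromosome must be separated by more than `min_separation` SNP positions.
#' If the panel cannot host `n_intervals` such intervals, the achievable
#' number is used with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param carriers carrier sample ids.
#' @param n_intervals number of control intervals (default 200).
#' @param max_flank,step as in [windowed_scan()].
#' @param seed RNG seed; a fixed seed makes the summary reproducible.
#' @param exclude_chrom chromosome(s) to exclude (typically the scan
#'   chromosome).
#' @param min_separation minimum SNP-rank separation of same-chromosome
#'   intervals (default `2 * max_flank`).
#' @return object of class `control_summary`: `n_intervals`, `half_widths`,
#'   `mean_curve`, `sd_curve`, `per_interval` (intervals x half-widths),
#'   `index_snps`.
#' @export
control_curves <- function(panel, carriers, n_intervals = 200L,
                           max_flank = 500L, step = 50L, seed = 1L,
                           exclude_chrom = NULL,
                           min_separation = 2L * max_flank) {
  if (is.null(panel$freqs)) panel <- estimate_freqs(panel)
  hs <- seq.int(step, max_flank, by = step)
  if (n_intervals == 0L) {
    return(structure(list(n_intervals = 0L, half_widths = hs,
                          mean_curve = rep(NA_real_, length(hs)),
                          sd_curve = rep(NA_real_, length(hs)),
                          per_interval = matrix(numeric(0), 0, length(hs)),
                          index_snps = integer(0)),
                     class = "control_summary"))
  }
  chrom <- panel$snps$chrom
  rank_in_chr <- stats::ave(seq_along(chrom), chrom, FUN = seq_along)
  n_in_chr <- stats::ave(seq_along(chrom), chrom, FUN = length)
  eligible <- which(rank_in_chr > max_flank & rank_in_chr <= n_in_chr - max_flank &
                      !(chrom %in% exclude_chrom))
  if (!length(eligible)) stop("no eligible control index SNPs in panel")

  chosen <- with_seed(seed, {
    acc <- integer(0)
    attempts <- 0L
    max_attempts <- 200L * n_intervals
    while (length(acc) < n_intervals && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- eligible[sample.int(length(eligible), 1L)]
      clash <- any(chrom[acc] == chrom[cand] &
                     abs(rank_in_chr[acc] - rank_in_chr[cand]) <= min_separation)
      if (!clash) acc <- c(acc, cand)
    }
    acc
  })
  if (length(chosen) < n_intervals)
    warning("panel only accommodates ", length(chosen), " of ", n_intervals,
            " non-overlapping control intervals")

  per <- t(vapply(chosen, function(i) {
    sc <- windowed_scan(panel, chrom[i], panel$snps$pos[i], carriers,
                        max_flank = max_flank, step = step)
    sc$mean_pihat
  }, numeric(length(hs))))

  structure(list(n_intervals = length(chosen), half_widths = hs,
                 mean_curve = colMeans(per, na.rm = TRUE),
                 sd_curve = apply(per, 2, stats::sd, na.rm = TRUE),
                 per_interval = per, index_snps = chosen,
                 seed = seed, step = step, max_flank = max_flank),
            class = "control_summary")
}

#' @export
print.control_summary <- function(x, ...) {
  cat("<control_summary> ", x$n_intervals, " randomized intervals, h = ",
      x$half_widths[1], "..", max(x$half_widths), "\n", sep = "")
  if (x$n_intervals > 0)
    print(round(rbind(mean = x$mean_curve, sd = x$sd_curve), 3))
  invisible(x)
}

#' Call a shared founder segment from a scan and its controls
#'
#' Decides whether the carrier set shares a haplotype around the index
#' variant, and estimates the shared segment's extent in SNPs and its
#' genomic span.
#'
#' *Decision*: founder-compatible when the carrier curve exceeds the control
#' envelope — control mean plus `margin_sd` control standard deviations — at
#' the smallest window, and the estimated extent reaches `min_extent_snps`.
#'
#' *Extent*: in an expanding window the mean PI_HAT of a shared segment of
#' S SNPs inside a window of W SNPs is diluted roughly by `min(S,W)/W`, so
#' a threshold-crossing on the raw curve cannot localize the segment edge.
#' The extent is instead fitted from the whole curve: the control-corrected
#' excess `pihat(h) - control_mean(h)` is regressed (through the origin) on
#' the dilution shape `min(S, W(h))/W(h)` and S is chosen by least squares
#' over a fine grid. When the fitted S reaches the widest window (no
#' dilution observed — sharing extends beyond the scan), the call is
#' flagged `unbounded`.
#'
#' @param scan a [scan_curve()].
#' @param control a [control_summary()] computed on the same `h` grid.
#' @param margin_sd control-envelope width in SDs (default 3).
#' @param min_extent_snps minimum extent for a founder-compatible call
#'   (default 100 SNPs).
#' @return list: `decision` (`"founder_compatible"` / `"negative"`),
#'   `extent_snps`, `span_mb`, `unbounded`, `plateau`, `threshold` (per-h
#'   envelope).
#' @export
shared_segment_call <- function(scan, control, margin_sd = 3,
                                min_extent_snps = 100L) {
  stopifnot(identical(scan$half_widths, control$half_widths))
  hs <- scan$half_widths
  thr <- unname(control$mean_curve + margin_sd * control$sd_curve)
  above <- unname(scan$mean_pihat) > thr
  plateau_excess <- scan$mean_pihat[1L] - control$mean_curve[1L]

  if (!isTRUE(above[1L]) || plateau_excess <= 0) {
    return(list(decision = "negative", extent_snps = 0L, span_mb = NA_real_,
                unbounded = FALSE, plateau = unname(scan$mean_pihat[1L]),
                threshold = thr))
  }
  k <- length(hs)
  w_max <- unname(scan$window_snps[k])
  e <- unname(scan$mean_pihat) - control$mean_curve
  W <- unname(scan$window_snps)
  grid <- seq(5, w_max, by = 5)
  rss <- vapply(grid, function(S) {
    x <- pmin(S, W) / W
    co <- sum(e * x) / sum(x * x)
    sum((e - co * x)^2)
  }, numeric(1))
  s_hat <- grid[which.min(rss)]
  unbounded <- s_hat >= 0.95 * w_max
  extent <- as.integer(round(if (unbounded) w_max else s_hat))

  # genomic span of the called extent, centred on the index SNP
  half <- min(extent %/% 2L, scan$effective_left[k], scan$effective_right[k])
  span_mb <- {
    frac <- (2 * half + 1) / w_max
    # interpolate span from the widest window's bp extent
    scan$window_span_bp[k] * frac / 1e6
  }
  decision <- if (extent >= min_extent_snps) "founder_compatible" else "negative"
  list(decision = decision, extent_snps = extent, span_mb = unname(span_mb),
       unbounded = unname(unbounded), plateau = unname(scan$mean_pihat[1L]),
       threshold = thr)
}

#' Write a scan and its control summary as TSV
#'
#' Columns: `h`, `mean_pihat`, `control_mean`, `control_sd`,
#' `window_snps`, `window_span_bp`.
#'
#' @param scan a [scan_curve()].
#' @param control a [control_summary()] (optional).
#' @param path output path.
#' @export
write_scan_tsv <- function(scan, control = NULL, path) {
  d <- data.frame(h = scan$half_widths, mean_pihat = scan$mean_pihat,
                  control_mean = if (is.null(control)) NA else control$mean_curve,
                  control_sd = if (is.null(control)) NA else control$sd_curve,
                  window_snps = scan$window_snps,
                  window_span_bp = scan$window_span_bp)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot a PI_HAT scan curve against its control envelope
#'
#' Reproduces the expanding-window layout: mean carrier PI_HAT versus
#' half-width, thin per-pair curves, and the control mean with a +/- 2 SD
#' band.
#'
#' @param x a [scan_curve()].
#' @param control optional [control_summary()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.scan_curve <- function(x, control = NULL, ...) {
  hs <- x$half_widths
  graphics::plot(hs, x$mean_pihat, type = "n", ylim = c(0, 1),
                 xlab = "window half-width (SNPs)", ylab = "mean PI_HAT", ...)
  if (!is.null(control)) {
    up <- pmin(control$mean_curve + 2 * control$sd_curve, 1)
    lo <- pmax(control$mean_curve - 2 * control$sd_curve, 0)
    graphics::polygon(c(hs, rev(hs)), c(up, rev(lo)),
                      col = grDevices::adjustcolor("grey60", 0.4), border = NA)
    graphics::lines(hs, control$mean_curve, lty = 2, col = "grey30")
  }
  for (i in seq_len(nrow(x$per_pair)))
    graphics::lines(hs, x$per_pair[i, ], col = grDevices::adjustcolor("steelblue", 0.5))
  graphics::lines(hs, x$mean_pihat, lwd = 2, col = "firebrick")
  graphics::points(hs, x$mean_pihat, pch = 16, col = "firebrick")
  invisible(x)
}
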