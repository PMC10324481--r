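#' Pearson correlation between two maps
#'
#' Product-moment correlation over the voxels of a region: the full map, or
#' a centered cube of a given edge length in Angstrom (the dialanine
#' experiments used the central 6 x 6 x 6 A region because the rest of the
#' enlarged cell was empty). Invariant under any affine rescaling with
#' positive slope of either map.
#'
#' @param pred,target [voxel_map()]s on the same grid, or arrays of equal
#'   shape.
#' @param region \code{"full"} or a numeric cube edge in Angstrom
#'   (requires voxel_map inputs for the spacing).
#' @return Correlation in [-1, 1].
#' @export
pearson_cc <- function(pred, target, region = "full") {
  p <- .loss_values(pred); t <- .loss_values(target)
  if (!identical(dim(p), dim(t))) stop("shape mismatch", call. = FALSE)
  if (!identical(region, "full")) {
    stopifnot(is.numeric(region), inherits(pred, "voxel_map"))
    g <- pred$grid
    m <- round(region / g$spacing)
    n <- c(g$nx, g$ny, g$nz)
    if (any(m < 2) || any(m > n)) {
      stop("central region out of range", call. = FALSE)
    }
    lo <- floor((n - m) / 2) + 1L
    p <- p[lo[1]:(lo[1] + m[1] - 1), lo[2]:(lo[2] + m[2] - 1),
           lo[3]:(lo[3] + m[3] - 1)]
    t <- t[lo[1]:(lo[1] + m[1] - 1), lo[2]:(lo[2] + m[2] - 1),
           lo[3]:(lo[3] + m[3] - 1)]
  }
  if (stats::sd(as.vector(p)) == 0 || stats::sd(as.vector(t)) == 0) {
    stop("correlation undefined: constant map over the selected region",
         call. = FALSE)
  }
  stats::cor(as.vector(p), as.vector(t))
}

#' Resolution shell scheme
#'
#' Partitions the resolution range from \code{d_max} (default infinity) to
#' \code{d_min} into \code{n_shells} bins of equal width in 1/d^2, the
#' standard reciprocal-space binning that gives shells of roughly equal
#' reflection counts.
#'
#' @param d_min High-resolution bound in Angstrom.
#' @param n_shells Number of shells (default 20).
#' @param d_max Low-resolution bound (default \code{Inf}).
#' @return A \code{shell_scheme} with bin edges in 1/d^2.
#' @export
shell_scheme <- function(d_min, n_shells = 20, d_max = Inf) {
  stopifnot(d_min > 0, n_shells >= 1, d_max > d_min)
  s2_lo <- if (is.infinite(d_max)) 0 else 1 / d_max^2
  s2_hi <- 1 / d_min^2
  edges <- seq(s2_lo, s2_hi, length.out = n_shells + 1)
  structure(list(d_min = d_min, d_max = d_max, n_shells = n_shells,
                 edges = edges),
            class = "shell_scheme")
}

# shell index per reflection (1..n_shells); d = Inf goes to shell 1
.shell_of <- function(d, scheme) {
  s2 <- ifelse(is.infinite(d), 0, 1 / d^2)
  idx <- findInterval(s2, scheme$edges, rightmost.closed = TRUE,
                      left.open = FALSE)
  pmin(pmax(idx, 1L), scheme$n_shells)
}

#' Phase error between predicted and true densities, by resolution shell
#'
#' Both maps are transformed back to structure factors
#' ([reflections_from_density()]); for each reflection the absolute wrapped
#' phase difference \code{|wrap(phi_pred - phi_true)|} in [0, 180] degrees
#' is computed, and shell means are formed, weighted by the true
#' amplitudes by default (the convention of standard phase-matching
#' tools; \code{weighted = FALSE} gives plain means). Shells containing no
#' reflections are reported as \code{NA}, not zero.
#'
#' @param pred,true [voxel_map()]s on one grid (role density).
#' @param d_min Resolution cutoff for the comparison, Angstrom.
#' @param scheme A [shell_scheme()] (default: 20 shells to \code{d_min}).
#' @param weighted Weight phase differences by true amplitude?
#' @return A list: \code{by_shell} data.frame (shell, d_hi, d_lo, n,
#'   mean_error_deg), \code{overall} mean error (degrees), and the
#'   per-reflection table.
#' @export
phase_error_by_shell <- function(pred, true, d_min,
                                 scheme = shell_scheme(d_min),
                                 weighted = TRUE) {
  stopifnot(inherits(pred, "voxel_map"), inherits(true, "voxel_map"))
  if (!identical(dim(pred$values), dim(true$values))) {
    stop("maps must share one grid", call. = FALSE)
  }
  rp <- reflections_from_density(pred, d_min)
  rt <- reflections_from_density(true, d_min)
  stopifnot(identical(rp$refl[, c("h", "k", "l")],
                      rt$refl[, c("h", "k", "l")]))
  if (max(rt$refl$amp) <= 0) stop("true map is empty", call. = FALSE)
  dphi <- abs(.wrap_phase(rp$refl$phase_deg - rt$refl$phase_deg))
  w <- if (weighted) rt$refl$amp else rep(1, nrow(rt$refl))
  shell <- .shell_of(rt$refl$d, scheme)
  by_shell <- lapply(seq_len(scheme$n_shells), function(s) {
    sel <- shell == s
    data.frame(
      shell = s,
      d_hi = 1 / sqrt(max(scheme$edges[s], .Machine$double.eps)),
      d_lo = 1 / sqrt(scheme$edges[s + 1]),
      n = sum(sel),
      mean_error_deg = if (any(sel)) {
        sum(w[sel] * dphi[sel]) / sum(w[sel])
      } else NA_real_)
  })
  list(by_shell = do.call(rbind, by_shell),
       overall = sum(w * dphi) / sum(w),
       reflections = data.frame(rp$refl[, c("h", "k", "l", "d")],
                                dphi_deg = dphi, amp_true = rt$refl$amp,
                                shell = shell))
}

#' Fraction of examples below a phase-error threshold, per shell
#'
#' @param shell_errors Numeric matrix (examples x shells) of shell-mean
#'   phase errors in degrees, as collected from repeated
#'   [phase_error_by_shell()] calls.
#' @param threshold Degrees, in (0, 180); the headline curves use 60.
#' @return Per-shell fractions in [0, 1] (NA shells are dropped from both
#'   numerator and denominator).
#' @export
fraction_below <- function(shell_errors, threshold = 60) {
  stopifnot(threshold > 0, threshold < 180)
  shell_errors <- as.matrix(shell_errors)
  if (nrow(shell_errors) == 0L) stop("empty example set", call. = FALSE)
  apply(shell_errors, 2, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    mean(col[ok] < threshold)
  })
}

#' Evaluate a set of predictions against true densities
#'
#' Computes per-example Pearson correlation and overall phase error, the
#' per-shell error curves and the fraction-below-60-degree curve, and the
#' medians across examples that summarize an experiment.
#'
#' @param preds,truths Lists of [voxel_map()]s (aligned).
#' @param d_min Resolution cutoff in Angstrom.
#' @param scheme A [shell_scheme()].
#' @param region Region passed to [pearson_cc()].
#' @param threshold Phase-error threshold in degrees for the fraction
#'   curve.
#' @param weighted Amplitude-weighted phase errors?
#' @return An \code{evaluation_report}: per-example data.frame,
#'   \code{median_cc}, \code{median_phase_error}, per-shell mean curve and
#'   fraction-below curve.
#' @export
evaluate_predictions <- function(preds, truths, d_min,
                                 scheme = shell_scheme(d_min),
                                 region = "full", threshold = 60,
                                 weighted = TRUE) {
  stopifnot(length(preds) == length(truths), length(preds) >= 1)
  n <- length(preds)
  cc <- numeric(n)
  overall <- numeric(n)
  shell_mat <- matrix(NA_real_, n, scheme$n_shells)
  for (i in seq_len(n)) {
    cc[i] <- pearson_cc(preds[[i]], truths[[i]], region = region)
    pe <- phase_error_by_shell(preds[[i]], truths[[i]], d_min,
                               scheme = scheme, weighted = weighted)
    overall[i] <- pe$overall
    shell_mat[i, ] <- pe$by_shell$mean_error_deg
  }
  structure(list(
    per_example = data.frame(example = seq_len(n), cc = cc,
                             phase_error_deg = overall),
    median_cc = stats::median(cc),
    median_phase_error = stats::median(overall),
    shell_mean_error = colMeans(shell_mat, na.rm = TRUE),
    shell_fraction_below = fraction_below(shell_mat, threshold),
    scheme = scheme, threshold = threshold),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation summary\n")
  cat(sprintf("  examples:            %d\n", nrow(x$per_example)))
  cat(sprintf("  median Pearson CC:   %.4f\n", x$median_cc))
  cat(sprintf("  median phase error:  %.1f deg\n", x$median_phase_error))
  invisible(x)
}

#' Write an evaluation report as CSV tables
#'
#' @param report An \code{evaluation_report}.
#' @param dir Output directory.
#' @return \code{dir} invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_example,
                   file.path(dir, "per_example.csv"), row.names = FALSE)
  edges <- report$scheme$edges
  shells <- data.frame(
    shell = seq_len(report$scheme$n_shells),
    d_hi = 1 / sqrt(pmax(edges[-length(edges)], .Machine$double.eps)),
    d_lo = 1 / sqrt(edges[-1]),
    mean_error_deg = report$shell_mean_error,
    fraction_below = report$shell_fraction_below)
  utils::write.csv(shells, file.path(dir, "shells.csv"), row.names = FALSE)
  summary <- data.frame(median_cc = report$median_cc,
                        median_phase_error = report$median_phase_error,
                        n_examples = nrow(report$per_example))
  utils::write.csv(summary, file.path(dir, "summary.csv"),
                   row.names = FALSE)
  invisible(dir)
}
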