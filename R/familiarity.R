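# Visual familiarity and the opponent drive.
#
# Mismatch between two views is the global root-mean-square pixel
# difference, computed at the facing alignment only (no rotation of
# either view). Familiarity against a bank is 1 minus the normalised
# lowest mismatch over the bank. The opponent drive subtracts the
# repulsive from the attractive familiarity; the attractive-only drive
# centres the attractive familiarity on a calibrated world average.

#' Familiarity context
#'
#' Holds the normalisation of raw mismatch values into [0, 1] and the
#' average world familiarity used by the attractive-only drive.
#'
#' The default `normalization_constant` of 1 is the theoretical maximum
#' RMS difference for luminances in [0, 1] (a full-contrast complement),
#' which keeps familiarity values comparable across worlds. An empirical
#' per-world alternative (the maximum mismatch over the calibration
#' sample) can be selected in [calibrate_average_world_familiarity()].
#'
#' @param normalization_constant maximum mismatch mapped to familiarity
#'   0; must be > 0. Default 1.
#' @param average_world_familiarity mean familiarity between two random
#'   views in the world, in [0, 1]; `NA` until calibrated.
#' @param n_calibration_views number of random views used by the
#'   calibration, >= 2. Default 32.
#' @param seed integer seed for calibration sampling.
#' @return an object of class `familiarity_context`.
#' @export
familiarity_context <- function(normalization_constant = 1.0,
                                average_world_familiarity = NA_real_,
                                n_calibration_views = 32L, seed = 1L) {
  if (normalization_constant <= 0)
    stop_invalid("normalization_constant must be > 0")
  if (!is.na(average_world_familiarity) &&
      (average_world_familiarity < 0 || average_world_familiarity > 1))
    stop_invalid("average_world_familiarity must lie in [0, 1]")
  structure(list(normalization_constant = normalization_constant,
                 average_world_familiarity = average_world_familiarity,
                 n_calibration_views = as.integer(n_calibration_views),
                 seed = as.integer(seed)),
            class = "familiarity_context")
}

#' Root-mean-square mismatch between two views
#'
#' Views are compared pixel-by-pixel at their facing alignment; neither
#' view is rotated. Symmetric; zero iff identical.
#'
#' @param a,b `panorama_view` objects (or plain matrices) of identical
#'   dimensions.
#' @return a nonnegative scalar.
#' @examples
#' view_mismatch(matrix(c(0, 1, 1, 0), 2), matrix(c(1, 0, 1, 0), 2))
#' @export
view_mismatch <- function(a, b) {
  pa <- if (inherits(a, "panorama_view")) a$pixels else a
  pb <- if (inherits(b, "panorama_view")) b$pixels else b
  if (!all(dim(pa) == dim(pb)))
    stop_invalid("views have mismatched dimensions (",
                 paste(dim(pa), collapse = "x"), " vs ",
                 paste(dim(pb), collapse = "x"), ")")
  sqrt(mean((pa - pb)^2))
}

# Cross RMS differences between the rows of two pixel matrices, via the
# |a-b|^2 = |a|^2 + |b|^2 - 2ab expansion. Cancellation in the expansion
# can leave O(1e-13) residue where rows are identical; squared distances
# below 1e-10 (RMS ~ 1e-7 luminance units, far below any real view
# difference) are snapped to exact zero so self-matches score exactly 1.
rms_cross <- function(A, B) {
  if (ncol(A) != ncol(B))
    stop_invalid("view and bank pixel dimensions differ")
  npx <- ncol(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 1e-10] <- 0
  sqrt(d2 / npx)
}

# Mismatch of one flattened view (or a matrix of them, one per row)
# against every bank view: returns an n_query x n_bank matrix.
mismatch_matrix <- function(qmat, bank) {
  if (is.null(dim(qmat))) qmat <- matrix(qmat, nrow = 1)
  rms_cross(qmat, bank$pixmat)
}

#' Familiarity of a view against a memory bank
#'
#' The current view is compared to every view in the bank (at facing
#' alignment), the lowest mismatch is normalised by the context's
#' `normalization_constant`, clipped to [0, 1], and subtracted from 1.
#'
#' @param v a `panorama_view` (or pixel matrix).
#' @param bank a `memory_bank` (non-empty by construction).
#' @param ctx a [familiarity_context()].
#' @return a familiarity value in [0, 1]; 1 means a perfect match with
#'   some memorised view.
#' @export
bank_familiarity <- function(v, bank, ctx = familiarity_context()) {
  if (is.null(bank) || length(bank$views) == 0)
    stop_invalid("memory bank is empty")
  px <- if (inherits(v, "panorama_view")) v$pixels else v
  mm <- mismatch_matrix(as.numeric(px), bank)
  1 - min(pmax(pmin(mm / ctx$normalization_constant, 1), 0))
}

new_drive_signal <- function(att, rep, opp, drive, mode) {
  structure(list(attractive_familiarity = att,
                 repulsive_familiarity = rep,
                 opponent_familiarity = opp,
                 overall_drive = drive,
                 memory_mode = mode),
            class = "drive_signal")
}

#' Opponent drive from attractive and repulsive familiarities
#'
#' The two valences are integrated by simple subtraction: the opponent
#' familiarity is attractive minus repulsive, and it is the overall drive
#' directly. Positive values mean the current view matches the
#' goal-facing memories better than the anti-goal-facing ones.
#'
#' @param att,rep familiarity values in [0, 1].
#' @return a `drive_signal` with fields `attractive_familiarity`,
#'   `repulsive_familiarity`, `opponent_familiarity` and `overall_drive`.
#' @examples
#' opponent_drive(0.8, 0.5)$overall_drive  # 0.3
#' @export
opponent_drive <- function(att, rep) {
  stopifnot(att >= 0, att <= 1, rep >= 0, rep <= 1)
  opp <- att - rep
  new_drive_signal(att, rep, opp, opp, "opponent")
}

#' Attractive-only drive
#'
#' When only the attractive bank is used, the drive is the attractive
#' familiarity centred on the calibrated average world familiarity, so
#' that -- as with the opponent integration -- the drive is normalised
#' around 0: positive for a rather good match, negative for a poor one.
#'
#' @param att attractive familiarity in [0, 1].
#' @param ctx a calibrated [familiarity_context()].
#' @return a `drive_signal`; `repulsive_familiarity` is `NA`.
#' @export
attractive_only_drive <- function(att, ctx) {
  if (is.na(ctx$average_world_familiarity))
    stop_invalid("context is not calibrated: run ",
                 "calibrate_average_world_familiarity() first")
  new_drive_signal(att, NA_real_, NA_real_,
                   att - ctx$average_world_familiarity, "attractive_only")
}

#' @export
print.drive_signal <- function(x, ...) {
  cat("<drive_signal>", x$memory_mode, "- overall drive",
      signif(x$overall_drive, 4), "\n")
  invisible(x)
}

#' Calibrate the average world familiarity
#'
#' Renders `ctx$n_calibration_views` views at uniform-random in-bounds
#' positions and uniform-random headings (seeded by `ctx$seed`) and sets
#' `average_world_familiarity` to the mean familiarity over all unordered
#' pairs of sampled views. With `normalization = "empirical"` the
#' context's `normalization_constant` is additionally replaced by the
#' maximum pairwise mismatch of the sample (a per-world scaling).
#'
#' @param world a `world_model`.
#' @param ctx a [familiarity_context()].
#' @param vp a [view_params()] object.
#' @param normalization `"theoretical"` (keep the context's constant) or
#'   `"empirical"`.
#' @return the calibrated `familiarity_context`, with attribute
#'   `n_pairs` (the number of pair comparisons averaged).
#' @export
calibrate_average_world_familiarity <- function(world, ctx = familiarity_context(),
                                                vp = view_params(),
                                                normalization = c("theoretical",
                                                                  "empirical")) {
  normalization <- match.arg(normalization)
  n <- ctx$n_calibration_views
  if (n < 2) stop_invalid("n_calibration_views must be >= 2")
  views <- with_seed(ctx$seed, {
    pos <- matrix(stats::runif(2 * n, -world$bounds, world$bounds), n, 2)
    hd <- stats::runif(n, 0, 360)
    lapply(seq_len(n), function(i)
      as.numeric(render_panorama(world, pos[i, ], hd[i], vp)$pixels))
  })
  V <- do.call(rbind, views)
  mm <- rms_cross(V, V)
  pair <- mm[upper.tri(mm)]
  if (normalization == "empirical") {
    k <- max(pair)
    if (k <= 0) k <- ctx$normalization_constant
    ctx$normalization_constant <- k
  }
  fam <- 1 - pmax(pmin(pair / ctx$normalization_constant, 1), 0)
  ctx$average_world_familiarity <- mean(fam)
  attr(ctx, "n_pairs") <- length(pair)
  ctx
}
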