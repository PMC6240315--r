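# 3D phase-correlation shift estimation and the online stage-tracking loop
# used for long-term light-sheet imaging of the elongating tailbud: stacks are
# downsampled to isotropic voxels, every interval-th timepoint is registered
# against a reference stack by phase correlation, the stage is moved by the
# negated shift and the reference replaced by the current stack. The same
# estimator drives offline consecutive-stack registration.

#' Construct a volume stack
#'
#' A `volume_stack` is a 3D intensity array in (z, y, x) order with per-axis
#' voxel sizes in microns and a timepoint index.
#'
#' @param data 3D numeric array (z, y, x).
#' @param voxel_size Micron extent per voxel along (z, y, x); default isotropic 1.
#' @param timepoint Integer timepoint index (0-based).
#' @return An object of class `volume_stack`.
#' @export
volume_stack <- function(data, voxel_size = c(1, 1, 1), timepoint = 0L) {
  data <- as.array(data)
  stopifnot(length(dim(data)) == 3, all(dim(data) > 0), all(voxel_size > 0))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 timepoint = as.integer(timepoint)),
            class = "volume_stack")
}

#' @export
print.volume_stack <- function(x, ...) {
  cat("volume_stack ", paste(dim(x$data), collapse = "x"),
      " voxels @ ", paste(x$voxel_size, collapse = "x"), " um, t=",
      x$timepoint, "\n", sep = "")
  invisible(x)
}

as_vol_array <- function(v) if (inherits(v, "volume_stack")) v$data else as.array(v)

#' Downsample a stack to isotropic voxels by block averaging
#'
#' Block-mean (anti-aliased) resampling to the target voxel size, the online
#' step that keeps per-timepoint computation cheap. Only integer downsampling
#' factors are supported and upsampling is refused; mean intensity is
#' conserved exactly for exact factor divisions and within 1% otherwise
#' (trailing partial blocks are averaged over their true extent).
#'
#' @param stack A [volume_stack].
#' @param target_voxel Target voxel edge in microns (default 1).
#' @return A [volume_stack] at the target voxel size.
#' @export
downsample_iso <- function(stack, target_voxel = 1) {
  stopifnot(inherits(stack, "volume_stack"))
  f <- target_voxel / stack$voxel_size
  if (any(f < 1 - 1e-9)) {
    stop("target voxel smaller than source voxel: refusing to upsample")
  }
  f <- pmax(1L, as.integer(round(f)))
  a <- stack$data
  d <- dim(a)
  nd <- ceiling(d / f)
  out <- array(0, nd)
  # block mean via index mapping; partial trailing blocks use their true size
  zi <- (seq_len(d[1]) - 1L) %/% f[1] + 1L
  yi <- (seq_len(d[2]) - 1L) %/% f[2] + 1L
  xi <- (seq_len(d[3]) - 1L) %/% f[3] + 1L
  idx <- cbind(zi[slice.index(a, 1)], yi[slice.index(a, 2)], xi[slice.index(a, 3)])
  sums <- array(0, nd); cnts <- array(0, nd)
  lin <- (idx[, 3] - 1L) * nd[1] * nd[2] + (idx[, 2] - 1L) * nd[1] + idx[, 1]
  sums[] <- tapply(as.vector(a), lin, sum)[as.character(seq_len(prod(nd)))]
  cnts[] <- tabulate(lin, nbins = prod(nd))
  out <- sums / cnts
  volume_stack(out, voxel_size = stack$voxel_size * f, timepoint = stack$timepoint)
}

fft3 <- function(a, inverse = FALSE) stats::fft(a, inverse = inverse)

# circular integer translation of a 3D array by (dz, dy, dx):
# result[i] = a[i - d] with wrap-around
translate_circular <- function(a, d) {
  dm <- dim(a)
  idx <- lapply(1:3, function(k) {
    s <- ((seq_len(dm[k]) - 1L - d[k]) %% dm[k]) + 1L
    s
  })
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

# translation with zero fill (non-circular), plus validity mask
translate_pad <- function(a, d, fill = 0) {
  dm <- dim(a)
  out <- array(fill, dm)
  src <- lapply(1:3, function(k) {
    lo <- max(1L, 1L - d[k]); hi <- min(dm[k], dm[k] - d[k])
    if (lo > hi) integer(0) else lo:hi
  })
  if (any(lengths(src) == 0)) return(out)
  dst <- lapply(1:3, function(k) src[[k]] + d[k])
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

hann3 <- function(dm) {
  w <- lapply(dm, function(n) {
    if (n == 1) 1 else 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  })
  outer(outer(w[[1]], w[[2]]), w[[3]]) |> array(dim = dm)
}

#' 3D phase-correlation shift between two stacks
#'
#' Estimates the integer translation carrying `ref` onto `mov` from the peak
#' of the inverse transform of the normalized cross-power spectrum. The
#' argmax is restricted to the `±max_shift` neighbourhood after wrap-around
#' unfolding (drift between registration events is assumed small); ties are
#' broken towards the smallest L2-norm shift. Confidence is the peak value
#' divided by the sum of the top five peak values in the search window.
#'
#' @param ref,mov [volume_stack]s (or arrays) of identical shape and voxel size.
#' @param max_shift Maximum absolute shift searched per axis, in voxels;
#'   default one quarter of each dimension.
#' @param window Apply a Hann window before the transform (default `FALSE`;
#'   enable for non-circular real data to suppress edge ringing).
#' @return List with `shift` (integer `c(dz, dy, dx)` such that `mov` is `ref`
#'   translated by `shift`) and `confidence`.
#' @export
phase_corr_shift <- function(ref, mov, max_shift = NULL, window = FALSE) {
  a <- as_vol_array(ref); b <- as_vol_array(mov)
  if (!identical(dim(a), dim(b))) stop("stacks differ in shape")
  if (inherits(ref, "volume_stack") && inherits(mov, "volume_stack") &&
      !isTRUE(all.equal(ref$voxel_size, mov$voxel_size))) {
    stop("stacks differ in voxel size")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("no signal: flat input volume")
  dm <- dim(a)
  if (is.null(max_shift)) max_shift <- pmax(1L, dm %/% 4L)
  max_shift <- rep_len(as.integer(max_shift), 3)
  if (window) {
    w <- hann3(dm)
    a <- a * w; b <- b * w
  }
  Fa <- fft3(a); Fb <- fft3(b)
  R <- Fb * Conj(Fa)
  mag <- Mod(R)
  R <- R / ifelse(mag == 0, 1, mag)
  r <- Re(fft3(R, inverse = TRUE)) / prod(dm)
  # unfold wrap-around: offsets 0..n-1 map to 0..n/2, -(n/2)..-1
  offs <- lapply(1:3, function(k) {
    o <- seq_len(dm[k]) - 1L
    ifelse(o > dm[k] %/% 2, o - dm[k], o)
  })
  ok <- lapply(1:3, function(k) abs(offs[[k]]) <= max_shift[k])
  rs <- r[ok[[1]], ok[[2]], ok[[3]], drop = FALSE]
  so <- lapply(1:3, function(k) offs[[k]][ok[[k]]])
  peak <- max(rs)
  cand <- which(rs >= peak - 1e-12, arr.ind = TRUE)
  shifts <- cbind(so[[1]][cand[, 1]], so[[2]][cand[, 2]], so[[3]][cand[, 3]])
  pick <- which.min(rowSums(shifts^2))
  top5 <- sort(as.vector(rs), decreasing = TRUE)[1:min(5, length(rs))]
  list(shift = as.integer(shifts[pick, ]),
       confidence = peak / sum(pmax(top5, 0)))
}

#' Simulate a drifting volume time series with ground truth
#'
#' Generates Gaussian-blob objects (optionally growing and translating, a
#' cartoon of the extending tailbud) observed over time while the whole field
#' drifts along a known path, with additive Gaussian noise. Default cadence is
#' one stack per 2.5 min over the study's 8-hour window scaled down to
#' `n_timepoints`. Circular boundary mode makes integer drifts exactly
#' recoverable; crop mode lets the object leave the field of view.
#'
#' @param shape Volume dimensions (z, y, x); default `c(32, 32, 32)`.
#' @param n_timepoints Number of stacks.
#' @param drift Either a single per-frame drift vector `c(dz, dy, dx)`
#'   (constant drift), or a `n_timepoints x 3` matrix of per-frame drifts, or
#'   `"random_walk"`.
#' @param drift_sd Step sd when `drift = "random_walk"`.
#' @param n_blobs,blob_sigma,blob_intensity Object model parameters.
#' @param noise_sd Additive Gaussian noise sd.
#' @param mode `"circular"` (wrap-around, exact) or `"crop"` (drift moves
#'   content out of the field).
#' @param growth Per-frame blob intensity growth factor (default 1).
#' @param seed Integer seed.
#' @param dt_min Minutes per frame metadata (default 2.5).
#' @return List of class `volume_series`: `stacks` (list of [volume_stack]),
#'   `drift` (per-frame true drift matrix), `cumulative_drift`, `centers`
#'   (true object centroid per frame), `mode`.
#' @export
simulate_drifting_volume <- function(shape = c(32, 32, 32), n_timepoints = 12,
                                     drift = c(0, 1, 2), drift_sd = 1,
                                     n_blobs = 4, blob_sigma = 2.5,
                                     blob_intensity = 100, noise_sd = 0,
                                     mode = c("circular", "crop"),
                                     growth = 1, seed = 1L, dt_min = 2.5) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  if (is.character(drift) && drift == "random_walk") {
    D <- matrix(round(stats::rnorm(3 * n_timepoints, 0, drift_sd)),
                n_timepoints, 3)
    D[1, ] <- 0
  } else if (is.matrix(drift)) {
    D <- drift
  } else {
    D <- rbind(0, matrix(rep(as.numeric(drift), n_timepoints - 1),
                         ncol = 3, byrow = TRUE))
  }
  stopifnot(nrow(D) == n_timepoints)
  ctr <- shape / 2
  blob_pos <- matrix(stats::runif(3 * n_blobs, 0.35, 0.65), n_blobs, 3) *
    matrix(rep(shape, each = n_blobs), n_blobs, 3)
  ax <- lapply(1:3, function(k) seq_len(shape[k]))
  base_vol <- function(scale, offset) {
    v <- array(0, shape)
    for (b in seq_len(n_blobs)) {
      g <- lapply(1:3, function(k)
        exp(-((ax[[k]] - blob_pos[b, k] - offset[k])^2) / (2 * blob_sigma^2)))
      v <- v + scale * blob_intensity *
        array(outer(outer(g[[1]], g[[2]]), g[[3]]), dim = shape)
    }
    v
  }
  cum <- apply(D, 2, cumsum)
  if (n_timepoints == 1) cum <- matrix(cum, 1, 3)
  stacks <- vector("list", n_timepoints)
  centers <- matrix(0, n_timepoints, 3)
  for (t in seq_len(n_timepoints)) {
    scale <- growth^(t - 1)
    if (mode == "circular") {
      v0 <- base_vol(scale, c(0, 0, 0))
      v <- translate_circular(v0, as.integer(round(cum[t, ])))
    } else {
      v <- base_vol(scale, cum[t, ])
    }
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    stacks[[t]] <- volume_stack(v, timepoint = t - 1L)
    w <- pmax(stacks[[t]]$data, 0)
    centers[t, ] <- vapply(1:3, function(k)
      sum(slice.index(w, k) * w) / sum(w), numeric(1))
  }
  structure(list(stacks = stacks, drift = D, cumulative_drift = cum,
                 centers = centers, mode = mode, dt_min = dt_min),
            class = "volume_series")
}

#' Online stage-tracking loop over a volume series
#'
#' Emulates the microscope feedback: at every `interval`-th timepoint the
#' current (downsampled) stack is phase-correlated against the reference
#' stack, the stage is moved by the negated estimated shift, and the reference
#' is replaced by the current stack so that gradual sample changes are
#' tolerated. Events with confidence below `confidence_floor` are logged but
#' the correction is withheld.
#'
#' @param series A `volume_series` (or list of [volume_stack]).
#' @param interval Registration cadence in timepoints (default 5).
#' @param max_shift Passed to [phase_corr_shift()].
#' @param confidence_floor Minimum confidence to apply a correction.
#' @param mode `"circular"` or `"crop"` translation when applying stage moves.
#' @return List with `log` (data frame: timepoint, estimated shift, applied
#'   correction, reference timepoint, confidence), `corrected` (list of
#'   corrected [volume_stack]s, i.e. what the camera would have seen with the
#'   stage following), and `cumulative_correction`.
#' @export
online_tracking <- function(series, interval = 5, max_shift = NULL,
                            confidence_floor = 0, mode = c("circular", "crop")) {
  mode <- match.arg(mode)
  stacks <- if (inherits(series, "volume_series")) series$stacks else series
  n <- length(stacks)
  if (n < interval + 1) stop("need at least interval+1 timepoints")
  correction <- c(0L, 0L, 0L)   # cumulative stage correction applied
  ref <- NULL; ref_t <- NA_integer_
  logs <- list()
  corrected <- vector("list", n)
  for (t in seq_len(n)) {
    raw <- as_vol_array(stacks[[t]])
    seen <- if (mode == "circular") translate_circular(raw, correction)
            else translate_pad(raw, correction)
    if ((t - 1L) %% interval == 0L) {
      if (!is.null(ref)) {
        est <- phase_corr_shift(ref, seen, max_shift = max_shift)
        apply_it <- est$confidence >= confidence_floor
        if (apply_it) correction <- as.integer(correction - est$shift)
        logs[[length(logs) + 1L]] <- data.frame(
          timepoint = t - 1L, ref_timepoint = ref_t,
          dz = est$shift[1], dy = est$shift[2], dx = est$shift[3],
          corr_z = -est$shift[1] * apply_it, corr_y = -est$shift[2] * apply_it,
          corr_x = -est$shift[3] * apply_it,
          confidence = est$confidence, applied = apply_it)
        # re-image at the corrected stage position before storing/reference
        seen <- if (mode == "circular") translate_circular(raw, correction)
                else translate_pad(raw, correction)
      }
      ref <- seen; ref_t <- t - 1L
    }
    corrected[[t]] <- volume_stack(seen,
                                   voxel_size = if (inherits(stacks[[t]], "volume_stack"))
                                     stacks[[t]]$voxel_size else c(1, 1, 1),
                                   timepoint = t - 1L)
  }
  log_df <- if (length(logs)) do.call(rbind, logs) else
    data.frame(timepoint = integer(0), ref_timepoint = integer(0),
               dz = integer(0), dy = integer(0), dx = integer(0),
               corr_z = integer(0), corr_y = integer(0), corr_x = integer(0),
               confidence = numeric(0), applied = logical(0))
  list(log = log_df, corrected = corrected, cumulative_correction = correction)
}

#' Offline registration of consecutive stacks
#'
#' Registers each stack to its predecessor by phase correlation and aligns the
#' whole series to frame 0 by the cumulative integer translations (prefix sums
#' of the pairwise shifts), removing the sudden displacements left by stage
#' moves. Non-circular alignment pads with zeros and reports a validity mask.
#'
#' @param series A `volume_series` or list of [volume_stack].
#' @param max_shift Passed to [phase_corr_shift()].
#' @param mode `"circular"` or `"crop"` fill behaviour for the applied shifts.
#' @return List with `registered` (list of [volume_stack]), `pairwise`
#'   (matrix of t -> t+1 shifts), `cumulative` (alignment applied to each
#'   frame) and `mask` (validity array, `NULL` in circular mode).
#' @export
offline_register <- function(series, max_shift = NULL,
                             mode = c("circular", "crop")) {
  mode <- match.arg(mode)
  stacks <- if (inherits(series, "volume_series")) series$stacks else series
  n <- length(stacks)
  if (n == 1) {
    return(list(registered = stacks,
                pairwise = matrix(0L, 0, 3),
                cumulative = matrix(0L, 1, 3), mask = NULL))
  }
  pair <- matrix(0L, n - 1, 3)
  for (t in seq_len(n - 1)) {
    pair[t, ] <- phase_corr_shift(stacks[[t]], stacks[[t + 1]],
                                  max_shift = max_shift)$shift
  }
  cum <- rbind(c(0L, 0L, 0L), apply(pair, 2, cumsum))
  registered <- vector("list", n)
  mask <- NULL
  if (mode == "crop") mask <- array(TRUE, dim(as_vol_array(stacks[[1]])))
  for (t in seq_len(n)) {
    a <- as_vol_array(stacks[[t]])
    d <- as.integer(-cum[t, ])
    registered[[t]] <- volume_stack(
      if (mode == "circular") translate_circular(a, d) else translate_pad(a, d),
      voxel_size = if (inherits(stacks[[t]], "volume_stack"))
        stacks[[t]]$voxel_size else c(1, 1, 1),
      timepoint = t - 1L)
    if (mode == "crop") {
      mask <- mask & (translate_pad(array(1, dim(a)), d) > 0)
    }
  }
  list(registered = registered, pairwise = pair, cumulative = cum, mask = mask)
}

#' Object centroid of each stack in a series
#'
#' Intensity-weighted centroid per timepoint, used to quantify how well the
#' online loop keeps the object near the volume center.
#'
#' @param stacks List of [volume_stack] (or arrays).
#' @return `n x 3` matrix of centroids (z, y, x), in voxels.
#' @export
series_centroids <- function(stacks) {
  t(vapply(stacks, function(s) {
    a <- pmax(as_vol_array(s), 0)
    vapply(1:3, function(k) sum(slice.index(a, k) * a) / sum(a), numeric(1))
  }, numeric(3)))
}

#' TIFF I/O for volume series
#'
#' Writes each timepoint as a multi-page TIFF `t####.tif` (requires the
#' `tiff` package) with a JSON sidecar recording voxel size.
#'
#' @param series `volume_series` or list of [volume_stack].
#' @param dir Output directory.
#' @return `dir` invisibly ([write_volume_series()]); list of [volume_stack]
#'   ([read_volume_series()]).
#' @export
write_volume_series <- function(series, dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  stacks <- if (inherits(series, "volume_series")) series$stacks else series
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in seq_along(stacks)) {
    a <- as_vol_array(stacks[[t]])
    mx <- max(a, 1e-12)
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / mx)
    tiff::writeTIFF(pages, file.path(dir, sprintf("t%04d.tif", t - 1L)),
                    bits.per.sample = 32L)
    jsonlite::write_json(
      list(voxel_size = stacks[[t]]$voxel_size, scale = mx),
      file.path(dir, sprintf("t%04d.json", t - 1L)), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' @rdname write_volume_series
#' @param dir Directory containing `t####.tif` files.
#' @export
read_volume_series <- function(dir) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF I/O")
  }
  files <- sort(list.files(dir, pattern = "^t\\d+\\.tif$", full.names = TRUE))
  lapply(seq_along(files), function(i) {
    pages <- tiff::readTIFF(files[i], all = TRUE)
    meta_f <- sub("\\.tif$", ".json", files[i])
    meta <- if (file.exists(meta_f)) jsonlite::read_json(meta_f) else
      list(voxel_size = c(1, 1, 1), scale = 1)
    a <- array(0, c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]] * meta$scale
    volume_stack(a, voxel_size = unlist(meta$voxel_size), timepoint = i - 1L)
  })
}
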