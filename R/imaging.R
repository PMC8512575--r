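#' Image volume container
#'
#' Voxelized delay-and-sum intensity on a [voxel_grid()], with an in-mold
#' mask and provenance. Linear-intensity volumes are nonnegative; dB volumes
#' are marked by the `db` flag.
#'
#' @param grid A [voxel_grid()].
#' @param values 3D numeric array congruent with the grid.
#' @param mask Logical 3D array of valid voxels.
#' @param db Is the volume in decibels?
#' @param provenance Free-form list (channels used, input kind, coverage).
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(grid, values, mask = NULL, db = FALSE,
                         provenance = list()) {
  stopifnot(inherits(grid, "voxel_grid"), all(dim(values) == grid$dim))
  if (is.null(mask)) mask <- array(TRUE, grid$dim)
  if (!db && any(values[mask] < -1e-12))
    stop("linear-intensity volumes must be nonnegative")
  structure(list(grid = grid, values = values, mask = mask, db = db,
                 provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("Image volume: %d x %d x %d voxels at %.3g mm pitch (%s)\n",
              x$grid$dim[1], x$grid$dim[2], x$grid$dim[3],
              x$grid$pitch * 1e3, if (x$db) "dB" else "linear"))
  v <- x$values[x$mask]
  cat(sprintf("  range %.4g .. %.4g, argmax at (%s) m\n", min(v), max(v),
              paste(signif(image_argmax(x), 3), collapse = ", ")))
  invisible(x)
}

#' Position of the maximum-intensity voxel
#'
#' @param v An `image_volume`.
#' @return Length-3 position (m) of the masked argmax voxel center.
#' @export
image_argmax <- function(v) {
  stopifnot(inherits(v, "image_volume"))
  vals <- v$values
  vals[!v$mask] <- -Inf
  idx <- arrayInd(which.max(vals), v$grid$dim)
  v$grid$origin + (idx[1, ] - 1) * v$grid$pitch
}

#' Delay-and-sum 3D image formation
#'
#' For each voxel `r0`, sums the absolute value of each channel's
#' clutter-removed differential signal at the round-trip delay
#' `tau_ch(r0) = (|tx - r0| + |r0 - rx|)/v`:
#' `I(r0) = sum_ch |dy_ch(tau_ch(r0))|`, with linear interpolation between
#' propagation-time samples. Delays beyond the signal support contribute 0
#' and are counted in the coverage report. Voxels outside the mold are
#' masked.
#'
#' @param signals List of `irf_signal` objects (or lists with `t`, `values`),
#'   one per selected channel; magnitudes or signed amplitudes.
#' @param geometry An [array_geometry()].
#' @param selection A [select_channels()] result (rows aligned with
#'   `signals`).
#' @param velocity Propagation velocity (m/s), e.g. [host_velocity()].
#' @param grid A [voxel_grid()].
#' @return An `image_volume` (linear intensity) with coverage counts in its
#'   provenance.
#' @export
das_image <- function(signals, geometry, selection, velocity, grid) {
  stopifnot(inherits(geometry, "array_geometry"),
            inherits(selection, "channel_selection"),
            length(signals) == nrow(selection), velocity > 0)
  xyz <- voxel_coords(grid)
  nvox <- nrow(xyz)
  I <- numeric(nvox)
  uncovered <- 0L
  for (k in seq_len(nrow(selection))) {
    sg <- signals[[k]]
    tx <- geometry$tx[selection$tx[k], ]
    rx <- geometry$rx[selection$rx[k], ]
    d1 <- sqrt((xyz[, 1] - tx[1])^2 + (xyz[, 2] - tx[2])^2 + (xyz[, 3] - tx[3])^2)
    d2 <- sqrt((xyz[, 1] - rx[1])^2 + (xyz[, 2] - rx[2])^2 + (xyz[, 3] - rx[3])^2)
    tau <- (d1 + d2) / velocity
    y <- stats::approx(sg$t, sg$values, xout = tau, yleft = 0, yright = 0)$y
    out_of_support <- tau < min(sg$t) | tau > max(sg$t)
    uncovered <- uncovered + sum(out_of_support)
    I <- I + abs(y)
  }
  mask <- array(in_mold(xyz, geometry), grid$dim)
  vol <- array(I, grid$dim)
  vol[!mask] <- 0
  image_volume(grid, vol, mask,
               provenance = list(n_channels = nrow(selection),
                                 uncovered_voxel_delays = uncovered))
}

#' Convert an image volume to decibels
#'
#' `I_dB = 10*log10(I^2) = 20*log10(I)`, optionally normalized to the
#' maximum of a reference volume (so the reference peak maps to 0 dB).
#'
#' @param v Linear-intensity `image_volume`.
#' @param normalize_to `"self"`, `"none"`, or a reference `image_volume`.
#' @param floor_db Value assigned to zero-intensity voxels.
#' @return A dB `image_volume`.
#' @export
to_db <- function(v, normalize_to = "self", floor_db = -120) {
  stopifnot(inherits(v, "image_volume"))
  if (v$db) stop("volume is already in dB")
  ref <- if (inherits(normalize_to, "image_volume")) {
    max(normalize_to$values[normalize_to$mask])
  } else if (identical(normalize_to, "self")) {
    max(v$values[v$mask])
  } else 1
  vals <- v$values / ref
  out <- array(floor_db, v$grid$dim)
  pos <- vals > 10^(floor_db / 20)
  out[pos] <- 20 * log10(vals[pos])
  image_volume(v$grid, out, v$mask, db = TRUE, provenance = v$provenance)
}

.sphere_mask <- function(grid, center, radius) {
  xyz <- voxel_coords(grid)
  d <- sqrt((xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
            (xyz[, 3] - center[3])^2)
  array(d <= radius, grid$dim)
}

#' Signal-to-clutter ratio of an image volume
#'
#' `S/C = 10*log10( mean(I^2) over the target region / mean(I^2) over the
#' breast region excluding the target )`. The target region defaults to a
#' sphere of the 2 mL target volume (radius ~7.8 mm) centered at the known
#' target position; the breast region defaults to the in-mold mask.
#'
#' @param v Linear-intensity `image_volume`.
#' @param target_center Length-3 target position (m).
#' @param target_radius Target-region radius (m).
#' @param breast_mask Logical array; defaults to the volume's mask.
#' @return Scalar S/C in dB.
#' @export
signal_to_clutter <- function(v, target_center, target_radius = 7.8e-3,
                              breast_mask = NULL) {
  stopifnot(inherits(v, "image_volume"), !v$db)
  if (is.null(breast_mask)) breast_mask <- v$mask
  tmask <- .sphere_mask(v$grid, target_center, target_radius) & breast_mask
  cmask <- breast_mask & !tmask
  if (!any(tmask)) stop("target region contains no voxels")
  if (!any(cmask)) stop("clutter (breast minus target) region contains no voxels")
  10 * log10(mean(v$values[tmask]^2) / mean(v$values[cmask]^2))
}

#' Subtract a PMF-only reference image
#'
#' Removes spurious PMF-coupling hot spots by subtracting the reference image
#' acquired without MNPs: `I = I_MNP - I_PMF`, negative voxels clipped to 0
#' (linear DAS intensities are nonnegative and downstream dB conversion
#' requires nonnegativity); the raw signed difference is retained in the
#' provenance for diagnostics.
#'
#' @param mnp,pmf_only Congruent linear `image_volume`s.
#' @return An `image_volume`.
#' @export
subtract_reference <- function(mnp, pmf_only) {
  stopifnot(inherits(mnp, "image_volume"), inherits(pmf_only, "image_volume"),
            !mnp$db, !pmf_only$db)
  if (!identical(mnp$grid$dim, pmf_only$grid$dim) ||
      any(abs(mnp$grid$origin - pmf_only$grid$origin) > 1e-12) ||
      mnp$grid$pitch != pmf_only$grid$pitch)
    stop("image grids are not congruent")
  raw <- mnp$values - pmf_only$values
  image_volume(mnp$grid, pmax(raw, 0), mnp$mask & pmf_only$mask,
               provenance = c(mnp$provenance, list(raw_difference = raw)))
}

#' Magnetic-field-inhomogeneity correction matrix
#'
#' For each voxel, the band-limited differential-response maximum
#' `dM(H(r0))` (see [band_limited_response_max()]) is computed at the local
#' field intensity from the field map, and the correction factor is its
#' reciprocal, scaled so that `CF = 1` at the reference intensity `H_ref`:
#' `CF_H(r0) = dM(H_ref) / dM(H(r0))`. Voxels where `dM = 0` (e.g. zero
#' local field) are masked. `dM(H)` is evaluated on an intensity sweep and
#' interpolated to the voxel fields.
#'
#' @param fm A `field_map`.
#' @param chi_model A `susceptibility_model`.
#' @param band Working band (Hz).
#' @param H_ref_ka_per_m Reference intensity (kA/m); default 80.
#' @param env Carrier environment.
#' @param n_sweep Number of intensities in the `dM(H)` sweep.
#' @return An object of class `correction_matrix` with the grid, `values`
#'   (`CF_H`), a validity mask and the number of masked voxels.
#' @export
correction_matrix <- function(fm, chi_model, band = c(1e9, 4e9),
                              H_ref_ka_per_m = 80,
                              env = medium_environment("immobilized"),
                              n_sweep = 33) {
  stopifnot(inherits(fm, "field_map"))
  H_ref <- ka_per_m_to_a_per_m(H_ref_ka_per_m)
  Hmax <- max(fm$values, H_ref)
  Hs <- seq(0, Hmax, length.out = n_sweep)
  dM <- vapply(Hs, function(h)
    band_limited_response_max(chi_model, h, 0, band = band, env = env),
    numeric(1))
  dM_ref <- band_limited_response_max(chi_model, H_ref, 0, band = band, env = env)
  if (dM_ref == 0) stop("dM(H_ref) = 0: correction undefined")
  dM_vox <- stats::approx(Hs, dM, xout = as.vector(fm$values))$y
  valid <- dM_vox > 0
  cf <- ifelse(valid, dM_ref / dM_vox, NA_real_)
  structure(list(grid = fm$grid, values = array(cf, fm$grid$dim),
                 mask = array(valid, fm$grid$dim),
                 H_ref = H_ref, n_masked = sum(!valid)),
            class = "correction_matrix")
}

#' Field-corrected delay-and-sum image
#'
#' `I_CF(r0) = CF_H(r0) * sum_ch |dy_ch(tau_ch(r0))|`: the plain
#' delay-and-sum image weighted voxelwise by the field-inhomogeneity
#' correction factor. Voxels masked in the correction matrix are masked in
#' the output.
#'
#' @inheritParams das_image
#' @param cf A [correction_matrix()] congruent with `grid`.
#' @return An `image_volume`.
#' @export
corrected_das <- function(signals, geometry, selection, velocity, grid, cf) {
  stopifnot(inherits(cf, "correction_matrix"))
  if (!identical(cf$grid$dim, grid$dim) ||
      any(abs(cf$grid$origin - grid$origin) > 1e-12) ||
      cf$grid$pitch != grid$pitch)
    stop("correction matrix grid is not congruent with the imaging grid")
  v <- das_image(signals, geometry, selection, velocity, grid)
  vals <- v$values * ifelse(is.na(cf$values), 0, cf$values)
  image_volume(grid, vals, v$mask & cf$mask,
               provenance = c(v$provenance, list(corrected = TRUE)))
}

#' @export
plot.image_volume <- function(x, plane = c("xy", "xz", "yz"), index = NULL, ...) {
  plane <- match.arg(plane)
  ax <- lapply(1:3, function(k) x$grid$origin[k] + x$grid$pitch * (seq_len(x$grid$dim[k]) - 1))
  k <- switch(plane, xy = 3, xz = 2, yz = 1)
  if (is.null(index)) {
    am <- image_argmax(x)
    index <- which.min(abs(ax[[k]] - am[k]))
  }
  sl <- switch(plane,
               xy = x$values[, , index], xz = x$values[, index, ],
               yz = x$values[index, , ])
  axes <- setdiff(1:3, k)
  graphics::image(ax[[axes[1]]], ax[[axes[2]]], sl,
                  xlab = c("x", "y", "z")[axes[1]],
                  ylab = c("x", "y", "z")[axes[2]],
                  main = sprintf("%s slice %d", plane, index), ...)
  invisible(x)
}
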