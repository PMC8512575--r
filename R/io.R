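#' Read / write tabulated susceptibility grids as CSV
#'
#' CSV schema: `freq_hz, field_a_per_m, chi_real, chi_imag`, sorted by field
#' then frequency, one row per grid node, forming a complete regular grid.
#' `chi_imag` stores the loss part chi'' (>= 0); internally the complex value
#' is `chi_real - 1i*chi_imag`.
#'
#' @param path CSV file path.
#' @return For the reader: a tabulated `susceptibility_model`.
#' @export
read_chi_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("freq_hz", "field_a_per_m", "chi_real", "chi_imag")
  if (!all(need %in% names(df)))
    stop("chi table CSV must have columns ", paste(need, collapse = ", "))
  freq <- sort(unique(df$freq_hz))
  field <- sort(unique(df$field_a_per_m))
  if (nrow(df) != length(freq) * length(field))
    stop("chi table is not a complete regular (freq x field) grid")
  if (any(df$chi_imag < 0)) stop("chi_imag (loss chi'') must be >= 0")
  key <- paste(df$freq_hz, df$field_a_per_m)
  ord <- match(paste(rep(freq, times = length(field)),
                     rep(field, each = length(freq))), key)
  if (anyNA(ord)) stop("chi table grid has duplicate or missing nodes")
  vals <- complex(real = df$chi_real[ord], imaginary = -df$chi_imag[ord])
  chi_table(freq, field, matrix(vals, nrow = length(freq)))
}

#' @rdname read_chi_table
#' @param model A tabulated `susceptibility_model`.
#' @export
write_chi_table <- function(model, path) {
  stopifnot(inherits(model, "susceptibility_model"), model$mode == "tabulated")
  df <- data.frame(freq_hz = rep(model$freq, times = length(model$field)),
                   field_a_per_m = rep(model$field, each = length(model$freq)),
                   chi_real = as.vector(Re(model$values)),
                   chi_imag = -as.vector(Im(model$values)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write dielectric spectra as CSV
#'
#' CSV schema: `freq_hz, eps_real, eps_imag` with `eps_imag` the loss part
#' eps'' (>= 0); internally `eps_real - 1i*eps_imag`.
#'
#' @param path CSV file path.
#' @return For the reader: a [dielectric_spectrum()].
#' @export
read_dielectric_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("freq_hz", "eps_real", "eps_imag")
  if (!all(need %in% names(df)))
    stop("dielectric CSV must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$freq_hz), ]
  dielectric_spectrum(df$freq_hz,
                      complex(real = df$eps_real, imaginary = -df$eps_imag))
}

#' @rdname read_dielectric_csv
#' @param spec A `dielectric_spectrum`.
#' @export
write_dielectric_csv <- function(spec, path) {
  stopifnot(inherits(spec, "dielectric_spectrum"))
  utils::write.csv(data.frame(freq_hz = spec$freq,
                              eps_real = Re(spec$eps_rel),
                              eps_imag = -Im(spec$eps_rel)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write magnetic field maps as CSV
#'
#' CSV schema: `x_m, y_m, z_m, h_a_per_m` on a complete regular grid; the
#' reader reconstructs the grid (origin, pitch, dimensions).
#'
#' @param path CSV file path.
#' @return For the reader: a `field_map`.
#' @export
read_field_map_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_m", "y_m", "z_m", "h_a_per_m")
  if (!all(need %in% names(df)))
    stop("field map CSV must have columns ", paste(need, collapse = ", "))
  ax <- lapply(c("x_m", "y_m", "z_m"), function(cn) sort(unique(df[[cn]])))
  dims <- vapply(ax, length, integer(1))
  if (nrow(df) != prod(dims)) stop("field map is not a complete regular grid")
  pitches <- vapply(ax, function(a) if (length(a) > 1) a[2] - a[1] else NA_real_,
                    numeric(1))
  pitch <- stats::na.omit(pitches)[1]
  for (a in ax) if (length(a) > 2 && max(abs(diff(a) - pitch)) > 1e-9)
    stop("field map grid is not uniform")
  key <- paste(df$x_m, df$y_m, df$z_m)
  ord <- match(paste(rep(ax[[1]], times = dims[2] * dims[3]),
                     rep(rep(ax[[2]], each = dims[1]), times = dims[3]),
                     rep(ax[[3]], each = dims[1] * dims[2])), key)
  if (anyNA(ord)) stop("field map grid has missing nodes")
  grid <- voxel_grid(c(ax[[1]][1], ax[[2]][1], ax[[3]][1]), pitch, dims)
  structure(list(grid = grid, values = array(df$h_a_per_m[ord], dims)),
            class = "field_map")
}

#' @rdname read_field_map_csv
#' @param fm A `field_map`.
#' @export
write_field_map_csv <- function(fm, path) {
  stopifnot(inherits(fm, "field_map"))
  xyz <- voxel_coords(fm$grid)
  utils::write.csv(data.frame(x_m = xyz[, 1], y_m = xyz[, 2], z_m = xyz[, 3],
                              h_a_per_m = as.vector(fm$values)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Persist a radargram set as a directory of CSVs plus JSON metadata
#'
#' Writes `meta.json` (seed, axes, channel list, PMF samples) and one
#' `channel_<tx>_<rx>.csv` per channel (t-by-T value matrix).
#'
#' @param rset A `radargram_set`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_radargram_set <- function(rset, dir) {
  stopifnot(inherits(rset, "radargram_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  r1 <- rset[[1]]
  meta <- list(seed = attr(rset, "seed"),
               t = r1$t, T = r1$T,
               pmf = r1$pmf,
               channels = data.frame(tx = vapply(rset, `[[`, numeric(1), "tx"),
                                     rx = vapply(rset, `[[`, numeric(1), "rx")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), digits = NA,
                       auto_unbox = TRUE)
  for (r in rset)
    utils::write.table(r$values,
                       file.path(dir, sprintf("channel_%d_%d.csv", r$tx, r$rx)),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_radargram_set
#' @export
read_radargram_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  pmf <- as.data.frame(meta$pmf)
  channels <- as.data.frame(meta$channels)
  rads <- lapply(seq_len(nrow(channels)), function(i) {
    tx <- channels$tx[i]; rx <- channels$rx[i]
    vals <- as.matrix(utils::read.table(
      file.path(dir, sprintf("channel_%d_%d.csv", tx, rx)), sep = ","))
    dimnames(vals) <- NULL
    structure(list(tx = tx, rx = rx, t = meta$t, T = meta$T,
                   values = vals, pmf = pmf),
              class = "radargram")
  })
  structure(rads, class = "radargram_set", seed = meta$seed)
}

#' Read a scenario configuration from YAML
#'
#' Thin mapping from a YAML file to [sim_config()]: recognized top-level keys
#' are `pmf` (list of [pmf_waveform()] arguments), `target` (list of
#' [target_spec()] arguments, or `null`), `geometry` (list of
#' [array_geometry()] arguments) and any remaining [sim_config()] scalar
#' arguments (`noise_sigma`, `seed`, ...).
#'
#' @param path YAML file path.
#' @return A [sim_config()].
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  geom <- do.call(array_geometry, as.list(y$geometry %||% list()))
  pmf <- do.call(pmf_waveform, as.list(y$pmf %||% list()))
  target <- if (is.null(y$target)) NULL else
    do.call(target_spec, lapply(as.list(y$target), unlist))
  rest <- y[setdiff(names(y), c("geometry", "pmf", "target"))]
  do.call(sim_config, c(list(geometry = geom, pmf = pmf, target = target),
                        rest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
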