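#' @title Autocorrelation and free-energy landscapes
#' @description The raw product autocorrelation function and its
#'   mean-subtracted normalized variant; 2D free-energy maps over reaction
#'   coordinates (RMSD, Rg) by Boltzmann inversion of the sampled
#'   histogram; extraction of the basin around the global minimum at a
#'   free-energy threshold; enumeration of local minima; and overlay of an
#'   independent trajectory on a landscape.
#' @name fel
NULL

#' Autocorrelation function of a time series
#'
#' The `raw` variant is the plain product estimator
#' `C(j) = 1/(N-j) * sum_{i=0}^{N-1-j} f(i) f(i+j)`; the
#' `normalized` variant applies the same estimator to the mean-subtracted
#' series and divides by the lag-0 value, so it decays from 1 toward 0 for
#' a mixing process.
#'
#' @param series Numeric vector (length >= 2).
#' @param max_lag Largest lag (frames), `< length(series)`.
#' @param variant `"raw"` or `"normalized"`.
#' @param frame_interval Time per lag unit, ps.
#' @return Object of class `acf_result`: `lags` (ps), `values`, `variant`.
#' @export
autocorrelation <- function(series, max_lag = length(series) %/% 4L,
                            variant = c("raw", "normalized"),
                            frame_interval = 1) {
  variant <- match.arg(variant)
  n <- length(series)
  stopifnot(n >= 2L)
  if (max_lag >= n) stop("max_lag must be smaller than the series length")
  f <- if (variant == "normalized") series - mean(series) else series
  vals <- vapply(0:max_lag, function(j) {
    sum(f[1:(n - j)] * f[(1 + j):n]) / (n - j)
  }, numeric(1))
  if (variant == "normalized") {
    if (vals[1] <= 0) stop("zero-variance series cannot be normalized")
    vals <- vals / vals[1]
  }
  structure(list(lags = (0:max_lag) * frame_interval, values = vals,
                 variant = variant),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> %s, %d lags (0..%g ps)\n", x$variant,
              length(x$lags), max(x$lags)))
  invisible(x)
}

#' Free-energy landscape over two reaction coordinates
#'
#' Boltzmann inversion of the 2D occupancy histogram:
#' `dG(bin) = -kB T ln(P(bin) / P_max)`, with `kB = 0.0083145` kJ/mol/K, so
#' the most-populated bin sits at 0 and all defined values are
#' non-negative. Empty bins are undefined (NA), not capped.
#'
#' @param x_series,y_series Equal-length coordinate samples (nm).
#' @param temperature Temperature in K (> 0).
#' @param bins Number of bins per axis, or `NULL` to use `bin_width`.
#' @param bin_width Bin width in nm (default 0.02) used when `bins` is
#'   `NULL`; the data range is padded by one bin on each side.
#' @return Object of class `fel_map`: `x_edges`, `y_edges`, `counts`
#'   (matrix), `delta_g` (kJ/mol, NA where empty), `temperature`,
#'   `n_samples`.
#' @export
free_energy_map <- function(x_series, y_series, temperature = 300,
                            bins = NULL, bin_width = 0.02) {
  stopifnot(length(x_series) == length(y_series), length(x_series) >= 1L,
            temperature > 0, all(is.finite(x_series)),
            all(is.finite(y_series)))
  make_edges <- function(v) {
    if (!is.null(bins)) {
      stopifnot(bins >= 2L)
      rng <- range(v)
      if (diff(rng) <= 0) rng <- rng + c(-1, 1) * max(1e-6, abs(rng[1]) * 1e-6)
      seq(rng[1], rng[2], length.out = bins + 1L)
    } else {
      lo <- floor(min(v) / bin_width) * bin_width - bin_width
      hi <- ceiling(max(v) / bin_width) * bin_width + bin_width
      seq(lo, hi, by = bin_width)
    }
  }
  x_edges <- make_edges(x_series)
  y_edges <- make_edges(y_series)
  ix <- findInterval(x_series, x_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(y_series, y_edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  counts <- matrix(0L, length(x_edges) - 1L, length(y_edges) - 1L)
  tab <- table(ix, iy)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)
  p <- counts / sum(counts)
  pmaxv <- max(p)
  dg <- matrix(NA_real_, nrow(counts), ncol(counts))
  nz <- counts > 0L
  dg[nz] <- -KB_KJMOL * temperature * log(p[nz] / pmaxv)
  structure(list(x_edges = x_edges, y_edges = y_edges, counts = counts,
                 delta_g = dg, temperature = temperature,
                 n_samples = length(x_series)),
            class = "fel_map")
}

#' @export
print.fel_map <- function(x, ...) {
  cat(sprintf(
    "<fel_map> %d x %d bins, %d samples at %g K; dG range 0..%.2f kJ/mol\n",
    nrow(x$counts), ncol(x$counts), x$n_samples, x$temperature,
    max(x$delta_g, na.rm = TRUE)))
  invisible(x)
}

# 8-connected component of sub-threshold bins containing the seed bin
connected_component <- function(below, seed) {
  nr <- nrow(below); nc <- ncol(below)
  member <- matrix(FALSE, nr, nc)
  stack <- list(seed)
  member[seed[1], seed[2]] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0L && dj == 0L) next
      i <- cur[1] + di; j <- cur[2] + dj
      if (i >= 1L && i <= nr && j >= 1L && j <= nc &&
          below[i, j] && !member[i, j]) {
        member[i, j] <- TRUE
        stack[[length(stack) + 1L]] <- c(i, j)
      }
    }
  }
  member
}

basin_from_member <- function(fel, member, threshold) {
  idx <- which(member, arr.ind = TRUE)
  structure(list(
    member_bins = idx,
    threshold = threshold,
    min_delta_g = min(fel$delta_g[member], na.rm = TRUE),
    rmsd_range = c(min(fel$x_edges[idx[, 1]]),
                   max(fel$x_edges[idx[, 1] + 1L])),
    rg_range = c(min(fel$y_edges[idx[, 2]]),
                 max(fel$y_edges[idx[, 2] + 1L])),
    occupancy = sum(fel$counts[member]) / sum(fel$counts)),
    class = "fel_basin")
}

#' @export
print.fel_basin <- function(x, ...) {
  cat(sprintf(
    "<fel_basin> dG <= %.2f kJ/mol: %d bins, RMSD %.3f-%.3f nm, Rg %.3f-%.3f nm (occupancy %.2f)\n",
    x$threshold, nrow(x$member_bins), x$rmsd_range[1], x$rmsd_range[2],
    x$rg_range[1], x$rg_range[2], x$occupancy))
  invisible(x)
}

#' Basin around the global free-energy minimum
#'
#' The 8-connected set of bins with `dG <= threshold` containing the
#' most-populated (dG = 0) bin. The reported RMSD/Rg ranges are the outer
#' edges of the member bins.
#'
#' @param fel A `fel_map`.
#' @param threshold Free-energy threshold in kJ/mol (the conventional
#'   choices are 1.5 for the vicinity of the global minimum and 2.5 for
#'   the region around its bottom).
#' @return A `fel_basin`: `member_bins` (index matrix), `threshold`,
#'   `min_delta_g`, `rmsd_range`, `rg_range`, `occupancy`.
#' @export
basin_extract <- function(fel, threshold = 2.5) {
  stopifnot(inherits(fel, "fel_map"), any(!is.na(fel$delta_g)))
  below <- !is.na(fel$delta_g) & fel$delta_g <= threshold
  seed <- which(fel$delta_g == 0, arr.ind = TRUE)[1, , drop = TRUE]
  if (!below[seed[1], seed[2]]) {
    # threshold below 0 never happens (dG >= 0); guard anyway
    return(basin_from_member(fel, {
      m <- matrix(FALSE, nrow(below), ncol(below)); m[seed[1], seed[2]] <- TRUE; m
    }, threshold))
  }
  member <- connected_component(below, seed)
  basin_from_member(fel, member, threshold)
}

#' All sub-threshold local minima of a landscape
#'
#' Maximal 8-connected components of bins with `dG <= threshold`, each
#' reported as a basin with its own minimum, sorted by that minimum.
#'
#' @inheritParams basin_extract
#' @return List of `fel_basin` objects (possibly empty).
#' @export
local_minima <- function(fel, threshold = 1.5) {
  stopifnot(inherits(fel, "fel_map"))
  below <- !is.na(fel$delta_g) & fel$delta_g <= threshold
  basins <- list()
  while (any(below)) {
    seed <- which(below, arr.ind = TRUE)[1, , drop = TRUE]
    member <- connected_component(below, seed)
    basins[[length(basins) + 1L]] <- basin_from_member(fel, member, threshold)
    below[member] <- FALSE
  }
  if (length(basins)) {
    basins <- basins[order(vapply(basins, `[[`, numeric(1), "min_delta_g"))]
  }
  basins
}

#' Overlay an independent trajectory on a landscape
#'
#' Maps samples to the landscape's bins and reports the visitation mask,
#' the number of out-of-range samples, and the fraction of in-range
#' samples falling inside a given basin (or the whole map).
#'
#' @param fel A `fel_map`.
#' @param x_series,y_series Coordinate samples to overlay.
#' @param basin Optional `fel_basin`; occupancy is computed over its bins.
#' @return List: `visited` (logical matrix), `n_out_of_range`,
#'   `occupancy` (fraction of all samples inside the basin/map).
#' @export
overlay_trajectory <- function(fel, x_series, y_series, basin = NULL) {
  stopifnot(inherits(fel, "fel_map"),
            length(x_series) == length(y_series))
  n <- length(x_series)
  inx <- x_series >= fel$x_edges[1] & x_series <= fel$x_edges[length(fel$x_edges)]
  iny <- y_series >= fel$y_edges[1] & y_series <= fel$y_edges[length(fel$y_edges)]
  ok <- inx & iny
  visited <- matrix(FALSE, nrow(fel$counts), ncol(fel$counts))
  occ_bins <- if (is.null(basin)) NULL else basin$member_bins
  inside <- 0L
  if (any(ok)) {
    ix <- findInterval(x_series[ok], fel$x_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    iy <- findInterval(y_series[ok], fel$y_edges, rightmost.closed = TRUE,
                       all.inside = TRUE)
    visited[cbind(ix, iy)] <- TRUE
    if (is.null(occ_bins)) {
      inside <- sum(ok)
    } else {
      bset <- paste(occ_bins[, 1], occ_bins[, 2])
      inside <- sum(paste(ix, iy) %in% bset)
    }
  }
  list(visited = visited, n_out_of_range = sum(!ok),
       occupancy = inside / n)
}

#' Export a landscape as a bin-center table
#'
#' @param fel A `fel_map`.
#' @return Data frame with `rmsd_nm`, `rg_nm`, `count`, `delta_g_kjmol`.
#' @export
fel_table <- function(fel) {
  xc <- (fel$x_edges[-1] + fel$x_edges[-length(fel$x_edges)]) / 2
  yc <- (fel$y_edges[-1] + fel$y_edges[-length(fel$y_edges)]) / 2
  data.frame(
    rmsd_nm = rep(xc, times = length(yc)),
    rg_nm = rep(yc, each = length(xc)),
    count = as.vector(fel$counts),
    delta_g_kjmol = as.vector(fel$delta_g)
  )
}
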