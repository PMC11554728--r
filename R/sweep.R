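## Uniform-sampling parameter sweeps with binned ensemble fractions.

#' Parameter sweep over a coil variable
#'
#' Samples a coil parameter (\code{E_w}, \code{D2} or \code{D3}) uniformly
#' on an interval, runs one deployment per sample, partitions the interval
#' into bins and reports per-bin ensemble volume fractions with
#' normal-approximation confidence bands.  Bins holding fewer than
#' \code{min_per_bin} samples are flagged (the reference protocol asks for
#' at least 30 per bin; scaled-down sweeps run with less and carry the
#' flag).
#'
#' @param variable one of "E_w", "D2", "D3"
#' @param interval length-2 numeric range (Pa for E_w, mm otherwise)
#' @param n_samples number of deployments
#' @param runner function(value, seed) returning either an
#'   \code{occlusion_report}, a named list/vector with elements
#'   \code{psi_BA}, \code{psi_CA}, \code{psi_AA}, \code{psi_SS}, or a
#'   \code{voxel_field} (then \code{domain} must be given)
#' @param n_bins number of subintervals
#' @param min_per_bin required samples per bin before flagging
#' @param seed master seed; sample values and per-run seeds derive from it
#' @param domain optional \code{aneurysm_domain} for voxel-field runners
#' @param conf confidence level of the bands
#' @return object of class \code{sweep_result}: data frame of per-bin
#'   means, standard errors and confidence bounds per fraction
#' @export
parameter_sweep <- function(variable = c("E_w", "D2", "D3"), interval, n_samples,
                            runner, n_bins = 5, min_per_bin = 30, seed = 1L,
                            domain = NULL, conf = 0.95) {
  variable <- match.arg(variable)
  stopifnot(length(interval) == 2, interval[2] > interval[1])
  frac_names <- c("psi_BA", "psi_CA", "psi_AA", "psi_SS")
  if (n_samples == 0) {
    out <- data.frame()
    return(structure(list(bins = out, samples = data.frame(),
                          variable = variable, interval = interval),
                     class = "sweep_result"))
  }
  vals <- with_seed(seed, runif(n_samples, interval[1], interval[2]))
  subseeds <- with_seed(seed + 1L, sample.int(.Machine$integer.max / 2L, n_samples))
  rows <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    r <- runner(vals[i], subseeds[i])
    if (inherits(r, "voxel_field")) {
      if (is.null(domain)) stop("voxel-field runner needs a domain")
      part <- partition_regions(domain, r)
      r <- volume_fractions(r, part)
    }
    rows[[i]] <- unlist(r[frac_names])
  }
  samples <- data.frame(value = vals, do.call(rbind, rows))
  edges <- seq(interval[1], interval[2], length.out = n_bins + 1L)
  bin <- pmin(n_bins, findInterval(vals, edges, rightmost.closed = TRUE))
  z <- qnorm(1 - (1 - conf) / 2)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    n <- sum(sel)
    res <- data.frame(bin = b, center = (edges[b] + edges[b + 1]) / 2,
                      n = n, underfilled = n < min_per_bin)
    for (fn in frac_names) {
      x <- samples[sel, fn]
      m <- if (n) mean(x) else NA_real_
      se <- if (n > 1) sd(x) / sqrt(n) else NA_real_
      res[[paste0(fn, "_mean")]] <- m
      res[[paste0(fn, "_lo")]] <- m - z * se
      res[[paste0(fn, "_hi")]] <- m + z * se
    }
    res
  }))
  if (any(out$underfilled))
    warning(sprintf("%d of %d bins hold fewer than %d samples",
                    sum(out$underfilled), n_bins, min_per_bin))
  structure(list(bins = out, samples = samples, variable = variable,
                 interval = interval),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s over [%g, %g], %d samples, %d bins\n",
              x$variable, x$interval[1], x$interval[2], nrow(x$samples),
              nrow(x$bins)))
  print(x$bins[, c("bin", "center", "n", "psi_AA_mean", "psi_SS_mean")])
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, which = "psi_AA", ...) {
  b <- x$bins
  m <- b[[paste0(which, "_mean")]]
  lo <- b[[paste0(which, "_lo")]]; hi <- b[[paste0(which, "_hi")]]
  plot(b$center, m, type = "b", ylim = range(c(lo, hi, m), na.rm = TRUE),
       xlab = x$variable, ylab = which, ...)
  graphics::arrows(b$center, lo, b$center, hi, angle = 90, code = 3,
                   length = 0.04, col = "grey40")
  invisible(x)
}
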