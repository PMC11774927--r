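#' Normalize and compare spectral curves on a shared grid
#'
#' Interpolates a set of power-like curves (data frames with `f_Hz` and a
#' power column) onto a shared log-frequency grid and normalizes them either
#' to unity at the lowest shared frequency or by a least-squares scalar
#' offset in log-power fitted against the first (reference) curve.  Used for
#' the five-curve overlays of fluctuation, linear, quadratic and
#' modified-admittance spectra.
#'
#' @param curves named list of data frames; the power column is the second
#'   column unless a column named `power`, `S_total` or `abs_Ym2` exists
#' @param normalization `"unity_lowest"` or `"log_offset"`
#' @param n_grid points of the shared log-spaced grid
#' @return A data frame `curve`, `f_Hz`, `power_norm` with attribute
#'   `discrepancy`: per-curve max and mean `|log10|` deviation from the
#'   reference (first) curve.
#' @export
compare_overlay <- function(curves,
                            normalization = c("unity_lowest", "log_offset"),
                            n_grid = 200) {
  normalization <- match.arg(normalization)
  if (is.null(names(curves)) || any(names(curves) == ""))
    stop("curves must be a named list")
  getp <- function(df) {
    for (nm in c("power", "S_total", "abs_Ym2", "psd"))
      if (nm %in% names(df)) return(df[[nm]])
    df[[2]]
  }
  lo <- max(vapply(curves, function(d) min(d$f_Hz[d$f_Hz > 0]), numeric(1)))
  hi <- min(vapply(curves, function(d) max(d$f_Hz), numeric(1)))
  if (!(hi > lo)) stop("curves have disjoint frequency ranges")
  grid <- 10^seq(log10(lo), log10(hi), length.out = n_grid)
  logs <- lapply(curves, function(d) {
    keep <- d$f_Hz > 0 & getp(d) > 0
    approx(log10(d$f_Hz[keep]), log10(getp(d)[keep]), xout = log10(grid),
           rule = 2)$y
  })
  ref <- logs[[1]]
  norm <- lapply(seq_along(logs), function(i) {
    lg <- logs[[i]]
    off <- switch(normalization,
                  unity_lowest = lg[1],
                  log_offset = if (i == 1) lg[1] else
                    mean(lg - ref) + ref[1])
    lg - off
  })
  disc <- t(vapply(seq_along(norm), function(i) {
    d <- norm[[i]] - norm[[1]]
    c(max_abs_dlog10 = max(abs(d)), mean_abs_dlog10 = mean(abs(d)))
  }, numeric(2)))
  rownames(disc) <- names(curves)
  structure(data.frame(
    curve = rep(names(curves), each = n_grid),
    f_Hz = rep(grid, length(curves)),
    power_norm = 10^unlist(norm, use.names = FALSE)),
    discrepancy = disc, normalization = normalization)
}

#' Binned log-power comparison of an empirical and an analytic spectrum
#'
#' Pools the empirical density over logarithmically spaced frequency bins
#' and compares `log10` of the bin means with the analytic spectrum pooled
#' over the same Fourier frequencies.  Frequencies in `exclude_f` (e.g.
#' stimulus fundamentals and their second-order combinations, which carry
#' deterministic response power) are dropped before binning.
#'
#' @param empirical data frame `f_Hz`, `psd` from [empirical_psd()] or
#'   [markov_psd()]
#' @param analytic data frame with `f_Hz` and `S_total` covering the range,
#'   or a function of `f_Hz`
#' @param fmin,fmax comparison range (Hz)
#' @param nbins number of logarithmic bins
#' @param exclude_f frequencies to drop (Hz)
#' @return Data frame per bin: `f_lo`, `f_hi`, `n`, `log10_emp`,
#'   `log10_ana`, `dlog10`; attribute `max_abs_dlog10`.
#' @export
psd_bin_compare <- function(empirical, analytic, fmin = 1, fmax = 1000,
                            nbins = 8, exclude_f = NULL) {
  keep <- empirical$f_Hz >= fmin & empirical$f_Hz <= fmax
  if (!is.null(exclude_f))
    keep <- keep & !(empirical$f_Hz %in% exclude_f)
  f <- empirical$f_Hz[keep]
  emp <- empirical$psd[keep]
  ana <- if (is.function(analytic)) analytic(f)
         else approx(analytic$f_Hz, analytic$S_total, xout = f)$y
  edges <- 10^seq(log10(fmin), log10(fmax), length.out = nbins + 1)
  bin <- cut(f, edges, include.lowest = TRUE)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    data.frame(n = sum(i), log10_emp = log10(mean(emp[i])),
               log10_ana = log10(mean(ana[i])))
  }))
  out <- cbind(f_lo = edges[-length(edges)], f_hi = edges[-1], out)
  out$dlog10 <- out$log10_emp - out$log10_ana
  out <- out[out$n > 0, ]
  structure(out, max_abs_dlog10 = max(abs(out$dlog10)))
}
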