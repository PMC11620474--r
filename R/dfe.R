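#' Parameters of the lineage-detection model
#'
#' The detection kernel converts counts of established, detectable beneficial
#' lineages into a mutation-rate density. Its parameters: the effective
#' population size `Ne` (cells at the serial-transfer bottleneck; 7e7 in the
#' study design, scaled down for desk-scale simulation), the offspring-number
#' variance `c` (~3.5; a new mutation escapes stochastic loss with probability
#' ~ s/c), the effective lineage size `n0` (~1000 cells; the size at which a
#' lineage becomes reliably detectable in barcode sequencing), the experiment
#' duration `T_total` in cycles, and the population mean-fitness trajectory
#' `xbar` (a function of time in cycles, e.g. from
#' [mean_fitness_trajectory()]).
#'
#' @param Ne Effective population size (cells).
#' @param c_var Offspring-number variance.
#' @param n0 Effective (detectable) lineage size in cells.
#' @param T_total Duration in transfer cycles.
#' @param xbar Mean-fitness trajectory: function of time (cycles) returning
#'   per-cycle mean fitness. Default: identically zero.
#' @return A list of class `dfe_params`.
#' @examples
#' dfe_params(Ne = 7e7, T_total = 22)
#' @export
dfe_params <- function(Ne = 7e7, c_var = 3.5, n0 = 1000, T_total = 22,
                       xbar = function(t) rep(0, length(t))) {
  stopifnot(Ne > 0, c_var > 0, n0 > 0, T_total > 0, is.function(xbar))
  structure(list(Ne = Ne, c_var = c_var, n0 = n0, T_total = T_total,
                 xbar = xbar),
            class = "dfe_params")
}

#' Mean-fitness trajectory from support points
#'
#' Piecewise-linear interpolation of per-cycle mean fitness, with constant
#' extrapolation beyond the first/last support point. Accepts the `xbar`
#' track of a simulation truth or a neutral-derived mean-fitness table.
#'
#' @param track Data frame with columns `t` (cycles) and `xbar`, or two
#'   numeric vectors via `t`/`xbar` columns after coercion.
#' @return A function of time (vectorized).
#' @examples
#' f <- mean_fitness_trajectory(data.frame(t = c(0, 10), xbar = c(0, 1)))
#' f(5)
#' @export
mean_fitness_trajectory <- function(track) {
  track <- tibble::as_tibble(track)
  stopifnot(all(c("t", "xbar") %in% names(track)))
  if (nrow(track) == 0L) stop("empty mean-fitness track", call. = FALSE)
  if (nrow(track) == 1L) {
    val <- track$xbar[[1L]]
    return(function(t) rep(val, length(t)))
  }
  stats::approxfun(track$t, track$xbar, rule = 2)
}

#' Detection kernel: expected detected mutants per unit mutation rate
#'
#' The expected number of mutations with selection coefficient in
#' `[s, s + ds]` that arise, establish, and reach detectable size by the end
#' of the experiment is `mu(s) ds * K(s)` with
#'
#' `K(s) = (s / c) * Ne * integral_0^tau(s) exp(-X(t)) dt`
#'
#' where `X(t)` is the cumulative mean fitness `integral_0^t xbar(u) du`
#' (default; the instantaneous variant uses `exp(-xbar(t))` instead) and the
#' origination deadline `tau(s) = min(T, max(0, T - (1/s) log(n0 s / c)))` is
#' the latest cycle at which a lineage established at size ~c/s can still
#' grow, at rate s, to the detectable size n0 by time T. The factor `s/c` is
#' the establishment probability; `Ne exp(-X(t))` is the pool of background
#' cells on which new first-step mutations can arise, shrinking as earlier
#' beneficial mutations take over.
#'
#' @param s Vector of positive selection coefficients (per cycle).
#' @param params A [dfe_params] object.
#' @param integrand `"cumulative"` (default) or `"instantaneous"`; which
#'   mean-fitness discount to use (the study's printed formula is ambiguous,
#'   so both are available).
#' @param rel_tol Relative tolerance of the numerical integration.
#' @return Numeric vector `K(s)`, same length as `s`.
#' @examples
#' p <- dfe_params(Ne = 7e7, T_total = 22)
#' detection_kernel(1, p)  # (1/3.5) * 7e7 * (22 - log(1000/3.5))
#' @export
detection_kernel <- function(s, params,
                             integrand = c("cumulative", "instantaneous"),
                             rel_tol = 1e-8) {
  stopifnot(inherits(params, "dfe_params"))
  integrand <- match.arg(integrand)
  if (any(s <= 0)) stop("selection coefficients must be positive", call. = FALSE)
  T_total <- params$T_total
  # cumulative mean fitness on a dense grid that contains the cycle knots,
  # so the trapezoid accumulation is exact for piecewise-linear tracks
  gx <- sort(unique(c(seq(0, T_total, length.out = 4097),
                      seq_len(floor(T_total)))))
  Xv <- pracma::cumtrapz(gx, params$xbar(gx))[, 1L]
  Xf <- stats::approxfun(gx, Xv, rule = 2)
  f <- switch(integrand,
    cumulative = function(t) exp(-Xf(t)),
    instantaneous = function(t) exp(-params$xbar(t))
  )
  quad <- function(upper) {
    tryCatch(
      stats::integrate(f, 0, upper, rel.tol = rel_tol,
                       subdivisions = 1000L)$value,
      error = function(e) {
        gg <- sort(unique(c(seq(0, upper, length.out = 4097),
                            gx[gx <= upper])))
        pracma::trapz(gg, f(gg))
      }
    )
  }
  purrr::map_dbl(s, function(si) {
    tau <- min(T_total,
               max(0, T_total - log(params$n0 * si / params$c_var) / si))
    if (tau <= 0) return(0)
    (si / params$c_var) * params$Ne * quad(tau)
  })
}

#' Invert detected-mutant counts into a mutation-rate density
#'
#' Bins detected established beneficial lineages by selection coefficient and
#' divides each bin's count by the detection kernel at the bin midpoint times
#' the bin width: `mu_hat(bin) = count / (K(s_mid) * ds)`, the density of
#' beneficial mutations per cell per cycle per unit s. Exact Poisson 95%
#' intervals on the counts propagate to the density.
#'
#' @param detected Numeric vector of selection coefficients of detected
#'   established mutants, or a data frame with column `s_hat`.
#' @param params A [dfe_params] object.
#' @param bins Vector of bin edges (increasing). Default: 25 log-spaced bins
#'   over [0.05, 5] per cycle.
#' @param conf_level Coverage of the Poisson interval (default 0.95).
#' @inheritParams detection_kernel
#' @return An object of class `dfe_grid`: tibble with `s_lo`, `s_hi`,
#'   `s_mid` (geometric midpoint), `count`, `K`, `mu_hat`, `mu_lo`, `mu_hi`,
#'   plus attributes `params` and `total_rate` (integral of `mu_hat` over the
#'   grid, the implied beneficial mutation rate Ub). Has [tidy()], [glance()]
#'   and [ggplot2::autoplot()] methods.
#' @examples
#' p <- dfe_params(Ne = 1e6, T_total = 22)
#' invert_dfe(rep(1, 40), p, bins = c(0.5, 1.5))
#' @export
invert_dfe <- function(detected, params,
                       bins = exp(seq(log(0.05), log(5), length.out = 26)),
                       conf_level = 0.95,
                       integrand = c("cumulative", "instantaneous")) {
  if (is.data.frame(detected)) detected <- detected$s_hat
  stopifnot(is.numeric(bins), length(bins) >= 2L, !is.unsorted(bins, strictly = TRUE))
  integrand <- match.arg(integrand)
  s_lo <- bins[-length(bins)]
  s_hi <- bins[-1L]
  s_mid <- sqrt(s_lo * s_hi)
  count <- as.vector(table(cut(detected, bins, include.lowest = TRUE)))
  K <- detection_kernel(s_mid, params, integrand = integrand)
  if (any(K == 0 & count > 0)) {
    stop("detected mutants fall in bins the kernel says are undetectable",
         call. = FALSE)
  }
  alpha <- 1 - conf_level
  grid <- tibble::tibble(
    s_lo = s_lo, s_hi = s_hi, s_mid = s_mid,
    count = count, K = K,
    mu_hat = ifelse(K > 0, count / (K * (s_hi - s_lo)), NA_real_),
    mu_lo = ifelse(K > 0,
                   stats::qgamma(alpha / 2, shape = count) / (K * (s_hi - s_lo)),
                   NA_real_),
    mu_hi = ifelse(K > 0,
                   stats::qgamma(1 - alpha / 2, shape = count + 1) /
                     (K * (s_hi - s_lo)),
                   NA_real_)
  )
  grid$mu_lo[grid$count == 0 & K > 0] <- 0
  structure(grid,
            class = c("dfe_grid", class(grid)),
            params = params,
            total_rate = sum(grid$mu_hat * (s_hi - s_lo), na.rm = TRUE))
}
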