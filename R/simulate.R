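#' Beneficial mutation-rate density specification
#'
#' Describes the density `mu(s)` of beneficial mutation rates by selection
#' coefficient: a total beneficial rate `Ub` (mutations per cell per cycle)
#' and a shape for the normalized density `mu(s)/Ub` -- a point mass, a
#' uniform interval, or a gamma distribution.
#'
#' @param dist `"point"`, `"uniform"` or `"gamma"`.
#' @param rate Total beneficial mutation rate Ub per cell per cycle.
#' @param s Location of the point mass (per cycle).
#' @param min,max Support of the uniform density.
#' @param shape,scale Gamma parameters.
#' @return A list of class `mu_spec` with elements `rate` and `sample(n)`.
#' @examples
#' mu_spec("point", rate = 1e-5, s = 1)
#' @export
mu_spec <- function(dist = c("point", "uniform", "gamma"), rate = 0,
                    s = 1, min = 0.5, max = 1.5, shape = 2, scale = 0.5) {
  dist <- match.arg(dist)
  stopifnot(rate >= 0)
  sampler <- switch(dist,
    point = {
      if (rate > 0 && s <= 0) {
        stop("point-mass mu(s) must sit at s > 0", call. = FALSE)
      }
      function(n) rep(s, n)
    },
    uniform = {
      if (rate > 0 && (min <= 0 || max <= min)) {
        stop("uniform mu(s) needs 0 < min < max", call. = FALSE)
      }
      function(n) stats::runif(n, min, max)
    },
    gamma = {
      if (rate > 0 && (shape <= 0 || scale <= 0)) {
        stop("gamma mu(s) needs positive shape and scale", call. = FALSE)
      }
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    }
  )
  structure(list(dist = dist, rate = rate, sample = sampler),
            class = "mu_spec")
}

#' Configuration of a barcoded evolution simulation
#'
#' Bundles the study-design parameters of a barcoded serial-transfer
#' evolution experiment: pool composition (a dominating unbarcoded-fitness
#' ancestor, two small neutral reference pools, and an adaptive pool),
#' per-cycle dynamics under composed per-lineage selection coefficients, a
#' beneficial mutation supply with establishment, the transfer bottleneck,
#' and sequencing depth. Defaults are desk-scale: a 1e6-cell bottleneck
#' stands in for the study-scale 5e7, which remains available by argument.
#'
#' @param seed Integer seed; fixing it makes all outputs bitwise reproducible.
#' @param n_neutral Lineages in each of the two neutral pools (default 60).
#' @param n_adaptive Lineages in the adaptive pool.
#' @param composition Named fractions for classes `ancestor`, `neutral`
#'   (split evenly over both pools), `adaptive`; must sum to 1. Defaults to
#'   0.94/0.04/0.02; use 0.91/0.04/0.05 for the 5% pooling design.
#' @param adaptive_profiles Optional tibble (`fer`, `res`, `sta`) of per-hour
#'   phase performances for the adaptive pool, one row per lineage. Default:
#'   drawn uniformly (fer in [0, 0.02], res in [0, 0.03], sta in [-0.01, 0]
#'   per hour, spanning the per-cycle fitness range seen in this system).
#' @param regime The [transfer_regime] the evolution runs under (default 2-Day).
#' @param mu A [mu_spec] for new beneficial mutations (default: rate 0).
#' @param bottleneck_size Cells transferred each cycle (default 1e6).
#' @param read_depth Barcode reads per sequenced timepoint (default 1e6).
#' @param c_var Offspring-number variance; establishment probability of a new
#'   mutation is min(1, s/c) (default 3.5).
#' @param n0 Effective lineage size at which a mutant counts as detectable
#'   (default 1000 cells).
#' @param ancestor_read_retention Fraction of ancestor-barcode reads
#'   surviving restriction-digest depletion in fitness assays (default 0.01);
#'   not applied to evolution-tracking sequencing, which skips the digest.
#' @param umi_duplication_rate Mean number of extra PCR copies per molecule
#'   in read generation (geometric per molecule).
#' @param n_transfers Number of transfer cycles (default 22, the 2-Day
#'   design).
#' @return A list of class `sim_config`.
#' @examples
#' sim_config(seed = 1, mu = mu_spec("point", rate = 1e-5, s = 1))
#' @export
sim_config <- function(seed = 1L, n_neutral = 60L, n_adaptive = 100L,
                       composition = c(ancestor = 0.94, neutral = 0.04,
                                       adaptive = 0.02),
                       adaptive_profiles = NULL,
                       regime = default_regimes("2D")[[1L]],
                       mu = mu_spec("point", rate = 0),
                       bottleneck_size = 1e6, read_depth = 1e6,
                       c_var = 3.5, n0 = 1000,
                       ancestor_read_retention = 0.01,
                       umi_duplication_rate = 0,
                       n_transfers = 22L) {
  stopifnot(
    inherits(regime, "transfer_regime"), inherits(mu, "mu_spec"),
    all(c("ancestor", "neutral", "adaptive") %in% names(composition)),
    all(composition >= 0),
    bottleneck_size > 0, read_depth > 0, c_var > 0, n0 > 0,
    ancestor_read_retention >= 0, ancestor_read_retention <= 1,
    umi_duplication_rate >= 0, n_transfers >= 1
  )
  if (abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must sum to 1", call. = FALSE)
  }
  if (composition[["adaptive"]] > 0 && n_adaptive < 1) {
    stop("adaptive composition > 0 requires n_adaptive >= 1", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_neutral = n_neutral,
         n_adaptive = n_adaptive, composition = composition,
         adaptive_profiles = adaptive_profiles, regime = regime, mu = mu,
         bottleneck_size = bottleneck_size, read_depth = read_depth,
         c_var = c_var, n0 = n0,
         ancestor_read_retention = ancestor_read_retention,
         umi_duplication_rate = umi_duplication_rate,
         n_transfers = as.integer(n_transfers)),
    class = "sim_config"
  )
}

# founder lineage table for a config: barcode, class, pool, phase profile
.sim_lineages <- function(config) {
  prof0 <- function(n) tibble::tibble(fer = rep(0, n), res = 0, sta = 0)
  adaptive <- if (config$n_adaptive > 0) {
    prof <- config$adaptive_profiles
    if (is.null(prof)) {
      prof <- tibble::tibble(
        fer = stats::runif(config$n_adaptive, 0, 0.02),
        res = stats::runif(config$n_adaptive, 0, 0.03),
        sta = stats::runif(config$n_adaptive, -0.01, 0)
      )
    }
    stopifnot(nrow(prof) == config$n_adaptive)
    dplyr::bind_cols(
      tibble::tibble(
        barcode = sprintf("A%04d", seq_len(config$n_adaptive)),
        class = "adaptive", pool = "adaptive"
      ),
      prof
    )
  }
  dplyr::bind_rows(
    dplyr::bind_cols(
      tibble::tibble(barcode = "ANC0000", class = "ancestor", pool = "ancestor"),
      prof0(1L)
    ),
    dplyr::bind_cols(
      tibble::tibble(
        barcode = sprintf("N%04d", seq_len(2L * config$n_neutral)),
        class = "neutral",
        pool = rep(c("neutral1", "neutral2"), each = config$n_neutral)
      ),
      prof0(2L * config$n_neutral)
    ),
    adaptive
  )
}

# initial frequencies: class fractions split evenly within class
.initial_freqs <- function(lineages, composition) {
  comp <- composition[lineages$class]
  f <- as.numeric(comp) / as.numeric(table(lineages$class)[lineages$class])
  f / sum(f)
}

#' Simulate a barcoded serial-transfer evolution experiment
#'
#' Forward simulation of lineage frequency dynamics over transfer cycles.
#' Within a cycle, growth is deterministic: frequencies update as
#' `f_i exp(s_i)` and renormalize (drift within a cycle is negligible at
#' these population sizes). New beneficial mutations arise as a Poisson
#' process at rate `Ub * N` per cycle, land on lineages in proportion to
#' frequency, draw their effect from `mu(s)/Ub`, and establish with
#' probability `min(1, s/c)`; an established mutant starts at its conditional
#' establishment size of `c/s` cells and keeps the barcode of its parent
#' lineage, as in lineage-tracking designs where mutations are seen as
#' lineage-level fitness changes. Each transfer then applies a multinomial
#' bottleneck of `bottleneck_size` cells, and sequencing draws
#' `read_depth` reads multinomially from the post-bottleneck frequencies
#' (evolution tracking skips ancestor-barcode depletion).
#'
#' @param config A [sim_config].
#' @return An object of class `evolution_sim`: list with
#'   \describe{
#'     \item{counts}{tibble `barcode`, `class`, `condition`, `replicate`,
#'       `timepoint`, `count` -- sequencing counts at timepoints 0..T.}
#'     \item{truth}{list with `lineages` (founders with profiles and composed
#'       per-cycle fitness `s`), `events` (one row per new mutation: `cycle`,
#'       `parent_barcode`, `parent_class`, `s` increment, `established`,
#'       `detected` -- established and early enough to reach size `n0` by the
#'       last transfer growing at rate `s`, the detectability rule of the
#'       inference kernel -- and `max_cells`, the realized peak size, which
#'       lags that rule when mean fitness rises steeply), `xbar` (tibble
#'       `t`, `xbar`: realized
#'       frequency-weighted mean fitness at the start of each cycle),
#'       `frequencies` (per-timepoint sub-lineage frequencies with fitness,
#'       from which `xbar` is exactly recomputable), and `config`.}
#'   }
#' @examples
#' sim <- simulate_evolution(sim_config(seed = 1, n_transfers = 3,
#'                                      bottleneck_size = 1e4,
#'                                      read_depth = 1e4))
#' head(sim$counts)
#' @export
simulate_evolution <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  lineages <- .sim_lineages(config)
  lineages <- compose_cycle_fitness(lineages, config$regime)
  N <- config$bottleneck_size
  Ub <- config$mu$rate
  n_founder <- nrow(lineages)

  # sub-lineage state (founders first, mutant sub-lineages appended)
  sl_barcode <- lineages$barcode
  sl_class <- lineages$class
  sl_s <- lineages$s
  sl_event <- rep(NA_integer_, n_founder)
  cells <- as.vector(stats::rmultinom(1L, N,
                                      .initial_freqs(lineages, config$composition)))

  events <- list()
  ev_max_cells <- numeric(0)
  xbar <- numeric(config$n_transfers + 1L)
  counts <- vector("list", config$n_transfers + 1L)
  freqs <- vector("list", config$n_transfers + 1L)

  record <- function(t) {
    f <- cells / sum(cells)
    counts[[t + 1L]] <<- tibble::tibble(
      timepoint = t, barcode = sl_barcode,
      count = as.vector(stats::rmultinom(1L, config$read_depth, f))
    )
    freqs[[t + 1L]] <<- tibble::tibble(
      t = t, sublineage = seq_along(cells), barcode = sl_barcode,
      s = sl_s, freq = f
    )
    xbar[[t + 1L]] <<- sum(f * sl_s)
  }
  record(0L)

  for (t in seq_len(config$n_transfers)) {
    f <- cells / sum(cells)
    w <- f * exp(sl_s)
    f_grown <- w / sum(w)

    if (Ub > 0) {
      n_new <- stats::rpois(1L, Ub * N)
      if (n_new > 0L) {
        parent <- sample.int(length(f), n_new, replace = TRUE, prob = f)
        s_inc <- config$mu$sample(n_new)
        est <- stats::runif(n_new) < pmin(1, s_inc / config$c_var)
        events[[t]] <- tibble::tibble(
          cycle = t, parent_barcode = sl_barcode[parent],
          parent_class = sl_class[parent], s = s_inc, established = est
        )
        if (any(est)) {
          k <- sum(est)
          idx <- length(ev_max_cells) + which(est)  # row ids in event log
          sl_barcode <- c(sl_barcode, sl_barcode[parent[est]])
          sl_class <- c(sl_class, rep("mutant", k))
          sl_s <- c(sl_s, sl_s[parent[est]] + s_inc[est])
          sl_event <- c(sl_event, idx)
          f_new <- (config$c_var / s_inc[est]) / N
          f_grown <- c(f_grown, f_new)
          f_grown <- f_grown / sum(f_grown)
        }
        ev_max_cells <- c(ev_max_cells, numeric(n_new))
      }
    }

    cells <- as.vector(stats::rmultinom(1L, N, f_grown))

    # prune extinct mutant sub-lineages, keep founders for complete tables
    mut <- !is.na(sl_event)
    if (any(mut)) {
      live <- cells[mut]
      ev_max_cells[sl_event[mut]] <- pmax(ev_max_cells[sl_event[mut]], live)
      keep <- !mut | cells > 0
      sl_barcode <- sl_barcode[keep]; sl_class <- sl_class[keep]
      sl_s <- sl_s[keep]; sl_event <- sl_event[keep]; cells <- cells[keep]
    }
    record(t)
  }

  events <- if (length(events) > 0L) dplyr::bind_rows(events) else {
    tibble::tibble(cycle = integer(), parent_barcode = character(),
                   parent_class = character(), s = numeric(),
                   established = logical())
  }
  events$max_cells <- if (nrow(events) > 0L) ev_max_cells else numeric(0)
  # detectability as the inference kernel defines it: the mutation arose
  # early enough for an established lineage (size ~c/s) to reach n0 by the
  # final transfer growing at its own rate s. `max_cells` records the
  # realized peak size instead; under strong clonal interference realized
  # growth (at s - xbar) lags this deadline rule.
  tau <- pmin(config$n_transfers,
              pmax(0, config$n_transfers -
                     log(config$n0 * events$s / config$c_var) / events$s))
  events$detected <- events$established & (events$cycle - 1L) <= tau

  count_tbl <- dplyr::bind_rows(counts) |>
    dplyr::group_by(.data$timepoint, .data$barcode) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::left_join(lineages[c("barcode", "class")], by = "barcode") |>
    dplyr::mutate(condition = config$regime$name, replicate = 1L) |>
    dplyr::select("barcode", "class", "condition", "replicate",
                  "timepoint", "count")

  structure(
    list(
      counts = count_tbl,
      truth = list(
        lineages = lineages,
        events = events,
        xbar = tibble::tibble(t = 0:config$n_transfers, xbar = xbar),
        frequencies = dplyr::bind_rows(freqs),
        config = config
      )
    ),
    class = "evolution_sim"
  )
}

#' @export
print.evolution_sim <- function(x, ...) {
  cfg <- x$truth$config
  cat("<evolution_sim> ", cfg$n_transfers, " transfers of ",
      cfg$regime$name, ", bottleneck ", format(cfg$bottleneck_size,
                                               scientific = TRUE),
      "\n  ", nrow(x$truth$lineages), " founder lineages, ",
      sum(x$truth$events$established), " established mutations (",
      sum(x$truth$events$detected), " detected)\n", sep = "")
  invisible(x)
}

#' Simulate a pooled multi-regime fitness measurement assay
#'
#' Generates barcode count trajectories for a pooled competition assay run in
#' parallel under several transfer regimes. Timepoint-0 frequencies follow
#' the pool composition (ancestor dominating, two neutral pools, adaptive
#' pool); each lineage's per-cycle fitness under a regime is composed from
#' its phase profile by [compose_cycle_fitness()]. Per replicate and cycle,
#' frequencies update deterministically, pass a multinomial transfer
#' bottleneck, and are sequenced multinomially at the given depth, with the
#' ancestor's reads thinned by the restriction-digest retention before depth
#' normalization.
#'
#' @param profiles Tibble of lineages: columns `lineage` (or `barcode`),
#'   `class` (`"ancestor"`, `"neutral"`, `"adaptive"`, ...), `fer`, `res`,
#'   `sta`.
#' @param regimes List of [transfer_regime]s (default all four).
#' @param n_transfers Named (by regime) or scalar number of transfer cycles;
#'   default 6 for 1-/2-Day and 2 for 3-/5-Day, the study design.
#' @param replicates Named or scalar replicate flasks per regime; default 2
#'   for 1-/2-Day and 3 for 3-/5-Day.
#' @param composition Named class fractions at timepoint 0 (must cover every
#'   class present and sum to 1).
#' @param read_depth Reads per sample.
#' @param bottleneck_size Cells per transfer.
#' @param ancestor_read_retention Fraction of ancestor reads surviving the
#'   barcode restriction digest (default 0.01).
#' @param seed Integer seed.
#' @return Object of class `assay_sim`: list with `counts` (tibble `barcode`,
#'   `class`, `condition`, `replicate`, `timepoint`, `count`) and `truth`
#'   (long tibble of composed per-cycle fitness `s` per lineage and
#'   condition, plus the starting cell frequency `f0`).
#' @examples
#' prof <- tibble::tibble(
#'   lineage = c("anc", "n1", "n2", "m1"),
#'   class = c("ancestor", "neutral", "neutral", "adaptive"),
#'   fer = c(0, 0, 0, 0.01), res = c(0, 0, 0, 0.02), sta = 0
#' )
#' sim <- simulate_fitness_assay(prof, read_depth = 1e4,
#'                               bottleneck_size = 1e4, seed = 1)
#' head(sim$counts)
#' @export
simulate_fitness_assay <- function(profiles,
                                   regimes = default_regimes(),
                                   n_transfers = c("1D" = 6, "2D" = 6,
                                                   "3D" = 2, "5D" = 2),
                                   replicates = c("1D" = 2, "2D" = 2,
                                                  "3D" = 3, "5D" = 3),
                                   composition = c(ancestor = 0.94,
                                                   neutral = 0.04,
                                                   adaptive = 0.02),
                                   read_depth = 1e6, bottleneck_size = 1e6,
                                   ancestor_read_retention = 0.01,
                                   seed = NULL) {
  profiles <- tibble::as_tibble(profiles)
  if ("barcode" %in% names(profiles) && !"lineage" %in% names(profiles)) {
    profiles <- dplyr::rename(profiles, lineage = "barcode")
  }
  stopifnot(all(c("lineage", "class", "fer", "res", "sta") %in% names(profiles)))
  if (inherits(regimes, "transfer_regime")) regimes <- list(regimes)
  names(regimes) <- purrr::map_chr(regimes, "name")
  if (read_depth <= 0) stop("read_depth must be positive", call. = FALSE)
  missing_cls <- setdiff(unique(profiles$class), names(composition))
  if (length(missing_cls) > 0L) {
    stop("composition missing class fraction(s): ",
         paste(missing_cls, collapse = ", "), call. = FALSE)
  }
  per_regime <- function(x, name, default) {
    if (length(x) == 1L && is.null(names(x))) return(as.integer(x))
    if (name %in% names(x)) return(as.integer(x[[name]]))
    as.integer(default)
  }
  if (!is.null(seed)) set.seed(seed)

  f0 <- .initial_freqs(profiles, composition)
  anc <- profiles$class == "ancestor"
  truth <- compose_cycle_fitness(profiles, regimes) |>
    dplyr::mutate(f0 = rep(f0, length(regimes))) |>
    dplyr::select("lineage", "class", "condition", "s", "f0")

  sequence_sample <- function(cells) {
    p <- cells / sum(cells)
    p[anc] <- p[anc] * ancestor_read_retention
    p <- p / sum(p)
    as.vector(stats::rmultinom(1L, read_depth, p))
  }

  out <- purrr::map(regimes, function(rg) {
    s <- truth$s[truth$condition == rg$name]
    n_t <- per_regime(n_transfers, rg$name, 2)
    n_r <- per_regime(replicates, rg$name, 2)
    purrr::map_dfr(seq_len(n_r), function(r) {
      cells <- as.vector(stats::rmultinom(1L, bottleneck_size, f0))
      tps <- vector("list", n_t + 1L)
      tps[[1L]] <- tibble::tibble(timepoint = 0L,
                                  barcode = profiles$lineage,
                                  count = sequence_sample(cells))
      for (t in seq_len(n_t)) {
        f <- cells / sum(cells)
        w <- f * exp(s)
        cells <- as.vector(stats::rmultinom(1L, bottleneck_size, w / sum(w)))
        tps[[t + 1L]] <- tibble::tibble(timepoint = t,
                                        barcode = profiles$lineage,
                                        count = sequence_sample(cells))
      }
      dplyr::bind_rows(tps) |>
        dplyr::mutate(condition = rg$name, replicate = r)
    })
  })
  counts <- dplyr::bind_rows(out) |>
    dplyr::left_join(
      dplyr::rename(profiles[c("lineage", "class")], barcode = "lineage"),
      by = "barcode"
    ) |>
    dplyr::select("barcode", "class", "condition", "replicate",
                  "timepoint", "count")
  structure(list(counts = counts, truth = truth), class = "assay_sim")
}
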