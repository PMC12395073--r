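#' Simulation configuration
#'
#' Builds the configuration object controlling cohort composition and all
#' sampling distributions. The defaults reproduce the reference study design:
#' 500 eumenorrheic and 50 PCOS-like subjects, 3 consecutive cycles each,
#' observed on a 28-point daily grid rescaled to each cycle's length.
#'
#' @param n_eumenorrheic number of eumenorrheic (ovulatory) subjects.
#' @param n_pcos number of PCOS-like (anovulatory) subjects.
#' @param cycles_per_subject consecutive cycles simulated per subject.
#' @param grid_points_per_cycle observation days per cycle (default 28).
#' @param master_seed integer seed from which all per-subject random
#'   substreams are derived deterministically.
#' @param overrides named list of parameter overrides, nested as in
#'   [default_params()] (e.g. `list(eum = list(cycle_length = list(sd = 0)))`).
#'   Entries replace the matching default fields; unknown names are an error.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_eumenorrheic = 5, n_pcos = 2, cycles_per_subject = 1)
#' cfg$params$eum$cycle_length
#' @export
sim_config <- function(n_eumenorrheic = 500, n_pcos = 50,
                       cycles_per_subject = 3, grid_points_per_cycle = 28,
                       master_seed = 20260101L, overrides = NULL) {
  counts <- c(n_eumenorrheic = n_eumenorrheic, n_pcos = n_pcos,
              cycles_per_subject = cycles_per_subject,
              grid_points_per_cycle = grid_points_per_cycle)
  # n_pcos = 0 (single-arm runs) is allowed; everything else must be positive
  if (n_eumenorrheic < 0 || n_pcos < 0)
    stop("subject counts must be non-negative")
  if (n_eumenorrheic + n_pcos < 1)
    stop("cohort must contain at least one subject")
  if (cycles_per_subject < 1 || grid_points_per_cycle < 2)
    stop("cycles_per_subject must be >= 1 and grid_points_per_cycle >= 2")
  params <- default_params()
  if (!is.null(overrides)) params <- apply_overrides(params, overrides)
  structure(list(
    n_eumenorrheic = as.integer(n_eumenorrheic),
    n_pcos = as.integer(n_pcos),
    cycles_per_subject = as.integer(cycles_per_subject),
    grid_points_per_cycle = as.integer(grid_points_per_cycle),
    master_seed = as.integer(master_seed),
    params = params
  ), class = "sim_config")
}

#' Default sampling distributions and fixed model constants
#'
#' Between-subject level parameters are truncated normal (rejection-sampled
#' inside their physiological range); width/timing parameters given in the
#' literature only as ranges are uniform over the range. `tn(mean, sd, lo, hi)`
#' and `un(lo, hi)` specs are interpreted by [draw_param()].
#'
#' @return nested list with components `eum`, `pcos`, `cycle`, `noise`,
#'   `caps` and `fsh` (feedback constants).
#' @export
default_params <- function() {
  tn <- function(mean, sd, lo = -Inf, hi = Inf)
    list(dist = "truncnorm", mean = mean, sd = sd, lo = lo, hi = hi)
  un <- function(lo, hi) list(dist = "uniform", lo = lo, hi = hi)
  list(
    eum = list(
      cycle_length = tn(28, 2, 24, 35),
      age          = un(20, 45),
      bmi          = tn(24, 2.5, 16, 40),
      e2_baseline  = tn(20, 5, 10, 30),       # pg/mL
      e2_peak1     = tn(268, 28, 150, 400),   # pre-ovulatory peak, pg/mL
      e2_peak2     = tn(125, 12, 100, 150),   # luteal peak, pg/mL
      lh_baseline  = tn(7, 2, 2, 12),         # mIU/mL
      lh_peak      = tn(53, 6.4, 35, 80),     # mIU/mL
      fsh_baseline = tn(7.8, 1.1, 5, 10),     # mIU/mL
      amh          = tn(2.9, 0.4, 1, 4),      # ng/mL, trait
      t_baseline   = tn(0.4, 0.04, 0.2, 0.6), # ng/mL
      gnrh_baseline = tn(1.0, 0.05, 0.8, 1.2),# AU
      sigma1       = un(0.9, 1.3),            # pre-ovulatory E2 width, d
      sigma2       = un(1.5, 2.5),            # luteal E2 width, d
      sigma_lh     = un(0.6, 0.9),            # LH surge width, d
      sigma_gnrh   = un(0.8, 1.2),            # GnRH bump width, d
      alpha_early  = un(1.0, 2.0),            # early FSH bump, mIU/mL
      alpha_periov = un(0.8, 1.6),            # peri-ovulatory FSH bump
      t_amplitude  = un(0.02, 0.06),          # testosterone sinusoid, ng/mL
      t_phase      = un(0, 2 * pi),
      gnrh_periov_frac = 0.22                 # A_periov = frac * GnRH0
    ),
    pcos = list(
      cycle_length = tn(35, 6, 28, 60),
      age          = un(20, 45),
      bmi          = tn(28, 3.2, 16, 45),
      e1_level     = tn(115, 12, 80, 150),    # pg/mL
      e2_level     = tn(33, 9, 10, 60),       # pg/mL, no surge
      lh_level     = tn(18, 3.4, 12, 25),     # mIU/mL, constrained < 30
      fsh_level    = tn(5.2, 0.5, 4, 8),      # mIU/mL
      gnrh_level   = tn(1.37, 0.06, 1.3, 1.6),# AU
      amh_alpha    = tn(5.7, 0.58),           # ng/mL before BMI effect
      amh_range    = c(4, 8),
      beta_bmi     = -0.055,                  # ng/mL per BMI unit above 25
      t_baseline   = tn(1.25, 0.12, 0.8, 2.0),
      t_amplitude  = un(0.02, 0.06),
      t_phase      = un(0, 2 * pi)
    ),
    cycle = list(
      surge_jitter_sd = 0.5,                  # d, around mid-cycle L/2
      delta = un(1.5, 2.0),                   # E2 peak -> LH surge lag (36-48 h)
      delta_luteal = un(5.5, 7.5)             # pre-ovulatory -> luteal E2 peak
    ),
    fsh = list(
      t_early = 2,                            # early bump center, cycle-time d
      sigma_early = 1.5, sigma_periov = 0.8,  # bump widths, d
      theta_e2 = 100,                         # suppression onset, pg/mL
      beta_e2 = 0.01                          # mIU/mL per pg/mL above theta
    ),
    noise = list(
      e2 = list(base = 8, kappa = 1.5),
      lh = list(base = 1.5, kappa = 2.0),
      fsh = list(base = 0.6),
      e1 = list(base = 10),                   # PCOS level
      e1_eum = list(base = 4),                # low EUM estrone track
      t = list(base = 0.03),
      gnrh = list(base = 0.04),
      amh = list(base = 0),                   # trait-like, no daily noise
      amp_width = 1.2                         # d, E2/LH variance amplification
    ),
    caps = list(                              # observation clipping bounds
      e2 = c(0, 600), e1 = c(0, 300), lh = c(0, 100), fsh = c(0, 30),
      amh = c(0, 12), t = c(0, 3), gnrh = c(0, 3)
    ),
    phase = list(periov_halfwidth = 1,        # d around the LH surge
                 surge_lh_min = 30,           # mIU/mL
                 surge_window = 0.5)          # d
  )
}

apply_overrides <- function(params, overrides) {
  stopifnot(is.list(overrides))
  for (grp in names(overrides)) {
    if (!grp %in% names(params))
      stop("unknown parameter group in overrides: ", grp)
    ov <- overrides[[grp]]
    if (!is.list(ov)) { params[[grp]] <- ov; next }
    for (nm in names(ov)) {
      if (!nm %in% names(params[[grp]]))
        stop("unknown parameter '", nm, "' in group '", grp, "'")
      cur <- params[[grp]][[nm]]
      if (is.list(cur) && is.list(ov[[nm]])) {
        params[[grp]][[nm]] <- utils::modifyList(cur, ov[[nm]])
      } else {
        params[[grp]][[nm]] <- ov[[nm]]
      }
    }
  }
  params
}

#' Read a simulation configuration from a YAML or JSON file
#'
#' The file may set any of the `sim_config()` arguments; a nested `overrides`
#' block adjusts individual distribution parameters.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return A `sim_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext))
  args <- raw[intersect(names(raw), c("n_eumenorrheic", "n_pcos",
    "cycles_per_subject", "grid_points_per_cycle", "master_seed"))]
  args$overrides <- raw$overrides
  do.call(sim_config, args)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  subjects: %d eumenorrheic + %d PCOS-like\n",
              x$n_eumenorrheic, x$n_pcos))
  cat(sprintf("  cycles per subject: %d  (grid: %d days/cycle)\n",
              x$cycles_per_subject, x$grid_points_per_cycle))
  cat(sprintf("  master seed: %d\n", x$master_seed))
  invisible(x)
}

# ---- random-number plumbing -------------------------------------------------

#' Derive a deterministic substream seed
#'
#' Mixes a master seed with an index and a salt so every subject (and every
#' per-subject noise stream) gets its own reproducible stream, independent of
#' cohort order. Plain 31-bit LCG mixing; all arithmetic stays exact in
#' doubles.
#'
#' @param master integer master seed.
#' @param index subject index (1-based).
#' @param salt stream discriminator (1 = parameters, 2 = observation noise).
#' @return integer in \[1, 2^31 - 1\].
#' @export
mix_seed <- function(master, index, salt = 1L) {
  m <- 2^31
  s <- abs(as.numeric(master)) %% m
  s <- (s * 69069 + as.numeric(index) * 7919 + 1) %% m
  s <- (s * 69069 + as.numeric(salt) * 104729 + 1) %% m
  s <- as.integer(s)
  if (s <= 0L) 1L else s
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw from a distribution spec
#'
#' Truncated-normal draws use rejection resampling (never clipping), so no
#' probability mass piles up at the bounds. A zero-sd normal is degenerate and
#' returns its mean (after a bounds check).
#'
#' @param spec list with `dist = "truncnorm"` (`mean`, `sd`, `lo`, `hi`) or
#'   `dist = "uniform"` (`lo`, `hi`), or a bare numeric constant.
#' @param n number of draws.
#' @param max_iter rejection cap per draw before erroring (distribution
#'   incompatible with its bounds).
#' @return numeric vector of length `n`.
#' @export
draw_param <- function(spec, n = 1, max_iter = 1000) {
  if (is.numeric(spec)) return(rep(spec, length.out = n))
  stopifnot(is.list(spec), !is.null(spec$dist))
  if (spec$dist == "uniform") return(stats::runif(n, spec$lo, spec$hi))
  if (spec$dist != "truncnorm") stop("unknown distribution: ", spec$dist)
  lo <- if (is.null(spec$lo)) -Inf else spec$lo
  hi <- if (is.null(spec$hi)) Inf else spec$hi
  if (lo > hi) stop("invalid truncation range [", lo, ", ", hi, "]")
  if (spec$sd == 0) {
    if (spec$mean < lo || spec$mean > hi)
      stop("degenerate distribution mean outside truncation range")
    return(rep(spec$mean, n))
  }
  out <- numeric(n)
  need <- seq_len(n)
  for (it in seq_len(max_iter)) {
    out[need] <- stats::rnorm(length(need), spec$mean, spec$sd)
    need <- need[out[need] < lo | out[need] > hi]
    if (!length(need)) return(out)
  }
  stop("rejection sampling failed after ", max_iter,
       " iterations; distribution incompatible with bounds [", lo, ", ", hi, "]")
}
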