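#' Configuration for the synthetic screen generator
#'
#' Builds and validates the parameter set for simulating an arrayed CRISPR-KO
#' electropermeabilization screen read out by per-cell Yo-Pro-1 (YP) uptake.
#' Knockout (KO) variants are plated together with non-targeting ("SCR")
#' controls; every variant is measured as a matched exposed/sham cuvette pair
#' in every independent experiment.
#'
#' Per-cell sham fluorescence follows a log-normal law (non-negative,
#' right-skewed, unimodal) with mean \code{sham_mean} and coefficient of
#' variation \code{sham_cv}. Electroporation adds a per-cell uptake increment
#' whose population mean grows linearly with the pulse number at
#' \code{slope_per_pulse} per pulse. A KO's multiplicative effect applies only
#' to the edited fraction of its cells (mosaicism); unedited cells respond as
#' SCR. Above \code{linear_limit} pulses a fraction \code{divergence_fraction}
#' of cells is reassigned to a broad high-variance component (a proxy for cell
#' swelling and membrane rupture) so the uptake histogram peak degrades.
#' Rare saturating dead-cell outliers are injected at \code{outlier_rate}
#' in both conditions.
#'
#' @param n_variants number of KO variants to simulate.
#' @param n_scr_per_plate number of SCR control variants added to each plate
#'   (typically 2--4).
#' @param plate_size number of KO variants processed together on one plate
#'   (typically 15--20).
#' @param n_experiments number of independent experiments (typically 3--8).
#' @param pulses number of 300-ns pulses delivered to exposed samples.
#' @param cells_per_sample cells identified per sample (typically 400--2000).
#' @param sham_mean mean per-cell YP fluorescence of sham samples (a.u.).
#' @param sham_cv coefficient of variation of sham per-cell fluorescence.
#' @param slope_per_pulse mean per-cell uptake increment per pulse (a.u.).
#' @param uptake_cv coefficient of variation of the per-cell uptake increment.
#' @param sample_cv day-to-day (per-sample) multiplicative variability of the
#'   mean uptake increment; models biological run-to-run scatter.
#' @param linear_limit pulse count above which dose-response divergence begins.
#' @param divergence_fraction fraction of cells reassigned to the broad
#'   component when \code{pulses > linear_limit}.
#' @param divergence_scatter multiplier applied to the broad component's mean
#'   and CV.
#' @param effect_map named numeric vector, variant id -> multiplicative effect
#'   on the uptake increment (1.0 = null). If \code{NULL}, all effects are 1.
#'   SCR variants always have effect 1.
#' @param editing_fraction named numeric vector, variant id -> fraction of
#'   cells carrying the functional KO, in [0, 1]; defaults to 1 for all KOs.
#' @param plate_scale_sd SD (log scale) of the per-experiment, per-plate
#'   multiplicative fluorescence scale factor.
#' @param outlier_rate per-cell probability of a high-fluorescence outlier.
#' @param outlier_mean mean fluorescence of outlier cells (a.u.).
#' @param seed integer master seed; expanded into per-sample substreams.
#'
#' @return An object of class \code{"screen_config"} (a validated list).
#' @export
screen_config <- function(n_variants = 18,
                          n_scr_per_plate = 3,
                          plate_size = 18,
                          n_experiments = 3,
                          pulses = 20,
                          cells_per_sample = 800,
                          sham_mean = 30,
                          sham_cv = 0.5,
                          slope_per_pulse = 6,
                          uptake_cv = 0.4,
                          sample_cv = 0.15,
                          linear_limit = 50,
                          divergence_fraction = 0.3,
                          divergence_scatter = 3,
                          effect_map = NULL,
                          editing_fraction = NULL,
                          plate_scale_sd = 0.15,
                          outlier_rate = 0.005,
                          outlier_mean = 2000,
                          seed = 1L) {
  ko_ids <- sprintf("KO%03d", seq_len(n_variants))
  if (is.null(effect_map)) {
    effect_map <- stats::setNames(rep(1, n_variants), ko_ids)
  }
  if (is.null(names(effect_map)) && length(effect_map) == n_variants) {
    names(effect_map) <- ko_ids
  }
  if (is.null(editing_fraction)) {
    editing_fraction <- stats::setNames(rep(1, length(effect_map)),
                                        names(effect_map))
  }
  cfg <- list(
    n_variants = as.integer(n_variants),
    n_scr_per_plate = as.integer(n_scr_per_plate),
    plate_size = as.integer(plate_size),
    n_experiments = as.integer(n_experiments),
    pulses = pulses,
    cells_per_sample = as.integer(cells_per_sample),
    sham_mean = sham_mean, sham_cv = sham_cv,
    slope_per_pulse = slope_per_pulse,
    uptake_cv = uptake_cv, sample_cv = sample_cv,
    linear_limit = linear_limit,
    divergence_fraction = divergence_fraction,
    divergence_scatter = divergence_scatter,
    effect_map = effect_map,
    editing_fraction = editing_fraction,
    plate_scale_sd = plate_scale_sd,
    outlier_rate = outlier_rate, outlier_mean = outlier_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "screen_config"
  validate_screen_config(cfg)
  cfg
}

validate_screen_config <- function(cfg) {
  stopifnot(
    cfg$n_variants >= 1, cfg$n_scr_per_plate >= 1, cfg$plate_size >= 1,
    cfg$n_experiments >= 1, cfg$cells_per_sample >= 1,
    cfg$pulses >= 0,
    cfg$sham_mean > 0, cfg$sham_cv >= 0,
    cfg$slope_per_pulse >= 0, cfg$uptake_cv >= 0, cfg$sample_cv >= 0,
    cfg$divergence_scatter >= 0, cfg$plate_scale_sd >= 0,
    cfg$outlier_mean >= 0
  )
  if (cfg$divergence_fraction < 0 || cfg$divergence_fraction > 1)
    stop("divergence_fraction must be in [0, 1]")
  if (cfg$outlier_rate < 0 || cfg$outlier_rate > 1)
    stop("outlier_rate must be in [0, 1]")
  if (length(cfg$effect_map) != cfg$n_variants)
    stop("effect_map must assign one effect per KO variant")
  if (any(cfg$editing_fraction < 0 | cfg$editing_fraction > 1))
    stop("editing fractions must be in [0, 1]")
  if (!setequal(names(cfg$effect_map), names(cfg$editing_fraction)))
    stop("effect_map and editing_fraction must cover the same variants")
  invisible(cfg)
}

# log-normal parameterized by arithmetic mean and CV
lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log1p(cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

rlnorm_mean_cv <- function(n, mean, cv) {
  if (n == 0) return(numeric(0))
  if (mean <= 0) return(rep(0, n))
  if (cv == 0) return(rep(mean, n))
  p <- lnorm_pars(mean, cv)
  stats::rlnorm(n, p$meanlog, p$sdlog)
}

# Deterministic per-sample substream seed: mixes the master seed with a
# small hash of the sample key so each sample is independently reproducible.
sample_seed <- function(seed, key) {
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 131 + cc) %% 1977326743 # 7^11
  as.integer((seed + h) %% .Machine$integer.max)
}

#' Expected sham-corrected uptake for a variant (closed form)
#'
#' Population mean of the per-cell uptake increment for an exposed sample of
#' the given variant, before plate scaling: the generator's ground-truth
#' expectation of ΔF at plate scale 1.
#'
#' @param cfg a \code{screen_config}.
#' @param variant variant id ("SCR" for controls).
#' @return expected ΔF in fluorescence a.u.
#' @export
expected_delta_f <- function(cfg, variant) {
  eff <- if (variant %in% names(cfg$effect_map)) cfg$effect_map[[variant]] else 1
  ef <- if (variant %in% names(cfg$editing_fraction))
    cfg$editing_fraction[[variant]] else 1
  base <- cfg$slope_per_pulse * cfg$pulses
  div <- if (cfg$pulses > cfg$linear_limit)
    (1 - cfg$divergence_fraction) + cfg$divergence_fraction * cfg$divergence_scatter
  else 1
  base * div * (ef * eff + (1 - ef))
}

#' Simulate per-cell fluorescence for one sample
#'
#' Draws one cuvette/well worth of cells for a variant under the exposed or
#' sham condition. See \code{\link{screen_config}} for the generating model.
#'
#' @param cfg a \code{screen_config}.
#' @param variant variant id; must be in \code{cfg$effect_map} or an SCR id
#'   (any id starting with "SCR" gets effect 1).
#' @param condition \code{"exposed"} or \code{"sham"}.
#' @param experiment experiment id (integer or string).
#' @param plate plate id.
#' @param plate_scale multiplicative fluorescence scale for this
#'   plate/experiment (default 1).
#' @return data.frame with columns \code{experiment, plate, variant,
#'   condition, cell_id, hoechst, yp}.
#' @export
simulate_cell_sample <- function(cfg, variant, condition = c("exposed", "sham"),
                                 experiment = 1L, plate = 1L,
                                 plate_scale = 1) {
  condition <- match.arg(condition)
  if (cfg$pulses < 0) stop("pulse count must be non-negative")
  is_scr <- grepl("^SCR", variant)
  if (!is_scr && !variant %in% names(cfg$effect_map))
    stop("unknown variant id: ", variant)
  key <- paste(experiment, plate, variant, condition, sep = "|")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sample_seed(cfg$seed, key))

  n <- cfg$cells_per_sample
  yp <- rlnorm_mean_cv(n, cfg$sham_mean, cfg$sham_cv)

  if (condition == "exposed" && cfg$pulses > 0) {
    eff <- if (is_scr) 1 else cfg$effect_map[[variant]]
    ef <- if (is_scr) 1 else cfg$editing_fraction[[variant]]
    edited <- stats::runif(n) < ef
    mu <- cfg$slope_per_pulse * cfg$pulses
    # day-to-day biological variability of the mean response, shared by all
    # cells in the sample
    samp_fac <- rlnorm_mean_cv(1, 1, cfg$sample_cv)
    inc_mean <- mu * samp_fac * ifelse(edited, eff, 1)
    if (cfg$pulses > cfg$linear_limit && cfg$divergence_fraction > 0) {
      wide <- stats::runif(n) < cfg$divergence_fraction
      inc <- numeric(n)
      inc[!wide] <- rlnorm_mean_cv(sum(!wide), 1, cfg$uptake_cv) *
        inc_mean[!wide]
      inc[wide] <- rlnorm_mean_cv(sum(wide), 1,
                                  cfg$uptake_cv * cfg$divergence_scatter) *
        inc_mean[wide] * cfg$divergence_scatter
    } else {
      inc <- rlnorm_mean_cv(n, 1, cfg$uptake_cv) * inc_mean
    }
    yp <- yp + inc
  }

  if (cfg$outlier_rate > 0) {
    out <- stats::runif(n) < cfg$outlier_rate
    yp[out] <- rlnorm_mean_cv(sum(out), cfg$outlier_mean, 0.2)
  }
  yp <- yp * plate_scale
  hoechst <- rlnorm_mean_cv(n, 100, 0.25) * plate_scale

  data.frame(
    experiment = as.character(experiment), plate = as.character(plate),
    variant = variant, condition = condition,
    cell_id = seq_len(n), hoechst = hoechst, yp = yp,
    stringsAsFactors = FALSE
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a full arrayed screen with known ground truth
#'
#' Partitions KO variants into plates of \code{plate_size}, adds
#' \code{n_scr_per_plate} SCR controls to each plate, and simulates every
#' variant as an exposed + sham pair in every experiment. Per-experiment,
#' per-plate multiplicative scale factors (log-normal, log-SD
#' \code{plate_scale_sd}) model between-plate variability and are recorded in
#' the ground truth. Fully reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{screen_config}.
#' @return list of class \code{"ep_screen"} with elements \code{cells} (long
#'   per-cell table), \code{truth} (list: \code{variants} data.frame with true
#'   effect and editing fraction; \code{plate_scales} data.frame), and
#'   \code{scr_ids}.
#' @export
simulate_screen <- function(cfg) {
  validate_screen_config(cfg)
  ko_ids <- names(cfg$effect_map)
  n_plates <- ceiling(cfg$n_variants / cfg$plate_size)
  plate_of <- rep(seq_len(n_plates), each = cfg$plate_size)[seq_len(cfg$n_variants)]
  scr_ids <- sprintf("SCR%02d", seq_len(cfg$n_scr_per_plate))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(sample_seed(cfg$seed, "plate-scales"))
  scales <- expand.grid(experiment = seq_len(cfg$n_experiments),
                        plate = seq_len(n_plates), KEEP.OUT.ATTRS = FALSE)
  scales$scale <- exp(stats::rnorm(nrow(scales), 0, cfg$plate_scale_sd))

  out <- vector("list", 2L * cfg$n_experiments * (cfg$n_variants +
                                                  n_plates * cfg$n_scr_per_plate))
  i <- 0L
  for (exp_i in seq_len(cfg$n_experiments)) {
    for (pl in seq_len(n_plates)) {
      sc <- scales$scale[scales$experiment == exp_i & scales$plate == pl]
      ids <- c(ko_ids[plate_of == pl], scr_ids)
      for (v in ids) {
        for (cond in c("exposed", "sham")) {
          i <- i + 1L
          out[[i]] <- simulate_cell_sample(cfg, v, cond, exp_i, pl, sc)
        }
      }
    }
  }
  cells <- do.call(rbind, out[seq_len(i)])

  truth <- list(
    variants = data.frame(
      variant = ko_ids,
      plate = as.character(plate_of),
      effect = unname(cfg$effect_map[ko_ids]),
      editing_fraction = unname(cfg$editing_fraction[ko_ids]),
      stringsAsFactors = FALSE
    ),
    plate_scales = data.frame(
      experiment = as.character(scales$experiment),
      plate = as.character(scales$plate),
      scale = scales$scale, stringsAsFactors = FALSE
    )
  )
  structure(list(cells = cells, truth = truth, scr_ids = scr_ids,
                 config = cfg),
            class = "ep_screen")
}

#' Simulate a replication series with attenuated editing
#'
#' Re-generates a screen after multiplying every KO's editing fraction by
#' \code{1 - attenuation}, modeling the fade of knockout effects as unedited
#' cells outgrow edited ones between independently generated KO series.
#' A fresh seed is derived from the configuration seed so replication series
#' are statistically independent of the original screen.
#'
#' @param cfg a \code{screen_config}.
#' @param attenuation fraction in [0, 1]; 0 reproduces the original screen's
#'   distribution, 1 makes all KOs behave as SCR.
#' @param series integer tag used to derive the fresh seed.
#' @return an \code{"ep_screen"}, as \code{\link{simulate_screen}}.
#' @export
simulate_replication <- function(cfg, attenuation = 0, series = 2L) {
  if (attenuation < 0 || attenuation > 1)
    stop("attenuation must be in [0, 1]")
  cfg$editing_fraction <- cfg$editing_fraction * (1 - attenuation)
  cfg$seed <- sample_seed(cfg$seed, paste0("replication-series-", series))
  simulate_screen(cfg)
}
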