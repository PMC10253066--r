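#' Summarize per-cell fluorescence of one sample
#'
#' @param yp numeric vector of per-cell YP fluorescence (a.u.).
#' @param metric \code{"mean"} or \code{"median"}. The median is robust to the
#'   small number of highly fluorescent (e.g. dead) cells present in samples.
#' @return a single summary value in fluorescence a.u.
#' @export
summarize_sample <- function(yp, metric = c("mean", "median")) {
  metric <- match.arg(metric)
  if (length(yp) < 1) stop("sample has no cells")
  if (metric == "mean") mean(yp) else stats::median(yp)
}

#' Sham-corrected uptake (ΔF) per variant, experiment and metric
#'
#' For every (variant, experiment) pair, subtracts the summary of the matched
#' sham-exposed sample from the exposed sample, yielding the fluorescence
#' change attributable to electroporation alone. Both the mean and the median
#' summary are computed from the same cell sets.
#'
#' @param cells long per-cell table with columns \code{experiment, plate,
#'   variant, condition, yp} (as written by \code{\link{simulate_screen}}).
#' @param metric \code{"mean"}, \code{"median"} or \code{"both"}.
#' @return data.frame with columns \code{variant, experiment, plate, metric,
#'   value} (ΔF in a.u.; may be negative).
#' @export
compute_delta_f <- function(cells, metric = c("both", "mean", "median")) {
  metric <- match.arg(metric)
  metrics <- if (metric == "both") c("mean", "median") else metric
  need <- c("experiment", "plate", "variant", "condition", "yp")
  if (!all(need %in% names(cells)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  key <- interaction(cells$variant, cells$experiment, cells$plate, drop = TRUE)
  rows <- lapply(split(cells, key), function(d) {
    expv <- d$yp[d$condition == "exposed"]
    shamv <- d$yp[d$condition == "sham"]
    if (length(expv) == 0 || length(shamv) == 0)
      stop("unpaired sample for variant ", d$variant[1],
           " in experiment ", d$experiment[1])
    data.frame(
      variant = d$variant[1], experiment = d$experiment[1],
      plate = d$plate[1], metric = metrics,
      value = vapply(metrics, function(m)
        summarize_sample(expv, m) - summarize_sample(shamv, m), numeric(1)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize ΔF to the plate's SCR mean (percent of control)
#'
#' Within each (experiment, plate, metric) group, expresses every ΔF as a
#' percentage of the mean ΔF of that group's SCR samples, which is taken as
#' 100\%. Normalization removes plate-to-plate scale differences. A group
#' whose SCR mean ΔF is zero or negative cannot be normalized; it is dropped
#' with a warning and reported in the \code{"failed_plates"} attribute.
#'
#' @param deltas data.frame from \code{\link{compute_delta_f}}.
#' @param scr_ids character vector of SCR (control) variant ids.
#' @return the input with a \code{normalized} column (percent); failed
#'   plate/experiment groups removed.
#' @export
normalize_plate <- function(deltas, scr_ids) {
  grp <- interaction(deltas$experiment, deltas$plate, deltas$metric,
                     drop = TRUE)
  failed <- character(0)
  parts <- lapply(split(deltas, grp), function(d) {
    scr <- d$value[d$variant %in% scr_ids]
    if (length(scr) == 0)
      stop("no SCR sample on plate ", d$plate[1],
           " in experiment ", d$experiment[1])
    m <- mean(scr)
    if (m <= 0) {
      failed <<- c(failed, paste0("experiment ", d$experiment[1], ", plate ",
                                  d$plate[1], ", metric ", d$metric[1]))
      return(NULL)
    }
    d$normalized <- 100 * d$value / m
    d
  })
  if (length(failed))
    warning("normalization undefined (SCR mean ΔF <= 0); dropped: ",
            paste(failed, collapse = "; "))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "failed_plates") <- failed
  out
}

#' Pool normalized ΔF across experiments for each variant
#'
#' For every (variant, metric), computes the mean of the per-experiment
#' normalized ΔF values and the squared standard error of that mean
#' (sample variance across experiments divided by the number of experiments).
#' These are the per-group mean and variance entering the SSMD.
#'
#' @param norm data.frame from \code{\link{normalize_plate}}.
#' @return data.frame with columns \code{variant, metric, dfbar} (mean
#'   normalized ΔF, \%), \code{s2} (squared SE of the mean, \%^2),
#'   \code{n} (number of experiments).
#' @export
pool_variants <- function(norm) {
  key <- interaction(norm$variant, norm$metric, drop = TRUE)
  rows <- lapply(split(norm, key), function(d) {
    n <- nrow(d)
    data.frame(
      variant = d$variant[1], metric = d$metric[1],
      dfbar = mean(d$normalized),
      s2 = if (n >= 2) stats::var(d$normalized) / n else NA_real_,
      n = n, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$metric, out$variant), ]
}

#' Pool all SCR samples into a single control group
#'
#' Collects the experiment-level normalized ΔF values of every SCR sample into
#' one control group per metric, and summarizes them like a variant
#' (mean, squared SE, n). By construction of the per-plate normalization the
#' control mean is exactly 100\% when each plate carries the full SCR set.
#'
#' @param norm data.frame from \code{\link{normalize_plate}}.
#' @param scr_ids character vector of SCR variant ids.
#' @return list with one element per metric, each a list with \code{values}
#'   (the individual normalized control values), \code{dfbar}, \code{s2} and
#'   \code{n}.
#' @export
pool_scr <- function(norm, scr_ids) {
  scr <- norm[norm$variant %in% scr_ids, ]
  if (nrow(scr) == 0) stop("no SCR rows found")
  lapply(split(scr, scr$metric), function(d) {
    list(values = d$normalized, dfbar = mean(d$normalized),
         s2 = stats::var(d$normalized) / nrow(d), n = nrow(d))
  })
}
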