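#' Strictly standardized mean difference (SSMD)
#'
#' SSMD for screens with unpaired replicates and unequal variance:
#' \deqn{SSMD = (\bar{\Delta F}_{KO} - \bar{\Delta F}_{SCR}) /
#'   \sqrt{S^2_{KO} + S^2_{SCR}}}
#' where each mean is the pooled normalized ΔF and each \eqn{S^2} the squared
#' standard error of that mean. The sign carries the direction of the effect;
#' |SSMD| > 1 is conventionally read as a strong effect.
#'
#' @param dfbar_ko,s2_ko pooled mean (\%) and squared SE for the KO group.
#' @param dfbar_scr,s2_scr the same for the SCR control group (the control
#'   mean is 100\% by construction of the plate normalization).
#' @return SSMD (dimensionless), vectorized over the KO arguments. When both
#'   variances are zero: 0 for equal means, signed \code{Inf} otherwise (with
#'   a warning).
#' @export
ssmd <- function(dfbar_ko, s2_ko, dfbar_scr = 100, s2_scr = 0) {
  denom <- sqrt(s2_ko + s2_scr)
  num <- dfbar_ko - dfbar_scr
  out <- ifelse(denom == 0, ifelse(num == 0, 0, sign(num) * Inf),
                num / denom)
  if (any(is.infinite(out)))
    warning("zero variance with unequal means: SSMD is infinite")
  out
}

# P(max_j |T_j| <= q) for Dunnett's many-to-one statistics under the global
# null, by conditioning on the shared control deviate z and the pooled
# standard-deviation ratio u = S/sigma:
#   T_j <= q  <=>  Z_j <= sqrt(n_j) * q * u * sqrt(1/n_j + 1/n0) + sqrt(n_j/n0) * z
# Integration is by composite Simpson rule over z (Gaussian weight) and over
# u (scaled-chi density with df degrees of freedom); both integrands are
# smooth, so the rule converges fast and is fully deterministic.
pdunnett_max_abs <- function(q, n_ko, n0, df,
                             nz = 81L, nu = 61L) {
  if (q <= 0) return(0)
  k <- length(n_ko)
  zmax <- 8.5
  z <- seq(-zmax, zmax, length.out = nz)
  umax <- sqrt(stats::qchisq(1 - 1e-12, df) / df)
  umin <- sqrt(stats::qchisq(1e-14, df) / df)
  u <- seq(umin, umax, length.out = nu)
  fu <- 2 * df * u * stats::dchisq(df * u^2, df) # density of S/sigma

  simpson_w <- function(n, h) {
    w <- rep(c(4, 2), length.out = n - 2)
    h / 3 * c(1, w, 1)
  }
  wz <- simpson_w(nz, z[2] - z[1])
  wu <- simpson_w(nu, u[2] - u[1])

  lam <- sqrt(n_ko / n0)                  # coefficient on z
  b <- sqrt(n_ko) * sqrt(1 / n_ko + 1 / n0) # coefficient on q*u
  Z <- matrix(z, nz, nu)                  # nodes on the (z, u) grid
  QU <- matrix(q * u, nz, nu, byrow = TRUE)
  pr <- matrix(1, nz, nu)
  for (j in seq_len(k)) {                 # P(-q <= T_j <= q | z, u)
    lz <- lam[j] * Z
    pr <- pr * (stats::pnorm(QU * b[j] + lz) - stats::pnorm(-QU * b[j] + lz))
  }
  min(1, sum((wz * stats::dnorm(z)) * pr %*% (wu * fu)))
}

#' Dunnett's many-to-one comparison against a shared control
#'
#' Computes, for each KO group, the Dunnett t statistic against the pooled
#' SCR control using a pooled error variance across all groups, and the
#' family-wise adjusted two-sided p value from the equicorrelated
#' multivariate-t null distribution induced by the shared control. The
#' adjusted p is evaluated by deterministic numerical integration over the
#' control deviate and the pooled-variance distribution. With a single
#' comparison the test reduces exactly to Student's two-sided two-sample
#' pooled t test.
#'
#' @param ko_values named list; one numeric vector of per-experiment
#'   normalized ΔF values per KO group (each of length >= 2).
#' @param control_values numeric vector of control (SCR) normalized ΔF values
#'   (length >= 2).
#' @return data.frame with columns \code{variant, t, p_adj, df}.
#' @export
dunnett_test <- function(ko_values, control_values) {
  if (length(control_values) < 2) stop("need >= 2 control replicates")
  ns <- vapply(ko_values, length, integer(1))
  if (any(ns < 2)) stop("every KO group needs >= 2 replicates")
  k <- length(ko_values)
  n0 <- length(control_values)
  groups <- c(list(control_values), unname(ko_values))
  df <- sum(vapply(groups, length, integer(1))) - (k + 1)
  s2p <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df
  if (s2p == 0) stop("pooled variance is zero; t statistics undefined")
  m0 <- mean(control_values)
  tval <- vapply(seq_len(k), function(j) {
    (mean(ko_values[[j]]) - m0) / sqrt(s2p * (1 / ns[j] + 1 / n0))
  }, numeric(1))
  p_adj <- if (k == 1) {
    2 * stats::pt(-abs(tval), df)
  } else {
    vapply(abs(tval), function(q)
      max(0, 1 - pdunnett_max_abs(q, ns, n0, df)), numeric(1))
  }
  data.frame(variant = names(ko_values), t = tval, p_adj = pmin(1, p_adj),
             df = df, stringsAsFactors = FALSE, row.names = NULL)
}

#' Critical |t| for Dunnett's test
#'
#' The two-sided family-wise critical value: the |t| at which the adjusted p
#' equals \code{alpha}.
#'
#' @param n_ko integer vector of per-KO group sizes (or a single size recycled
#'   over \code{k} groups when \code{k} is given).
#' @param n0 control group size.
#' @param alpha family-wise error rate.
#' @param k number of comparisons (defaults to \code{length(n_ko)}).
#' @return the critical |t| value.
#' @export
dunnett_critical <- function(n_ko, n0, alpha = 0.05, k = length(n_ko)) {
  if (length(n_ko) == 1 && k > 1) n_ko <- rep(n_ko, k)
  df <- sum(n_ko) + n0 - (k + 1)
  if (k == 1) return(stats::qt(1 - alpha / 2, df))
  f <- function(q) pdunnett_max_abs(q, n_ko, n0, df) - (1 - alpha)
  stats::uniroot(f, c(1, 12), tol = 1e-7)$root
}

#' Classify variants by the dual SSMD + significance criterion
#'
#' A variant is an \code{up_hit} when its adjusted p is below \code{alpha}
#' \emph{and} its SSMD exceeds \code{ssmd_thresh}; \code{down_hit} is the
#' mirror image. Variants whose SSMD crosses the threshold without reaching
#' significance are \code{possible_up}/\code{possible_down}; everything else
#' is \code{none}. Infinite SSMD (zero variance) is flagged and excluded from
#' hit classes.
#'
#' @param stats data.frame with columns \code{ssmd} and \code{p_adj} (as
#'   built by \code{\link{analyze_screen}}).
#' @param alpha significance level for the adjusted p (default 0.05).
#' @param ssmd_thresh SSMD magnitude threshold (default 1.0, the conservative
#'   "strong effect" reading).
#' @return the input with a \code{hit_class} factor column.
#' @export
classify_hits <- function(stats, alpha = 0.05, ssmd_thresh = 1.0) {
  cls <- rep("none", nrow(stats))
  sig <- !is.na(stats$p_adj) & stats$p_adj < alpha
  up <- stats$ssmd > ssmd_thresh
  dn <- stats$ssmd < -ssmd_thresh
  cls[up & sig] <- "up_hit"
  cls[dn & sig] <- "down_hit"
  cls[up & !sig] <- "possible_up"
  cls[dn & !sig] <- "possible_down"
  cls[is.infinite(stats$ssmd)] <- "none" # degenerate zero-variance groups
  stats$hit_class <- factor(cls, levels = c("up_hit", "down_hit",
                                            "possible_up", "possible_down",
                                            "none"))
  stats
}

#' Full per-variant analysis of a screen
#'
#' Runs the quantification pipeline end to end: sham-corrected ΔF, per-plate
#' SCR normalization, pooling across experiments, SSMD against the pooled SCR
#' control, Dunnett's adjusted test (one family per plate group, as variants
#' share their plate's control), and hit classification.
#'
#' @param x an \code{"ep_screen"} from \code{\link{simulate_screen}}, or a
#'   long per-cell table.
#' @param scr_ids SCR variant ids (taken from the screen object when given).
#' @param alpha,ssmd_thresh hit-calling thresholds, see
#'   \code{\link{classify_hits}}.
#' @param metric \code{"both"}, \code{"mean"} or \code{"median"}.
#' @return data.frame with one row per (variant, metric): \code{dfbar, s2, n,
#'   ssmd, t, p_adj, hit_class}.
#' @export
analyze_screen <- function(x, scr_ids = NULL, alpha = 0.05, ssmd_thresh = 1.0,
                           metric = c("both", "mean", "median")) {
  metric <- match.arg(metric)
  if (inherits(x, "ep_screen")) {
    if (is.null(scr_ids)) scr_ids <- x$scr_ids
    cells <- x$cells
  } else cells <- x
  if (is.null(scr_ids)) stop("scr_ids required for a plain cell table")
  deltas <- compute_delta_f(cells, metric)
  norm <- normalize_plate(deltas, scr_ids)
  pooled <- pool_variants(norm)
  scr <- pool_scr(norm, scr_ids)
  ko_pooled <- pooled[!pooled$variant %in% scr_ids, ]

  plate_of <- norm[!duplicated(paste(norm$variant, norm$plate)),
                   c("variant", "plate")]
  res <- lapply(split(ko_pooled, ko_pooled$metric), function(pm) {
    m <- pm$metric[1]
    ctrl <- scr[[m]]
    pm$ssmd <- ssmd(pm$dfbar, pm$s2, ctrl$dfbar, ctrl$s2)
    nm <- norm[norm$metric == m, ]
    # one Dunnett family per plate (variants screened as a group share the
    # control on their plate)
    dt <- do.call(rbind, lapply(split(pm$variant,
                                      plate_of$plate[match(pm$variant,
                                                           plate_of$variant)]),
                                function(vs) {
      kvals <- lapply(vs, function(v) nm$normalized[nm$variant == v])
      names(kvals) <- vs
      cvals <- nm$normalized[nm$variant %in% scr_ids]
      dunnett_test(kvals, cvals)
    }))
    pm$t <- dt$t[match(pm$variant, dt$variant)]
    pm$p_adj <- dt$p_adj[match(pm$variant, dt$variant)]
    classify_hits(pm, alpha, ssmd_thresh)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-series replication concordance
#'
#' Combines hit calls from two independently generated screen series.
#' A variant is a final hit when it reaches the dual criterion
#' (\code{up_hit}/\code{down_hit}) in at least one series \emph{and} the
#' other series supports the same direction: SSMD beyond the threshold, or a
#' normalized ΔF excess of at least \code{margin} percentage points, in the
#' same direction. A series pointing in the opposite direction demotes the
#' variant to \code{none}. Variants absent from one series are
#' \code{untested}.
#'
#' @param stats1,stats2 per-variant stats for one metric (rows of the output
#'   of \code{\link{analyze_screen}}).
#' @param ssmd_thresh SSMD threshold used for confirmation.
#' @param margin confirmation margin in percentage points (default 20: ΔF̄
#'   at or beyond 120\% / 80\% confirms).
#' @return data.frame with \code{variant, status} (\code{hit}, \code{none} or
#'   \code{untested}) and \code{direction} (\code{up}, \code{down} or
#'   \code{NA}).
#' @export
replication_concordance <- function(stats1, stats2, ssmd_thresh = 1.0,
                                    margin = 20) {
  all_v <- union(stats1$variant, stats2$variant)
  dir_of <- function(cls) {
    if (cls %in% c("up_hit", "possible_up")) 1L
    else if (cls %in% c("down_hit", "possible_down")) -1L else 0L
  }
  rows <- lapply(all_v, function(v) {
    i1 <- match(v, stats1$variant); i2 <- match(v, stats2$variant)
    if (is.na(i1) || is.na(i2))
      return(data.frame(variant = v, status = "untested",
                        direction = NA_character_, stringsAsFactors = FALSE))
    s <- list(stats1[i1, ], stats2[i2, ])
    full <- vapply(s, function(d)
      d$hit_class %in% c("up_hit", "down_hit"), logical(1))
    if (!any(full))
      return(data.frame(variant = v, status = "none",
                        direction = NA_character_, stringsAsFactors = FALSE))
    hit_i <- which(full)[1]
    other <- s[[3 - hit_i]]
    d <- dir_of(as.character(s[[hit_i]]$hit_class))
    confirmed <- (sign(other$ssmd) == d && abs(other$ssmd) > ssmd_thresh) ||
      (sign(other$dfbar - 100) == d && abs(other$dfbar - 100) >= margin) ||
      (full[3 - hit_i] && dir_of(as.character(other$hit_class)) == d)
    conflict <- (other$ssmd * d < 0 && abs(other$ssmd) > ssmd_thresh) ||
      (full[3 - hit_i] && dir_of(as.character(other$hit_class)) == -d) ||
      (sign(other$dfbar - 100) == -d && abs(other$dfbar - 100) >= margin) ||
      (other$ssmd * d < 0) # any opposite-direction estimate blocks confirmation
    status <- if (confirmed && !conflict) "hit" else "none"
    data.frame(variant = v, status = status,
               direction = if (status == "hit") c("down", "up")[(d + 3) / 2]
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen-wide asymmetry summary
#'
#' Counts, per metric, the variants whose pooled normalized ΔF lies above
#' 110\% and 120\% or below 90\% and 80\%, the variants with SSMD beyond
#' +1/−1, and the significant variants split by direction. These counts
#' summarize the up/down asymmetry of a screen.
#'
#' @param stats per-variant stats from \code{\link{analyze_screen}}.
#' @param alpha significance level for the direction-split counts.
#' @return data.frame with one row per metric and columns \code{gt110, gt120,
#'   lt90, lt80, ssmd_gt1, ssmd_lt_m1, sig_up, sig_down, n_variants}.
#' @export
screen_summary <- function(stats, alpha = 0.05) {
  rows <- lapply(split(stats, stats$metric), function(d) {
    fin <- is.finite(d$ssmd)
    data.frame(
      metric = d$metric[1],
      gt110 = sum(d$dfbar > 110), gt120 = sum(d$dfbar > 120),
      lt90 = sum(d$dfbar < 90), lt80 = sum(d$dfbar < 80),
      ssmd_gt1 = sum(fin & d$ssmd > 1), ssmd_lt_m1 = sum(fin & d$ssmd < -1),
      sig_up = sum(d$p_adj < alpha & d$dfbar > 100, na.rm = TRUE),
      sig_down = sum(d$p_adj < alpha & d$dfbar < 100, na.rm = TRUE),
      n_variants = nrow(d), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
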