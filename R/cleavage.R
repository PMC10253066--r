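#' Cleaved fraction from gel band intensities
#'
#' For the T7 endonuclease I (T7EI) genomic cleavage assay: the target region
#' is PCR-amplified, denatured and re-annealed, and mismatched heteroduplexes
#' are cut by T7EI. On the gel the parental band (intensity \code{A}) and two
#' cleavage products (\code{B}, \code{C}) yield the cleaved fraction
#' \deqn{CF = (B + C) / (A + B + C).}
#' Band intensity is taken as proportional to DNA mass, uncorrected for
#' fragment length.
#'
#' @param A parental band intensity (>= 0).
#' @param B,C cleaved band intensities (>= 0).
#' @return cleaved fraction in [0, 1]; vectorized.
#' @export
cleaved_fraction <- function(A, B, C) {
  if (any(A < 0 | B < 0 | C < 0)) stop("band intensities must be >= 0")
  tot <- A + B + C
  if (any(tot == 0)) stop("all band intensities are zero")
  (B + C) / tot
}

#' Expected mismatch fraction under random strand re-annealing
#'
#' Given allele-class frequencies \eqn{p_i} (wild type plus distinct indel
#' classes), a random re-annealed duplex pairs two strands of different
#' classes with probability \eqn{1 - \sum_i p_i^2}. With a single indel class
#' this is maximized at equal frequencies, giving the assay's 50\% detection
#' ceiling: half the strands re-anneal with a complementary strand carrying
#' no indel or the same indel and remain uncut. Pools with several distinct
#' indel classes can exceed 50\%.
#'
#' @param p numeric vector of allele-class frequencies; must be non-negative
#'   and sum to 1 (within 1e-8).
#' @return expected fraction of mismatched (cleavable) duplexes, in [0, 1].
#' @export
expected_mismatch_fraction <- function(p) {
  if (any(p < 0)) stop("allele frequencies must be >= 0")
  if (abs(sum(p) - 1) > 1e-8) stop("allele frequencies must sum to 1")
  1 - sum(p^2)
}

#' Simulate random re-annealing and score the resulting gel
#'
#' Draws duplexes by independently sampling two strands from the allele pool,
#' scores a duplex as cleaved when its strands belong to different classes
#' (one T7EI cut producing two equal-mass fragments), accumulates band masses
#' and applies \code{\link{cleaved_fraction}}.
#'
#' @param p allele-class frequencies (see
#'   \code{\link{expected_mismatch_fraction}}).
#' @param n_duplexes number of duplexes to draw.
#' @param seed integer seed.
#' @return list with \code{cf} (simulated cleaved fraction), \code{lanes}
#'   (band masses A, B, C) and \code{n_duplexes}.
#' @export
simulate_reannealing <- function(p, n_duplexes = 1e5, seed = 1L) {
  expected_mismatch_fraction(p) # validates p
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  k <- length(p)
  s1 <- sample.int(k, n_duplexes, replace = TRUE, prob = p)
  s2 <- sample.int(k, n_duplexes, replace = TRUE, prob = p)
  cut <- s1 != s2
  A <- sum(!cut)            # intact parental duplex mass (duplex units)
  B <- sum(cut) / 2         # one cut splits the duplex into two equal masses
  C <- sum(cut) / 2
  list(cf = cleaved_fraction(A, B, C), lanes = c(A = A, B = B, C = C),
       n_duplexes = n_duplexes)
}

#' Cleaved fractions for a lane table
#'
#' Applies \code{\link{cleaved_fraction}} to T7EI-treated lanes of a band
#' intensity table; untreated lanes get \code{NA} (no digestion, CF
#' undefined as an editing readout).
#'
#' @param lanes data.frame with columns \code{lane, A, B, C, treated}
#'   (\code{treated} logical: incubated with T7EI).
#' @return the input with a \code{cf} column.
#' @export
cleavage_table <- function(lanes) {
  need <- c("lane", "A", "B", "C", "treated")
  if (!all(need %in% names(lanes)))
    stop("lane table must have columns: ", paste(need, collapse = ", "))
  lanes$cf <- NA_real_
  tr <- as.logical(lanes$treated)
  lanes$cf[tr] <- cleaved_fraction(lanes$A[tr], lanes$B[tr], lanes$C[tr])
  lanes
}
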