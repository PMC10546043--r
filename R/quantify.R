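#' Reads per million per motif (RPMPM)
#'
#' Normalizes per-region hit counts both by library size and by the number of
#' motif sites in the region:
#' `RPMPM_i = 1e6 * (c_i / m_i) / D`,
#' where `c_i` is the region's hit count, `m_i` its motif count, and `D` the
#' library-wide total of hits assigned to *all* sites of the analysis
#' pattern (not merely the within-region-set sum), so that scores are
#' comparable across region sets covering different genome proportions.
#' Regions with no motif sites and no hits score 0 and are flagged rather
#' than dropped.
#'
#' @param c Integer region hit counts.
#' @param m Integer region motif counts.
#' @param denominator Library-wide total of assigned hits `D`; defaults to
#'   `sum(c)` (appropriate only when the regions tile the site registry).
#' @return Numeric RPMPM vector, with attribute `"no_motif"` flagging
#'   regions with `m == 0`.
#' @examples
#' rpmpm(c = 5, m = 2, denominator = 1e6)
#' @export
rpmpm <- function(c, m, denominator = sum(c)) {
  if (length(c) != length(m)) stop("c and m must have equal length")
  if (any(c < 0) || any(m < 0)) stop("counts must be non-negative")
  if (any(c > 0 & m == 0))
    stop("regions with hits but no motif sites: impossible assignment")
  if (denominator <= 0) stop("denominator must be positive")
  out <- numeric(length(c))
  nz <- m > 0
  out[nz] <- 1e6 * (c[nz] / m[nz]) / denominator
  attr(out, "no_motif") <- m == 0
  out
}

#' Log-transformed RPMPM score
#'
#' `log10(RPMPM + 1)`: monotone, zero at zero, compresses the heavy right
#' tail of count-derived scores.
#'
#' @param rpmpm Non-negative RPMPM values.
#' @return `log10(rpmpm + 1)`.
#' @export
log_score <- function(rpmpm) {
  if (any(rpmpm < 0)) stop("RPMPM values must be non-negative")
  log10(rpmpm + 1)
}

#' Posterior probability of correct alignment from MAPQ
#'
#' MAPQ is Phred-scaled: `1 - 10^(-mapq/10)`. MAPQ 10 corresponds to a 0.9
#' posterior probability of correct alignment, the confident-alignment
#' threshold used throughout.
#'
#' @param mapq Non-negative mapping quality.
#' @return Probability in `[0, 1)`.
#' @examples
#' mapq_to_posterior(10)
#' @export
mapq_to_posterior <- function(mapq) {
  if (any(mapq < 0)) stop("MAPQ must be non-negative")
  1 - 10^(-mapq / 10)
}

#' Subsample hit counts to a lower sequencing depth
#'
#' Draws `target` hit events without replacement from the observed counts
#' (multivariate hypergeometric), emulating a shallower sequencing run of
#' the same library for rarefaction analysis.
#'
#' @param counts Integer per-site or per-region counts.
#' @param target Target total depth (`0 <= target <= sum(counts)`).
#' @param seed Optional integer seed.
#' @return Integer vector of the same length with `sum == target`.
#' @export
subsample_counts <- function(counts, target, seed = NULL) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts)
  if (target > total) stop("target depth exceeds total counts")
  if (target < 0) stop("target depth must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  out <- integer(length(counts))
  remaining <- total
  need <- target
  for (i in seq_along(counts)) {
    if (need == 0L) break
    # draw this bin's share from the remaining pool
    x <- stats::rhyper(1L, counts[i], remaining - counts[i], need)
    out[i] <- x
    need <- need - x
    remaining <- remaining - counts[i]
  }
  out
}
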