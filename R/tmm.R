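#' TMM normalization factors
#'
#' Trimmed mean of M-values between-sample normalization. A reference sample
#' is chosen as the one whose upper-quartile count-per-million is closest to
#' the mean upper-quartile. For each sample j, over genes with positive
#' counts in both j and the reference r,
#' \deqn{M_g = \log_2\frac{y_{gj}/N_j}{y_{gr}/N_r}, \quad
#'       A_g = \tfrac12 \log_2\left(\frac{y_{gj}}{N_j}\frac{y_{gr}}{N_r}\right)}
#' the gene set is doubly trimmed (30\% of the M tails, 5\% of the A tails by
#' rank) and the factor is \eqn{2^{\bar M}} with \eqn{\bar M} the
#' inverse-asymptotic-variance weighted mean of the retained \eqn{M_g},
#' weights \eqn{1/v_g},
#' \eqn{v_g = (N_j-y_{gj})/(N_j y_{gj}) + (N_r-y_{gr})/(N_r y_{gr})}.
#' Factors are rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix (every sample total > 0).
#' @param m_trim fraction trimmed from each tail of the M (log-ratio)
#'   distribution (default 0.30).
#' @param a_trim fraction trimmed from each tail of the A (log-abundance)
#'   distribution (default 0.05).
#' @param ref_column optional reference sample (index or name); chosen by the
#'   upper-quartile rule when NULL.
#' @param weighted use inverse-variance weights (TRUE, the standard
#'   algorithm) or unit weights.
#' @return Named numeric vector of per-sample factors with attributes
#'   \code{ref_sample}, \code{m_trim}, \code{a_trim}.
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05,
                        ref_column = NULL, weighted = TRUE) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  # genes unobserved in every sample carry no information and would distort
  # the upper-quartile reference choice
  counts <- counts[rowSums(counts > 0) > 0L, , drop = FALSE]
  if (is.null(ref_column)) {
    uq <- apply(counts, 2L, stats::quantile, probs = 0.75) / lib
    ref_column <- if (stats::median(uq) < 1e-20) {
      which.max(colSums(sqrt(counts)))
    } else {
      which.min(abs(uq - mean(uq)))
    }
  } else if (is.character(ref_column)) {
    ref_column <- match(ref_column, colnames(counts))
  }
  yr <- counts[, ref_column]
  nr <- lib[ref_column]
  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], lib[j], yr, nr,
             m_trim = m_trim, a_trim = a_trim, weighted = weighted,
             sample_id = colnames(counts)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  attr(f, "ref_sample") <- colnames(counts)[ref_column]
  attr(f, "m_trim") <- m_trim
  attr(f, "a_trim") <- a_trim
  f
}

# one sample vs reference; mirrors the canonical double-trimmed weighted mean
tmm_pair <- function(yj, nj, yr, nr, m_trim, a_trim, weighted, sample_id = NULL) {
  pos <- yj > 0 & yr > 0
  if (!any(pos)) {
    stop("sample ", sample_id %||% "?",
         " shares no positively expressed gene with the reference")
  }
  yj <- yj[pos]; yr <- yr[pos]
  M <- log2((yj / nj) / (yr / nr))
  A <- (log2(yj / nj) + log2(yr / nr)) / 2
  v <- (nj - yj) / (nj * yj) + (nr - yr) / (nr * yr)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
  rM <- rank(M); rA <- rank(A)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep)) {
    stop("sample ", sample_id %||% "?", ": trimming removed every gene")
  }
  mbar <- if (weighted) {
    sum(M[keep] / v[keep]) / sum(1 / v[keep])
  } else {
    mean(M[keep])
  }
  f <- 2^mbar
  if (!is.finite(f)) 1 else f
}

#' Log2 counts-per-million on TMM-effective libraries
#'
#' \eqn{\log_2\mathrm{CPM}_{gj} = \log_2\left(10^6 (y_{gj} + p_j) /
#' (\tilde N_j + 2 p_j)\right)} where \eqn{\tilde N_j = N_j f_j} is the
#' TMM-effective library and \eqn{p_j = p\,\tilde N_j / \overline{\tilde N}}
#' is the library-scaled prior count. Finite for zero counts, monotone in
#' the raw count, and scale-invariant as the prior tends to zero.
#'
#' @param counts genes x samples count matrix.
#' @param factors per-sample normalization factors from
#'   \code{\link{tmm_factors}} (default: all 1).
#' @param prior_count prior count p (default 0.5).
#' @param lib_sizes optional explicit library sizes (default column sums).
#' @return Numeric matrix of log2-CPM values, same dimnames as counts.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5,
                    lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  eff <- lib_sizes * factors
  if (any(eff <= 0)) {
    stop("nonpositive effective library size for sample(s): ",
         paste(colnames(counts)[eff <= 0], collapse = ", "))
  }
  prior <- prior_count * eff / mean(eff)
  lc <- log2(t((t(counts) + prior) / (eff + 2 * prior)) * 1e6)
  dimnames(lc) <- dimnames(counts)
  lc
}
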