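#' Build the dual contrasts for a target group
#'
#' Every analyzed group is tested twice: against all other samples
#' (one-vs-rest, including background groups and NT in the reference) and
#' against normal tissue only. NT itself gets the single one-vs-rest
#' contrast. Clinical-group membership includes the group's autoantibody
#' subgroups; a subgroup's reference side keeps the remainder of its own
#' clinical group.
#'
#' @param annotations validated sample annotations.
#' @param hierarchy a \code{\link{myositis_hierarchy}}.
#' @param target_group an analyzed group label or the control label.
#' @return List of \code{contrast_spec} objects (fields \code{name},
#'   \code{group_samples}, \code{reference_samples}, \code{kind}); two specs
#'   (\code{vs_rest}, \code{vs_nt}) for analyzed groups, one for NT.
#' @export
build_contrasts <- function(annotations, hierarchy, target_group) {
  grp <- group_samples(annotations, hierarchy, target_group)
  if (length(grp) < 2L) {
    stop("group ", target_group, " has fewer than 2 samples")
  }
  rest <- setdiff(annotations$sample_id, grp)
  specs <- list(vs_rest = contrast_spec(
    name = paste0(target_group, "_vs_rest"),
    group_samples = grp, reference_samples = rest, kind = "vs_rest"
  ))
  if (target_group != hierarchy$control_group) {
    nt <- group_samples(annotations, hierarchy, hierarchy$control_group)
    if (length(nt) < 2L) stop("control group has fewer than 2 samples")
    specs$vs_nt <- contrast_spec(
      name = paste0(target_group, "_vs_NT"),
      group_samples = grp, reference_samples = nt, kind = "vs_nt"
    )
  }
  specs
}

contrast_spec <- function(name, group_samples, reference_samples, kind) {
  if (length(intersect(group_samples, reference_samples))) {
    stop("contrast sides are not disjoint")
  }
  if (length(group_samples) < 2L || length(reference_samples) < 2L) {
    stop("each contrast side needs at least 2 samples")
  }
  structure(list(name = name, group_samples = group_samples,
                 reference_samples = reference_samples, kind = kind),
            class = "contrast_spec")
}

#' Moderated-t two-group differential expression
#'
#' Per gene, an ordinary two-group equal-variance linear model on
#' log-expression gives the log2 fold change \eqn{\beta_g} (group minus
#' reference mean), residual variance \eqn{s_g^2} on \eqn{d_g = n-2} df.
#' Gene-wise variances are then shrunk toward a prior \eqn{(d_0, s_0^2)}
#' estimated across genes by moment-matching the distribution of
#' \eqn{\log s_g^2} (digamma/trigamma inversion):
#' \deqn{\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \quad
#'  \tilde t_g = \frac{\beta_g}{\tilde s_g \sqrt{1/n_1 + 1/n_2}}}
#' with two-sided p-values on \eqn{d_0 + d_g} df and Benjamini-Hochberg
#' q-values.
#'
#' @param log_expr genes x samples matrix of (finite) log expression.
#' @param contrast a \code{contrast_spec} from \code{\link{build_contrasts}}.
#' @param prior_df NULL to estimate \eqn{d_0} (the default); 0 forces
#'   ordinary t-statistics; Inf forces full shrinkage to \eqn{s_0^2}.
#' @return data.frame of class \code{de_result} with columns \code{gene},
#'   \code{log2FC}, \code{t}, \code{p}, \code{q}, \code{s2} and attributes
#'   \code{d0}, \code{s02}, \code{df_residual}, \code{contrast},
#'   \code{kind}, \code{n_group}, \code{n_reference}.
#' @export
fit_moderated <- function(log_expr, contrast, prior_df = NULL) {
  stopifnot(inherits(contrast, "contrast_spec"))
  i1 <- match(contrast$group_samples, colnames(log_expr))
  i2 <- match(contrast$reference_samples, colnames(log_expr))
  if (anyNA(i1) || anyNA(i2)) {
    stop("contrast samples missing from expression matrix")
  }
  if (!all(is.finite(log_expr[, c(i1, i2)]))) {
    stop("log expression must be finite")
  }
  n1 <- length(i1); n2 <- length(i2)
  e1 <- log_expr[, i1, drop = FALSE]
  e2 <- log_expr[, i2, drop = FALSE]
  m1 <- rowMeans(e1); m2 <- rowMeans(e2)
  beta <- m1 - m2
  d <- n1 + n2 - 2L
  s2 <- (rowSums((e1 - m1)^2) + rowSums((e2 - m2)^2)) / d
  if (all(s2 == 0)) stop("degenerate input: zero residual variance in every gene")

  if (is.null(prior_df)) {
    eb <- estimate_variance_prior(s2, d)
  } else if (identical(prior_df, 0) || identical(prior_df, 0L)) {
    eb <- list(d0 = 0, s02 = exp(mean(log(s2[s2 > 0]))))
  } else if (is.infinite(prior_df)) {
    ez <- log(s2[s2 > 0]) - digamma(d / 2) + log(d / 2)
    eb <- list(d0 = Inf, s02 = exp(mean(ez)))
  } else {
    stop("prior_df must be NULL, 0 or Inf")
  }
  d0 <- eb$d0; s02 <- eb$s02
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2)) else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, sign(beta) * Inf))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(
    gene = rownames(log_expr), log2FC = beta, t = tstat, p = p,
    q = bh_adjust(p), s2 = s2, row.names = NULL, stringsAsFactors = FALSE
  )
  attr(res, "d0") <- d0
  attr(res, "s02") <- s02
  attr(res, "df_residual") <- d
  attr(res, "contrast") <- contrast$name
  attr(res, "kind") <- contrast$kind
  attr(res, "n_group") <- n1
  attr(res, "n_reference") <- n2
  class(res) <- c("de_result", "data.frame")
  res
}

# moment-matching of (d0, s02) on z = log s2: E[z] and Var[z] follow
# scaled-F/log-chi-square identities; trigamma inverted by Newton steps.
estimate_variance_prior <- function(s2, d) {
  ok <- s2 > 0
  if (sum(ok) < 2L) {
    warning("too few positive variances; falling back to d0 = 0")
    return(list(d0 = 0, s02 = exp(mean(log(s2[ok])))))
  }
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar)) {
    warning("variance-prior estimation failed; falling back to d0 = 0")
    return(list(d0 = 0, s02 = exp(mean(z))))
  }
  if (evar <= 0) {
    # observed spread no wider than sampling noise: infinite prior df
    return(list(d0 = Inf, s02 = exp(mean(e))))
  }
  d0 <- 2 * trigamma_inverse(evar)
  if (!is.finite(d0) || d0 < 0) {
    warning("trigamma inversion failed; falling back to d0 = 0")
    return(list(d0 = 0, s02 = exp(mean(z))))
  }
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function on (0, Inf)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{q_{(i)} = \min_{j \ge i} \min(1, m\,p_{(j)}/j)} over the sorted
#' p-values; tied p-values receive identical q-values.
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Vector of q-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  o <- order(pvals)
  q_sorted <- pmin(1, m * pvals[o] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("Contrast %s (%d vs %d samples): d0 = %.3g, s0^2 = %.3g\n",
              attr(x, "contrast"), attr(x, "n_group"), attr(x, "n_reference"),
              attr(x, "d0"), attr(x, "s02")))
  cat(sprintf("  %d genes, %d with q < 0.001\n", nrow(x), sum(x$q < 0.001)))
  invisible(x)
}

#' Write a DE result table
#'
#' @param result a \code{de_result}.
#' @param path output TSV; floats are written with 6 significant digits.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(result, path) {
  out <- data.frame(
    gene = result$gene,
    log2FC = signif(result$log2FC, 6), t = signif(result$t, 6),
    p = signif(result$p, 6), q = signif(result$q, 6),
    contrast = attr(result, "contrast"), stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
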