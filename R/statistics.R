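# Normality screening, two-group comparison of the eight proportions,
# and Benjamini-Hochberg correction.

#' Kolmogorov-Smirnov normality screen
#'
#' One-sample KS statistic of the sample against a normal distribution
#' with the sample's own mean and standard deviation, with the asymptotic
#' p-value. Estimating the parameters from the same sample makes this
#' screen anticonservative (the Lilliefors effect); set
#' \code{lilliefors = TRUE} for a corrected p-value.
#'
#' @param sample Numeric vector, length >= 3, finite, non-constant.
#' @param lilliefors Use the Lilliefors-corrected test (via the
#'   \pkg{nortest} package) instead of the plain KS p-value.
#' @return List with \code{D} (statistic in [0, 1]) and \code{p}.
#' @export
#' @examples
#' ks_normality(qnorm(ppoints(50)))
ks_normality <- function(sample, lilliefors = FALSE) {
  sample <- as.numeric(sample)
  if (length(sample) < 3) stop("need at least 3 observations")
  if (!all(is.finite(sample))) stop("non-finite values in sample")
  s <- sd(sample)
  if (s == 0) stop("constant sample: normality test undefined")
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      stop("the Lilliefors correction requires the 'nortest' package")
    }
    lt <- nortest::lillie.test(sample)
    return(list(D = unname(lt$statistic), p = unname(lt$p.value)))
  }
  kt <- suppressWarnings(ks.test(sample, "pnorm", mean(sample), s))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Welch two-sample t-test
#'
#' Two-sided t-test for a difference in means; by default the Welch
#' unequal-variance form with Welch-Satterthwaite degrees of freedom.
#'
#' @param sample_a,sample_b Numeric vectors, each length >= 2, finite.
#' @param var_equal Use the pooled-variance Student form instead.
#' @return List with \code{t}, \code{df} and two-sided \code{p}.
#' @export
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))
welch_t <- function(sample_a, sample_b, var_equal = FALSE) {
  a <- as.numeric(sample_a); b <- as.numeric(sample_b)
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 observations")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values in sample")
  if (sd(a) == 0 && sd(b) == 0) {
    stop("undefined statistic: both samples are constant")
  }
  tt <- t.test(a, b, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = unname(tt$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false-discovery-rate adjustment: with the m p-values sorted
#' ascending, \code{adj(i) = min over j >= i of min(1, p(j) * m / j)},
#' mapped back to the input order.
#'
#' @param pvals Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Two-group comparison of proportion vectors
#'
#' Compares each proportion between two groups of specimens: group means,
#' Welch t-test p-values, Benjamini-Hochberg adjustment across the set of
#' proportions, and significance flags at \code{alpha}. Degenerate columns
#' where both groups are constant and identical (possible only in
#' synthetic edge cases) are recorded with \code{raw_p = 1}.
#'
#' @param props_a,props_b Numeric matrices (specimens x proportions, same
#'   columns) or lists of proportion vectors.
#' @param alpha Significance level for the adjusted p-values.
#' @param labels Length-2 character vector naming the groups.
#' @param var_equal Passed to \code{\link{welch_t}}.
#' @return A \code{group_comparison} data frame with columns
#'   \code{proportion}, \code{mean_a}, \code{mean_b}, \code{raw_p},
#'   \code{adj_p}, \code{significant}.
#' @export
compare_groups <- function(props_a, props_b, alpha = 0.05,
                           labels = c("A", "B"), var_equal = FALSE) {
  to_mat <- function(x) if (is.matrix(x)) x else do.call(rbind, x)
  A <- to_mat(props_a); B <- to_mat(props_b)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both groups must be non-empty")
  if (ncol(A) != ncol(B)) stop("groups measure different proportion sets")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  cols <- colnames(A)
  if (is.null(cols)) cols <- sprintf("P%02d", seq_len(ncol(A)))
  raw_p <- vapply(seq_len(ncol(A)), function(j) {
    a <- A[, j]; b <- B[, j]
    if (sd(a) == 0 && sd(b) == 0 && isTRUE(all.equal(mean(a), mean(b)))) {
      return(1)
    }
    welch_t(a, b, var_equal = var_equal)$p
  }, numeric(1))
  adj_p <- bh_adjust(raw_p)
  out <- data.frame(
    proportion = cols,
    mean_a = colMeans(A),
    mean_b = colMeans(B),
    raw_p = raw_p,
    adj_p = adj_p,
    significant = adj_p < alpha,
    row.names = NULL
  )
  attr(out, "alpha") <- alpha
  attr(out, "labels") <- labels
  attr(out, "n") <- c(nrow(A), nrow(B))
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Normality screen across a proportion matrix
#'
#' Runs \code{\link{ks_normality}} on each column of a proportion matrix.
#'
#' @param props Numeric matrix, specimens x proportions.
#' @param group Group label recorded in the output.
#' @param alpha Normality is assumed when p >= alpha.
#' @param lilliefors Passed to \code{\link{ks_normality}}.
#' @return Data frame with columns \code{group}, \code{proportion},
#'   \code{D}, \code{p}, \code{normal_assumed} (NA where the screen is
#'   undefined, e.g. constant columns).
#' @export
normality_screen <- function(props, group = "", alpha = 0.05,
                             lilliefors = FALSE) {
  cols <- colnames(props)
  if (is.null(cols)) cols <- sprintf("P%02d", seq_len(ncol(props)))
  rows <- lapply(seq_len(ncol(props)), function(j) {
    res <- tryCatch(ks_normality(props[, j], lilliefors = lilliefors),
                    error = function(e) list(D = NA_real_, p = NA_real_))
    data.frame(group = group, proportion = cols[j], D = res$D, p = res$p,
               normal_assumed = if (is.na(res$p)) NA else res$p >= alpha)
  })
  do.call(rbind, rows)
}

#' Fixed-width text rendering of a comparison table
#'
#' @param x A \code{group_comparison}.
#' @param digits Decimals for the reported means and adjusted p-values.
#' @return Character vector of lines ("Proportion | mean A | mean B |
#'   Adj. p-Value").
#' @export
format_comparison_table <- function(x, digits = 3) {
  labels <- attr(x, "labels")
  header <- sprintf("%-10s | %10s | %10s | %12s", "Proportion",
                    paste("mean", labels[1]), paste("mean", labels[2]),
                    "Adj. p-Value")
  body <- sprintf("%-10s | %10.*f | %10.*f | %12.*f",
                  x$proportion, digits, x$mean_a, digits, x$mean_b,
                  digits, x$adj_p)
  c(header, strrep("-", nchar(header)), body)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(format_comparison_table(x), sep = "\n")
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' @param x A \code{group_comparison}.
#' @param path Output path.
#' @export
write_comparison_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
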