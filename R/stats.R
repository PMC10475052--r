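# Nonparametric group comparisons used throughout the pipeline:
# Kruskal-Wallis omnibus (tie-corrected H, chi-square approximation) and
# post hoc pairwise two-sided Wilcoxon rank-sum tests with multiplicity
# control. These wrap the standard stats routines behind a grouped-values
# interface; correctness is checked in the test suite against hand rank
# computation, a permutation null and exact enumeration of the rank-sum
# distribution.

.as_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(!lengths(groups))) {
    stop("empty group(s): ", paste(names(groups)[!lengths(groups)], collapse = ", "))
  }
  groups
}

#' Kruskal-Wallis omnibus test on grouped values
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom. All-identical observations give H = 0, p = 1 (not
#' an error).
#'
#' @param groups Named list of numeric vectors (>= 2 non-empty groups).
#' @return List of class \code{kw_test}: statistic, df, p_value, n.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .as_groups(groups)
  n <- sum(lengths(groups))
  if (n < length(groups) + 1L) {
    stop("need at least one more observation than groups")
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    res <- list(statistic = 0, df = length(groups) - 1L, p_value = 1, n = n)
  } else {
    kt <- stats::kruskal.test(groups)
    res <- list(statistic = unname(kt$statistic), df = unname(kt$parameter),
                p_value = kt$p.value, n = n)
  }
  structure(res, class = "kw_test")
}

#' @export
print.kw_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  invisible(x)
}

#' Post hoc pairwise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test per unordered group pair with the chosen
#' multiplicity adjustment. With \code{exact = NULL} (default) the exact
#' null distribution is used for small tie-free samples and the normal
#' approximation with tie and continuity correction otherwise (the
#' standard behaviour of the underlying routine); the choice is recorded
#' in the result.
#'
#' @param groups Named list of numeric vectors.
#' @param adjust Multiplicity adjustment: holm (default), bonferroni, none.
#' @param exact Force (TRUE) or forbid (FALSE) the exact path; NULL lets
#'   sample size decide.
#' @return data.frame: group1, group2, p_raw, p_adj; attribute
#'   \code{adjust}.
#' @export
pairwise_wilcoxon <- function(groups, adjust = c("holm", "bonferroni", "none"),
                              exact = NULL) {
  adjust <- match.arg(adjust)
  groups <- .as_groups(groups)
  nm <- names(groups)
  combos <- utils::combn(length(groups), 2L)
  p_raw <- apply(combos, 2L, function(ij) {
    suppressWarnings(stats::wilcox.test(groups[[ij[1L]]], groups[[ij[2L]]],
                                        alternative = "two.sided",
                                        exact = exact, correct = TRUE)$p.value)
  })
  out <- data.frame(group1 = nm[combos[1L, ]], group2 = nm[combos[2L, ]],
                    p_raw = p_raw,
                    p_adj = stats::p.adjust(p_raw, method = adjust),
                    stringsAsFactors = FALSE)
  attr(out, "adjust") <- adjust
  out
}

#' Empirical type-I error of the Kruskal-Wallis test
#'
#' Simulates \code{n_reps} null datasets (iid continuous draws, no group
#' effect) and reports the fraction rejected at \code{alpha}. A correctly
#' sized test gives a rate near \code{alpha}.
#'
#' @param n_groups,n_per_group Null design.
#' @param n_reps Number of simulations.
#' @param alpha Significance level.
#' @param seed Seed.
#' @return List: rate, n_reps, alpha, se (binomial standard error at the
#'   nominal level).
#' @export
type_one_error_sim <- function(n_groups = 4L, n_per_group = 10L,
                               n_reps = 1000L, alpha = 0.05, seed = 1L) {
  set.seed(seed)
  g <- rep(seq_len(n_groups), each = n_per_group)
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    x <- stats::rnorm(n_groups * n_per_group)
    p <- stats::kruskal.test(split(x, g))$p.value
    rej[r] <- p < alpha
  }
  list(rate = mean(rej), n_reps = n_reps, alpha = alpha,
       se = sqrt(alpha * (1 - alpha) / n_reps))
}
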