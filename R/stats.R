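#' One-way ANOVA p-value (classic equal-variance F test)
#'
#' Small fast helper used by the tuning tests; numerically identical to
#' `oneway.test(..., var.equal = TRUE)` and, for two groups, to the
#' equal-variance two-sample t-test (F = t^2).
#'
#' Degenerate inputs: zero between- and within-group variance (all values
#' identical) returns p = 1; zero within-group variance with distinct group
#' means returns p = 0.
#'
#' @param x numeric observations.
#' @param g group labels (coerced to factor).
#' @return two-sided p-value.
#' @export
oneway_anova_p <- function(x, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(x)
  if (k < 2L) stop("need at least two groups")
  if (n != length(g)) stop("x and g lengths differ")
  means <- tapply(x, g, mean)
  counts <- tabulate(g)
  grand <- mean(x)
  ss_between <- sum(counts * (means - grand)^2)
  ss_within <- sum((x - means[as.integer(g)])^2)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 <= 0L) stop("need more observations than groups")
  if (ss_within <= 0) {
    if (ss_between <= 0) return(1)
    return(0)
  }
  f <- (ss_between / df1) / (ss_within / df2)
  pf(f, df1, df2, lower.tail = FALSE)
}

#' Task-related test: movement versus rest firing
#'
#' For each neuron, compares per-trial mean firing rates in the REST bins
#' against per-trial mean rates in the MOVE bins with a two-group one-way
#' ANOVA; a neuron is task-related when p < `alpha`.
#'
#' @param binned a `binned_rates` object.
#' @param alpha significance level (default 0.05).
#' @param observations `"trial_means"` (default; one rest and one move mean
#'   per trial) or `"bins"` (every trial x bin rate is an observation).
#' @return data frame `neuron`, `p_task_related`, `is_task_related`.
#' @export
task_related_test <- function(binned, alpha = 0.05,
                              observations = c("trial_means", "bins")) {
  if (!inherits(binned, "binned_rates")) stop("not a binned_rates")
  observations <- match.arg(observations)
  rest <- binned$bin_epochs == "REST"
  move <- !rest
  if (!any(rest) || !any(move)) stop("need at least one REST and one MOVE bin")
  n_trials <- dim(binned$values)[1]
  if (n_trials < 2L) stop("need at least 2 trials")
  p <- vapply(seq_along(binned$neuron_ids), function(j) {
    m <- binned$values[, j, , drop = TRUE]
    if (observations == "trial_means") {
      x <- c(rowMeans(m[, rest, drop = FALSE]),
             rowMeans(m[, move, drop = FALSE]))
      g <- rep(c("rest", "move"), each = n_trials)
    } else {
      x <- c(m[, rest], m[, move])
      g <- rep(c("rest", "move"), c(n_trials * sum(rest), n_trials * sum(move)))
    }
    oneway_anova_p(x, g)
  }, numeric(1))
  data.frame(neuron = binned$neuron_ids, p_task_related = p,
             is_task_related = p < alpha, stringsAsFactors = FALSE)
}

#' Per-bin tuning test across actions
#'
#' For each neuron and each MOVE bin, a one-way ANOVA compares firing rates
#' across the four actions. A neuron passes the tuning criterion when at
#' least `min_bins` bins are significant at `alpha` — the rate for at least
#' one action differs from the others in at least two bins.
#'
#' @param binned a `binned_rates` object.
#' @param alpha per-bin significance level (default 0.05, no correction).
#' @param min_bins significant-bin count required (default 2).
#' @return data frame `neuron`, `tuned_bins`, `is_tuned_anova`.
#' @export
tuning_test <- function(binned, alpha = 0.05, min_bins = 2L) {
  if (!inherits(binned, "binned_rates")) stop("not a binned_rates")
  labels <- binned$labels
  counts <- table(labels)
  if (length(counts) != 4L || any(counts < 2L))
    stop("need 4 action groups with at least 2 trials each")
  move <- which(binned$bin_epochs == "MOVE")
  if (!length(move)) stop("no MOVE bins")
  g <- factor(labels)
  res <- t(vapply(seq_along(binned$neuron_ids), function(j) {
    pvals <- vapply(move, function(b)
      oneway_anova_p(binned$values[, j, b], g), numeric(1))
    tuned <- sum(pvals < alpha)
    c(tuned, as.numeric(tuned >= min_bins))
  }, numeric(2)))
  data.frame(neuron = binned$neuron_ids, tuned_bins = as.integer(res[, 1]),
             is_tuned_anova = res[, 2] > 0, stringsAsFactors = FALSE)
}

#' Combined ANOVA report for a session
#'
#' @param binned a `binned_rates` object.
#' @param alpha significance level applied to both tests.
#' @param min_bins see [tuning_test()].
#' @return data frame joining [task_related_test()] and [tuning_test()],
#'   with an `alpha` attribute.
#' @export
anova_report <- function(binned, alpha = 0.05, min_bins = 2L) {
  tr <- task_related_test(binned, alpha)
  tu <- tuning_test(binned, alpha, min_bins)
  out <- merge(tr, tu, by = "neuron", sort = FALSE)
  attr(out, "alpha") <- alpha
  out
}
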