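#' Plug-in mutual information between a spike indicator and action labels
#'
#' Computes `I(spk; y) = sum_y p(y) sum_spk p(spk|y) log2(p(spk|y)/p(spk))`
#' in bits from empirical frequencies on the 2 x 4 contingency table of the
#' binary 10-ms spike indicator against the four action labels. Terms with
#' `p(spk|y) = 0` contribute zero. Under the balanced designs used here
#' `p(y)` is fixed at 1/4; pass `p_y = "empirical"` for unbalanced data.
#' The result is clipped at 0 to absorb floating-point round-off.
#'
#' @param spk 0/1 integer vector of indicator samples for one neuron.
#' @param labels action label (1-4) of each sample's trial.
#' @param p_y `NULL` (require balanced labels, use 1/4) or `"empirical"`.
#' @return mutual information in bits, in `[0, 1]`.
#' @export
spike_action_mi <- function(spk, labels, p_y = NULL) {
  if (!length(spk)) stop("no samples")
  if (length(spk) != length(labels)) stop("spk and labels lengths differ")
  if (any(spk != 0L & spk != 1L)) stop("spk must be binary")
  counts <- tabulate(labels, nbins = 4L)
  if (any(counts == 0L))
    stop("action label(s) absent from samples: ",
         paste(which(counts == 0L), collapse = ", "))
  if (is.null(p_y)) {
    if (length(unique(counts)) != 1L)
      stop("unbalanced labels; pass p_y = \"empirical\" to estimate p(y)")
    py <- rep(0.25, 4L)
  } else if (identical(p_y, "empirical")) {
    py <- counts / sum(counts)
  } else stop("p_y must be NULL or \"empirical\"")
  n1 <- vapply(1:4, function(y) sum(spk[labels == y]), numeric(1))
  p1y <- n1 / counts           # p(spk = 1 | y)
  p1 <- sum(py * p1y)          # p(spk = 1)
  term <- function(pc, pm) ifelse(pc > 0, pc * log2(pc / pm), 0)
  mi <- sum(py * (term(p1y, p1) + term(1 - p1y, 1 - p1)))
  max(mi, 0)
}

#' Cumulative-information threshold
#'
#' Sorts the per-neuron MI values in descending order and accumulates until
#' the running sum reaches `fraction` (default 90%) of the total; the last
#' value added is the task's tuning threshold. Computed per task per session.
#'
#' @param mi_values nonnegative MI values in bits, one per neuron.
#' @param fraction cumulative fraction of total information (default 0.9).
#' @return threshold in bits; 0 when all values are zero.
#' @export
mi_threshold <- function(mi_values, fraction = 0.9) {
  if (!length(mi_values)) stop("empty MI list")
  if (any(mi_values < 0)) stop("MI values must be >= 0")
  total <- sum(mi_values)
  if (total == 0) return(0)
  sorted <- sort(mi_values, decreasing = TRUE)  # stable: ties keep input order
  cs <- cumsum(sorted)
  k <- which(cs >= fraction * total - 1e-12)[1]
  sorted[k]
}

#' Assign tuning categories from MI values and thresholds
#'
#' A neuron is `BOTH` when its MI meets the threshold in both tasks,
#' `REACH_ONLY`/`GRASP_ONLY` when it meets exactly one, and `UNTUNED`
#' otherwise. Comparison is inclusive (`>=`): the neuron whose MI equals the
#' threshold was the last one added to the cumulative sum and counts as
#' tuned, as do any ties.
#'
#' @param mi_reach,mi_grasp per-neuron MI in bits.
#' @param thr_reach,thr_grasp task thresholds from [mi_threshold()].
#' @return character vector of categories.
#' @export
categorize_neurons <- function(mi_reach, mi_grasp, thr_reach, thr_grasp) {
  if (length(mi_reach) != length(mi_grasp)) stop("MI vector lengths differ")
  r <- mi_reach >= thr_reach
  g <- mi_grasp >= thr_grasp
  ifelse(r & g, "BOTH",
         ifelse(r, "REACH_ONLY", ifelse(g, "GRASP_ONLY", "UNTUNED")))
}

#' Per-neuron MI profile across the reach and grasp tasks
#'
#' Computes the plug-in MI of every neuron in each task from pooled
#' indicator samples, derives the two cumulative-information thresholds, and
#' assigns tuning categories. The two sessions must share a neuron roster.
#'
#' @param ind_reach,ind_grasp `indicator_samples` from the reach and grasp
#'   sessions of one recording day.
#' @param fraction cumulative-MI fraction for [mi_threshold()].
#' @return data frame of class `mi_profile` (`neuron`, `mi_reach`,
#'   `mi_grasp`, `category`) with attributes `thr_reach`, `thr_grasp`.
#' @export
mi_profile <- function(ind_reach, ind_grasp, fraction = 0.9) {
  if (!inherits(ind_reach, "indicator_samples") ||
      !inherits(ind_grasp, "indicator_samples"))
    stop("inputs must be indicator_samples")
  if (!identical(ind_reach$neuron_ids, ind_grasp$neuron_ids))
    stop("reach and grasp sessions must share the neuron roster")
  mi_r <- vapply(seq_along(ind_reach$neuron_ids), function(j)
    spike_action_mi(ind_reach$spk[, j], ind_reach$labels), numeric(1))
  mi_g <- vapply(seq_along(ind_grasp$neuron_ids), function(j)
    spike_action_mi(ind_grasp$spk[, j], ind_grasp$labels), numeric(1))
  thr_r <- mi_threshold(mi_r, fraction)
  thr_g <- mi_threshold(mi_g, fraction)
  out <- data.frame(neuron = ind_reach$neuron_ids, mi_reach = mi_r,
                    mi_grasp = mi_g,
                    category = categorize_neurons(mi_r, mi_g, thr_r, thr_g),
                    stringsAsFactors = FALSE)
  attr(out, "thr_reach") <- thr_r
  attr(out, "thr_grasp") <- thr_g
  attr(out, "fraction") <- fraction
  class(out) <- c("mi_profile", "data.frame")
  out
}

#' Information contribution of each tuning category
#'
#' For each task, the share of the session's total MI carried by each
#' category of neurons: `share(cat) = sum MI over neurons of cat / total MI
#' x 100%`. Shares over the four categories sum to 100% per task. With
#' several profiles (sessions), per-session shares and neuron counts are
#' averaged arithmetically.
#'
#' @param profiles an `mi_profile` or list of them.
#' @return data frame with one row per task x category: `task`, `category`,
#'   `share_pct` (NA when a session's total MI is zero), `n_neurons`.
#' @export
contribution_table <- function(profiles) {
  if (inherits(profiles, "mi_profile")) profiles <- list(profiles)
  per_session <- lapply(profiles, function(p) {
    do.call(rbind, lapply(c("reach", "grasp"), function(task) {
      mi <- if (task == "reach") p$mi_reach else p$mi_grasp
      total <- sum(mi)
      share <- vapply(NEURON_CATEGORIES, function(cat) {
        if (total == 0) return(NA_real_)
        sum(mi[p$category == cat]) / total * 100
      }, numeric(1))
      data.frame(task = task, category = NEURON_CATEGORIES,
                 share_pct = share,
                 n_neurons = vapply(NEURON_CATEGORIES,
                                    function(cat) sum(p$category == cat),
                                    numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- per_session[[1]]
  if (length(per_session) > 1L) {
    shares <- sapply(per_session, function(d) d$share_pct)
    counts <- sapply(per_session, function(d) d$n_neurons)
    out$share_pct <- rowMeans(shares)
    out$n_neurons <- rowMeans(counts)
  }
  rownames(out) <- NULL
  out
}
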