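#' PPV-sensitivity and ROC points of a ranked prediction
#'
#' Scores an ordered list of predicted modulators against a set of true
#' modulators: at every rank depth k, TP is the number of true modulators in
#' the top k, and the cumulative curves follow from the standard definitions
#' PPV = TP/(TP+FP), Sensitivity = TP/(TP+FN), Specificity = TN/(TN+FP),
#' FPR = 1 - Specificity.
#'
#' @param ranking Character vector of gene ids, best prediction first.
#' @param truth Character vector of the true modulator ids (must be a subset
#'   of the evaluated universe, i.e. of `ranking` unless some positives were
#'   excluded upstream — sensitivity is computed against `length(truth)`).
#' @return A data frame of class `dmi_ranked_eval` with one row per depth and
#'   columns `depth`, `id`, `label`, `tp`, `fp`, `fn`, `tn`, `ppv`,
#'   `sensitivity`, `specificity`, `fpr`.
#' @export
#' @examples
#' ppv_sensitivity_curve(c("a", "b", "c", "d"), truth = c("a", "b", "d"))
ppv_sensitivity_curve <- function(ranking, truth) {
  ranking <- as.character(ranking)
  truth <- unique(as.character(truth))
  if (length(ranking) == 0L) stop("'ranking' is empty", call. = FALSE)
  if (length(truth) == 0L) {
    stop("'truth' is empty: sensitivity undefined", call. = FALSE)
  }
  label <- ranking %in% truth
  n <- length(ranking)
  npos <- length(truth)
  tp <- cumsum(label)
  fp <- cumsum(!label)
  fn <- npos - tp
  tn <- (n - npos) - fp
  nneg <- n - npos
  out <- data.frame(
    depth = seq_len(n), id = ranking, label = label, tp = tp, fp = fp,
    fn = fn, tn = tn, ppv = tp / seq_len(n), sensitivity = tp / npos,
    specificity = if (nneg > 0) tn / nneg else rep(NA_real_, n),
    fpr = if (nneg > 0) fp / nneg else rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  class(out) <- c("dmi_ranked_eval", "data.frame")
  out
}

eleven_levels <- seq(0, 1, by = 0.1)

as_eval_list <- function(curves) {
  if (inherits(curves, "dmi_ranked_eval")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "dmi_ranked_eval")))
  curves
}

#' 11-point interpolated average precision across curves
#'
#' For each curve, the interpolated PPV at sensitivity level r is the
#' highest PPV attained at any sensitivity r' >= r; the interpolated PPV at
#' sensitivity 0 is 1 by definition. The composite curve is the arithmetic
#' mean of the interpolated values across curves at each of the 11 levels
#' 0.0, 0.1, ..., 1.0.
#'
#' @param curves A [ppv_sensitivity_curve()] result or a list of them.
#' @return A data frame of class `dmi_composite` with columns `level`
#'   (sensitivity), `value` (mean interpolated PPV) and `n_curves`, plus the
#'   per-curve interpolated values as attribute `"per_curve"`.
#' @export
average_precision_11pt <- function(curves) {
  curves <- as_eval_list(curves)
  per <- vapply(curves, function(cv) {
    sens <- c(0, cv$sensitivity)
    ppv <- c(1, cv$ppv)  # interpolated PPV at sensitivity 0 is 1 by definition
    vapply(eleven_levels, function(r) {
      ok <- sens >= r - 1e-12
      if (!any(ok)) 0 else max(ppv[ok])
    }, numeric(1))
  }, numeric(length(eleven_levels)))
  out <- data.frame(level = eleven_levels, value = rowMeans(per),
                    n_curves = length(curves))
  attr(out, "per_curve") <- per
  class(out) <- c("dmi_composite", "data.frame")
  out
}

#' Vertically averaged ROC curve
#'
#' Takes vertical samples of each ROC curve at the 11 fixed horizontal-axis
#' levels 0.0, 0.1, ..., 1.0 (false positive rate; the origin (0,0) and the
#' terminal point (1,1) are always part of a curve) and averages the
#' corresponding sensitivities across curves. Levels absent from a curve are
#' filled by linear interpolation between the neighboring points.
#'
#' @param curves A [ppv_sensitivity_curve()] result or a list of them.
#' @return A data frame of class `dmi_composite` with columns `level` (FPR),
#'   `value` (mean sensitivity) and `n_curves`, plus attribute `"per_curve"`.
#' @export
roc_vertical_average <- function(curves) {
  curves <- as_eval_list(curves)
  per <- vapply(curves, function(cv) {
    fpr <- c(0, cv$fpr)
    sens <- c(0, cv$sensitivity)
    if (max(fpr, na.rm = TRUE) < 1) { fpr <- c(fpr, 1); sens <- c(sens, 1) }
    # a step ROC revisits the same FPR with rising sensitivity: keep the
    # upper envelope before interpolating
    stats::approx(fpr, sens, xout = eleven_levels, ties = max, rule = 2)$y
  }, numeric(length(eleven_levels)))
  out <- data.frame(level = eleven_levels, value = rowMeans(per),
                    n_curves = length(curves))
  attr(out, "per_curve") <- per
  class(out) <- c("dmi_composite", "data.frame")
  out
}

#' Area under the PPV-sensitivity curve
#'
#' Trapezoidal area of the cumulative PPV over sensitivity, a single-number
#' summary used to compare a ranking against the random baseline (whose
#' expected PPV at every depth is the prevalence of true modulators).
#'
#' @param curve A [ppv_sensitivity_curve()] result.
#' @return Scalar area in `[0, 1]`.
#' @export
ppv_sensitivity_auc <- function(curve) {
  stopifnot(inherits(curve, "dmi_ranked_eval"))
  sens <- c(0, curve$sensitivity)
  ppv <- c(1, curve$ppv)
  ord <- order(sens)
  sens <- sens[ord]; ppv <- ppv[ord]
  sum(diff(sens) * (utils::head(ppv, -1) + utils::tail(ppv, -1)) / 2)
}

# Weighted running-sum enrichment score of one set within a ranked,
# scored gene list (scores sorted decreasing). weight = 1 is the standard
# pre-ranked weighting, 0 the classic Kolmogorov-Smirnov statistic.
enrichment_score <- function(scores, hits, weight = 1) {
  n <- length(scores)
  w <- abs(scores)^weight
  inc <- numeric(n)
  inc[hits] <- w[hits]
  sum_hit <- sum(inc)
  if (sum_hit == 0) return(0)
  n_miss <- n - length(hits)
  p_hit <- cumsum(inc) / sum_hit
  miss <- rep(1 / n_miss, n)
  miss[hits] <- 0
  p_miss <- cumsum(miss)
  dev <- p_hit - p_miss
  dev[which.max(abs(dev))]
}

#' Pre-ranked gene-set enrichment on a modulator ranking
#'
#' Applies the weighted running-sum enrichment statistic to a scored,
#' ranked gene list (e.g. modulators ranked by normalized Delta-I) for each
#' gene set: walking down the ranking, the running sum increases by the
#' normalized |score|^weight at each set member and decreases uniformly at
#' non-members; the enrichment score (ES) is the maximum deviation from
#' zero. Significance is assessed by gene-label permutation: the set labels
#' are reassigned to random positions `n_permutations` times and the p-value
#' is the fraction of permutations whose |ES| strictly exceeds the observed
#' |ES| (two-sided on the magnitude, so p = 0 is possible and p-values are
#' uniform under a random ranking). Sets with fewer than two members present
#' in the ranking are dropped.
#'
#' @param scores Named numeric vector: ranking statistic per gene (names are
#'   gene ids). Sorted in decreasing order internally.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param n_permutations Number of label permutations.
#' @param weight Running-sum weight exponent (default 1; 0 = classic KS).
#' @param p_cut Optional p-value threshold; sets at or above it are dropped
#'   from the report (use e.g. 0.01 to mirror a reporting cut).
#' @param seed Integer seed for the permutations.
#' @return A data frame with columns `set`, `size`, `es`, `p_value`, sorted
#'   by p-value then decreasing |ES|.
#' @export
preranked_enrichment <- function(scores, gene_sets, n_permutations = 1000L,
                                 weight = 1, p_cut = NULL, seed = 1L) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  scores <- sort(scores, decreasing = TRUE)
  n <- length(scores)
  keep <- vapply(gene_sets, function(s) sum(names(scores) %in% s) >= 2L,
                 logical(1))
  if (!any(keep)) {
    warning("no gene set has more than one member in the ranking", call. = FALSE)
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  gene_sets <- gene_sets[keep]
  withr::with_seed(as.integer(seed), {
    rows <- lapply(names(gene_sets), function(nm) {
      hits <- which(names(scores) %in% gene_sets[[nm]])
      es <- enrichment_score(scores, hits, weight)
      null <- vapply(seq_len(n_permutations), function(i) {
        enrichment_score(scores, sample.int(n, length(hits)), weight)
      }, numeric(1))
      p <- mean(abs(null) > abs(es))
      data.frame(set = nm, size = length(hits), es = es, p_value = p,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(out$p_value, -abs(out$es)), , drop = FALSE]
    if (!is.null(p_cut)) out <- out[out$p_value < p_cut, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
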