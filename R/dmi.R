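#' Configuration of a DMI run
#'
#' @param n_bins Number of equal-size sample bins the profiles are split into
#'   after sorting by modulator expression (>= 2; default 3, giving
#'   Low/Medium/High).
#' @param fc_threshold Fold-change prefilter threshold. A modulator passes
#'   only if its fold change between the High and Low bins exceeds this
#'   value. On the default `fc_scale = "log2"` the threshold is in log2
#'   units (1.0 = two-fold linear).
#' @param fc_scale `"log2"` (difference of bin means, for log-scale
#'   expression data) or `"ratio"` (ratio of bin means as stored).
#' @param n_permutations Number of permutation trials L for the Delta-I null
#'   distribution (default 10,000).
#' @param alpha_significance Adjusted-p cutoff used when `significant_only`
#'   is requested in [run_dmi()].
#' @param p_pseudocount If `TRUE`, p-values are `(x+1)/(L+1)` (x = number of
#'   exceeding trials) instead of the literal exceedance fraction `x/L`
#'   (which can be exactly 0).
#' @param rmi An [rmi_config()] for the underlying estimator.
#' @param seed Integer seed governing the permutation draws.
#' @return An object of class `dmi_config`.
#' @export
dmi_config <- function(n_bins = 3L, fc_threshold = 1.0, fc_scale = c("log2", "ratio"),
                       n_permutations = 10000L, alpha_significance = 0.05,
                       p_pseudocount = FALSE, rmi = rmi_config(), seed = 1L) {
  n_bins <- as.integer(n_bins)
  n_permutations <- as.integer(n_permutations)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1", call. = FALSE)
  if (!inherits(rmi, "rmi_config")) stop("'rmi' must be an rmi_config", call. = FALSE)
  structure(
    list(n_bins = n_bins, fc_threshold = fc_threshold,
         fc_scale = match.arg(fc_scale), n_permutations = n_permutations,
         alpha_significance = alpha_significance,
         p_pseudocount = isTRUE(p_pseudocount), rmi = rmi,
         seed = as.integer(seed)),
    class = "dmi_config"
  )
}

check_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("'expr' must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(expr))) stop("'expr' must have gene ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(expr)) > 0L) {
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  }
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  invisible(expr)
}

#' Split samples into bins by modulator expression
#'
#' Samples are sorted in ascending order of the modulator's expression and
#' split into `n_bins` contiguous subsets of (near-)equal size: the first
#' subset is the "Low" bin, the last the "High" bin. When the sample count
#' is not divisible by `n_bins`, the remainder is assigned one extra sample
#' per bin starting from the Low bin. The sort is stable on
#' (value, sample index), so ties across a boundary resolve deterministically.
#'
#' @param expr Genes x samples numeric matrix with gene ids as rownames.
#' @param modulator_id Gene id of the modulator to sort by.
#' @param n_bins Number of bins (>= 2).
#' @return A named list of integer sample-index vectors (first element
#'   `"low"`, last `"high"`), disjoint and covering all samples.
#' @export
#' @examples
#' expr <- matrix(1:9, nrow = 1, dimnames = list("M", paste0("s", 1:9)))
#' bin_samples_by_modulator(expr, "M", 3)
bin_samples_by_modulator <- function(expr, modulator_id, n_bins = 3L) {
  check_expression_matrix(expr)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2", call. = FALSE)
  if (!modulator_id %in% rownames(expr)) {
    stop(sprintf("modulator '%s' not found in expression matrix", modulator_id),
         call. = FALSE)
  }
  m <- ncol(expr)
  if (m < n_bins) stop("fewer samples than bins", call. = FALSE)
  ord <- order(expr[modulator_id, ], method = "radix")  # stable on ties
  base <- m %/% n_bins
  rem <- m %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  bins <- split(ord, rep(seq_len(n_bins), times = sizes))
  names(bins) <- paste0("bin_", seq_len(n_bins))
  names(bins)[1L] <- "low"
  names(bins)[n_bins] <- "high"
  lapply(bins, as.integer)
}

#' Modulator fold change between the High and Low bins
#'
#' On the default log2 scale this is the difference of the modulator's mean
#' expression in the High and Low bins (log-scale data); on the `"ratio"`
#' scale it is the ratio of the bin means as stored.
#'
#' @param expr Genes x samples numeric matrix.
#' @param modulator_id Modulator gene id.
#' @param low,high Integer sample indices of the Low and High bins.
#' @param scale `"log2"` or `"ratio"`.
#' @return The scalar fold change.
#' @export
fold_change <- function(expr, modulator_id, low, high,
                        scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  if (length(low) == 0L || length(high) == 0L) {
    stop("bins must be non-empty", call. = FALSE)
  }
  mh <- mean(expr[modulator_id, high])
  ml <- mean(expr[modulator_id, low])
  if (scale == "log2") mh - ml else mh / ml
}

#' Differential Multi-Information of a target set for one modulator
#'
#' Sorts the samples by the modulator's expression, splits them into bins,
#' and estimates the Rényi multi-information of the target-gene submatrix
#' separately in the High and the Low bin (the copula transform is applied
#' within each bin). Delta-I = I_high - I_low: positive values mean the
#' targets are co-regulated when the modulator is highly expressed
#' (activating modulator), negative values the opposite. The normalized
#' statistic `(I_high - I_low) / (I_high + I_low)` makes values comparable
#' across target sets of different size.
#'
#' @param expr Genes x samples numeric matrix with gene ids as rownames.
#' @param target_ids Character vector of target gene ids (>= 2, not
#'   containing the modulator).
#' @param modulator_id Modulator gene id.
#' @param config A [dmi_config()].
#' @return A list with elements `modulator_id`, `i_high`, `i_low`, `delta_i`,
#'   `delta_i_norm`, `fold_change`, `bins`, and `skipped` (a reason string
#'   when a bin was too small for the estimator, in which case the
#'   information values are `NA`).
#' @export
delta_information <- function(expr, target_ids, modulator_id,
                              config = dmi_config()) {
  check_expression_matrix(expr)
  target_ids <- as.character(target_ids)
  missing_t <- setdiff(target_ids, rownames(expr))
  if (length(missing_t) > 0L) {
    stop(sprintf("target gene(s) not in matrix: %s",
                 paste(missing_t, collapse = ", ")), call. = FALSE)
  }
  if (length(target_ids) < 2L) stop("need at least 2 target genes", call. = FALSE)
  if (modulator_id %in% target_ids) {
    stop(sprintf("modulator '%s' is in the target set (confounded)", modulator_id),
         call. = FALSE)
  }
  bins <- bin_samples_by_modulator(expr, modulator_id, config$n_bins)
  low <- bins[["low"]]; high <- bins[["high"]]
  fc <- fold_change(expr, modulator_id, low, high, config$fc_scale)
  out <- list(modulator_id = modulator_id, i_high = NA_real_, i_low = NA_real_,
              delta_i = NA_real_, delta_i_norm = NA_real_, fold_change = fc,
              bins = bins, skipped = NA_character_)
  min_n <- config$rmi$min_n
  if (length(low) < min_n || length(high) < min_n) {
    out$skipped <- sprintf("bin size below estimator minimum (%d)", min_n)
    message(sprintf("skipping '%s': %s", modulator_id, out$skipped))
    return(out)
  }
  d <- length(target_ids)
  xh <- t(expr[target_ids, high, drop = FALSE])
  xl <- t(expr[target_ids, low, drop = FALSE])
  out$i_high <- renyi_multi_information(xh, config$rmi,
                                        gamma_for(config$rmi, d, length(high)))
  out$i_low <- renyi_multi_information(xl, config$rmi,
                                       gamma_for(config$rmi, d, length(low)))
  out$delta_i <- out$i_high - out$i_low
  denom <- out$i_high + out$i_low
  out$delta_i_norm <- if (denom != 0) out$delta_i / denom else NaN
  out
}

#' Permutation p-value for an observed Delta-I
#'
#' Builds the null distribution of Delta-I for one modulator by drawing, in
#' each of L trials, d genes uniformly at random from the whole expression
#' matrix (the modulator itself excluded) and recomputing Delta-I with the
#' same High/Low bins. The p-value is the fraction of trials whose null
#' Delta-I strictly exceeds the observed value, so p = 0 is possible (set
#' `p_pseudocount` in the config for `(r+1)/(L+1)` instead).
#'
#' @param expr Genes x samples numeric matrix.
#' @param observed_delta Observed Delta-I for the modulator.
#' @param d Number of target genes drawn per trial.
#' @param modulator_id Modulator gene id (excluded from the null gene pool).
#' @param bins Bin list from [bin_samples_by_modulator()] (the modulator's
#'   own bins; only the `low` and `high` elements are used).
#' @param config A [dmi_config()]; `n_permutations` sets L.
#' @param return_null Also return the null Delta-I values?
#' @return The p-value in `[0, 1]`; when `return_null = TRUE`, a list with
#'   elements `p_value` and `null`.
#' @export
permutation_pvalue <- function(expr, observed_delta, d, modulator_id, bins,
                               config = dmi_config(), return_null = FALSE) {
  check_expression_matrix(expr)
  L <- config$n_permutations
  pool <- setdiff(rownames(expr), modulator_id)
  if (length(pool) < d) stop("not enough genes for null draws", call. = FALSE)
  alpha <- config$rmi$alpha
  p_exp <- d * (1 - alpha)
  low <- bins[["low"]]; high <- bins[["high"]]
  gamma_h <- gamma_for(config$rmi, d, length(high))
  gamma_l <- gamma_for(config$rmi, d, length(low))
  high_m <- t(expr[pool, high, drop = FALSE])
  low_m <- t(expr[pool, low, drop = FALSE])
  coef <- 1 / (alpha - 1)
  log_ch <- log(gamma_h) + (1 - p_exp / d) * log(length(high))
  log_cl <- log(gamma_l) + (1 - p_exp / d) * log(length(low))
  null <- perm_null_delta_cpp(high_m, low_m, as.integer(d), L,
                              config$rmi$neighbor_set, p_exp, coef,
                              log_ch, log_cl)
  if (anyNA(null)) {
    warning("degenerate null trials dropped", call. = FALSE)
    null <- null[!is.na(null)]
  }
  r <- sum(null > observed_delta)
  p <- if (config$p_pseudocount) (r + 1) / (length(null) + 1) else r / length(null)
  if (return_null) list(p_value = p, null = null) else p
}

#' Run the full DMI modulator screen
#'
#' For each candidate modulator: bin the samples by its expression, apply the
#' fold-change prefilter, estimate Delta-I between the High and Low bins,
#' attach a permutation p-value and a Benjamini-Hochberg adjusted p-value,
#' and rank the surviving modulators. Within one TF the primary ranking key
#' is descending raw `delta_i` (activating modulators first), with ascending
#' p-value and then gene id as tiebreakers. A secondary ranking by
#' descending `|delta_i_norm|` is emitted as `rank_norm`: the normalized
#' statistic exists to compare modulators *across* TFs with different
#' target-set sizes, but within one screen its denominator `i_high + i_low`
#' can sit near zero for null modulators, which makes it an unstable
#' primary key.
#'
#' @param expr Genes x samples numeric matrix with gene ids as rownames.
#' @param target_ids Character vector of the TF's target gene ids.
#' @param modulator_ids Character vector of candidate modulator gene ids.
#' @param config A [dmi_config()].
#' @param significant_only Drop modulators with adjusted p >=
#'   `alpha_significance` from the ranking?
#' @return A data frame of class `dmi_result`, one row per candidate, with
#'   columns `modulator_id`, `i_low`, `i_high`, `delta_i`, `delta_i_norm`,
#'   `fold_change`, `p_value`, `p_adjusted`, `passed_filter`, `rank`,
#'   `rank_norm`, ordered by `rank` (filtered/skipped candidates last). The
#'   configuration is attached as attribute `"config"`.
#' @export
run_dmi <- function(expr, target_ids, modulator_ids, config = dmi_config(),
                    significant_only = FALSE) {
  check_expression_matrix(expr)
  target_ids <- as.character(target_ids)
  modulator_ids <- as.character(modulator_ids)
  missing_m <- setdiff(modulator_ids, rownames(expr))
  if (length(missing_m) > 0L) {
    stop(sprintf("modulator gene(s) not in matrix: %s",
                 paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  d <- length(target_ids)
  # pre-calibrate gamma for the two bin sizes this run will use
  m <- ncol(expr)
  base <- m %/% config$n_bins
  for (nb in unique(c(base, base + sign(m %% config$n_bins)))) {
    if (nb >= config$rmi$min_n) gamma_for(config$rmi, d, nb)
  }
  set.seed(config$seed)
  rows <- vector("list", length(modulator_ids))
  for (i in seq_along(modulator_ids)) {
    mid <- modulator_ids[i]
    di <- delta_information(expr, target_ids, mid, config)
    passed <- !is.na(di$delta_i) && di$fold_change > config$fc_threshold
    p <- NA_real_
    if (passed) {
      p <- permutation_pvalue(expr, di$delta_i, d, mid, di$bins, config)
    }
    rows[[i]] <- data.frame(
      modulator_id = mid, i_low = di$i_low, i_high = di$i_high,
      delta_i = di$delta_i, delta_i_norm = di$delta_i_norm,
      fold_change = di$fold_change, p_value = p, p_adjusted = NA_real_,
      passed_filter = passed, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, rows)
  sel <- res$passed_filter
  res$p_adjusted[sel] <- stats::p.adjust(res$p_value[sel], method = "BH")
  if (!any(sel)) warning("no modulator passed the fold-change prefilter",
                         call. = FALSE)
  res$rank <- NA_integer_
  res$rank_norm <- NA_integer_
  if (any(sel)) {
    idx <- which(sel)
    key <- order(-res$delta_i[idx], res$p_value[idx], res$modulator_id[idx],
                 method = "radix")
    res$rank[idx[key]] <- seq_along(idx)
    key2 <- order(-abs(res$delta_i_norm[idx]), res$p_value[idx],
                  res$modulator_id[idx], method = "radix")
    res$rank_norm[idx[key2]] <- seq_along(idx)
  }
  if (significant_only) {
    keep <- !is.na(res$p_adjusted) & res$p_adjusted < config$alpha_significance
    res$rank[!keep] <- NA_integer_
    res$rank_norm[!keep] <- NA_integer_
    res$passed_filter <- res$passed_filter & keep
  }
  res <- res[order(res$rank, res$modulator_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "config") <- config
  class(res) <- c("dmi_result", "data.frame")
  res
}

#' @export
print.dmi_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("DMI screen: %d candidates, %d passed the fold-change filter\n",
              nrow(x), sum(x$passed_filter)))
  if (!is.null(cfg)) {
    cat(sprintf("  bins = %d, fc > %g (%s), L = %d, alpha = %g\n",
                cfg$n_bins, cfg$fc_threshold, cfg$fc_scale,
                cfg$n_permutations, cfg$rmi$alpha))
  }
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... %d more rows\n", nrow(x) - 10))
  invisible(x)
}
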