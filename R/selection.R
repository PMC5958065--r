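# Permutation-based evaluation statistic and top-percentile candidate
# selection with cross-window deduplication.

#' Best deviances under phenotype permutation
#'
#' For each permutation, subject phenotypes are shuffled (both chromosome
#' copies of a subject move together, so the case count is preserved), the
#' full multi-restart search is re-run on the window, and the best 3-SNP
#' deviance is recorded. The permutation searches use
#' `config$perm_restarts` restarts.
#'
#' @param cohort a [phased_cohort()].
#' @param window a pruned `gene_window`.
#' @param config a [search_config()].
#' @param n_perm number of permutations (default 20; at least 2).
#' @param seed seed for the permutation draws (default: derived from the
#'   config seed and window id).
#' @return numeric vector of `n_perm` best deviances.
#' @export
permutation_deviances <- function(cohort, window, config = search_config(),
                                  n_perm = 20L, seed = NULL) {
  if (n_perm < 2L) stop("n_perm must be at least 2")
  seed <- seed %||% derive_seed(config$seed, window$window_id, "perm")
  pheno <- cohort$subjects$phenotype
  perm_config <- config
  perm_config$n_restarts <- config$perm_restarts
  vapply(seq_len(n_perm), function(p) {
    shuffled <- with_seed(derive_seed(seed, p), sample(pheno))
    pcfg <- perm_config
    pcfg$seed <- derive_seed(seed, "search", p)
    fit <- search_window(cohort, window, pcfg, phenotype = shuffled)
    if (is.null(fit)) NA_real_ else fit$deviance
  }, numeric(1))
}

#' Permutation-based evaluation statistic
#'
#' For permutation deviances `D_1..D_n`, the null deviations are the
#' leave-one-out differences `d_i = D_i - median(D_{-i})`; the statistic is
#' `(D_obs - D_med) / MAD(d)`, where `D_med` is the median of all `n`
#' permutation deviances and `MAD(d)` the median absolute deviation of the
#' deviations (scaled by 1.4826 by default; set `mad_scale = 1` for the raw
#' MAD). More negative values indicate an observed fit farther below its
#' permutation null. A zero MAD (all permutation deviances equal) yields the
#' degenerate sentinel (`NA` statistic) and is excluded from ranking.
#'
#' @param d_obs observed best deviance of the window.
#' @param perm_deviances the permutation deviances (typically 20).
#' @param mad_scale consistency factor for the MAD (default 1.4826).
#' @return a `perm_stat` list: `d_obs`, `perm_deviances`, `deviations`,
#'   `d_med`, `mad`, `statistic`, `degenerate`.
#' @export
evaluation_statistic <- function(d_obs, perm_deviances, mad_scale = 1.4826) {
  n <- length(perm_deviances)
  stopifnot(n >= 2, !anyNA(perm_deviances), is.finite(d_obs))
  dev_i <- vapply(seq_len(n), function(i)
    perm_deviances[i] - stats::median(perm_deviances[-i]), numeric(1))
  d_med <- stats::median(perm_deviances)
  mad <- stats::median(abs(dev_i - stats::median(dev_i))) * mad_scale
  degenerate <- mad <= 0
  structure(list(
    d_obs = d_obs, perm_deviances = perm_deviances, deviations = dev_i,
    d_med = d_med, mad = mad,
    statistic = if (degenerate) NA_real_ else (d_obs - d_med) / mad,
    degenerate = degenerate),
    class = "perm_stat")
}

#' @exportS3Method base::print
print.perm_stat <- function(x, ...) {
  cat("perm_stat: D_obs", formatC(x$d_obs, digits = 4, format = "f"),
      "D_med", formatC(x$d_med, digits = 4, format = "f"),
      "MAD", formatC(x$mad, digits = 4, format = "f"),
      "statistic", if (x$degenerate) "degenerate"
      else formatC(x$statistic, digits = 4, format = "f"), "\n")
  invisible(x)
}

#' Select candidate haplotypes by top-percentile statistic
#'
#' Deduplicates trees across windows by structural canonical key, keeping the
#' most negative statistic per unique tree, then selects the lowest
#' `ceiling(fraction * n_unique)` statistics. Degenerate statistics are
#' excluded from ranking.
#'
#' @param results list of per-window entries, each a list with elements
#'   `fit` (a `hap_fit`, tree included) and `stat` (a `perm_stat`).
#' @param fraction selection fraction (default 0.01, the top one percentile).
#' @return a list with `candidates` (data frame: `key`, `window_id`,
#'   `tree_text`, `d_obs`, `statistic`), `trees` (the selected tree objects),
#'   `n_unique`, and the realized `cutoff` statistic.
#' @export
select_candidates <- function(results, fraction = 0.01) {
  if (!length(results))
    return(list(candidates = data.frame(), trees = list(),
                n_unique = 0L, cutoff = NA_real_))
  rows <- lapply(results, function(r) {
    if (is.null(r$fit) || is.null(r$stat) || isTRUE(r$stat$degenerate) ||
        is.na(r$stat$statistic)) return(NULL)
    data.frame(key = canonical_key(r$fit$tree),
               window_id = r$fit$window_id %||% NA_character_,
               d_obs = r$fit$deviance,
               statistic = r$stat$statistic,
               stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep))
    return(list(candidates = data.frame(), trees = list(),
                n_unique = 0L, cutoff = NA_real_))
  df <- do.call(rbind, rows[keep])
  trees <- lapply(results[keep], function(r) r$fit$tree)
  # dedup across windows: keep the most negative statistic per unique tree
  ord <- order(df$statistic, df$key, method = "radix")
  df <- df[ord, , drop = FALSE]
  trees <- trees[ord]
  first <- !duplicated(df$key)
  df <- df[first, , drop = FALSE]
  trees <- trees[first]
  n_unique <- nrow(df)
  n_sel <- ceiling(fraction * n_unique)
  sel <- seq_len(min(n_sel, n_unique))
  cand <- df[sel, , drop = FALSE]
  cand$tree_text <- vapply(trees[sel], format_tree, character(1))
  rownames(cand) <- NULL
  list(candidates = cand[, c("key", "window_id", "tree_text", "d_obs",
                             "statistic")],
       trees = trees[sel], n_unique = n_unique,
       cutoff = if (length(sel)) max(cand$statistic) else NA_real_)
}
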