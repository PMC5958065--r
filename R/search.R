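# Per-window simulated-annealing logic-regression search. The search scores
# trees by the chromosome-level logistic deviance (2N observations, each
# subject's phenotype duplicated onto both chromosome copies); subject-level
# inference for reported haplotypes is a separate model (see fit_additive).

#' Search configuration
#'
#' Defaults follow common logic-regression practice: geometric cooling over a
#' fixed iteration budget with many random restarts; the restart count echoes
#' the 100-initialization protocol of the discovery analysis. The annealing
#' schedule itself (iterations, temperatures) is this package's choice and is
#' fully configurable.
#'
#' @param n_restarts number of random restarts per window (default 100).
#' @param n_iter annealing iterations per restart (default 25000).
#' @param t_start,t_end geometric cooling schedule endpoints (default 10 to
#'   0.01; must be decreasing).
#' @param move_weights probabilities over the six proposal moves
#'   `replace` (leaf SNP), `flip` (leaf allele), `toggle` (operator),
#'   `grow` (add leaf, capped at 3), `prune` (remove leaf), and `reshape`
#'   (re-draw which leaf of a 3-leaf tree sits outside the inner pair,
#'   together with both operators). The reshape move makes re-association
#'   a single step; without it the annealer must cross large deviance
#'   barriers to rearrange a tree that already holds the right SNPs.
#' @param seed master seed; restart and permutation seeds are derived from it
#'   deterministically per (window id, restart index).
#' @param min_leaves smallest distinct-SNP count a reported best tree may
#'   have (default 3: only 3-SNP haplotypes are reported; the search itself
#'   also visits 1- and 2-leaf states).
#' @param perm_restarts restarts used inside permutation re-searches
#'   (default: same as `n_restarts`).
#' @return a `search_config` list.
#' @export
search_config <- function(n_restarts = 100L, n_iter = 25000L,
                          t_start = 10, t_end = 0.01,
                          move_weights = c(replace = 0.30, flip = 0.15,
                                           toggle = 0.10, grow = 0.15,
                                           prune = 0.10, reshape = 0.20),
                          seed = 1L, min_leaves = 3L,
                          perm_restarts = NULL) {
  stopifnot(n_restarts >= 1, n_iter >= 1, t_start > t_end, t_end > 0,
            length(move_weights) == 6, all(move_weights >= 0),
            sum(move_weights) > 0, min_leaves %in% 1:3)
  structure(list(n_restarts = as.integer(n_restarts),
                 n_iter = as.integer(n_iter),
                 t_start = t_start, t_end = t_end,
                 move_weights = move_weights / sum(move_weights),
                 seed = as.integer(seed), min_leaves = as.integer(min_leaves),
                 perm_restarts = as.integer(perm_restarts %||% n_restarts)),
            class = "search_config")
}

#' Chromosome-level logistic deviance of a haplotype tree
#'
#' Logistic regression of phenotype on the binary tree indicator over the
#' `2N` chromosome observations (each subject's status duplicated onto both
#' copies). With a binary predictor the ML fit is the group proportions, so
#' the residual deviance has a closed form. Chromosomes missing an allele at
#' a leaf SNP are excluded. A constant indicator returns the null deviance
#' with `beta = 0` and flag `"constant"`; perfect separation returns
#' deviance 0 with flag `"separation"`.
#'
#' @param tree a logic tree (leaf SNPs index the cohort's variant table).
#' @param cohort a [phased_cohort()].
#' @return a `hap_fit` list: `tree`, `deviance`, `null_deviance`, `beta`
#'   (log-odds of the indicator; `NA` under separation), `n_used`
#'   (chromosome observations), `flag`.
#' @export
haplotype_deviance <- function(tree, cohort) {
  x <- tree_indicator(tree, cohort$haps)
  y <- chromosome_phenotype(cohort)
  ok <- !is.na(x)
  x <- x[ok]
  y <- y[ok]
  if (!length(y)) stop("no chromosome observations after missingness exclusion")
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    stop("both case and control chromosomes are required")
  bin_dev <- function(k, n) {
    if (n == 0) return(0)
    p <- k / n
    -2 * (ifelse(k > 0, k * log(p), 0) +
            ifelse(n - k > 0, (n - k) * log(1 - p), 0))
  }
  n1 <- sum(x); k1 <- sum(y[x])
  n0 <- sum(!x); k0 <- sum(y[!x])
  null_dev <- bin_dev(k1 + k0, n1 + n0)
  if (n1 == 0 || n0 == 0) {
    fit <- list(deviance = null_dev, beta = 0, flag = "constant")
  } else {
    dev <- bin_dev(k1, n1) + bin_dev(k0, n0)
    sep1 <- k1 %in% c(0L, n1)
    sep0 <- k0 %in% c(0L, n0)
    beta <- if (sep1 || sep0) NA_real_
      else log(k1 / (n1 - k1)) - log(k0 / (n0 - k0))
    flag <- if (sep1 && sep0) "separation" else "ok"
    fit <- list(deviance = dev, beta = beta, flag = flag)
  }
  structure(c(list(tree = tree), fit,
              list(null_deviance = null_dev, n_used = n1 + n0,
                   counts = c(n1 = n1, k1 = k1, n0 = n0, k0 = k0))),
            class = "hap_fit")
}

#' @exportS3Method base::print
print.hap_fit <- function(x, ...) {
  cat("hap_fit:", format_tree(x$tree), "\n  deviance",
      formatC(x$deviance, digits = 6, format = "f"),
      "(null", formatC(x$null_deviance, digits = 6, format = "f"),
      ") on", x$n_used, "chromosomes; flag:", x$flag, "\n")
  invisible(x)
}

# Run the compiled multi-restart annealer on one window; returns the best
# tree per restart (any size, and 3-leaf specifically) in global SNP indices.
run_sa <- function(cohort, window, config, seeds,
                   phenotype = NULL) {
  snps <- window$snp_indices_pruned
  haps <- cohort$haps[, snps, drop = FALSE]
  y <- if (is.null(phenotype)) chromosome_phenotype(cohort)
       else rep(as.integer(phenotype), each = 2L)
  res <- .sa_search_cpp(haps, y, as.integer(seeds), config$n_iter,
                        config$t_start, config$t_end,
                        as.numeric(config$move_weights))
  decode <- function(row, dev) {
    if (is.na(dev)) return(NULL)
    nl <- row[1]
    loc <- row[2:4][seq_len(nl)] + 1L
    tree_from_flat(nl, snps[loc], row[5:7][seq_len(nl)], row[8], row[9])
  }
  list(
    any = lapply(seq_along(seeds), function(r)
      list(tree = decode(res$tree_any[r, ], res$dev_any[r]),
           deviance = res$dev_any[r])),
    three = lapply(seq_along(seeds), function(r)
      list(tree = decode(res$tree3[r, ], res$dev3[r]),
           deviance = res$dev3[r])))
}

pick_best <- function(fits) {
  devs <- vapply(fits, function(f) f$deviance %||% NA_real_, numeric(1))
  if (all(is.na(devs))) return(NULL)
  dmin <- min(devs, na.rm = TRUE)
  cand <- which(!is.na(devs) & devs <= dmin + 1e-9)
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(i) canonical_key(fits[[i]]$tree),
                   character(1))
    cand <- cand[order(keys, method = "radix")]
  }
  fits[[cand[1]]]
}

#' One annealing run from a single restart seed
#'
#' Starts from a random one-leaf tree, proposes moves from the configured
#' move set, accepts with probability `min(1, exp(-delta_D / T))` under the
#' geometric schedule, and returns the best state visited. Bit-identical
#' across runs for a fixed `restart_seed`.
#'
#' @param cohort a [phased_cohort()].
#' @param window a pruned `gene_window`.
#' @param config a [search_config()].
#' @param restart_seed integer seed for this trajectory.
#' @return a `hap_fit` for the best visited tree with at least
#'   `config$min_leaves` leaves (`NULL` if no such state was visited).
#' @export
anneal_once <- function(cohort, window, config = search_config(),
                        restart_seed = config$seed) {
  res <- run_sa(cohort, window, config, restart_seed)
  pool <- if (config$min_leaves >= 3L) res$three else res$any
  best <- pick_best(pool)
  if (is.null(best)) return(NULL)
  fit <- haplotype_deviance(best$tree, cohort)
  fit$window_id <- window$window_id
  fit
}

#' Multi-restart search for a window's best haplotype tree
#'
#' Runs `config$n_restarts` independent annealing trajectories (seeds derived
#' from the master seed, window id and restart index) and returns the
#' minimum-deviance tree, ties broken by canonical-key order. With the
#' default `min_leaves = 3` the reported best is the best tree over three
#' distinct SNPs, matching the 3-SNP haplotype definition.
#'
#' @inheritParams anneal_once
#' @param phenotype optional replacement phenotype vector (one entry per
#'   subject), used by the permutation machinery.
#' @return a `hap_fit` with `window_id` and `restart_deviances` attached, or
#'   `NULL` when no tree of the required size is reachable (e.g. fewer than
#'   three pruned SNPs).
#' @export
search_window <- function(cohort, window, config = search_config(),
                          phenotype = NULL) {
  stopifnot(length(window$snp_indices_pruned) >= 2)
  seeds <- vapply(seq_len(config$n_restarts), function(r)
    derive_seed(config$seed, window$window_id, r), integer(1))
  res <- run_sa(cohort, window, config, seeds, phenotype = phenotype)
  pool <- if (config$min_leaves >= 3L) res$three else res$any
  best <- pick_best(pool)
  if (is.null(best)) return(NULL)
  coh <- cohort
  if (!is.null(phenotype)) coh$subjects$phenotype <- as.integer(phenotype)
  fit <- haplotype_deviance(best$tree, coh)
  fit$window_id <- window$window_id
  fit$restart_deviances <- vapply(pool, function(f)
    f$deviance %||% NA_real_, numeric(1))
  fit
}

#' Exhaustive search over all canonical trees of a window
#'
#' Enumerates every structurally distinct tree with `min_leaves` to 3 leaves
#' over the pruned SNPs and scores each with the closed-form chromosome-level
#' deviance. Feasible for small windows; the global optimum it returns is the
#' reference the annealer is expected to attain.
#'
#' @inheritParams anneal_once
#' @param min_leaves smallest leaf count to enumerate (default 3).
#' @return a `hap_fit` for the global minimum (canonical-key tie-break).
#' @export
search_window_exhaustive <- function(cohort, window, min_leaves = 3L) {
  snps <- window$snp_indices_pruned
  trees <- enumerate_trees(snps, n_leaves = seq(min_leaves, 3L))
  if (!length(trees)) return(NULL)
  haps <- cohort$haps[, snps, drop = FALSE]
  y <- chromosome_phenotype(cohort)
  loc <- function(s) match(s, snps) - 1L
  devs <- vapply(trees, function(tr) {
    fl <- tree_to_flat(tr)
    .tree_deviance_cpp(haps, y, fl$nl, loc(fl$snps), as.integer(fl$als),
                       fl$op_in, fl$op_out)
  }, numeric(1))
  dmin <- min(devs)
  cand <- which(devs <= dmin + 1e-9)
  if (length(cand) > 1L) {
    keys <- vapply(trees[cand], canonical_key, character(1))
    cand <- cand[order(keys, method = "radix")]
  }
  fit <- haplotype_deviance(trees[[cand[1]]], cohort)
  fit$window_id <- window$window_id
  fit
}
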