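# Boolean haplotype trees: AND/OR combinations of (SNP, allele) literals
# evaluated per chromosome copy. For biallelic SNPs (SNP = ref) is the
# negation of (SNP = alt), so explicit NOT nodes are unnecessary and not
# represented.

#' Logic-tree literal
#'
#' A literal `(SNP = allele)` evaluated on one haplotype.
#'
#' @param snp variant column index (into the cohort's variant table).
#' @param allele matched allele: 0 (reference) or 1 (alternative).
#' @return a leaf node.
#' @export
lt_leaf <- function(snp, allele) {
  stopifnot(allele %in% c(0L, 1L))
  structure(list(snp = as.integer(snp), allele = as.integer(allele)),
            class = "lt_leaf")
}

lt_node <- function(op, children) {
  stopifnot(op %in% c("and", "or"), length(children) >= 2)
  structure(list(op = op, children = children), class = "lt_node")
}

#' @rdname lt_leaf
#' @param ... child nodes (leaves or nested nodes).
#' @export
lt_and <- function(...) lt_node("and", list(...))

#' @rdname lt_leaf
#' @export
lt_or <- function(...) lt_node("or", list(...))

#' Collect the leaves of a tree
#'
#' @param tree a logic tree.
#' @return list of `lt_leaf` nodes, left-to-right.
#' @export
tree_leaves <- function(tree) {
  if (inherits(tree, "lt_leaf")) return(list(tree))
  do.call(c, lapply(tree$children, tree_leaves))
}

#' @rdname tree_leaves
#' @return `tree_snps()`: integer vector of leaf SNP indices.
#' @export
tree_snps <- function(tree) {
  vapply(tree_leaves(tree), function(l) l$snp, integer(1))
}

#' Evaluate a tree on every chromosome row of a haplotype matrix
#'
#' Standard Boolean semantics; a chromosome missing an allele at any leaf SNP
#' yields `NA` (missingness always propagates, it is never short-circuited
#' away by an OR).
#'
#' @param tree a logic tree.
#' @param hapmat 0/1/`NA` matrix, chromosomes by variants.
#' @return logical vector with one entry per chromosome row.
#' @export
tree_indicator <- function(tree, hapmat) {
  ev <- function(node) {
    if (inherits(node, "lt_leaf"))
      return(hapmat[, node$snp] == node$allele)
    vals <- lapply(node$children, ev)
    Reduce(if (node$op == "and") `&` else `|`, vals)
  }
  out <- ev(tree)
  snps <- unique(tree_snps(tree))
  miss <- rowSums(is.na(hapmat[, snps, drop = FALSE])) > 0L
  out[miss] <- NA
  out
}

#' @rdname tree_indicator
#' @param haplotype a single 0/1/`NA` allele vector.
#' @return `tree_evaluate()`: a single logical.
#' @export
tree_evaluate <- function(tree, haplotype) {
  tree_indicator(tree, matrix(haplotype, nrow = 1))[1]
}

#' Per-subject haplotype copy count
#'
#' The number of a subject's two chromosome copies satisfying the tree:
#' `L` in `{0, 1, 2}`, or `NA` when either copy is missing an allele at a
#' leaf SNP (such subjects are dropped from the additive association model).
#'
#' @param tree a logic tree.
#' @param cohort a [phased_cohort()] (or a bare haplotype matrix with an even
#'   number of rows).
#' @return integer vector, one entry per subject.
#' @export
copy_count <- function(tree, cohort) {
  hapmat <- if (inherits(cohort, "phased_cohort")) cohort$haps else cohort
  stopifnot(nrow(hapmat) %% 2L == 0L)
  ind <- tree_indicator(tree, hapmat)
  n <- nrow(hapmat) / 2L
  as.integer(ind[seq(1L, 2L * n, 2L)]) + as.integer(ind[seq(2L, 2L * n, 2L)])
}

#' Canonical structural key of a tree
#'
#' Commutative operands are sorted (by SNP index then allele) and chains of
#' the same operator are flattened, so two trees get the same key exactly
#' when they are the same tree up to commutativity/associativity. Used for
#' cross-window deduplication, which is structural ("exact SNP and logic
#' tree structure match"), not truth-table equivalence.
#'
#' @param tree a logic tree.
#' @return character key.
#' @export
canonical_key <- function(tree) {
  if (inherits(tree, "lt_leaf"))
    return(sprintf("s%da%d", tree$snp, tree$allele))
  flat <- list()
  for (ch in tree$children) {
    if (inherits(ch, "lt_node") && ch$op == tree$op)
      flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  keys <- sort(vapply(flat, canonical_key, character(1)), method = "radix")
  paste0("(", tree$op, ":", paste(keys, collapse = ","), ")")
}

#' Render a tree as text
#'
#' Mirrors the usual published form, e.g.
#' `"(rs3129881 = C) or ((rs375244 = A) and (rs3132947 = G))"`. When a
#' variant table is supplied, rsIDs and allele letters are resolved from it;
#' otherwise literals print as `(s12 = 1)`.
#'
#' @param tree a logic tree.
#' @param variants optional variant table (`id`, `ref`, `alt`).
#' @return character scalar.
#' @export
format_tree <- function(tree, variants = NULL) {
  leaf_txt <- function(l) {
    if (is.null(variants))
      sprintf("(s%d = %d)", l$snp, l$allele)
    else
      sprintf("(%s = %s)", variants$id[l$snp],
              if (l$allele == 1) variants$alt[l$snp] else variants$ref[l$snp])
  }
  render <- function(node, top) {
    if (inherits(node, "lt_leaf")) return(leaf_txt(node))
    parts <- vapply(node$children, render, character(1), top = FALSE)
    txt <- paste(parts, collapse = paste0(" ", node$op, " "))
    if (top) txt else paste0("(", txt, ")")
  }
  render(tree, top = TRUE)
}

# Flat encoding used by the C++ search: (nl, snp[3], al[3], op_in, op_out)
# with shape leaf / (l0 op_out l1) / ((l0 op_in l1) op_out l2).
tree_from_flat <- function(nl, snps, als, op_in, op_out) {
  ops <- c("and", "or")
  leaf <- function(j) lt_leaf(snps[j], als[j])
  if (nl == 1) return(leaf(1))
  if (nl == 2) return(lt_node(ops[op_out + 1], list(leaf(1), leaf(2))))
  inner <- lt_node(ops[op_in + 1], list(leaf(1), leaf(2)))
  lt_node(ops[op_out + 1], list(inner, leaf(3)))
}

tree_to_flat <- function(tree) {
  op_code <- function(op) if (op == "or") 1L else 0L
  if (inherits(tree, "lt_leaf"))
    return(list(nl = 1L, snps = tree$snp, als = tree$allele,
                op_in = 0L, op_out = 0L))
  # flatten same-op chains first so ((a and b) and c) becomes a 3-chain
  flat <- list()
  for (ch in tree$children) {
    if (inherits(ch, "lt_node") && ch$op == tree$op)
      flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  is_leaf <- vapply(flat, inherits, logical(1), what = "lt_leaf")
  leaves <- tree_leaves(tree)
  if (length(leaves) > 3L) stop("trees with more than 3 leaves not supported")
  if (all(is_leaf)) {
    snps <- vapply(flat, `[[`, integer(1), "snp")
    als <- vapply(flat, `[[`, integer(1), "allele")
    k <- length(flat)
    return(list(nl = as.integer(k), snps = snps, als = als,
                op_in = op_code(tree$op), op_out = op_code(tree$op)))
  }
  if (length(flat) != 2L || sum(is_leaf) != 1L)
    stop("unsupported tree shape")
  inner <- flat[[which(!is_leaf)]]
  outer_leaf <- flat[[which(is_leaf)]]
  inner_leaves <- tree_leaves(inner)
  if (length(inner_leaves) != 2L) stop("unsupported tree shape")
  list(nl = 3L,
       snps = c(inner_leaves[[1]]$snp, inner_leaves[[2]]$snp,
                outer_leaf$snp),
       als = c(inner_leaves[[1]]$allele, inner_leaves[[2]]$allele,
               outer_leaf$allele),
       op_in = op_code(inner$op), op_out = op_code(tree$op))
}

#' Enumerate all canonical trees over a SNP set
#'
#' Generates every structurally distinct AND/OR tree with the requested leaf
#' counts over distinct SNPs from `snps`, deduplicated by [canonical_key()].
#' Intended for exact search on small windows and for oracle checks.
#'
#' @param snps vector of variant column indices.
#' @param n_leaves leaf counts to include (subset of `1:3`).
#' @return list of logic trees.
#' @export
enumerate_trees <- function(snps, n_leaves = 3L) {
  snps <- sort(unique(as.integer(snps)))
  out <- list()
  if (1L %in% n_leaves) {
    for (s in snps) for (a in 0:1) out <- c(out, list(lt_leaf(s, a)))
  }
  if (2L %in% n_leaves && length(snps) >= 2) {
    prs <- utils::combn(snps, 2)
    for (i in seq_len(ncol(prs))) {
      for (a1 in 0:1) for (a2 in 0:1) for (op in c("and", "or")) {
        out <- c(out, list(lt_node(op, list(lt_leaf(prs[1, i], a1),
                                            lt_leaf(prs[2, i], a2)))))
      }
    }
  }
  if (3L %in% n_leaves && length(snps) >= 3) {
    trs <- utils::combn(snps, 3)
    for (i in seq_len(ncol(trs))) {
      s <- trs[, i]
      for (a1 in 0:1) for (a2 in 0:1) for (a3 in 0:1) {
        als <- c(a1, a2, a3)
        for (op in c("and", "or")) {  # flat 3-chains
          out <- c(out, list(lt_node(op, list(lt_leaf(s[1], als[1]),
                                              lt_leaf(s[2], als[2]),
                                              lt_leaf(s[3], als[3])))))
        }
        for (outer_j in 1:3) {        # mixed (a op_in b) op_out c
          inn <- setdiff(1:3, outer_j)
          for (op_in in c("and", "or")) {
            op_out <- setdiff(c("and", "or"), op_in)
            inner <- lt_node(op_in, list(lt_leaf(s[inn[1]], als[inn[1]]),
                                         lt_leaf(s[inn[2]], als[inn[2]])))
            out <- c(out, list(lt_node(op_out,
                                       list(inner, lt_leaf(s[outer_j],
                                                           als[outer_j])))))
          }
        }
      }
    }
  }
  keys <- vapply(out, canonical_key, character(1))
  out[!duplicated(keys)]
}
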