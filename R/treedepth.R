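# Per-locus gene-tree depth.
#
# Each locus's distinct alleles are related by neighbor-joining on the
# Jukes-Cantor distance matrix, midpoint-rooted (the loci have no
# outgroup), and the depth is the longest root-to-tip path in expected
# substitutions per site. Monomorphic loci have depth 0 by definition.

#' Gene tree and depth of one locus
#'
#' @param seqs allele copies at the locus (duplicates are removed).
#' @return list with `n_alleles`, `depth` (substitutions per site; `NA`
#'   when any allele pair is saturated, p >= 3/4), and `tree` (a `phylo`
#'   for three or more distinct alleles, else NULL).
#' @export
#' @examples
#' locus_tree(c(strrep("A", 100), strrep("A", 100)))$depth  # 0
locus_tree <- function(seqs) {
  alleles <- sort(unique(seqs))
  n <- length(alleles)
  if (n == 0L) stop("no alleles supplied")
  if (n == 1L) return(list(n_alleles = 1L, depth = 0, tree = NULL))
  L <- nchar(alleles[1L])
  P <- pairwise_hamming(alleles) / L
  if (any(P[upper.tri(P)] >= 0.75)) {
    return(list(n_alleles = n, depth = NA_real_, tree = NULL))
  }
  D <- -0.75 * log(1 - 4 * P / 3)
  if (n == 2L) {
    return(list(n_alleles = 2L, depth = D[1L, 2L] / 2, tree = NULL))
  }
  dimnames(D) <- list(paste0("a", seq_len(n)), paste0("a", seq_len(n)))
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  depth <- max(ape::node.depth.edgelength(tr))
  list(n_alleles = n, depth = depth, tree = tr)
}

#' Mean gene-tree depth over a random subsample of loci
#'
#' Depths are averaged over a seeded uniform subsample of loci without
#' replacement (all loci when fewer than `n_sample`); monomorphic loci
#' contribute depth 0 and saturated loci are skipped.
#'
#' @param x a `rad_assembly` or a copy table.
#' @param n_sample number of loci to sample (default 1000).
#' @param seed sampling seed.
#' @return list with `mean_depth`, `n_loci` used, `n_saturated`, and the
#'   per-locus `depths` (named by locus).
#' @export
mean_tree_depth <- function(x, n_sample = 1000L, seed = 1L) {
  tab <- if (inherits(x, "rad_assembly")) allele_table(x) else x
  groups <- locus_groups(tab)
  set.seed(seed)
  if (length(groups) > n_sample) {
    groups <- groups[sort(sample.int(length(groups), n_sample))]
  }
  depths <- vapply(groups, function(g) locus_tree(g$sequence)$depth,
                   numeric(1))
  n_sat <- sum(is.na(depths))
  list(mean_depth = mean(depths, na.rm = TRUE),
       n_loci = sum(!is.na(depths)), n_saturated = n_sat,
       depths = depths)
}
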