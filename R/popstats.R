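# Population-genetic summaries over an allele table.
#
# All functions consume a "copy table": one row per allele copy with
# columns locus, individual, population, sequence (two copies per diploid
# per locus). Both the assembler (allele_table) and the simulator
# (true_allele_table) emit this shape, so every statistic can be computed
# on assembled data and on ground truth alike.

#' Proportion of differing sites between two sequences
#'
#' @param a,b equal-length sequences.
#' @return p-distance in [0, 1].
#' @export
#' @examples
#' p_distance(strrep("A", 100), paste0(strrep("A", 99), "T"))  # 0.01
p_distance <- function(a, b) {
  hamming(a, b) / nchar(a)
}

#' Jukes-Cantor correction of a p-distance
#'
#' `d = -(3/4) log(1 - 4p/3)`; saturated inputs (p >= 3/4, where the
#' correction is undefined) return `NA` and are excluded from means by the
#' callers rather than clamped.
#'
#' @param p p-distance(s).
#' @return corrected distance(s) in substitutions per site; `NA` when
#'   saturated.
#' @export
#' @examples
#' jc_distance(0.01)
jc_distance <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p must lie in [0, 1]")
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Pairwise Hamming distance matrix over a small set of sequences.
pairwise_hamming <- function(seqs) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0, 0, 0))
  X <- one_hot_block(seq_matrix(seqs))
  nchar(seqs[1L]) - crossprod(X)
}

locus_groups <- function(tab) split(tab, tab$locus)

#' Mean distance between two individuals at one locus
#'
#' The average of the metric over all allele-copy pairs (one copy from each
#' individual); a homozygote contributes its single allele twice, so a
#' diploid pair always averages 2 x 2 comparisons.
#'
#' @param locus_tab copy-table rows for one locus.
#' @param ind_i,ind_j individual identifiers.
#' @param metric `"p"` or `"jc"`.
#' @return mean per-site distance, or `NA` if either individual is not
#'   genotyped at the locus (or the mean is saturated under `"jc"`).
#' @export
individual_pair_distance <- function(locus_tab, ind_i, ind_j,
                                     metric = c("p", "jc")) {
  metric <- match.arg(metric)
  ai <- locus_tab$sequence[locus_tab$individual == ind_i]
  aj <- locus_tab$sequence[locus_tab$individual == ind_j]
  if (length(ai) == 0L || length(aj) == 0L) return(NA_real_)
  L <- nchar(ai[1L])
  d <- outer(ai, aj, Vectorize(function(a, b) hamming(a, b))) / L
  p <- mean(d)
  if (metric == "jc") jc_distance(p) else p
}

#' Pairwise genetic distances between all individuals
#'
#' Per unordered pair of individuals: the per-locus distance of
#' [individual_pair_distance()] averaged over the loci at which both are
#' genotyped; p and Jukes-Cantor versions are both reported. The JC
#' correction is applied per locus and saturated loci are dropped from the
#' JC mean (and counted).
#'
#' @param tab a copy table (see [allele_table()]).
#' @return data.frame with one row per pair: `ind_i`, `ind_j`, `n_loci`,
#'   `p_mean`, `jc_mean`, `n_saturated`.
#' @export
pair_distances <- function(tab) {
  inds <- sort(unique(tab$individual))
  groups <- locus_groups(tab)
  L <- nchar(tab$sequence[1L])
  # per locus, full copy-level distance matrix once
  per_locus <- lapply(groups, function(g) {
    D <- pairwise_hamming(g$sequence) / L
    list(ind = g$individual, D = D)
  })
  pairs <- utils::combn(inds, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    p_loc <- vapply(per_locus, function(pl) {
      ri <- which(pl$ind == i); rj <- which(pl$ind == j)
      if (length(ri) == 0L || length(rj) == 0L) return(NA_real_)
      mean(pl$D[ri, rj, drop = FALSE])
    }, numeric(1))
    p_loc <- p_loc[!is.na(p_loc)]
    jc_loc <- jc_distance(p_loc)
    data.frame(ind_i = i, ind_j = j, n_loci = length(p_loc),
               p_mean = mean(p_loc),
               jc_mean = mean(jc_loc, na.rm = TRUE),
               n_saturated = sum(is.na(jc_loc)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hudson Fst from allele-copy differences
#'
#' Per polymorphic locus, `Fst = 1 - Hw/Hb`, where `Hw` is the mean number
#' of pairwise differences between allele copies sampled within
#' populations (both populations pooled by default) and `Hb` the mean over
#' between-population pairs. Loci that are monomorphic or have `Hb = 0`
#' are excluded; the summary is the mean of per-locus ratios by default.
#'
#' @param tab a copy table.
#' @param hw pool within-population pairs across both populations
#'   (`"pooled"`, default) or average the two per-population means
#'   (`"average"`).
#' @param distinct_only if TRUE, within-population pairs with identical
#'   sequences are excluded from `Hw` (an alternative reading of
#'   "different sequences"); default FALSE counts all draws.
#' @param summary `"mean_of_ratios"` (default) or `"ratio_of_sums"`.
#' @return list with `per_locus` (data.frame `locus`, `Hw`, `Hb`, `fst`)
#'   and `mean_fst`.
#' @export
hudson_fst <- function(tab, hw = c("pooled", "average"),
                       distinct_only = FALSE,
                       summary = c("mean_of_ratios", "ratio_of_sums")) {
  hw <- match.arg(hw)
  summary <- match.arg(summary)
  groups <- locus_groups(tab)
  rows <- lapply(names(groups), function(lid) {
    g <- groups[[lid]]
    pops <- unique(g$population)
    if (length(pops) != 2L) return(NULL)
    if (length(unique(g$sequence)) < 2L) return(NULL)  # monomorphic
    D <- pairwise_hamming(g$sequence)
    in1 <- g$population == pops[1L]
    in2 <- g$population == pops[2L]
    if (sum(in1) < 2L || sum(in2) < 2L) return(NULL)
    within_vals <- function(sel) {
      M <- D[sel, sel, drop = FALSE]
      v <- M[upper.tri(M)]
      if (distinct_only) v <- v[v > 0]
      v
    }
    w1 <- within_vals(in1); w2 <- within_vals(in2)
    Hw <- if (hw == "pooled") {
      if (length(w1) + length(w2) == 0L) return(NULL)
      mean(c(w1, w2))
    } else {
      if (length(w1) == 0L || length(w2) == 0L) return(NULL)
      (mean(w1) + mean(w2)) / 2
    }
    Hb <- mean(D[in1, in2, drop = FALSE])
    data.frame(locus = g$locus[1L], Hw = Hw, Hb = Hb,
               fst = if (Hb > 0) 1 - Hw / Hb else NA_real_)
  })
  per_locus <- do.call(rbind, rows)
  if (is.null(per_locus)) {
    per_locus <- data.frame(locus = integer(0), Hw = numeric(0),
                            Hb = numeric(0), fst = numeric(0))
  }
  ok <- !is.na(per_locus$fst)
  mean_fst <- if (summary == "mean_of_ratios") {
    if (any(ok)) mean(per_locus$fst[ok]) else NA_real_
  } else {
    if (sum(per_locus$Hb[ok]) > 0) {
      1 - sum(per_locus$Hw[ok]) / sum(per_locus$Hb[ok])
    } else NA_real_
  }
  list(per_locus = per_locus, mean_fst = mean_fst)
}

#' Segregating sites of one locus
#'
#' @param seqs allele copies (equal-length strings).
#' @return number of columns with more than one base.
#' @export
segregating_sites <- function(seqs) {
  if (length(seqs) < 2L) return(0L)
  X <- seq_matrix(seqs)
  sum(apply(X, 1L, function(r) length(unique(r)) > 1L))
}

#' Watterson's estimator of theta per site
#'
#' `S / (a_n * L)` summed over loci, with `a_n` the harmonic number of the
#' locus's copy count minus one; with a constant number of copies this is
#' the textbook `S_total / (a_n * L * n_loci)`.
#'
#' @param tab a copy table.
#' @return per-site theta estimate.
#' @export
watterson_theta <- function(tab) {
  groups <- locus_groups(tab)
  L <- nchar(tab$sequence[1L])
  S <- 0; denom <- 0
  for (g in groups) {
    n <- nrow(g)
    if (n < 2L) next
    S <- S + segregating_sites(g$sequence)
    denom <- denom + sum(1 / seq_len(n - 1L)) * L
  }
  if (denom == 0) stop("need at least two copies at some locus")
  S / denom
}

#' Nucleotide diversity (pi) per site
#'
#' Mean pairwise p-distance over allele copies, averaged over loci
#' (equally weighted). With `by_population`, copies are restricted to one
#' population at a time.
#'
#' @param tab a copy table.
#' @param by_population return one value per population.
#' @return numeric scalar, or named vector when `by_population`.
#' @export
nucleotide_diversity <- function(tab, by_population = FALSE) {
  if (by_population) {
    pops <- sort(unique(tab$population))
    return(stats::setNames(
      vapply(pops, function(p) {
        nucleotide_diversity(tab[tab$population == p, , drop = FALSE])
      }, numeric(1)), pops))
  }
  groups <- locus_groups(tab)
  L <- nchar(tab$sequence[1L])
  vals <- vapply(groups, function(g) {
    n <- nrow(g)
    if (n < 2L) return(NA_real_)
    D <- pairwise_hamming(g$sequence)
    mean(D[upper.tri(D)]) / L
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Moment estimator of ancestral theta and divergence time
#'
#' Under the isolation model, the count `K` of differences between one
#' allele copy drawn from each population at a locus of length `L`
#' satisfies `E[K] = L (2 tau + thetaA)` and
#' `Var[K] = L (2 tau + thetaA) + L^2 thetaA^2`: the Poisson mutation noise
#' contributes the mean, and the exponentially distributed ancestral
#' coalescence time contributes the extra `L^2 thetaA^2`. Solving the two
#' moment equations gives `thetaA = sqrt(max(0, var(K) - mean(K))) / L`
#' and `tau = max(0, (mean(K)/L - thetaA) / 2)`. One copy is sampled per
#' population per locus so that the variance relation stays exact
#' (within-locus pairs share a genealogy and would correlate).
#'
#' Contemporary `theta1`/`theta2` are estimated by within-population
#' nucleotide diversity over all copies.
#'
#' @param x a copy table or a `rad_assembly`.
#' @param seed seed for the per-locus copy sampling.
#' @param min_loci below this many informative loci the fit is flagged
#'   low-confidence.
#' @return an object of class `isolation_fit` with `coef()` giving
#'   `theta1`, `theta2`, `thetaA`, `tau`.
#' @export
#' @examples
#' sim <- simulate_rad(sim_params(n_loci = 200, seed = 3))
#' fit <- isolation_moments(true_allele_table(sim), seed = 1)
#' coef(fit)
isolation_moments <- function(x, seed = 1L, min_loci = 50L) {
  tab <- if (inherits(x, "rad_assembly")) allele_table(x) else x
  L <- nchar(tab$sequence[1L])
  pops <- sort(unique(tab$population))
  if (length(pops) != 2L) stop("exactly two populations required")
  groups <- locus_groups(tab)
  set.seed(seed)
  K <- vapply(groups, function(g) {
    s1 <- g$sequence[g$population == pops[1L]]
    s2 <- g$sequence[g$population == pops[2L]]
    if (length(s1) == 0L || length(s2) == 0L) return(NA_real_)
    a <- s1[sample.int(length(s1), 1L)]
    b <- s2[sample.int(length(s2), 1L)]
    as.numeric(hamming(a, b))
  }, numeric(1))
  K <- K[!is.na(K)]
  n_loci <- length(K)
  if (n_loci < 2L) stop("need at least two informative loci")
  m <- mean(K) / L
  v <- stats::var(K)
  disc <- v - mean(K)
  thetaA <- sqrt(max(0, disc)) / L
  tau <- max(0, (m - thetaA) / 2)
  pi_pop <- nucleotide_diversity(tab, by_population = TRUE)
  structure(list(
    coefficients = c(theta1 = unname(pi_pop[pops[1L]]),
                     theta2 = unname(pi_pop[pops[2L]]),
                     thetaA = thetaA, tau = tau),
    floored = disc < 0,
    mean_K = mean(K), var_K = v, n_loci = n_loci, L = L,
    low_confidence = n_loci < min_loci
  ), class = "isolation_fit")
}

#' @export
coef.isolation_fit <- function(object, ...) object$coefficients

#' @export
print.isolation_fit <- function(x, ...) {
  cat("Isolation-model moment estimates (per site)\n")
  print(signif(x$coefficients, 4))
  cat(sprintf("  from %d loci of %d bp (mean K = %.3f, var K = %.3f)\n",
              x$n_loci, x$L, x$mean_K, x$var_K))
  if (x$floored) cat("  note: var(K) < mean(K); thetaA floored at 0\n")
  if (x$low_confidence) cat("  warning: fewer informative loci than",
                            "requested; estimates are low-confidence\n")
  invisible(x)
}
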