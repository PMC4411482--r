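#' Simulation parameters for the two-population isolation model
#'
#' Bundles the study-design and demographic parameters of the synthetic
#' RAD-Seq generator. The design mirrors a typical reduced-representation
#' study of a vertebrate lineage: two populations, four diploid individuals
#' each, 100-bp single-end reads anchored at a restriction site, and
#' per-allele read depths around 10x.
#'
#' Population sizes are mutation-scaled (`theta = 4*Ne*mu` per site) and the
#' divergence time `tau` is in expected substitutions per site per lineage,
#' so all times in the simulator are in mutation units.
#'
#' @param n_loci number of independent loci to simulate.
#' @param L locus (and read) length in bases.
#' @param n_individuals_per_pop diploid individuals sampled per population.
#' @param theta1,theta2 mutation-scaled sizes of the two daughter populations.
#' @param thetaA mutation-scaled size of the ancestral population.
#' @param tau divergence time in expected substitutions per site.
#' @param paralog_fraction proportion of loci carrying a duplicated copy.
#' @param paralog_divergence substitutions per site separating the duplicate
#'   copy's root from the original ancestral sequence.
#' @param depth_mean expected reads per allele copy (Poisson mean).
#' @param error_rate per-base sequencing error probability.
#' @param seed integer seed; all randomness flows from it via per-locus
#'   substreams, so outputs are byte-reproducible.
#' @return an object of class `sim_params`.
#' @export
#' @examples
#' sim_params(n_loci = 100, tau = 0.01)
sim_params <- function(n_loci = 2000L, L = 100L, n_individuals_per_pop = 4L,
                       theta1 = 0.005, theta2 = 0.005, thetaA = 0.005,
                       tau = 0.005, paralog_fraction = 0,
                       paralog_divergence = 0.04, depth_mean = 10,
                       error_rate = 0.005, seed = 1L) {
  stopifnot(n_loci >= 1, L >= 1, n_individuals_per_pop >= 1)
  if (theta1 < 0 || theta2 < 0 || thetaA < 0 || tau < 0 ||
      paralog_divergence < 0 || depth_mean < 0 || error_rate < 0) {
    stop("all rates must be non-negative")
  }
  if (paralog_fraction < 0 || paralog_fraction > 1) {
    stop("paralog_fraction must lie in [0, 1]")
  }
  if (error_rate > 1) stop("error_rate is a probability")
  structure(list(
    n_loci = as.integer(n_loci), L = as.integer(L),
    n_individuals_per_pop = as.integer(n_individuals_per_pop),
    theta1 = theta1, theta2 = theta2, thetaA = thetaA, tau = tau,
    paralog_fraction = paralog_fraction,
    paralog_divergence = paralog_divergence,
    depth_mean = depth_mean, error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Two-population isolation-model simulation parameters\n")
  cat(sprintf("  loci: %d x %d bp; %d diploids per population\n",
              x$n_loci, x$L, x$n_individuals_per_pop))
  cat(sprintf("  theta1 = %g, theta2 = %g, thetaA = %g, tau = %g\n",
              x$theta1, x$theta2, x$thetaA, x$tau))
  cat(sprintf("  paralogs: fraction %g at divergence %g subs/site\n",
              x$paralog_fraction, x$paralog_divergence))
  cat(sprintf("  reads: depth %g per allele, error rate %g/base, seed %d\n",
              x$depth_mean, x$error_rate, x$seed))
  invisible(x)
}

#' Assembly parameters for threshold clustering
#'
#' Parameters of the de novo clustering step: the percent similarity
#' threshold (translated into a mismatch budget on fixed-length reads), the
#' minimum stack depth for an allele to be called, and the maximum number of
#' alleles retained per individual per locus (one above ploidy, so that
#' paralog-contaminated loci are identifiable by their excess alleles).
#'
#' The within-individual and across-individual mismatch budgets are exposed
#' separately but default to the same similarity value, the usual sweep
#' configuration.
#'
#' @param similarity integer percent similarity threshold in (0, 100].
#' @param min_depth minimum reads per stack for the allele to be retained.
#' @param max_alleles alleles retained per individual per locus.
#' @param L locus length in bases.
#' @param catalog_similarity percent threshold for merging loci across
#'   individuals; defaults to `similarity`.
#' @return an object of class `assembly_params`.
#' @export
#' @examples
#' assembly_params(similarity = 95)
assembly_params <- function(similarity = 95L, min_depth = 10L,
                            max_alleles = 3L, L = 100L,
                            catalog_similarity = similarity) {
  if (similarity <= 0 || similarity > 100 ||
      catalog_similarity <= 0 || catalog_similarity > 100) {
    stop("similarity thresholds must lie in (0, 100]")
  }
  stopifnot(min_depth >= 1, max_alleles >= 1, L >= 1)
  structure(list(
    similarity = as.integer(similarity),
    catalog_similarity = as.integer(catalog_similarity),
    min_depth = as.integer(min_depth),
    max_alleles = as.integer(max_alleles),
    L = as.integer(L)
  ), class = "assembly_params")
}

#' @export
print.assembly_params <- function(x, ...) {
  cat(sprintf(
    "Assembly parameters: similarity %d%% (budget %d mismatches/%d bp),\n",
    x$similarity, mismatch_budget(x$similarity, x$L), x$L))
  cat(sprintf("  catalog similarity %d%%, min depth %d, max alleles %d\n",
              x$catalog_similarity, x$min_depth, x$max_alleles))
  invisible(x)
}
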