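# Synthetic RAD-Seq generator under a two-population isolation model.
#
# Times are in mutation units (expected substitutions per site), so a pair
# of lineages inside a population of scaled size theta coalesces at rate
# 2/theta and the expected pairwise TMRCA is theta/2. Sequence evolution is
# finite-sites Jukes-Cantor: multiple hits at a site are possible, matching
# the JC-corrected distances used downstream.

DNA_BASES <- c("A", "C", "G", "T")

#' Simulate a genealogy under the two-population isolation model
#'
#' Runs a Kingman coalescent within each daughter population back to the
#' divergence time `tau`, then merges the surviving lineages into a single
#' ancestral population. Branch lengths are in expected substitutions per
#' site. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param n1,n2 number of sampled gene copies (tips) per population; a
#'   diploid individual contributes two.
#' @param theta1,theta2,thetaA mutation-scaled population sizes.
#' @param tau divergence time in substitutions per site.
#' @return a `genealogy`: list with `parent` and `time` vectors over the
#'   `2*(n1+n2) - 1` nodes (tips first, at time 0), tip population labels,
#'   and the root index.
#' @export
#' @examples
#' set.seed(1)
#' g <- simulate_genealogy(4, 4, 0.005, 0.005, 0.005, tau = 0.01)
#' max(g$time)  # TMRCA, always >= tau for cross-population pairs
simulate_genealogy <- function(n1, n2, theta1, theta2, thetaA, tau) {
  stopifnot(n1 >= 1, n2 >= 1, tau >= 0)
  n_tips <- n1 + n2
  n_nodes <- 2L * n_tips - 1L
  parent <- integer(n_nodes)
  time <- numeric(n_nodes)
  nxt <- n_tips + 1L

  coalesce <- function(active, theta, t0, t_end) {
    t <- t0
    while (length(active) > 1L) {
      k <- length(active)
      if (theta <= 0) stop("non-positive theta for a coalescing population")
      t_wait <- stats::rexp(1L, rate = k * (k - 1) / theta)
      if (t + t_wait > t_end) break
      t <- t + t_wait
      pick <- sample.int(k, 2L)
      parent[active[pick]] <<- nxt
      time[nxt] <<- t
      active <- c(active[-pick], nxt)
      nxt <<- nxt + 1L
    }
    active
  }

  a1 <- if (tau > 0) coalesce(seq_len(n1), theta1, 0, tau) else seq_len(n1)
  a2 <- if (tau > 0) coalesce(n1 + seq_len(n2), theta2, 0, tau)
        else n1 + seq_len(n2)
  root_set <- coalesce(c(a1, a2), thetaA, tau, Inf)

  structure(list(
    parent = parent, time = time, n_tips = n_tips,
    pop = c(rep(1L, n1), rep(2L, n2)), root = root_set[1L]
  ), class = "genealogy")
}

#' Genealogical separation between two tips
#'
#' Total branch length separating two tips (twice the TMRCA on an
#' ultrametric genealogy), in substitutions per site.
#'
#' @param g a `genealogy`.
#' @param i,j tip indices.
#' @return numeric separation.
#' @export
pair_separation <- function(g, i, j) {
  anc_i <- i
  node <- i
  while (node != g$root) {
    node <- g$parent[node]
    anc_i <- c(anc_i, node)
  }
  node <- j
  while (!(node %in% anc_i)) node <- g$parent[node]
  2 * g$time[node]
}

# Apply n_mut JC mutations (uniform site, uniform different base) to an
# integer-coded sequence (values 1..4). Sequential so repeat hits compose.
mutate_seq <- function(s, n_mut) {
  if (n_mut == 0L) return(s)
  sites <- sample.int(length(s), n_mut, replace = TRUE)
  shifts <- sample.int(3L, n_mut, replace = TRUE)
  for (m in seq_len(n_mut)) {
    s[sites[m]] <- (s[sites[m]] - 1L + shifts[m]) %% 4L + 1L
  }
  s
}

int_to_seq <- function(s) intToUtf8(utf8ToInt(paste(DNA_BASES, collapse = ""))[s])

#' Drop mutations on a genealogy to produce tip haplotypes
#'
#' Draws a uniform random root sequence (unless given), then applies a
#' Poisson(branch length x L) number of Jukes-Cantor substitutions along
#' every branch: each mutation hits a uniformly chosen site and changes it
#' to a uniformly chosen different base, so multiple hits can occur.
#'
#' @param g a `genealogy` from [simulate_genealogy()].
#' @param L sequence length in bases.
#' @param root_seq optional integer-coded (1..4) root sequence of length L.
#' @return character vector of `g$n_tips` haplotype strings.
#' @export
drop_mutations <- function(g, L, root_seq = NULL) {
  L <- as.integer(L)
  if (is.null(root_seq)) root_seq <- sample.int(4L, L, replace = TRUE)
  n_nodes <- length(g$parent)
  seqs <- vector("list", n_nodes)
  seqs[[g$root]] <- root_seq
  # parents are created after children, so descending index order works
  for (node in seq(n_nodes, 1L)) {
    if (node == g$root || is.null(seqs[[g$parent[node]]])) next
    blen <- g$time[g$parent[node]] - g$time[node]
    seqs[[node]] <- mutate_seq(seqs[[g$parent[node]]],
                               stats::rpois(1L, blen * L))
  }
  vapply(seqs[seq_len(g$n_tips)], int_to_seq, character(1))
}

#' Simulate sequencing reads from a set of haplotypes
#'
#' Per haplotype, the read count is Poisson(`depth_mean`) and each read is
#' the haplotype with independent per-base substitution errors at
#' `error_rate` (to a uniformly chosen different base).
#'
#' @param haplotypes character vector of equal-length haplotypes.
#' @param depth_mean expected reads per haplotype.
#' @param error_rate per-base error probability.
#' @return data.frame with columns `haplotype` (index into input) and
#'   `sequence`.
#' @export
generate_reads <- function(haplotypes, depth_mean, error_rate) {
  stopifnot(depth_mean > 0, error_rate >= 0, error_rate <= 1)
  counts <- stats::rpois(length(haplotypes), depth_mean)
  hap_idx <- rep(seq_along(haplotypes), counts)
  seqs <- haplotypes[hap_idx]
  if (error_rate > 0 && length(seqs)) {
    L <- nchar(haplotypes[1L])
    n_err <- stats::rbinom(length(seqs), L, error_rate)
    for (r in which(n_err > 0L)) {
      s <- utf8ToInt(seqs[r])
      sites <- sample.int(L, n_err[r])
      for (p in sites) {
        b <- match(s[p], DNA_CODES)
        s[p] <- DNA_CODES[(b - 1L + sample.int(3L, 1L)) %% 4L + 1L]
      }
      seqs[r] <- intToUtf8(s)
    }
  }
  data.frame(haplotype = hap_idx, sequence = seqs)
}

# Individual labels and the tip pair backing each diploid.
sim_individuals <- function(n_per_pop) {
  ind <- c(sprintf("pop1_ind%d", seq_len(n_per_pop)),
           sprintf("pop2_ind%d", seq_len(n_per_pop)))
  data.frame(
    individual = ind,
    population = rep(c("pop1", "pop2"), each = n_per_pop),
    tip1 = seq(1L, 4L * n_per_pop, by = 2L),
    tip2 = seq(2L, 4L * n_per_pop, by = 2L)
  )
}

#' Simulate a full synthetic RAD-Seq dataset with known truth
#'
#' Orchestrates the generator: per locus, a genealogy under the isolation
#' model, Jukes-Cantor mutations, an optional duplicated (paralogous) copy
#' with its own independent genealogy rooted at a mutated version of the
#' original ancestral sequence, and error-bearing reads at the requested
#' depth. Each locus consumes its own deterministic RNG substream derived
#' from `params$seed`, so increasing `n_loci` does not reshuffle earlier
#' loci.
#'
#' With `depth_mean = 0` no reads are generated (truth-only simulation,
#' useful for calibrating the model without assembly noise).
#'
#' @param params a [sim_params()] object.
#' @return an object of class `rad_sim`: list with `params`, `popmap`
#'   (individual/population data.frame), `loci` (per-locus truth: haplotype
#'   vectors per copy, genealogy TMRCA, paralog flag) and `reads` (one row
#'   per read with truth tags: `read_id`, `individual`, `population`,
#'   `locus`, `copy`, `haplotype`, `sequence`).
#' @export
#' @examples
#' sim <- simulate_rad(sim_params(n_loci = 5, seed = 42))
#' head(sim$reads)
simulate_rad <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  n_per_pop <- p$n_individuals_per_pop
  n_copies <- 2L * n_per_pop  # gene copies per population
  inds <- sim_individuals(n_per_pop)
  tip_ind <- rep(inds$individual, each = 2L)
  tip_pop <- rep(inds$population, each = 2L)

  set.seed(p$seed)
  locus_seeds <- sample.int(.Machine$integer.max, p$n_loci)

  loci <- vector("list", p$n_loci)
  read_chunks <- vector("list", p$n_loci)
  for (l in seq_len(p$n_loci)) {
    set.seed(locus_seeds[l])
    g <- simulate_genealogy(n_copies, n_copies, p$theta1, p$theta2,
                            p$thetaA, p$tau)
    root_seq <- sample.int(4L, p$L, replace = TRUE)
    haps <- drop_mutations(g, p$L, root_seq = root_seq)
    copies <- list(haps)
    is_paralog <- p$paralog_fraction > 0 && stats::runif(1L) < p$paralog_fraction
    if (is_paralog) {
      copies[[2L]] <- add_paralog(root_seq, p)
    }
    loci[[l]] <- list(haplotypes = copies, tmrca = max(g$time),
                      paralog = is_paralog)
    chunk <- vector("list", length(copies))
    for (cp in if (p$depth_mean > 0) seq_along(copies) else integer(0)) {
      rd <- generate_reads(copies[[cp]], p$depth_mean, p$error_rate)
      if (nrow(rd)) {
        chunk[[cp]] <- data.frame(
          individual = tip_ind[rd$haplotype],
          population = tip_pop[rd$haplotype],
          locus = l, copy = cp,
          haplotype = rd$haplotype,
          sequence = rd$sequence
        )
      }
    }
    read_chunks[[l]] <- do.call(rbind, chunk)
  }
  reads <- do.call(rbind, read_chunks)
  if (is.null(reads)) {
    reads <- data.frame(individual = character(0), population = character(0),
                        locus = integer(0), copy = integer(0),
                        haplotype = integer(0), sequence = character(0))
  }
  reads <- cbind(read_id = sprintf("r%07d", seq_len(nrow(reads))), reads)
  rownames(reads) <- NULL
  structure(list(params = p, popmap = inds[, c("individual", "population")],
                 loci = loci, reads = reads),
            class = "rad_sim")
}

#' Simulate a duplicated (paralogous) locus copy
#'
#' The duplicate's root is the original ancestral sequence mutated by a
#' Poisson(`paralog_divergence` x L) number of substitutions; the copy then
#' evolves on its own independent isolation-model genealogy, so individuals
#' carry up to four distinct haplotypes at the locus.
#'
#' @param root_seq integer-coded (1..4) ancestral sequence of the original.
#' @param params a [sim_params()] object.
#' @return character vector of duplicate-copy haplotypes (one pair per
#'   individual).
#' @export
add_paralog <- function(root_seq, params) {
  p <- params
  if (p$paralog_divergence < 0) stop("paralog_divergence must be >= 0")
  n_copies <- 2L * p$n_individuals_per_pop
  dup_root <- mutate_seq(root_seq,
                         stats::rpois(1L, p$paralog_divergence * p$L))
  g2 <- simulate_genealogy(n_copies, n_copies, p$theta1, p$theta2,
                           p$thetaA, p$tau)
  drop_mutations(g2, p$L, root_seq = dup_root)
}

#' @export
print.rad_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic RAD-Seq dataset: %d loci x %d bp, %d individuals, %d reads\n",
    x$params$n_loci, x$params$L, nrow(x$popmap), nrow(x$reads)))
  cat(sprintf("  paralogous loci: %d; seed %d\n",
              sum(vapply(x$loci, `[[`, logical(1), "paralog")),
              x$params$seed))
  invisible(x)
}

#' True allele table of a simulated dataset
#'
#' One row per haplotype copy per individual per locus: the ground-truth
#' analog of the assembled allele table, used for simulator calibration and
#' estimator validation without assembly noise.
#'
#' @param sim a `rad_sim`.
#' @param copies which locus copies to include (default primary copy only).
#' @return data.frame with columns `locus`, `individual`, `population`,
#'   `sequence`.
#' @export
true_allele_table <- function(sim, copies = 1L) {
  inds <- sim_individuals(sim$params$n_individuals_per_pop)
  tip_ind <- rep(inds$individual, each = 2L)
  tip_pop <- rep(inds$population, each = 2L)
  chunks <- list()
  for (l in seq_along(sim$loci)) {
    for (cp in intersect(copies, seq_along(sim$loci[[l]]$haplotypes))) {
      haps <- sim$loci[[l]]$haplotypes[[cp]]
      chunks[[length(chunks) + 1L]] <- data.frame(
        locus = l, individual = tip_ind, population = tip_pop,
        sequence = haps
      )
    }
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  out
}
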