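# Distances, Hudson Fst, diversity estimators and the isolation-model
# moment estimator, against enumeration oracles.

copy_table <- function(locus, individual, population, sequence) {
  data.frame(locus = locus, individual = individual,
             population = population, sequence = sequence)
}

# two copies per individual; seqs is a list: individual -> c(a1, a2)
diploid_locus <- function(seqs, pops, locus = 1L) {
  do.call(rbind, lapply(names(seqs), function(ind) {
    copy_table(locus, ind, pops[[ind]], seqs[[ind]])
  }))
}

test_that("p-distance counts mismatches per site", {
  a <- strrep("A", 100)
  expect_identical(p_distance(a, a), 0)
  b <- paste0("T", strrep("A", 99))
  expect_equal(p_distance(a, b), 0.01)
  expect_error(p_distance(a, "AA"), "length")
  set.seed(61)
  for (k in 1:25) {
    x <- random_seqs(2, 37)
    expect_equal(p_distance(x[1], x[2]), brute_hamming(x[1], x[2]) / 37)
  }
})

test_that("Jukes-Cantor correction matches the closed form and dominates p", {
  expect_identical(jc_distance(0), 0)
  expect_equal(jc_distance(0.01), 0.01006727, tolerance = 1e-6)
  expect_true(is.na(jc_distance(0.75)))
  expect_true(is.na(jc_distance(0.8)))
  p <- seq(0.001, 0.74, by = 0.01)
  d <- jc_distance(p)
  expect_true(all(d > p))
  expect_error(jc_distance(-0.1), "0, 1")
})

test_that("individual pair distance averages the four allele comparisons", {
  a <- strrep("A", 50)
  b <- mut_at(a, 1:5)
  tab <- diploid_locus(list(i = c(a, b), j = c(a, a)),
                       c(i = "pop1", j = "pop1"))
  # pairs: (a,a), (a,a), (b,a), (b,a) -> mean = d(a,b)/2
  expect_equal(individual_pair_distance(tab, "i", "j"), (5 / 50) / 2)
  hom <- diploid_locus(list(i = c(a, a), j = c(a, a)),
                       c(i = "pop1", j = "pop1"))
  expect_identical(individual_pair_distance(hom, "i", "j"), 0)
  expect_true(is.na(individual_pair_distance(tab, "i", "missing")))
  set.seed(62)
  for (k in 1:20) {
    s <- random_seqs(4, 30)
    t2 <- diploid_locus(list(i = s[1:2], j = s[3:4]),
                        c(i = "pop1", j = "pop2"))
    want <- mean(c(brute_hamming(s[1], s[3]), brute_hamming(s[1], s[4]),
                   brute_hamming(s[2], s[3]), brute_hamming(s[2], s[4]))) / 30
    expect_equal(individual_pair_distance(t2, "i", "j"), want)
  }
})

test_that("fixed differences give Fst = 1, shared monomorphism is excluded", {
  a <- strrep("A", 50)
  b <- mut_at(a, 1)
  inds <- sprintf("i%d", 1:4)
  tab <- rbind(
    diploid_locus(setNames(list(c(a, a), c(a, a)), inds[1:2]),
                  setNames(rep("pop1", 2), inds[1:2])),
    diploid_locus(setNames(list(c(b, b), c(b, b)), inds[3:4]),
                  setNames(rep("pop2", 2), inds[3:4])))
  res <- hudson_fst(tab)
  expect_equal(res$per_locus$Hw, 0)
  expect_equal(res$per_locus$Hb, 1)
  expect_equal(res$mean_fst, 1)
  mono <- tab; mono$sequence <- a
  expect_identical(nrow(hudson_fst(mono)$per_locus), 0L)
})

test_that("identical allele compositions give the enumerated Hudson value", {
  # pop1 = pop2 = {X, X, Y, Y}: Hw = 4d/6 over distinct within pairs,
  # Hb = 8d/16, so formula (3) gives exactly 1 - (2/3)/(1/2) = -1/3
  x <- strrep("A", 40); y <- mut_at(x, 1:4)
  tab <- rbind(
    diploid_locus(list(i1 = c(x, x), i2 = c(y, y)),
                  c(i1 = "pop1", i2 = "pop1")),
    diploid_locus(list(i3 = c(x, x), i4 = c(y, y)),
                  c(i3 = "pop2", i4 = "pop2")))
  res <- hudson_fst(tab)
  expect_equal(res$per_locus$Hw, 4 * 4 / 6)
  expect_equal(res$per_locus$Hb, 8 * 4 / 16)
  expect_equal(res$mean_fst, -1 / 3)
})

test_that("Hudson Fst matches exhaustive pair enumeration on random data", {
  set.seed(63)
  for (trial in 1:15) {
    L <- 20
    alleles <- random_seqs(2, L)
    inds <- sprintf("i%d", 1:8)
    pops <- setNames(rep(c("pop1", "pop2"), each = 4), inds)
    seqs <- setNames(lapply(inds, function(i) sample(alleles, 2, TRUE)),
                     inds)
    tab <- diploid_locus(seqs, pops)
    res <- hudson_fst(tab)
    # oracle: all C(16,2) copy pairs, classified by population
    copies <- tab$sequence
    pop_of <- tab$population
    dw <- c(); db <- c()
    for (i in 1:15) for (j in (i + 1):16) {
      d <- brute_hamming(copies[i], copies[j])
      if (pop_of[i] == pop_of[j]) dw <- c(dw, d) else db <- c(db, d)
    }
    if (length(unique(copies)) < 2) {
      expect_identical(nrow(res$per_locus), 0L)
    } else {
      expect_equal(res$per_locus$Hw, mean(dw))
      expect_equal(res$per_locus$Hb, mean(db))
      if (mean(db) > 0) {
        expect_equal(res$mean_fst, 1 - mean(dw) / mean(db))
      }
    }
  }
})

test_that("Fst is invariant to population relabeling; Hb to duplication", {
  set.seed(64)
  alleles <- random_seqs(3, 25)
  inds <- sprintf("i%d", 1:8)
  pops <- setNames(rep(c("pop1", "pop2"), each = 4), inds)
  seqs <- setNames(lapply(inds, function(i) sample(alleles, 2, TRUE)), inds)
  tab <- diploid_locus(seqs, pops)
  swapped <- tab
  swapped$population <- ifelse(tab$population == "pop1", "pop2", "pop1")
  expect_equal(hudson_fst(tab)$mean_fst, hudson_fst(swapped)$mean_fst)
  doubled <- rbind(tab, transform(tab, individual = paste0(individual, "_d")))
  expect_equal(hudson_fst(doubled)$per_locus$Hb, hudson_fst(tab)$per_locus$Hb)
})

test_that("segregating sites, Watterson theta and pi behave as defined", {
  a <- strrep("A", 50)
  expect_identical(segregating_sites(rep(a, 4)), 0L)
  expect_identical(segregating_sites(c(a, mut_at(a, c(3, 9)))), 2L)
  # n = 2 copies per locus: harmonic factor is 1, theta = S / (L * n_loci)
  b <- mut_at(a, 1:3)
  tab <- rbind(copy_table(1, "i", "pop1", c(a, b)),
               copy_table(2, "i", "pop1", c(a, a)))
  expect_equal(watterson_theta(tab), 3 / (50 * 2))
  expect_equal(nucleotide_diversity(tab), mean(c(3 / 50, 0)))
})

test_that("pi and Watterson theta agree with the coalescent expectation", {
  theta <- 0.005
  sim <- simulate_rad(sim_params(n_loci = 1500, tau = 0, theta1 = theta,
                                 theta2 = theta, thetaA = theta,
                                 depth_mean = 0, seed = 65))
  tab <- true_allele_table(sim)
  tab1 <- tab[tab$population == "pop1", ]
  groups <- split(tab1, tab1$locus)
  L <- 100
  pis <- vapply(groups, function(g) {
    D <- brute_dist_matrix(g$sequence)
    mean(D[upper.tri(D)]) / L
  }, numeric(1))
  se <- sd(pis) / sqrt(length(pis))
  expect_lt(abs(nucleotide_diversity(tab1) - mean(pis)), 1e-12)
  expect_lt(abs(mean(pis) - theta), 3 * se)
  expect_lt(abs(watterson_theta(tab1) - theta), 3 * se)
})

test_that("the moment estimator solves its two moment equations", {
  a <- strrep("A", 100)
  mk <- function(locus, k) {
    seq2 <- if (k > 0) mut_at(a, seq_len(k)) else a
    rbind(copy_table(locus, "i1", "pop1", c(a, a)),
          copy_table(locus, "i2", "pop2", c(seq2, seq2)))
  }
  # all K = 0 -> both estimates zero
  fit0 <- isolation_moments(rbind(mk(1, 0), mk(2, 0), mk(3, 0)), seed = 1)
  expect_equal(unname(coef(fit0)[c("thetaA", "tau")]), c(0, 0))
  # K = {0, 1, 2}: sample variance equals the mean (pure Poisson), so
  # thetaA = 0 and tau = mean(K) / (2 L)
  fitp <- isolation_moments(rbind(mk(1, 0), mk(2, 1), mk(3, 2)), seed = 1)
  expect_equal(unname(coef(fitp)["thetaA"]), 0)
  expect_equal(unname(coef(fitp)["tau"]), 1 / (2 * 100))
  expect_true(fitp$low_confidence)
})

test_that("the moment estimator recovers theta_A and tau from truth", {
  sim <- simulate_rad(sim_params(n_loci = 3000, tau = 0.005, thetaA = 0.005,
                                 depth_mean = 0, seed = 66))
  fit <- isolation_moments(true_allele_table(sim), seed = 2)
  cf <- coef(fit)
  expect_lt(abs(cf[["thetaA"]] - 0.005) / 0.005, 0.25)
  expect_lt(abs(cf[["tau"]] - 0.005) / 0.005, 0.25)
  expect_lt(abs(cf[["theta1"]] - 0.005) / 0.005, 0.25)
})
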