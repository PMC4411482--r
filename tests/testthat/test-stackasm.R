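# Assembler: mismatch budgets, dereplication, depth filtering, clustering
# and catalog construction, checked against brute-force oracles.

test_that("mismatch budget reproduces the printed anchor points", {
  expect_identical(mismatch_budget(93, 100), 7L)
  expect_identical(mismatch_budget(99, 100), 1L)
  expect_identical(mismatch_budget(100, 100), 0L)
  expect_identical(mismatch_budget(100, 250), 0L)
  expect_identical(mismatch_budget(95, 50), 2L)  # floor(50 * 5 / 100)
  expect_error(mismatch_budget(0, 100), "similarity")
  expect_error(mismatch_budget(95, 0), "L")
})

test_that("dereplication counts identical reads into stacks", {
  st <- dereplicate(rep("AAA", 10))
  expect_identical(nrow(st), 1L)
  expect_identical(st$depth, 10L)
  st2 <- dereplicate(c(rep("AAA", 3), rep("AAT", 2)))
  expect_identical(st2$sequence, c("AAA", "AAT"))
  expect_identical(st2$depth, c(3L, 2L))
  expect_error(dereplicate(c("AA", "AAA")), "length")
})

test_that("dereplication matches an independent frequency table", {
  set.seed(31)
  pool <- random_seqs(40, 20)
  reads <- sample(pool, 500, replace = TRUE)
  st <- dereplicate(reads)
  tab <- table(reads)
  expect_identical(sum(st$depth), 500L)
  expect_identical(st$depth, unname(as.integer(tab[st$sequence])))
  expect_identical(sort(st$sequence), sort(names(tab)))
  # members partition the read indices
  expect_identical(sort(unlist(st$members)), seq_along(reads))
})

test_that("depth filtering keeps order and discards shallow stacks", {
  st <- data.frame(sequence = c("A", "C", "G"), depth = c(12L, 10L, 9L))
  kept <- filter_depth(st, 10)
  expect_identical(kept$depth, c(12L, 10L))
  expect_identical(filter_depth(st, 1), st)
})

test_that("clustering respects the threshold on a hand-built pair", {
  a <- strrep("A", 100)
  b <- paste0(strrep("T", 4), strrep("A", 96))  # 4 mismatches from a
  st <- dereplicate(c(rep(a, 10), rep(b, 10)))
  expect_length(cluster_stacks(st, mismatch_budget(99, 100)), 2L)
  expect_length(cluster_stacks(st, mismatch_budget(95, 100)), 1L)
  expect_length(cluster_stacks(st[1, ], 1), 1L)
})

test_that("clustering equals brute-force connected components", {
  set.seed(32)
  for (trial in 1:120) {
    n <- sample(2:25, 1)
    L <- 30
    # mix of related and unrelated sequences so components are non-trivial
    base <- random_seqs(max(1, n %/% 3), L)
    seqs <- vapply(seq_len(n), function(i) {
      s <- strsplit(sample(base, 1), "")[[1]]
      k <- sample(0:6, 1)
      if (k > 0) {
        pos <- sample(L, k)
        s[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      }
      paste(s, collapse = "")
    }, character(1))
    st <- dereplicate(seqs)
    M <- sample(0:8, 1)
    got <- canonical_partition(cluster_stacks(st, M))
    D <- brute_dist_matrix(st$sequence)
    want <- partition_from_membership(brute_components(D, M))
    expect_identical(got, want)
  }
})

test_that("allele calling ranks by depth then sequence and truncates", {
  st <- data.frame(sequence = c("CCC", "AAA", "GGG", "TTT"),
                   depth = c(5L, 9L, 5L, 2L))
  one <- call_alleles(st[2, , drop = FALSE], 3)
  expect_identical(nrow(one$alleles), 1L)
  two <- call_alleles(st[1:2, ], 3)
  expect_identical(two$alleles$sequence, c("AAA", "CCC"))
  full <- call_alleles(st, 3)
  expect_identical(full$alleles$sequence, c("AAA", "CCC", "GGG"))
  expect_identical(full$raw_allele_count, 4L)
  expect_error(call_alleles(st[0, ], 3), "empty")
})

test_that("catalog construction merges shared alleles across individuals", {
  L <- 60
  shared <- strrep("ACGT", 15)
  reads <- do.call(rbind, lapply(sprintf("ind%02d", 1:8), function(ind) {
    data.frame(individual = ind, population = "pop1",
               sequence = rep(shared, 10))
  }))
  asm <- assemble_reads(reads, assembly_params(similarity = 95, L = L))
  expect_length(asm$loci, 1L)
  expect_identical(sort(unique(asm$loci[[1]]$genotypes$individual)),
                   sprintf("ind%02d", 1:8))
  expect_identical(asm$loci[[1]]$consensus, shared)
})

test_that("across-individual merging follows the catalog budget", {
  a <- strrep("A", 100)
  b <- paste0(strrep("T", 4), strrep("A", 96))
  reads <- rbind(
    data.frame(individual = "i1", population = "pop1", sequence = rep(a, 10)),
    data.frame(individual = "i2", population = "pop2", sequence = rep(b, 10)))
  asm99 <- assemble_reads(reads, assembly_params(similarity = 99))
  expect_length(asm99$loci, 2L)
  asm95 <- assemble_reads(reads, assembly_params(similarity = 95))
  expect_length(asm95$loci, 1L)
  expect_identical(nrow(asm95$loci[[1]]$genotypes), 2L)
})

test_that("an individual with three alleles flags the locus as paralogous", {
  a <- strrep("A", 100)
  vars <- vapply(1:3, function(k) {
    paste0(strrep("C", k), substr(a, k + 1, 100))
  }, character(1))
  reads <- data.frame(individual = "i1", population = "pop1",
                      sequence = rep(vars, each = 10))
  asm <- assemble_reads(reads, assembly_params(similarity = 93))
  expect_length(asm$loci, 1L)
  expect_true(asm$loci[[1]]$paralog)
  expect_identical(flag_undersplit(asm)$n, 1L)
})

test_that("every depth-surviving read lands in exactly one catalog locus", {
  sim <- simulate_rad(sim_params(n_loci = 60, seed = 41, error_rate = 0.005))
  asm <- assemble_reads(sim, assembly_params(similarity = 95))
  assigned <- unlist(lapply(asm$loci, `[[`, "reads"))
  expect_false(any(duplicated(assigned)))
  # surviving reads are exactly those in stacks with depth >= 10
  st <- lapply(split(sim$reads, sim$reads$individual), function(d) {
    filter_depth(dereplicate(d$sequence, d$read_id), 10)
  })
  surviving <- sort(unname(unlist(lapply(st, function(s) unlist(s$members)))))
  expect_identical(sort(assigned), surviving)
})

test_that("liberal partitions are coarsenings of stringent ones", {
  sim <- simulate_rad(sim_params(n_loci = 50, seed = 42, error_rate = 0,
                                 tau = 0.02, theta1 = 0.01, theta2 = 0.01,
                                 thetaA = 0.01))
  asms <- lapply(c(93, 96, 99), function(s) {
    assemble_reads(sim, assembly_params(similarity = s))
  })
  read_part <- function(asm) {
    m <- lapply(asm$loci, `[[`, "reads")
    stats::setNames(rep(seq_along(m), lengths(m)), unlist(m))
  }
  parts <- lapply(asms, read_part)
  # stringent (99) classes are subsets of liberal (93, 96) classes
  for (liberal in 1:2) {
    p_lib <- parts[[liberal]]; p_str <- parts[[3]]
    shared <- intersect(names(p_lib), names(p_str))
    tab <- table(p_str[shared], p_lib[shared])
    expect_true(all(rowSums(tab > 0) == 1L))
  }
})

test_that("error-free low-divergence data recovers the truth exactly", {
  sim <- simulate_rad(sim_params(n_loci = 80, seed = 43, error_rate = 0,
                                 depth_mean = 40, theta1 = 0.001,
                                 theta2 = 0.001, thetaA = 0.001,
                                 tau = 0.001))
  asm <- assemble_reads(sim, assembly_params(similarity = 93))
  expect_length(asm$loci, 80L)
  # every true allele appears among the called alleles of its catalog locus
  called <- unlist(lapply(asm$loci, function(l) l$genotypes$sequence))
  true_haps <- unlist(lapply(sim$loci, function(l) l$haplotypes[[1]]))
  expect_true(all(true_haps %in% called))
  rates <- true_split_rates(asm, sim$reads)
  expect_identical(rates$true_oversplit_rate, 0)
  expect_identical(rates$true_undersplit_rate, 0)
})

test_that("reads of the wrong length are rejected", {
  reads <- data.frame(individual = "i1", population = "pop1",
                      sequence = c(strrep("A", 99)))
  expect_error(assemble_reads(reads, assembly_params(similarity = 95)),
               "length")
})
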