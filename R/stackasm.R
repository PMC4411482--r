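# De novo assembly of fixed-length reads into alleles and catalog loci.
#
# The workflow mirrors a Stacks-style pipeline restricted to primary
# stacks: dereplicate reads per individual, drop shallow stacks, cluster
# the survivors into within-individual loci under a mismatch budget, then
# merge individual loci across individuals into catalog loci. Clustering is
# single-linkage (connected components of the <=M mismatch graph), which is
# deterministic and order-independent, unlike Stacks' depth-ordered greedy
# matching; see the package vignette for the consequences.

#' Mismatch budget implied by a percent similarity threshold
#'
#' `floor(L * (100 - s) / 100)` mismatches: at L = 100 this gives 7
#' mismatches for 93% similarity and 1 mismatch for 99%.
#'
#' @param similarity integer percent similarity in (0, 100].
#' @param L sequence length in bases.
#' @return integer number of mismatches allowed.
#' @export
#' @examples
#' mismatch_budget(93, 100)  # 7
#' mismatch_budget(99, 100)  # 1
mismatch_budget <- function(similarity, L) {
  if (any(similarity <= 0) || any(similarity > 100)) {
    stop("similarity must lie in (0, 100]")
  }
  if (any(L < 1)) stop("L must be >= 1")
  as.integer(floor(L * (100 - similarity) / 100))
}

#' Dereplicate one individual's reads into stacks
#'
#' A stack is the multiset of identical reads; its consensus is the shared
#' sequence and its depth the read count. Output is sorted by depth
#' (decreasing) then sequence (increasing) for determinism.
#'
#' @param sequences character vector of equal-length reads.
#' @param read_ids optional identifiers, carried through as stack members.
#' @return data.frame with columns `sequence`, `depth` and list-column
#'   `members`.
#' @export
dereplicate <- function(sequences, read_ids = NULL) {
  if (length(sequences) &&
      length(unique(nchar(sequences))) != 1L) {
    stop("reads must all have the same length")
  }
  if (is.null(read_ids)) read_ids <- seq_along(sequences)
  grp <- split(read_ids, sequences)  # sorted by sequence
  depth <- lengths(grp)
  ord <- order(-depth, names(grp))
  out <- data.frame(sequence = names(grp)[ord], depth = as.integer(depth[ord]))
  out$members <- unname(grp[ord])
  rownames(out) <- NULL
  out
}

#' Drop stacks below the minimum depth
#'
#' Removed stacks are discarded entirely; there is no secondary-read rescue
#' of shallow variants onto deeper stacks.
#'
#' @param stacks data.frame from [dereplicate()].
#' @param min_depth minimum reads per stack.
#' @return filtered stacks, order preserved.
#' @export
filter_depth <- function(stacks, min_depth) {
  stacks[stacks$depth >= min_depth, , drop = FALSE]
}

#' Cluster one individual's stacks into loci
#'
#' Builds the graph with an edge between stacks at Hamming distance `<= M`
#' and returns its connected components, ordered by their lexicographically
#' smallest member sequence.
#'
#' @param stacks data.frame from [dereplicate()] / [filter_depth()].
#' @param M mismatch budget (see [mismatch_budget()]).
#' @return list of integer index vectors into `stacks`, one per locus.
#' @export
cluster_stacks <- function(stacks, M) {
  n <- nrow(stacks)
  if (n == 0L) return(list())
  X <- seq_matrix(stacks$sequence)
  e <- hamming_pairs(X, M)
  comp <- uf_components(n, e$i, e$j)
  groups <- split(seq_len(n), comp)
  key <- vapply(groups, function(ix) min(stacks$sequence[ix]), character(1))
  unname(groups[order(key)])
}

#' Call alleles for one within-individual locus cluster
#'
#' Stacks in the cluster are ranked by depth (decreasing) then sequence and
#' the top `max_alleles` distinct consensi are retained as called alleles;
#' the pre-truncation count is kept so paralog-rich clusters remain
#' identifiable.
#'
#' @param stacks stacks data.frame restricted to one cluster.
#' @param max_alleles maximum alleles retained.
#' @return list with `alleles` (data.frame `sequence`, `depth`, `members`)
#'   and `raw_allele_count`.
#' @export
call_alleles <- function(stacks, max_alleles) {
  if (nrow(stacks) == 0L) stop("empty cluster")
  ord <- order(-stacks$depth, stacks$sequence)
  keep <- utils::head(ord, max_alleles)
  list(alleles = stacks[keep, , drop = FALSE],
       raw_allele_count = nrow(stacks))
}

# Per-individual pipeline: reads -> called individual loci.
individual_loci <- function(sequences, read_ids, params) {
  st <- filter_depth(dereplicate(sequences, read_ids), params$min_depth)
  M <- mismatch_budget(params$similarity, params$L)
  lapply(cluster_stacks(st, M), function(ix) {
    call_alleles(st[ix, , drop = FALSE], params$max_alleles)
  })
}

#' Merge individual loci across individuals into a catalog
#'
#' Individual loci are merged (connected components again) whenever the
#' minimum Hamming distance between their allele sets is within the
#' catalog mismatch budget. Each component becomes a catalog locus with
#' per-individual genotypes, a consensus (the most frequent allele by
#' diploid dosage, ties broken lexicographically) and a paralog flag set
#' when any individual carries more than two distinct alleles.
#'
#' @param ind_loci data.frame of called alleles across individuals, with
#'   columns `individual`, `unit` (individual-locus id), `sequence`,
#'   `depth`, `members`.
#' @param M catalog mismatch budget.
#' @param params an [assembly_params()] object.
#' @param popmap individual/population data.frame.
#' @return object of class `rad_assembly`.
#' @export
build_catalog <- function(ind_loci, M, params, popmap) {
  n_alleles <- nrow(ind_loci)
  loci <- list()
  if (n_alleles > 0L) {
    X <- seq_matrix(ind_loci$sequence)
    e <- hamming_pairs(X, M)
    # merge units (individual loci), not just alleles
    unit_ids <- unique(ind_loci$unit)
    u_of <- match(ind_loci$unit, unit_ids)
    comp <- uf_components(length(unit_ids), u_of[e$i], u_of[e$j])
    allele_comp <- comp[u_of]
    groups <- split(seq_len(n_alleles), allele_comp)
    key <- vapply(groups, function(ix) min(ind_loci$sequence[ix]),
                  character(1))
    groups <- unname(groups[order(key)])
    loci <- lapply(seq_along(groups), function(cid) {
      rows <- ind_loci[groups[[cid]], , drop = FALSE]
      # distinct alleles per individual (same sequence twice can arise if
      # two clusters of one individual merge at catalog stage)
      geno <- do.call(rbind, lapply(split(rows, rows$individual), function(g) {
        agg <- vapply(split(g$depth, g$sequence), sum, numeric(1))
        data.frame(individual = g$individual[1L], sequence = names(agg),
                   depth = as.integer(agg))
      }))
      rownames(geno) <- NULL
      geno <- geno[order(geno$individual, -geno$depth, geno$sequence), ,
                   drop = FALSE]
      n_per_ind <- table(geno$individual)
      dosage <- ifelse(geno$individual %in% names(n_per_ind)[n_per_ind == 1L],
                       2L, 1L)
      cnt <- vapply(split(dosage, geno$sequence), sum, numeric(1))
      consensus <- names(cnt)[order(-cnt, names(cnt))][1L]
      list(id = cid,
           consensus = consensus,
           genotypes = geno,
           paralog = any(n_per_ind > 2L),
           reads = unlist(rows$members, use.names = FALSE))
    })
  }
  structure(list(params = params, popmap = popmap, loci = loci),
            class = "rad_assembly")
}

#' Assemble reads into catalog loci at one similarity threshold
#'
#' Full pipeline: per-individual dereplication, depth filtering, clustering
#' and allele calling, then across-individual catalog construction.
#'
#' @param reads data.frame with columns `individual`, `sequence` and
#'   optionally `read_id` (a `rad_sim` is also accepted).
#' @param params an [assembly_params()] object.
#' @param popmap individual/population map; taken from the `rad_sim` when
#'   omitted.
#' @return a `rad_assembly`: `params`, `popmap` and `loci`, each locus
#'   holding per-individual genotypes, consensus, paralog flag and member
#'   read ids.
#' @export
#' @examples
#' sim <- simulate_rad(sim_params(n_loci = 20, seed = 7, error_rate = 0))
#' asm <- assemble_reads(sim, assembly_params(similarity = 95))
#' asm
assemble_reads <- function(reads, params, popmap = NULL) {
  if (inherits(reads, "rad_sim")) {
    if (is.null(popmap)) popmap <- reads$popmap
    reads <- reads$reads
  }
  if (is.null(popmap)) {
    if (!"population" %in% names(reads)) {
      stop("popmap required when reads carry no population column")
    }
    popmap <- unique(reads[, c("individual", "population")])
  }
  if (is.null(reads$read_id)) reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
  if (any(nchar(reads$sequence) != params$L)) {
    stop("all reads must have length L = ", params$L)
  }
  by_ind <- split(reads[, c("read_id", "sequence")], reads$individual)
  chunks <- list()
  unit <- 0L
  for (ind in sort(names(by_ind))) {
    il <- individual_loci(by_ind[[ind]]$sequence, by_ind[[ind]]$read_id,
                          params)
    for (loc in il) {
      unit <- unit + 1L
      a <- loc$alleles
      chunks[[unit]] <- data.frame(individual = ind, unit = unit,
                                   sequence = a$sequence, depth = a$depth,
                                   raw_allele_count = loc$raw_allele_count)
      chunks[[unit]]$members <- a$members
    }
  }
  ind_loci <- if (length(chunks)) do.call(rbind, chunks) else
    data.frame(individual = character(0), unit = integer(0),
               sequence = character(0), depth = integer(0),
               raw_allele_count = integer(0), members = I(list()))
  M <- mismatch_budget(params$catalog_similarity, params$L)
  build_catalog(ind_loci, M, params, popmap)
}

#' @export
print.rad_assembly <- function(x, ...) {
  n <- length(x$loci)
  flagged <- sum(vapply(x$loci, `[[`, logical(1), "paralog"))
  cat(sprintf(
    "RAD assembly at %d%% similarity: %d catalog loci (%d paralog-flagged)\n",
    x$params$similarity, n, flagged))
  invisible(x)
}

#' Allele table of an assembly
#'
#' Diploid-expanded allele copies per genotyped individual per locus: a
#' single called allele contributes two copies (homozygote), two alleles
#' one copy each. Loci flagged as paralogous (any individual with more than
#' two alleles) are dropped by default, matching their removal ahead of all
#' downstream statistics.
#'
#' @param assembly a `rad_assembly`.
#' @param drop_flagged drop paralog-flagged loci (default TRUE).
#' @param expand_diploid expand to two copies per individual (default TRUE);
#'   otherwise one row per distinct called allele.
#' @return data.frame with columns `locus`, `individual`, `population`,
#'   `sequence` (and `depth` when not expanded).
#' @export
allele_table <- function(assembly, drop_flagged = TRUE,
                         expand_diploid = TRUE) {
  pop_of <- stats::setNames(assembly$popmap$population,
                            assembly$popmap$individual)
  chunks <- lapply(assembly$loci, function(loc) {
    if (drop_flagged && loc$paralog) return(NULL)
    g <- loc$genotypes
    if (expand_diploid) {
      n_per_ind <- table(g$individual)
      if (any(n_per_ind > 2L)) {
        g <- g[g$individual %in% names(n_per_ind)[n_per_ind <= 2L], ,
               drop = FALSE]
      }
      if (nrow(g) == 0L) return(NULL)
      reps <- ifelse(table(g$individual)[g$individual] == 1L, 2L, 1L)
      g <- g[rep(seq_len(nrow(g)), reps), c("individual", "sequence")]
    } else {
      g <- g[, c("individual", "sequence", "depth")]
    }
    cbind(locus = loc$id, g)
  })
  out <- do.call(rbind, chunks)
  if (is.null(out)) {
    out <- data.frame(locus = integer(0), individual = character(0),
                      sequence = character(0))
  }
  out$population <- unname(pop_of[out$individual])
  rownames(out) <- NULL
  out[, c("locus", "individual", "population",
          setdiff(names(out), c("locus", "individual", "population")))]
}
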