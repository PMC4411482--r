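# Threshold-sweep orchestration: assemble one read set at every similarity
# threshold, run the splitting diagnostics and population-genetic
# summaries, and tabulate how each statistic responds. Reads are
# dereplicated and depth-filtered once; only the clustering depends on the
# threshold.

#' Assemble and summarise a dataset across a similarity-threshold sweep
#'
#' For each threshold the reads are assembled, under-split (paralog-
#' flagged) loci are removed, and the retained loci are summarised:
#' locus counts, mean individuals represented, segregating sites and
#' alleles per locus, mean p/Jukes-Cantor distance between individuals,
#' mean Hudson Fst, mean gene-tree depth over a locus subsample, and the
#' isolation-model estimates of contemporary and ancestral theta and tau.
#' Stringent thresholds are additionally mapped onto the most liberal
#' (reference) threshold to score the over-split proxy, with the
#' reference's self-mapping baseline subtracted. When the input is a
#' simulation, truth-based over/under-split rates are included.
#'
#' @param x a `rad_sim`, or a reads data.frame (see [assemble_reads()]).
#' @param thresholds integer percent similarity values; must include
#'   `reference` for the over-split proxy.
#' @param min_depth,max_alleles assembly settings (see
#'   [assembly_params()]).
#' @param reference the liberal reference threshold for over-split mapping
#'   (default 93); set NA to skip the proxy.
#' @param seed seed for the tree subsample and allele sampling of the
#'   moment estimator.
#' @param tree_sample loci sampled per threshold for mean tree depth.
#' @param popmap required when `x` is a plain reads data.frame.
#' @param out_dir optional directory; when given, the report is written as
#'   `sweep_report.tsv` and each threshold's catalog as
#'   `threshold_<s>/catalog.tsv`.
#' @return a `sweep_report` data.frame (one row per threshold) with the
#'   per-threshold assemblies attached as attribute `"assemblies"`.
#' @export
#' @examples
#' sim <- simulate_rad(sim_params(n_loci = 60, seed = 11))
#' rep <- run_sweep(sim, thresholds = c(93, 97), tree_sample = 50)
#' rep
run_sweep <- function(x, thresholds = 93:99, min_depth = 10L,
                      max_alleles = 3L, reference = 93L, seed = 1L,
                      tree_sample = 1000L, popmap = NULL, out_dir = NULL) {
  thresholds <- sort(as.integer(thresholds))
  if (!is.na(reference) && !(reference %in% thresholds)) {
    stop("the reference threshold (", reference,
         ") must be part of the sweep, or set reference = NA")
  }
  truth_reads <- NULL
  if (inherits(x, "rad_sim")) {
    truth_reads <- x$reads
    if (is.null(popmap)) popmap <- x$popmap
    reads <- x$reads
  } else {
    reads <- x
    if (is.null(popmap)) {
      if (!"population" %in% names(reads)) stop("popmap required")
      popmap <- unique(reads[, c("individual", "population")])
    }
    if (all(c("locus", "copy") %in% names(reads))) truth_reads <- reads
  }
  if (is.null(reads$read_id)) {
    reads$read_id <- sprintf("r%07d", seq_len(nrow(reads)))
  }
  L <- nchar(reads$sequence[1L])

  # threshold-independent work: dereplicate + depth filter per individual
  by_ind <- split(reads[, c("read_id", "sequence")], reads$individual)
  stacks_by_ind <- lapply(by_ind, function(d) {
    filter_depth(dereplicate(d$sequence, d$read_id), min_depth)
  })

  assemble_at <- function(s) {
    params <- assembly_params(similarity = s, min_depth = min_depth,
                              max_alleles = max_alleles, L = L)
    M <- mismatch_budget(s, L)
    chunks <- list(); unit <- 0L
    for (ind in sort(names(stacks_by_ind))) {
      st <- stacks_by_ind[[ind]]
      for (ix in cluster_stacks(st, M)) {
        unit <- unit + 1L
        called <- call_alleles(st[ix, , drop = FALSE], max_alleles)
        a <- called$alleles
        ch <- data.frame(individual = ind, unit = unit,
                         sequence = a$sequence, depth = a$depth,
                         raw_allele_count = called$raw_allele_count)
        ch$members <- a$members
        chunks[[unit]] <- ch
      }
    }
    ind_loci <- if (length(chunks)) do.call(rbind, chunks) else
      data.frame(individual = character(0), unit = integer(0),
                 sequence = character(0), depth = integer(0),
                 raw_allele_count = integer(0), members = I(list()))
    build_catalog(ind_loci, M, params, popmap)
  }

  assemblies <- lapply(thresholds, assemble_at)
  names(assemblies) <- as.character(thresholds)

  baseline <- NA_integer_
  if (!is.na(reference)) {
    baseline <- selfmap_baseline(assemblies[[as.character(reference)]],
                                 min_identity = reference)
  }

  rows <- lapply(seq_along(thresholds), function(k) {
    s <- thresholds[k]
    asm <- assemblies[[k]]
    us <- flag_undersplit(asm)
    tab <- allele_table(asm, drop_flagged = TRUE)
    n_total <- length(asm$loci)
    n_retained <- n_total - us$n
    per_locus <- locus_groups(tab)
    mean_inds <- mean(vapply(per_locus, function(g) {
      length(unique(g$individual))
    }, numeric(1)))
    mean_segsites <- mean(vapply(per_locus, function(g) {
      as.numeric(segregating_sites(g$sequence))
    }, numeric(1)))
    mean_alleles <- mean(vapply(per_locus, function(g) {
      length(unique(g$sequence))
    }, numeric(1)))
    pd <- pair_distances(tab)
    fst <- hudson_fst(tab)
    td <- mean_tree_depth(tab, n_sample = tree_sample, seed = seed)
    fit <- isolation_moments(tab, seed = seed)
    cf <- coef(fit)
    os_count <- NA_integer_; os_prop <- NA_real_
    if (!is.na(reference) && s > reference) {
      os <- oversplit_index(asm, assemblies[[as.character(reference)]],
                            min_identity = reference, baseline = baseline)
      os_count <- os$count; os_prop <- os$proportion
    }
    row <- data.frame(
      threshold = s, n_loci_total = n_total, n_loci = n_retained,
      undersplit_n = us$n, undersplit_prop = us$proportion,
      oversplit_n = os_count, oversplit_prop = os_prop,
      mean_individuals = mean_inds, mean_segsites = mean_segsites,
      mean_alleles = mean_alleles,
      mean_p_dist = mean(pd$p_mean, na.rm = TRUE),
      mean_jc_dist = mean(pd$jc_mean, na.rm = TRUE),
      mean_fst = fst$mean_fst,
      mean_tree_depth = td$mean_depth,
      theta1 = cf[["theta1"]], theta2 = cf[["theta2"]],
      thetaA = cf[["thetaA"]], tau = cf[["tau"]]
    )
    if (!is.null(truth_reads)) {
      tr <- true_split_rates(asm, truth_reads)
      row$true_oversplit <- tr$true_oversplit_rate
      row$true_undersplit <- tr$true_undersplit_rate
    }
    row
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "baseline") <- baseline
  attr(report, "assemblies") <- assemblies
  class(report) <- c("sweep_report", "data.frame")

  if (!is.null(out_dir)) write_sweep(report, out_dir)
  report
}

#' Write a sweep report (and its catalogs) to disk
#'
#' @param report a `sweep_report`.
#' @param out_dir output directory.
#' @return invisibly, the report path.
#' @export
write_sweep <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- file.path(out_dir, "sweep_report.tsv")
  utils::write.table(as.data.frame(report), fp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (s in names(attr(report, "assemblies"))) {
    asm <- attr(report, "assemblies")[[s]]
    d <- file.path(out_dir, paste0("threshold_", s))
    if (!dir.exists(d)) dir.create(d)
    gt <- allele_table(asm, drop_flagged = FALSE, expand_diploid = FALSE)
    utils::write.table(gt, file.path(d, "catalog.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cons <- catalog_consensi(asm, drop_flagged = FALSE)
    writeLines(paste0(">locus_", seq_along(cons), "\n", cons),
               file.path(d, "catalog.fasta"))
  }
  invisible(fp)
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("Similarity-threshold sweep over", nrow(x), "thresholds\n")
  cols <- c("threshold", "n_loci", "undersplit_prop", "oversplit_prop",
            "mean_alleles", "mean_jc_dist", "mean_fst",
            "mean_tree_depth", "thetaA", "tau")
  cols <- intersect(cols, names(x))
  print(format(as.data.frame(x)[, cols], digits = 4), row.names = FALSE)
  invisible(x)
}

#' Plot the bias curves of a threshold sweep
#'
#' Base-graphics panels of the statistics most sensitive to the threshold:
#' alleles per locus, split proportions, mean JC distance, mean Fst, mean
#' tree depth and ancestral theta, each against the similarity threshold.
#'
#' @param x a `sweep_report`.
#' @param ... ignored.
#' @return invisibly, `x`.
#' @export
plot.sweep_report <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  panel <- function(col, ylab) {
    if (!col %in% names(x) || all(is.na(x[[col]]))) return()
    graphics::plot(x$threshold, x[[col]], type = "b", pch = 19,
                   xlab = "similarity threshold (%)", ylab = ylab)
  }
  panel("mean_alleles", "mean alleles per locus")
  panel("oversplit_prop", "over-split proxy proportion")
  panel("mean_jc_dist", "mean JC distance")
  panel("mean_fst", "mean Fst")
  panel("mean_tree_depth", "mean gene-tree depth")
  panel("thetaA", "ancestral theta")
  invisible(x)
}

#' Compare sweep reports across lineages
#'
#' Restricts the reports to their shared thresholds and, for each
#' statistic and threshold, reports each lineage's ratio to a baseline
#' lineage and the variance of the statistic across lineages.
#'
#' @param ... two or more `sweep_report` objects (optionally named).
#' @param baseline index or name of the baseline lineage (default first).
#' @return list with `ratios` (long data.frame: `statistic`, `threshold`,
#'   `lineage`, `value`, `ratio`) and `variance` (`statistic`,
#'   `threshold`, `var`).
#' @export
compare_lineages <- function(..., baseline = 1L) {
  reports <- list(...)
  if (length(reports) == 1L && is.list(reports[[1L]]) &&
      !inherits(reports[[1L]], "data.frame")) {
    reports <- reports[[1L]]
  }
  if (length(reports) < 2L) stop("need at least two reports")
  if (is.null(names(reports)) || any(!nzchar(names(reports)))) {
    names(reports) <- paste0("lineage", seq_along(reports))
  }
  shared <- Reduce(intersect, lapply(reports, function(r) r$threshold))
  if (length(shared) == 0L) stop("reports share no thresholds")
  if (any(vapply(reports, function(r) length(r$threshold), integer(1)) >
          length(shared))) {
    warning("thresholds differ across reports; restricted to intersection")
  }
  shared_cols <- Reduce(intersect, lapply(reports, names))
  stats_cols <- setdiff(shared_cols,
                        c("threshold", "n_loci_total", "undersplit_n",
                          "oversplit_n"))
  base_name <- if (is.numeric(baseline)) names(reports)[baseline]
               else baseline
  rows <- list(); vrows <- list()
  for (st in stats_cols) {
    for (s in shared) {
      vals <- vapply(reports, function(r) {
        v <- r[[st]][r$threshold == s]
        if (length(v)) as.numeric(v[1L]) else NA_real_
      }, numeric(1))
      bv <- vals[[base_name]]
      rows[[length(rows) + 1L]] <- data.frame(
        statistic = st, threshold = s, lineage = names(vals),
        value = unname(vals),
        ratio = if (!is.na(bv) && bv != 0) unname(vals) / bv else NA_real_)
      vrows[[length(vrows) + 1L]] <- data.frame(
        statistic = st, threshold = s, var = stats::var(vals))
    }
  }
  ratios <- do.call(rbind, rows); rownames(ratios) <- NULL
  variance <- do.call(rbind, vrows); rownames(variance) <- NULL
  list(ratios = ratios, variance = variance)
}
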