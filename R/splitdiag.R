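# Over- and under-splitting diagnostics.
#
# Two assembly pathologies are quantified: under-splitting (paralogous
# loci merged, betrayed by individuals with more alleles than their ploidy
# allows) and over-splitting (divergent alleles of one locus split into
# several). The over-split proxy maps loci assembled at a stringent
# threshold onto the loci from the most liberal threshold (93%) by best
# ungapped Hamming hit and counts collisions, minus a same-threshold
# self-mapping baseline. On simulated data the truth-based rates are also
# available.

#' Flag under-split (putative paralogous) catalog loci
#'
#' Returns the loci where any individual carries more than two distinct
#' alleles; these are presumed to contain paralogous reads and are removed
#' ahead of all downstream statistics.
#'
#' @param assembly a `rad_assembly`.
#' @return list with `ids`, `n`, `n_loci` and `proportion`.
#' @export
flag_undersplit <- function(assembly) {
  flags <- vapply(assembly$loci, `[[`, logical(1), "paralog")
  ids <- vapply(assembly$loci, `[[`, integer(1), "id")[flags]
  n_loci <- length(flags)
  list(ids = ids, n = length(ids), n_loci = n_loci,
       proportion = if (n_loci) length(ids) / n_loci else 0)
}

#' Map locus consensus sequences onto a reference set
#'
#' Ungapped fixed-length mapping: a query maps to the reference consensi
#' within Hamming identity `min_identity` percent; the best hit is the
#' minimum distance, ties broken by the lexicographically smallest
#' reference sequence. When query and reference are the same assembly,
#' self-hits are excluded.
#'
#' @param query,reference `rad_assembly` objects or character vectors of
#'   consensus sequences.
#' @param min_identity minimum percent identity (default 93).
#' @param drop_flagged when assemblies are given, drop paralog-flagged loci
#'   first (default TRUE).
#' @return data.frame `query`, `ref`, `distance`, one row per mapped query
#'   (index into the respective consensus vectors).
#' @export
map_loci <- function(query, reference, min_identity = 93,
                     drop_flagged = TRUE) {
  qs <- catalog_consensi(query, drop_flagged)
  rs <- catalog_consensi(reference, drop_flagged)
  self <- identical(qs, rs)
  if (length(qs) == 0L || length(rs) == 0L) {
    return(data.frame(query = integer(0), ref = integer(0),
                      distance = integer(0)))
  }
  L <- nchar(qs[1L])
  if (nchar(rs[1L]) != L) stop("query and reference locus lengths differ")
  budget <- mismatch_budget(min_identity, L)
  pairs <- hamming_pairs(seq_matrix(qs), budget, Y = seq_matrix(rs))
  if (self) pairs <- pairs[pairs$i != pairs$j, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.frame(query = integer(0), ref = integer(0),
                      distance = integer(0)))
  }
  # best hit per query: min distance, ties -> smallest reference sequence
  ord <- order(pairs$i, pairs$d, rs[pairs$j])
  pairs <- pairs[ord, , drop = FALSE]
  best <- pairs[!duplicated(pairs$i), , drop = FALSE]
  data.frame(query = best$i, ref = best$j, distance = best$d,
             row.names = NULL)
}

catalog_consensi <- function(x, drop_flagged = TRUE) {
  if (is.character(x)) return(x)
  stopifnot(inherits(x, "rad_assembly"))
  keep <- if (drop_flagged) {
    !vapply(x$loci, `[[`, logical(1), "paralog")
  } else rep(TRUE, length(x$loci))
  vapply(x$loci[keep], `[[`, character(1), "consensus")
}

#' Over-split proxy: collisions of stringent loci on the liberal catalog
#'
#' Maps the loci assembled at a stringent threshold onto the loci from the
#' most liberal threshold (93%) and counts instances where several
#' stringent loci share the same liberal best hit. A baseline -- the number
#' of liberal-threshold loci that map to a *different* locus of their own
#' assembly -- is subtracted (floored at zero), so a perfectly one-to-one
#' mapping scores zero.
#'
#' @param stringent a `rad_assembly` at threshold > 93.
#' @param liberal the reference `rad_assembly` at the 93% threshold.
#' @param min_identity mapping identity floor (default 93).
#' @param baseline self-mapping baseline count; computed from `liberal`
#'   when NULL.
#' @param mode count `k - 1` extra loci per collided reference (default
#'   "extra") or all `k` involved loci ("all").
#' @return list with `raw`, `baseline`, `count`, `n_query` and
#'   `proportion`.
#' @export
oversplit_index <- function(stringent, liberal, min_identity = 93,
                            baseline = NULL, mode = c("extra", "all")) {
  mode <- match.arg(mode)
  if (inherits(stringent, "rad_assembly") &&
      inherits(liberal, "rad_assembly") &&
      stringent$params$similarity <= liberal$params$similarity) {
    stop("the reference assembly must use the more liberal (lower) threshold")
  }
  m <- map_loci(stringent, liberal, min_identity)
  k <- table(m$ref)
  raw <- if (mode == "extra") sum(pmax(0L, k - 1L)) else sum(k[k >= 2L])
  if (is.null(baseline)) baseline <- selfmap_baseline(liberal, min_identity)
  n_query <- length(catalog_consensi(stringent))
  count <- max(0L, raw - baseline)
  list(raw = as.integer(raw), baseline = as.integer(baseline),
       count = as.integer(count), n_query = n_query,
       proportion = if (n_query) count / n_query else 0)
}

#' @rdname oversplit_index
#' @export
selfmap_baseline <- function(liberal, min_identity = 93) {
  nrow(map_loci(liberal, liberal, min_identity))
}

#' Truth-based split rates for an assembly of simulated reads
#'
#' Available only in simulation, where every read carries its source locus:
#' the true over-split rate is the fraction of true loci (paralog copies
#' counted separately) whose depth-surviving reads end up in two or more
#' catalog loci; the true under-split rate is the fraction of catalog loci
#' containing reads from two or more true loci.
#'
#' @param assembly a `rad_assembly` built from simulated reads.
#' @param reads the truth-tagged reads data.frame (e.g. `sim$reads`).
#' @return list with `true_oversplit_rate`, `true_undersplit_rate`,
#'   `n_true_loci`, `n_catalog_loci`.
#' @export
true_split_rates <- function(assembly, reads) {
  if (is.null(reads$locus) || is.null(reads$copy)) {
    stop("reads lack truth tags (locus/copy columns)")
  }
  true_key <- stats::setNames(paste(reads$locus, reads$copy, sep = "/"),
                              reads$read_id)
  cat_of_read <- list()
  per_cat <- vapply(assembly$loci, function(loc) {
    keys <- unique(true_key[as.character(loc$reads)])
    length(keys)
  }, integer(1))
  # true locus -> set of catalog loci its retained reads occupy
  read_cat <- rep(seq_along(assembly$loci),
                  vapply(assembly$loci, function(l) length(l$reads),
                         integer(1)))
  read_ids <- unlist(lapply(assembly$loci, `[[`, "reads"), use.names = FALSE)
  keys <- true_key[as.character(read_ids)]
  if (anyNA(keys)) stop("assembly contains reads absent from the truth table")
  cats_per_true <- vapply(split(read_cat, keys),
                          function(x) length(unique(x)), integer(1))
  n_true <- length(cats_per_true)
  n_cat <- length(per_cat)
  list(
    true_oversplit_rate = if (n_true) mean(cats_per_true >= 2L) else 0,
    true_undersplit_rate = if (n_cat) mean(per_cat >= 2L) else 0,
    n_true_loci = n_true, n_catalog_loci = n_cat
  )
}
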