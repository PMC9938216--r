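#' Gene-set collection over a declared background
#'
#' @param sets named list of character vectors (gene ids).
#' @param universe character vector, the background gene universe.
#' @return object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(universe) > 0)
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("gene_set_collection: sets must have unique names")
  universe <- unique(as.character(universe))
  structure(list(sets = lapply(sets, function(s) unique(as.character(s))),
                 universe = universe),
            class = "gene_set_collection")
}

#' Restrict gene sets to the background universe
#'
#' Genes absent from the background (here, the detected membrane
#' proteome) carry no information for over-representation against it and
#' are excluded from every set. Sets emptied by the restriction are
#' flagged.
#'
#' @param sets named list of gene sets or a `"gene_set_collection"`.
#' @param universe background gene universe.
#' @return a `"gene_set_collection"` with attribute `empty_sets`.
#' @export
restrict_to_background <- function(sets, universe) {
  if (inherits(sets, "gene_set_collection")) sets <- sets$sets
  stopifnot(length(universe) > 0)
  restricted <- lapply(sets, intersect, y = universe)
  empty <- names(restricted)[lengths(restricted) == 0]
  out <- gene_set_collection(restricted, universe)
  attr(out, "empty_sets") <- empty
  out
}

#' Hypergeometric over-representation of a query in a target set
#'
#' Tests whether the overlap `k` between a query list (size `n_query`)
#' and a target set (size `K_set`) within a universe of `N_universe`
#' genes exceeds chance. The upper tail includes the observed overlap,
#' `p = P(X >= k)`; the two-sided variant doubles the smaller tail,
#' capped at 1. Enrichment is reported as fold over the chance
#' expectation `n_query * K_set / N_universe` and as percent increase
#' over chance, `(fold - 1) * 100`.
#'
#' @param query,target character vectors, subsets of `universe`.
#' @param universe background gene universe.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param set_name optional label carried into the result.
#' @return one-row data.frame: set_name, k, n_query, K_set, N_universe,
#'   expected, fold, pct_enrichment, p.
#' @export
hypergeom_enrich <- function(query, target, universe,
                             alternative = c("greater", "two.sided"),
                             set_name = NA_character_) {
  alternative <- match.arg(alternative)
  universe <- unique(universe)
  query <- unique(intersect(query, universe))
  target <- unique(intersect(target, universe))
  if (length(query) == 0 || length(target) == 0)
    stop("hypergeom_enrich: empty query or target after restriction ",
         "to the universe")
  N <- length(universe)
  K <- length(target)
  n <- length(query)
  k <- length(intersect(query, target))
  expected <- n * K / N
  upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- if (alternative == "greater") upper else {
    lower <- stats::phyper(k, K, N - K, n)
    min(1, 2 * min(upper, lower))
  }
  data.frame(set_name = set_name, k = k, n_query = n, K_set = K,
             N_universe = N, expected = expected, fold = k / expected,
             pct_enrichment = (k / expected - 1) * 100, p = p,
             stringsAsFactors = FALSE)
}

#' Disease gene-set profile of up- and downregulated proteins
#'
#' Runs [hypergeom_enrich()] of each direction's gene list against every
#' set in the collection (after restriction to the background) and
#' applies Benjamini-Hochberg correction within each direction's family.
#'
#' @param up,down disjoint character vectors of gene ids.
#' @param collection a `"gene_set_collection"`.
#' @param alternative tail convention passed to [hypergeom_enrich()];
#'   default `"two.sided"` matching the profile's reporting convention.
#' @return data.frame with a `direction` column, one row per
#'   (direction, set), `p_adj` BH-adjusted within direction; empty sets
#'   are skipped.
#' @export
disease_profile <- function(up, down, collection,
                            alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(intersect(up, down)) > 0)
    stop("disease_profile: up and down lists must be disjoint")
  coll <- restrict_to_background(collection, collection$universe)
  sets <- coll$sets[lengths(coll$sets) > 0]
  res <- list()
  for (dir in c("up", "down")) {
    genes <- intersect(if (dir == "up") up else down, coll$universe)
    if (length(genes) == 0 || length(sets) == 0) next
    rows <- do.call(rbind, lapply(names(sets), function(nm)
      hypergeom_enrich(genes, sets[[nm]], coll$universe,
                       alternative = alternative, set_name = nm)))
    rows$p_adj <- stats::p.adjust(rows$p, method = "BH")
    rows <- cbind(direction = dir, rows, stringsAsFactors = FALSE)
    res[[dir]] <- rows
  }
  if (length(res) == 0)
    return(data.frame(direction = character(0), set_name = character(0),
                      k = integer(0), p = numeric(0), p_adj = numeric(0)))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Call interactors from bait-vs-IgG spectral counts
#'
#' A protein joins the interactome when its mean bait spectral count is
#' at least `fold_min` times its mean control (IgG) count and a
#' one-tailed Welch t-test of bait > control has `p < p_max`. Proteins
#' absent from the control (mean IgG count 0, positive bait mean) pass
#' the fold criterion by convention and are tagged `not_in_control`.
#'
#' @param counts data.frame with `protein_id`, bait replicate columns
#'   (`bait_*`) and control columns (`igg_*`); counts must be
#'   non-negative integers.
#' @param fold_min minimum bait/control mean ratio; default 2.
#' @param p_max one-tailed t-test threshold; default 0.1.
#' @return data.frame: protein_id, mean_bait, mean_igg, fold (Inf when
#'   absent in control), not_in_control, p, called.
#' @export
call_interactome <- function(counts, fold_min = 2, p_max = 0.1) {
  bait_cols <- grep("^bait", names(counts), value = TRUE)
  igg_cols <- grep("^igg", names(counts), value = TRUE)
  stopifnot(length(bait_cols) >= 2, length(igg_cols) >= 2)
  bm <- as.matrix(counts[bait_cols])
  im <- as.matrix(counts[igg_cols])
  if (any(bm != round(bm)) || any(im != round(im)) ||
      any(bm < 0) || any(im < 0))
    stop("call_interactome: counts must be non-negative integers")
  n <- nrow(counts)
  mean_bait <- rowMeans(bm)
  mean_igg <- rowMeans(im)
  p <- vapply(seq_len(n), function(i) {
    b <- bm[i, ]; g <- im[i, ]
    if (stats::sd(b) == 0 && stats::sd(g) == 0)
      return(if (mean(b) > mean(g)) 0 else 1)
    stats::t.test(b, g, alternative = "greater")$p.value
  }, numeric(1))
  not_in_control <- mean_igg == 0 & mean_bait > 0
  fold <- ifelse(mean_igg > 0, mean_bait / mean_igg,
                 ifelse(mean_bait > 0, Inf, NA_real_))
  pass_fold <- not_in_control | (mean_igg > 0 & mean_bait >= fold_min * mean_igg)
  data.frame(protein_id = counts$protein_id,
             mean_bait = mean_bait, mean_igg = mean_igg,
             fold = fold, not_in_control = not_in_control, p = p,
             called = pass_fold & p < p_max,
             stringsAsFactors = FALSE)
}

#' Overlap and effect-size concordance between two gene lists
#'
#' Computes the overlap of two lists, its hypergeometric enrichment over
#' the shared universe, and (optionally) the Pearson correlation of
#' paired effect sizes over the overlapping genes. An exclusion list
#' (e.g. genes inside the duplicated locus, whose cis dosage effects
#' correlate trivially) can be removed first.
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param universe background gene universe.
#' @param effects_a,effects_b named numeric vectors of effect sizes
#'   (names are gene ids); both required for the correlation.
#' @param exclude genes removed from both lists before analysis.
#' @return list with `overlap` (character), `enrichment` (one-row
#'   data.frame) and `correlation` (list r, r2, p, n, or NULL with
#'   attribute-style `flag` when fewer than 3 paired genes).
#' @export
cross_dataset_overlap <- function(list_a, list_b, universe,
                                  effects_a = NULL, effects_b = NULL,
                                  exclude = NULL) {
  if (!is.null(exclude)) {
    list_a <- setdiff(list_a, exclude)
    list_b <- setdiff(list_b, exclude)
    universe <- setdiff(universe, exclude)
  }
  ov <- intersect(intersect(list_a, list_b), universe)
  enr <- hypergeom_enrich(list_a, list_b, universe,
                          alternative = "greater")
  correlation <- NULL
  if (!is.null(effects_a) && !is.null(effects_b)) {
    paired <- ov[ov %in% names(effects_a) & ov %in% names(effects_b)]
    if (length(paired) >= 3) {
      ct <- stats::cor.test(effects_a[paired], effects_b[paired])
      correlation <- list(r = unname(ct$estimate),
                          r2 = unname(ct$estimate)^2,
                          p = ct$p.value, n = length(paired))
    } else {
      correlation <- list(flag = "overlap_too_small", n = length(paired))
    }
  }
  list(overlap = ov, enrichment = enr, correlation = correlation)
}

#' Read a GMT gene-set file
#'
#' Tab-delimited, one set per line: name, description, member genes.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept as
#'   attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[`, "", 2), names(sets))
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional character vector recycled over sets.
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
}
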