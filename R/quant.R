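#' Quality filter on peptide-fit r2
#'
#' Retains entries whose light/heavy chromatogram fit quality exceeds
#' `r2_min` (strictly). Entries at or below the threshold are unreliable
#' ratio measurements and are dropped.
#'
#' @param table a quantification table (data.frame with columns
#'   protein_id, replicate_id, genotype, ratio, r2).
#' @param r2_min minimum r2, in `[0, 1]`; default 0.5.
#' @return the filtered table; attribute `n_removed` holds the count of
#'   dropped entries.
#' @export
filter_quality <- function(table, r2_min = 0.5) {
  stopifnot(r2_min >= 0, r2_min <= 1)
  keep <- table$r2 > r2_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("filter_quality: no entries passed the r2 filter")
  attr(out, "n_removed") <- sum(!keep)
  out
}

# Two-sided Grubbs critical value at significance alpha for sample size n.
.grubbs_crit <- function(n, alpha) {
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Iterative Grubbs outlier filter
#'
#' Repeatedly removes the single most extreme value while the two-sided
#' Grubbs statistic `G = max|x - mean| / sd` exceeds its critical value
#' at level `alpha`. Testing needs at least 3 values; shorter inputs (or
#' zero-variance inputs, where G is undefined) are returned unchanged
#' with a flag.
#'
#' @param values numeric vector (e.g. one protein's replicate ratios).
#' @param alpha significance level of each Grubbs test; default 0.01.
#' @return list with `values` (retained), `removed` (in removal order)
#'   and `flag` (`"ok"`, `"too_few"` or `"constant"`).
#' @export
grubbs_filter <- function(values, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  x <- values
  removed <- numeric(0)
  if (length(x) < 3)
    return(list(values = x, removed = removed, flag = "too_few"))
  repeat {
    n <- length(x)
    if (n < 3) break
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      return(list(values = x, removed = removed,
                  flag = if (length(removed)) "ok" else "constant"))
    dev <- abs(x - mean(x))
    G <- max(dev) / s
    if (G > .grubbs_crit(n, alpha)) {
      i <- which.max(dev)
      removed <- c(removed, x[i])
      x <- x[-i]
    } else break
  }
  list(values = x, removed = removed, flag = "ok")
}

#' Replicate-coverage filter
#'
#' Keeps proteins quantified (non-missing) in at least `min_per_genotype`
#' replicates of each genotype, mirroring the requirement of at least
#' three samples per genotype before enrichment analysis.
#'
#' @param table long quantification table (missing cells are absent rows).
#' @param min_per_genotype minimum replicates per genotype; default 3.
#' @return the filtered table.
#' @export
coverage_filter <- function(table, min_per_genotype = 3) {
  stopifnot("genotype" %in% names(table))
  if (min_per_genotype <= 0) return(table)
  cnt <- table(table$protein_id, table$genotype)
  genos <- colnames(cnt)
  ok <- rownames(cnt)[apply(cnt >= min_per_genotype, 1, all)]
  if (length(genos) < 2) ok <- character(0)
  out <- table[table$protein_id %in% ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-replicate protein Z-scores
#'
#' Standardizes each biological replicate over its quantified proteins:
#' `Z_(P,i) = (P_i - Mean_i) / SD_i`, with `Mean_i` and `SD_i` computed
#' across proteins measured in replicate `i` (sample SD, n-1). Ratios are
#' log2-transformed first by default, since light/heavy ratio noise is
#' multiplicative.
#'
#' @param table long quantification table (one row per protein x
#'   replicate; duplicates, e.g. peptide-level rows, are aggregated by
#'   median first).
#' @param log_transform log2-transform ratios before standardizing
#'   (default TRUE).
#' @return object of class `"zscore_matrix"`: list with `z` (protein x
#'   replicate matrix, NA for missing cells), `mean_i`, `sd_i` and
#'   `genotype` (named by replicate).
#' @export
zscore_replicates <- function(table, log_transform = TRUE) {
  stopifnot(all(c("protein_id", "replicate_id", "genotype", "ratio")
                %in% names(table)))
  if (any(table$ratio <= 0, na.rm = TRUE))
    stop("zscore_replicates: ratios must be positive")
  val <- if (log_transform) log2(table$ratio) else table$ratio
  # peptide-level duplicates -> protein value by median
  key <- paste(table$protein_id, table$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    agg <- tapply(val, key, stats::median)
    parts <- strsplit(names(agg), "\r", fixed = TRUE)
    tab2 <- data.frame(protein_id = vapply(parts, `[`, "", 1),
                       replicate_id = vapply(parts, `[`, "", 2),
                       value = as.numeric(agg), stringsAsFactors = FALSE)
    geno_map <- table$genotype[!duplicated(table$replicate_id)]
    names(geno_map) <- table$replicate_id[!duplicated(table$replicate_id)]
  } else {
    tab2 <- data.frame(protein_id = table$protein_id,
                       replicate_id = table$replicate_id,
                       value = val, stringsAsFactors = FALSE)
    geno_map <- table$genotype[!duplicated(table$replicate_id)]
    names(geno_map) <- table$replicate_id[!duplicated(table$replicate_id)]
  }
  prots <- sort(unique(tab2$protein_id))
  reps <- unique(tab2$replicate_id)
  m <- matrix(NA_real_, length(prots), length(reps),
              dimnames = list(prots, reps))
  m[cbind(match(tab2$protein_id, prots),
          match(tab2$replicate_id, reps))] <- tab2$value

  mean_i <- colMeans(m, na.rm = TRUE)
  sd_i <- apply(m, 2, stats::sd, na.rm = TRUE)
  n_i <- colSums(!is.na(m))
  if (any(n_i < 2))
    stop("zscore_replicates: replicate ", reps[which(n_i < 2)[1]],
         " has fewer than 2 quantified proteins")
  if (any(!is.finite(sd_i)) || any(sd_i == 0))
    stop("zscore_replicates: zero variance in replicate ",
         reps[which(!is.finite(sd_i) | sd_i == 0)[1]])
  z <- sweep(sweep(m, 2, mean_i), 2, sd_i, "/")
  structure(list(z = z, mean_i = mean_i, sd_i = sd_i,
                 genotype = geno_map[reps]),
            class = "zscore_matrix")
}

#' Between-genotype Z-ratios
#'
#' For each protein, averages its replicate Z-scores within each genotype
#' and standardizes the difference by the empirical SD of those
#' differences over all quantified proteins:
#' `Zratio_p = (Z_dup_avg - Z_wt_avg) / SD(Zdiff over all proteins)`.
#' The shared denominator is attached to every row.
#'
#' @param zmat a `"zscore_matrix"` from [zscore_replicates()].
#' @return data.frame: protein_id, z_wt_avg, z_dup_avg, z_diff, z_ratio,
#'   sd_zdiff.
#' @export
zratio <- function(zmat) {
  stopifnot(inherits(zmat, "zscore_matrix"))
  geno <- zmat$genotype
  if (!all(c("WT", "DUP") %in% geno))
    stop("zratio: both genotypes (WT, DUP) must be present")
  wt <- zmat$z[, geno == "WT", drop = FALSE]
  du <- zmat$z[, geno == "DUP", drop = FALSE]
  z_wt <- rowMeans(wt, na.rm = TRUE)
  z_du <- rowMeans(du, na.rm = TRUE)
  ok <- is.finite(z_wt) & is.finite(z_du)
  z_wt <- z_wt[ok]; z_du <- z_du[ok]
  if (sum(ok) < 2)
    stop("zratio: need at least 2 proteins quantified in both genotypes")
  zdiff <- z_du - z_wt
  sd_zdiff <- stats::sd(zdiff)
  if (sd_zdiff == 0)
    stop("zratio: degenerate input, SD of Z-differences is 0")
  data.frame(protein_id = names(zdiff),
             z_wt_avg = unname(z_wt), z_dup_avg = unname(z_du),
             z_diff = unname(zdiff),
             z_ratio = unname(zdiff) / sd_zdiff,
             sd_zdiff = sd_zdiff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify proteins by Z-ratio
#'
#' Strict thresholds: `up` if `z_ratio > threshold`, `down` if
#' `z_ratio < -threshold`, otherwise `null`.
#'
#' @param results data.frame from [zratio()].
#' @param threshold positive cutoff; default 1.96.
#' @return `results` with a `call` column; attribute `counts` holds the
#'   partition sizes.
#' @export
classify <- function(results, threshold = 1.96) {
  stopifnot(threshold > 0)
  call <- ifelse(results$z_ratio > threshold, "up",
                 ifelse(results$z_ratio < -threshold, "down", "null"))
  results$call <- call
  attr(results, "counts") <-
    c(up = sum(call == "up"), down = sum(call == "down"),
      null = sum(call == "null"))
  results
}

#' Full quantification chain
#'
#' Runs the post-processing pipeline in fixed order: r2 quality filter,
#' peptide-to-protein aggregation (median, inside the Z-score step),
#' per-protein iterative Grubbs outlier removal, replicate-coverage
#' filter, per-replicate Z-scores, Z-ratios, and dysregulation calls.
#' Filters precede standardization so outliers never drive `Mean_i`/`SD_i`.
#'
#' @param table long quantification table.
#' @param r2_min r2 quality threshold (strict); default 0.5.
#' @param grubbs_alpha per-test Grubbs level; default 0.01.
#' @param min_per_genotype replicate-coverage minimum; default 3.
#' @param threshold Z-ratio call threshold; default 1.96.
#' @param log_transform log2-transform ratios; default TRUE.
#' @return classified [zratio()] data.frame.
#' @export
quantify_zratio <- function(table, r2_min = 0.5, grubbs_alpha = 0.01,
                            min_per_genotype = 3, threshold = 1.96,
                            log_transform = TRUE) {
  tab <- filter_quality(table, r2_min)
  # per-protein Grubbs on (log) ratio values across replicates
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$protein_id),
                        function(idx) {
    lv <- if (log_transform) log2(tab$ratio[idx]) else tab$ratio[idx]
    live <- seq_along(lv)
    repeat {
      if (length(live) < 3) break
      s <- stats::sd(lv[live])
      if (!is.finite(s) || s == 0) break
      dev <- abs(lv[live] - mean(lv[live]))
      if (max(dev) / s > .grubbs_crit(length(live), grubbs_alpha)) {
        live <- live[-which.max(dev)]
      } else break
    }
    idx[live]
  }), use.names = FALSE)
  tab <- tab[sort(keep), , drop = FALSE]
  tab <- coverage_filter(tab, min_per_genotype)
  zm <- zscore_replicates(tab, log_transform = log_transform)
  classify(zratio(zm), threshold)
}
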