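#' Protein abundance table
#'
#' A proteins x samples matrix of non-negative abundances with a missingness
#' mask and a sample-to-condition map. Missing (undetected) values are `NA`
#' in the abundance matrix and `FALSE` in the `detected` mask.
#'
#' @param abundance numeric matrix, proteins in rows (rownames = protein
#'   ids), samples in columns (colnames = sample ids); `NA` marks undetected.
#' @param conditions factor or character of conditions, one per sample
#'   (named by sample id or in column order).
#' @param protein_ids optional protein ids; defaults to rownames.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(abundance, conditions, protein_ids = NULL) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop_bad_arg("abundance", "must be a numeric proteins x samples matrix")
  }
  if (any(abundance < 0, na.rm = TRUE)) {
    stop_bad_arg("abundance", "abundances must be non-negative")
  }
  if (is.null(protein_ids)) protein_ids <- rownames(abundance)
  if (is.null(protein_ids)) {
    protein_ids <- sprintf("P%04d", seq_len(nrow(abundance)))
  }
  if (anyDuplicated(protein_ids)) {
    stop_bad_arg("protein_ids", "must be unique")
  }
  rownames(abundance) <- protein_ids
  if (length(conditions) != ncol(abundance)) {
    stop_bad_arg("conditions", "need one condition per sample")
  }
  if (!is.null(names(conditions)) && !is.null(colnames(abundance))) {
    conditions <- conditions[colnames(abundance)]
  }
  conditions <- as.factor(conditions)
  if (nlevels(conditions) < 1L) stop_bad_arg("conditions", "must be non-empty")
  structure(list(abundance = abundance, detected = !is.na(abundance),
                 conditions = conditions, protein_ids = protein_ids),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf(
    "Abundance table: %d proteins x %d samples, %d conditions (%s), %.1f%% missing\n",
    nrow(x$abundance), ncol(x$abundance), nlevels(x$conditions),
    paste(levels(x$conditions), collapse = ", "),
    100 * mean(!x$detected)))
  invisible(x)
}

#' Presence filtering
#'
#' Keeps a protein only if there exists a condition in which it is detected
#' in strictly more than `min_frac` of that condition's samples (the > 75%
#' rule by default; a protein detected in exactly 3 of 4 samples is
#' dropped). Protein order is preserved.
#'
#' @param tab an [abundance_table()].
#' @param min_frac detection fraction threshold (strict).
#' @return the filtered `abundance_table`.
#' @export
presence_filter <- function(tab, min_frac = 0.75) {
  stopifnot(inherits(tab, "abundance_table"))
  check_finite_scalar(min_frac, "min_frac", min = 0)
  keep <- rep(FALSE, nrow(tab$abundance))
  for (lv in levels(tab$conditions)) {
    cols <- tab$conditions == lv
    keep <- keep | rowMeans(tab$detected[, cols, drop = FALSE]) > min_frac
  }
  out <- abundance_table(tab$abundance[keep, , drop = FALSE],
                         conditions = tab$conditions)
  if (!is.null(attr(tab, "imputed"))) {
    attr(out, "imputed") <- attr(tab, "imputed")[keep, , drop = FALSE]
  }
  out
}

#' Low-quantile imputation of undetected values
#'
#' Replaces each sample's undetected entries by that sample's `q`-quantile
#' (2.5% by default, linear-interpolation quantile) of its detected
#' abundances — a left-censoring model: what was not seen is assumed to sit
#' at the bottom of the sample's detection range. Imputation is strictly
#' per-sample. The detection mask is preserved, not overwritten: downstream
#' presence filtering and ranking still see the true detection status
#' (imputed entries keep ranking as undetected), and the imputed positions
#' are also recorded in the `imputed` attribute.
#'
#' @param tab an [abundance_table()].
#' @param q lower quantile used as the imputed constant.
#' @return a complete `abundance_table` (no `NA`s).
#' @export
impute_low_quantile <- function(tab, q = 0.025) {
  stopifnot(inherits(tab, "abundance_table"))
  if (!is.numeric(q) || q < 0 || q > 1) stop_bad_arg("q", "must be in [0, 1]")
  x <- tab$abundance
  imputed <- !tab$detected
  for (s in seq_len(ncol(x))) {
    det <- x[tab$detected[, s], s]
    if (!length(det)) {
      stop(sprintf("sample '%s' has no detected values; cannot impute",
                   colnames(x)[s]), call. = FALSE)
    }
    if (any(imputed[, s])) {
      x[imputed[, s], s] <- quantile(det, probs = q, names = FALSE)
    }
  }
  out <- abundance_table(x, conditions = tab$conditions)
  out$detected <- tab$detected # keep the true detection status
  attr(out, "imputed") <- imputed
  out
}

#' Trimmed mean of M-values (TMM) scale factors
#'
#' Per-sample scaling factors for compositional abundance data, following
#' the trimmed-mean-of-M-values algorithm: the reference is the sample whose
#' 75th abundance percentile (of library-size-normalized values) is closest
#' to the mean such percentile; per sample, log2 ratios (M) and mean log2
#' abundances (A) against the reference are computed on library-size
#' normalized values, doubly trimmed (30% of M, 5% of A on each side), and
#' the factor is 2 to the precision-weighted mean of the surviving M values
#' (delta-method weights). The returned values are *effective* per-sample
#' scale factors — library size times the TMM factor — normalized to
#' geometric mean 1, so a sample loaded at 4x its twin gets a factor 4x
#' larger. The raw TMM factors (geometric mean 1) are attached as
#' `attr(, "tmm")`.
#'
#' @param tab an [abundance_table()], complete (imputed, strictly positive).
#' @param trim_m M-value trim fraction (each side).
#' @param trim_a A-value trim fraction (each side).
#' @return named numeric vector of effective scale factors, with attributes
#'   `tmm` (raw TMM factors) and `lib_sizes`.
#' @export
tmm_factors <- function(tab, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(tab, "abundance_table"))
  x <- tab$abundance
  if (ncol(x) < 2L) stop_bad_arg("tab", "needs at least two samples")
  if (anyNA(x)) stop_bad_arg("tab", "contains missing values; impute first")
  if (any(x <= 0)) {
    stop_bad_arg("tab", "contains non-positive abundances; log undefined")
  }
  lib <- colSums(x)
  uq <- apply(sweep(x, 2, lib, `/`), 2, quantile, probs = 0.75, names = FALSE)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(s) {
    if (s == ref) return(1)
    xs <- x[, s] / lib[s]
    xr <- x[, ref] / lib[ref]
    m <- log2(xs / xr)
    a <- 0.5 * log2(xs * xr)
    # delta-method variance of M; precision weighting uses its inverse
    v <- (lib[s] - x[, s]) / (lib[s] * x[, s]) +
      (lib[ref] - x[, ref]) / (lib[ref] * x[, ref])
    n <- length(m)
    lo_m <- floor(n * trim_m) + 1
    hi_m <- n + 1 - lo_m
    lo_a <- floor(n * trim_a) + 1
    hi_a <- n + 1 - lo_a
    rm_ <- rank(m)
    ra <- rank(a)
    keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  tmm <- f / exp(mean(log(f)))
  eff <- lib * tmm
  eff <- eff / exp(mean(log(eff)))
  names(eff) <- colnames(x)
  structure(eff, tmm = stats::setNames(tmm, colnames(x)),
            lib_sizes = stats::setNames(lib, colnames(x)))
}

#' Within-sample abundance ranks
#'
#' Ranks the proteins of each sample by relative abundance (rank 1 = most
#' abundant; ties get the average rank) — the scale-free comparison used
#' when per-sample loading cannot be normalized away. Undetected proteins
#' share the worst tied rank of their sample, so rank averages stay
#' comparable across samples of different detection depth. Per-condition
#' mean ranks are computed across each condition's samples.
#'
#' @param tab an [abundance_table()].
#' @return an object of class `rank_table`: the proteins x samples rank
#'   matrix, the per-condition mean-rank matrix, conditions, protein ids.
#' @export
rank_proteins <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  x <- tab$abundance
  x[!tab$detected] <- -Inf # undetected sink to the worst tied rank
  ranks <- apply(x, 2, function(v) rank(-v, ties.method = "average"))
  rownames(ranks) <- tab$protein_ids
  cond_mean <- vapply(levels(tab$conditions), function(lv) {
    rowMeans(ranks[, tab$conditions == lv, drop = FALSE])
  }, numeric(nrow(ranks)))
  structure(list(ranks = ranks, cond_mean = cond_mean,
                 conditions = tab$conditions,
                 protein_ids = tab$protein_ids),
            class = "rank_table")
}

#' @export
print.rank_table <- function(x, ...) {
  cat(sprintf("Rank table: %d proteins x %d samples (%d conditions)\n",
              nrow(x$ranks), ncol(x$ranks), nlevels(x$conditions)))
  invisible(x)
}

#' Rank-based differential comparison between two conditions
#'
#' Per protein, compares its within-sample ranks between two conditions with
#' a two-sided rank-sum (Wilcoxon) test, reports the mean-rank difference
#' (condition A minus B; negative = more abundant in A since rank 1 is the
#' top), and adjusts p-values by Benjamini-Hochberg.
#'
#' @param ranks a [rank_proteins()] result.
#' @param cond_a,cond_b condition names to compare.
#' @param fdr significance threshold applied to the adjusted q-values.
#' @return a data frame (class `differential_result`) with columns
#'   `protein_id`, `mean_rank_diff`, `p_value`, `q_value`, `significant`,
#'   sorted by `q_value` then by decreasing absolute difference.
#' @export
differential_rank_test <- function(ranks, cond_a, cond_b, fdr = 0.05) {
  stopifnot(inherits(ranks, "rank_table"))
  for (cn in c(cond_a, cond_b)) {
    if (!cn %in% levels(ranks$conditions)) {
      stop(sprintf("condition '%s' absent from the table", cn), call. = FALSE)
    }
  }
  ia <- ranks$conditions == cond_a
  ib <- ranks$conditions == cond_b
  if (sum(ia) < 3L || sum(ib) < 3L) {
    warning("fewer than 3 samples in a condition; rank-sum test is weak",
            call. = FALSE)
  }
  ra <- ranks$ranks[, ia, drop = FALSE]
  rb <- ranks$ranks[, ib, drop = FALSE]
  p <- vapply(seq_len(nrow(ra)), function(i) {
    if (all(ra[i, ] == rb[i, 1]) && all(rb[i, ] == rb[i, 1])) return(1)
    suppressWarnings(wilcox.test(ra[i, ], rb[i, ])$p.value)
  }, 0)
  diff <- rowMeans(ra) - rowMeans(rb)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(protein_id = ranks$protein_ids,
                    mean_rank_diff = diff, p_value = p, q_value = q,
                    significant = q < fdr, row.names = NULL)
  out <- out[order(out$q_value, -abs(out$mean_rank_diff)), ]
  rownames(out) <- NULL
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Most abundant proteins of a condition
#'
#' The `n` proteins with the smallest mean rank (i.e. highest relative
#' abundance) in a condition; ties are broken by protein id.
#'
#' @param ranks a [rank_proteins()] result.
#' @param condition condition name.
#' @param n list length.
#' @return a character vector of protein ids, most abundant first.
#' @export
top_n_list <- function(ranks, condition, n = 100) {
  stopifnot(inherits(ranks, "rank_table"))
  if (!condition %in% colnames(ranks$cond_mean)) {
    stop(sprintf("condition '%s' absent from the table", condition),
         call. = FALSE)
  }
  if (n > nrow(ranks$ranks)) stop_bad_arg("n", "exceeds the protein count")
  mr <- ranks$cond_mean[, condition]
  ranks$protein_ids[order(mr, ranks$protein_ids)][seq_len(n)]
}

#' Overlap percentage of two protein lists
#'
#' Similarity of two protein lists as the shared fraction of their union,
#' expressed as a whole percentage (truncated to the printed precision:
#' 95 shared over a union of 117 gives 81%).
#'
#' @param list_a,list_b character vectors of unique protein ids.
#' @return an object of class `overlap_result`: list with `size_a`,
#'   `size_b`, `shared`, `union`, `percent` (integer) and `percent_exact`.
#' @export
#' @examples
#' overlap_percent(sprintf("P%03d", 1:117), sprintf("P%03d", 23:117))$percent
overlap_percent <- function(list_a, list_b) {
  if (anyDuplicated(list_a) || anyDuplicated(list_b)) {
    stop_bad_arg("list_a/list_b", "ids must be unique within each list")
  }
  shared <- length(intersect(list_a, list_b))
  un <- length(union(list_a, list_b))
  if (un == 0L) stop_bad_arg("list_a/list_b", "both lists are empty")
  pct <- shared / un * 100
  structure(list(size_a = length(list_a), size_b = length(list_b),
                 shared = shared, union = un,
                 percent = as.integer(floor(pct)), percent_exact = pct),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Protein list overlap: %d%% (%d/%d); |A| = %d, |B| = %d\n",
              x$percent, x$shared, x$union, x$size_a, x$size_b))
  invisible(x)
}
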