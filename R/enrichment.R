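# Contingency-table enrichment of restricted genes among caste-biased
# expression sets: EST-to-gene set construction, observed/expected tables,
# Pearson chi-square (with Yates continuity correction restricted to 2x2
# tables), per-cell percentage deviations, and p-value-cutoff sensitivity
# scans.

#' Map expression EST sets to gene sets
#'
#' Converts per-label EST sets into distinct gene sets using accepted
#' EST-to-gene alignments. Genes recruited into both opposite-bias sets are
#' dropped from both with a warning; a gene appearing in a biased set and
#' in `no_difference` keeps its biased assignment (the no-difference set is
#' a complement set by construction).
#'
#' @param expression An `expression_sets` object (or named list of
#'   data.frames with an `id` column of EST ids).
#' @param alignments data.frame with columns `est_id`, `gene_id`,
#'   `accepted` (logical); unaccepted or unlisted ESTs contribute nothing.
#' @return Named list of character vectors of gene ids, one per label.
#' @export
build_gene_sets <- function(expression, alignments) {
  stopifnot(all(c("est_id", "gene_id", "accepted") %in% names(alignments)))
  acc <- alignments[alignments$accepted & !is.na(alignments$gene_id), ,
                    drop = FALSE]
  lookup <- setNames(acc$gene_id, acc$est_id)
  sets <- lapply(expression, function(df) {
    ids <- if (is.data.frame(df)) df$id else as.character(df)
    unique(unname(lookup[ids[ids %in% names(lookup)]]))
  })
  contrast <- attr(expression, "contrast") %||%
    setdiff(names(sets), "no_difference")[1:2]
  if (all(contrast %in% names(sets))) {
    both <- intersect(sets[[contrast[1]]], sets[[contrast[2]]])
    if (length(both) > 0) {
      warning(length(both), " gene(s) recruited by both opposite-bias sets; ",
              "excluded: ", paste(head(both, 5), collapse = ", "))
      sets[[contrast[1]]] <- setdiff(sets[[contrast[1]]], both)
      sets[[contrast[2]]] <- setdiff(sets[[contrast[2]]], both)
    }
  }
  if ("no_difference" %in% names(sets)) {
    biased <- unlist(sets[setdiff(names(sets), "no_difference")],
                     use.names = FALSE)
    sets$no_difference <- setdiff(sets$no_difference, biased)
  }
  sets
}

#' Build a homology-class by expression-group contingency table
#'
#' Cross-tabulates gene homology classes against expression groups.
#' `collapse = "orphan"` (the headline analysis) uses two rows, orphan vs
#' non-orphan; `"trg_group"` pools the five restricted classes against the
#' rest; `"none"` keeps all seven classes as rows.
#'
#' @param classes Named character vector gene_id -> class covering every
#'   gene in the sets.
#' @param gene_sets Named list of gene-id vectors (the expression columns).
#' @param collapse One of `"orphan"`, `"trg_group"`, `"none"`.
#' @return Object of class `contingency_table`: list with `observed`,
#'   `expected`, `row_totals`, `col_totals`, `n`.
#' @export
build_contingency <- function(classes, gene_sets,
                              collapse = c("orphan", "trg_group", "none")) {
  collapse <- match.arg(collapse)
  if (length(gene_sets) == 0 || all(lengths(gene_sets) == 0))
    stop("gene sets are empty")
  missing <- setdiff(unlist(gene_sets, use.names = FALSE), names(classes))
  if (length(missing) > 0)
    stop("genes without a class: ", paste(head(missing, 5), collapse = ", "))
  rowlab <- switch(collapse,
    orphan = function(cl) ifelse(cl == "orphan", "orphan", "non_orphan"),
    trg_group = function(cl) ifelse(cl %in% TRG_CLASSES, "trg", "non_trg"),
    none = function(cl) cl)
  levels <- switch(collapse,
    orphan = c("orphan", "non_orphan"),
    trg_group = c("trg", "non_trg"),
    none = HOMOLOGY_CLASSES)
  obs <- sapply(gene_sets, function(gs) {
    table(factor(rowlab(classes[gs]), levels = levels))
  })
  obs <- matrix(as.integer(obs), nrow = length(levels),
                dimnames = list(levels, names(gene_sets)))
  contingency_from_observed(obs)
}

#' Construct a contingency table from observed counts
#'
#' @param observed Integer matrix of non-negative counts with row and
#'   column names.
#' @return A `contingency_table` with expected counts
#'   `E_ij = row_total_i * col_total_j / N`.
#' @export
contingency_from_observed <- function(observed) {
  if (any(observed < 0)) stop("observed counts must be non-negative")
  n <- sum(observed)
  if (n == 0) stop("contingency table is empty")
  rt <- rowSums(observed); ct <- colSums(observed)
  expected <- outer(rt, ct) / n
  structure(list(observed = observed, expected = expected,
                 row_totals = rt, col_totals = ct, n = n),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("contingency_table (N =", x$n, ")\n")
  print(x$observed)
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Computes `sum((|O - E| - c)^2 / E)` with `c = 0.5` under the Yates
#' continuity correction (permitted only for 2x2 tables) and `c = 0`
#' otherwise; `df = (rows - 1)(cols - 1)`; p-value from the chi-square
#' distribution. Zero expected cells are an error naming the cell.
#'
#' @param table A `contingency_table`.
#' @param yates Logical; apply the continuity correction (2x2 only).
#' @return Object of class `enrichment_result`: list with `statistic`,
#'   `df`, `p_value`, `yates`, `observed`, `expected`,
#'   `percent_deviation` (per-cell `100 (O - E) / E`).
#' @export
chi_square <- function(table, yates = FALSE) {
  O <- table$observed; E <- table$expected
  if (any(E == 0)) {
    idx <- which(E == 0, arr.ind = TRUE)[1, ]
    stop("expected count is zero in cell (",
         rownames(E)[idx[1]], ", ", colnames(E)[idx[2]], ")")
  }
  if (yates && !all(dim(O) == c(2, 2)))
    stop("Yates continuity correction is only defined for 2x2 tables")
  c0 <- if (yates) 0.5 else 0
  dev <- pmax(abs(O - E) - c0, 0)
  stat <- sum(dev^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  structure(list(statistic = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE),
                 yates = yates, observed = O, expected = E,
                 percent_deviation = 100 * (O - E) / E),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("chi-square = %.4g, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$yates) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Per-cell percentage deviations of a contingency table
#'
#' The effect-direction measure `100 (O - E) / E` for every cell, plus the
#' cell with the largest absolute deviation.
#'
#' @param table A `contingency_table`.
#' @return List with `deviations` (numeric matrix) and `extreme_cell`
#'   (named list: row, col, deviation).
#' @export
percentage_deviations <- function(table) {
  if (any(table$expected == 0)) stop("expected counts must be positive")
  dev <- 100 * (table$observed - table$expected) / table$expected
  idx <- which(abs(dev) == max(abs(dev)), arr.ind = TRUE)[1, ]
  list(deviations = dev,
       extreme_cell = list(row = rownames(dev)[idx[1]],
                           col = colnames(dev)[idx[2]],
                           deviation = dev[idx[1], idx[2]]))
}

#' Sensitivity of the enrichment test to the differential-expression cutoff
#'
#' Re-forms the biased EST sets at each p-value threshold (an EST is biased
#' when its p-value is at or below the threshold; all others join the
#' no-difference set), rebuilds the orphan vs non-orphan contingency table
#' at the gene level, and re-runs the chi-square test. Thresholds that
#' leave a biased set empty are reported as insufficient data rather than
#' raising.
#'
#' @param est_records data.frame with columns `est_id`, `gene_id` (NA when
#'   unmapped), `direction` (one of the two biased labels, NA for
#'   non-candidate ESTs), `p_value`.
#' @param classes Named character vector gene_id -> class.
#' @param thresholds Descending numeric vector of p-value cutoffs (>= 1
#'   element; empty is an error).
#' @param alpha Significance level for the per-threshold flag.
#' @return data.frame with one row per threshold: `threshold`, `n_biased_1`,
#'   `n_biased_2`, `statistic`, `df`, `p_value`, `significant`,
#'   `insufficient_data`.
#' @export
cutoff_sensitivity_scan <- function(est_records, classes, thresholds,
                                    alpha = 0.05) {
  if (length(thresholds) == 0) stop("thresholds must be non-empty")
  stopifnot(all(c("est_id", "gene_id", "direction", "p_value") %in%
                  names(est_records)))
  labels <- sort(unique(est_records$direction[!is.na(est_records$direction)]))
  if (length(labels) != 2) stop("need exactly two bias directions")
  rows <- list()
  for (th in thresholds) {
    biased <- !is.na(est_records$direction) &
      !is.na(est_records$p_value) & est_records$p_value <= th
    sets <- list()
    for (lab in labels) {
      idx <- biased & est_records$direction == lab
      sets[[lab]] <- unique(est_records$gene_id[idx & !is.na(est_records$gene_id)])
    }
    nd_idx <- !biased
    sets$no_difference <- setdiff(
      unique(est_records$gene_id[nd_idx & !is.na(est_records$gene_id)]),
      unlist(sets[labels], use.names = FALSE))
    if (any(lengths(sets[labels]) == 0)) {
      rows[[length(rows) + 1]] <- data.frame(
        threshold = th, n_biased_1 = length(sets[[labels[1]]]),
        n_biased_2 = length(sets[[labels[2]]]), statistic = NA_real_,
        df = NA_integer_, p_value = NA_real_, significant = NA,
        insufficient_data = TRUE, stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(chi_square(build_contingency(classes, sets, "orphan")),
                    error = function(e) NULL)
    rows[[length(rows) + 1]] <- data.frame(
      threshold = th,
      n_biased_1 = length(sets[[labels[1]]]),
      n_biased_2 = length(sets[[labels[2]]]),
      statistic = if (is.null(res)) NA_real_ else res$statistic,
      df = if (is.null(res)) NA_integer_ else res$df,
      p_value = if (is.null(res)) NA_real_ else res$p_value,
      significant = if (is.null(res)) NA else res$p_value < alpha,
      insufficient_data = is.null(res),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
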