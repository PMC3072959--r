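# Expression gene/EST sets: one-identifier-per-line lists with an optional
# second p-value column, as produced by microarray differential-expression
# studies. The non-differential set of a contrast is derived by subtracting
# both biased lists from the complete array list.

read_id_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(data.frame(id = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1)
  pv <- vapply(parts, function(x)
    if (length(x) >= 2) suppressWarnings(as.numeric(x[2])) else NA_real_,
    numeric(1))
  if (any(!is.na(pv) & (pv < 0 | pv > 1)))
    stop("p-values outside [0, 1] in ", path)
  data.frame(id = ids, p_value = pv, stringsAsFactors = FALSE)
}

#' Read the expression lists of a two-way contrast
#'
#' Reads the two biased lists (e.g. queen- and worker-biased ESTs) and the
#' complete array list, computes the `no_difference` set as the complete
#' list minus both biased lists, and validates that the biased lists are
#' disjoint. Duplicated identifiers within one list are collapsed with a
#' warning (set semantics).
#'
#' @param paths Named list/vector with entries for both contrast labels and
#'   `full` (the complete array list), e.g.
#'   `list(queen = ..., worker = ..., full = ...)`.
#' @param contrast Character vector of the two biased labels, in the order
#'   they appear in `paths`.
#' @return Object of class `expression_sets`: list with one element per
#'   label (`<label1>`, `<label2>`, `no_difference`), each a data.frame of
#'   `id` and `p_value`, plus attribute `contrast`.
#' @export
read_expression_lists <- function(paths, contrast = c("queen", "worker")) {
  stopifnot(length(contrast) == 2)
  if (!all(c(contrast, "full") %in% names(paths)))
    stop("paths must name both contrast labels and 'full'")
  sets <- lapply(paths[c(contrast, "full")], read_id_list)
  names(sets) <- c(contrast, "full")
  for (lab in names(sets)) {
    dup <- duplicated(sets[[lab]]$id)
    if (any(dup)) {
      warning(sum(dup), " duplicated identifier(s) in '", lab,
              "' list; deduplicated")
      sets[[lab]] <- sets[[lab]][!dup, , drop = FALSE]
    }
  }
  both <- intersect(sets[[contrast[1]]]$id, sets[[contrast[2]]]$id)
  if (length(both) > 0)
    stop("identifier(s) present in both biased lists: ",
         paste(head(both, 5), collapse = ", "))
  if (nrow(sets$full) == 0 &&
      (nrow(sets[[contrast[1]]]) > 0 || nrow(sets[[contrast[2]]]) > 0))
    stop("complete array list is empty but biased lists are not")
  biased <- c(sets[[contrast[1]]]$id, sets[[contrast[2]]]$id)
  nd <- sets$full[!sets$full$id %in% biased, , drop = FALSE]
  out <- list(sets[[contrast[1]]], sets[[contrast[2]]], nd)
  names(out) <- c(contrast, "no_difference")
  structure(out, contrast = contrast, class = "expression_sets")
}

#' @export
print.expression_sets <- function(x, ...) {
  cat("expression_sets:",
      paste(sprintf("%s=%d", names(x), vapply(x, nrow, integer(1))),
            collapse = ", "), "\n")
  invisible(x)
}
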