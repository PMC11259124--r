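# Descriptive cohort statistics and diagnostic-yield summaries.

#' Summarise a cohort manifest
#'
#' Computes, per numeric field: n (non-missing), median (mean of the central
#' two values for even n), arithmetic mean, and sample standard deviation
#' (n - 1 denominator; `NA` for a single value). Per categorical field:
#' proportions of each level among non-missing values.
#'
#' @param manifest Data frame, one row per individual.
#' @param numeric_fields Character vector of numeric column names; defaults
#'   to all numeric columns.
#' @param categorical_fields Character vector of categorical column names;
#'   defaults to all character/factor columns.
#' @return Object of class `"cohort_summary"`: list with `n`, `numeric`
#'   (data frame: field, n, median, mean, sd, n_missing) and `categorical`
#'   (named list of proportion tables).
#' @export
describe_cohort <- function(manifest, numeric_fields = NULL,
                            categorical_fields = NULL) {
  stopifnot(nrow(manifest) >= 1)
  if (is.null(numeric_fields))
    numeric_fields <- names(manifest)[vapply(manifest, is.numeric, logical(1))]
  if (is.null(categorical_fields))
    categorical_fields <- names(manifest)[vapply(manifest, function(x)
      is.character(x) || is.factor(x), logical(1))]
  num <- do.call(rbind, lapply(numeric_fields, function(f) {
    x <- manifest[[f]]
    xx <- x[!is.na(x)]
    data.frame(field = f, n = length(xx),
               median = if (length(xx)) stats::median(xx) else NA_real_,
               mean = if (length(xx)) mean(xx) else NA_real_,
               sd = if (length(xx) > 1) stats::sd(xx) else NA_real_,
               n_missing = sum(is.na(x)), stringsAsFactors = FALSE)
  }))
  cat_ <- lapply(categorical_fields, function(f) {
    x <- manifest[[f]]
    x <- x[!is.na(x) & nzchar(as.character(x))]
    if (!length(x)) return(numeric(0))
    tab <- table(x)
    as.numeric(tab) / length(x) -> p
    names(p) <- names(tab)
    p
  })
  names(cat_) <- categorical_fields
  structure(list(n = nrow(manifest), numeric = num, categorical = cat_),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, digits = 1, ...) {
  cat("Cohort of", x$n, "individuals\n")
  if (!is.null(x$numeric) && nrow(x$numeric)) {
    df <- x$numeric
    df$median <- round(df$median, digits)
    df$mean <- round(df$mean, digits)
    df$sd <- round(df$sd, digits)
    print(df, row.names = FALSE)
  }
  for (f in names(x$categorical)) {
    p <- x$categorical[[f]]
    if (!length(p)) next
    cat(f, ": ", paste(sprintf("%s %.1f%%", names(p), 100 * p),
                       collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-gene diagnostic yield of a cohort
#'
#' An individual is "diagnosed" when the reported-gene field is non-empty.
#' Overall yield is diagnosed / total. Gene shares divide each gene's count
#' by the number of diagnosed individuals; an individual with several
#' reported genes (separated by `sep`) counts once in the yield denominator
#' but once per gene in the shares, so shares can sum above 1.
#'
#' @param manifest Data frame with a reported-gene column.
#' @param gene_col Name of that column; empty string or `NA` = undiagnosed.
#' @param sep Separator for multi-gene entries.
#' @return List with `n`, `n_diagnosed`, `yield_pct`, and `genes` (data
#'   frame: gene, count, share_pct, sorted by count).
#' @export
diagnostic_yield <- function(manifest, gene_col = "reported_genes",
                             sep = ";") {
  x <- manifest[[gene_col]]
  if (is.null(x)) stop("column not found: ", gene_col)
  x <- as.character(x)
  diagnosed <- !is.na(x) & nzchar(x)
  n_diag <- sum(diagnosed)
  genes <- if (n_diag) {
    tab <- sort(table(unlist(strsplit(x[diagnosed], sep, fixed = TRUE))),
                decreasing = TRUE)
    data.frame(gene = names(tab), count = as.integer(tab),
               share_pct = 100 * as.integer(tab) / n_diag,
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(gene = character(0), count = integer(0),
                    share_pct = numeric(0))
  list(n = nrow(manifest), n_diagnosed = n_diag,
       yield_pct = 100 * n_diag / nrow(manifest), genes = genes)
}
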