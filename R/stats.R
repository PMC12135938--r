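#' Per-group summary of a measure
#'
#' Mean, sample standard deviation (n-1 denominator) and n per group;
#' groups with a single observation report `NA` SD. Missing values are
#' dropped listwise per measure and the drop count reported.
#'
#' @param table a data.frame with one group-label column and numeric
#'   measures
#' @param measure name of the measure column
#' @param group name of the group column
#' @return data.frame with `group`, `mean`, `sd`, `n`, and attribute
#'   `n_dropped`
#' @export
group_summary <- function(table, measure, group = "group") {
  if (!measure %in% names(table)) {
    stop(sprintf("unknown measure column '%s'", measure), call. = FALSE)
  }
  if (!group %in% names(table)) {
    stop(sprintf("unknown group column '%s'", group), call. = FALSE)
  }
  x <- table[[measure]]
  g <- table[[group]]
  keep <- !is.na(x)
  n_dropped <- sum(!keep)
  x <- x[keep]
  g <- g[keep]
  groups <- unique(g)
  out <- data.frame(
    group = groups,
    mean = vapply(groups, function(k) mean(x[g == k]), 0),
    sd = vapply(groups, function(k) {
      if (sum(g == k) < 2) NA_real_ else stats::sd(x[g == k])
    }, 0),
    n = vapply(groups, function(k) sum(g == k), 0L),
    stringsAsFactors = FALSE
  )
  attr(out, "n_dropped") <- n_dropped
  rownames(out) <- NULL
  out
}

#' Welch's two-sample t test
#'
#' Unequal-variance t test with Welch-Satterthwaite degrees of freedom and a
#' two-tailed p-value, the comparison used throughout the study for
#' two-group contrasts. Wraps `stats::t.test(var.equal = FALSE)`, with an
#' explicit resolution of the degenerate case in which both samples are
#' constant (t = 0 / p = 1 when the means agree, p = 0 otherwise).
#'
#' @param a,b numeric vectors, each of length >= 2
#' @return a `test_result` list: `statistic`, `df`, `p`, `means`, `n`,
#'   `direction` (sign of `mean(a) - mean(b)`), `method`, `stars`
#' @export
welch_t <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  res <- tryCatch(
    stats::t.test(a, b, var.equal = FALSE),
    error = function(e) NULL
  )
  if (is.null(res)) {
    # both samples constant
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    res <- list(
      statistic = c(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf),
      parameter = c(df = length(a) + length(b) - 2),
      p.value = if (eq) 1 else 0
    )
  }
  p <- res$p.value
  structure(
    list(
      statistic = unname(res$statistic),
      df = unname(res$parameter),
      p = p,
      means = c(a = mean(a), b = mean(b)),
      n = c(a = length(a), b = length(b)),
      direction = sign(mean(a) - mean(b)),
      method = "Welch two-sample t test (two-tailed)",
      stars = p_stars(p)
    ),
    class = "test_result"
  )
}

#' Significance stars
#'
#' The study's thresholds: `****` < 0.0001, `***` < 0.001, `**` < 0.01,
#' `*` < 0.05, otherwise `"ns"`.
#'
#' @param p p-value(s)
#' @return character vector of star codes
#' @export
p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) return(NA_character_)
    if (x < 1e-4) "****"
    else if (x < 1e-3) "***"
    else if (x < 1e-2) "**"
    else if (x < 0.05) "*"
    else "ns"
  }, character(1))
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s\n  t/F = %.4g, df = %s, p = %.4g (%s)\n", x$method,
              x$statistic, paste(signif(x$df, 4), collapse = ", "),
              x$p, x$stars))
  invisible(x)
}

#' One-way ANOVA with Tukey post hoc
#'
#' Fixed-effects one-way analysis of variance across two or more groups,
#' with optional Tukey HSD adjusted pairwise comparisons (the post hoc used
#' for the multi-group morphometric comparison). Implemented on
#' `stats::aov` / `stats::TukeyHSD`. When every value in every group is
#' identical the F statistic is reported as 0 with p = 1 rather than an
#' error.
#'
#' @param groups named list of numeric vectors (each n >= 2)
#' @param pairwise compute Tukey-adjusted pairwise p-values
#' @return a `test_result` with `statistic` (F), `df` (c(between, within)),
#'   `p`, `group_means`, `group_n`, and `pairwise` (data.frame with
#'   `comparison`, `diff`, `p_adj`, `stars`) when requested
#' @export
anova_oneway <- function(groups, pairwise = FALSE) {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (any(lengths(groups) < 2)) {
    stop("each group needs at least 2 non-missing values", call. = FALSE)
  }
  value <- unlist(groups, use.names = FALSE)
  lab <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df1 <- length(groups) - 1
  df2 <- length(value) - length(groups)
  if (stats::var(value) < 1e-24) {
    out <- list(statistic = 0, df = c(df1, df2), p = 1)
  } else {
    fit <- stats::aov(value ~ lab)
    s <- summary(fit)[[1]]
    out <- list(statistic = s[["F value"]][1], df = c(df1, df2),
                p = s[["Pr(>F)"]][1])
  }
  res <- structure(
    c(out, list(
      group_means = vapply(groups, mean, 0),
      group_n = lengths(groups),
      method = "One-way ANOVA",
      stars = p_stars(out$p)
    )),
    class = "test_result"
  )
  if (pairwise) {
    if (stats::var(value) < 1e-24) {
      cmb <- utils::combn(names(groups), 2)
      res$pairwise <- data.frame(
        comparison = paste(cmb[2, ], cmb[1, ], sep = "-"),
        diff = 0, p_adj = 1, stars = "ns", stringsAsFactors = FALSE
      )
    } else {
      tk <- stats::TukeyHSD(stats::aov(value ~ lab))$lab
      res$pairwise <- data.frame(
        comparison = rownames(tk),
        diff = tk[, "diff"],
        p_adj = tk[, "p adj"],
        stars = p_stars(tk[, "p adj"]),
        stringsAsFactors = FALSE
      )
      rownames(res$pairwise) <- NULL
    }
  }
  res
}

#' Ingest a supplementary-data table into a long group table
#'
#' Reads a supplementary-style wide sheet (one column per group, one value
#' per row, ragged columns padded with blanks) from CSV or XLSX and
#' normalizes it to a long `GroupTable` (`group`, `value`) with provenance
#' metadata. The layout is validated defensively: every column must have a
#' non-numeric header naming the group, at least one column must contain
#' numeric data, and unrecognized layouts raise a schema-mismatch error
#' rather than silently coercing. An explicit `columns` mapping can select
#' or rename group columns.
#'
#' @param path CSV or XLSX file
#' @param figure_key free-text provenance label (e.g. a figure panel)
#' @param sheet sheet name or index for XLSX workbooks; required when the
#'   workbook has several sheets
#' @param columns optional named character vector mapping output group
#'   labels to column names in the file
#' @return data.frame with `group` and `value`, attributes `figure_key`,
#'   `source`, `sheet`, `n_dropped`
#' @export
ingest_supplementary <- function(path, figure_key, sheet = NULL,
                                 columns = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("supplementary file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package", call. = FALSE)
    }
    sheets <- readxl::excel_sheets(path)
    if (is.null(sheet)) {
      if (length(sheets) > 1) {
        stop(sprintf(
          "workbook has %d sheets (%s); pass `sheet` explicitly",
          length(sheets), paste(sheets, collapse = ", ")
        ), call. = FALSE)
      }
      sheet <- sheets[1]
    }
    raw <- as.data.frame(readxl::read_excel(path, sheet = sheet,
                                            col_types = "text"))
  } else if (ext %in% c("csv", "tsv", "txt")) {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character",
                           sep = if (ext == "tsv") "\t" else ",",
                           check.names = FALSE)
    sheet <- NA_character_
  } else {
    stop(sprintf("unsupported supplementary format '.%s'", ext),
         call. = FALSE)
  }
  if (ncol(raw) < 1 || nrow(raw) < 1) {
    stop("schema mismatch: supplementary table is empty", call. = FALSE)
  }
  hdr <- names(raw)
  if (any(!is.na(suppressWarnings(as.numeric(hdr))))) {
    stop("schema mismatch: numeric column headers suggest a missing header row",
         call. = FALSE)
  }
  if (!is.null(columns)) {
    missing_cols <- setdiff(unname(columns), hdr)
    if (length(missing_cols) > 0) {
      stop(sprintf("schema mismatch: mapped columns not found: %s",
                   paste(missing_cols, collapse = ", ")), call. = FALSE)
    }
    raw <- raw[, unname(columns), drop = FALSE]
    names(raw) <- names(columns)
  }
  long <- list()
  n_dropped <- 0L
  numeric_cols <- 0L
  for (col in names(raw)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    nonblank <- !(is.na(raw[[col]]) | trimws(raw[[col]]) == "")
    if (!any(!is.na(vals))) next
    numeric_cols <- numeric_cols + 1L
    bad <- nonblank & is.na(vals)
    n_dropped <- n_dropped + sum(bad)
    keep <- !is.na(vals)
    long[[col]] <- data.frame(group = col, value = vals[keep],
                              stringsAsFactors = FALSE)
  }
  if (numeric_cols == 0L) {
    stop("schema mismatch: no numeric data columns found", call. = FALSE)
  }
  out <- do.call(rbind, c(long, list(make.row.names = FALSE)))
  attr(out, "figure_key") <- figure_key
  attr(out, "source") <- path
  attr(out, "sheet") <- sheet
  attr(out, "n_dropped") <- n_dropped
  out
}
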