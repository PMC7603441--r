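# Categorical association statistics for palate-shape by mandible-shape
# tables: Pearson chi-squared with expected counts and per-cell
# contributions, 2x2 collapse, Fisher's exact test (point-probability
# two-sided rule), and Bonferroni correction.

#' Construct a labelled contingency table
#'
#' @param counts r x c matrix of non-negative integers, grand total > 0.
#' @param row_labels,col_labels category names; default taken from the
#'   matrix dimnames.
#' @return Object of class `"contingency_table"` (an integer matrix with
#'   dimnames).
#' @export
contingency_table <- function(counts, row_labels = rownames(counts),
                              col_labels = colnames(counts)) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("grand total must be positive")
  if (is.null(row_labels)) row_labels <- paste0("r", seq_len(nrow(counts)))
  if (is.null(col_labels)) col_labels <- paste0("c", seq_len(ncol(counts)))
  if (length(row_labels) != nrow(counts) || length(col_labels) != ncol(counts))
    stop("label counts do not match table dimensions")
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Reference palate-by-mandible shape counts
#'
#' The 3x3 joint frequencies of mandible shape (rows: curved, horizontal,
#' oblique) by palate shape (columns: concave, convex, horizontal) observed
#' in a published clinical series of 100 lateral cephalometric radiographs.
#' Used as the default joint distribution for synthetic shape labels and as
#' the worked example for the association statistics.
#'
#' @return A 3x3 [contingency_table()] with grand total 100.
#' @export
shape_reference_counts <- function() {
  contingency_table(
    matrix(c(9, 5, 21,
             13, 3, 15,
             6, 15, 13), nrow = 3, byrow = TRUE),
    row_labels = c("curved", "horizontal", "oblique"),
    col_labels = c("concave", "convex", "horizontal"))
}

#' Pearson chi-squared test of independence for an r x c table
#'
#' Expected counts are `row_i * col_j / N`; per-cell contributions are
#' `(obs - exp)^2 / exp`; the statistic is their sum, referred to a
#' chi-squared distribution on `(r-1)(c-1)` degrees of freedom. No
#' continuity correction is applied.
#'
#' @param t a [contingency_table()] (or plain count matrix).
#' @return Object of class `"chi_square_result"`: `observed`, `expected`,
#'   `contributions`, `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(t) {
  obs <- unclass(contingency_table(t))
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  if (any(rs == 0) || any(cs == 0))
    stop("zero row or column margin: expected counts would be zero")
  expected <- outer(rs, cs) / n
  contrib <- (obs - expected)^2 / expected
  stat <- sum(contrib)
  df <- (nrow(obs) - 1L) * (ncol(obs) - 1L)
  structure(list(observed = obs, expected = expected,
                 contributions = contrib, statistic = stat, df = df,
                 p = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-squared test of independence: X^2 = %.3f, df = %d, p = %.3g\n",
              x$statistic, x$df, x$p))
  invisible(x)
}

#' Collapse an r x c table to 2x2 around two target categories
#'
#' Dichotomizes the table into presence/absence of each target category
#' (each may live on either margin of the input), preserving the grand
#' total. The output is laid out with `col_category` on the rows and
#' `row_category` on the columns — the orientation in which the
#' convex-palate-versus-oblique-mandible comparison is conventionally
#' printed — so cells are
#' `[[both, col & !row], [row & !col, neither]]`.
#'
#' @param t a [contingency_table()].
#' @param row_category,col_category names of the target categories.
#' @return A 2x2 [contingency_table()].
#' @export
collapse_to_2x2 <- function(t, row_category, col_category) {
  t <- contingency_table(t)
  mask <- function(category, what) {
    i <- match(category, rownames(t))
    if (!is.na(i))
      return(list(m = matrix(seq_len(nrow(t)) == i, nrow(t), ncol(t)),
                  dim = "rows"))
    j <- match(category, colnames(t))
    if (!is.na(j))
      return(list(m = matrix(rep(seq_len(ncol(t)) == j, each = nrow(t)),
                             nrow(t), ncol(t)), dim = "cols"))
    stop("unknown ", what, " category: ", category)
  }
  r <- mask(row_category, "row")
  c2 <- mask(col_category, "column")
  if (identical(r$dim, c2$dim))
    stop("categories must dichotomize the table on different margins")
  mr <- r$m; mc <- c2$m
  both <- sum(t[mr & mc])
  col_only <- sum(t[!mr & mc])
  row_only <- sum(t[mr & !mc])
  neither <- sum(t[!mr & !mc])
  contingency_table(matrix(c(both, col_only, row_only, neither), 2,
                           byrow = TRUE),
                    row_labels = c(col_category, paste0("not_", col_category)),
                    col_labels = c(row_category, paste0("not_", row_category)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the point-probability rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables whose point probability does
#' not exceed the observed table's, with a 1e-7 relative tolerance for
#' probability ties. The odds ratio is the sample cross-product `ad / bc`
#' (infinite when `bc = 0`).
#'
#' @param t a 2x2 [contingency_table()] with positive margins.
#' @return Object of class `"fisher_result"`: `p_two_sided`, `odds_ratio`.
#' @export
fisher_exact_2x2 <- function(t) {
  t <- unclass(contingency_table(t))
  if (!all(dim(t) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("degenerate margins")
  a <- t[1, 1]; b <- t[1, 2]; cc <- t[2, 1]; d <- t[2, 2]
  r1 <- a + b; c1 <- a + cc; c2 <- b + d
  support <- max(0, r1 - c2):min(r1, c1)
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(p_two_sided = p, odds_ratio = (a * d) / (b * cc)),
            class = "fisher_result")
}

#' Bonferroni adjustment of a p-value
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param m number of comparisons, >= 1 (nine for the full 3x3 family of
#'   one-vs-rest shape collapses).
#' @return `min(1, m * p)`.
#' @export
bonferroni_adjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  pmin(1, m * p)
}

#' Write an association table as TSV
#'
#' Emits observed, expected and per-cell contribution blocks per mandible
#' shape row, plus a footer with the statistic, degrees of freedom and
#' p-value.
#'
#' @param chi a [chi_square_independence()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_tsv <- function(chi, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cols <- colnames(chi$observed)
  writeLines(paste(c("row", "block", cols, "All"), collapse = "\t"), con)
  for (i in seq_len(nrow(chi$observed))) {
    rn <- rownames(chi$observed)[i]
    writeLines(paste(c(rn, "observed", chi$observed[i, ],
                       sum(chi$observed[i, ])), collapse = "\t"), con)
    writeLines(paste(c(rn, "expected", sprintf("%.3f", chi$expected[i, ]),
                       sprintf("%.3f", sum(chi$expected[i, ]))),
                     collapse = "\t"), con)
    writeLines(paste(c(rn, "contribution",
                       sprintf("%.5f", chi$contributions[i, ]), ""),
                     collapse = "\t"), con)
  }
  writeLines(paste(c("All", "observed", colSums(chi$observed),
                     sum(chi$observed)), collapse = "\t"), con)
  writeLines(sprintf("# chi-square=%.6g\tdf=%d\tp=%.3g",
                     chi$statistic, chi$df, chi$p), con)
  invisible(path)
}
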