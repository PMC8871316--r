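#' Contingency table of two ordinal raters
#'
#' A `contingency_table` is a square integer matrix of counts with
#' identical, identically ordered row and column labels: rows hold the
#' first rater's category (measured volume, MV, in this package's
#' analyses), columns the second rater's (estimated volume, EV).
#'
#' @param counts A square numeric matrix of non-negative integer counts.
#' @param labels Ordered category labels; defaults to the matrix's
#'   rownames.
#' @return A `contingency_table` object.
#' @examples
#' contingency_table(matrix(c(10, 2, 1, 5), 2), labels = c("a", "b"))
#' @export
contingency_table <- function(counts, labels = rownames(counts)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts) || nrow(counts) < 2)
    stop("`counts` must be a square matrix with k >= 2", call. = FALSE)
  if (is.null(labels))
    labels <- as.character(seq_len(nrow(counts)))
  if (length(labels) != nrow(counts) || anyDuplicated(labels))
    stop("`labels` must be distinct and match the matrix dimension",
         call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8))
    stop("`counts` must be non-negative integers", call. = FALSE)
  counts <- round(counts)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(labels, labels)
  class(counts) <- c("contingency_table", class(matrix()))
  counts
}

#' Cross-classify paired categories into a contingency table
#'
#' Tallies paired category assignments (one pair per item) into a k-by-k
#' [contingency_table()]. Factor levels supply the label order; for
#' plain vectors pass `labels` explicitly.
#'
#' @param a,b Category assignments of the two raters, same length.
#'   Factors, or vectors coercible to the `labels` set. `NA` pairs are
#'   an error: drop incomplete items before tallying.
#' @param labels Ordered category labels; defaults to the union of
#'   factor levels of `a` and `b`.
#' @return A `contingency_table`.
#' @examples
#' build_table(c("neg", "neg"), c("neg", "ind"), labels = c("neg", "ind"))
#' @export
build_table <- function(a, b, labels = NULL) {
  if (length(a) != length(b))
    stop("`a` and `b` must have the same length", call. = FALSE)
  if (is.null(labels)) {
    if (!is.factor(a) && !is.factor(b))
      stop("supply `labels` when `a` and `b` are not factors", call. = FALSE)
    labels <- union(levels(a), levels(b))
  }
  a <- as.character(a); b <- as.character(b)
  if (anyNA(a) || anyNA(b))
    stop("`a` and `b` must not contain missing values", call. = FALSE)
  bad <- setdiff(unique(c(a, b)), labels)
  if (length(bad))
    stop("categories not in `labels`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  fa <- factor(a, levels = labels)
  fb <- factor(b, levels = labels)
  contingency_table(unclass(table(fa, fb)), labels = labels)
}

#' Disagreement weight matrix for weighted kappa
#'
#' Agreement weights \eqn{w_{ij}} on a k-category ordinal scale:
#' `unweighted` gives identity weights (full credit on the diagonal
#' only); `linear` gives \eqn{1 - |i-j|/(k-1)}; `quadratic`
#' (Fleiss-Cohen) gives \eqn{1 - (|i-j|/(k-1))^2}. All schemes are
#' symmetric with a unit diagonal.
#'
#' @param k Number of categories, at least 2.
#' @param scheme One of `"quadratic"`, `"linear"`, `"unweighted"`.
#' @return A k-by-k numeric weight matrix.
#' @examples
#' weight_matrix(3, "quadratic")
#' @export
weight_matrix <- function(k, scheme = c("quadratic", "linear", "unweighted")) {
  scheme <- match.arg(scheme)
  stopifnot(is.numeric(k), length(k) == 1, k >= 2, k == round(k))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  switch(scheme,
    unweighted = (d == 0) * 1,
    linear = 1 - d,
    quadratic = 1 - d^2
  )
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between the two raters of a
#' [contingency_table()], with partial credit for near-diagonal
#' disagreement set by the weight scheme. With weights \eqn{w_{ij}},
#' cell counts \eqn{n_{ij}}, marginals \eqn{r_i, c_j} and total N:
#' \deqn{P_o = \sum w_{ij} n_{ij} / N, \quad
#'       P_e = \sum w_{ij} r_i c_j / N^2, \quad
#'       \kappa = (P_o - P_e) / (1 - P_e).}
#'
#' The package default is quadratic (Fleiss-Cohen) weights, the scheme
#' that reproduces the published agreement coefficients on the fixture
#' tables (see `vignette("nodule-volumetry")`); unweighted kappa is the
#' `"unweighted"` scheme.
#'
#' @param table A `contingency_table`, or a square count matrix.
#' @param scheme Weight scheme, see [weight_matrix()].
#' @return A `kappa_result` object: list with elements `scheme`,
#'   `kappa`, `observed_agreement` (\eqn{P_o}), `expected_agreement`
#'   (\eqn{P_e}), `n` and `labels`. Has [tidy()] and [glance()] methods.
#' @examples
#' tab <- contingency_table(matrix(c(40, 5, 3, 52), 2), c("lo", "hi"))
#' weighted_kappa(tab, "quadratic")
#' @export
weighted_kappa <- function(table, scheme = c("quadratic", "linear", "unweighted")) {
  scheme <- match.arg(scheme)
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table)
  n <- sum(table)
  if (n == 0)
    stop("the table is empty: kappa is undefined", call. = FALSE)
  w <- weight_matrix(nrow(table), scheme)
  po <- sum(w * table) / n
  pe <- sum(w * outer(rowSums(table), colSums(table))) / n^2
  if (1 - pe < .Machine$double.eps * 8)
    stop("degenerate marginals (expected agreement = 1): kappa is undefined",
         call. = FALSE)
  structure(
    list(scheme = scheme,
         kappa = (po - pe) / (1 - pe),
         observed_agreement = po,
         expected_agreement = pe,
         n = n,
         labels = rownames(table)),
    class = "kappa_result"
  )
}

#' Percent agreement
#'
#' Proportion of items on which the two raters of a contingency table
#' assign the same category: diagonal sum over grand total.
#'
#' @inheritParams weighted_kappa
#' @return A proportion in \[0, 1\].
#' @examples
#' percent_agreement(contingency_table(diag(c(3, 4)), c("a", "b")))
#' @export
percent_agreement <- function(table) {
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table)
  n <- sum(table)
  if (n == 0)
    stop("the table is empty: agreement is undefined", call. = FALSE)
  sum(diag(table)) / n
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted Cohen's kappa (%s weights, n = %d)\n",
              x$scheme, as.integer(x$n)))
  cat(sprintf("  kappa = %.2f  (P_o = %.4f, P_e = %.4f)\n",
              round_half_up(x$kappa, 2), x$observed_agreement,
              x$expected_agreement))
  invisible(x)
}

#' Tidy a kappa result
#'
#' @param x A `kappa_result` from [weighted_kappa()].
#' @param ... Unused.
#' @return A one-row tibble with columns `scheme`, `kappa`,
#'   `observed_agreement`, `expected_agreement`, `n`.
#' @export
tidy.kappa_result <- function(x, ...) {
  tibble::tibble(
    scheme = x$scheme,
    kappa = x$kappa,
    observed_agreement = x$observed_agreement,
    expected_agreement = x$expected_agreement,
    n = x$n
  )
}

#' @rdname tidy.kappa_result
#' @export
glance.kappa_result <- function(x, ...) tidy.kappa_result(x)

#' Tidy a contingency table into long form
#'
#' @param x A `contingency_table`.
#' @param ... Unused.
#' @return A tibble with one row per cell: columns `row`, `col`, `n`.
#' @export
tidy.contingency_table <- function(x, ...) {
  labels <- rownames(x)
  tibble::tibble(
    row = factor(rep(labels, times = ncol(x)), levels = labels),
    col = factor(rep(labels, each = nrow(x)), levels = labels),
    n = as.vector(unclass(x))
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  storage.mode(m) <- "integer"
  print(m)
  cat(sprintf("total = %d, off-diagonal = %d\n",
              as.integer(sum(x)), as.integer(sum(x) - sum(diag(x)))))
  invisible(x)
}

# half-up rounding used for reported coefficients (round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
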