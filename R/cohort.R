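#' Classify achievement impairment
#'
#' A subject is impaired in a competency when the standard score is strictly
#' below the cut-off (default 85, i.e. 1 SD below the normative mean of 100);
#' comorbid means impaired in both. Percentages are exact fractions times
#' 100; the print method rounds them to the nearest integer for display.
#'
#' @param pheno phenotype table with `literacy_ss` and `numeracy_ss`.
#' @param cutoff impairment cut-off (strict inequality).
#' @return Object of class `impairment_report`: per-subject flags plus cohort
#'   counts and percentages.
#' @export
classify_impairment <- function(pheno, cutoff = 85) {
  for (col in c("literacy_ss", "numeracy_ss"))
    if (is.null(pheno[[col]]) || anyNA(pheno[[col]]))
      stop("missing scores in '", col, "'")
  n <- nrow(pheno)
  lit <- pheno$literacy_ss < cutoff
  num <- pheno$numeracy_ss < cutoff
  structure(list(
    impaired_literacy = lit, impaired_numeracy = num,
    comorbid = lit & num, n = n, cutoff = cutoff,
    count_literacy = sum(lit), count_numeracy = sum(num),
    count_comorbid = sum(lit & num),
    pct_literacy = 100 * sum(lit) / n,
    pct_numeracy = 100 * sum(num) / n,
    pct_comorbid = 100 * sum(lit & num) / n),
    class = "impairment_report")
}

#' @export
print.impairment_report <- function(x, ...) {
  cat("Impairment (standard score < ", x$cutoff, "), n = ", x$n, ":\n",
      "  literacy: ", x$count_literacy, " (", round(x$pct_literacy), "%)\n",
      "  numeracy: ", x$count_numeracy, " (", round(x$pct_numeracy), "%)\n",
      "  both:     ", x$count_comorbid, "\n", sep = "")
  invisible(x)
}

#' Paired t-test on two score vectors
#'
#' Classical paired t on `a - b` with n - 1 degrees of freedom (delegates to
#' [stats::t.test()]). Zero-variance differences are an error rather than
#' t = 0.
#'
#' @param a,b equal-length numeric vectors (n >= 3).
#' @return object of class `htest`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    stop("need equal-length vectors with n >= 3")
  if (stats::sd(a - b) == 0)
    stop("zero-variance differences; paired t undefined")
  stats::t.test(a, b, paired = TRUE)
}

#' Pearson correlation with two-sided p
#'
#' Pearson r with the t-based p-value on n - 2 degrees of freedom (delegates
#' to [stats::cor.test()]).
#'
#' @param a,b equal-length numeric vectors (n >= 4, both nonconstant).
#' @return object of class `htest`.
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b) || length(a) < 4L)
    stop("need equal-length vectors with n >= 4")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant input")
  stats::cor.test(a, b, method = "pearson")
}
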