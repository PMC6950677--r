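#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement for paired categorical ratings:
#' `kappa = (p_o - p_e) / (1 - p_e)`, with `p_o` the observed agreement
#' proportion and `p_e` the chance agreement from the product of the two
#' raters' marginal distributions. Unweighted (nominal categories). When
#' both raters are constant and identical, `p_e = 1` and kappa is
#' undefined: the function returns `NA` with a `"diagnostic"` attribute
#' rather than dividing by zero.
#'
#' @param rater_a,rater_b Equal-length vectors of categorical codes
#'   (character, factor, or logical).
#' @return Kappa in \[-1, 1\], or `NA` with attribute `"diagnostic"` when
#'   the marginals are degenerate.
#' @export
#' @examples
#' cohens_kappa(c("x", "x", "y"), c("x", "y", "y"))
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) {
    stop("cohens_kappa: rating vectors differ in length", call. = FALSE)
  }
  n <- length(rater_a)
  if (n < 2) stop("cohens_kappa: need at least 2 items", call. = FALSE)
  a <- as.character(rater_a)
  b <- as.character(rater_b)
  if (anyNA(a) || anyNA(b)) {
    stop("cohens_kappa: missing ratings not allowed", call. = FALSE)
  }
  levels <- sort(unique(c(a, b)))
  p_o <- mean(a == b)
  pa <- table(factor(a, levels = levels)) / n
  pb <- table(factor(b, levels = levels)) / n
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (1 - p_e < .Machine$double.eps^0.5) {
    out <- NA_real_
    attr(out, "diagnostic") <-
      "degenerate marginals (p_e = 1): kappa undefined"
    return(out)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Intraclass correlation for double-entered numeric data
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (conventionally ICC(2,1)), from the standard mean-squares decomposition
#' of the items x raters table:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E) / n)`
#' with `MS_R` the between-item, `MS_C` the between-rater, and `MS_E` the
#' residual mean square, `n` items and `k = 2` entries. The variant name is
#' recorded in the `"variant"` attribute of the result.
#'
#' @param entry_a,entry_b Equal-length numeric vectors: first and second
#'   entry of the same items.
#' @return ICC estimate, or `NA` with a `"diagnostic"` attribute when the
#'   data have zero total variance.
#' @export
icc_absolute <- function(entry_a, entry_b) {
  if (length(entry_a) != length(entry_b)) {
    stop("icc_absolute: entry vectors differ in length", call. = FALSE)
  }
  n <- length(entry_a)
  if (n < 3) stop("icc_absolute: need at least 3 items", call. = FALSE)
  x <- cbind(as.numeric(entry_a), as.numeric(entry_b))
  if (anyNA(x)) stop("icc_absolute: missing entries not allowed", call. = FALSE)
  k <- 2
  grand <- mean(x)
  if (sum((x - grand)^2) < .Machine$double.eps^0.5) {
    out <- NA_real_
    attr(out, "diagnostic") <- "zero total variance: ICC undefined"
    attr(out, "variant") <- "two-way random, absolute agreement, single measure"
    return(out)
  }
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ms_r <- k * sum((row_means - grand)^2) / (n - 1)
  ms_c <- n * sum((col_means - grand)^2) / (k - 1)
  ss_total <- sum((x - grand)^2)
  ss_e <- ss_total - k * sum((row_means - grand)^2) - n * sum((col_means - grand)^2)
  ms_e <- ss_e / ((n - 1) * (k - 1))
  icc <- (ms_r - ms_e) / (ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n)
  attr(icc, "variant") <- "two-way random, absolute agreement, single measure"
  icc
}

#' Agreement report over double-entered variables
#'
#' One row per double-entered variable: Cohen's kappa for categorical
#' pairs, ICC (two-way random, absolute agreement, single measure) for
#' numeric pairs, with a qualitative band. Coefficients at or above the
#' cut-off (default 0.80) band as "strong to almost perfect"; below it,
#' "below strong"; undefined statistics band as "undefined".
#'
#' @param double_entries Named list; each element is a list or data frame
#'   with components `a` and `b` (the two entries of one variable).
#' @param strong_cutoff Agreement considered strong at or above this value.
#' @return Tibble: `variable`, `type` ("kappa"/"icc"), `n`, `estimate`,
#'   `band`, `note`.
#' @export
agreement_report <- function(double_entries, strong_cutoff = 0.80) {
  stopifnot(length(double_entries) > 0, !is.null(names(double_entries)))
  rows <- lapply(names(double_entries), function(nm) {
    de <- double_entries[[nm]]
    a <- de$a
    b <- de$b
    numeric_pair <- is.numeric(a) && is.numeric(b)
    est <- if (numeric_pair) icc_absolute(a, b) else cohens_kappa(a, b)
    note <- attr(est, "diagnostic")
    band <- if (is.na(est)) {
      "undefined"
    } else if (est >= strong_cutoff) {
      "strong to almost perfect"
    } else {
      "below strong"
    }
    tibble::tibble(
      variable = nm,
      type = if (numeric_pair) "icc" else "kappa",
      n = length(a),
      estimate = as.numeric(est),
      band = band,
      note = if (is.null(note)) NA_character_ else note
    )
  })
  dplyr::bind_rows(rows)
}
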