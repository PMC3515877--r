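# Family-vs-background comparison of divergence/diversity statistics:
# OLS regressions, two-sample Wilcoxon rank-sum tests (exact by full
# enumeration, or normal approximation with continuity and tie
# corrections), and box-plot five-number summaries.

#' Ordinary least squares of y on x
#'
#' @param x_values,y_values Numeric vectors (>= 2 finite pairs; pairs with
#'   a non-finite member are dropped).
#' @return Named numeric vector \code{c(slope = ..., intercept = ...)}.
#' @export
fit_regression <- function(x_values, y_values) {
  ok <- is.finite(x_values) & is.finite(y_values)
  x <- x_values[ok]
  y <- y_values[ok]
  if (length(x) < 2) stop("need >= 2 finite pairs")
  if (stats::var(x) == 0) stop("zero variance in x: regression undefined")
  fit <- stats::lm.fit(cbind(1, x), y)
  c(slope = unname(fit$coefficients[2]),
    intercept = unname(fit$coefficients[1]))
}

# Mann-Whitney U for sample a (midranks for ties).
.u_stat <- function(ranks_a, n_a) {
  sum(ranks_a) - n_a * (n_a + 1) / 2
}

#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test
#'
#' U is the rank-sum statistic of \code{sample_a} with midranks for ties.
#' Exact mode enumerates all C(n, n_a) label assignments and takes the
#' two-sided p as the probability of a U at least as far from its mean
#' n_a n_b / 2 as observed.  The normal approximation uses a continuity
#' correction and the tie-corrected variance.  \code{"auto"} picks exact
#' when both samples have <= 12 observations.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @return List: \code{U}, \code{p_two_sided}, \code{mode} used.
#' @export
wilcoxon_rank_sum <- function(sample_a, sample_b,
                              mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  n_a <- length(sample_a)
  n_b <- length(sample_b)
  if (n_a == 0 || n_b == 0) stop("both samples must be non-empty")
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled)
  U <- .u_stat(rk[seq_len(n_a)], n_a)
  if (mode == "auto") {
    mode <- if (n_a <= 12 && n_b <= 12) "exact" else "normal_approx"
  }
  n <- n_a + n_b
  mu <- n_a * n_b / 2
  if (mode == "exact") {
    sets <- utils::combn(n, n_a)
    us <- apply(sets, 2, function(idx) .u_stat(rk[idx], n_a))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n_a * n_b / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * stats::pnorm(-z))
    }
  }
  list(U = U, p_two_sided = p, mode = mode)
}

#' Box-plot five-number summary
#'
#' Quartiles by linear interpolation (R quantile type 7); whiskers are the
#' most extreme data points within 1.5 x IQR beyond the quartiles, clipped
#' to observed data.
#'
#' @param values Numeric vector with >= 1 finite value (non-finite values
#'   dropped).
#' @return Named vector: median, q1, q3, whisker_low, whisker_high, n.
#' @export
boxplot_summary <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0) stop("need >= 1 finite value")
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  lo <- min(v[v >= q[1] - 1.5 * iqr])
  hi <- max(v[v <= q[3] + 1.5 * iqr])
  c(median = q[2], q1 = q[1], q3 = q[3],
    whisker_low = lo, whisker_high = hi, n = length(v))
}

#' Compare a gene family against the genome-wide background
#'
#' For each requested statistic: five-number summaries of family and
#' background, a two-sided Wilcoxon rank-sum test, and -- when the table
#' carries the corresponding axis pair (Ks/Ka or pi_s/pi_a) -- OLS
#' regression lines for family and background.  Family genes are removed
#' from the background before testing; genes with an undefined (NA) value
#' are excluded from that statistic only, with exclusion counts reported.
#'
#' @param family_table,background_table data.frames keyed by a
#'   \code{gene} column, statistics in further columns (e.g. Ka, Ks,
#'   ratio, pi_a, pi_s).
#' @param stat_list Statistic column names to compare (default: all
#'   numeric columns shared by both tables).
#' @param wilcoxon_mode Passed to \code{\link{wilcoxon_rank_sum}}.
#' @return List of per-statistic reports, each with stat_name, summaries,
#'   wilcoxon (U, p), exclusion counts and (when available) the
#'   regressions.  No multiple-testing correction is applied across
#'   statistics (reported individually, as is conventional for these
#'   figures); noted in the \code{meta} attribute.
#' @export
compare_family <- function(family_table, background_table, stat_list = NULL,
                           wilcoxon_mode = "auto") {
  if (!"gene" %in% names(family_table) ||
      !"gene" %in% names(background_table)) {
    stop("tables need a 'gene' column")
  }
  if (nrow(family_table) == 0) stop("empty family table")
  bg <- background_table[!background_table$gene %in% family_table$gene, ,
                         drop = FALSE]
  if (nrow(bg) == 0) stop("background is empty after removing family genes")
  if (is.null(stat_list)) {
    shared <- intersect(names(family_table), names(bg))
    stat_list <- shared[vapply(family_table[shared], is.numeric, TRUE) &
                          shared != "gene"]
  }
  axis_pair <- function(tab) {
    if (all(c("Ks", "Ka") %in% names(tab))) c("Ks", "Ka")
    else if (all(c("pi_s", "pi_a") %in% names(tab))) c("pi_s", "pi_a")
    else NULL
  }
  ap <- axis_pair(family_table)
  regression_family <- regression_background <- NULL
  if (!is.null(ap)) {
    regression_family <- tryCatch(
      fit_regression(family_table[[ap[1]]], family_table[[ap[2]]]),
      error = function(e) NULL)
    regression_background <- tryCatch(
      fit_regression(bg[[ap[1]]], bg[[ap[2]]]),
      error = function(e) NULL)
  }
  reports <- lapply(stat_list, function(st) {
    fam <- family_table[[st]]
    bgv <- bg[[st]]
    excl_fam <- sum(!is.finite(fam))
    excl_bg <- sum(!is.finite(bgv))
    fam <- fam[is.finite(fam)]
    bgv <- bgv[is.finite(bgv)]
    if (length(fam) == 0 || length(bgv) == 0) {
      stop("no finite values for statistic ", st)
    }
    w <- wilcoxon_rank_sum(fam, bgv, mode = wilcoxon_mode)
    list(
      stat_name = st,
      family_summary = boxplot_summary(fam),
      background_summary = boxplot_summary(bgv),
      wilcoxon = c(U = w$U, p = w$p_two_sided),
      excluded = c(family = excl_fam, background = excl_bg),
      regression_family = regression_family,
      regression_background = regression_background
    )
  })
  names(reports) <- stat_list
  attr(reports, "meta") <- list(multiple_testing_correction = "none")
  reports
}
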