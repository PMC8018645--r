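#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(i,j) = \sum_c |x_{ic} - x_{jc}| / \sum_c (x_{ic} + x_{jc})},
#' defined for non-negative profiles. Because the pipeline's standard
#' pre-processing centres and scales compounds (producing negatives), a
#' shift policy states how the input is made non-negative first:
#' \describe{
#'   \item{`minshift`}{(default) shift each compound column so its
#'     minimum is 0;}
#'   \item{`raise`}{no transformation - raise an error if any value is
#'     negative;}
#'   \item{`range01`}{rescale each compound column to the unit interval.}
#' }
#'
#' @param m sample x compound matrix.
#' @param shift_policy one of `"minshift"`, `"raise"`, `"range01"`.
#' @return `dist` object; the `meta` attribute of `m`, if any, is carried
#'   along as attribute `meta`.
#' @export
bray_curtis <- function(m, shift_policy = c("minshift", "raise", "range01")) {
  shift_policy <- match.arg(shift_policy)
  x <- switch(shift_policy,
    minshift = sweep(m, 2, apply(m, 2, min)),
    raise = {
      if (any(m < 0))
        stop("negative values under shift_policy='raise'; ",
             "Bray-Curtis needs non-negative input", call. = FALSE)
      m
    },
    range01 = {
      rng <- apply(m, 2, range)
      span <- rng[2, ] - rng[1, ]
      span[span == 0] <- 1
      sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
    })
  d <- vegan::vegdist(x, method = "bray")
  if (anyNA(d)) {
    dm <- as.matrix(d)
    bad <- which(is.na(dm), arr.ind = TRUE)[1, ]
    lab <- rownames(dm)
    stop("undefined Bray-Curtis distance between all-zero samples ",
         if (!is.null(lab)) paste(lab[bad[1]], "and", lab[bad[2]])
         else paste(bad[1], "and", bad[2]), call. = FALSE)
  }
  attr(d, "meta") <- attr(m, "meta")
  d
}

#' Permutational multivariate analysis of variance
#'
#' Partitions a dissimilarity matrix by a crossed two-factor design (or a
#' single factor) with sequential (Type I) sums of squares, in the term
#' order `a`, `b`, `a:b`. The partition and the free-permutation test are
#' delegated to [vegan::adonis2()]; this wrapper fixes the term order,
#' seeds the permutations, and reshapes the result into the standard
#' partition table with mean squares and mean-square shares.
#'
#' @param d `dist` object (e.g. from [bray_curtis()]).
#' @param a,b design factors, each of length `n`; `b` may be `NULL` for a
#'   one-factor partition.
#' @param interaction include the `a:b` interaction term (default `TRUE`).
#' @param n_perm number of free permutations (default 9999).
#' @param seed integer seed controlling the permutations.
#' @return object of class `"permanova_table"`: a `data.frame` with one
#'   row per term (then Residual and Total) and columns `Df`, `SumOfSqs`,
#'   `MeanSqs`, `MeanSqShare`, `R2`, `F`, `Pr`. The permutation p-value
#'   uses the +1 correction: `(1 + #\{F* >= F\}) / (1 + n_perm)`.
#' @export
permanova <- function(d, a, b = NULL, interaction = TRUE,
                      n_perm = 9999, seed = 1L) {
  stopifnot(inherits(d, "dist"))
  n <- attr(d, "Size")
  a <- factor(a)
  if (length(a) != n) stop("factor 'a' does not match the distance matrix",
                           call. = FALSE)
  dat <- data.frame(A = a)
  form <- d ~ A
  if (!is.null(b)) {
    b <- factor(b)
    if (length(b) != n)
      stop("factor 'b' does not match the distance matrix", call. = FALSE)
    dat$B <- b
    form <- if (interaction) d ~ A * B else d ~ A + B
  }
  environment(form) <- environment()
  set.seed(seed)
  fit <- vegan::adonis2(form, data = dat, permutations = n_perm,
                        by = "terms")
  if (fit["Residual", "Df"] == 0)
    stop("saturated design: no residual degrees of freedom", call. = FALSE)
  tab <- data.frame(Df = fit$Df, SumOfSqs = fit$SumOfSqs,
                    MeanSqs = fit$SumOfSqs / fit$Df,
                    R2 = fit$R2, F = fit$F, Pr = fit$`Pr(>F)`,
                    row.names = rownames(fit))
  tab["Total", "MeanSqs"] <- NA
  ms <- tab$MeanSqs[rownames(tab) != "Total"]
  tab$MeanSqShare <- NA_real_
  tab$MeanSqShare[rownames(tab) != "Total"] <- 100 * ms / sum(ms)
  tab <- tab[, c("Df", "SumOfSqs", "MeanSqs", "MeanSqShare", "R2", "F", "Pr")]
  structure(tab, class = c("permanova_table", "data.frame"),
            n_perm = n_perm, seed = seed)
}

#' @export
print.permanova_table <- function(x, digits = 4, ...) {
  cat(sprintf("PERMANOVA partition (%d free permutations, seed %d)\n",
              attr(x, "n_perm"), attr(x, "seed")))
  print.data.frame(x, digits = digits, ...)
  invisible(x)
}

#' Recompute derived columns of a printed partition table
#'
#' Given degrees of freedom and sums of squares of a partition (terms
#' plus a residual row), recomputes mean squares, mean-square shares,
#' R-squared and pseudo-F - the arithmetic that links the columns of a
#' published partition table. Useful for auditing reported tables.
#'
#' @param df integer degrees of freedom per term, residual last.
#' @param ss sums of squares per term, residual last.
#' @param terms optional term labels.
#' @return `"permanova_table"` (without permutation p-values).
#' @export
partition_arithmetic <- function(df, ss, terms = NULL) {
  stopifnot(length(df) == length(ss), length(df) >= 2)
  k <- length(df)
  if (is.null(terms)) terms <- c(paste0("term", seq_len(k - 1)), "Residual")
  ms <- ss / df
  total_ss <- sum(ss); total_df <- sum(df)
  f <- c(ms[-k] / ms[k], NA)
  tab <- data.frame(
    Df = c(df, total_df), SumOfSqs = c(ss, total_ss),
    MeanSqs = c(ms, NA),
    MeanSqShare = c(100 * ms / sum(ms), NA),
    R2 = c(ss / total_ss, 1), F = c(f, NA), Pr = NA_real_,
    row.names = c(terms, "Total"))
  structure(tab, class = c("permanova_table", "data.frame"),
            n_perm = 0L, seed = 0L)
}
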