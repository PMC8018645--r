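#' Phenotypic-plasticity amplitudes
#'
#' For each compound accumulated by every variety, the plasticity
#' amplitude of a variety is the range (max - min) of its block-mean
#' content across environments. By default each compound's variety x
#' environment mean matrix is z-scaled (centred and divided by its
#' overall sample sd) first, so amplitudes of compounds measured in
#' heterogeneous units are comparable; `scale_mode = "raw"` keeps
#' original units for single-family analyses.
#'
#' @param x long-format panel `data.frame` or a named list of variety x
#'   environment block-mean matrices (see [block_means()]).
#' @param scale_mode `"zscore"` (default) or `"raw"`.
#' @param presence_threshold compounds are screened only when every
#'   observed variety x environment mean exceeds this value (default 0,
#'   i.e. accumulated by all varieties in all environments); compounds
#'   failing the filter, or with missing cells, are dropped.
#' @return variety x compound matrix of amplitudes (class keeps plain
#'   `matrix`), with dropped compounds recorded in attribute `dropped`.
#' @export
amplitudes <- function(x, scale_mode = c("zscore", "raw"),
                       presence_threshold = 0) {
  scale_mode <- match.arg(scale_mode)
  mats <- if (is.data.frame(x)) block_means(x) else x
  stopifnot(is.list(mats), length(mats) > 0)
  if (ncol(mats[[1]]) < 2)
    stop("amplitudes need >= 2 environments", call. = FALSE)
  keep <- vapply(mats, function(m)
    !anyNA(m) && all(m > presence_threshold), logical(1))
  dropped <- names(mats)[!keep]
  mats <- mats[keep]
  if (length(mats) == 0)
    stop("no compound passes the presence filter", call. = FALSE)
  amp <- vapply(mats, function(m) {
    if (scale_mode == "zscore") m <- (m - mean(m)) / sd(as.vector(m))
    apply(m, 1, function(r) max(r) - min(r))
  }, numeric(nrow(mats[[1]])))
  if (is.null(dim(amp)))
    amp <- matrix(amp, nrow = 1, dimnames = list(rownames(mats[[1]]),
                                                 names(mats)))
  attr(amp, "dropped") <- dropped
  attr(amp, "scale_mode") <- scale_mode
  amp
}

#' Expected amplitudes and standardized Pearson residuals
#'
#' Treats the non-negative amplitude matrix like a contingency table:
#' with row (variety) sums \eqn{S_{ci}}, column (compound) sums
#' \eqn{S_{rj}} and grand total \eqn{S_t}, the theoretical amplitude of a
#' cell is the margin product \eqn{E = S_{ci} S_{rj} / S_t}, and the
#' standardized Pearson residual is \eqn{r = (A - E)/\sqrt{E}}. A large
#' positive residual flags a variety whose plasticity for that compound
#' exceeds what its overall plasticity level and the compound's overall
#' lability jointly predict - a plasticity differential.
#'
#' @param A non-negative variety x compound amplitude matrix.
#' @param adjusted if `TRUE`, divide each residual additionally by
#'   \eqn{\sqrt{(1 - S_{ci}/S_t)(1 - S_{rj}/S_t)}} (the fully
#'   standardized, unit-variance form).
#' @return list with `observed`, `expected`, `residuals` (matrices),
#'   `row_sums`, `col_sums`, `total`. Residuals of cells with a zero row
#'   or column margin are `NA` (flagged undefined).
#' @export
expected_amplitudes <- function(A, adjusted = FALSE) {
  A <- as.matrix(A)
  if (any(A < 0)) stop("amplitudes must be non-negative", call. = FALSE)
  rs <- rowSums(A); cs <- colSums(A); tot <- sum(A)
  if (tot <= 0) stop("total amplitude must be positive", call. = FALSE)
  E <- outer(rs, cs) / tot
  r <- (A - E) / sqrt(E)
  if (adjusted)
    r <- r / sqrt(outer(1 - rs / tot, 1 - cs / tot))
  r[E == 0] <- NA_real_
  list(observed = A, expected = E, residuals = r,
       row_sums = rs, col_sums = cs, total = tot)
}

#' Select compounds with a high plasticity differential
#'
#' Summarizes the standardized Pearson residuals per compound by the sum,
#' mean and sd of their absolute values over varieties, then selects
#' compounds whose absolute-residual sum strictly exceeds the median of
#' those sums (default rule; the median compound itself is excluded).
#'
#' @param r variety x compound residual matrix (from
#'   [expected_amplitudes()]).
#' @param rule `"median"` (strict `>` median) or `"threshold"`.
#' @param threshold cutoff for `rule = "threshold"`.
#' @return `data.frame(compound, sum_abs, mean_abs, sd_abs, selected)`
#'   sorted by decreasing `sum_abs`, with the applied cutoff as attribute
#'   `cutoff`.
#' @export
screen_compounds <- function(r, rule = c("median", "threshold"),
                             threshold = NULL) {
  rule <- match.arg(rule)
  r <- as.matrix(r)
  if (anyNA(r))
    stop("residuals must be defined for every variety of each compound",
         call. = FALSE)
  s <- colSums(abs(r))
  cutoff <- if (rule == "median") median(s) else {
    if (is.null(threshold)) stop("threshold required", call. = FALSE)
    threshold
  }
  out <- data.frame(compound = colnames(r), sum_abs = s,
                    mean_abs = colMeans(abs(r)),
                    sd_abs = apply(abs(r), 2, sd),
                    selected = s > cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$sum_abs), ]
  attr(out, "cutoff") <- cutoff
  out
}
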