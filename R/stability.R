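.check_means_matrix <- function(mm, min_v = 2, min_e = 2) {
  if (!is.matrix(mm)) stop("expected a variety x environment matrix",
                           call. = FALSE)
  if (anyNA(mm)) {
    bad <- which(is.na(mm), arr.ind = TRUE)[1, ]
    stop("incomplete means matrix: missing cell (",
         rownames(mm)[bad[1]], ", ", colnames(mm)[bad[2]], ")",
         call. = FALSE)
  }
  if (nrow(mm) < min_v || ncol(mm) < min_e)
    stop("means matrix must be at least ", min_v, " x ", min_e,
         call. = FALSE)
  invisible(mm)
}

#' Environmental index
#'
#' The mean content over all varieties in each environment - the
#' regressor of the Finlay-Wilkinson joint regression.
#'
#' @param mm complete variety x environment block-mean matrix for one
#'   compound.
#' @return named numeric vector, one value per environment.
#' @export
environmental_index <- function(mm) {
  .check_means_matrix(mm)
  colMeans(mm)
}

#' Finlay-Wilkinson joint regression
#'
#' Regresses each variety's content on the environmental index (the
#' all-variety mean per environment) by ordinary least squares. The slope
#' \eqn{b_v} is the variety's environmental sensitivity: \eqn{b_v > 1}
#' marks hypersensitive varieties, \eqn{b_v < 1} buffered ones, and the
#' slopes average exactly to 1 across varieties because the index is the
#' variety mean.
#'
#' @param mm complete variety x environment block-mean matrix; needs >= 3
#'   environments and a non-degenerate index.
#' @return object of class `"fw_fit"`: `coefficients`
#'   (`data.frame(variety, intercept, slope, resid_sd)`), `index`, and
#'   the input matrix. Methods: `print`, `coef`, `fitted`, `residuals`,
#'   `predict(newindex =)`, `plot`.
#' @export
fw_regression <- function(mm) {
  .check_means_matrix(mm, min_e = 3)
  I <- colMeans(mm)
  vI <- var(I)
  if (vI <= 0) stop("degenerate environmental index (zero variance)",
                    call. = FALSE)
  n <- length(I)
  coefs <- t(apply(mm, 1, function(y) {
    b <- cov(y, I) / vI
    a <- mean(y) - b * mean(I)
    res <- y - (a + b * I)
    se_b <- sqrt(sum(res^2) / (n - 2) / ((n - 1) * vI))
    c(intercept = a, slope = b, slope_se = se_b,
      resid_sd = sqrt(sum(res^2) / (n - 2)))
  }))
  structure(list(
    coefficients = data.frame(variety = rownames(mm), coefs,
                              row.names = NULL, stringsAsFactors = FALSE),
    index = I, data = mm), class = "fw_fit")
}

#' @export
print.fw_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Finlay-Wilkinson joint regression: %d varieties, %d environments\n",
              nrow(x$data), ncol(x$data)))
  print(x$coefficients, digits = digits)
  invisible(x)
}

#' @export
coef.fw_fit <- function(object, ...) {
  setNames(object$coefficients$slope, object$coefficients$variety)
}

#' @export
fitted.fw_fit <- function(object, ...) {
  co <- object$coefficients
  out <- outer(co$slope, object$index) + co$intercept
  dimnames(out) <- dimnames(object$data)
  out
}

#' @export
residuals.fw_fit <- function(object, ...) object$data - fitted(object)

#' @export
predict.fw_fit <- function(object, newindex = NULL, ...) {
  if (is.null(newindex)) return(fitted(object))
  co <- object$coefficients
  out <- outer(co$slope, newindex) + co$intercept
  rownames(out) <- co$variety
  out
}

#' @export
plot.fw_fit <- function(x, main = "Environmental sensitivity", ...) {
  co <- x$coefficients
  rng <- range(x$index)
  plot(rng, range(predict(x, newindex = rng)), type = "n",
       xlab = "environmental index", ylab = "predicted content",
       main = main, ...)
  cols <- grDevices::rainbow(nrow(co))
  for (i in seq_len(nrow(co)))
    abline(co$intercept[i], co$slope[i], col = cols[i])
  legend("topleft", legend = sprintf("%s (b=%.2f)", co$variety, co$slope),
         col = cols, lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

#' Wricke ecovalence
#'
#' A variety's contribution to the genotype-by-environment interaction
#' sum of squares of the two-way means table:
#' \eqn{W_v = \sum_e (y_{ve} - \bar y_{v\cdot} - \bar y_{\cdot e} +
#' \bar y_{\cdot\cdot})^2}. Low ecovalence marks dynamically stable
#' varieties; the \eqn{W_v} sum exactly to the interaction SS.
#'
#' @param mm complete variety x environment block-mean matrix.
#' @return `data.frame(variety, ecovalence, share)` with the interaction
#'   sum of squares as attribute `interaction_ss`.
#' @export
ecovalence <- function(mm) {
  .check_means_matrix(mm)
  R <- .double_centre(mm)
  W <- rowSums(R^2)
  ss <- sum(W)
  out <- data.frame(variety = rownames(mm), ecovalence = W,
                    share = if (ss > 0) W / ss else NA_real_,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "interaction_ss") <- ss
  out
}

#' AMMI decomposition of a variety-by-environment means table
#'
#' Additive Main effects and Multiplicative Interaction model: the means
#' table is decomposed as
#' \deqn{y_{ve} = \mu + g_v + h_e + \sum_k \lambda_k \alpha_{vk}
#'   \gamma_{ek} + \rho_{ve}}
#' with additive variety (\eqn{g_v}) and environment (\eqn{h_e}) main
#' effects and a singular value decomposition of the doubly centred
#' interaction. The squared singular values partition the interaction sum
#' of squares over the interaction principal component axes (IPCAs). Axis
#' signs follow a deterministic convention (the environment with the
#' largest absolute score on each axis is positive).
#'
#' @param mm complete variety x environment block-mean matrix.
#' @param K number of multiplicative terms retained for fitted values and
#'   biplots (default `2`, capped at full rank `min(V, E) - 1`).
#' @return object of class `"ammi"`: `mu`, `g`, `h`, `lambda` (all
#'   singular values), `alpha` (variety scores), `gamma` (environment
#'   scores), `K`, `interaction_ss`. Methods: `print`, `summary`,
#'   `fitted`, `residuals`, `predict`, `plot` (biplot);
#'   see also [biplot_coords()] and [best_environments()].
#' @export
ammi <- function(mm, K = 2) {
  .check_means_matrix(mm)
  M <- min(nrow(mm), ncol(mm)) - 1
  if (K < 0 || K > M)
    stop("K must be between 0 and min(V, E) - 1 = ", M, call. = FALSE)
  mu <- mean(mm)
  g <- rowMeans(mm) - mu
  h <- colMeans(mm) - mu
  R <- .double_centre(mm)
  sv <- svd(R)
  lambda <- sv$d[seq_len(M)]
  alpha <- sv$u[, seq_len(M), drop = FALSE]
  gamma <- sv$v[, seq_len(M), drop = FALSE]
  for (k in seq_len(M)) {
    j <- which.max(abs(gamma[, k]))
    if (gamma[j, k] < 0) {
      gamma[, k] <- -gamma[, k]
      alpha[, k] <- -alpha[, k]
    }
  }
  dimnames(alpha) <- list(rownames(mm), paste0("IPC", seq_len(M)))
  dimnames(gamma) <- list(colnames(mm), paste0("IPC", seq_len(M)))
  structure(list(mu = mu, g = g, h = h, lambda = lambda,
                 alpha = alpha, gamma = gamma, K = K,
                 interaction_ss = sum(R^2), data = mm), class = "ammi")
}

#' @export
print.ammi <- function(x, digits = 4, ...) {
  cat(sprintf("AMMI model: %d varieties x %d environments, K = %d retained\n",
              length(x$g), length(x$h), x$K))
  expl <- 100 * x$lambda^2 / sum(x$lambda^2)
  cat("  interaction SS: ", format(x$interaction_ss, digits = digits),
      "\n  IPCA shares: ",
      paste(sprintf("%.1f%%", expl[seq_len(min(4, length(expl)))]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ammi <- function(object, ...) {
  data.frame(axis = paste0("IPC", seq_along(object$lambda)),
             lambda = object$lambda,
             ss = object$lambda^2,
             share = object$lambda^2 / sum(object$lambda^2),
             row.names = NULL)
}

#' @export
fitted.ammi <- function(object, K = object$K, ...) {
  out <- object$mu + outer(object$g, object$h, "+")
  if (K > 0) {
    ak <- object$alpha[, seq_len(K), drop = FALSE]
    gk <- object$gamma[, seq_len(K), drop = FALSE]
    out <- out + ak %*% (diag(object$lambda[seq_len(K)],
                              nrow = K) %*% t(gk))
  }
  dimnames(out) <- dimnames(object$data)
  out
}

#' @export
residuals.ammi <- function(object, K = object$K, ...) {
  object$data - fitted(object, K = K)
}

#' @export
predict.ammi <- function(object, variety = NULL, K = object$K, ...) {
  fit <- fitted(object, K = K)
  if (is.null(variety)) return(fit)
  if (!variety %in% rownames(fit))
    stop("unknown variety: ", variety, call. = FALSE)
  fit[variety, ]
}

#' Biplot coordinates of an AMMI model
#'
#' @param model an `"ammi"` fit.
#' @param scaling `"symmetric"` (both sides scaled by the square root of
#'   the singular values; default), `"environment"` (environments carry
#'   the singular values), or `"genotype"`.
#' @param axes which two IPCA axes to return (default 1:2).
#' @return list with `varieties` and `environments` coordinate matrices.
#' @export
biplot_coords <- function(model,
                          scaling = c("symmetric", "environment",
                                      "genotype"),
                          axes = 1:2) {
  stopifnot(inherits(model, "ammi"))
  scaling <- match.arg(scaling)
  axes <- axes[axes <= length(model$lambda)]
  l <- model$lambda[axes]
  a <- model$alpha[, axes, drop = FALSE]
  g <- model$gamma[, axes, drop = FALSE]
  sc <- switch(scaling,
    symmetric = list(v = sweep(a, 2, sqrt(l), "*"),
                     e = sweep(g, 2, sqrt(l), "*")),
    environment = list(v = a, e = sweep(g, 2, l, "*")),
    genotype = list(v = sweep(a, 2, l, "*"), e = g))
  list(varieties = sc$v, environments = sc$e)
}

#' @export
plot.ammi <- function(x, scaling = "symmetric", axes = 1:2,
                      main = "AMMI biplot", ...) {
  bc <- biplot_coords(x, scaling = scaling, axes = axes)
  all_pts <- rbind(bc$varieties, bc$environments)
  plot(all_pts, type = "n", xlab = colnames(bc$varieties)[1],
       ylab = colnames(bc$varieties)[2], main = main, ...)
  abline(h = 0, v = 0, col = "grey70", lty = 3)
  arrows(0, 0, bc$environments[, 1], bc$environments[, 2],
         length = 0.08, col = "steelblue")
  text(bc$environments, labels = rownames(bc$environments),
       col = "steelblue", cex = 0.7, pos = 3)
  points(bc$varieties, pch = 19)
  text(bc$varieties, labels = rownames(bc$varieties), pos = 1, cex = 0.8)
  invisible(x)
}

#' Rank environments for a variety under a fitted AMMI model
#'
#' Environments are ordered by the modelled cell value
#' \eqn{\mu + g_v + h_e + \sum_{k \le K} \lambda_k \alpha_{vk}
#' \gamma_{ek}}; the top environments are where the variety's content is
#' enhanced most, relative to what main effects alone predict.
#'
#' @param model an `"ammi"` fit with `K >= 1` retained axes (a `K = 0`
#'   model ranks identically for every variety).
#' @param variety variety label.
#' @param K number of multiplicative terms used (default the model's).
#' @return `data.frame(environment, predicted)` sorted by decreasing
#'   predicted content.
#' @export
best_environments <- function(model, variety, K = model$K) {
  stopifnot(inherits(model, "ammi"))
  y <- predict(model, variety = variety, K = K)
  data.frame(environment = names(sort(y, decreasing = TRUE)),
             predicted = sort(y, decreasing = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}
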