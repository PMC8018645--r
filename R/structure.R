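#' Principal component analysis of a scaled panel
#'
#' Thin wrapper around [stats::prcomp()] for pre-scaled sample x compound
#' matrices (see [scale_compounds()]), adding per-component inertia
#' fractions and a deterministic sign convention: on every component the
#' compound with the largest absolute loading gets a positive loading, so
#' scores are reproducible across platforms.
#'
#' @param m sample x compound matrix (already centred/scaled; columns are
#'   re-centred defensively).
#' @return object of class `"pca_model"`: list with `scores` (sample x
#'   component), `loadings` (compound x component), `inertia`
#'   (eigenvalue fractions), `sdev`, and the `meta` attribute of `m`.
#' @export
pca <- function(m) {
  if (nrow(m) < 3 || ncol(m) < 2)
    stop("need >= 3 samples and >= 2 compounds", call. = FALSE)
  fit <- prcomp(m, center = TRUE, scale. = FALSE)
  for (k in seq_len(ncol(fit$rotation))) {
    j <- which.max(abs(fit$rotation[, k]))
    if (fit$rotation[j, k] < 0) {
      fit$rotation[, k] <- -fit$rotation[, k]
      fit$x[, k] <- -fit$x[, k]
    }
  }
  ev <- fit$sdev^2
  structure(list(scores = fit$x, loadings = fit$rotation,
                 inertia = ev / sum(ev), sdev = fit$sdev,
                 meta = attr(m, "meta")), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- min(5, length(x$inertia))
  cat(sprintf("PCA model: %d samples, %d components\n",
              nrow(x$scores), ncol(x$scores)))
  cat("  inertia (first ", k, "): ",
      paste(sprintf("%.2f%%", 100 * x$inertia[seq_len(k)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Triangle area spanned by three environment points in PC space
#'
#' The variability of a variety grown in three environments is summarized
#' by the area of the triangle its three points span on the first three
#' principal components: half the norm of the cross product of two edge
#' vectors (the mixed-product construction). The weighted variant
#' stretches each component axis by a weight derived from its inertia
#' fraction before taking the area.
#'
#' @param points 3 x 3 numeric matrix: one row per environment point, one
#'   column per principal component.
#' @param inertia optional length-3 inertia fractions used for the
#'   weighted area.
#' @param weight_mode `"normalized"` (default): weight_k = inertia_k /
#'   mean(inertia_1..3), keeping the weighted area on the scale of the
#'   raw one; `"raw"`: weight_k = inertia_k.
#' @return `data.frame(area, weighted_area)`; `weighted_area` is `NA`
#'   when `inertia` is not supplied.
#' @examples
#' variety_area(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))  # 0.5
#' @export
variety_area <- function(points, inertia = NULL,
                         weight_mode = c("normalized", "raw")) {
  weight_mode <- match.arg(weight_mode)
  points <- as.matrix(points)
  if (!all(dim(points) == c(3, 3)))
    stop("the area metric needs exactly 3 points with 3 coordinates",
         call. = FALSE)
  tri_area <- function(p) {
    u <- p[2, ] - p[1, ]; v <- p[3, ] - p[1, ]
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  area <- tri_area(points)
  weighted <- NA_real_
  if (!is.null(inertia)) {
    stopifnot(length(inertia) == 3)
    w <- if (weight_mode == "normalized") inertia / mean(inertia) else inertia
    weighted <- tri_area(sweep(points, 2, w, "*"))
  }
  data.frame(area = area, weighted_area = weighted)
}

#' Per-variety PC-space areas for a three-environment design
#'
#' Applies [variety_area()] to every variety of a fitted [pca()] model
#' whose samples are (variety, environment) block means over exactly
#' three environments.
#'
#' @param model a `"pca_model"` whose `meta` has columns `variety` and
#'   `environment`.
#' @param weight_mode passed to [variety_area()].
#' @return `data.frame(variety, area, weighted_area)` sorted by
#'   decreasing area.
#' @export
pca_areas <- function(model, weight_mode = c("normalized", "raw")) {
  stopifnot(inherits(model, "pca_model"))
  meta <- model$meta
  if (is.null(meta) || !all(c("variety", "environment") %in% names(meta)))
    stop("model lacks (variety, environment) sample metadata", call. = FALSE)
  if (ncol(model$scores) < 3)
    stop("need at least 3 principal components", call. = FALSE)
  rows <- lapply(split(seq_len(nrow(meta)), meta$variety), function(idx) {
    if (length(idx) != 3)
      stop("the area metric is defined for exactly 3 environments per ",
           "variety (got ", length(idx), ")", call. = FALSE)
    variety_area(model$scores[idx, 1:3], inertia = model$inertia[1:3],
                 weight_mode = weight_mode)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(variety = names(rows), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(-out$area), ]
}

#' Ward hierarchical clustering of varieties
#'
#' Agglomerative clustering with the Ward minimum-variance criterion on
#' Euclidean distances (`hclust` method `"ward.D2"`, which operates on
#' untransformed Euclidean distances).
#'
#' @param m variety x compound matrix (typically scaled block means over
#'   selected compounds); row names are the variety labels.
#' @param k optional number of flat clusters to cut.
#' @return object of class `"ward_clust"`: list with the `hclust` tree,
#'   `clusters` (named integer vector, or `NULL`), and `k`.
#' @export
ward_clustering <- function(m, k = NULL) {
  if (nrow(m) < 2) stop("need >= 2 varieties", call. = FALSE)
  hc <- hclust(dist(m), method = "ward.D2")
  clusters <- NULL
  if (!is.null(k)) {
    if (k > nrow(m)) stop("k exceeds the number of varieties", call. = FALSE)
    clusters <- cutree(hc, k = k)
  }
  structure(list(hclust = hc, clusters = clusters, k = k),
            class = "ward_clust")
}

#' @export
print.ward_clust <- function(x, ...) {
  cat(sprintf("Ward clustering of %d varieties",
              length(x$hclust$labels)))
  if (!is.null(x$k)) cat(sprintf(" (cut at k = %d)", x$k))
  cat("\n")
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' @param clust a `"ward_clust"` object (or an `hclust`).
#' @param path optional file to write the tree to.
#' @return Newick string, invisibly when `path` is given.
#' @export
dendrogram_newick <- function(clust, path = NULL) {
  hc <- if (inherits(clust, "ward_clust")) clust$hclust else clust
  phy <- ape::as.phylo(hc)
  nwk <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

#' Random-forest screen for variety-discriminant compounds
#'
#' Pipeline glue over [randomForest::randomForest()]: fits a
#' classification forest of varieties on compound profiles, then
#' estimates a permutation p-value for each compound's Gini importance by
#' refitting the forest on label-permuted data. A compound is selected
#' when its permutation p-value passes `p_threshold` and its mean
#' decrease in Gini exceeds `importance_floor`. Classification error is
#' the out-of-bag estimate.
#'
#' @param m sample x compound matrix (scaled).
#' @param labels variety labels, one per sample (>= 2 samples per class).
#' @param n_trees trees per forest (default 500).
#' @param n_perm label permutations for the importance null (default
#'   2000; expensive - each permutation refits the forest).
#' @param p_threshold selection p-value threshold (default 0.05).
#' @param importance_floor minimum mean decrease in Gini (default 1).
#' @param seed integer seed.
#' @return object of class `"marker_screen"`: `data.frame(compound,
#'   importance, p_value, selected)` ranked by importance, with the OOB
#'   error as attribute `oob_error`.
#' @export
marker_screen <- function(m, labels, n_trees = 500, n_perm = 2000,
                          p_threshold = 0.05, importance_floor = 1,
                          seed = 1L) {
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("need at least two variety classes", call. = FALSE)
  if (any(table(labels) < 2))
    stop("need >= 2 samples per variety", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(x = m, y = labels, ntree = n_trees)
  obs <- fit$importance[, "MeanDecreaseGini"]
  oob <- mean(fit$predicted != labels)
  hits <- numeric(length(obs))
  for (i in seq_len(n_perm)) {
    perm <- randomForest::randomForest(x = m, y = sample(labels),
                                       ntree = n_trees)
    hits <- hits + (perm$importance[, "MeanDecreaseGini"] >= obs)
  }
  p <- (1 + hits) / (1 + n_perm)
  res <- data.frame(compound = colnames(m), importance = obs,
                    p_value = p,
                    selected = p < p_threshold & obs > importance_floor,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(-res$importance), ]
  structure(res, class = c("marker_screen", "data.frame"),
            oob_error = oob, n_trees = n_trees, n_perm = n_perm)
}

#' @export
print.marker_screen <- function(x, ...) {
  cat(sprintf(
    "Marker screen: %d/%d compounds selected; OOB error %.2f%%\n",
    sum(x$selected), nrow(x), 100 * attr(x, "oob_error")))
  print.data.frame(utils::head(x, 10), digits = 3)
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}
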