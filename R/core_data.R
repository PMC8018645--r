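#' Read a long-format metabolite panel
#'
#' Expects a delimited text file with header columns `variety`, `block`,
#' `compound`, `value` and either an `environment` column or a
#' `location` + `year` pair (concatenated as `location_year`). Duplicate
#' (variety, environment, block, compound) keys are rejected.
#'
#' @param path CSV (or TSV, by extension) file path.
#' @return `data.frame` with columns `variety`, `environment`, `block`,
#'   `compound`, `value` (plus `location`/`year` when present).
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE)
  need <- c("variety", "block", "compound", "value")
  missing_cols <- setdiff(need, names(tab))
  if (!("environment" %in% names(tab))) {
    if (all(c("location", "year") %in% names(tab)))
      tab$environment <- paste(tab$location, tab$year, sep = "_")
    else missing_cols <- c(missing_cols, "environment (or location+year)")
  }
  if (length(missing_cols))
    stop("panel file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab$value <- as.numeric(tab$value)
  if (anyNA(tab$value))
    stop("non-numeric values in 'value' column", call. = FALSE)
  key <- paste(tab$variety, tab$environment, tab$block, tab$compound,
               sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate (variety, environment, block, compound) keys: ",
         paste(utils::head(gsub("\r", "/", key[dup]), 5), collapse = "; "),
         call. = FALSE)
  front <- intersect(c("variety", "location", "year", "environment",
                       "block", "compound", "value"), names(tab))
  tab[, c(front, setdiff(names(tab), front))]
}

.as_panel <- function(table) {
  if (!is.data.frame(table))
    stop("expected a long-format panel data.frame", call. = FALSE)
  if (!("environment" %in% names(table))) {
    if (all(c("location", "year") %in% names(table)))
      table$environment <- paste(table$location, table$year, sep = "_")
    else stop("panel lacks an 'environment' (or location+year) column",
              call. = FALSE)
  }
  table
}

#' Block-mean variety-by-environment matrices
#'
#' Averages replicate blocks for every (variety, environment, compound)
#' cell. Missing variety-by-environment combinations stay `NA`; they are
#' represented, never imputed.
#'
#' @param table long-format panel (see [read_panel()]).
#' @param compound optional single compound name; if given, one matrix is
#'   returned instead of a list.
#' @return named list of variety x environment matrices (one per
#'   compound), or a single matrix.
#' @export
block_means <- function(table, compound = NULL) {
  table <- .as_panel(table)
  if (!is.null(compound)) {
    table <- table[table$compound == compound, , drop = FALSE]
    if (nrow(table) == 0) stop("no rows for compound ", compound,
                               call. = FALSE)
  }
  varieties <- sort(unique(table$variety))
  environments <- sort(unique(table$environment))
  out <- lapply(split(table, table$compound), function(tc) {
    agg <- aggregate(value ~ variety + environment, data = tc, FUN = mean)
    m <- matrix(NA_real_, length(varieties), length(environments),
                dimnames = list(varieties, environments))
    m[cbind(match(agg$variety, varieties),
            match(agg$environment, environments))] <- agg$value
    m
  })
  if (!is.null(compound)) out[[compound]] else out
}

#' Sample-by-compound matrix of a panel
#'
#' Pivots the long table into a numeric matrix with one row per sample -
#' either each (variety, environment, block) plot (`level = "block"`) or
#' each (variety, environment) block mean (`level = "mean"`) - and one
#' column per compound. The sample design factors are attached as the
#' `"meta"` attribute.
#'
#' @param table long-format panel.
#' @param level `"block"` (replicate plots) or `"mean"` (block means).
#' @return numeric matrix with attribute `meta` (a `data.frame` of
#'   `variety`, `environment` and, for block level, `block`).
#' @export
panel_matrix <- function(table, level = c("block", "mean")) {
  level <- match.arg(level)
  table <- .as_panel(table)
  if (level == "mean") {
    table <- aggregate(value ~ variety + environment + compound,
                       data = table, FUN = mean)
    table$block <- "mean"
  }
  sample_id <- paste(table$variety, table$environment, table$block,
                     sep = "\r")
  samples <- unique(sample_id)
  compounds <- sort(unique(table$compound))
  m <- matrix(NA_real_, length(samples), length(compounds),
              dimnames = list(NULL, compounds))
  m[cbind(match(sample_id, samples), match(table$compound, compounds))] <-
    table$value
  idx <- match(samples, sample_id)
  meta <- data.frame(variety = table$variety[idx],
                     environment = table$environment[idx],
                     stringsAsFactors = FALSE)
  if (level == "block") meta$block <- table$block[idx]
  rownames(m) <- paste(meta$variety, meta$environment,
                       if (level == "block") meta$block else NULL, sep = ".")
  attr(m, "meta") <- meta
  m
}

#' Centre and scale compound columns
#'
#' Each compound column is centred to mean 0 and scaled to sample
#' standard deviation 1 (n-1 denominator). Zero-variance columns cannot
#' be scaled and are dropped with a warning.
#'
#' @param m sample x compound numeric matrix.
#' @return scaled matrix, with the `meta` attribute of `m` preserved.
#' @export
scale_compounds <- function(m) {
  if (nrow(m) < 2) stop("need >= 2 samples to scale", call. = FALSE)
  sds <- apply(m, 2, sd)
  bad <- !is.na(sds) & sds == 0
  if (any(bad)) {
    warning("dropping constant compound(s): ",
            paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
    m <- m[, !bad, drop = FALSE]
  }
  out <- scale(m)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "meta") <- attr(m, "meta")
  out
}

#' Environmental coefficient of variation
#'
#' Static-stability measure of one compound: for each variety, the
#' standard deviation of its block-mean content across environments
#' divided by its mean content, as a percentage
#' (\eqn{CV = 100 \cdot Sd_{var} / Y_{var}}). Computed on raw (unscaled)
#' block means; a CV of centred data would be meaningless.
#'
#' @param mm variety x environment block-mean matrix for one compound
#'   (from [block_means()]).
#' @return `data.frame(variety, sd, mean, cv_percent)`; `cv_percent` is
#'   `NA` (flagged undefined) when the variety mean is 0, and varieties
#'   with fewer than two observed environments are `NA` throughout.
#' @export
environmental_cv <- function(mm) {
  stopifnot(is.matrix(mm))
  res <- data.frame(variety = rownames(mm),
                    sd = NA_real_, mean = NA_real_,
                    cv_percent = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(mm))) {
    y <- mm[i, ]; y <- y[!is.na(y)]
    if (length(y) < 2) next
    res$sd[i] <- sd(y); res$mean[i] <- mean(y)
    if (res$mean[i] != 0)
      res$cv_percent[i] <- 100 * res$sd[i] / res$mean[i]
  }
  res
}
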