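#' Default pipeline configuration
#'
#' Returns the complete list of recognized configuration keys with their
#' defaults. [run_pipeline()] rejects any key not listed here.
#'
#' @return named list.
#' @export
default_config <- function() {
  list(
    input = NULL,             # panel CSV/TSV path (or pass `table=`)
    out_dir = "metaplast_out",
    seed = 1L,
    stages = c("permanova", "structure", "screen", "stability"),
    n_perm = 9999L,           # PERMANOVA permutations
    shift_policy = "minshift",
    scale_mode = "zscore",    # amplitude scaling
    presence_threshold = 0,
    screen_rule = "median",
    cluster_k = NULL,         # flat clusters cut (default: no cut)
    weight_mode = "normalized",
    ammi_k = 2L,
    markers = FALSE,          # opt-in random-forest marker screen
    marker_trees = 500L,
    marker_perms = 100L)
}

.load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  base[names(config)] <- config
  stochastic <- any(c("permanova") %in% base$stages) || isTRUE(base$markers)
  if (stochastic && is.null(base$seed))
    stop("a seed is required when stochastic stages are enabled",
         call. = FALSE)
  base
}

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  path
}

.matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_csv(df, path)
}

#' Run the full plasticity pipeline on a panel
#'
#' Executes, in order: ingest, block-mean aggregation, per-compound
#' scaling, PERMANOVA variance partitioning, structure analysis (PCA,
#' triangle areas when each variety was grown in exactly three
#' environments, Ward clustering, environmental CVs), the amplitude /
#' Pearson-residual plasticity screen, and the stability models (FW
#' regression, ecovalence, AMMI) on the compounds the screen selects.
#' Every stage writes its result to `out_dir` and a machine-readable
#' `manifest.json` records the configuration, seed, configuration hash
#' and output files; re-running with the same configuration and seed
#' reproduces all numeric outputs byte for byte.
#'
#' @param config configuration list (see [default_config()]) or the path
#'   of a YAML/JSON file holding one.
#' @param table optional in-memory panel `data.frame`, overriding
#'   `config$input`.
#' @return invisibly, a list with every stage result plus `manifest`.
#' @export
run_pipeline <- function(config = list(), table = NULL) {
  cfg <- .load_config(config)
  if (is.null(table)) {
    if (is.null(cfg$input))
      stop("no input: set config$input or pass `table=`", call. = FALSE)
    table <- read_panel(cfg$input)
  } else table <- .as_panel(table)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = cfg)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    files <<- c(files, name)
  }

  mats <- block_means(table)
  blocks <- panel_matrix(table, level = "block")
  means <- panel_matrix(table, level = "mean")
  scaled_blocks <- scale_compounds(blocks)
  scaled_means <- scale_compounds(means)

  if ("permanova" %in% cfg$stages) {
    meta <- attr(scaled_blocks, "meta")
    d <- bray_curtis(scaled_blocks, shift_policy = cfg$shift_policy)
    out$permanova <- tryCatch(
      permanova(d, a = meta$environment, b = meta$variety,
                n_perm = cfg$n_perm, seed = cfg$seed),
      error = function(e) stop("stage permanova: ", conditionMessage(e),
                               call. = FALSE))
    emit("permanova.csv", function(p) .write_csv(
      data.frame(term = rownames(out$permanova),
                 as.data.frame(out$permanova)), p))
  }

  if ("structure" %in% cfg$stages) {
    out$pca <- pca(scaled_means)
    emit("pca_scores.csv", function(p) .matrix_csv(out$pca$scores, p))
    emit("pca_loadings.csv", function(p) .matrix_csv(out$pca$loadings, p))
    emit("pca_inertia.csv", function(p) .write_csv(
      data.frame(component = seq_along(out$pca$inertia),
                 inertia = out$pca$inertia), p))
    env_per_variety <- base::table(attr(scaled_means, "meta")$variety)
    if (all(env_per_variety == 3)) {
      out$areas <- pca_areas(out$pca, weight_mode = cfg$weight_mode)
      emit("pca_areas.csv", function(p) .write_csv(out$areas, p))
    }
    vm <- attr(scaled_means, "meta")$variety
    variety_means <- apply(scaled_means, 2, function(col)
      tapply(col, vm, mean))
    out$clustering <- ward_clustering(variety_means, k = cfg$cluster_k)
    emit("dendrogram.nwk", function(p)
      dendrogram_newick(out$clustering, path = p))
    cvs <- do.call(rbind, lapply(names(mats), function(cmp) {
      cv <- environmental_cv(mats[[cmp]])
      data.frame(compound = cmp, cv, stringsAsFactors = FALSE)
    }))
    out$cv <- cvs
    emit("environmental_cv.csv", function(p) .write_csv(cvs, p))
    if (isTRUE(cfg$markers)) {
      out$markers <- marker_screen(
        scaled_blocks, attr(scaled_blocks, "meta")$variety,
        n_trees = cfg$marker_trees, n_perm = cfg$marker_perms,
        seed = cfg$seed)
      emit("marker_screen.csv", function(p) .write_csv(
        as.data.frame(out$markers), p))
    }
  }

  if ("screen" %in% cfg$stages) {
    A <- amplitudes(mats, scale_mode = cfg$scale_mode,
                    presence_threshold = cfg$presence_threshold)
    ea <- expected_amplitudes(A)
    out$amplitudes <- ea
    out$screen <- screen_compounds(ea$residuals, rule = cfg$screen_rule)
    emit("amplitudes_observed.csv", function(p) .matrix_csv(ea$observed, p))
    emit("amplitudes_expected.csv", function(p) .matrix_csv(ea$expected, p))
    emit("amplitude_residuals.csv", function(p) .matrix_csv(ea$residuals, p))
    emit("plasticity_screen.csv", function(p) .write_csv(
      as.data.frame(out$screen), p))
  }

  if ("stability" %in% cfg$stages) {
    if (is.null(out$screen)) {
      message("stability stage skipped: no plasticity screen selection")
    } else {
      sel <- out$screen$compound[out$screen$selected]
      fw_rows <- list(); eco_rows <- list(); ammi_list <- list()
      for (cmp in sel) {
        mm <- mats[[cmp]]
        fw <- fw_regression(mm)
        eco <- ecovalence(mm)
        am <- ammi(mm, K = min(cfg$ammi_k, min(dim(mm)) - 1))
        fw_rows[[cmp]] <- data.frame(compound = cmp, fw$coefficients)
        eco_rows[[cmp]] <- data.frame(compound = cmp, eco)
        bc <- biplot_coords(am)
        ammi_list[[cmp]] <- list(
          mu = am$mu, g = as.list(am$g), h = as.list(am$h),
          lambda = am$lambda, K = am$K,
          interaction_ss = am$interaction_ss,
          biplot = list(varieties = as.data.frame(bc$varieties),
                        environments = as.data.frame(bc$environments)))
      }
      if (length(sel)) {
        out$fw <- do.call(rbind, c(fw_rows, list(make.row.names = FALSE)))
        out$ecovalence <- do.call(rbind, c(eco_rows,
                                           list(make.row.names = FALSE)))
        out$ammi <- ammi_list
        emit("fw_regression.csv", function(p) .write_csv(out$fw, p))
        emit("ecovalence.csv", function(p) .write_csv(out$ecovalence, p))
        emit("ammi.json", function(p) jsonlite::write_json(
          ammi_list, p, auto_unbox = TRUE, digits = NA))
      }
    }
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  manifest <- list(
    package = "metaplast",
    version = as.character(packageVersion("metaplast")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg,
    config_md5 = unname(tools::md5sum(tmp)),
    outputs = files)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  out$manifest <- manifest
  invisible(out)
}
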