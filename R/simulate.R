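#' Simulate a multi-environment metabolite panel
#'
#' Draws a replicated panel under the crossed generating model of
#' [sim_spec()] and returns both the long-format table and a ground-truth
#' sidecar holding every realized effect, the generating (or implied)
#' Finlay-Wilkinson slope per variety and compound, and per-compound
#' variance-component shares. Given the same spec (including its seed)
#' the output is bit-reproducible.
#'
#' @param spec a [sim_spec()] object.
#' @return list with elements
#'   \describe{
#'     \item{table}{`data.frame(variety, location, year, block, compound,
#'       value)` with one row per design cell; the environment label used
#'       downstream is `location_year`.}
#'     \item{truth}{object of class `"sim_truth"`: design labels, block
#'       effects (environment x block), and per compound `mu`, centred
#'       variety effects `g`, centred environment effects `h`, doubly
#'       centred interaction matrix, `fw_slope`, and `var_shares`.}
#'   }
#' @examples
#' sp <- sim_spec(4, 3, n_blocks = 2,
#'                compounds = sim_compound("X", mu = 5, sd_g = 0, sd_e = 0,
#'                                         sd_gxe = 0, sd_eps = 0))
#' simulate_panel(sp)$table$value  # all exactly 5
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  V <- spec$n_varieties; L <- spec$n_locations
  Y <- spec$n_years; B <- spec$n_blocks
  E <- L * Y
  varieties <- sprintf("V%02d", seq_len(V))
  locations <- sprintf("L%02d", seq_len(L))
  years <- sprintf("Y%d", seq_len(Y))
  blocks <- sprintf("B%d", seq_len(B))
  env_grid <- expand.grid(location = locations, year = years,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  environments <- paste(env_grid$location, env_grid$year, sep = "_")

  # block-within-environment effects are shared across compounds and
  # varieties, so they come from the master stream
  set.seed(spec$seed)
  block_eff <- matrix(if (spec$block_sd > 0)
    rnorm(E * B, 0, spec$block_sd) else 0, E, B,
    dimnames = list(environments, blocks))

  comp <- spec$compounds
  design <- expand.grid(block = blocks, environment = environments,
                        variety = varieties,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  per_compound <- vector("list", nrow(comp))
  names(per_compound) <- comp$name
  tables <- vector("list", nrow(comp))

  for (ci in seq_len(nrow(comp))) {
    cc <- comp[ci, ]
    set.seed(.compound_seed(spec$seed, cc$name))
    g <- rnorm(V, 0, cc$sd_g); g <- g - mean(g)
    h <- rnorm(E, 0, cc$sd_e); h <- h - mean(h)
    names(g) <- varieties; names(h) <- environments

    beta <- NULL
    if (!is.null(spec$fw_slopes)) beta <- spec$fw_slopes[, ci]
    if (!is.null(beta)) {
      gh <- outer(beta - 1, h)
    } else if (!is.null(spec$interaction_rank)) {
      r <- spec$interaction_rank
      gh <- matrix(0, V, E)
      if (r > 0 && cc$sd_gxe > 0) {
        for (k in seq_len(min(r, V - 1, E - 1))) {
          u <- rnorm(V); w <- rnorm(E)
          u <- u - mean(u); w <- w - mean(w)
          u <- u / sqrt(sum(u^2)); w <- w / sqrt(sum(w^2))
          gh <- gh + outer(u, w)
        }
        gh <- .double_centre(gh)
        rms <- sqrt(mean(gh^2))
        if (rms > 0) gh <- gh * (cc$sd_gxe / rms)
      }
    } else if (cc$sd_gxe > 0) {
      gh <- .double_centre(matrix(rnorm(V * E, 0, cc$sd_gxe), V, E))
    } else gh <- matrix(0, V, E)
    dimnames(gh) <- list(varieties, environments)

    offsets <- setNames(numeric(V), varieties)
    mo <- spec$marker_offsets
    if (!is.null(mo)) {
      mi <- mo[mo$compound == cc$name, , drop = FALSE]
      if (nrow(mi)) offsets[as.character(mi$variety)] <- mi$offset
    }

    eps <- if (cc$sd_eps > 0) rnorm(V * E * B, 0, cc$sd_eps) else 0
    iv <- match(design$variety, varieties)
    ie <- match(design$environment, environments)
    ib <- match(design$block, blocks)
    lin <- cc$mu + g[iv] + offsets[iv] + h[ie] + gh[cbind(iv, ie)] +
      block_eff[cbind(ie, ib)] + eps
    value <- if (spec$noise_model == "lognormal") exp(lin) else lin

    fw <- if (sum(h^2) > 0) 1 + as.vector(gh %*% h) / sum(h^2)
      else rep(NA_real_, V)
    names(fw) <- varieties
    comps <- c(genotype = .pop_var(g + offsets), environment = .pop_var(h),
               interaction = mean(gh^2), block = spec$block_sd^2,
               residual = cc$sd_eps^2)
    per_compound[[ci]] <- list(
      mu = cc$mu, family = cc$family, g = g + offsets, h = h,
      interaction = gh, fw_slope = fw,
      var_shares = if (sum(comps) > 0) comps / sum(comps) else comps)

    tables[[ci]] <- data.frame(
      variety = design$variety,
      location = env_grid$location[match(design$environment, environments)],
      year = env_grid$year[match(design$environment, environments)],
      block = design$block, compound = cc$name, value = value,
      stringsAsFactors = FALSE)
  }

  table <- do.call(rbind, tables)
  rownames(table) <- NULL
  truth <- structure(list(
    seed = spec$seed, noise_model = spec$noise_model,
    varieties = varieties, environments = environments, blocks = blocks,
    block_effects = block_eff, compounds = per_compound), class = "sim_truth")
  list(table = table, truth = truth)
}

.double_centre <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m) - mean(m))
}

# population (divide-by-n) variance of realized, centred effects
.pop_var <- function(x) mean((x - mean(x))^2)

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "Ground truth for %d compounds, %d varieties x %d environments (seed %d)\n",
    length(x$compounds), length(x$varieties), length(x$environments), x$seed))
  invisible(x)
}

#' Write a panel to a delimited text file
#'
#' Values are serialized with `%.17g`, so a write/read round trip through
#' [read_panel()] reproduces every double bit-for-bit.
#'
#' @param table long-format panel `data.frame` with columns `variety`,
#'   `location`, `year`, `block`, `compound`, `value` (or `environment`
#'   in place of location/year).
#' @param path output path; a `.tsv` extension selects tab separation,
#'   anything else is written as CSV.
#' @return `path`, invisibly.
#' @export
write_panel <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0)
    stop("table must be a non-empty data.frame", call. = FALSE)
  need <- c("variety", "block", "compound", "value")
  if (!all(need %in% names(table)))
    stop("missing columns: ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  cols <- intersect(c("variety", "location", "year", "environment",
                      "block", "compound", "value"), names(table))
  out <- table[, cols]
  out$value <- sprintf("%.17g", out$value)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  ok <- tryCatch({
    write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write panel to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar as JSON
#'
#' @param truth a `"sim_truth"` object from [simulate_panel()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
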