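#' Describe one simulated compound
#'
#' Helper building one row of the compound table of a [sim_spec()]. All
#' standard deviations are on the scale of the (possibly log) response:
#' under the gaussian noise model they are in the compound's measurement
#' units, under the lognormal model they act on the log scale.
#'
#' @param name compound label (unique within a spec).
#' @param family free-text family tag (e.g. "terpene", "polyphenol");
#'   carried through to outputs, not interpreted.
#' @param mu base level; must be >= 0 (and > 0 under the lognormal model,
#'   where it is the log-scale location).
#' @param sd_g genotype (variety main effect) standard deviation.
#' @param sd_e environment main-effect standard deviation.
#' @param sd_gxe standard deviation of the variety-by-environment
#'   interaction term.
#' @param sd_eps residual (within-block) standard deviation.
#' @return one-row `data.frame` suitable for `rbind`-ing into the
#'   `compounds` argument of [sim_spec()].
#' @export
sim_compound <- function(name, family = "general", mu = 10,
                         sd_g = 1, sd_e = 2, sd_gxe = 0.5, sd_eps = 0.5) {
  data.frame(name = as.character(name), family = as.character(family),
             mu = mu, sd_g = sd_g, sd_e = sd_e, sd_gxe = sd_gxe,
             sd_eps = sd_eps, stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-environment metabolite panel
#'
#' Defines a crossed variety x location x year x block design and the
#' generating model for each compound:
#' \deqn{y_{vebc} = \mu_c + g_{vc} + h_{ec} + (gh)_{vec} + b_{eb} +
#'   \varepsilon}{y = mu + g + h + gh + block + eps}
#' with environment defined as the location-by-year combination. Under
#' `noise_model = "lognormal"` the simulated value is the exponential of
#' that sum, giving strictly positive abundances. Genotype and
#' environment effects are centred to sum to zero and the interaction
#' matrix is doubly centred, so generated effects are identifiable.
#'
#' Three interaction regimes are available, per compound:
#' \itemize{
#'   \item unstructured (default, `interaction_rank = NULL`): i.i.d.
#'     gaussian interaction, doubly centred;
#'   \item low rank (`interaction_rank = r`): a rank-`r` product of
#'     centred unit score vectors, scaled so its root-mean-square equals
#'     `sd_gxe` - the regime recovered by an AMMI fit;
#'   \item regression (`fw_slopes` given): \eqn{(gh)_{vec} =
#'     (\beta_{vc}-1) h_{ec}}, so the Finlay-Wilkinson slope of variety
#'     v is \eqn{\beta_{vc}} by construction (exactly so when the slopes
#'     average to 1 across varieties; otherwise the fitted slopes are
#'     \eqn{\beta_{vc}/\bar\beta_c} and a warning is issued).
#' }
#'
#' @param n_varieties,n_locations,n_years,n_blocks positive design counts;
#'   `n_blocks >= 2` is required (downstream variance partitioning needs
#'   residual degrees of freedom).
#' @param compounds `data.frame` as built by [sim_compound()]; compound
#'   names must be unique.
#' @param fw_slopes optional generating Finlay-Wilkinson slopes: a numeric
#'   vector of length `n_varieties` (applied to every compound) or a
#'   `n_varieties x nrow(compounds)` matrix. Overrides the interaction
#'   regime for the affected compounds.
#' @param interaction_rank optional non-negative integer; `0` disables the
#'   interaction, `NULL` leaves it unstructured.
#' @param block_sd non-negative standard deviation of the block-within-
#'   environment effect (shared by all compounds and varieties).
#' @param marker_offsets optional `data.frame(variety, compound, offset)`
#'   of planted variety-specific level shifts (discriminant markers).
#' @param noise_model `"gaussian"` or `"lognormal"`.
#' @param seed integer master seed; per-compound generator sub-streams are
#'   derived from it and the compound name, so adding a compound does not
#'   perturb the values simulated for the others.
#' @return object of class `"sim_spec"`.
#' @seealso [simulate_panel()], [sim_spec_diversity()],
#'   [sim_spec_plasticity()]
#' @export
sim_spec <- function(n_varieties, n_locations, n_years = 1L, n_blocks = 2L,
                     compounds,
                     fw_slopes = NULL, interaction_rank = NULL,
                     block_sd = 0, marker_offsets = NULL,
                     noise_model = c("gaussian", "lognormal"),
                     seed = 1L) {
  noise_model <- match.arg(noise_model)
  counts <- c(n_varieties = n_varieties, n_locations = n_locations,
              n_years = n_years, n_blocks = n_blocks)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("design counts must be positive integers", call. = FALSE)
  if (n_blocks < 2)
    stop("n_blocks must be >= 2 (replicates are needed for a residual term)",
         call. = FALSE)
  if (!is.data.frame(compounds) ||
      !all(c("name", "mu", "sd_g", "sd_e", "sd_gxe", "sd_eps") %in%
           names(compounds)))
    stop("'compounds' must be a data.frame as built by sim_compound()",
         call. = FALSE)
  if (anyDuplicated(compounds$name))
    stop("compound names must be unique", call. = FALSE)
  sds <- as.matrix(compounds[, c("sd_g", "sd_e", "sd_gxe", "sd_eps")])
  if (any(sds < 0) || block_sd < 0)
    stop("all standard deviations must be >= 0", call. = FALSE)
  if (any(compounds$mu < 0))
    stop("base levels mu must be >= 0", call. = FALSE)
  if (noise_model == "lognormal" && any(compounds$mu == 0))
    stop("lognormal noise model requires mu > 0 for every compound",
         call. = FALSE)
  if (!is.null(interaction_rank)) {
    if (interaction_rank < 0 || interaction_rank != round(interaction_rank))
      stop("interaction_rank must be a non-negative integer", call. = FALSE)
  }
  if (!is.null(fw_slopes)) {
    fw_slopes <- if (is.matrix(fw_slopes)) fw_slopes else
      matrix(fw_slopes, nrow = n_varieties, ncol = nrow(compounds))
    if (nrow(fw_slopes) != n_varieties || ncol(fw_slopes) != nrow(compounds))
      stop("fw_slopes must be n_varieties x n_compounds", call. = FALSE)
    off <- abs(colMeans(fw_slopes) - 1) > 1e-8
    if (any(off))
      warning("fw_slopes do not average to 1 for ",
              sum(off), " compound(s); fitted slopes will be beta/mean(beta)",
              call. = FALSE)
  }
  if (!is.null(marker_offsets) &&
      (!is.data.frame(marker_offsets) ||
       !all(c("variety", "compound", "offset") %in% names(marker_offsets))))
    stop("marker_offsets must have columns variety, compound, offset",
         call. = FALSE)
  structure(list(
    n_varieties = as.integer(n_varieties),
    n_locations = as.integer(n_locations),
    n_years = as.integer(n_years),
    n_blocks = as.integer(n_blocks),
    compounds = compounds,
    fw_slopes = fw_slopes,
    interaction_rank = interaction_rank,
    block_sd = block_sd,
    marker_offsets = marker_offsets,
    noise_model = noise_model,
    seed = as.integer(seed)), class = "sim_spec")
}

#' @export
print.sim_spec <- function(x, ...) {
  cat("Synthetic panel specification\n")
  cat(sprintf("  design: %d varieties x %d locations x %d year(s) x %d blocks\n",
              x$n_varieties, x$n_locations, x$n_years, x$n_blocks))
  cat(sprintf("  compounds: %d (%s noise)\n", nrow(x$compounds), x$noise_model))
  if (!is.null(x$fw_slopes)) cat("  interaction: regression (fw_slopes)\n")
  else if (!is.null(x$interaction_rank))
    cat(sprintf("  interaction: rank %d\n", x$interaction_rank))
  else cat("  interaction: unstructured\n")
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# deterministic 31-bit hash of (seed, name); drives per-compound sub-streams
.compound_seed <- function(seed, name) {
  h <- as.numeric(seed) %% 2147483629
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483629
  as.integer(h)
}

# default compound families: base levels and relative variance components
# chosen as round values typical of root-vegetable panels where environment
# dominates genotype (see the methods vignette)
.family_defaults <- function() {
  data.frame(
    family = c("carbohydrate", "organic_acid", "carotenoid", "terpene",
               "sesquiterpene", "polyacetylene", "phenolic",
               "phenylpropanoid", "polyphenol"),
    mu     = c(40, 6, 8, 50, 30, 20, 4, 6, 10),
    rel_g  = 0.18, rel_e = 0.25, rel_gxe = 0.08, rel_eps = 0.06,
    stringsAsFactors = FALSE)
}

.compounds_from_codes <- function(codes, families) {
  fam <- .family_defaults()
  rows <- lapply(seq_along(codes), function(i) {
    f <- fam[fam$family == families[i], ]
    sim_compound(codes[i], families[i], mu = f$mu,
                 sd_g = f$rel_g * f$mu, sd_e = f$rel_e * f$mu,
                 sd_gxe = f$rel_gxe * f$mu, sd_eps = f$rel_eps * f$mu)
  })
  do.call(rbind, rows)
}

# the 39 compounds quantified in every variety of the reduced panel,
# tagged by chemical family (codes follow field conventions: T terpene,
# S sesquiterpene, PP phenylpropanoid, Fa* polyacetylenes, 6MM phenolic)
.core_codes <- function() {
  list(
    codes = c("PP2", "S6", "T2", "S10", "PP1", "6MM", "S1", "T15", "T3",
              "T5", "T18", "T1", "FaDOAc", "S5", "T16", "S2", "S11",
              "acar", "T17", "S4", "S9", "FaDOH", "T14", "FaOH", "SAC",
              "T7", "S13", "T8", "CIT", "T6", "lut", "S7", "GLU", "T9",
              "T4", "Bcar", "MAL", "FRU", "S3"),
    families = c("phenylpropanoid", "sesquiterpene", "terpene",
                 "sesquiterpene", "phenylpropanoid", "phenolic",
                 "sesquiterpene", "terpene", "terpene", "terpene",
                 "terpene", "terpene", "polyacetylene", "sesquiterpene",
                 "terpene", "sesquiterpene", "sesquiterpene", "carotenoid",
                 "terpene", "sesquiterpene", "sesquiterpene",
                 "polyacetylene", "terpene", "polyacetylene",
                 "carbohydrate", "terpene", "sesquiterpene", "terpene",
                 "organic_acid", "terpene", "carotenoid", "sesquiterpene",
                 "carbohydrate", "terpene", "terpene", "carotenoid",
                 "organic_acid", "carbohydrate", "sesquiterpene"))
}

#' Default spec for the diversity-panel design
#'
#' 16 varieties grown at 3 contrasted locations in one year, two blocks,
#' 86 compounds (the 39 core compounds plus 47 polyphenols), emulating a
#' first-year varietal diversity trial.
#'
#' @param seed master seed.
#' @param ... passed on to [sim_spec()] (e.g. `fw_slopes`,
#'   `interaction_rank`).
#' @return a `"sim_spec"` object.
#' @export
sim_spec_diversity <- function(seed = 1L, ...) {
  core <- .core_codes()
  poly <- sprintf("P%02d", seq_len(47))
  comp <- rbind(.compounds_from_codes(core$codes, core$families),
                .compounds_from_codes(poly, rep("polyphenol", 47)))
  sim_spec(n_varieties = 16, n_locations = 3, n_years = 1, n_blocks = 2,
           compounds = comp, block_sd = 0.2, seed = seed, ...)
}

#' Default spec for the plasticity-panel design
#'
#' 5 varieties grown in 20 environments (10 locations x 2 years), three
#' blocks, on the 39 compounds accumulated by every variety - the design
#' used for the amplitude-based plasticity screen and the stability
#' models.
#'
#' @inheritParams sim_spec_diversity
#' @return a `"sim_spec"` object.
#' @export
sim_spec_plasticity <- function(seed = 1L, ...) {
  core <- .core_codes()
  comp <- .compounds_from_codes(core$codes, core$families)
  sim_spec(n_varieties = 5, n_locations = 10, n_years = 2, n_blocks = 3,
           compounds = comp, block_sd = 0.2, seed = seed, ...)
}

#' Read a panel specification from a YAML or JSON file
#'
#' The file holds the scalar fields of [sim_spec()] plus a `compounds`
#' list of records with the [sim_compound()] fields.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return a `"sim_spec"` object.
#' @export
read_sim_spec <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  comp <- cfg$compounds
  if (is.list(comp) && !is.data.frame(comp))
    comp <- do.call(rbind, lapply(comp, function(r) do.call(sim_compound, r)))
  args <- cfg[setdiff(names(cfg), "compounds")]
  do.call(sim_spec, c(list(compounds = comp), args))
}
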