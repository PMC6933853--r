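#' Run configuration and thoroughness presets
#'
#' Three presets control how much computation a run invests: `quick` uses a
#' coarse 20-level contour schedule and no helix template search (unless
#' fragments are supplied); `medium` (the default) uses the full 40-level
#' schedule with helix search on, set to maximize the amount of model
#' built; `thorough` runs quick then medium and merges the two chain sets
#' with [combine_models()].
#'
#' @param mode `"quick"`, `"medium"` or `"thorough"`.
#' @param seed Integer seed fixed before any stochastic step.
#' @param resolution Nominal map resolution in Angstroms (`NA` = take the
#'   map's `resolution_hint`).
#' @param n_workers Worker processes for per-region work (results are
#'   independent of the worker count).
#' @param seg_params,path_params,morph_params,build_params,hbond_params
#'   Module parameter blocks; `NULL` means the preset default.
#' @param helix_search Override the preset's helix-search switch.
#' @param min_chain_cc Chains whose map-model correlation falls below this
#'   are discarded before combination (0.5 is where the density-fit score
#'   U changes sign, i.e. where a chain stops paying for its size).
#' @return A `run_config` list.
#' @export
run_preset <- function(mode = c("medium", "quick", "thorough"), seed = 1L,
                       resolution = NA_real_, n_workers = 1L,
                       seg_params = NULL, path_params = NULL,
                       morph_params = NULL, build_params = NULL,
                       hbond_params = NULL, helix_search = NULL,
                       min_chain_cc = 0.5) {
  mode <- match.arg(mode)
  path_params <- path_params %||% path_weight_params()
  n_levels <- switch(mode, quick = 20L, medium = 40L, thorough = 40L)
  seg <- seg_params %||%
    segmentation_params(n_levels = n_levels, path_params = path_params)
  if (is.null(seg_params)) seg$n_levels <- n_levels
  structure(list(
    mode = mode, seed = as.integer(seed), resolution = resolution,
    n_workers = as.integer(n_workers),
    seg_params = seg, path_params = path_params,
    # in call position R finds the function even though the argument
    # shadows the name
    morph_params = morph_params %||% morph_params(),
    build_params = build_params %||% ca_build_params(),
    hbond_params = hbond_params %||% hbond_params(),
    helix_search = helix_search %||% (mode != "quick"),
    min_chain_cc = min_chain_cc
  ), class = "run_config")
}

#' Trace density and build Calpha models
#'
#' The full pipeline: locate helices (template search, or supplied
#' fragments), grow density segments by iterative contour lowering with
#' branch rejection, then per region trace the minimum-weight path between
#' the region end points, extract ridgeline bones, morph the path onto
#' them, identify Cbeta candidates, place/optimize/refine Calpha positions,
#' splice in secondary-structure fragments, score both chain directions and
#' keep the better, and finally combine all chains, removing overlaps.
#' Fully deterministic given the map, configuration and seed.
#'
#' For `mode = "thorough"`, the quick and medium pipelines are both run and
#' their chain sets merged with [combine_models()].
#'
#' @param map A [density_map()].
#' @param config A `run_config` from [run_preset()].
#' @param ss_fragments Optional list of secondary-structure fragments (atom
#'   tibbles) to seed segmentation and splicing.
#' @return A `catrace_run`: list with `models` (list of `ca_model`),
#'   `report` (per-chain tibble), `summary` (one-row tibble), `config`.
#' @export
trace_and_build <- function(map, config = run_preset(),
                            ss_fragments = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (config$mode == "thorough") {
    rq <- trace_and_build(map, preset_variant(config, "quick"), ss_fragments)
    rm_ <- trace_and_build(map, preset_variant(config, "medium"), ss_fragments)
    models <- combine_models(c(rq$models, rm_$models), map)
    return(finish_run(models, map, config, t0,
                      n_regions = rm_$summary$n_regions))
  }

  resolution <- if (is.finite(config$resolution)) config$resolution
                else map$resolution_hint
  fragments <- ss_fragments
  if (is.null(fragments) && isTRUE(config$helix_search) &&
      is.finite(resolution) && resolution <= 5) {
    fragments <- find_helices(map, resolution)
  }
  fragments <- fragments %||% list()

  seeds <- if (length(fragments) > 0)
    seed_regions_from_fragments(map, fragments, config$seg_params) else NULL
  state <- grow_segments(map, config$seg_params, seeds = seeds)

  worker <- function(ri) {
    build_region_model(state$regions[[ri]], map, config, fragments,
                       region_seed = config$seed + ri)
  }
  idx <- seq_along(state$regions)
  results <- if (config$n_workers > 1 && length(idx) > 1 &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(idx, worker, mc.cores = config$n_workers,
                       mc.preschedule = TRUE)
  } else {
    lapply(idx, worker)
  }
  # deterministic region order regardless of completion order
  models <- Filter(Negate(is.null), results)
  models <- Filter(function(m) {
    cc <- tryCatch(map_model_cc(m, map), error = function(e) -1)
    cc >= config$min_chain_cc
  }, models)
  models <- combine_models(models, map)
  finish_run(models, map, config, t0, n_regions = length(state$regions))
}

preset_variant <- function(config, mode) {
  run_preset(mode, seed = config$seed, resolution = config$resolution,
             n_workers = config$n_workers,
             path_params = config$path_params,
             morph_params = config$morph_params,
             build_params = config$build_params,
             hbond_params = config$hbond_params,
             min_chain_cc = config$min_chain_cc)
}

# one region -> one (direction-chosen) chain, or NULL
build_region_model <- function(region, map, config, fragments,
                               region_seed) {
  path <- region$path
  if (is.null(path)) {
    region <- detect_branching(region, map, config$seg_params)
    path <- region$path
  }
  if (is.null(path) || nrow(path$points) < 2 ||
      path$unweighted_length < config$build_params$target_ca_ca / 2)
    return(NULL)
  bones <- extract_bones(map, region)
  path <- morph_path(path, bones, config$morph_params)
  side <- side_chain_bones(bones, path, config$build_params)
  cbetas <- cbeta_candidates(path, side, config$build_params)
  model <- place_initial_ca(path, cbetas, config$build_params)
  if (nrow(model) < 2) return(NULL)
  model <- optimize_ca(model, map, path, cbetas, config$build_params,
                       seed = region_seed)
  model <- attach_cbetas(model, cbetas, config$build_params)
  model <- refine_ca(model, map, config$build_params)
  if (length(fragments) > 0) {
    ok <- fragment_fit_ok(fragments, map, model,
                          config$build_params$splice_min_density_ratio)
    if (any(ok))
      model <- splice_ss(model, fragments[ok], config$build_params)
  }
  reverse <- model[rev(seq_len(nrow(model))), ]
  reverse$residue_index <- seq_len(nrow(reverse))
  class(reverse) <- class(model)
  choose_direction(model, reverse, map, config$hbond_params)
}

# density support of fragment Calphas relative to the traced model's
fragment_fit_ok <- function(fragments, map, model, min_ratio) {
  ref <- mean(interp_density(map, ca_xyz(model)))
  vapply(fragments, function(f) {
    fca <- f[f$atom == "CA", c("x", "y", "z")]
    ref > 0 && mean(interp_density(map, as.matrix(fca))) / ref >= min_ratio
  }, logical(1))
}

attach_cbetas <- function(model, cbetas, params) {
  if (nrow(cbetas) == 0) return(model)
  ca <- ca_xyz(model)
  for (j in seq_len(nrow(cbetas))) {
    d2 <- (ca[, 1] - cbetas[j, 1])^2 + (ca[, 2] - cbetas[j, 2])^2 +
      (ca[, 3] - cbetas[j, 3])^2
    k <- which.min(d2)
    if (d2[k] <= params$cb_attach_max^2 &&
        !is.finite(model$cb_x[k])) {
      model$cb_x[k] <- cbetas[j, 1]
      model$cb_y[k] <- cbetas[j, 2]
      model$cb_z[k] <- cbetas[j, 3]
    }
  }
  model
}

finish_run <- function(models, map, config, t0, n_regions = NA_integer_) {
  report <- if (length(models) > 0) {
    dplyr::bind_rows(lapply(models, function(m) {
      dplyr::bind_cols(tibble::tibble(chain_id = m$chain_id[1]),
                       score_breakdown(m, map),
                       tibble::tibble(direction =
                                        attr(m, "direction") %||% "forward"))
    }))
  } else {
    tibble::tibble(chain_id = character(0), n_residues = integer(0),
                   n_atoms = integer(0), cc = numeric(0),
                   hbond_score = numeric(0), density_fit_U = numeric(0),
                   combined_T = numeric(0), direction = character(0))
  }
  summary <- tibble::tibble(
    mode = config$mode, seed = config$seed,
    n_regions = n_regions, n_chains = length(models),
    total_residues = sum(report$n_residues),
    mean_chain_length = if (length(models) > 0)
      mean_chain_length(models) else NA_real_,
    mean_cc = if (nrow(report) > 0) mean(report$cc) else NA_real_,
    wall_time_s = proc.time()[["elapsed"]] - t0)
  structure(list(models = models, report = report, summary = summary,
                 config = config), class = "catrace_run")
}

#' @export
print.catrace_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<catrace_run> mode %s: %d chain(s), %d residues built (mean chain length %.1f)\n",
    s$mode, s$n_chains, s$total_residues,
    ifelse(is.na(s$mean_chain_length), 0, s$mean_chain_length)))
  if (nrow(x$report) > 0) print(x$report)
  invisible(x)
}

#' Compare built models against a reference
#'
#' Fraction of reference Calpha atoms matched by a built Calpha within
#' `cutoff`, the RMSD over the matched pairs, and the mean chain length of
#' the built models.
#'
#' @param built List of `ca_model`s (or a single one).
#' @param reference Atom tibble containing CA records.
#' @param cutoff Match radius, Angstroms (default 3).
#' @return One-row tibble: `fraction_matched` (percent), `rmsd_matched`
#'   (Angstroms, `NA` if nothing matched), `mean_chain_length`,
#'   `n_reference`, `n_built`.
#' @export
compare_to_reference <- function(built, reference, cutoff = 3) {
  if (inherits(built, "ca_model")) built <- list(built)
  ref_ca <- reference[reference$atom == "CA", , drop = FALSE]
  if (nrow(ref_ca) == 0) stop("reference contains no CA atoms",
                              call. = FALSE)
  built_ca <- do.call(rbind, lapply(built, ca_xyz))
  if (is.null(built_ca) || nrow(built_ca) == 0) {
    return(tibble::tibble(fraction_matched = 0, rmsd_matched = NA_real_,
                          mean_chain_length = NA_real_,
                          n_reference = nrow(ref_ca), n_built = 0L))
  }
  rxyz <- as.matrix(ref_ca[, c("x", "y", "z")])
  dmin <- vapply(seq_len(nrow(rxyz)), function(i) {
    sqrt(min((built_ca[, 1] - rxyz[i, 1])^2 +
               (built_ca[, 2] - rxyz[i, 2])^2 +
               (built_ca[, 3] - rxyz[i, 3])^2))
  }, numeric(1))
  matched <- dmin <= cutoff
  tibble::tibble(
    fraction_matched = 100 * mean(matched),
    rmsd_matched = if (any(matched)) sqrt(mean(dmin[matched]^2)) else NA_real_,
    mean_chain_length = mean(vapply(built, nrow, integer(1))),
    n_reference = nrow(ref_ca),
    n_built = nrow(built_ca))
}

#' Tidy per-chain results of a run
#'
#' @param x A `catrace_run`.
#' @param ... Unused.
#' @return The per-chain score tibble.
#' @export
tidy.catrace_run <- function(x, ...) x$report

#' One-row summary of a run
#'
#' @param x A `catrace_run`.
#' @param ... Unused.
#' @return One-row tibble with chain and residue totals, mean chain length,
#'   mean CC and wall time.
#' @export
glance.catrace_run <- function(x, ...) x$summary

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot per-chain results of a run
#'
#' Bar chart of residues built per chain, filled by map-model correlation.
#'
#' @param object A `catrace_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.catrace_run <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$chain_id,
                                    y = .data$n_residues,
                                    fill = .data$cc)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_gradient(low = "grey70", high = "steelblue4",
                                 limits = c(0, 1), name = "CC") +
    ggplot2::labs(x = "chain", y = "residues built",
                  title = sprintf("catrace %s run: %d residues in %d chains",
                                  object$summary$mode,
                                  object$summary$total_residues,
                                  object$summary$n_chains)) +
    ggplot2::theme_minimal()
}

#' Plot a density-map slice
#'
#' Raster of one z-section of the map (the densest section by default).
#'
#' @param object A `density_map`.
#' @param k 0-based section index (`NULL` = densest section).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_map <- function(object, k = NULL, ...) {
  d <- dim(object$values)
  if (is.null(k)) {
    sums <- apply(object$values, 3, max)
    k <- which.max(sums) - 1L
  }
  sl <- object$values[, , k + 1L]
  df <- tibble::tibble(
    x = object$origin[1] + (rep(seq_len(d[1]), d[2]) - 1) *
      object$voxel_size[1],
    y = object$origin[2] + (rep(seq_len(d[2]), each = d[1]) - 1) *
      object$voxel_size[2],
    density = as.vector(sl))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("map section z = %.1f A",
                                  object$origin[3] + k *
                                    object$voxel_size[3]),
                  x = "x (A)", y = "y (A)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Write a run report as JSON
#'
#' @param run A `catrace_run`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_run_report <- function(run, path) {
  jsonlite::write_json(
    list(summary = as.list(run$summary), chains = run$report),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
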