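#' Pipeline run configuration
#'
#' @param seed integer seed used for every stochastic stage.
#' @param n_permutations permutations for the PERMANOVA / dispersion tests
#'   (>= 99; the canonical analysis value is 9999).
#' @param alpha significance level.
#' @param bonferroni_k number of tests the Bonferroni-adjusted alpha divides
#'   over (3 for the per-phase dip comparisons).
#' @param column_map optional named character vector mapping the metrics
#'   schema column names to the column names of an external CSV, e.g.
#'   `c(bpi_pct = "BP1_rel_area", group = "Period")`.
#' @param out_dir output directory for result files.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, n_permutations = 9999L, alpha = 0.05,
                       bonferroni_k = 3L, column_map = NULL,
                       out_dir = tempdir()) {
  stopifnot(n_permutations >= 99L, alpha > 0, alpha < 1, bonferroni_k >= 1L)
  cfg <- structure(list(seed = as.integer(seed),
                        n_permutations = as.integer(n_permutations),
                        alpha = alpha, bonferroni_k = as.integer(bonferroni_k),
                        column_map = column_map, out_dir = out_dir),
                   class = "run_config")
  cfg$hash <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg[c("seed", "n_permutations", "alpha",
                             "bonferroni_k", "column_map")],
                       tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Measure one aligned specimen
#'
#' Computes the wear-facet composition, the per-phase mean dip angles
#' (unweighted mean over a phase's facets by default, area-weighted behind
#' the flag) and the occlusal relief index of a crown mesh already aligned
#' to its occlusal frame (cervical plane z = 0).
#'
#' @param mesh aligned [triangle_mesh()].
#' @param annotation a [facet_annotation()].
#' @param catalog a [facet_catalog()].
#' @param specimen_id,group,sex,age_class record metadata.
#' @param fossa_point optional explicit fossa point for the ORI.
#' @param area_weighted_dips use area-weighted per-phase mean dips.
#' @return a [tooth_record()].
#' @export
measure_specimen <- function(mesh, annotation, catalog, specimen_id,
                             group = "unknown", sex = "indeterminate",
                             age_class = "unknown", fossa_point = NULL,
                             area_weighted_dips = FALSE) {
  cerv <- plane3d(c(0, 0, 1), 0)
  pa <- phase_areas(mesh, annotation, catalog)
  comp <- wear_composition(pa)
  fac <- pa$facets
  fac$dip <- vapply(fac$label, function(lb)
    dip_angle(mesh, annotation$face_index[annotation$facet_label == lb], cerv),
    numeric(1))
  dips <- vapply(c("BPI", "LPI", "PII"), function(cc) {
    sel <- fac$class == cc
    if (!any(sel)) return(NA_real_)
    if (area_weighted_dips) sum(fac$dip[sel] * fac$area_mm2[sel]) / sum(fac$area_mm2[sel])
    else mean(fac$dip[sel])
  }, numeric(1))
  ori <- occlusal_relief_index(mesh, cerv, fossa_point = fossa_point)
  tooth_record(specimen_id, group, sex, age_class, comp, dips, ori$ori)
}

#' Batch-measure specimens to a metrics CSV
#'
#' Per-specimen failures are logged and skipped; the batch never aborts. A
#' run with zero successful specimens is an error.
#'
#' @param specimens data.frame with columns `specimen_id`, `mesh_path`,
#'   `annotation_path`, and optionally `group`, `sex`, `age_class`.
#' @param catalog a [facet_catalog()].
#' @param config a [run_config()].
#' @param out_csv output CSV path (default `<out_dir>/metrics.csv`).
#' @return the `metrics_table`, invisibly; written to `out_csv`.
#' @export
cmd_measure <- function(specimens, catalog = default_facet_catalog(),
                        config = run_config(),
                        out_csv = file.path(config$out_dir, "metrics.csv")) {
  recs <- list()
  for (i in seq_len(nrow(specimens))) {
    s <- specimens[i, ]
    rec <- tryCatch({
      mesh <- read_mesh(s$mesh_path)
      ann <- read_facet_annotation(s$annotation_path)
      measure_specimen(mesh, ann, catalog, s$specimen_id,
                       group = s$group %||% "unknown",
                       sex = s$sex %||% "indeterminate",
                       age_class = s$age_class %||% "unknown")
    }, error = function(e) {
      log_msg("warn", "specimen ", s$specimen_id, " failed: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (length(recs) == 0L)
    stop("no specimen could be measured", call. = FALSE)
  tab <- build_metrics_table(recs)
  write_metrics_table(tab, out_csv)
  log_msg("info", sprintf("measured %d/%d specimens -> %s",
                          nrow(tab), nrow(specimens), out_csv))
  invisible(tab)
}

apply_column_map <- function(d, column_map) {
  if (is.null(column_map)) return(d)
  for (ours in names(column_map)) {
    theirs <- column_map[[ours]]
    if (!theirs %in% names(d))
      stop("column-mapping refers to missing column: ", theirs, call. = FALSE)
    d[[ours]] <- d[[theirs]]
  }
  d
}

#' Run the group-comparison statistics on a metrics table
#'
#' Reproduces the analysis flow on a metrics table: ilr transform of the
#' (BPI, LPI, PII) composition, one-way PERMANOVA on the Euclidean ilr
#' distances, homogeneity-of-dispersion test, pairwise PERMANOVA, Welch
#' t-tests for each dip-angle phase and ORI (two-group tables only),
#' compositional centers and ternary coordinates. Results are written as
#' JSON plus CSV tables, each carrying the seed and config hash.
#'
#' @param metrics a `metrics_table`, or path to a metrics CSV (the
#'   `column_map` of `config` is applied to external CSVs).
#' @param group_col grouping column (>= 2 levels).
#' @param config a [run_config()].
#' @return list of class `stats_bundle` with elements `permanova`,
#'   `dispersion`, `pairwise`, `welch` (per-variable), `centers`,
#'   `ternary`, `config`; files under `config$out_dir`.
#' @export
cmd_stats <- function(metrics, group_col = "group", config = run_config()) {
  if (is.character(metrics)) {
    d <- utils::read.csv(metrics, stringsAsFactors = FALSE)
    d <- apply_column_map(d, config$column_map)
    missing <- setdiff(metrics_table_columns, names(d))
    if (length(missing) > 0L)
      stop("metrics input missing column(s) ", paste(missing, collapse = ", "),
           "; supply a column_map entry for each", call. = FALSE)
  } else {
    d <- as.data.frame(metrics)
  }
  if (!group_col %in% names(d))
    stop("grouping column not found: ", group_col, call. = FALSE)
  groups <- droplevels(as.factor(d[[group_col]]))
  if (nlevels(groups) < 2L)
    stop("grouping column needs at least 2 levels", call. = FALSE)

  comp <- as.matrix(d[, c("bpi_pct", "lpi_pct", "pii_pct")]) / 100
  comp <- comp / rowSums(comp)
  if (any(comp == 0)) comp <- replace_zeros(comp)
  y <- ilr_transform(comp)
  dmat <- stats::dist(y)

  perm <- permanova_oneway(dmat, groups, n_perm = config$n_permutations,
                           seed = config$seed)
  disp <- dispersion_test(dmat, groups, n_perm = config$n_permutations,
                          seed = config$seed)
  pw <- pairwise_permanova(y, groups, n_perm = config$n_permutations,
                           seed = config$seed)

  welch <- NULL
  if (nlevels(groups) == 2L) {
    lv <- levels(groups)
    welch <- lapply(c(bpi = "bpi_dip_deg", lpi = "lpi_dip_deg",
                      pii = "pii_dip_deg", ori = "ori"), function(col) {
      x <- d[[col]][groups == lv[2L]]
      yv <- d[[col]][groups == lv[1L]]
      welch_t_test(x[!is.na(x)], yv[!is.na(yv)])
    })
  }

  centers <- lapply(levels(groups), function(lv) {
    list(group = lv,
         geometric = compositional_center(comp[groups == lv, , drop = FALSE]),
         arithmetic = compositional_center(comp[groups == lv, , drop = FALSE],
                                           mode = "arithmetic"))
  })
  tern <- cbind(d[group_col], as.data.frame(ternary_coordinates(comp)))

  out <- structure(list(permanova = perm, dispersion = disp, pairwise = pw,
                        welch = welch, centers = centers, ternary = tern,
                        config = config),
                   class = "stats_bundle")
  write_stats_bundle(out, config)
  invisible(out)
}

write_stats_bundle <- function(bundle, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(seed = config$seed, n_permutations = config$n_permutations,
               config_hash = config$hash)
  js <- list(provenance = prov,
             permanova = unclass(bundle$permanova),
             dispersion = unclass(bundle$dispersion)[
               c("group_means", "SS_between", "SS_within", "F", "p_value",
                 "n_perm")],
             pairwise = list(p_raw = bundle$pairwise$p_raw,
                             p_adjusted = bundle$pairwise$p_adjusted,
                             method = bundle$pairwise$method),
             welch = lapply(bundle$welch, unclass),
             bonferroni_alpha = bonferroni_alpha(config$alpha,
                                                 config$bonferroni_k),
             centers = bundle$centers)
  jsonlite::write_json(js, file.path(config$out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  utils::write.csv(bundle$ternary,
                   file.path(config$out_dir, "ternary_coordinates.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(bundle$welch)) {
    wt <- do.call(rbind, lapply(names(bundle$welch), function(nm) {
      w <- bundle$welch[[nm]]
      data.frame(variable = nm, t = w$t, df = w$df, p = w$p_value,
                 cohen_d = w$cohen_d, d_lo = w$d_ci[1], d_hi = w$d_ci[2])
    }))
    utils::write.csv(wt, file.path(config$out_dir, "welch_tests.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}

#' Run a power-stroke simulation to disk
#'
#' @param lower,upper [triangle_mesh()] objects (lower at the first
#'   trajectory waypoint).
#' @param annotation lower-mesh [facet_annotation()].
#' @param catalog a [facet_catalog()].
#' @param traj a [trajectory()].
#' @param config a [run_config()].
#' @param sim a [simulation_config()].
#' @return the `contact_timeline`, invisibly; writes `timeline.csv` and
#'   `simulation_summary.json` under `config$out_dir`.
#' @export
cmd_simulate <- function(lower, upper, annotation,
                         catalog = default_facet_catalog(), traj,
                         config = run_config(), sim = simulation_config()) {
  tl <- simulate_power_stroke(lower, upper, annotation, catalog, traj, sim)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_timeline_csv(tl, file.path(config$out_dir, "timeline.csv"))
  sm <- timeline_summary(tl)
  jsonlite::write_json(
    list(provenance = list(seed = config$seed, config_hash = config$hash),
         n_steps = sm$n_steps, phase1_steps = sm$phase1_steps,
         phase2_steps = sm$phase2_steps, contact_steps = sm$contact_steps,
         exclusive_pii_steps = sm$exclusive_pii_steps),
    file.path(config$out_dir, "simulation_summary.json"),
    auto_unbox = TRUE, digits = NA)
  log_msg("info", sprintf("simulated %d timesteps -> %s", sm$n_steps,
                          config$out_dir))
  invisible(tl)
}
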