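# End-to-end orchestration: structures -> A2/A23 per variant x pH ->
# optional calibration -> feature table -> PCA + MLR -> threshold
# predictions, plus pose mining on a chosen condition. Configurations are
# flat declarative lists, serializable to YAML, and every artifact carries
# the config hash and seed.

# FNV-1a 32-bit hash of a string (used to stamp outputs with a config id).
# Arithmetic kept within double precision: the byte xor touches only the low
# 8 bits, and the 32-bit modular product is split into 16-bit halves.
.fnv1a <- function(s) {
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(s)) {
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * m + ((hi * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  .fnv1a(paste(deparse(unclass(config)), collapse = "\n"))
}

#' Build a pipeline configuration
#'
#' Assembles and validates the declarative configuration driving
#' [run_pipeline()]. Variants are either toy-body specifications
#' (arguments to [make_toy_body()]) or paths to externally prepared PQR
#' files; the "open" conformation of each variant is derived from the
#' "closed" one by removing `tail_residues` leading residues (mirroring
#' removal of a terminal tail from a binding groove), or by explicit
#' `range_closed`/`range_open` residue windows for PQR inputs.
#'
#' @param variants named list; each element is a list with either `toy`
#'   (a list of [make_toy_body()] arguments) or `pqr` (a file path), plus
#'   optional `mutations` (character vector like `"H35S"`),
#'   `range_closed`, `range_open` (length-2 residue windows).
#' @param partner the A23 partner body: a list with `toy` or `pqr` as
#'   above (typically a short acidic peptide).
#' @param pH numeric vector of pH values (default `c(7, 8)`).
#' @param thresholds named numeric vector of measured phase-separation
#'   thresholds in uM, names `"<variant>_pH<pH>"`; `NA` marks conditions
#'   that did not phase-separate (imputed at `impute`). If `NULL`, the
#'   regression stage is skipped unless `turbidity_files` is given.
#' @param turbidity_files named character vector of CSV paths (columns
#'   `concentration`, `A340`), same naming scheme; thresholds are
#'   extracted with [extract_threshold()].
#' @param tail_residues number of leading residues removed to form the
#'   open conformation of a toy variant (default 1).
#' @param energy list of [energy_params()] overrides.
#' @param sampling list with `n_orientations` (default 60), `spacing`
#'   (default 1.0), `r_cut` (optional).
#' @param regression list with `components` (default `c("PC1", "PC4")`),
#'   `impute` (default 400), `standardize` (default `FALSE`).
#' @param calibration optional list with `feature`, `condition`, `value`:
#'   calibrate that feature column to the experimental anchor.
#' @param poses optional list with `variant`, `pH`, `top_k` (default
#'   1000), `cutoff` (default 9), `min_size` (default 10): run pose
#'   mining of the variant against the partner at that pH.
#' @param output_dir optional directory for CSV/JSON artifacts.
#' @param seed master seed (default 1); all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(variants, partner = NULL, pH = c(7, 8),
                       thresholds = NULL, turbidity_files = NULL,
                       tail_residues = 1L, energy = list(),
                       sampling = list(), regression = list(),
                       calibration = NULL, poses = NULL,
                       output_dir = NULL, seed = 1L) {
  if (!length(variants) || is.null(names(variants)) ||
      any(!nzchar(names(variants))))
    stopf("variants must be a non-empty named list")
  sampling <- utils::modifyList(
    list(n_orientations = 60, spacing = 1.0, r_cut = NULL), sampling)
  regression <- utils::modifyList(
    list(components = c("PC1", "PC4"), impute = 400, standardize = FALSE),
    regression)
  cfg <- list(variants = variants, partner = partner, pH = pH,
              thresholds = thresholds, turbidity_files = turbidity_files,
              tail_residues = as.integer(tail_residues), energy = energy,
              sampling = sampling, regression = regression,
              calibration = calibration, poses = poses,
              output_dir = output_dir, seed = as.integer(seed))
  validate_config(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks structural completeness and that every referenced file exists.
#'
#' @param config a configuration list.
#' @return the config, invisibly; errors on problems.
#' @export
validate_config <- function(config) {
  for (nm in names(config$variants)) {
    v <- config$variants[[nm]]
    if (is.null(v$toy) && is.null(v$pqr))
      stopf("variant '%s' needs a 'toy' spec or a 'pqr' path", nm)
    if (!is.null(v$pqr) && !file.exists(v$pqr))
      stopf("variant '%s': PQR file not found: %s", nm, v$pqr)
  }
  if (!is.null(config$partner) && !is.null(config$partner$pqr) &&
      !file.exists(config$partner$pqr))
    stopf("partner PQR file not found: %s", config$partner$pqr)
  for (f in config$turbidity_files)
    if (!file.exists(f)) stopf("turbidity file not found: %s", f)
  invisible(config)
}

#' Write / read a configuration as YAML
#'
#' @param config a `run_config`.
#' @param path file path.
#' @return `read_config` returns the configuration (validated);
#'   `write_config` the path, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  do.call(run_config, cfg[intersect(names(cfg), names(formals(run_config)))])
}

.build_body <- function(spec, seed) {
  if (!is.null(spec$toy)) {
    args <- spec$toy
    if (is.null(args$seed)) args$seed <- seed
    do.call(make_toy_body, args)
  } else {
    read_pqr(spec$pqr)
  }
}

.condition_key <- function(variant, pH) sprintf("%s_pH%g", variant, pH)

#' Run the full analysis pipeline
#'
#' Executes the analysis graph declared in a [run_config()]: builds all
#' variant structures (closed and open conformations), computes the four
#' virial features A2_open, A2_closed, A23_open, A23_closed for every
#' variant x pH condition, optionally calibrates a feature column to an
#' experimental anchor, assembles the feature table with measured (or
#' extracted, or imputed) thresholds, fits the PCA + multilinear
#' regression, and reports per-condition predicted vs measured thresholds.
#' If requested, also mines and clusters the lowest-energy poses of one
#' condition against the partner.
#'
#' @param config a `run_config`.
#' @return list of class `pipeline_result`: `virials` (per-condition
#'   `virial_result`s), `features` (the [feature_table()]), `pca`, `mlr`,
#'   `predictions` (data frame variant/pH/measured/predicted), `poses`
#'   (if configured: `pose_table`, `decomposition`, `clusters`),
#'   `calibration` (offset applied, if any), `config_hash`, `seed`.
#'   Artifacts are also written under `output_dir` when configured.
#' @export
run_pipeline <- function(config) {
  validate_config(config)
  p <- do.call(energy_params, config$energy)
  sm <- config$sampling
  stage <- "structures"
  res <- tryCatch({
    bodies <- list()
    for (nm in names(config$variants)) {
      v <- config$variants[[nm]]
      body <- .build_body(v, config$seed)
      for (mu in v$mutations) body <- apply_mutation(body, mu)
      closed <- if (!is.null(v$range_closed)) {
        slice_conformation(body, v$range_closed[1], v$range_closed[2],
                           "closed")
      } else {
        body$conformation_tag <- "closed"; body
      }
      open <- if (!is.null(v$range_open)) {
        slice_conformation(body, v$range_open[1], v$range_open[2], "open")
      } else {
        rids <- sort(unique(body$atoms$residue_id))
        keep_from <- rids[min(config$tail_residues + 1L, length(rids))]
        slice_conformation(body, keep_from, max(rids), "open")
      }
      bodies[[nm]] <- list(closed = closed, open = open)
    }
    partner <- if (!is.null(config$partner))
      .build_body(config$partner, config$seed + 1L)

    stage <- "virials"
    virials <- list()
    rows <- list()
    for (nm in names(bodies)) for (ph in config$pH) {
      key <- .condition_key(nm, ph)
      a2c <- compute_A2(bodies[[nm]]$closed, ph, p, sm$n_orientations,
                        sm$spacing, config$seed, sm$r_cut)
      a2o <- compute_A2(bodies[[nm]]$open, ph, p, sm$n_orientations,
                        sm$spacing, config$seed, sm$r_cut)
      if (!is.null(partner)) {
        a23c <- compute_A23(bodies[[nm]]$closed, partner, ph, p,
                            sm$n_orientations, sm$spacing, config$seed,
                            sm$r_cut)
        a23o <- compute_A23(bodies[[nm]]$open, partner, ph, p,
                            sm$n_orientations, sm$spacing, config$seed,
                            sm$r_cut)
      } else {
        a23c <- a23o <- NULL
      }
      virials[[key]] <- list(A2_closed = a2c, A2_open = a2o,
                             A23_closed = a23c, A23_open = a23o)
      rows[[key]] <- data.frame(
        variant = nm, pH = ph,
        A2_open = a2o$value, A2_closed = a2c$value,
        A23_open = if (is.null(a23o)) a2o$value else a23o$value,
        A23_closed = if (is.null(a23c)) a2c$value else a23c$value)
    }
    tab <- do.call(rbind, rows)

    stage <- "calibration"
    calib <- NULL
    if (!is.null(config$calibration)) {
      cb <- config$calibration
      keys <- .condition_key(tab$variant, tab$pH)
      vals <- stats::setNames(tab[[cb$feature]], keys)
      shifted <- calibrate(vals, cb$condition, cb$value)
      tab[[cb$feature]] <- unname(shifted$values)
      calib <- list(feature = cb$feature, offset = unname(shifted$offset))
    }

    stage <- "thresholds"
    keys <- .condition_key(tab$variant, tab$pH)
    thr <- rep(NA_real_, nrow(tab))
    if (!is.null(config$thresholds)) {
      thr <- unname(config$thresholds[keys])
    } else if (!is.null(config$turbidity_files)) {
      for (i in seq_along(keys)) {
        f <- config$turbidity_files[[keys[i]]]
        if (is.null(f) || is.na(f)) next
        ts <- utils::read.csv(f)
        est <- extract_threshold(turbidity_series(ts$concentration, ts$A340))
        thr[i] <- est$threshold
      }
    }

    stage <- "regression"
    features <- feature_table(tab$variant, tab$pH, tab$A2_open,
                              tab$A2_closed, tab$A23_open, tab$A23_closed,
                              thr, impute = config$regression$impute)
    pca <- mlr <- predictions <- NULL
    have_thresholds <- !is.null(config$thresholds) ||
      !is.null(config$turbidity_files)
    if (have_thresholds && !all(is.na(thr))) {
      pca <- virial_pca(features,
                        standardize = config$regression$standardize)
      comp <- intersect(config$regression$components, colnames(pca$scores))
      mlr <- mlr_on_components(pca$scores, features$threshold, comp)
      predictions <- data.frame(
        variant = features$variant, pH = features$pH,
        measured = thr, imputed = features$imputed,
        predicted = mlr$predictions)
    }

    stage <- "poses"
    pose_out <- NULL
    if (!is.null(config$poses)) {
      ps <- utils::modifyList(list(top_k = 1000, cutoff = 9, min_size = 10),
                              config$poses)
      if (is.null(partner)) stopf("pose analysis requires a partner body")
      body <- bodies[[ps$variant]]$closed
      ms <- enumerate_protonation(body, ps$pH)
      wmax <- which.max(vapply(ms, `[[`, numeric(1), "weight"))
      rots <- sample_orientations(sm$n_orientations, config$seed)
      fields <- lapply(seq_along(rots$rotations), function(r) {
        translational_scan(body, partner, rots$rotations[[r]], p,
                           sm$spacing, charges_A = ms[[wmax]]$charges,
                           rotation_id = r)
      })
      poses <- top_k_poses(fields, ps$top_k)
      decomp <- decompose_by_residue(body, partner, poses, p)
      clus <- cluster_poses(poses, partner, ps$cutoff, ps$min_size)
      pose_out <- list(poses = poses, decomposition = decomp,
                       clusters = clus)
    }

    list(virials = virials, features = features, pca = pca, mlr = mlr,
         predictions = predictions, poses = pose_out, calibration = calib,
         config_hash = config_hash(config), seed = config$seed)
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  class(res) <- "pipeline_result"
  if (!is.null(config$output_dir)) .write_bundle(res, config)
  res
}

.write_bundle <- function(res, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  od <- config$output_dir
  stamp <- list(config_hash = res$config_hash, seed = res$seed)
  write_config(config, file.path(od, "config.yaml"))
  utils::write.csv(as.data.frame(res$features),
                   file.path(od, "feature_table.csv"), row.names = FALSE)
  if (!is.null(res$predictions))
    utils::write.csv(res$predictions, file.path(od, "predictions.csv"),
                     row.names = FALSE)
  if (!is.null(res$poses)) {
    utils::write.csv(as.data.frame(res$poses$poses),
                     file.path(od, "poses.csv"), row.names = FALSE)
    utils::write.csv(res$poses$decomposition,
                     file.path(od, "residue_decomposition.csv"),
                     row.names = FALSE)
  }
  summary <- c(stamp, list(
    mlr = if (!is.null(res$mlr)) list(
      coefficients = as.list(res$mlr$coefficients),
      intercept = res$mlr$intercept, r_squared = res$mlr$r_squared),
    calibration = res$calibration))
  jsonlite::write_json(summary, file.path(od, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(od)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d conditions; config %s, seed %d\n",
              length(x$virials), x$config_hash, x$seed))
  if (!is.null(x$mlr))
    cat(sprintf("  MLR on %s: R^2 = %.3f\n",
                paste(x$mlr$selected_components, collapse = " + "),
                x$mlr$r_squared))
  invisible(x)
}
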