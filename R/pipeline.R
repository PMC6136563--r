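#' Study configuration for the multi-period retraction simulation
#'
#' @param anatomy an [anatomy_config()].
#' @param target_edge mesh edge length near the root (mm).
#' @param order element order (1 = tet4, 2 = tet10).
#' @param force_magnitude retraction force (N).
#' @param law `"eq1"` for the calibrated law ([calibrated_movement_law()]),
#'   `"refit"` to refit on the packaged calibration table, or a
#'   `quadratic_law` object.
#' @param exclude_c1m drop the C1M series when refitting.
#' @param periods number of monthly periods to simulate.
#' @param wire_axis optional sliding-archwire axis (unit 3-vector).
#' @param stress_measure `"von_mises"` or `"max_principal"`.
#' @param out_dir optional output directory for CSV/VTK/JSON results.
#' @param write_vtk write a VTK file with displacement and von Mises
#'   fields per period (requires `out_dir`).
#' @param seed integer seed controlling all randomness.
#' @return a `study_config`.
#' @export
study_config <- function(anatomy = anatomy_config(),
                         target_edge = 0.7,
                         order = 1L,
                         force_magnitude = 1.0,
                         law = "eq1",
                         exclude_c1m = FALSE,
                         periods = 4L,
                         wire_axis = NULL,
                         stress_measure = "von_mises",
                         out_dir = NULL,
                         write_vtk = FALSE,
                         seed = 1L) {
  if (periods < 1) stop("periods must be >= 1")
  if (!(is.character(law) && law %in% c("eq1", "refit")) &&
      !inherits(law, "quadratic_law"))
    stop("law must be 'eq1', 'refit' or a quadratic_law")
  structure(list(anatomy = anatomy, target_edge = target_edge,
                 order = as.integer(order),
                 force_magnitude = force_magnitude, law = law,
                 exclude_c1m = exclude_c1m, periods = as.integer(periods),
                 wire_axis = wire_axis, stress_measure = stress_measure,
                 out_dir = out_dir, write_vtk = write_vtk,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' Top-level keys mirror the [study_config()] arguments; an `anatomy` block
#' mirrors [anatomy_config()].
#'
#' @param path YAML file path.
#' @return a `study_config`.
#' @export
study_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  an <- do.call(anatomy_config, y$anatomy %||% list())
  y$anatomy <- NULL
  if (!is.null(y$bone_block)) stop("bone_block belongs under 'anatomy'")
  do.call(study_config, c(list(anatomy = an), y))
}

resolve_law <- function(law, exclude_c1m = FALSE) {
  if (inherits(law, "quadratic_law")) return(law)
  if (identical(law, "eq1")) return(calibrated_movement_law())
  fit_movement_law(load_calibration_table(),
                   exclude = if (exclude_c1m) "C1M" else NULL)$law
}

#' Run one monthly period: solve, sample stress, predict movement
#'
#' @param mesh a `volume_mesh` of the current geometry.
#' @param spec a [load_boundary_spec()].
#' @param law a [quadratic_law()].
#' @param landmarks landmark matrix (rows C1D, C2D, C1M).
#' @param materials a [material_table()].
#' @param stress_measure invariant passed to [von_mises_at()].
#' @param period period label.
#' @return data.frame with one row per landmark: stress sample and
#'   predicted movement (mm, unrounded).
#' @export
run_period <- function(mesh, spec, law, landmarks,
                       materials = material_table(),
                       stress_measure = "von_mises",
                       period = NA_character_) {
  sys <- assemble(mesh, materials)
  res <- solve_fem(sys, spec)
  samples <- von_mises_at(res, landmarks, measure = stress_measure,
                          period = period)
  samples$predicted <- predict_movement(law, samples$stress)
  attr(samples, "result") <- res
  samples
}

#' Advance the model geometry by the predicted landmark movements
#'
#' The three scalar landmark movements are turned into displacement targets
#' along the current distal load direction (projected into the
#' mesio-distal/occlusal plane), a best-fit rigid motion of the tooth is
#' recovered from them by [rigid_superimpose()], and the tooth (with its
#' PDL and socket) is moved accordingly while the bone block stays fixed.
#' The least-squares residual of the rigid fit is attached as attribute
#' `fit_residual`.
#'
#' @param model an `anatomy_model`.
#' @param predicted named numeric vector of per-landmark movements (mm),
#'   names matching `rownames(model$landmarks)`.
#' @return the advanced `anatomy_model`.
#' @export
advance_geometry <- function(model, predicted) {
  stopifnot(all(is.finite(predicted)))
  ids <- rownames(model$landmarks)
  if (!all(ids %in% names(predicted)))
    stop("predicted must be named after the model landmarks")
  d <- predicted[ids]
  if (all(abs(d) < .Machine$double.eps)) {
    attr(model, "fit_residual") <- 0
    return(model)
  }
  dir <- unit_vector(model$tad_point - model$bracket_point)
  dir[2] <- 0                       # constrain to mesio-distal/occlusal plane
  dir <- unit_vector(dir)
  targets <- model$landmarks + outer(as.numeric(d), dir)
  tr <- rigid_superimpose(fixed = targets, moving = model$landmarks)

  model$landmarks <- transform_points(tr, model$landmarks)
  model$bracket_point <- as.numeric(transform_points(tr,
                                                     model$bracket_point))
  for (nm in c("tooth", "pdl")) {
    model$surfaces[[nm]]$vertices <-
      transform_points(tr, model$surfaces[[nm]]$vertices)
  }
  model$transform <- compose_transforms(tr, model$transform)
  attr(model, "fit_residual") <- attr(tr, "rmsd")
  attr(model, "last_transform") <- tr
  model
}

#' Run the full multi-period retraction study
#'
#' Loops mesh -> solve -> stress sampling -> movement prediction ->
#' geometry advance for `periods` monthly periods, re-tetrahedralizing the
#' advanced model each period.  The "clinical" movement of each period is
#' measured with the same machinery used on real casts: the post-period
#' model is superimposed on the pre-period model over the (bone-fixed)
#' palatal reference patch and the landmark displacement is read off.
#'
#' @param config a [study_config()].
#' @return a `study_result` with elements `samples` (per period/landmark
#'   stress + prediction), `records` (movement records), `cumulative`
#'   (per-landmark cumulative movement), `validation`
#'   (a `validation_summary`), `law` and `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  cfg_an <- config$anatomy
  cfg_an$random_seed <- config$seed
  model <- build_model(cfg_an)
  law <- resolve_law(config$law, config$exclude_c1m)
  materials <- material_table()

  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  all_samples <- list()
  records <- list()
  cumulative <- stats::setNames(numeric(nrow(model$landmarks)),
                                rownames(model$landmarks))
  cum_track <- list()
  for (p in seq_len(config$periods)) {
    label <- paste0("T", p - 1L)
    mesh <- tetrahedralize(model, target_edge = config$target_edge,
                           order = config$order)
    spec <- load_boundary_spec(
      force_magnitude = config$force_magnitude,
      bracket_nodes = mesh$node_sets$bracket_nodes,
      force_direction = unit_vector(model$tad_point - model$bracket_point),
      fixed_nodes = mesh$node_sets$fixed_base,
      wire_axis = config$wire_axis)
    samples <- run_period(mesh, spec, law, model$landmarks,
                          materials = materials,
                          stress_measure = config$stress_measure,
                          period = label)
    res <- attr(samples, "result")
    if (!is.null(out_dir) && isTRUE(config$write_vtk)) {
      write_vtk(mesh, file.path(out_dir, sprintf("period_%s.vtk", label)),
                point_data = list(displacement = res$u),
                cell_data = list(von_mises = von_mises(res$stress)))
    }
    pred <- stats::setNames(samples$predicted, samples$landmark)

    before <- model$landmarks
    patch_before <- model$palatal_patch
    model <- advance_geometry(model, pred)
    # emulate the clinical measurement: superimpose on the stable (bone)
    # reference; the palatal patch of the crown moves with the tooth, so the
    # stable reference here is the bone block which does not move -> identity
    sup <- rigid_transform(diag(3), c(0, 0, 0))
    clinical <- landmark_displacement(sup, before, model$landmarks)

    movement_label <- sprintf("T%d-%d", p - 1L, p)
    rec <- data.frame(landmark = samples$landmark,
                      period = movement_label,
                      stress = samples$stress,
                      predicted = samples$predicted,
                      clinical = as.numeric(clinical[samples$landmark]),
                      stringsAsFactors = FALSE)
    rec$diff <- abs(rec$predicted - rec$clinical)
    rec$percent <- 100 * rec$diff / rec$predicted
    records[[p]] <- rec
    all_samples[[p]] <- samples
    cumulative <- cumulative + pred[names(cumulative)]
    cum_track[[p]] <- cumulative
  }
  samples <- do.call(rbind, lapply(all_samples, function(s) {
    attr(s, "result") <- NULL; s
  }))
  records <- do.call(rbind, records)
  cumulative <- do.call(rbind, cum_track)
  rownames(cumulative) <- paste0("T", seq_len(config$periods))
  validation <- validate_records(records)

  result <- structure(list(samples = samples, records = records,
                           cumulative = cumulative,
                           validation = validation,
                           law = law, config = config),
                      class = "study_result")
  if (!is.null(out_dir)) {
    utils::write.csv(samples, file.path(out_dir, "stress_samples.csv"),
                     row.names = FALSE)
    utils::write.csv(records, file.path(out_dir, "movement_records.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(cumulative = as.data.frame(cumulative),
           law = unclass(law)[c("a", "b", "c")],
           min_diff = validation$min_diff, max_diff = validation$max_diff),
      file.path(out_dir, "study_summary.json"),
      auto_unbox = TRUE, digits = NA)
    write_run_log(config, out_dir)
  }
  result
}

write_run_log <- function(config, out_dir) {
  tmp <- tempfile()
  saveRDS(unclass(config)[setdiff(names(unclass(config)), "out_dir")], tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  lines <- c(sprintf("orthofem %s",
                     as.character(utils::packageVersion("orthofem"))),
             sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
             sprintf("seed: %d", config$seed),
             sprintf("config_md5: %s", hash))
  writeLines(lines, file.path(out_dir, "run.log"))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d periods x %d landmarks\n",
              x$config$periods, length(unique(x$records$landmark))))
  print(x$validation)
  invisible(x)
}

#' Reproduce the printed calibration/validation analysis
#'
#' From the packaged tables alone (no FE solve): (i) evaluates the
#' calibrated quadratic law on the validation-table stresses and checks
#' every printed predicted cell at 3 decimals; (ii) computes the
#' difference and percent-difference ranges; (iii) refits the quadratic on
#' the calibration table and reports the coefficients next to the
#' calibrated ones; (iv) reports the calibration stress/movement ranges.
#'
#' @param table2 path to a calibration CSV (NULL = packaged fixture).
#' @param table3 path to a validation CSV (NULL = packaged fixture).
#' @return a `reproduction_report` list.
#' @export
reproduce_paper <- function(table2 = NULL, table3 = NULL) {
  cal <- load_calibration_table(table2)
  val <- load_validation_table(table3)
  law <- calibrated_movement_law()

  recs <- movement_records(law, data.frame(landmark = val$landmark,
                                           period = val$movement_period,
                                           stress = val$stress,
                                           clinical = val$clinical))
  cell_match <- abs(recs$predicted_display - val$calculated) < 1e-9
  summary <- validate_records(recs)
  refit <- fit_movement_law(cal)

  structure(list(
    n_cells = length(cell_match),
    n_cells_matched = sum(cell_match),
    cell_match = cell_match,
    diff_range = c(summary$min_diff, summary$max_diff),
    percent_range = c(summary$min_percent, summary$max_percent),
    predicted_range = c(summary$min_predicted, summary$max_predicted),
    calibration_stress_range = range(cal$stress),
    calibration_movement_range = range(cal$movement),
    law = law,
    refit_law = refit$law,
    refit_rmse = refit$rmse,
    records = recs
  ), class = "reproduction_report")
}

#' @export
print.reproduction_report <- function(x, ...) {
  cat("reproduction_report\n")
  cat(sprintf("  predicted cells matched at 3 dp: %d / %d\n",
              x$n_cells_matched, x$n_cells))
  cat(sprintf("  |F - C| range: %.3f to %.3f mm\n",
              x$diff_range[1], x$diff_range[2]))
  cat(sprintf("  percent range: %.2f to %.2f %%\n",
              x$percent_range[1], x$percent_range[2]))
  cat(sprintf("  predicted range: %.3f to %.3f mm\n",
              x$predicted_range[1], x$predicted_range[2]))
  cat(sprintf("  calibration stress range: %.3f to %.3f N/mm^2\n",
              x$calibration_stress_range[1], x$calibration_stress_range[2]))
  cat(sprintf("  calibration movement range: %.3f to %.3f mm\n",
              x$calibration_movement_range[1],
              x$calibration_movement_range[2]))
  cat(sprintf("  calibrated law:  a=%g b=%g c=%g\n",
              x$law$a, x$law$b, x$law$c))
  cat(sprintf("  refit on calibration table: a=%.4g b=%.4g c=%.4g (rmse %.3f)\n",
              x$refit_law$a, x$refit_law$b, x$refit_law$c, x$refit_rmse))
  invisible(x)
}
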