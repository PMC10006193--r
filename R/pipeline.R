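#' Write a tensile curve as delimited text
#'
#' Two-column (stretch, force in N) whitespace-delimited text with a
#' comment-line header carrying the orientation, gauge length, area and seed.
#'
#' @param curve a [tensile_curve()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_tensile_curve <- function(curve, path) {
  stopifnot(inherits(curve, "tensile_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# meniscusCDM tensile curve",
               sprintf("# orientation: %s", attr(curve, "orientation")),
               sprintf("# gauge_length_mm: %.10g", attr(curve, "gauge_length")),
               sprintf("# area_mm2: %.10g", attr(curve, "area")),
               if (!is.null(attr(curve, "seed")))
                 sprintf("# seed: %d", attr(curve, "seed")),
               "stretch force_N"), con)
  write.table(data.frame(format(curve$stretch, digits = 15),
                         format(curve$force, digits = 15)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a tensile curve file
#'
#' Parses the two-column delimited format written by
#' [write_tensile_curve()], enforcing units and monotone stretch (a
#' non-monotone stretch column raises an error naming the offending row).
#'
#' @param path file path.
#' @return A [tensile_curve()].
#' @export
read_tensile_curve <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (grepl("^[A-Za-z]", body[1])) body <- body[-1]  # column-name line
  tab <- read.table(text = body, col.names = c("stretch", "force"))
  cv <- tensile_curve(tab$stretch, tab$force,
                      orientation = meta$orientation %||% "longitudinal",
                      gauge_length = as.numeric(meta$gauge_length_mm %||% NA),
                      area = as.numeric(meta$area_mm2 %||% NA))
  if (!is.null(meta$seed)) attr(cv, "seed") <- as.integer(meta$seed)
  cv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a mesh and fields as a legacy VTK unstructured grid
#'
#' ASCII legacy-format VTK file with linear tetrahedra. Point data matrices
#' with 3 columns become VECTORS; cell data vectors become SCALARS; cell data
#' matrices with 6 columns become FIELD arrays in Voigt order
#' (xx, yy, zz, xy, yz, xz).
#'
#' @param mesh an `fe_mesh`.
#' @param file output path (conventionally `.vtk`).
#' @param point_data named list of per-node data (length-n vectors or n x 3
#'   matrices).
#' @param cell_data named list of per-element data (length-m vectors or
#'   m x 6 matrices).
#' @return The path, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  stopifnot(inherits(mesh, "fe_mesh"))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$tets)
  con <- file(file, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  num <- function(m) apply(m, 1, function(r) paste(format(r, digits = 9), collapse = " "))
  w("# vtk DataFile Version 3.0")
  w("meniscusCDM unstructured grid")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d float", nn)
  writeLines(num(mesh$nodes), con)
  w("CELLS %d %d", ne, 5 * ne)
  writeLines(num(cbind(4L, mesh$tets)), con)
  w("CELL_TYPES %d", ne)
  writeLines(rep("10", ne), con)
  if (length(point_data)) {
    w("POINT_DATA %d", nn)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        w("VECTORS %s float", nm)
        writeLines(num(v), con)
      } else {
        w("SCALARS %s float 1", nm)
        w("LOOKUP_TABLE default")
        writeLines(format(as.numeric(v), digits = 9), con)
      }
    }
  }
  if (length(cell_data)) {
    w("CELL_DATA %d", ne)
    fields <- Filter(function(nm) is.matrix(cell_data[[nm]]), names(cell_data))
    scalars <- setdiff(names(cell_data), fields)
    for (nm in scalars) {
      w("SCALARS %s float 1", nm)
      w("LOOKUP_TABLE default")
      writeLines(format(as.numeric(cell_data[[nm]]), digits = 9), con)
    }
    if (length(fields)) {
      w("FIELD elemfields %d", length(fields))
      for (nm in fields) {
        v <- cell_data[[nm]]
        w("%s %d %d float", nm, ncol(v), ne)
        writeLines(num(v), con)
      }
    }
  }
  invisible(file)
}

# default pipeline configuration (see read_run_config for the schema)
default_run_config <- function() {
  list(
    seed = 1,
    criteria = c("von_mises", "max_normal_strain"),
    out_dir = "meniscusCDM-run",
    synth = list(n_per_orientation = 2, noise_frac = 0.01),
    fit = list(damage_budget = 150),
    fe = list(enabled = FALSE, refine_factor = 1, n_steps = 12,
              target_stretch_longitudinal = 1.18,
              target_stretch_transverse = 1.45,
              export_vtk = TRUE)
  )
}

#' Read and validate a pipeline configuration
#'
#' YAML configuration with blocks `seed`, `criteria`, `out_dir`, `synth`
#' (`n_per_orientation`, `noise_frac`), `fit` (`damage_budget`), `fe`
#' (`enabled`, `refine_factor`, `n_steps`, per-orientation target stretches,
#' `export_vtk`). Unknown keys are rejected; omitted keys take the defaults.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (blk in intersect(names(user), c("synth", "fit", "fe"))) {
      badk <- setdiff(names(user[[blk]]), names(cfg[[blk]]))
      if (length(badk))
        stop(sprintf("unknown keys in '%s': %s", blk,
                     paste(badk, collapse = ", ")))
    }
    cfg <- modifyList(cfg, user)
  }
  stopifnot(is.numeric(cfg$seed),
            all(cfg$criteria %in% c("von_mises", "max_normal_strain")))
  class(cfg) <- "run_config"
  cfg
}

#' Run the end-to-end pipeline
#'
#' Generates synthetic tensile curves for both orientations, runs the
#' sequential calibration for each requested damage criterion, optionally
#' solves the finite element dogbone models with the fitted parameters and
#' extracts tear-region metrics, and writes the report bundle: a
#' damage-parameter table, a fit-quality table, a model-versus-target
#' comparison table, curve files, optional VTK fields, and a log of seeds
#' and settings with a JSON metadata sidecar. Stage failures are recorded in
#' a machine-readable error manifest (`errors.json`) and leave a partial
#' bundle.
#'
#' @param config a [read_run_config()] list (or `NULL` for defaults).
#' @return The report bundle, invisibly: a list with `fits`, `tables`,
#'   `tear`, `files`, `errors`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- list()
  files <- character()
  log <- c(sprintf("meniscusCDM pipeline, seed %d", cfg$seed),
           sprintf("R %s, meniscusCDM %s", getRversion(),
                   as.character(utils::packageVersion("meniscusCDM"))))
  logf <- function(...) log <<- c(log, sprintf(...))

  # --- synth -----------------------------------------------------------
  n <- cfg$synth$n_per_orientation
  curves <- list(longitudinal = list(), transverse = list())
  truths <- list(longitudinal = list(), transverse = list())
  for (o in names(curves)) {
    tr <- synthetic_truth(o)
    for (i in seq_len(n)) {
      sp <- generator_spec(o, seed = cfg$seed * 1000 + i,
                           noise_sd = cfg$synth$noise_frac *
                             generator_spec(o)$uts_force)
      gen <- generate_curve_model_based(tr$params, tr$dp, sp)
      curves[[o]][[i]] <- gen$curve
      truths[[o]][[i]] <- gen$truth
      fp <- file.path(cfg$out_dir, sprintf("curve_%s_%02d.txt", o, i))
      write_tensile_curve(gen$curve, fp)
      files <- c(files, fp)
    }
    logf("generated %d %s curves (noise %.3g N)", n, o,
         cfg$synth$noise_frac * generator_spec(o)$uts_force)
  }

  # --- fit -------------------------------------------------------------
  fits <- list()
  for (cr in cfg$criteria) {
    fits[[cr]] <- tryCatch(
      lapply(seq_len(n), function(i)
        cdm_fit(curves$transverse[[i]], curves$longitudinal[[i]],
                criterion = cr, damage_budget = cfg$fit$damage_budget)),
      error = function(e) { errors[[paste0("fit_", cr)]] <<- conditionMessage(e); NULL })
  }

  damage_tab <- do.call(rbind, lapply(names(Filter(Negate(is.null), fits)),
                                      function(cr) {
    do.call(rbind, lapply(fits[[cr]], function(ft)
      do.call(rbind, lapply(c("longitudinal", "transverse"), function(o)
        data.frame(orientation = o, criterion = cr,
                   mu_min = ft$damage[[o]]$dp$mu_min,
                   mu_max = ft$damage[[o]]$dp$mu_max,
                   D_max = ft$damage[[o]]$dp$D_max,
                   success = ft$damage[[o]]$success)))))
  }))
  quality_tab <- do.call(rbind, lapply(names(Filter(Negate(is.null), fits)),
                                       function(cr) {
    do.call(rbind, lapply(fits[[cr]], function(ft)
      do.call(rbind, lapply(c("longitudinal", "transverse"), function(o)
        data.frame(orientation = o, criterion = cr,
                   nrmse_pct = ft$quality[[o]]$nrmse,
                   r2 = ft$quality[[o]]$r2)))))
  }))

  # model-vs-target ultimate point comparison
  comparison_tab <- do.call(rbind, lapply(names(Filter(Negate(is.null), fits)),
                                          function(cr) {
    do.call(rbind, lapply(seq_along(fits[[cr]]), function(i) {
      ft <- fits[[cr]][[i]]
      do.call(rbind, lapply(c("longitudinal", "transverse"), function(o) {
        tgt <- locate_uts(curves[[o]][[i]])
        mod <- locate_uts(predict(ft, o))
        data.frame(orientation = o, criterion = cr, specimen = i,
                   uts_force_target = tgt$force, uts_force_model = mod$force,
                   uts_stretch_target = tgt$stretch,
                   uts_stretch_model = mod$stretch)
      }))
    }))
  }))

  tables <- list(damage_parameters = damage_tab, fit_quality = quality_tab,
                 comparison = comparison_tab)
  for (nm in names(tables)) {
    fp <- file.path(cfg$out_dir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], fp, sep = "\t", row.names = FALSE, quote = FALSE)
    files <- c(files, fp)
  }

  # --- FE + tear metrics ----------------------------------------------
  tear <- list()
  if (isTRUE(cfg$fe$enabled) && length(Filter(Negate(is.null), fits))) {
    for (cr in names(Filter(Negate(is.null), fits))) {
      ft <- fits[[cr]][[1]]
      for (o in c("longitudinal", "transverse")) {
        key <- paste(o, cr, sep = ".")
        res <- tryCatch({
          msh <- build_dogbone_mesh(dogbone_geometry(o),
                                    refine_factor = cfg$fe$refine_factor)
          tgt <- if (o == "longitudinal") cfg$fe$target_stretch_longitudinal
                 else cfg$fe$target_stretch_transverse
          sol <- solve_quasistatic(msh, ft$params, ft$damage[[o]]$dp, tgt,
                                   n_steps = cfg$fe$n_steps)
          us <- uts_step(sol)
          roi <- locate_roi(sol, us)
          rs <- roi_strains(sol, roi, us)
          ta <- tear_angle(sol, length(sol$steps))
          if (isTRUE(cfg$fe$export_vtk)) {
            st <- sol$steps[[length(sol$steps)]]
            fl <- element_fields(sol, length(sol$steps))
            fp <- file.path(cfg$out_dir, sprintf("fields_%s_%s.vtk", o, cr))
            write_vtk(msh, fp,
                      point_data = list(displacement = matrix(st$u, ncol = 3,
                                                              byrow = TRUE)),
                      cell_data = list(
                        D = st$D, Xi = fl$xi,
                        E = as.matrix(fl[, c("Exx", "Eyy", "Ezz", "Exy",
                                             "Eyz", "Exz")]),
                        S0 = as.matrix(fl[, c("S0xx", "S0yy", "S0zz", "S0xy",
                                              "S0yz", "S0xz")])))
            files <- c(files, fp)
          }
          list(solution_status = sol$status, roi = rs, angle = ta)
        }, error = function(e) {
          errors[[paste0("fe_", key)]] <<- conditionMessage(e); NULL })
        tear[[key]] <- res
      }
    }
    roi_tab <- do.call(rbind, lapply(names(Filter(Negate(is.null), tear)),
                                     function(k) {
      r <- tear[[k]]
      data.frame(model = k, E_yy = r$roi$E_yy, E_xx = r$roi$E_xx,
                 E_xy = r$roi$E_xy, E1 = r$roi$E1, E2 = r$roi$E2,
                 gamma_max = r$roi$gamma_max, mean_D = r$roi$mean_D,
                 tear_angle_deg = r$angle$angle,
                 tear_angle_outer = r$angle$outer,
                 tear_angle_inner = r$angle$inner)
    }))
    if (!is.null(roi_tab)) {
      fp <- file.path(cfg$out_dir, "roi_strains.tsv")
      write.table(roi_tab, fp, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, fp)
      tables$roi_strains <- roi_tab
    }
  }

  # --- bundle ----------------------------------------------------------
  meta <- list(seed = cfg$seed, criteria = cfg$criteria,
               n_per_orientation = n,
               damage_budget = cfg$fit$damage_budget,
               fe = cfg$fe,
               generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(meta, file.path(cfg$out_dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(errors))
    jsonlite::write_json(errors, file.path(cfg$out_dir, "errors.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  logf("tables: %s", paste(names(tables), collapse = ", "))
  writeLines(log, file.path(cfg$out_dir, "run.log"))
  files <- c(files, file.path(cfg$out_dir, c("metadata.json", "run.log")))

  invisible(list(fits = fits, tables = tables, tear = tear,
                 curves = curves, files = files, errors = errors,
                 config = cfg))
}
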