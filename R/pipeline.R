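#' Run configuration
#'
#' Reads and validates the single human-editable YAML configuration driving
#' [run_pipeline()]. Unknown keys are rejected; every run writes the resolved
#' configuration next to its outputs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param ... named overrides applied on top of the file/defaults.
#' @return a named list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  defaults <- list(
    stages = c("generate", "laminate", "fit", "indent", "swap", "stats"),
    seed = 1L,
    outdir = "daphniarmor-run",
    replicates = 8L,
    n_curves = 25L,
    strip_count = 8L,
    n_across = 12L,
    n_z_per_cylinder = 2L,
    drop_threshold = 0.15,
    afm_poisson = 0.5,
    micro_poisson = 0.15,
    afm_face_angle_deg = 35,
    micro_tip_radius_um = 12.37,
    max_cylinders = 6L)
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  if (length(cfg$stages) == 0L) stop("configuration selects no stages")
  bad <- setdiff(cfg$stages, defaults$stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = c("run_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages against synthetic study data and writes all
#' tabular results as CSV into `outdir`: `generate` (synthetic procuticle
#' populations and force curves), `laminate` (cylinder-stack simulation
#' series per laminate model), `fit` (power-law fits and extrapolations,
#' including the reference-table extrapolations), `indent` (Hertz fits and
#' critical forces on the generated curves), `swap` (the 2x2
#' shape-versus-structure shell simulations), `stats` (group comparisons).
#' Deterministic for a fixed seed; a `MANIFEST.csv` records per-stage
#' completion and timing, and the resolved configuration is written alongside
#' the outputs.
#'
#' @param config a [run_config()].
#' @return the output directory path, invisibly; stage failure raises an
#'   error after writing the partial `MANIFEST.csv`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config), file.path(config$outdir, "config.yaml"))
  set.seed(config$seed)
  manifest <- data.frame(stage = character(0), status = character(0),
                         seconds = numeric(0))
  flush_manifest <- function() {
    utils::write.csv(manifest, file.path(config$outdir, "MANIFEST.csv"),
                     row.names = FALSE)
  }
  gc_cfg <- generator_config(seed = config$seed,
                             replicates = config$replicates)
  ref <- morphotype_reference()
  state <- new.env()

  run_stage <- function(name, fun) {
    if (!(name %in% config$stages)) return(invisible(NULL))
    t0 <- Sys.time()
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     manifest <<- rbind(manifest, data.frame(
                       stage = name, status = paste("failed:",
                                                    conditionMessage(e)),
                       seconds = as.numeric(Sys.time() - t0, "secs")))
                     flush_manifest()
                     stop(sprintf("stage '%s' failed: %s", name,
                                  conditionMessage(e)), call. = FALSE)
                   })
    manifest <<- rbind(manifest, data.frame(
      stage = name, status = "ok",
      seconds = round(as.numeric(Sys.time() - t0, "secs"), 2)))
    flush_manifest()
    invisible(ok)
  }

  run_stage("generate", function() {
    obs <- do.call(rbind, lapply(ref$morphotype, function(m) {
      pop <- gen_procuticle_population(gc_cfg, m)
      data.frame(morphotype = m,
                 thickness_um = vapply(pop, `[[`, 0, "thickness_um"),
                 layers = vapply(pop, `[[`, 0L, "layer_count"))
    }))
    utils::write.csv(obs, file.path(config$outdir, "procuticle_observations.csv"),
                     row.names = FALSE)
    state$observations <- obs
  })

  run_stage("laminate", function() {
    models <- ref[!duplicated(ref$laminate_model), ]
    series <- do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
      obs <- procuticle_observation(models$thickness_median_um[i],
                                    models$layers_median[i],
                                    models$morphotype[i])
      s <- run_lamination_series(obs, max_cylinders = config$max_cylinders,
                                 strip_count = config$strip_count,
                                 n_across = config$n_across,
                                 n_z_per_cylinder = config$n_z_per_cylinder)
      data.frame(laminate_model = models$laminate_model[i],
                 n_cylinders = s$n_cylinders,
                 deformation_nm = s$bottom_max_deformation_nm)
    }))
    utils::write.csv(series, file.path(config$outdir, "lamination_series.csv"),
                     row.names = FALSE)
    state$series <- series
  })

  run_stage("fit", function() {
    # fits of this run's own simulation series (when available) ...
    if (!is.null(state$series)) {
      own <- do.call(rbind, lapply(split(state$series,
                                         state$series$laminate_model),
                                   function(s) {
        f <- fit_power_law(s[, c("n_cylinders", "deformation_nm")])
        nc <- ref$cylinders[match(s$laminate_model[1], ref$laminate_model)]
        data.frame(laminate_model = s$laminate_model[1], a = f$a, b = f$b,
                   r_squared = f$r_squared, n_extrapolation = nc,
                   deformation_nm = extrapolate_deformation(f, nc))
      }))
      utils::write.csv(own, file.path(config$outdir, "power_law_fits_simulated.csv"),
                       row.names = FALSE)
    }
    # ... and of the reference deformation table (the published series)
    utils::write.csv(extrapolation_table(),
                     file.path(config$outdir, "power_law_fits_reference.csv"),
                     row.names = FALSE)
  })

  run_stage("indent", function() {
    afm <- indenter_spec("pyramidal", face_angle_deg = config$afm_face_angle_deg,
                         poisson_ratio = config$afm_poisson)
    micro <- indenter_spec("parabolic",
                           tip_radius_m = config$micro_tip_radius_um * 1e-6,
                           poisson_ratio = config$micro_poisson)
    rows <- list()
    for (i in seq_len(nrow(ref))) {
      for (k in seq_len(config$n_curves)) {
        cv <- gen_force_curve(ref$afm_modulus_mean_mpa[i] * 1e6, afm,
                              instrument = "afm",
                              baseline_sd_frac = gc_cfg$baseline_sd_frac,
                              multiplicative_sd = gc_cfg$multiplicative_sd)
        fit <- fit_young_modulus(cv, afm)
        mc <- gen_force_curve(ref$structural_modulus_mean_kpa[i] * 1e3, micro,
                              instrument = "microindenter",
                              baseline_sd_frac = gc_cfg$baseline_sd_frac,
                              multiplicative_sd = gc_cfg$multiplicative_sd,
                              collapse = list(at_fraction = 0.6,
                                              drop_fraction = 0.4))
        cf <- tryCatch(detect_critical_force(mc, config$drop_threshold),
                       error = function(e) NULL)
        sfit <- fit_young_modulus(mc, micro,
                                  contact_index = detect_contact_point(mc))
        rows[[length(rows) + 1L]] <- data.frame(
          morphotype = ref$morphotype[i], replicate = k,
          afm_modulus_mpa = fit$young_modulus_pa / 1e6,
          structural_modulus_kpa = sfit$young_modulus_pa / 1e3,
          critical_force_mn = if (is.null(cf)) NA_real_ else
            cf$critical_force_n * 1e3)
      }
    }
    d <- do.call(rbind, rows)
    utils::write.csv(d, file.path(config$outdir, "indentation_fits.csv"),
                     row.names = FALSE)
    state$indent <- d
  })

  run_stage("swap", function() {
    swaps <- do.call(rbind, lapply(c("pulex", "longicephala"), function(sp) {
      r_u <- ref[ref$species == sp & ref$induction == "uninduced", ]
      r_i <- ref[ref$species == sp & ref$induction == "induced", ]
      sw <- run_swap_matrix(
        carapace_template(sp, induced = FALSE),
        carapace_template(sp, induced = TRUE),
        procuticle_structure(r_u$thickness_median_um,
                             r_u$afm_modulus_mean_mpa * 1e6),
        procuticle_structure(r_i$thickness_median_um,
                             r_i$afm_modulus_mean_mpa * 1e6))
      cbind(species = sp, sw)
    }))
    utils::write.csv(swaps, file.path(config$outdir, "shape_swap_results.csv"),
                     row.names = FALSE)
  })

  run_stage("stats", function() {
    if (is.null(state$indent)) {
      state$indent <- utils::read.csv(file.path(config$outdir,
                                                "indentation_fits.csv"))
    }
    d <- state$indent
    out <- do.call(rbind, lapply(c("pulex", "longicephala"), function(sp) {
      morphs <- ref$morphotype[ref$species == sp]
      u <- d[d$morphotype == morphs[1], ]
      i <- d[d$morphotype == morphs[2], ]
      tt <- students_t(u$structural_modulus_kpa, i$structural_modulus_kpa)
      mw <- mann_whitney_u(u$afm_modulus_mpa, i$afm_modulus_mpa)
      data.frame(species = sp,
                 test = c("t (structural modulus)", "MWU (AFM modulus)"),
                 statistic = c(tt$t, mw$U),
                 p_value = c(tt$p_value, mw$p_value),
                 stars = significance_stars(c(tt$p_value, mw$p_value)))
    }))
    utils::write.csv(out, file.path(config$outdir, "group_comparisons.csv"),
                     row.names = FALSE)
  })

  invisible(config$outdir)
}
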