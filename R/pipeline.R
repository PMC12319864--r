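#' Pipeline configuration
#'
#' A single validated list of every stage parameter, serializable to YAML
#' (see [read_config()] / [write_config()]). Defaults reproduce the
#' standard synthetic-cohort workflow: a 2.5 mm seed grid in a thalamus-
#' sized ellipsoid, a level-3 icosphere cortex, 50 subjects with 3 planted
#' components, 3 mm FWHM smoothing with 0.01 truncation, 5 mm endpoint
#' radius, the <100-connected-vertex seed filter, scaled-sigmoid
#' normalization, a 20-subject term template with 5-component Procrustes
#' alignment, and permutation inference with TFCE.
#'
#' @param out_dir output directory for all stage products.
#' @param rng_seed integer seed driving every stochastic stage.
#' @param n_subjects,k,age_range,preterm_fraction cohort parameters
#'   ([simulate_cohort()]).
#' @param noise_sd_at_min_age,noise_sd_at_max_age subject noise profile
#'   ([plant_structure()]).
#' @param spacing,semi_axes seed grid ([make_seed_grid()]).
#' @param mesh_level,medial_angle surface ([make_sphere_mesh()]).
#' @param radius endpoint assignment radius, mm.
#' @param fwhm,epsilon smoothing kernel parameters.
#' @param min_connected_vertices seed filter threshold.
#' @param normalize apply [normalize_sigmoid()] before decomposition.
#' @param n_template,k_align template and alignment sizes.
#' @param n_perm,use_tfce group-inference parameters.
#' @param leave_one_out use per-subject leave-one-out templates instead of
#'   the single term template.
#' @param preterm_effect optional per-vertex offsets for preterm subjects.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, rng_seed = 1, n_subjects = 50, k = 3,
                            age_range = c(29, 45), preterm_fraction = 0,
                            noise_sd_at_min_age = 0.5,
                            noise_sd_at_max_age = 0.1,
                            spacing = 2.5, semi_axes = c(13, 10, 7.5),
                            mesh_level = 3, medial_angle = 35, radius = 5,
                            fwhm = 3, epsilon = 0.01,
                            min_connected_vertices = 100, normalize = TRUE,
                            n_template = 20, k_align = 5, n_perm = 1000,
                            use_tfce = TRUE, leave_one_out = FALSE,
                            preterm_effect = NULL) {
  cfg <- as.list(environment())
  if (spacing <= 0 || any(semi_axes <= 0))
    stop("seed grid geometry must be positive")
  if (fwhm <= 0 || epsilon < 0 || epsilon >= 1 || radius <= 0)
    stop("invalid smoothing/assignment parameters")
  if (k < 1 || k > 5) stop("k must be in 1..5")
  if (k_align < 1) stop("k_align must be >= 1")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (preterm_fraction < 0 || preterm_fraction > 1)
    stop("preterm_fraction must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the end-to-end synthetic workflow
#'
#' Executes, in order: simulate (seed grid, surface, planted structure,
#' cohort) -> seed filter on the across-subject mean -> optional sigmoid
#' normalization -> term template -> per-subject decomposition and
#' Procrustes alignment -> similarity-vs-age summaries and FDR age maps ->
#' (if the cohort has a preterm group) vertexwise permutation GLM with
#' TFCE. Every stage's outputs are written under `config$out_dir` and
#' checksummed into a run manifest; any stage failure aborts with the stage
#' name.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `run_manifest`: configuration snapshot,
#'   package version, per-file MD5 checksums, timestamps, and a structured
#'   log of stage counts.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list()
  outputs <- character(0)
  started <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(path) outputs[[length(outputs) + 1]] <<- path

  # -- simulate ------------------------------------------------------------
  sim <- stage("simulate", {
    grid <- make_seed_grid(config$spacing, config$semi_axes)
    mesh <- make_sphere_mesh(config$mesh_level, medial_angle = config$medial_angle)
    planted <- plant_structure(grid, mesh, k = config$k,
                               rng_seed = config$rng_seed,
                               noise_sd_at_min_age = config$noise_sd_at_min_age,
                               noise_sd_at_max_age = config$noise_sd_at_max_age)
    cohort <- simulate_cohort(planted, n_subjects = config$n_subjects,
                              age_range = config$age_range,
                              preterm_fraction = config$preterm_fraction,
                              preterm_effect = config$preterm_effect,
                              rng_seed = config$rng_seed,
                              n_template = config$n_template)
    ph_path <- file.path(config$out_dir, "phenotypes.tsv")
    write_phenotypes(cohort$phenotypes, ph_path)
    emit(ph_path)
    mesh_paths <- file.path(config$out_dir,
                            c("white.surf.gii", "sphere.surf.gii",
                              "medialwall.label.gii"))
    write_mesh(mesh, mesh_paths[1], mesh_paths[2], mesh_paths[3])
    for (p in mesh_paths) emit(p)
    list(grid = grid, mesh = mesh, planted = planted, cohort = cohort)
  })
  log$n_subjects <- nrow(sim$cohort$phenotypes)
  log$n_seeds <- nrow(sim$grid$coordinates)
  log$n_vertices <- length(cortex_indices(sim$mesh))

  # -- filter --------------------------------------------------------------
  filtered <- stage("filter", {
    avg <- mean_matrix(sim$cohort$matrices)
    retained <- filter_seeds(avg, config$min_connected_vertices)
    mats <- lapply(sim$cohort$matrices, subset_seeds, seed_index = retained)
    avg_path <- file.path(config$out_dir, "group_mean.mtx")
    write_matrix(subset_seeds(avg, retained), avg_path)
    emit(avg_path)
    emit(paste0(avg_path, ".json"))
    list(matrices = mats, retained = retained)
  })
  log$n_seeds_retained <- length(filtered$retained)

  # -- normalize -----------------------------------------------------------
  analysed <- stage("normalize", {
    if (isTRUE(config$normalize))
      lapply(filtered$matrices, function(mm) normalize_sigmoid(mm)$matrix)
    else filtered$matrices
  })

  # -- template + align ----------------------------------------------------
  ph <- sim$cohort$phenotypes
  template <- stage("template", {
    build_template(analysed, ph, n_template = config$n_template,
                   k = max(config$k_align, config$k))
  })
  stage("template", {
    write_decomposition(template$decomposition, config$out_dir, "template")
    for (suffix in c("_scores.tsv", "_loadings.tsv", "_meta.json"))
      emit(file.path(config$out_dir, paste0("template", suffix)))
  })
  template_ids <- if (config$leave_one_out) vector("list", nrow(ph))
                  else template$subject_ids

  aligned <- stage("align", {
    lapply(seq_len(nrow(ph)), function(i) {
      ref <- if (config$leave_one_out) {
        loo <- build_template(analysed, ph, n_template = config$n_template,
                              k = max(config$k_align, config$k),
                              exclude = ph$subject_id[i])
        template_ids[[i]] <<- loo$subject_ids
        loo$decomposition
      } else template$decomposition
      dec <- decompose_matrix(analysed[[i]], max(config$k_align, config$k))
      procrustes_align(dec, ref, k_align = config$k_align)
    })
  })
  log$n_subjects_aligned <- length(aligned)

  # -- similarity and age maps ---------------------------------------------
  stats_out <- stage("age_maps", {
    sims <- data.frame(
      subject_id = ph$subject_id,
      scan_age_weeks = ph$scan_age_weeks,
      similarity_scores_pc1 = vapply(aligned, similarity_to_template,
                                     numeric(1), template$decomposition,
                                     component = 1, domain = "scores"),
      similarity_loadings_pc1 = vapply(aligned, similarity_to_template,
                                       numeric(1), template$decomposition,
                                       component = 1, domain = "loadings"))
    sims_path <- file.path(config$out_dir, "similarity.tsv")
    utils::write.table(sims, sims_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    emit(sims_path)
    seed_map <- age_correlation_map(aligned, ph$scan_age_weeks, 1, "scores")
    vert_map <- age_correlation_map(aligned, ph$scan_age_weeks, 1, "loadings")
    for (nm in c("age_map_seeds", "age_map_vertices")) {
      p <- file.path(config$out_dir, paste0(nm, ".tsv"))
      write_stat_map(if (nm == "age_map_seeds") seed_map else vert_map, p)
      emit(p)
    }
    list(similarity = sims, seed_map = seed_map, vertex_map = vert_map)
  })
  log$similarity_age_r <- stats::cor(stats_out$similarity$similarity_scores_pc1,
                                     ph$scan_age_weeks)

  # -- group inference -----------------------------------------------------
  if (any(ph$group == "preterm")) {
    group_map <- stage("group_glm", {
      y <- t(vapply(filtered$matrices, vertex_totals,
                    numeric(ncol(filtered$matrices[[1]]$values))))
      design <- glm_design(ph)
      permutation_fwer(y, design, n_perm = config$n_perm,
                       rng_seed = config$rng_seed,
                       use_tfce = config$use_tfce, mesh = sim$mesh)
    })
    gp <- file.path(config$out_dir, "group_glm.tsv")
    write_stat_map(group_map, gp)
    emit(gp)
    log$n_permutations <- group_map$n_perm
    log$n_fwer_significant <- sum(group_map$mask)
  }

  manifest <- structure(
    list(config = unclass(config),
         version = as.character(utils::packageVersion("thalagrad")),
         started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
         finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         template_subjects = template_ids,
         checksums = as.list(tools::md5sum(unlist(outputs))),
         log = log),
    class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> thalagrad %s, %d output files\n", x$version,
              length(x$checksums)))
  for (nm in names(x$log)) cat(sprintf("  %s: %s\n", nm,
                                       format(x$log[[nm]])))
  invisible(x)
}
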