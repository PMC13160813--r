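#' Configuration of the split-half reproducibility experiment
#'
#' The defaults are the package's standard desk-scale study conditions: an
#' s = 3 icosphere (642 vertices), 12 planted networks, 40 subjects per
#' cohort with 600 frames at TR 0.8 s, within-network correlation 0.35
#' versus 0.05 between, unit observation noise, 40 contiguous parcels, the
#' default density grid, Jaccard > 0.15 template matching, and 1,000 spin
#' rotations. `min_retained` (the per-subject inclusion floor) is 240
#' frames, i.e. 40% of the run, the same retention fraction the real
#' acquisitions required (600 of ~1,500 frames).
#'
#' @param n_subjects Subjects per cohort.
#' @param subdivisions Icosphere subdivisions.
#' @param n_networks Planted networks K.
#' @param n_parcels Parcels for parcel-level connectivity.
#' @param within_network_corr,between_network_corr,noise_sd,n_frames,tr,
#'   motion_burst_rate,n_subcortical Generator settings, see
#'   [cohort_spec()].
#' @param densities Edge-density grid.
#' @param jaccard_threshold,min_community_size Template matching, see
#'   [match_config()].
#' @param n_restarts Community-detection restarts per density.
#' @param n_rotations Spin rotations for the NMI null.
#' @param min_retained Per-subject retained-frame inclusion floor.
#' @param seed Master seed; cohort A uses `seed`, cohort B `seed + 1`.
#' @return A `splithalf_config` list.
#' @export
splithalf_config <- function(n_subjects = 40L, subdivisions = 3L,
                             n_networks = 12L, n_parcels = 40L,
                             within_network_corr = 0.35,
                             between_network_corr = 0.05,
                             noise_sd = 1.0, n_frames = 600L, tr = 0.8,
                             motion_burst_rate = 2, n_subcortical = 300L,
                             densities = default_density_grid(),
                             jaccard_threshold = 0.15,
                             min_community_size = 5L,
                             n_restarts = 10L, n_rotations = 1000L,
                             min_retained = 240L, seed = 1L) {
  structure(as.list(environment()), class = "splithalf_config")
}

# simulate + preprocess one cohort and accumulate its group matrices;
# returns group vertex FC, group parcel FC, and cached per-subject data
# needed later for winner-take-all assignment
process_cohort <- function(template, parcellation, config, cohort_seed) {
  spec <- cohort_spec(
    n_subjects = config$n_subjects, n_frames = config$n_frames,
    repetition_time = config$tr,
    within_network_corr = config$within_network_corr,
    between_network_corr = config$between_network_corr,
    noise_sd = config$noise_sd,
    motion_burst_rate = config$motion_burst_rate,
    n_subcortical = config$n_subcortical, seed = cohort_seed)
  dcfg <- denoise_config(min_retained = config$min_retained)
  cohort <- simulate_cohort(template, spec)
  n_v <- length(template$labels)
  acc_v <- matrix(0, n_v, n_v)
  acc_p <- NULL
  kept <- list()
  n_inc <- 0L
  for (s in cohort$subjects) {
    pre <- preprocess_subject(s$timeseries, s$fd_trace, dcfg, config$tr)
    if (!pre$included) next
    n_inc <- n_inc + 1L
    acc_v <- acc_v + unclass(subject_fc(pre$timeseries, pre$retain))
    pfc <- parcel_fc(pre$timeseries, parcellation, pre$retain)
    acc_p <- if (is.null(acc_p)) unclass(pfc) else acc_p + unclass(pfc)
    sc <- preprocess_subject(s$subcortical_timeseries, s$fd_trace, dcfg,
                             config$tr)
    kept[[n_inc]] <- list(timeseries = pre$timeseries,
                          voxel_series = sc$timeseries,
                          retain = pre$retain,
                          subcortical_truth = s$subcortical_truth)
  }
  if (n_inc == 0) stop("no subject met the retained-frame criterion")
  list(
    fc_vertex = fc_matrix(acc_v / n_inc, level = "vertex"),
    fc_parcel = fc_matrix(acc_p / n_inc,
                          node_ids = parcellation$parcel_names,
                          level = "parcel"),
    subjects = kept,
    n_included = n_inc
  )
}

#' Run the split-half reproducibility experiment
#'
#' Simulates two independent synthetic cohorts from one generative model,
#' runs each through censoring/denoising, group-average connectivity, the
#' multi-density network-mapping pipeline and group winner-take-all
#' subcortical assignment, then quantifies reproducibility: vertex- and
#' parcel-level FC correlation, cortical consensus-map NMI with a spin
#' permutation p-value, subcortical NMI, and per-network Dice.
#'
#' @param config A [splithalf_config()].
#' @return A `splithalf_report` list with the similarity statistics, the
#'   per-cohort consensus maps, audits, and a [run_manifest()].
#' @export
run_splithalf_experiment <- function(config = splithalf_config()) {
  mesh <- make_icosphere(config$subdivisions)
  template <- make_template(mesh, config$n_networks, seed = config$seed)
  parcellation <- make_parcellation(mesh, config$n_parcels,
                                    seed = config$seed + 1L)
  seeds <- list(cohort_a = config$seed, cohort_b = config$seed + 1L,
                mapping = config$seed + 10L, spin = config$seed + 20L)
  cfg_match <- match_config(config$jaccard_threshold,
                            config$min_community_size)

  halves <- list(
    a = process_cohort(template, parcellation, config, seeds$cohort_a),
    b = process_cohort(template, parcellation, config, seeds$cohort_b))

  maps <- lapply(halves, function(h)
    map_networks(h$fc_vertex, template, config$densities, cfg_match,
                 seed = seeds$mapping, n_restarts = config$n_restarts))
  wta <- lapply(names(halves), function(k)
    group_wta(halves[[k]]$subjects, maps[[k]]))
  names(wta) <- names(halves)

  spin <- spin_pvalue(nmi, maps$a, maps$b, mesh,
                      n_rot = config$n_rotations, seed = seeds$spin)

  structure(list(
    fc_r_vertex = fc_similarity(halves$a$fc_vertex, halves$b$fc_vertex),
    fc_r_parcel = fc_similarity(halves$a$fc_parcel, halves$b$fc_parcel),
    nmi_cortical = spin$observed,
    spin_cortical = spin,
    nmi_subcortical = nmi(wta$a, wta$b),
    dice_network = dice_by_network(maps$a, maps$b),
    consensus_maps = maps,
    wta_maps = wta,
    fc_parcel = lapply(halves, `[[`, "fc_parcel"),
    n_included = vapply(halves, `[[`, integer(1), "n_included"),
    audit = lapply(maps, attr, "audit"),
    template = template,
    mesh = mesh,
    manifest = run_manifest(unclass(config), seeds)
  ), class = "splithalf_report")
}

#' @export
print.splithalf_report <- function(x, ...) {
  cat("Split-half reproducibility report\n")
  cat("  subjects included:      ", paste(x$n_included, collapse = " / "),
      "\n")
  cat("  vertex FC correlation:  ", round(x$fc_r_vertex, 4), "\n")
  cat("  parcel FC correlation:  ", round(x$fc_r_parcel, 4), "\n")
  cat("  cortical NMI:           ", round(x$nmi_cortical, 4),
      " (spin p = ", signif(x$spin_cortical$p_value, 3), ", ",
      x$spin_cortical$n_perm, " rotations)\n", sep = "")
  cat("  subcortical NMI:        ", round(x$nmi_subcortical, 4), "\n")
  cat("  per-network Dice:\n")
  print(round(x$dice_network, 3))
  invisible(x)
}

#' Shift network boundaries of a template
#'
#' Produces a perturbed copy of a template in which approximately
#' `fraction` of all vertices have been reassigned to a neighboring
#' network, by repeatedly flipping boundary vertices to the label of a
#' random neighbor. Used to emulate a second population whose network
#' topography differs from the first (e.g. adults versus children).
#'
#' @param template A `network_template`.
#' @param mesh The `surface_mesh` it lives on.
#' @param fraction Fraction of vertices to reassign (0 disables).
#' @param seed Integer seed.
#' @return A perturbed `network_template`.
#' @export
perturb_template <- function(template, mesh, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction < 1)
  if (fraction == 0) return(template)
  adj <- mesh_adjacency(mesh)
  labels <- template$labels
  n_flip <- round(fraction * length(labels))
  withr::with_seed(seed, {
    flipped <- 0L
    while (flipped < n_flip) {
      boundary <- which(vapply(seq_along(labels), function(v)
        any(labels[adj[[v]]] != labels[v]), logical(1)))
      if (length(boundary) == 0) break
      v <- boundary[sample.int(length(boundary), 1L)]
      other <- setdiff(labels[adj[[v]]], labels[v])
      labels[v] <- other[sample.int(length(other), 1L)]
      flipped <- flipped + 1L
    }
  })
  structure(list(labels = labels, names = template$names, K = template$K),
            class = "network_template")
}

#' Run the cross-group comparison experiment
#'
#' Simulates two cohorts from a reference template T (within-group
#' baseline) and one cohort from a boundary-perturbed template T', then
#' quantifies within-group versus cross-group similarity: consensus-map
#' NMI, per-network Dice, Mantel tests (rank and linear) on parcel
#' matrices, and participation coefficients with their per-parcel and
#' per-network differences.
#'
#' @param config A [splithalf_config()].
#' @param perturb_fraction Fraction of vertices whose network label is
#'   shifted in the second group's template.
#' @param n_perm Mantel permutations.
#' @return A `crossgroup_report` list.
#' @export
run_crossgroup_experiment <- function(config = splithalf_config(),
                                      perturb_fraction = 0.15,
                                      n_perm = 999L) {
  mesh <- make_icosphere(config$subdivisions)
  template <- make_template(mesh, config$n_networks, seed = config$seed)
  template_b <- perturb_template(template, mesh, perturb_fraction,
                                 seed = config$seed + 5L)
  parcellation <- make_parcellation(mesh, config$n_parcels,
                                    seed = config$seed + 1L)
  seeds <- list(within_1 = config$seed, within_2 = config$seed + 1L,
                cross = config$seed + 2L, mapping = config$seed + 10L,
                mantel = config$seed + 30L)
  cfg_match <- match_config(config$jaccard_threshold,
                            config$min_community_size)

  h1 <- process_cohort(template, parcellation, config, seeds$within_1)
  h2 <- process_cohort(template, parcellation, config, seeds$within_2)
  hx <- process_cohort(template_b, parcellation, config, seeds$cross)

  map1 <- map_networks(h1$fc_vertex, template, config$densities, cfg_match,
                       seed = seeds$mapping, n_restarts = config$n_restarts)
  map2 <- map_networks(h2$fc_vertex, template, config$densities, cfg_match,
                       seed = seeds$mapping, n_restarts = config$n_restarts)
  mapx <- map_networks(hx$fc_vertex, template_b, config$densities,
                       cfg_match, seed = seeds$mapping,
                       n_restarts = config$n_restarts)

  parcel_labels <- parcel_majority_labels(map1, parcellation)
  pc1 <- participation_coefficient(h1$fc_parcel, parcel_labels)
  pcx <- participation_coefficient(hx$fc_parcel, parcel_labels)

  structure(list(
    nmi_within = nmi(map1, map2),
    nmi_cross = nmi(map1, mapx),
    dice_within = dice_by_network(map1, map2),
    dice_cross = dice_by_network(map1, mapx),
    mantel_rank = mantel(h1$fc_parcel, hx$fc_parcel, "rank", n_perm,
                         seed = seeds$mantel),
    mantel_linear = mantel(h1$fc_parcel, hx$fc_parcel, "linear", n_perm,
                           seed = seeds$mantel),
    pc_group_a = pc1,
    pc_group_b = pcx,
    delta_pc = delta_pc(pcx, pc1),
    network_mean_pc = list(a = network_mean_pc(pc1, parcel_labels),
                           b = network_mean_pc(pcx, parcel_labels)),
    perturb_fraction = perturb_fraction,
    manifest = run_manifest(c(unclass(config),
                              perturb_fraction = perturb_fraction), seeds)
  ), class = "crossgroup_report")
}

#' @export
print.crossgroup_report <- function(x, ...) {
  cat("Cross-group comparison report (perturbation ",
      x$perturb_fraction, ")\n", sep = "")
  cat("  within-group NMI:  ", round(x$nmi_within, 4), "\n")
  cat("  cross-group NMI:   ", round(x$nmi_cross, 4), "\n")
  cat("  Mantel rank r:     ", round(x$mantel_rank$observed, 4),
      " (p = ", signif(x$mantel_rank$p_value, 3), ")\n", sep = "")
  cat("  Mantel linear r:   ", round(x$mantel_linear$observed, 4),
      " (p = ", signif(x$mantel_linear$p_value, 3), ")\n", sep = "")
  cat("  mean cross Dice:   ", round(mean(x$dice_cross, na.rm = TRUE), 4),
      "\n")
  invisible(x)
}

#' Majority network label per parcel
#'
#' Assigns each parcel the most frequent vertex network label among its
#' members (ties to the alphabetically first label); parcels whose majority
#' vertex label is unassigned stay unassigned.
#'
#' @param vertex_labels Character label map over vertices.
#' @param parcellation A `parcellation`.
#' @return Character label per parcel.
#' @export
parcel_majority_labels <- function(vertex_labels, parcellation) {
  vapply(split(vertex_labels, parcellation$assignment), function(l) {
    tb <- sort(table(l), decreasing = TRUE)
    names(tb)[1]
  }, character(1))
}
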