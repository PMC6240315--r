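# End-to-end preset pipelines with seed handling and a reproducibility
# manifest. Each stage derives its own seed from the global one, so inserting
# a stage does not shift the random streams of the others. The analysis
# scripts shipped with this repository are thin drivers over these functions.

#' One ScarTrace recovery trial: simulate a fish and score organ grouping
#'
#' Simulates a single scarred fish under `params`, applies the within-fish
#' filter stages (fraction filter, replicate merge, binarization), computes
#' the IWSS distance matrix over organs and reports whether the clonally
#' shared pair sits closer than the non-shared pair — the computational
#' analogue of spinal cord grouping with muscle rather than brain.
#'
#' @param params A [scar_sim_params]; the default tissue map shares
#'   progenitors between spinal cord and muscle but not brain.
#' @param seed Integer seed.
#' @param shared_pair,cross_pair Organ name pairs compared (defaults: spinal
#'   cord/muscle vs spinal cord/brain).
#' @return List with `D` (organ-labelled IWSS matrix), `B` (binary matrix),
#'   `recovered` (logical), `margin` (cross-pair minus shared-pair distance)
#'   and `n_scars`.
#' @export
scar_grouping_trial <- function(params = scar_sim_params(), seed = 1L,
                                shared_pair = c("spinal_cord", "muscle"),
                                cross_pair = c("spinal_cord", "brain")) {
  emb <- simulate_embryo(params, seed = derive_seed(seed, "embryo"))
  tab <- sample_organs(emb, seed = derive_seed(seed, "organs"), fish_id = "f")
  ff <- suppressWarnings(apply_fraction_filter(tab))
  merged <- merge_replicates(ff$table)
  B <- suppressWarnings(binarize(merged))
  rownames(B$presence) <- merged$sample_meta$organ
  D <- distance_matrix(B)$D
  margin <- D[cross_pair[1], cross_pair[2]] - D[shared_pair[1], shared_pair[2]]
  list(D = D, B = B, recovered = margin > 0, margin = unname(margin),
       n_scars = ncol(B$presence))
}

#' Bootstrap frequency of two-organ cherries
#'
#' Resamples scar columns `n_boot` times, rebuilds the NJ tree each time, and
#' counts for every organ pair how often the pair forms its own clade
#' (a cherry bipartition) — used to compare support for truly clonally related
#' pairs against unrelated ones.
#'
#' @param B A `binary_scar_matrix` (or 0/1 matrix) with organ row names.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param alpha Pseudocount for [scar_weights()].
#' @return Symmetric matrix of cherry counts per organ pair.
#' @export
pair_split_support <- function(B, n_boot = 50, seed = 1L, alpha = 0.5) {
  pres <- if (inherits(B, "binary_scar_matrix")) B$presence else as.matrix(B)
  organs <- rownames(pres)
  counts <- matrix(0L, length(organs), length(organs),
                   dimnames = list(organs, organs))
  set.seed(as.integer(seed))
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(pres), ncol(pres), replace = TRUE)
    tb <- suppressWarnings(nj_tree(distance_matrix(pres[, cols, drop = FALSE],
                                                   alpha = alpha)))
    splits <- tree_bipartitions(tb)
    for (s in splits) {
      side <- strsplit(s, "|", fixed = TRUE)[[1]]
      if (length(side) == 2) {
        counts[side[1], side[2]] <- counts[side[1], side[2]] + 1L
        counts[side[2], side[1]] <- counts[side[2], side[1]] + 1L
      }
      comp <- setdiff(organs, side)
      if (length(comp) == 2) {
        counts[comp[1], comp[2]] <- counts[comp[1], comp[2]] + 1L
        counts[comp[2], comp[1]] <- counts[comp[2], comp[1]] + 1L
      }
    }
  }
  counts
}

write_manifest <- function(out_dir, pipeline, seed, params_summary, stages,
                           files) {
  files <- sort(files)
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(pipeline = pipeline, seed = seed,
                   parameters = params_summary, stages = stages,
                   outputs = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest
}

#' Run the clonal-analysis preset end to end
#'
#' Simulates a cohort of scarred fish, runs the four-stage filter chain,
#' computes IWSS distances, the log-distance clustering and the bootstrapped
#' neighbor-joining tree per kept fish, and writes all tables plus a manifest
#' (seed, parameters, md5 of every output) to `out_dir`.
#'
#' @param out_dir Output directory (created; existing outputs require
#'   `force = TRUE`).
#' @param seed Global integer seed.
#' @param params A [scar_sim_params]; default preset conditions.
#' @param n_fish Number of fish to simulate (default 3).
#' @param n_boot Bootstrap replicates for tree support (default 100).
#' @param min_scars,max_unscarred Fish QC thresholds.
#' @param force Overwrite existing outputs.
#' @return The manifest, invisibly.
#' @export
run_scar_pipeline <- function(out_dir, seed = 1L, params = scar_sim_params(),
                              n_fish = 3, n_boot = 100,
                              min_scars = 100, max_unscarred = 50,
                              force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output dir not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- simulate_scar_cohort(params, n_fish = n_fish, seed = seed)
  files <- character(0)
  for (fish in names(tabs)) {
    f <- sprintf("counts_%s.tsv", fish)
    write_scar_table(tabs[[fish]], file.path(out_dir, f))
    files <- c(files, f)
  }
  res <- filter_scar_pipeline(tabs, max_unscarred = max_unscarred,
                              min_scars = min_scars)
  utils::write.table(res$report$stages, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, "filter_report.tsv")
  stages <- c("simulate", "filter")
  for (fish in res$kept_fish) {
    B <- res$binary[[fish]]
    D <- distance_matrix(B)
    fD <- sprintf("iwss_%s.tsv", fish)
    write_distance_matrix(D, file.path(out_dir, fD))
    cl <- cluster_log_distance(D)
    fO <- sprintf("leaf_order_%s.txt", fish)
    writeLines(cl$order, file.path(out_dir, fO))
    tr <- bootstrap_support(B, n_boot = n_boot,
                            seed = derive_seed(seed, paste0("boot", fish)))
    fT <- sprintf("tree_%s.nwk", fish)
    write_newick(tr, file.path(out_dir, fT))
    files <- c(files, fD, fO, fT)
  }
  stages <- c(stages, "distance", "cluster", "tree")
  man <- write_manifest(out_dir, "scar", seed,
                        list(n_fish = n_fish, n_boot = n_boot,
                             window = params$window_preset,
                             scar_rate = params$scar_rate,
                             n_divisions = params$n_divisions),
                        stages, files)
  invisible(man)
}

#' Run the fate-mapping preset end to end
#'
#' Simulates a lineage forest with known fates, classifies terminal cells from
#' their reporters, scores terminal divisions and writes fate calls, division
#' classes, the divisions-per-track histogram, the recovery report and a
#' manifest to `out_dir`.
#'
#' @inheritParams run_scar_pipeline
#' @param params A [track_sim_params].
#' @return The manifest, invisibly.
#' @export
run_track_pipeline <- function(out_dir, seed = 1L,
                               params = track_sim_params(), force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output dir not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_forest(params, seed = derive_seed(seed, "forest"))
  write_tracks_csv(sim$forest, file.path(out_dir, "tracks.csv"))
  thr <- (params$reporter_baseline + params$reporter_high) / 2
  rules <- list(mezzo_threshold = thr, sox17_threshold = thr, k_frames = 3)
  fates <- classify_cell_fate(sim$forest, rules)
  utils::write.csv(fates, file.path(out_dir, "fate_calls.csv"), row.names = FALSE)
  td <- terminal_division_fates(sim$forest, fates)
  utils::write.csv(td$divisions, file.path(out_dir, "terminal_divisions.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(divisions = names(td$divisions_per_track),
                              tracks = as.integer(td$divisions_per_track)),
                   file.path(out_dir, "divisions_per_track.csv"),
                   row.names = FALSE)
  rr <- recovery_report(sim, rules)
  jsonlite::write_json(list(beta_hat = rr$beta_hat, beta_true = rr$beta_true,
                            ci = rr$ci, n_terminal = rr$n_terminal),
                       file.path(out_dir, "recovery.json"),
                       auto_unbox = TRUE, digits = NA)
  man <- write_manifest(out_dir, "tracks", seed,
                        list(n_cells = params$n_cells,
                             fate_probs = as.list(params$fate_probs),
                             n_frames = params$n_frames),
                        c("simulate", "classify", "terminal_divisions",
                          "recovery"),
                        c("tracks.csv", "fate_calls.csv",
                          "terminal_divisions.csv", "divisions_per_track.csv",
                          "recovery.json"))
  invisible(man)
}

#' Run the stage-tracking registration preset end to end
#'
#' Simulates a drifting volume series, runs the online every-`interval`
#' feedback loop and the offline consecutive registration, and writes the
#' drift log, shift tables, centroid trajectories and a manifest to `out_dir`.
#'
#' @inheritParams run_scar_pipeline
#' @param shape,n_timepoints,drift Passed to [simulate_drifting_volume()].
#' @param interval Online registration cadence (default 5).
#' @param max_shift Search window per axis in voxels.
#' @return The manifest, invisibly.
#' @export
run_registration_pipeline <- function(out_dir, seed = 1L,
                                      shape = c(32, 32, 32), n_timepoints = 16,
                                      drift = c(0, 1, 2), interval = 5,
                                      max_shift = 12, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force) {
    stop("output dir not empty; use force = TRUE to overwrite")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ser <- simulate_drifting_volume(shape = shape, n_timepoints = n_timepoints,
                                  drift = drift, seed = derive_seed(seed, "vol"))
  ot <- online_tracking(ser, interval = interval, max_shift = max_shift)
  utils::write.csv(ot$log, file.path(out_dir, "drift_log.csv"), row.names = FALSE)
  off <- offline_register(ser, max_shift = max_shift)
  utils::write.csv(as.data.frame(off$pairwise),
                   file.path(out_dir, "pairwise_shifts.csv"), row.names = FALSE)
  cen <- data.frame(uncorrected = series_centroids(ser$stacks),
                    corrected = series_centroids(ot$corrected))
  utils::write.csv(cen, file.path(out_dir, "centroids.csv"), row.names = FALSE)
  man <- write_manifest(out_dir, "registration", seed,
                        list(shape = shape, n_timepoints = n_timepoints,
                             drift = drift, interval = interval),
                        c("simulate", "online", "offline"),
                        c("drift_log.csv", "pairwise_shifts.csv",
                          "centroids.csv"))
  invisible(man)
}
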