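# Synthetic lineage-forest generator with known latent fates, division
# statistics, reporter dynamics, drift and track loss, used to validate the
# fate classifier and terminal-division scoring against ground truth.

#' Parameters for the lineage-forest simulator
#'
#' Cells carry a latent fate: `N` (neural), `M` (mesoderm), `NM` (bi-fated
#' neuromesodermal: its division yields one N and one M daughter), or `endo`
#' (endoderm, to be excluded by the sox17 reporter). Division waiting times
#' are exponential per fate class; setting a rate to zero makes that class
#' quiescent (the tailbud scenario). The mesendoderm reporter (`mezzo`)
#' switches from baseline to high intensity a fixed delay after commitment,
#' with Gaussian observation noise.
#'
#' @param n_cells Number of starting cells (roots).
#' @param layout `"mixed"` (fates spatially interleaved) or `"sorted"` (start
#'   positions segregated by fate along x).
#' @param fate_probs Named probabilities `c(N=, M=, NM=, endo=)`, summing to 1.
#' @param division_rate Named per-minute division rates per fate class,
#'   applying to the starting cells. Daughters of mono-fated cells inherit the
#'   parent fate, daughters of an NM division are one N and one M cell; all
#'   daughters divide at `child_division_rate`.
#' @param child_division_rate Division rate of daughter cells (default 0:
#'   every observed division is terminal; set > 0 for multi-division tracks).
#' @param n_frames Number of observation frames.
#' @param dt Minutes per frame (default 2.5).
#' @param reporter_baseline,reporter_high Mezzo/sox17 intensity levels.
#' @param reporter_delay Minutes from commitment to reporter onset.
#' @param reporter_sd Gaussian intensity noise.
#' @param drift Per-minute drift velocity, length 3 (µm/min).
#' @param brownian_sd Per-frame isotropic Brownian displacement sd (µm).
#' @param track_loss_prob Per-frame probability a track is lost (censored).
#' @param box Extent of the initial cell layout (µm).
#' @return A list of class `track_sim_params`.
#' @export
track_sim_params <- function(n_cells = 100, layout = c("mixed", "sorted"),
                             fate_probs = c(N = 0.35, M = 0.4, NM = 0.15, endo = 0.1),
                             division_rate = c(N = 0.008, M = 0.008, NM = 0.008,
                                               endo = 0.008),
                             child_division_rate = 0,
                             n_frames = 40, dt = 2.5,
                             reporter_baseline = 10, reporter_high = 100,
                             reporter_delay = 5, reporter_sd = 3,
                             drift = c(0.1, 0, 0), brownian_sd = 0.5,
                             track_loss_prob = 0.002, box = 100) {
  layout <- match.arg(layout)
  stopifnot(abs(sum(fate_probs) - 1) < 1e-9, all(division_rate >= 0))
  structure(list(n_cells = n_cells, layout = layout, fate_probs = fate_probs,
                 division_rate = division_rate,
                 child_division_rate = child_division_rate,
                 n_frames = n_frames, dt = dt,
                 reporter_baseline = reporter_baseline,
                 reporter_high = reporter_high,
                 reporter_delay = reporter_delay, reporter_sd = reporter_sd,
                 drift = drift, brownian_sd = brownian_sd,
                 track_loss_prob = track_loss_prob, box = box),
            class = "track_sim_params")
}

#' Simulate a lineage forest with ground truth
#'
#' Grows each starting cell in continuous time (exponential division waiting
#' times, fate-dependent), discretizes to frames, applies drift, Brownian
#' motion, reporter dynamics and per-frame track loss, and returns both the
#' observable [lineage_forest] (channels `mezzo`, `sox17`) and a ground-truth
#' record (per cell: latent fate, commitment time; per division: true class).
#' A lost track censors its whole subtree, exercising the unassigned pathway.
#'
#' @param params A [track_sim_params].
#' @param seed Integer seed.
#' @return List with `forest` ([lineage_forest]), `truth` (list with `cells`,
#'   `divisions` data frames; `divisions$division_node_id` keys the last
#'   observation of the dividing cell) and `params`.
#' @export
simulate_forest <- function(params, seed = 1L) {
  stopifnot(inherits(params, "track_sim_params"))
  set.seed(as.integer(seed))
  t_end <- (params$n_frames - 1) * params$dt
  fates <- sample(names(params$fate_probs), params$n_cells, replace = TRUE,
                  prob = params$fate_probs)
  if (params$layout == "sorted") {
    ord <- order(match(fates, c("N", "NM", "M", "endo")))
    fates <- fates[ord]
    x0 <- seq(0, params$box, length.out = params$n_cells) +
      stats::rnorm(params$n_cells, 0, params$box / (4 * params$n_cells))
  } else {
    x0 <- stats::runif(params$n_cells, 0, params$box)
  }
  y0 <- stats::runif(params$n_cells, 0, params$box)
  z0 <- stats::runif(params$n_cells, 0, params$box)

  # continuous-time cell records grown breadth-first
  cells <- list(); divisions <- list()
  queue <- lapply(seq_len(params$n_cells), function(i) {
    list(cid = i, fate = fates[i], birth = 0,
         commit = if (fates[i] %in% c("M", "endo")) 0 else NA_real_,
         pos = c(x0[i], y0[i], z0[i]), parent_cell = NA_integer_,
         rate = unname(params$division_rate[fates[i]]), root = i)
  })
  next_cid <- params$n_cells + 1L
  qi <- 1L
  while (qi <= length(queue)) {
    cell <- queue[[qi]]; qi <- qi + 1L
    wait <- if (cell$rate > 0) stats::rexp(1, cell$rate) else Inf
    div_t <- cell$birth + wait
    if (div_t < t_end) {
      cell$end <- div_t; cell$divides <- TRUE
      child_fates <- if (cell$fate == "NM") c("N", "M") else rep(cell$fate, 2)
      cls <- if (cell$fate == "NM") "N/M"
             else if (cell$fate == "N") "N/N"
             else if (cell$fate == "M") "M/M" else "endo"
      divisions[[length(divisions) + 1L]] <-
        data.frame(cell_id = cell$cid, time = div_t, true_class = cls,
                   root = cell$root, stringsAsFactors = FALSE)
      for (cf in child_fates) {
        # daughters of an already committed cell inherit its commitment time
        # (reporter stays on); only NM daughters commit at the division itself
        child_commit <- if (cf %in% c("M", "endo")) {
          if (cell$fate == "NM") div_t else cell$commit
        } else NA_real_
        queue[[length(queue) + 1L]] <- list(
          cid = next_cid, fate = cf, birth = div_t,
          commit = child_commit,
          pos = cell$pos + stats::rnorm(3, 0, 1), parent_cell = cell$cid,
          rate = params$child_division_rate,
          root = cell$root)
        next_cid <- next_cid + 1L
      }
    } else {
      cell$end <- t_end; cell$divides <- FALSE
    }
    cells[[cell$cid]] <- cell
  }

  # discretize to frames with drift, noise, reporters and censoring; divisions
  # are quantized so every cell owns at least one observation frame and its
  # daughters first appear at the following frame
  frame_t <- (seq_len(params$n_frames) - 1) * params$dt
  cap <- length(cells) * params$n_frames
  o_cell <- integer(cap); o_parent <- rep(NA_integer_, cap); o_t <- integer(cap)
  o_pos <- matrix(0, cap, 3); o_mezzo <- numeric(cap); o_sox <- numeric(cap)
  next_oid <- 1L
  last_obs_of_cell <- integer(length(cells))
  censored <- logical(length(cells))
  birth_frame <- integer(length(cells))
  end_frame <- integer(length(cells))
  for (cell in cells) {
    bf <- if (is.na(cell$parent_cell)) 1L
          else end_frame[cell$parent_cell] + 1L
    birth_frame[cell$cid] <- bf
    ef <- if (cell$divides) {
      max(bf, min(params$n_frames, floor(cell$end / params$dt) + 1L))
    } else params$n_frames
    end_frame[cell$cid] <- ef
    if (!is.na(cell$parent_cell) &&
        (censored[cell$parent_cell] || bf > params$n_frames)) {
      censored[cell$cid] <- TRUE   # subtree lost with the parent / off-window
      next
    }
    prev <- if (!is.na(cell$parent_cell)) last_obs_of_cell[cell$parent_cell] else NA_integer_
    if (!is.na(prev) && prev == 0L) prev <- NA_integer_
    frames <- bf:ef
    loss <- which(stats::runif(length(frames)) < params$track_loss_prob)
    if (length(loss)) {
      censored[cell$cid] <- TRUE
      frames <- frames[seq_len(loss[1] - 1L)]
    }
    nf <- length(frames)
    if (nf > 0) {
      steps <- matrix(stats::rnorm(3 * nf, 0, params$brownian_sd), nf, 3)
      steps <- sweep(steps, 2, params$drift * params$dt, "+")
      cs <- apply(steps, 2, cumsum)
      if (nf == 1) cs <- matrix(cs, 1, 3)
      oids <- next_oid:(next_oid + nf - 1L)
      on_t <- if (!is.na(cell$commit))
        frame_t[frames] >= cell$commit + params$reporter_delay else rep(FALSE, nf)
      o_cell[oids] <- oids
      o_parent[oids] <- c(prev, oids[-nf])
      o_t[oids] <- frames - 1L
      o_pos[oids, ] <- sweep(cs, 2, cell$pos, "+")
      o_mezzo[oids] <- ifelse(cell$fate == "M" & on_t, params$reporter_high,
                              params$reporter_baseline) +
        stats::rnorm(nf, 0, params$reporter_sd)
      o_sox[oids] <- ifelse(cell$fate == "endo" & on_t, params$reporter_high,
                            params$reporter_baseline) +
        stats::rnorm(nf, 0, params$reporter_sd)
      prev <- oids[nf]
      next_oid <- next_oid + nf
    }
    last_obs_of_cell[cell$cid] <- if (is.na(prev)) 0L else prev
  }
  n_obs <- next_oid - 1L
  nodes <- data.frame(cell_id = o_cell[seq_len(n_obs)],
                      parent_id = o_parent[seq_len(n_obs)],
                      t = o_t[seq_len(n_obs)],
                      x = o_pos[seq_len(n_obs), 1], y = o_pos[seq_len(n_obs), 2],
                      z = o_pos[seq_len(n_obs), 3],
                      mezzo = o_mezzo[seq_len(n_obs)], sox17 = o_sox[seq_len(n_obs)])
  forest <- lineage_forest(nodes, channels = c("mezzo", "sox17"),
                           time_step = params$dt)
  div_df <- if (length(divisions)) do.call(rbind, divisions) else
    data.frame(cell_id = integer(0), time = numeric(0),
               true_class = character(0), root = integer(0))
  if (nrow(div_df)) {
    div_df$division_node_id <- last_obs_of_cell[div_df$cell_id]
    div_df$observed <- div_df$division_node_id > 0 &
      !censored[div_df$cell_id] &
      vapply(div_df$cell_id, function(cid) {
        kids_cids <- which(vapply(cells, function(c2)
          !is.na(c2$parent_cell) && c2$parent_cell == cid, logical(1)))
        all(!censored[kids_cids]) && all(last_obs_of_cell[kids_cids] > 0)
      }, logical(1))
  }
  truth_cells <- data.frame(
    cell_id = vapply(cells, function(cl) as.integer(cl$cid), integer(1)),
    fate = vapply(cells, function(cl) cl$fate, character(1)),
    birth = vapply(cells, function(cl) cl$birth, numeric(1)),
    censored = censored, stringsAsFactors = FALSE)
  list(forest = forest, truth = list(cells = truth_cells, divisions = div_df),
       params = params)
}

#' Score fate-classification recovery against simulator truth
#'
#' Runs [classify_cell_fate()] and [terminal_division_fates()] on a simulated
#' forest and compares the called terminal-division classes with the true
#' classes, reporting a confusion matrix and the estimated bi-fated (N/M)
#' fraction with an exact binomial confidence interval.
#'
#' @param sim Output of [simulate_forest()].
#' @param rules Classifier rules for [classify_cell_fate()]; defaults derived
#'   from the simulator's reporter levels (threshold halfway between baseline
#'   and high).
#' @return List with `confusion` (called class x true class), `beta_hat`,
#'   `beta_true`, `ci` (95% binomial CI for `beta_hat`), and `n_terminal`.
#' @export
recovery_report <- function(sim, rules = NULL) {
  params <- sim$params
  if (is.null(rules)) {
    thr <- (params$reporter_baseline + params$reporter_high) / 2
    rules <- list(mezzo_threshold = thr, sox17_threshold = thr, k_frames = 3)
  }
  fates <- classify_cell_fate(sim$forest, rules)
  td <- terminal_division_fates(sim$forest, fates)
  called <- td$divisions
  truth <- sim$truth$divisions
  truth_key <- stats::setNames(truth$true_class, truth$division_node_id)
  called$true_class <- truth_key[as.character(called$division_id)]
  confusion <- table(called = called$class, truth = called$true_class)
  complete <- called[called$class != "incomplete", , drop = FALSE]
  n_term <- nrow(complete)
  n_nm <- sum(complete$class == "N/M")
  beta_hat <- if (n_term > 0) n_nm / n_term else NA_real_
  true_complete <- truth[truth$observed & truth$true_class != "endo", , drop = FALSE]
  beta_true <- if (nrow(true_complete) > 0)
    mean(true_complete$true_class == "N/M") else NA_real_
  ci <- if (n_term > 0) stats::binom.test(n_nm, n_term)$conf.int else c(NA, NA)
  list(confusion = confusion, beta_hat = beta_hat, beta_true = beta_true,
       ci = as.numeric(ci), n_terminal = n_term)
}
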