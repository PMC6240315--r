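# Synthetic ScarTrace generator: a synchronous embryonic division tree whose
# cells carry an 8-copy GFP target array, scarred stochastically within a
# developmental time window; organs are sampled from configurable progenitor
# subtrees so that ground-truth clonal sharing between tissues is known.

scar_id_string <- function(k) sprintf("%d:d%d", ((k - 1L) %% 263L) + 1L, k)

#' Parameters for the ScarTrace simulator
#'
#' Defaults encode the study conditions: an 8-copy histone-GFP target array,
#' heavy-tailed scar identity probabilities whose rare tail reaches the 1e-5
#' creation probabilities that make scars usable as clone marks, and two
#' scarring-window presets — `"rna"` (long window, scarring throughout
#' gastrulation, about 10 hpf) versus `"protein"` (short window, scarring over
#' in early cleavage, about 3 hpf) — mapped onto synchronous division rounds.
#'
#' @param n_copies Number of independent target copies per cell (default 8).
#' @param scar_rate Per-copy, per-division scarring probability while the
#'   window is active (default 0.25).
#' @param scar_window Integer vector `c(first, last)` of division rounds during
#'   which scarring is active; a first round of 0 scars the zygote itself, so
#'   those scars are shared by every cell of the fish.
#' @param window_preset `"rna"` (rounds 1-9) or `"protein"` (rounds 1-3);
#'   ignored when `scar_window` is given.
#' @param scar_alphabet_size Number of distinct scar identities (default 50000).
#' @param scar_exponent Power-law exponent of the identity distribution
#'   (default 0.8; the rare tail then has creation probabilities of order
#'   1e-5 and below).
#' @param n_divisions Rounds from zygote to the leaf pool (default 11, i.e.
#'   2048 leaves).
#' @param progenitor_generation Generation whose cells define the progenitor
#'   subtrees that `tissue_map` indexes (default 4, i.e. 16 subtrees).
#' @param tissue_map Named list: organ -> integer indices of progenitor
#'   subtrees it draws cells from. The default encodes the axial-sharing
#'   scenario: spinal cord and muscle draw from overlapping subtree sets, brain
#'   and skin from a common disjoint set, intestine and liver (endoderm) from a
#'   third.
#' @param cells_per_organ Cells dissected per organ sample (default 100).
#' @param n_replicates Technical replicates per organ (default 2).
#' @param dropout_prob Per-scar dropout probability per sample (default 0.05).
#' @param depth Sequencing reads per organ sample (default 20000).
#' @param seq_error_scars Number of spurious sequencing-error scar identities
#'   injected per sample (default 40). These are what the 10x minimum-fraction
#'   filter is designed to remove.
#' @param seq_error_copies Effective copy abundance of each error identity
#'   (default 0.04, i.e. around one read at default depth).
#' @return A list of class `scar_sim_params`.
#' @export
scar_sim_params <- function(n_copies = 8, scar_rate = 0.25,
                            scar_window = NULL,
                            window_preset = c("rna", "protein"),
                            scar_alphabet_size = 50000, scar_exponent = 0.8,
                            n_divisions = 11, progenitor_generation = 4,
                            tissue_map = NULL,
                            cells_per_organ = 100, n_replicates = 2,
                            dropout_prob = 0.05, depth = 20000,
                            seq_error_scars = 40, seq_error_copies = 0.04) {
  window_preset <- match.arg(window_preset)
  if (is.null(scar_window)) {
    scar_window <- if (window_preset == "rna") c(1L, 9L) else c(1L, 3L)
    scar_window <- pmin(scar_window, n_divisions)  # presets clamp to the tree
  }
  if (is.null(tissue_map)) {
    # organ pools are interleaved across the early-cleavage quadrants (early
    # zebrafish cleavage is indeterminate); clonal structure appears at the
    # progenitor generation, where spinal cord and muscle overlap, brain and
    # skin share a disjoint pool, and the endoderm organs a third
    tissue_map <- list(
      spinal_cord = c(1, 2, 5, 6, 9, 10), muscle = c(2, 3, 6, 7, 10, 11),
      brain = c(4, 8, 12), skin = c(4, 8, 12),
      intestine = 13:16, liver = 13:16
    )
  }
  stopifnot(scar_window[1] >= 0, scar_window[1] <= scar_window[2],
            scar_window[2] <= n_divisions,
            progenitor_generation <= n_divisions,
            all(unlist(tissue_map) >= 1),
            all(unlist(tissue_map) <= 2^progenitor_generation))
  probs <- seq_len(scar_alphabet_size)^(-scar_exponent)
  probs <- probs / sum(probs)
  structure(list(
    n_copies = n_copies, scar_rate = scar_rate, scar_window = scar_window,
    window_preset = window_preset, scar_alphabet_size = scar_alphabet_size,
    scar_probs = probs, n_divisions = n_divisions,
    progenitor_generation = progenitor_generation, tissue_map = tissue_map,
    cells_per_organ = cells_per_organ, n_replicates = n_replicates,
    dropout_prob = dropout_prob, depth = depth,
    seq_error_scars = seq_error_scars, seq_error_copies = seq_error_copies
  ), class = "scar_sim_params")
}

#' Simulate a scarred embryonic division tree
#'
#' Grows a synchronous binary division tree from the zygote. At every division
#' round inside the scarring window, each still-unscarred target copy of each
#' daughter cell acquires a scar with probability `scar_rate`; the scar
#' identity is drawn from the heavy-tailed identity distribution. Scars are
#' irreversible and inherited by all descendants, so a cell's scar multiset
#' always contains its ancestors'.
#'
#' @param params A [scar_sim_params] object.
#' @param seed Integer seed.
#' @param keep_history If `TRUE`, the full per-generation cell states are
#'   returned (for inheritance checks); default `FALSE` keeps leaves only.
#' @return List of class `scar_embryo`: `leaf_scars` (per-leaf integer vectors
#'   of scar identities, one entry per scarred copy), `leaf_unscarred`
#'   (unscarred copy counts), `params`, and optionally `history`.
#' @export
simulate_embryo <- function(params, seed = 1L, keep_history = FALSE) {
  stopifnot(inherits(params, "scar_sim_params"))
  set.seed(as.integer(seed))
  cells <- list(integer(0))          # zygote: no scars
  if (params$scar_window[1] == 0 && params$scar_rate > 0) {
    # round 0: scarring of the zygote itself, shared by every descendant
    n_new <- stats::rbinom(1, params$n_copies, params$scar_rate)
    if (n_new > 0) {
      cells[[1]] <- sample.int(params$scar_alphabet_size, n_new, replace = TRUE,
                               prob = params$scar_probs)
    }
  }
  history <- if (keep_history) list(cells) else NULL
  for (d in seq_len(params$n_divisions)) {
    active <- d >= params$scar_window[1] && d <= params$scar_window[2]
    parents <- rep(cells, each = 2)
    if (active && params$scar_rate > 0) {
      unscarred <- params$n_copies - lengths(parents)
      n_new <- stats::rbinom(length(parents), unscarred, params$scar_rate)
      tot <- sum(n_new)
      if (tot > 0) {
        ids <- sample.int(params$scar_alphabet_size, tot, replace = TRUE,
                          prob = params$scar_probs)
        idx <- rep(seq_along(parents), n_new)
        new_by_cell <- split(ids, factor(idx, levels = seq_along(parents)))
        parents <- mapply(c, parents, new_by_cell, SIMPLIFY = FALSE)
      }
    }
    cells <- parents
    if (keep_history) history[[d + 1L]] <- cells
  }
  structure(list(leaf_scars = cells,
                 leaf_unscarred = params$n_copies - lengths(cells),
                 params = params, history = history),
            class = "scar_embryo")
}

leaves_of_subtrees <- function(params, subtrees) {
  per <- 2^(params$n_divisions - params$progenitor_generation)
  unlist(lapply(subtrees, function(j) ((j - 1L) * per + 1L):(j * per)))
}

#' Sample organ scar tables from a simulated embryo
#'
#' Emulates dissection and bulk scar sequencing: for every organ and technical
#' replicate, `cells_per_organ` leaves are drawn from the organ's progenitor
#' subtrees, copy states are aggregated, scar identities suffer independent
#' dropout, and reads are drawn multinomially at the configured depth (row
#' sums equal `depth` exactly). Unscarred copies feed the reserved
#' `GFP_unscarred` column.
#'
#' @param embryo A `scar_embryo` from [simulate_embryo()].
#' @param seed Integer seed.
#' @param fish_id Fish identifier recorded in the metadata.
#' @return A [scar_table] with one row per organ x replicate.
#' @export
sample_organs <- function(embryo, seed = 1L, fish_id = "sim1") {
  stopifnot(inherits(embryo, "scar_embryo"))
  params <- embryo$params
  set.seed(as.integer(seed))
  rows <- list(); meta <- list()
  for (organ in names(params$tissue_map)) {
    pool <- leaves_of_subtrees(params, params$tissue_map[[organ]])
    if (length(pool) == 0) stop("empty progenitor subtree for organ ", organ)
    for (rep_i in seq_len(params$n_replicates)) {
      idx <- sample(pool, params$cells_per_organ,
                    replace = length(pool) < params$cells_per_organ)
      scars <- unlist(embryo$leaf_scars[idx], use.names = FALSE)
      unscarred <- sum(embryo$leaf_unscarred[idx])
      ab <- table(scars)
      ids <- as.integer(names(ab)); ab <- as.numeric(ab)
      if (length(ids)) {
        kept <- stats::runif(length(ids)) >= params$dropout_prob
        ids <- ids[kept]; ab <- ab[kept]
      }
      # spurious low-abundance identities emulate sequencing errors; they sit
      # far below real single-copy scars and are the fraction filter's prey
      if (params$seq_error_scars > 0) {
        err_ids <- setdiff(sample.int(params$scar_alphabet_size,
                                      params$seq_error_scars, replace = TRUE), ids)
        ids <- c(ids, err_ids)
        ab <- c(ab, rep(params$seq_error_copies, length(err_ids)))
      }
      abund <- c(ab, unscarred)
      labels <- c(scar_id_string(ids), GFP_UNSCARRED)
      if (sum(abund) == 0) {
        reads <- c(rep(0, length(ab)), params$depth)  # degenerate: no template
      } else {
        reads <- as.numeric(stats::rmultinom(1, params$depth, abund / sum(abund)))
      }
      rows[[length(rows) + 1L]] <- stats::setNames(reads, labels)
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = sprintf("%s.%s.r%d", fish_id, organ, rep_i),
        fish_id = fish_id, organ = organ, axis_position = NA_character_,
        replicate_id = sprintf("r%d", rep_i), stringsAsFactors = FALSE)
    }
  }
  all_ids <- unique(unlist(lapply(rows, names)))
  all_ids <- c(setdiff(all_ids, GFP_UNSCARRED), GFP_UNSCARRED)
  counts <- matrix(0, length(rows), length(all_ids),
                   dimnames = list(NULL, all_ids))
  for (i in seq_along(rows)) counts[i, names(rows[[i]])] <- rows[[i]]
  scar_table(counts, do.call(rbind, meta),
             provenance = sprintf("simulated fish %s", fish_id))
}

#' Expected organ grouping implied by the tissue map
#'
#' Returns the partition of organs induced by progenitor sharing: two organs
#' are in the same group when their progenitor subtree sets are connected
#' through (possibly indirect) overlaps. This is the ground truth against
#' which distance- and tree-based recovery is scored.
#'
#' @param params A [scar_sim_params] object.
#' @return Named integer vector: organ -> group id; organs sharing a group id
#'   share a progenitor pool.
#' @export
ground_truth <- function(params) {
  organs <- names(params$tissue_map)
  n <- length(organs)
  group <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (length(intersect(params$tissue_map[[i]], params$tissue_map[[j]])) > 0 &&
          group[i] != group[j]) {
        group[group == max(group[i], group[j])] <- min(group[i], group[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(match(group, unique(group)), organs)
}

#' Simulate a cohort of scarred fish
#'
#' One independent embryo and organ-sampling pass per fish.
#'
#' @param params A [scar_sim_params] object.
#' @param n_fish Number of fish.
#' @param seed Integer seed; each fish uses a derived sub-seed.
#' @return Named list of [scar_table]s (`fish1`, `fish2`, ...).
#' @export
simulate_scar_cohort <- function(params, n_fish = 3, seed = 1L) {
  stats::setNames(lapply(seq_len(n_fish), function(i) {
    fid <- sprintf("fish%d", i)
    emb <- simulate_embryo(params, seed = derive_seed(seed, paste0("embryo", i)))
    sample_organs(emb, seed = derive_seed(seed, paste0("organs", i)), fish_id = fid)
  }), sprintf("fish%d", seq_len(n_fish)))
}
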