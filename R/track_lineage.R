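# Lineage-forest data model over cell-tracking output (TGMM-style per-timepoint
# XML or a flat table), in-silico photolabelling (clone selection with
# descendant closure and far-side elimination), reporter-based fate
# classification, terminal-division scoring and the label/axis summaries.

#' Construct a lineage forest
#'
#' A lineage forest holds one row per cell observation: `cell_id` (globally
#' unique), `parent_id` (the observation at the previous timepoint this cell
#' continues from, `NA` for track starts), integer timepoint `t`, micron
#' positions `x`, `y`, `z`, and any number of reporter intensity channels.
#' A node with two children is a cell division. A "track" is a root cell and
#' all of its progeny.
#'
#' @param nodes Data frame with at least the columns above.
#' @param channels Character vector naming the intensity channels among the
#'   columns of `nodes`; defaults to all numeric columns after `z`.
#' @param time_step Real time per timepoint (minutes), metadata only.
#' @param stages Optional named vector mapping timepoints to stage labels.
#' @return An object of class `lineage_forest`.
#' @export
lineage_forest <- function(nodes, channels = NULL, time_step = 1, stages = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  req <- c("cell_id", "parent_id", "t", "x", "y", "z")
  if (!all(req %in% names(nodes))) {
    stop("nodes must have columns: ", paste(req, collapse = ", "))
  }
  if (is.null(channels)) {
    rest <- setdiff(names(nodes), req)
    channels <- rest[vapply(nodes[rest], is.numeric, logical(1))]
  }
  if (anyDuplicated(nodes$cell_id)) stop("cell_id values must be unique")
  idx <- match(nodes$parent_id, nodes$cell_id)
  has_parent <- !is.na(nodes$parent_id)
  if (any(has_parent & is.na(idx))) {
    stop("parent_id not found for node(s): ",
         paste(utils::head(nodes$cell_id[has_parent & is.na(idx)], 3), collapse = ", "))
  }
  bad_t <- has_parent & nodes$t[idx] >= nodes$t
  if (any(bad_t, na.rm = TRUE)) {
    stop("parent timepoint must precede child timepoint (node ",
         nodes$cell_id[which(bad_t)[1]], ")")
  }
  kids <- table(nodes$parent_id[has_parent])
  if (any(kids > 2)) {
    stop("node '", names(kids)[which(kids > 2)[1]], "' has more than 2 children")
  }
  structure(list(nodes = nodes, channels = channels, time_step = time_step,
                 stages = stages),
            class = "lineage_forest")
}

#' @export
print.lineage_forest <- function(x, ...) {
  n <- x$nodes
  cat("lineage_forest: ", nrow(n), " observations, ",
      sum(is.na(n$parent_id)), " roots, timepoints ",
      min(n$t), "-", max(n$t), "\n", sep = "")
  cat("  channels: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

children_map <- function(forest) {
  n <- forest$nodes
  split(n$cell_id[!is.na(n$parent_id)], n$parent_id[!is.na(n$parent_id)])
}

#' Import TGMM-style per-timepoint XML tracking output
#'
#' One XML file per timepoint (lexicographic order = time order); each cell is
#' an element with attributes `id` (unique within the timepoint), `parent`
#' (the `id` at the previous timepoint, or -1), `lineage`, and `m` = "x y z"
#' voxel coordinates. Additional numeric attributes are imported as intensity
#' channels. Positions are scaled to microns by `voxel_size`. A parent id
#' absent from the previous timepoint is reported as an orphan and the track
#' treated as a new root.
#'
#' @param dir Directory of per-timepoint XML files (pattern `*.xml`).
#' @param voxel_size Micron scale per axis, `c(x, y, z)`.
#' @param time_step Minutes per timepoint (metadata).
#' @return A [lineage_forest].
#' @export
read_tgmm <- function(dir, voxel_size = c(1, 1, 1), time_step = 1) {
  files <- sort(list.files(dir, pattern = "\\.xml$", full.names = TRUE))
  if (!length(files)) stop("no XML files in ", dir)
  rows <- list()
  prev_map <- integer(0)   # timepoint-local id -> global id at t-1
  next_gid <- 1L
  orphans <- 0L
  for (ti in seq_along(files)) {
    doc <- xml2::read_xml(files[ti])
    cells <- xml2::xml_find_all(doc, ".//*[@id and @m]")
    ids <- as.integer(xml2::xml_attr(cells, "id"))
    if (anyDuplicated(ids)) {
      stop("duplicate ids within timepoint file ", basename(files[ti]))
    }
    parents <- suppressWarnings(as.integer(xml2::xml_attr(cells, "parent")))
    m <- do.call(rbind, lapply(strsplit(xml2::xml_attr(cells, "m"), "\\s+"),
                               as.numeric))
    gids <- next_gid + seq_along(ids) - 1L
    next_gid <- next_gid + length(ids)
    pgid <- rep(NA_integer_, length(ids))
    known <- !is.na(parents) & parents >= 0
    hit <- match(parents[known], as.integer(names(prev_map)))
    pgid[known] <- unname(prev_map[hit])
    orphans <- orphans + sum(known & is.na(pgid))
    df <- data.frame(cell_id = gids, parent_id = pgid, t = ti - 1L,
                     x = m[, 1] * voxel_size[1], y = m[, 2] * voxel_size[2],
                     z = m[, 3] * voxel_size[3])
    # extra numeric attributes become channels
    extra <- setdiff(names(xml2::xml_attrs(cells[[1]])), c("id", "parent", "lineage", "m"))
    for (at in extra) {
      v <- suppressWarnings(as.numeric(xml2::xml_attr(cells, at)))
      if (!all(is.na(v))) df[[at]] <- v
    }
    rows[[ti]] <- df
    prev_map <- stats::setNames(gids, ids)
  }
  nodes <- do.call(rbind, rows)
  if (orphans > 0) {
    warning(orphans, " orphan parent reference(s); treating as new roots")
  }
  lineage_forest(nodes, time_step = time_step)
}

#' Export a lineage forest as TGMM-style per-timepoint XML
#'
#' Inverse of [read_tgmm()] (positions divided by `voxel_size`); files are
#' named `GMEMfinalResult_frame%04d.xml`.
#'
#' @param forest A [lineage_forest].
#' @param dir Output directory (created if needed).
#' @param voxel_size Micron scale per axis used at import.
#' @return `dir`, invisibly.
#' @export
write_tgmm <- function(forest, dir, voxel_size = c(1, 1, 1)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- forest$nodes
  ts <- sort(unique(n$t))
  # timepoint-local ids are just the global ids; parents refer to t-1 ids
  for (ti in seq_along(ts)) {
    sub <- n[n$t == ts[ti], , drop = FALSE]
    doc <- xml2::xml_new_root("document")
    for (i in seq_len(nrow(sub))) {
      attrs <- list(
        id = as.character(sub$cell_id[i]),
        lineage = "0",
        parent = as.character(ifelse(is.na(sub$parent_id[i]), -1L, sub$parent_id[i])),
        m = paste(sub$x[i] / voxel_size[1], sub$y[i] / voxel_size[2],
                  sub$z[i] / voxel_size[3])
      )
      for (ch in forest$channels) attrs[[ch]] <- as.character(sub[[ch]][i])
      do.call(xml2::xml_add_child, c(list(doc, "GaussianMixtureModel"), attrs))
    }
    xml2::write_xml(doc, file.path(dir, sprintf("GMEMfinalResult_frame%04d.xml", ti - 1L)))
  }
  invisible(dir)
}

#' Flat-table I/O for lineage forests
#'
#' CSV with columns `cell_id,parent_id,t,x,y,z` followed by channel columns.
#'
#' @param forest A [lineage_forest].
#' @param path CSV path.
#' @return `path` invisibly ([write_tracks_csv()]); a [lineage_forest]
#'   ([read_tracks_csv()]).
#' @export
write_tracks_csv <- function(forest, path) {
  utils::write.csv(forest$nodes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  lineage_forest(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Spatial region constructors
#'
#' Regions for in-silico photolabelling: a sphere (`center`, `radius`) or an
#' axis-aligned box (`lower`, `upper` corners), both in microns.
#'
#' @param center,radius Sphere center (length-3) and radius.
#' @return A region spec usable by [select_clone()] and [zone_assign()].
#' @export
region_sphere <- function(center, radius) {
  list(type = "sphere", center = as.numeric(center), radius = radius)
}

#' @rdname region_sphere
#' @param lower,upper Box corners (length-3 each).
#' @export
region_box <- function(lower, upper) {
  list(type = "box", lower = as.numeric(lower), upper = as.numeric(upper))
}

point_in_region <- function(p, region) {
  if (region$type == "sphere") {
    sqrt(sum((p - region$center)^2)) <= region$radius
  } else if (region$type == "box") {
    all(p >= region$lower) && all(p <= region$upper)
  } else stop("unknown region type: ", region$type)
}

#' In-silico photolabelling: select a clone and its descendants
#'
#' Roots are the cells whose position at timepoint `t0` lies inside `region`
#' and — if a viewer half-space is given — on the viewer's side of the plane
#' (cells on the far side of the embryo are eliminated, mirroring the optional
#' far-side clean-up of interactive track selection). The selection is the
#' roots plus all their descendants at any later timepoint (exact closure).
#'
#' @param forest A [lineage_forest].
#' @param region A [region_sphere()] or [region_box()] spec.
#' @param t0 Timepoint of selection.
#' @param viewpoint Optional half-space `list(point =, normal =)`: cells with
#'   `(pos - point) . normal > 0` are kept.
#' @return An object of class `clonal_selection`: list with `roots` (cell
#'   ids), `nodes` (the induced subforest rows), `region`, `t0`.
#' @export
select_clone <- function(forest, region, t0, viewpoint = NULL) {
  n <- forest$nodes
  if (t0 < min(n$t) || t0 > max(n$t)) stop("t0 outside forest time span")
  at0 <- n[n$t == t0, , drop = FALSE]
  inside <- vapply(seq_len(nrow(at0)), function(i)
    point_in_region(c(at0$x[i], at0$y[i], at0$z[i]), region), logical(1))
  if (!is.null(viewpoint)) {
    side <- as.matrix(at0[, c("x", "y", "z")]) %*% viewpoint$normal -
      sum(viewpoint$point * viewpoint$normal)
    inside <- inside & (side[, 1] > 0)
  }
  roots <- at0$cell_id[inside]
  if (!length(roots)) {
    warning("empty clonal selection")
    return(structure(list(roots = integer(0),
                          nodes = n[0, , drop = FALSE],
                          region = region, t0 = t0), class = "clonal_selection"))
  }
  # descendant closure by walking forward over timepoints
  selected <- roots
  frontier <- roots
  repeat {
    nxt <- n$cell_id[!is.na(n$parent_id) & n$parent_id %in% frontier]
    nxt <- setdiff(nxt, selected)
    if (!length(nxt)) break
    selected <- c(selected, nxt)
    frontier <- nxt
  }
  structure(list(roots = roots,
                 nodes = n[n$cell_id %in% selected, , drop = FALSE],
                 region = region, t0 = t0),
            class = "clonal_selection")
}

#' @export
print.clonal_selection <- function(x, ...) {
  cat("clonal_selection: ", length(x$roots), " roots, ",
      nrow(x$nodes), " observations\n", sep = "")
  invisible(x)
}

# Decompose a forest into cell segments: maximal observation chains between
# divisions. Returns row-aligned segment ids and child counts.
forest_segments <- function(forest) {
  n <- forest$nodes
  pidx <- match(n$parent_id, n$cell_id)              # parent row per node row
  n_children <- tabulate(pidx[!is.na(pidx)], nbins = nrow(n))
  seg_start <- is.na(pidx) | n_children[ifelse(is.na(pidx), 1L, pidx)] == 2
  seg_start[is.na(pidx)] <- TRUE
  seg_id <- integer(nrow(n))
  ord <- order(n$t)                                  # parents precede children
  sid <- 0L
  for (r in ord) {
    if (seg_start[r]) {
      sid <- sid + 1L
      seg_id[r] <- sid
    } else {
      seg_id[r] <- seg_id[pidx[r]]
    }
  }
  list(seg_id = seg_id, n_children = n_children, parent_row = pidx)
}

#' Reporter-based fate classification of terminal cells
#'
#' Classifies every terminal cell (a track segment ending without further
#' division) from its reporter traces: cells with the endoderm reporter
#' (`sox17`) above threshold in at least `k_frames` observations are excluded
#' as endoderm; otherwise sustained mesendoderm reporter expression (`mezzo`
#' at or above threshold for `k_frames` consecutive observations) calls
#' mesoderm; otherwise a track surviving to the end of the observation window
#' is neural; tracks lost early are unassigned. The consecutive-frame
#' requirement rejects single-frame intensity flicker.
#'
#' @param forest A [lineage_forest] (or `clonal_selection$nodes` wrapped in
#'   one).
#' @param rules List with `mezzo_threshold`, `sox17_threshold`, `k_frames`
#'   (default 3), and optionally `t_end` (defaults to the forest's last
#'   timepoint) and channel names `mezzo` / `sox17`.
#' @return Data frame of class `fate_calls`: one row per terminal cell with
#'   `leaf_id`, `root_id`, `fate` in
#'   `{neural, mesoderm, endoderm_excluded, unassigned}` and the evidence.
#' @export
classify_cell_fate <- function(forest, rules) {
  defaults <- list(k_frames = 3, t_end = max(forest$nodes$t),
                   mezzo = "mezzo", sox17 = "sox17")
  rules <- utils::modifyList(defaults, rules)
  if (!rules$mezzo %in% forest$channels) {
    stop("missing channel '", rules$mezzo, "'")
  }
  has_sox17 <- rules$sox17 %in% forest$channels
  n <- forest$nodes
  segs <- forest_segments(forest)
  leaf_rows <- which(segs$n_children == 0)
  roots_of <- track_roots(forest)
  seg_rows <- split(seq_len(nrow(n)), segs$seg_id)
  k <- rules$k_frames
  run <- function(v) { # longest consecutive run of TRUE
    if (!any(v)) return(0L)
    max(rle(v)$lengths[rle(v)$values])
  }
  fate <- character(length(leaf_rows))
  start_t <- end_t <- nfr <- integer(length(leaf_rows))
  for (i in seq_along(leaf_rows)) {
    lr <- leaf_rows[i]
    rows <- seg_rows[[segs$seg_id[lr]]]
    rows <- rows[order(n$t[rows])]
    mezzo <- n[[rules$mezzo]][rows]
    sox <- if (has_sox17) n[[rules$sox17]][rows] else rep(0, length(rows))
    fate[i] <- if (sum(sox >= rules$sox17_threshold, na.rm = TRUE) >= k) {
      "endoderm_excluded"
    } else if (run(!is.na(mezzo) & mezzo >= rules$mezzo_threshold) >= k) {
      "mesoderm"
    } else if (max(n$t[rows]) >= rules$t_end) {
      "neural"
    } else {
      "unassigned"
    }
    start_t[i] <- min(n$t[rows]); end_t[i] <- max(n$t[rows])
    nfr[i] <- length(rows)
  }
  res <- data.frame(leaf_id = n$cell_id[leaf_rows], root_id = roots_of[leaf_rows],
                    seg_start_t = start_t, seg_end_t = end_t,
                    n_frames = nfr, fate = fate, stringsAsFactors = FALSE)
  class(res) <- c("fate_calls", "data.frame")
  res
}

# root cell id of the track containing each node (row-aligned)
track_roots <- function(forest) {
  n <- forest$nodes
  parent_row <- match(n$parent_id, n$cell_id)
  root <- seq_len(nrow(n))
  repeat {
    pr <- parent_row[root]
    has <- !is.na(pr)
    if (!any(has)) break
    root[has] <- pr[has]
  }
  n$cell_id[root]
}

#' Terminal-division fate classes and division histogram
#'
#' A terminal division is a division none of whose descendants divide again
#' within the observation window; its class comes from the fates of its two
#' daughter cells: `N/N` (both neural), `M/M` (both mesoderm), `N/M` (one of
#' each — a bi-fated neuromesodermal division), or `incomplete` when a
#' daughter is unassignable. Undivided tracks are reported mono-fated from
#' their single terminal cell. Also returns the divisions-per-track histogram.
#'
#' @param forest A [lineage_forest] (typically the selection subforest).
#' @param fates A `fate_calls` data frame from [classify_cell_fate()].
#' @return List with `divisions` (per terminal division: node, class, daughter
#'   fates), `class_counts`, `divisions_per_track` (named table over 0,1,...),
#'   and `undivided_fates` (fate table of never-dividing tracks).
#' @export
terminal_division_fates <- function(forest, fates) {
  n <- forest$nodes
  segs <- forest_segments(forest)
  pidx <- segs$parent_row
  is_div <- segs$n_children == 2
  roots_of <- track_roots(forest)
  all_roots <- unique(n$cell_id[is.na(n$parent_id)])
  div_count <- table(factor(roots_of[is_div], levels = all_roots))
  hist_tab <- table(factor(as.integer(div_count),
                           levels = 0:max(c(as.integer(div_count), 0))))
  # bottom-up sweep: does any strict descendant of a row divide?
  has_div_below <- logical(nrow(n))
  for (r in order(n$t, decreasing = TRUE)) {
    p <- pidx[r]
    if (!is.na(p)) {
      has_div_below[p] <- has_div_below[p] || is_div[r] || has_div_below[r]
    }
  }
  term_div_rows <- which(is_div & !has_div_below)
  # each child of a terminal division heads a segment ending in a leaf; map
  # segment id -> its leaf's fate call
  leaf_rows <- which(segs$n_children == 0)
  fate_by_seg <- stats::setNames(
    fates$fate[match(n$cell_id[leaf_rows], fates$leaf_id)],
    segs$seg_id[leaf_rows])
  child_rows <- split(which(!is.na(pidx)), pidx[!is.na(pidx)])
  div_list <- lapply(term_div_rows, function(d) {
    ch <- child_rows[[as.character(d)]]
    f1 <- unname(fate_by_seg[as.character(segs$seg_id[ch[1]])])
    f2 <- unname(fate_by_seg[as.character(segs$seg_id[ch[2]])])
    cls <- if (any(c(f1, f2) %in% c("unassigned", "endoderm_excluded"))) {
      "incomplete"
    } else if (f1 == "neural" && f2 == "neural") "N/N"
    else if (f1 == "mesoderm" && f2 == "mesoderm") "M/M"
    else "N/M"
    data.frame(division_id = n$cell_id[d], root_id = roots_of[d],
               fate1 = f1, fate2 = f2, class = cls, stringsAsFactors = FALSE)
  })
  divisions <- if (length(div_list)) do.call(rbind, div_list) else
    data.frame(division_id = integer(0), root_id = integer(0),
               fate1 = character(0), fate2 = character(0),
               class = character(0), stringsAsFactors = FALSE)
  class_counts <- table(factor(divisions$class,
                               levels = c("N/N", "M/M", "N/M", "incomplete")))
  undivided_roots <- all_roots[as.integer(div_count) == 0]
  undiv <- fates[fates$root_id %in% undivided_roots, , drop = FALSE]
  list(divisions = divisions, class_counts = class_counts,
       divisions_per_track = hist_tab,
       undivided_fates = table(undiv$fate))
}

#' Classify a photolabel from its fate counts
#'
#' A label is called `neural` when strictly more than `cutoff` (default 90%)
#' of its cells contribute to neural tissue, `mesoderm` when strictly more
#' than `cutoff` contribute to paraxial mesoderm, and `both` otherwise. The
#' inequality is strict ("over 90%"), so a 90/10 split is `both`. The call is
#' scale-invariant in the counts.
#'
#' @param neural_count,mesoderm_count Non-negative cell counts.
#' @param cutoff Fraction strictly required for a single-fate call; default 0.90.
#' @return One of `"neural"`, `"mesoderm"`, `"both"`.
#' @export
classify_label <- function(neural_count, mesoderm_count, cutoff = 0.90) {
  stopifnot(neural_count >= 0, mesoderm_count >= 0)
  tot <- neural_count + mesoderm_count
  if (tot == 0) stop("label with zero classified cells")
  if (neural_count / tot > cutoff) "neural"
  else if (mesoderm_count / tot > cutoff) "mesoderm"
  else "both"
}

norm3 <- function(v) {
  l <- sqrt(sum(v^2))
  if (l == 0) stop("zero-length vector")
  v / l
}

#' Polar placement of a photolabel on the embryo sphere
#'
#' The early embryo is approximated as a sphere about `embryo_center`. The
#' label position is reported as (i) the great-circle arc from the animal
#' pole, and (ii) the azimuth about the animal-vegetal axis measured from the
#' shield (dorsal) meridian, in degrees within `[-180, 180]`. A label at a
#' pole has undefined azimuth and is reported `NA` with a warning.
#'
#' @param label_center,animal_pole,shield_point,embryo_center 3D points (µm).
#' @return Named numeric vector `c(arc_from_AP =, angle_from_dorsal =)`.
#' @export
label_polar_position <- function(label_center, animal_pole, shield_point,
                                 embryo_center) {
  u_lab <- norm3(label_center - embryo_center)
  u_ap <- norm3(animal_pole - embryo_center)
  u_sh <- norm3(shield_point - embryo_center)
  arc <- acos(max(-1, min(1, sum(u_lab * u_ap)))) * 180 / pi
  lab_perp <- u_lab - sum(u_lab * u_ap) * u_ap
  sh_perp <- u_sh - sum(u_sh * u_ap) * u_ap
  if (sqrt(sum(lab_perp^2)) < 1e-9) {
    warning("label at a pole: azimuth undefined")
    return(c(arc_from_AP = arc, angle_from_dorsal = NA_real_))
  }
  if (sqrt(sum(sh_perp^2)) < 1e-9) stop("shield point lies on the AP axis")
  a <- norm3(sh_perp); b <- norm3(lab_perp)
  crossab <- c(a[2] * b[3] - a[3] * b[2],
               a[3] * b[1] - a[1] * b[3],
               a[1] * b[2] - a[2] * b[1])
  ang <- atan2(sum(crossab * u_ap), sum(a * b)) * 180 / pi
  c(arc_from_AP = arc, angle_from_dorsal = ang)
}

#' Per-segment anterior-posterior contribution histograms
#'
#' Counts labelled cells per somite-level segment, split by tissue compartment
#' (neural tube vs somitic mesoderm), and reports each compartment's occupied
#' axial span (e.g. somites 25th to 32nd).
#'
#' @param cells Data frame with columns `segment_index` (1-based somite
#'   number) and `compartment` (`"neural"` or `"somite"`).
#' @param n_segments Total number of segments along the axis.
#' @return List with `neural` and `somite` integer vectors (length
#'   `n_segments`) and `spans` (per-compartment `c(first, last)` or `NA`).
#' @export
ap_contribution <- function(cells, n_segments) {
  stopifnot(all(c("segment_index", "compartment") %in% names(cells)))
  if (nrow(cells) > 0 &&
      (any(cells$segment_index < 1) || any(cells$segment_index > n_segments))) {
    stop("segment_index out of range [1, ", n_segments, "]")
  }
  counts <- function(comp) {
    tabulate(cells$segment_index[cells$compartment == comp], nbins = n_segments)
  }
  neural <- counts("neural"); somite <- counts("somite")
  span <- function(v) if (any(v > 0)) range(which(v > 0)) else c(NA_integer_, NA_integer_)
  list(neural = neural, somite = somite,
       spans = list(neural = span(neural), somite = span(somite)))
}

#' Clone-number fold change between two stages
#'
#' @param n_t0 Labelled cell count at the first stage (> 0).
#' @param n_t1 Labelled cell count at the second stage.
#' @return `n_t1 / n_t0`.
#' @export
clone_fold_change <- function(n_t0, n_t1) {
  if (n_t0 <= 0) stop("fold change needs a positive starting count")
  n_t1 / n_t0
}

#' Retrospective zone-based fate assignment
#'
#' Assigns each track a fate from the anatomical zone containing its terminal
#' position (`neural`, `mesoderm`, or the `unassigned` sox2+/tbxta+
#' co-expression zone); positions outside all zones fall to `other` with a
#' warning. Fates are mapped back to the tracks' start positions, and a
#' spatial mixing summary is computed: for each classified track, the fraction
#' of its `k` nearest neighbours (by start position) sharing its fate — an
#' invented segregation statistic, reported as such, where 1 means fully
#' sorted.
#'
#' @param forest A [lineage_forest].
#' @param zone_masks Named list of region specs ([region_sphere()] /
#'   [region_box()]); expected names include `neural`, `mesoderm`,
#'   `unassigned`.
#' @param k Number of nearest start-position neighbours for the mixing
#'   summary; default 5.
#' @return List with `tracks` (root id, start position, terminal position,
#'   fate), `mixing` (per-fate mean neighbour-sharing fraction) and
#'   `fate_counts`.
#' @export
zone_assign <- function(forest, zone_masks, k = 5) {
  n <- forest$nodes
  segs <- forest_segments(forest)
  roots_of <- track_roots(forest)
  leaves <- which(segs$n_children == 0)
  root_row_of <- match(roots_of, n$cell_id)
  rows <- lapply(leaves, function(lr) {
    p <- c(n$x[lr], n$y[lr], n$z[lr])
    zone <- "other"
    for (nm in names(zone_masks)) {
      if (point_in_region(p, zone_masks[[nm]])) { zone <- nm; break }
    }
    root_row <- root_row_of[lr]
    data.frame(root_id = roots_of[lr], leaf_id = n$cell_id[lr],
               start_x = n$x[root_row], start_y = n$y[root_row],
               start_z = n$z[root_row],
               end_x = p[1], end_y = p[2], end_z = p[3],
               fate = zone, stringsAsFactors = FALSE)
  })
  tracks <- do.call(rbind, rows)
  if (any(tracks$fate == "other")) {
    warning(sum(tracks$fate == "other"),
            " track(s) terminate outside all zones; assigned 'other'")
  }
  classified <- tracks[tracks$fate %in% c("neural", "mesoderm"), , drop = FALSE]
  mixing <- NULL
  if (nrow(classified) > k) {
    P <- as.matrix(classified[, c("start_x", "start_y", "start_z")])
    Dm <- as.matrix(stats::dist(P))
    frac <- vapply(seq_len(nrow(classified)), function(i) {
      nb <- order(Dm[i, ])[2:(k + 1)]
      mean(classified$fate[nb] == classified$fate[i])
    }, numeric(1))
    mixing <- tapply(frac, classified$fate, mean)
  }
  list(tracks = tracks, mixing = mixing, fate_counts = table(tracks$fate))
}
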