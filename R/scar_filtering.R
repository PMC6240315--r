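# Four-stage scar filter: (1) sequencing-error fraction filter, (2) per-fish
# QC on unscarred-GFP and scar yield, (3) cross-fish rare-scar filter,
# (4) binarization. Scar sets are monotone non-increasing through the stages.

#' Create an empty filter report
#'
#' A `filter_report` accumulates one record per filter stage (scars and samples
#' in/out) plus per-fish QC metrics and blacklist hits, so that downstream code
#' can audit what each stage removed.
#'
#' @return An object of class `filter_report`.
#' @export
filter_report <- function() {
  structure(list(stages = data.frame(stage = character(), scars_in = integer(),
                                     scars_out = integer(), samples_in = integer(),
                                     samples_out = integer(), note = character(),
                                     stringsAsFactors = FALSE),
                 fish_qc = NULL, blacklist_hits = character()),
            class = "filter_report")
}

report_stage <- function(report, stage, scars_in, scars_out,
                         samples_in, samples_out, note = "") {
  stopifnot(scars_out <= scars_in, samples_out <= samples_in)
  report$stages <- rbind(report$stages, data.frame(
    stage = stage, scars_in = as.integer(scars_in), scars_out = as.integer(scars_out),
    samples_in = as.integer(samples_in), samples_out = as.integer(samples_out),
    note = note, stringsAsFactors = FALSE))
  report
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  print(x$stages, row.names = FALSE)
  if (!is.null(x$fish_qc)) {
    cat("fish QC:\n")
    print(x$fish_qc, row.names = FALSE)
  }
  invisible(x)
}

n_scar_cols <- function(m) sum(colnames(m) != GFP_UNSCARRED)

#' Remove low-fraction scars likely to be sequencing errors
#'
#' A scar observation is kept only when its within-sample fraction is at least
#' `factor` times the minimum detected scar fraction (boundary inclusive, so an
#' entry exactly at `factor * f_min` survives). `f_min` is the smallest nonzero
#' scar fraction over the chosen scope, by default all samples of each fish
#' (sequencing depth, and hence the detection floor, varies by fish). The
#' reserved unscarred-GFP column is exempt: it is QC, not a scar.
#'
#' @param fr A `scar_fractions` object (see [scar_fractions()]).
#' @param factor Multiplier on the minimum detected fraction; default 10.
#' @param fmin_scope Scope over which the minimum detected fraction is
#'   computed: `"fish"` (default), `"sample"` (per row) or `"global"`.
#' @param f_min Optional fixed detection floor. By default the floor is
#'   estimated from the data per `fmin_scope`; passing the previously
#'   estimated value makes the censoring map idempotent (re-estimating from
#'   already-filtered data would raise the floor).
#' @param report A `filter_report` to append to.
#' @return List with `fractions` (filtered `scar_fractions`, censored entries
#'   set to 0), `f_min` (the floor(s) used, named by group) and `report`.
#' @export
filter_low_fraction <- function(fr, factor = 10,
                                fmin_scope = c("fish", "sample", "global"),
                                f_min = NULL,
                                report = filter_report()) {
  stopifnot(inherits(fr, "scar_fractions"))
  fmin_scope <- match.arg(fmin_scope)
  f <- fr$fractions
  scar_cols <- colnames(f) != GFP_UNSCARRED
  fs <- f[, scar_cols, drop = FALSE]
  if (all(fs == 0)) stop("no detected scars: all scar fractions are zero")

  fmin_of <- function(m) {
    nz <- m[m > 0]
    if (!length(nz)) NA_real_ else min(nz)
  }
  thresh <- matrix(NA_real_, nrow(fs), ncol(fs))
  fmin_used <- NULL
  if (!is.null(f_min)) {
    thresh[] <- factor * f_min
    fmin_used <- c(fixed = f_min)
  } else if (fmin_scope == "global") {
    fmin_used <- c(global = fmin_of(fs))
    thresh[] <- factor * fmin_used
  } else if (fmin_scope == "sample") {
    fmin_used <- vapply(seq_len(nrow(fs)),
                        function(i) fmin_of(fs[i, , drop = FALSE]), numeric(1))
    names(fmin_used) <- rownames(fs)
    thresh[] <- factor * fmin_used
  } else {
    grp <- fr$sample_meta$fish_id
    fmin_used <- stats::setNames(numeric(0), character(0))
    for (g in unique(grp)) {
      rows <- grp == g
      fm <- fmin_of(fs[rows, , drop = FALSE])
      fmin_used[g] <- fm
      thresh[rows, ] <- factor * fm
    }
  }
  keep <- !is.na(thresh) & fs >= thresh
  n_in <- sum(fs > 0)
  fs[!keep] <- 0
  all_equal_note <- if (all(thresh > 0, na.rm = TRUE) && sum(fs > 0) == 0 && n_in > 0)
    "pathological input: every scar entry below factor x f_min" else ""
  f[, scar_cols] <- fs
  out <- structure(list(fractions = f, sample_meta = fr$sample_meta),
                   class = "scar_fractions")
  report <- report_stage(report, "low_fraction",
                         scars_in = sum(colSums(fr$fractions[, scar_cols, drop = FALSE] > 0) > 0),
                         scars_out = sum(colSums(fs > 0) > 0),
                         samples_in = nrow(f), samples_out = nrow(f),
                         note = all_equal_note)
  list(fractions = out, f_min = fmin_used, report = report)
}

#' Apply the low-fraction filter to a count table
#'
#' Convenience wrapper: computes fractions, applies [filter_low_fraction()] and
#' zeroes the corresponding count entries, so the remaining pipeline can keep
#' working in count space.
#'
#' @inheritParams filter_low_fraction
#' @param table A `scar_table`.
#' @return List with `table` (counts censored) and `report`.
#' @export
apply_fraction_filter <- function(table, factor = 10,
                                  fmin_scope = "fish",
                                  report = filter_report()) {
  fr <- scar_fractions(table)
  res <- filter_low_fraction(fr, factor = factor, fmin_scope = fmin_scope,
                             report = report)
  counts <- table$counts
  counts[res$fractions$fractions == 0 & counts > 0] <- 0
  counts[, GFP_UNSCARRED] <- table$counts[, GFP_UNSCARRED]
  out <- scar_table(counts, table$sample_meta, provenance = table$provenance)
  list(table = out, report = res$report)
}

#' Per-fish quality control on scarring efficiency
#'
#' A fish passes QC only if its mean unscarred-GFP percentage across organs is
#' strictly below `max_unscarred` and it carries strictly more than
#' `min_scars` distinct surviving scars (both inequalities strict, as the
#' thresholds are printed: "less than 50%", "more than 100 scars").
#'
#' @param tables Named list of merged, fraction-filtered `scar_table`s, one per
#'   fish (names = fish ids).
#' @param max_unscarred Maximum mean unscarred-GFP percentage (exclusive);
#'   default 50.
#' @param min_scars Minimum number of distinct surviving scars (exclusive);
#'   default 100.
#' @param report A `filter_report` to append to.
#' @return List with `kept` (character vector of fish ids), `metrics` (per-fish
#'   data frame) and `report`.
#' @export
fish_qc <- function(tables, max_unscarred = 50, min_scars = 100,
                    report = filter_report()) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  metrics <- do.call(rbind, lapply(names(tables), function(fish) {
    tab <- tables[[fish]]
    if (nrow(tab$counts) == 0) {
      warning("fish '", fish, "' has zero organs; dropped")
      return(data.frame(fish_id = fish, mean_unscarred_pct = NA_real_,
                        n_scars_after_filter = 0L, kept = FALSE,
                        stringsAsFactors = FALSE))
    }
    fr <- scar_fractions(tab)
    unscarred_pct <- 100 * fr$fractions[, GFP_UNSCARRED]
    scars <- tab$counts[, colnames(tab$counts) != GFP_UNSCARRED, drop = FALSE]
    n_scars <- sum(colSums(scars) > 0)
    mean_pct <- mean(unscarred_pct)
    data.frame(fish_id = fish, mean_unscarred_pct = mean_pct,
               n_scars_after_filter = n_scars,
               kept = (mean_pct < max_unscarred) && (n_scars > min_scars),
               stringsAsFactors = FALSE)
  }))
  report$fish_qc <- metrics
  report <- report_stage(report, "fish_qc",
                         scars_in = length(tables), scars_out = sum(metrics$kept),
                         samples_in = length(tables), samples_out = sum(metrics$kept),
                         note = "counts here are fish, not scars/samples")
  list(kept = metrics$fish_id[metrics$kept], metrics = metrics, report = report)
}

#' Cross-fish rare-scar filter
#'
#' Scars created independently in more than one embryo are not clone-specific;
#' to keep only rare scars (creation probability on the order of 1e-5), any
#' scar detected (count > 0) in two or more fish is removed from every fish,
#' as is any scar on the user-supplied blacklist (e.g. scars seen in external
#' experiments). The unscarred-GFP column is exempt.
#'
#' @param fish_tables Named list of `scar_table`s, one per fish.
#' @param blacklist Character vector of scar ids to remove unconditionally.
#' @param report A `filter_report` to append to.
#' @return List with `tables` (same structure, shared/blacklisted scar columns
#'   dropped) and `report`.
#' @export
filter_shared_scars <- function(fish_tables, blacklist = character(),
                                report = filter_report()) {
  stopifnot(is.list(fish_tables), length(fish_tables) >= 1)
  all_scars <- unique(unlist(lapply(fish_tables, function(t)
    setdiff(colnames(t$counts), GFP_UNSCARRED))))
  support <- vapply(all_scars, function(s) {
    sum(vapply(fish_tables, function(t) {
      s %in% colnames(t$counts) && any(t$counts[, s] > 0)
    }, logical(1)))
  }, integer(1))
  shared <- all_scars[support >= 2]
  hits <- intersect(all_scars, blacklist)
  drop <- union(shared, hits)
  out <- lapply(fish_tables, function(t) {
    keep <- !(colnames(t$counts) %in% drop)
    scar_table(t$counts[, keep, drop = FALSE], t$sample_meta, t$provenance)
  })
  report$blacklist_hits <- hits
  report <- report_stage(report, "shared_scars",
                         scars_in = length(all_scars),
                         scars_out = length(all_scars) - length(drop),
                         samples_in = sum(vapply(fish_tables, function(t) nrow(t$counts), integer(1))),
                         samples_out = sum(vapply(out, function(t) nrow(t$counts), integer(1))),
                         note = sprintf("%d shared, %d blacklisted", length(shared), length(hits)))
  list(tables = out, report = report)
}

#' Binarize a filtered scar table
#'
#' Final processing step: presence/absence of each surviving scar per merged
#' sample. The unscarred-GFP column is dropped (QC only, not a clone marker)
#' and all-zero scar columns are removed with a warning.
#'
#' @param table A filtered `scar_table`.
#' @return An object of class `binary_scar_matrix`: list with `presence`
#'   (0/1 matrix, rows = samples, columns = surviving scars) and `sample_meta`.
#' @export
binarize <- function(table) {
  validate_scar_table(table)
  counts <- table$counts[, colnames(table$counts) != GFP_UNSCARRED, drop = FALSE]
  pres <- (counts > 0) * 1
  empty <- colSums(pres) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " all-zero scar column(s) at binarization")
    pres <- pres[, !empty, drop = FALSE]
  }
  structure(list(presence = pres, sample_meta = table$sample_meta),
            class = "binary_scar_matrix")
}

#' @export
print.binary_scar_matrix <- function(x, ...) {
  cat("binary_scar_matrix: ", nrow(x$presence), " samples x ",
      ncol(x$presence), " scars\n", sep = "")
  invisible(x)
}

#' Run the full scar filter chain
#'
#' Convenience driver for the standard order of operations: per-fish
#' low-fraction filter, per-fish QC, cross-fish rare-scar filter, summation of
#' technical replicates, binarization. Replicates are merged late, after all
#' scar-level filters, so the detection floor is computed on the replicate-level
#' fractions actually sequenced.
#'
#' @param tables Named list of raw `scar_table`s, one per fish.
#' @param factor Low-fraction filter multiplier (default 10).
#' @param max_unscarred,min_scars Fish QC thresholds (defaults 50, 100).
#' @param blacklist Scar-id blacklist for [filter_shared_scars()].
#' @param fmin_scope Scope for the detection floor, see [filter_low_fraction()].
#' @return List with `binary` (named list of `binary_scar_matrix`, kept fish
#'   only), `tables` (filtered count tables), `kept_fish` and `report`.
#' @export
filter_scar_pipeline <- function(tables, factor = 10, max_unscarred = 50,
                                 min_scars = 100, blacklist = character(),
                                 fmin_scope = "fish") {
  report <- filter_report()
  filtered <- list()
  for (fish in names(tables)) {
    res <- apply_fraction_filter(tables[[fish]], factor = factor,
                                 fmin_scope = fmin_scope, report = report)
    filtered[[fish]] <- res$table
    report <- res$report
  }
  qc <- fish_qc(filtered, max_unscarred = max_unscarred, min_scars = min_scars,
                report = report)
  report <- qc$report
  kept <- filtered[qc$kept]
  if (length(kept) == 0) {
    return(list(binary = list(), tables = list(), kept_fish = character(),
                report = report))
  }
  shared <- filter_shared_scars(kept, blacklist = blacklist, report = report)
  report <- shared$report
  merged <- lapply(shared$tables, merge_replicates)
  binary <- lapply(merged, binarize)
  list(binary = binary, tables = merged, kept_fish = qc$kept,
       report = report)
}
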