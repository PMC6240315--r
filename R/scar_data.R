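#' @keywords internal
"_PACKAGE"

# Reserved column holding reads from unedited GFP target copies. It is a QC
# quantity (scarring efficiency per organ), not a clone marker, and is treated
# specially throughout the filter chain.
GFP_UNSCARRED <- "GFP_unscarred"

META_COLS <- c("sample_id", "fish_id", "organ", "axis_position", "replicate_id")

#' Construct a scar count table
#'
#' A `scar_table` holds per-sample read counts for CRISPR scars amplified from
#' dissected body structures, together with the sample metadata needed by the
#' clonal analysis (fish of origin, organ, position along the body axis,
#' technical replicate). Scar identifiers are opaque strings of the form
#' `"position:indel-signature"`; one reserved column, `"GFP_unscarred"`, counts
#' reads from unedited GFP target copies and is used only for per-fish QC.
#'
#' @param counts Non-negative integer matrix, rows = samples, columns = scars.
#'   Must contain exactly one `"GFP_unscarred"` column.
#' @param sample_meta Data frame with one row per sample and columns
#'   `sample_id`, `fish_id`, `organ`, `axis_position` (one of `"head"`,
#'   `"mid"`, `"tail"` or `NA`) and `replicate_id`.
#' @param provenance Free-text provenance string.
#'
#' @return An object of class `scar_table` with elements `counts`,
#'   `sample_meta` and `provenance`.
#' @export
scar_table <- function(counts, sample_meta, provenance = "") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  for (col in META_COLS) {
    if (!col %in% names(sample_meta)) {
      if (col == "axis_position" || col == "replicate_id") {
        sample_meta[[col]] <- NA_character_
      } else {
        stop("sample_meta lacks required column '", col, "'")
      }
    }
  }
  rownames(counts) <- sample_meta$sample_id
  obj <- structure(
    list(counts = counts, sample_meta = sample_meta,
         provenance = as.character(provenance)),
    class = "scar_table"
  )
  validate_scar_table(obj)
  obj
}

#' Validate a scar table
#'
#' Checks the structural invariants: all counts non-negative integers, unique
#' sample ids, exactly one reserved `"GFP_unscarred"` column, and fish/organ
#' metadata present for every sample.
#'
#' @param x A `scar_table`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_scar_table <- function(x) {
  stopifnot(inherits(x, "scar_table"))
  counts <- x$counts
  meta <- x$sample_meta
  if (nrow(counts) != nrow(meta)) {
    stop("counts and sample_meta disagree on the number of samples")
  }
  n_gfp <- sum(colnames(counts) == GFP_UNSCARRED)
  if (n_gfp != 1L) {
    stop("reserved column missing: expected exactly one '", GFP_UNSCARRED,
         "' column, found ", n_gfp)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  bad <- which(counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("negative or non-integer count at row '", rownames(counts)[bad[1, 1]],
         "', column '", colnames(counts)[bad[1, 2]], "'")
  }
  if (anyNA(meta$fish_id) || anyNA(meta$organ)) {
    stop("every sample needs fish_id and organ metadata")
  }
  invisible(x)
}

#' @export
print.scar_table <- function(x, ...) {
  cat("scar_table: ", nrow(x$counts), " samples x ", ncol(x$counts) - 1L,
      " scars (+", GFP_UNSCARRED, ")\n", sep = "")
  cat("  fish: ", paste(unique(x$sample_meta$fish_id), collapse = ", "), "\n", sep = "")
  cat("  organs: ", paste(unique(x$sample_meta$organ), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read a scar count table from TSV
#'
#' The TSV dialect is tab-separated UTF-8 with a header row: the metadata
#' columns `sample_id`, `fish_id`, `organ`, `axis_position`, `replicate_id`
#' precede the scar count columns. Unknown leading metadata columns are
#' preserved in the `provenance` field.
#'
#' @param path Path to a TSV file.
#' @return A validated [scar_table].
#' @export
read_scar_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta_present <- intersect(META_COLS, names(df))
  if (!all(c("sample_id", "fish_id", "organ") %in% meta_present)) {
    stop("TSV must carry sample_id, fish_id and organ columns")
  }
  # any non-count, non-standard columns before the first scar column are kept
  # as provenance text rather than silently dropped
  scar_cols <- setdiff(names(df), META_COLS)
  is_count <- vapply(df[scar_cols], is.numeric, logical(1))
  extra <- scar_cols[!is_count]
  scar_cols <- scar_cols[is_count]
  counts <- as.matrix(df[, scar_cols, drop = FALSE])
  meta <- df[, meta_present, drop = FALSE]
  prov <- if (length(extra)) {
    paste0("extra columns: ", paste(extra, collapse = ","))
  } else ""
  scar_table(counts, meta, provenance = prov)
}

#' Write a scar table to TSV
#'
#' Inverse of [read_scar_table()]: metadata columns first, then scar counts.
#'
#' @param x A `scar_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scar_table <- function(x, path) {
  validate_scar_table(x)
  df <- cbind(x$sample_meta[, META_COLS, drop = FALSE],
              as.data.frame(x$counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sum technical replicates of the same dissected body structure
#'
#' Rows sharing the merge key `(fish_id, organ, axis_position)` are summed
#' element-wise, mirroring the summation of technical replicas of the same
#' dissected structure; the grand total of every scar column is conserved.
#' After merging, `replicate_id` is cleared and `sample_id` becomes
#' `fish.organ[.axis]`.
#'
#' @param x A `scar_table`.
#' @return A `scar_table` with one row per merge key.
#' @export
merge_replicates <- function(x) {
  validate_scar_table(x)
  meta <- x$sample_meta
  axis <- ifelse(is.na(meta$axis_position), "", as.character(meta$axis_position))
  key <- paste(meta$fish_id, meta$organ, axis, sep = "\r")
  # one sample_id mapping to several organs would silently merge different
  # structures; refuse
  for (sid in unique(meta$sample_id)) {
    orgs <- unique(meta$organ[meta$sample_id == sid])
    if (length(orgs) > 1) {
      stop("sample_id '", sid, "' carries conflicting organ labels: ",
           paste(orgs, collapse = ", "))
    }
  }
  keys <- unique(key)
  counts <- rowsum(x$counts, group = factor(key, levels = keys), reorder = FALSE)
  first <- match(keys, key)
  new_meta <- meta[first, , drop = FALSE]
  new_meta$replicate_id <- NA_character_
  new_meta$sample_id <- ifelse(
    axis[first] == "",
    paste(new_meta$fish_id, new_meta$organ, sep = "."),
    paste(new_meta$fish_id, new_meta$organ, axis[first], sep = ".")
  )
  rownames(new_meta) <- NULL
  scar_table(counts, new_meta, provenance = x$provenance)
}

#' Per-sample scar fractions
#'
#' Normalizes each sample's counts by its row total, the exact-fraction
#' analogue of expressing scar percentages in a normalized histogram. Rows with
#' zero total yield all-zero fractions with a warning.
#'
#' @param x A `scar_table`.
#' @return An object of class `scar_fractions`: list with `fractions` (matrix
#'   in `[0,1]`, same shape and labels as the counts) and `sample_meta`.
#' @export
scar_fractions <- function(x) {
  validate_scar_table(x)
  totals <- rowSums(x$counts)
  if (any(totals == 0)) {
    warning("samples with zero total count yield all-zero fractions: ",
            paste(rownames(x$counts)[totals == 0], collapse = ", "))
  }
  denom <- ifelse(totals == 0, 1, totals)
  fr <- x$counts / denom
  structure(list(fractions = fr, sample_meta = x$sample_meta),
            class = "scar_fractions")
}

#' @export
print.scar_fractions <- function(x, ...) {
  cat("scar_fractions: ", nrow(x$fractions), " samples x ",
      ncol(x$fractions), " columns\n", sep = "")
  invisible(x)
}
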