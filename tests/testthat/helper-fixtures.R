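# Fixtures built in code: small scar tables, random forests, toy volumes.

make_scar_table <- function(counts, fish = "f1", organs = NULL,
                            replicates = NULL) {
  n <- nrow(counts)
  if (is.null(organs)) organs <- paste0("organ", seq_len(n))
  if (is.null(replicates)) replicates <- rep(NA_character_, n)
  if (!GFP_col() %in% colnames(counts)) {
    counts <- cbind(counts, GFP_unscarred = rep(10L, n))
  }
  meta <- data.frame(
    sample_id = paste0(fish, ".", organs,
                       ifelse(is.na(replicates), "", paste0(".", replicates))),
    fish_id = fish, organ = organs, axis_position = NA_character_,
    replicate_id = replicates, stringsAsFactors = FALSE)
  scar_table(counts, meta)
}

GFP_col <- function() "GFP_unscarred"

random_scar_table <- function(n_samples, n_scars, fish = "f1", seed = 1,
                              max_count = 50) {
  set.seed(seed)
  counts <- matrix(rpois(n_samples * n_scars, 2), n_samples, n_scars)
  colnames(counts) <- paste0(seq_len(n_scars), ":d", seq_len(n_scars))
  counts <- cbind(counts, GFP_unscarred = rpois(n_samples, max_count) + 1L)
  make_scar_table(counts, fish = fish)
}

# small random forest: n roots, each a chain, some with one division
random_forest <- function(n_roots = 5, n_frames = 6, p_divide = 0.4, seed = 1) {
  set.seed(seed)
  rows <- list(); oid <- 0L
  for (r in seq_len(n_roots)) {
    prev <- NA_integer_
    div_at <- if (runif(1) < p_divide) sample(2:(n_frames - 1), 1) else Inf
    branches <- list(list(prev = NA_integer_, pos = runif(3, 0, 50)))
    for (t in seq_len(n_frames) - 1L) {
      nb <- list()
      for (br in branches) {
        oid <- oid + 1L
        pos <- br$pos + rnorm(3, 0, 0.5)
        rows[[oid]] <- data.frame(cell_id = oid, parent_id = br$prev, t = t,
                                  x = pos[1], y = pos[2], z = pos[3],
                                  mezzo = 10, sox17 = 10)
        if (t == div_at) {
          nb <- c(nb, list(list(prev = oid, pos = pos), list(prev = oid, pos = pos)))
        } else {
          nb <- c(nb, list(list(prev = oid, pos = pos)))
        }
      }
      branches <- nb
    }
  }
  lineage_forest(do.call(rbind, rows))
}

# binary matrix where samples s1,s2 share `n_shared` private scars and all
# other samples carry independent noise scars
engineered_cherry_matrix <- function(n_other = 4, n_shared = 50,
                                     n_noise = 30, seed = 1) {
  set.seed(seed)
  n <- 2 + n_other
  shared <- matrix(0, n, n_shared)
  shared[1:2, ] <- 1
  noise <- matrix(0, n, n_noise * n_other)
  for (i in seq_len(n_other)) {
    noise[2 + i, (i - 1) * n_noise + seq_len(n_noise)] <- 1
  }
  B <- cbind(shared, noise)
  rownames(B) <- c("s1", "s2", paste0("o", seq_len(n_other)))
  colnames(B) <- paste0("scar", seq_len(ncol(B)))
  B
}
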