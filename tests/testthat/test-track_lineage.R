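toy_forest <- function() {
  # one root dividing at t=1 into two daughters tracked to t=3, plus one
  # undivided bystander
  nodes <- data.frame(
    cell_id = 1:10,
    parent_id = c(NA, 1, 2, 2, 3, 4, NA, 7, 8, 9),
    t = c(0, 1, 2, 2, 3, 3, 0, 1, 2, 3),
    x = c(0, 0, -1, 1, -1, 1, 10, 10, 10, 10),
    y = 0, z = 0,
    mezzo = c(10, 10, 10, 80, 10, 80, 10, 10, 10, 10),
    sox17 = 10)
  lineage_forest(nodes)
}

test_that("lineage_forest rejects structural violations", {
  n <- data.frame(cell_id = 1:3, parent_id = c(NA, 1, 1), t = c(0, 1, 1),
                  x = 0, y = 0, z = 0)
  expect_s3_class(lineage_forest(n), "lineage_forest")
  n3 <- rbind(n, data.frame(cell_id = 4, parent_id = 1, t = 1, x = 0, y = 0, z = 0))
  expect_error(lineage_forest(n3), "more than 2 children")
  nt <- data.frame(cell_id = 1:2, parent_id = c(NA, 1), t = c(1, 1),
                   x = 0, y = 0, z = 0)
  expect_error(lineage_forest(nt), "precede")
  nd <- data.frame(cell_id = c(1, 1), parent_id = NA, t = 0:1, x = 0, y = 0, z = 0)
  expect_error(lineage_forest(nd), "unique")
})

test_that("TGMM XML round trip preserves topology and coordinates", {
  fo <- toy_forest()
  dir <- withr::local_tempdir()
  write_tgmm(fo, dir, voxel_size = c(0.5, 0.5, 2))
  back <- read_tgmm(dir, voxel_size = c(0.5, 0.5, 2))
  expect_equal(nrow(back$nodes), nrow(fo$nodes))
  # same division structure: one node with two children
  kid_counts <- table(back$nodes$parent_id)
  expect_equal(sum(kid_counts == 2), 1)
  expect_equal(sort(back$nodes$x), sort(fo$nodes$x), tolerance = 1e-9)
  expect_equal(sort(back$nodes$t), sort(fo$nodes$t))
  expect_true(all(c("mezzo", "sox17") %in% back$channels))

  # CSV round trip is exact
  f <- withr::local_tempfile(fileext = ".csv")
  write_tracks_csv(fo, f)
  back2 <- read_tracks_csv(f)
  expect_equal(back2$nodes, fo$nodes)
})

test_that("orphan parents are reported and become new roots", {
  dir <- withr::local_tempdir()
  writeLines('<document><GaussianMixtureModel id="0" lineage="0" parent="-1" m="1 1 1"/></document>',
             file.path(dir, "f0000.xml"))
  writeLines('<document><GaussianMixtureModel id="0" lineage="0" parent="5" m="2 2 2"/></document>',
             file.path(dir, "f0001.xml"))
  expect_warning(fo <- read_tgmm(dir), "orphan")
  expect_equal(sum(is.na(fo$nodes$parent_id)), 2)

  dir2 <- withr::local_tempdir()
  writeLines('<document><GaussianMixtureModel id="0" lineage="0" parent="-1" m="1 1 1"/><GaussianMixtureModel id="0" lineage="0" parent="-1" m="2 2 2"/></document>',
             file.path(dir2, "f0000.xml"))
  expect_error(read_tgmm(dir2), "duplicate ids")
})

test_that("clone selection takes region, viewpoint and exact closure", {
  fo <- toy_forest()
  sel <- select_clone(fo, region_sphere(c(0, 0, 0), 2), t0 = 0)
  expect_equal(sel$roots, 1L)
  expect_setequal(sel$nodes$cell_id, 1:6)

  selbox <- select_clone(fo, region_box(c(-5, -5, -5), c(15, 5, 5)), t0 = 0)
  expect_setequal(selbox$roots, c(1L, 7L))

  # far-side elimination by viewer half-space
  selv <- select_clone(fo, region_box(c(-5, -5, -5), c(15, 5, 5)), t0 = 0,
                       viewpoint = list(point = c(5, 0, 0), normal = c(1, 0, 0)))
  expect_equal(selv$roots, 7L)

  expect_warning(sel0 <- select_clone(fo, region_sphere(c(99, 99, 99), 1), t0 = 0),
                 "empty")
  expect_length(sel0$roots, 0)
})

test_that("descendant closure equals igraph reachability on random forests", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    fo <- random_forest(n_roots = 6, n_frames = 5, seed = seed)
    n <- fo$nodes
    t0_cells <- n[n$t == 0, ]
    region <- region_sphere(c(t0_cells$x[1], t0_cells$y[1], t0_cells$z[1]), 20)
    sel <- suppressWarnings(select_clone(fo, region, t0 = 0))
    g <- igraph::graph_from_data_frame(
      data.frame(from = n$parent_id[!is.na(n$parent_id)],
                 to = n$cell_id[!is.na(n$parent_id)]),
      vertices = data.frame(name = n$cell_id))
    want <- unique(unlist(lapply(sel$roots, function(r)
      as.integer(names(igraph::subcomponent(g, as.character(r), mode = "out"))))))
    expect_setequal(sel$nodes$cell_id, want)
  }
})

test_that("reporter rules classify terminal cells as specified", {
  rules <- list(mezzo_threshold = 50, sox17_threshold = 50, k_frames = 3)
  mk <- function(mezzo, sox = rep(10, length(mezzo)), t_end_pad = 0) {
    n <- length(mezzo)
    lineage_forest(data.frame(cell_id = 1:n, parent_id = c(NA, 1:(n - 1)),
                              t = 0:(n - 1), x = 0, y = 0, z = 0,
                              mezzo = mezzo, sox17 = sox))
  }
  # stable rise above threshold -> mesoderm
  expect_equal(classify_cell_fate(mk(c(10, 10, 60, 70, 80)), rules)$fate, "mesoderm")
  # flat negative reaching movie end -> neural
  expect_equal(classify_cell_fate(mk(rep(10, 5)), rules)$fate, "neural")
  # single-frame spike rejected with k_frames = 3
  expect_equal(classify_cell_fate(mk(c(10, 10, 90, 10, 10)), rules)$fate, "neural")
  # sustained endoderm reporter wins over mezzo
  expect_equal(classify_cell_fate(mk(rep(80, 5), sox = rep(80, 5)), rules)$fate,
               "endoderm_excluded")
  # track lost before movie end with no reporter evidence -> unassigned
  fo <- mk(rep(10, 3))
  fo$nodes <- rbind(fo$nodes,
                    data.frame(cell_id = 4, parent_id = NA, t = 4,
                               x = 0, y = 0, z = 0, mezzo = 10, sox17 = 10))
  fo2 <- lineage_forest(fo$nodes)
  calls <- classify_cell_fate(fo2, rules)
  expect_equal(calls$fate[calls$leaf_id == 3], "unassigned")
  # missing channel is an error
  bad <- mk(rep(10, 4)); bad$channels <- "sox17"
  expect_error(classify_cell_fate(bad, rules), "missing channel")
})

test_that("terminal divisions are scored from daughter fates", {
  fo <- toy_forest()
  rules <- list(mezzo_threshold = 50, sox17_threshold = 50, k_frames = 2)
  fates <- classify_cell_fate(fo, rules)
  td <- terminal_division_fates(fo, fates)
  expect_equal(nrow(td$divisions), 1)
  expect_equal(td$divisions$class, "N/M")
  expect_equal(unname(td$class_counts[["N/M"]]), 1)
  # divisions-per-track histogram: one root with 1 division, one with 0
  expect_equal(as.integer(td$divisions_per_track), c(1, 1))
  # the undivided bystander is mono-fated neural
  expect_equal(unname(td$undivided_fates[["neural"]]), 1)

  # in a chain of two divisions only the last is terminal
  nodes <- data.frame(
    cell_id = 1:7,
    parent_id = c(NA, 1, 1, 2, 2, 4, 5),
    t = c(0, 1, 1, 2, 2, 3, 3),
    x = 0, y = 0, z = 0,
    mezzo = c(10, 10, 10, 10, 10, 10, 10), sox17 = 10)
  fo2 <- lineage_forest(nodes)
  fates2 <- classify_cell_fate(fo2, rules)
  td2 <- terminal_division_fates(fo2, fates2)
  expect_equal(sort(td2$divisions$division_id), 2)
  # one root, two divisions: histogram bins 0,1,2 read (0,0,1)
  expect_equal(as.integer(td2$divisions_per_track), c(0, 0, 1))
  expect_equal(names(td2$divisions_per_track)[td2$divisions_per_track == 1], "2")
})

test_that("bookkeeping conserves roots across division classes", {
  for (seed in 1:5) {
    p <- track_sim_params(n_cells = 60, track_loss_prob = 0,
                          division_rate = c(N = 0.02, M = 0.02, NM = 0.02, endo = 0.02))
    sim <- simulate_forest(p, seed = seed)
    thr <- 55
    fates <- classify_cell_fate(sim$forest,
                                list(mezzo_threshold = thr, sox17_threshold = thr))
    td <- terminal_division_fates(sim$forest, fates)
    n_roots <- sum(is.na(sim$forest$nodes$parent_id))
    accounted <- nrow(td$divisions) + sum(td$undivided_fates)
    expect_equal(accounted, n_roots)
  }
})

test_that("the 90% label rule is strict and scale-invariant", {
  expect_equal(classify_label(95, 5), "neural")
  expect_equal(classify_label(9, 91), "mesoderm")
  expect_equal(classify_label(50, 50), "both")
  expect_equal(classify_label(90, 10), "both")       # strict "over 90%"
  expect_equal(classify_label(900, 100), "both")     # scale invariance
  expect_equal(classify_label(950, 50), "neural")
  expect_error(classify_label(0, 0), "zero")
})

test_that("polar label placement handles poles, meridian and antipode", {
  ctr <- c(0, 0, 0); ap <- c(0, 0, 10); shield <- c(10, 0, 0)
  expect_warning(res <- label_polar_position(c(0, 0, 10), ap, shield, ctr),
                 "pole")
  expect_equal(unname(res["arc_from_AP"]), 0)
  expect_true(is.na(res["angle_from_dorsal"]))

  on_meridian <- label_polar_position(c(5, 0, 5), ap, shield, ctr)
  expect_equal(unname(on_meridian["angle_from_dorsal"]), 0)
  expect_equal(unname(on_meridian["arc_from_AP"]), 45)

  anti <- label_polar_position(c(-7, 0, 0), ap, shield, ctr)
  expect_equal(abs(unname(anti["angle_from_dorsal"])), 180)
})

test_that("AP contribution histograms count and span correctly", {
  cells <- data.frame(
    segment_index = c(25:31, 23:31),
    compartment = c(rep("somite", 7), rep("neural", 9)))
  h <- ap_contribution(cells, n_segments = 32)
  expect_equal(sum(h$somite), 7)
  expect_equal(sum(h$neural), 9)
  expect_equal(h$spans$somite, c(25, 31))
  expect_equal(h$spans$neural, c(23, 31))

  h0 <- ap_contribution(cells[0, ], n_segments = 10)
  expect_equal(sum(h0$neural) + sum(h0$somite), 0)
  expect_true(all(is.na(h0$spans$neural)))
  expect_error(ap_contribution(data.frame(segment_index = 40,
                                          compartment = "neural"), 32),
               "out of range")
})

test_that("clone fold change is a guarded ratio", {
  expect_equal(clone_fold_change(10, 20), 2)
  expect_equal(clone_fold_change(10, 10), 1)
  expect_error(clone_fold_change(0, 5), "positive")
})

test_that("zone assignment scores terminal positions and spatial sorting", {
  # two roots ending in different zones
  nodes <- data.frame(cell_id = 1:4, parent_id = c(NA, 1, NA, 3),
                      t = c(0, 1, 0, 1),
                      x = c(0, 0, 10, 10), y = 0, z = 0,
                      mezzo = 10, sox17 = 10)
  fo <- lineage_forest(nodes)
  zones <- list(neural = region_box(c(-5, -5, -5), c(5, 5, 5)),
                mesoderm = region_box(c(6, -5, -5), c(15, 5, 5)))
  za <- zone_assign(fo, zones, k = 1)
  expect_equal(sort(za$tracks$fate), c("mesoderm", "neural"))

  # the sox2+tbxta co-expression zone maps to 'unassigned'
  zones2 <- list(unassigned = region_box(c(-5, -5, -5), c(5, 5, 5)),
                 mesoderm = region_box(c(6, -5, -5), c(15, 5, 5)))
  za2 <- zone_assign(fo, zones2, k = 1)
  expect_true("unassigned" %in% za2$tracks$fate)

  # a terminal position outside all zones warns and falls to 'other'
  zones3 <- list(neural = region_box(c(-5, -5, -5), c(5, 5, 5)))
  expect_warning(za3 <- zone_assign(fo, zones3, k = 1), "outside")
  expect_true("other" %in% za3$tracks$fate)

  # fully sorted start layout: every neighbour shares the fate
  p <- track_sim_params(n_cells = 40, layout = "sorted",
                        fate_probs = c(N = 0.5, M = 0.5, NM = 0, endo = 0),
                        division_rate = c(N = 0, M = 0, NM = 0, endo = 0),
                        drift = c(0, 0, 0), brownian_sd = 0.01,
                        track_loss_prob = 0)
  sim <- simulate_forest(p, seed = 2)
  truth <- sim$truth$cells
  ends <- sim$forest$nodes[sim$forest$nodes$t == max(sim$forest$nodes$t), ]
  xs <- ends$x[order(ends$cell_id)]
  cut <- mean(range(xs))
  zones4 <- list(neural = region_box(c(-1e3, -1e3, -1e3), c(1e3, 1e3, cut)),
                 mesoderm = region_box(c(-1e3, -1e3, cut), c(1e3, 1e3, 1e3)))
  # zones keyed on x by rotating coordinates: use x as z for the box test
  fo4 <- sim$forest
  fo4$nodes$z <- fo4$nodes$x
  za4 <- zone_assign(fo4, zones4, k = 3)
  expect_true(all(unlist(za4$mixing) > 0.9))
})
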