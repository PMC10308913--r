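glucose_macro_net <- function() macro_network(glucose_macro_reactions(),
                                              substrates = c(glucose = 1))

test_that("EFM yields reproduce the packaged macroscopic coefficients", {
  mn <- glucose_macro_net()
  efms <- enumerate_efms(mn, substrate_id = "glucose[e]")
  expect_equal(n_efms(efms), 9L) # one mode per macroscopic reaction
  # biomass[e] in this network is already g/mmol: no molar conversion
  yt <- efm_yields(efms, mn, "glucose[e]")
  ac <- sort(yt[["acetate[e]"]], decreasing = TRUE)
  expect_equal(ac[1], 2.623, tolerance = 1e-9)
  e2row <- yt[abs(yt[["acetate[e]"]] - 2.623) < 1e-9, ]
  expect_equal(e2row[["biomass[e]"]], 0.019, tolerance = 1e-9)
  expect_equal(max(yt[["succinate[e]"]]), 1.562)
  expect_equal(max(yt[["formate[e]"]]), 3.881)
  expect_equal(max(yt[["biomass[e]"]]), 0.144)
})

test_that("yields are invariant to mode scaling and demand substrate use", {
  tc <- toy_network_suite()$ferment
  net <- tc$network
  efms <- enumerate_efms(net, substrate_id = tc$substrate_id)
  y1 <- efm_yields(efms, net, tc$substrate_id)
  efms2 <- efms; efms2$modes <- efms$modes * 7
  y2 <- efm_yields(efms2, net, tc$substrate_id)
  expect_equal(as.data.frame(y1), as.data.frame(y2))

  nosub <- tsv_net(c("upt\tA[e] -> A[c]", "sec\tA[c] -> B[e]"))
  ef <- enumerate_efms(nosub)
  expect_error(efm_yields(ef, nosub, "Z[e]"), "neither")
})

test_that("biomass yield column converts to grams per mmol substrate", {
  tc <- toy_network_suite()$ferment
  net <- tc$network
  # give the biomass species a C-mol composition
  net$metabolites$formula[net$metabolites$id == "X[e]"] <- biomass_formula
  efms <- enumerate_efms(net, substrate_id = tc$substrate_id)
  kept <- filter_efms(efms, net, tc$substrate_id, "X[e]")
  yt <- efm_yields(kept, net, tc$substrate_id, biomass_id = "X[e]")
  # 6 mol X per mol substrate, X weighs 97.42 g/mol -> 0.5845 g/mmol
  expect_equal(yt[["X[e]"]], 6 * molar_mass(biomass_formula) / 1000, tolerance = 1e-9)
})

test_that("2-D hulls match the half-plane oracle, degenerate cases included", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
  h <- convex_hull_2d(sq)
  expect_setequal(h, 1:4)
  # counter-clockwise orientation: positive signed area
  P <- sq[h, ]
  area2 <- sum(P[, 1] * c(P[-1, 2], P[1, 2]) - c(P[-1, 1], P[1, 1]) * P[, 2])
  expect_gt(area2, 0)

  same <- matrix(1, 5, 2)
  expect_equal(convex_hull_2d(same), 1L)
  coll <- cbind(seq(0, 1, 0.25), seq(0, 2, 0.5))
  expect_setequal(convex_hull_2d(coll), c(1L, 5L))

  set.seed(11)
  cloud <- cbind(rnorm(100), rnorm(100))
  expect_setequal(convex_hull_2d(cloud), hull_oracle_vertices(cloud))
})

test_that("triangle clouds select exactly their corners", {
  corners <- rbind(c(0, 0), c(4, 0), c(0, 3))
  set.seed(5)
  w <- matrix(stats::runif(3 * 40), 40)
  w <- w / rowSums(w)
  pts <- w %*% corners
  yt <- as.data.frame(rbind(corners, pts))
  names(yt) <- c("acetate", "succinate")
  sel <- select_vertex_efms(yt, product_pairs = list(c("acetate", "succinate")))
  expect_setequal(sel$selected_indices, 1:3)
})

test_that("selected polygons enclose the reference data (ray-casting oracle)", {
  set.seed(21)
  pts <- cbind(stats::rnorm(60), stats::rnorm(60))
  yt <- as.data.frame(pts); names(yt) <- c("a", "b")
  data_pts <- as.data.frame(pts[sample(60, 10), , drop = FALSE] * 0.3)
  names(data_pts) <- c("a", "b")
  sel <- select_vertex_efms(yt, product_pairs = list(c("a", "b")),
                            data_points = data_pts)
  poly <- as.matrix(yt[sel$polygon_vertices[["a~b"]], ])
  for (k in seq_len(nrow(data_pts))) {
    p <- as.numeric(data_pts[k, ])
    # oracle is strict; nudge boundary cases inward by a hair
    expect_true(ray_cast_inside(p * (1 - 1e-9), poly) ||
                  ray_cast_inside(p, poly))
  }
  # vertices are a subset of the hull
  expect_true(all(sel$polygon_vertices[["a~b"]] %in% sel$hull_indices[["a~b"]]))
})

test_that("selection is deterministic and falls back when data lie outside", {
  set.seed(3)
  pts <- cbind(stats::runif(30), stats::runif(30))
  yt <- as.data.frame(pts); names(yt) <- c("a", "b")
  s1 <- select_vertex_efms(yt, product_pairs = list(c("a", "b")))
  s2 <- select_vertex_efms(yt, product_pairs = list(c("a", "b")))
  expect_identical(s1$selected_indices, s2$selected_indices)

  outside <- data.frame(a = 5, b = 5)
  expect_warning(s3 <- select_vertex_efms(yt, product_pairs = list(c("a", "b")),
                                          data_points = outside),
                 "full hull")
  expect_setequal(s3$polygon_vertices[["a~b"]], s3$hull_indices[["a~b"]])
})

test_that("selection on the packaged glucose modes picks hull vertices of every panel", {
  mn <- glucose_macro_net()
  efms <- enumerate_efms(mn, substrate_id = "glucose[e]")
  yt <- efm_yields(efms, mn, "glucose[e]")
  names(yt) <- sub("\\[e\\]$", "", names(yt))
  pairs <- utils::combn(c("biomass", "acetate", "succinate", "formate"), 2,
                        simplify = FALSE)
  sel <- select_vertex_efms(yt, product_pairs = pairs, efms = efms,
                            biomass_col = "biomass")
  expect_true(length(sel$selected_indices) >= 3)
  expect_true(length(sel$selected_indices) <= 9)
  for (key in names(sel$polygon_vertices)) {
    expect_true(all(sel$polygon_vertices[[key]] %in% sel$hull_indices[[key]]))
  }
})

test_that("deduplication collapses copies and scalings, rejects mixed networks", {
  tc <- toy_network_suite()$ferment
  efms <- enumerate_efms(tc$network, substrate_id = tc$substrate_id)
  doubled <- efms; doubled$modes <- efms$modes * 3
  dd <- deduplicate_efms(list(efms, doubled))
  expect_equal(n_efms(dd), n_efms(efms))

  other <- enumerate_efms(toy_network_suite()$chain$network)
  expect_error(deduplicate_efms(list(efms, other)), "different networks")

  # disjoint sets concatenate
  half1 <- efms; half1$modes <- efms$modes[, 1, drop = FALSE]
  half2 <- efms; half2$modes <- efms$modes[, 2:3, drop = FALSE]
  expect_equal(n_efms(deduplicate_efms(list(half1, half2))), 3L)
})
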