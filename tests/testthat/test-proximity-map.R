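toy_screen <- function(edges, verdicts = "positive", compartment = "endocytic_sites") {
  tibble::tibble(
    donor_protein = sub("-.*", "", edges[, 1]),
    donor_terminus = sub(".*-", "", edges[, 1]),
    acceptor_protein = sub("-.*", "", edges[, 2]),
    acceptor_terminus = sub(".*-", "", edges[, 2]),
    compartment = compartment,
    mean_E_pct = 5,
    verdict = rep(verdicts, length.out = nrow(edges)))
}

test_that("graph edges are exactly the positive verdicts", {
  empty <- build_graph(toy_screen(matrix(c("A-N", "B-C"), 1), "negative"))
  expect_equal(nrow(empty$edges), 0)
  expect_equal(igraph::gsize(empty$graph), 0)
  tab1 <- published_screen(compartment = "cytoplasm")
  g <- build_graph(tab1, compartment = "cytoplasm")
  expect_equal(nrow(tab1), 5)
  expect_equal(nrow(g$edges), sum(tab1$verdict == "positive"))
  expect_equal(nrow(g$edges), 4) # 1.5 +/- 2.2 stays out
  # at endocytic sites only two of the five comparison pairs keep FRET
  endo <- published_screen(groups = c("isolated", "cross", "table1"),
                           compartment = "endocytic_sites")
  endo <- endo[paste(endo$donor_protein, endo$acceptor_protein) %in%
                 c("Syp1 Ede1", "End3 Pan1", "Las17 Sla1"), ]
  ge <- build_graph(endo)
  expect_equal(nrow(ge$edges), 2)
  # conflicting duplicate verdicts are rejected
  dup <- dplyr::bind_rows(toy_screen(matrix(c("A-N", "B-C"), 1), "positive"),
                          toy_screen(matrix(c("B-C", "A-N"), 1), "negative"))
  expect_error(build_graph(dup), "conflicting")
})

test_that("network decomposition separates components by size", {
  edges <- rbind(c("A-N", "B-N"), c("B-N", "C-N"), c("C-N", "A-N"),
                 c("D-C", "E-C"), c("E-C", "F-C"), c("F-C", "D-C"),
                 c("G-N", "H-C"))
  nets <- find_networks(build_graph(toy_screen(edges)))
  expect_length(nets$networks, 2)
  expect_length(nets$isolated_pairs, 1)
  expect_equal(nets$isolated_pairs[[1]], c("G-N", "H-C"))
  # membership is invariant to record order
  nets2 <- find_networks(build_graph(toy_screen(edges[sample(nrow(edges)), ])))
  expect_equal(nets$networks, nets2$networks)
})

test_that("the curated screen decomposes into two networks and three isolated pairs", {
  scr <- published_screen(groups = c("green", "red", "isolated"),
                          compartment = "endocytic_sites")
  nets <- find_networks(build_graph(scr))
  expect_length(nets$networks, 2)
  expect_length(nets$isolated_pairs, 3)
  sizes <- sort(lengths(nets$networks), decreasing = TRUE)
  expect_true(all(sizes > 2))
  green <- nets$networks[[1]]
  expect_true(all(c("Sla2-N", "Gts1-N", "Gts1-C", "Pan1-N", "Sla1-C",
                    "End3-N") %in% green))
  expect_true(all(c("Sla2-C", "Pan1-C", "Sla1-N", "End3-C") %in%
                    nets$networks[[2]]))
})

test_that("orientation calls follow the Welch comparison and are antisymmetric", {
  expect_equal(infer_orientation(mean_n = 3, mean_c = 3)$closer, "unresolved")
  set.seed(15)
  vn <- stats::rnorm(20, 6.7, 3.4)
  vc <- stats::rnorm(20, 2.8, 3.2)
  call_nc <- infer_orientation(vn, vc)
  call_cn <- infer_orientation(vc, vn)
  if (call_nc$confident) {
    expect_equal(call_nc$closer, "N")
    expect_equal(call_cn$closer, "C")
  }
  expect_equal(call_nc$p, call_cn$p)
  # means-only fallback is flagged low-confidence
  lc <- infer_orientation(mean_n = 6.7, mean_c = 2.8)
  expect_true(lc$low_confidence)
  expect_equal(lc$closer, "N")
})

test_that("orientation power matches the printed terminus comparison design", {
  # per-cell SDs back-computed from CI halfwidths of +/-1.6 and +/-1.5 at n = 20
  sd_n <- 1.6 * sqrt(20) / stats::qt(0.975, 19)
  sd_c <- 1.5 * sqrt(20) / stats::qt(0.975, 19)
  set.seed(16)
  calls <- replicate(60, {
    o <- infer_orientation(stats::rnorm(20, 6.7, sd_n), stats::rnorm(20, 2.8, sd_c))
    o$confident && o$closer == "N"
  })
  expect_gte(mean(calls), 0.9)
})

test_that("ruler evidence emits the published distance bounds", {
  scr <- published_screen(groups = c("truncation", "tested_negative"))
  rl <- apply_ruler_evidence(scr)
  pan1_clc1 <- rl[rl$node == "Pan1-C" & rl$marker == "Clc1-C", ]
  expect_equal(pan1_clc1$type, "min_dist")
  expect_equal(pan1_clc1$distance_nm, 10)
  expect_equal(rl$type[rl$node == "Pan1(1-1050)-C" & rl$marker == "Clc1-C"],
               "max_dist")
  expect_equal(rl$type[rl$node == "Sla2(dTHATCH)-C" & rl$marker == "Clc1-C"],
               "max_dist")
  # no truncation records -> no constraints
  none <- apply_ruler_evidence(published_screen(groups = "green"))
  expect_equal(nrow(none), 0)
  # contradictory evidence is reported, not resolved
  contr <- tibble::tibble(
    donor_protein = "X", donor_terminus = "C",
    donor_variant = c(NA, "1-100"),
    acceptor_protein = "M", acceptor_terminus = "C", acceptor_variant = NA,
    compartment = "endocytic_sites", mean_E_pct = c(5, NA),
    verdict = c("positive", "negative"))
  out <- apply_ruler_evidence(contr)
  expect_gt(nrow(attr(out, "contradictions")), 0)
})

test_that("a two-anchor chain forces the middle node midway", {
  scr <- toy_screen(rbind(c("A-C", "B-C"), c("B-C", "C-C")))
  cm <- assign_layers(build_graph(scr),
                      anchor_constraints(c("A-C", "C-C"), lo = c(0, 20)),
                      n_starts = 8)
  b <- cm$coordinates$x_nm[cm$coordinates$node == "B-C"]
  expect_lt(abs(b - 10), 0.5)
})

test_that("optimizer matches brute-force grid search on small instances", {
  set.seed(17)
  for (rep in 1:3) {
    edges <- rbind(c("A-C", "B-C"), c("B-C", "C-C"), c("C-C", "D-C"),
                   c("B-C", "D-C"), c("D-C", "E-C"))
    scr <- toy_screen(edges)
    scr$verdict[5] <- "negative"
    scr$mean_E_pct <- stats::runif(5, 2, 9)
    pg <- build_graph(scr)
    anchors <- anchor_constraints(c("A-C", "E-C"),
                                  lo = c(0, 15 + 5 * rep))
    cfg <- map_config(w_tiebreak = 0) # pure penalty objective for the oracle
    cm <- assign_layers(pg, anchors, cfg = cfg, n_starts = 16)
    # exhaustive 1-nm grid over the three free nodes
    span <- 15 + 5 * rep + 10
    grid <- seq(0, span, by = 1)
    prm_obj <- function(xb, xc, xd) {
      x <- c("A-C" = 0, "B-C" = xb, "C-C" = xc, "D-C" = xd,
             "E-C" = 15 + 5 * rep)
      pos <- pg$edges
      o <- sum(pmax(0, abs(x[pos$from] - x[pos$to]) - 10)^2)
      neg <- pg$negatives
      if (nrow(neg) > 0)
        o <- o + 0.1 * sum(pmax(0, 12 - abs(x[neg$from] - x[neg$to]))^2)
      o
    }
    best_grid <- Inf
    for (xb in grid) for (xc in grid) for (xd in grid) {
      v <- prm_obj(xb, xc, xd)
      if (v < best_grid) best_grid <- v
    }
    expect_lte(cm$objective, best_grid * 1.01 + 1e-9)
  }
})

test_that("planted 1-D geometry is recovered in order", {
  taus <- sapply(1:6, function(s) planted_recovery_tau(100 + s, s))
  expect_gte(mean(taus), 0.9)
})

test_that("the published-record map reproduces the stated architecture", {
  pm <- published_coat_map(seed = 2)
  x <- stats::setNames(pm$coordinates$x_nm, pm$coordinates$node)
  lattice <- x[c("Chc1-C", "Clc1-C")]
  expect_lt(x["Chc1-C"], x["Clc1-C"]) # heavy chain membrane-proximal
  red <- x[c("Sla2-C", "Pan1-C", "Sla1-N", "End3-C")]
  expect_true(all(red > max(lattice)))
  expect_equal(names(which.max(red)), "Pan1-C")
  # adaptor-layer members sit below the lattice markers
  expect_lt(x["Sla2-N"], min(lattice))
  expect_lt(x["Gts1-N"], min(lattice))
})
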