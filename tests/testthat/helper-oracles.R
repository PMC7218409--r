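# Independent oracles shared across tests.

# Explicit per-pixel loop reference for the de-quenching estimator,
# kept deliberately naive and independent of the vectorised implementation.
fret_pixel_loop <- function(pre, post, mask, threshold,
                            convention = "increase_over_pre") {
  es <- c()
  for (r in seq_len(nrow(pre))) {
    for (c in seq_len(ncol(pre))) {
      if (mask[r, c] && pre[r, c] > threshold && post[r, c] > threshold) {
        e <- if (convention == "increase_over_pre")
          100 * (post[r, c] - pre[r, c]) / pre[r, c]
        else
          100 * (post[r, c] - pre[r, c]) / post[r, c]
        es <- c(es, e)
      }
    }
  }
  if (length(es) == 0) return(list(E = NA_real_, n = 0L))
  list(E = mean(es), n = length(es))
}

# Random convex polygon (convex hull of jittered ellipse points).
random_convex_polygon <- function(area_min = 100, center = c(20, 20)) {
  repeat {
    n <- sample(6:12, 1)
    th <- sort(stats::runif(n, 0, 2 * pi))
    R <- stats::runif(1, 7, 14)
    x <- center[1] + R * cos(th) * stats::runif(n, 0.8, 1)
    y <- center[2] + R * sin(th) * stats::runif(n, 0.8, 1)
    h <- grDevices::chull(x, y)
    x <- x[h]; y <- y[h]
    j <- c(length(x), seq_len(length(x) - 1))
    A <- abs(sum(x[j] * y - x * y[j])) / 2
    if (A >= area_min) return(list(x = x, y = y, area = A))
  }
}

# Planted 1-D geometry: random positions whose proximity graph is
# connected (consecutive gaps below the FRET radius, so ordering is
# identifiable), with edge magnitude decreasing in distance.
planted_geometry <- function(n = 12, span = 40, d_max = 10) {
  repeat {
    pos <- sort(stats::runif(n, 0, span))
    if (all(diff(pos) < d_max)) break
  }
  names(pos) <- paste0("P", seq_len(n), "-C")
  ed <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    if (abs(pos[i] - pos[j]) < d_max)
      ed <- rbind(ed, c(names(pos)[i], names(pos)[j],
                        d_max - abs(pos[i] - pos[j])))
  screen <- tibble::tibble(
    donor_protein = sub("-.*", "", ed[, 1]), donor_terminus = "C",
    acceptor_protein = sub("-.*", "", ed[, 2]), acceptor_terminus = "C",
    compartment = "endocytic_sites", mean_E_pct = as.numeric(ed[, 3]),
    verdict = "positive")
  list(pos = pos, screen = screen)
}

planted_recovery_tau <- function(seed_data, seed_opt) {
  set.seed(seed_data)
  g <- planted_geometry()
  cm <- assign_layers(build_graph(g$screen),
                      anchor_constraints(c(names(g$pos)[1],
                                           names(g$pos)[length(g$pos)]),
                                         lo = c(g$pos[1], g$pos[length(g$pos)])),
                      n_starts = 16, seed = seed_opt)
  got <- cm$coordinates$x_nm[match(names(g$pos), cm$coordinates$node)]
  stats::cor(got, g$pos, method = "kendall")
}

# Tiny default scene/config for fast pipeline tests.
tiny_scene <- function(seed = 1, n_patches = 6, ...) {
  cell_scene(shape = c(40L, 40L), n_patches = n_patches,
             min_patch_sep_px = 5, seed = seed, ...)
}
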