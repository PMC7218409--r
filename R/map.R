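# Terminus-level proximity mapping: graph construction from the classified
# screen, network decomposition, terminus-orientation calls, and
# anchor-constrained 1-D (membrane-normal) layer assignment.

#' Axial map configuration
#'
#' @param d_max_nm FRET proximity radius in nm: energy transfer requires
#'   fluorophore separations below ~10 nm, so a positive edge constrains the
#'   two termini to within `d_max_nm`.
#' @param negative_margin_nm Extra margin for tested-but-negative pairs:
#'   their soft repulsion activates below `d_max_nm + negative_margin_nm`.
#' @param w_edge,w_negative,w_anchor Penalty weights for positive edges,
#'   negative-pair repulsion, and soft/interval anchors. Absence of FRET is
#'   weak evidence (orientation and stoichiometry also suppress transfer),
#'   hence the low default negative weight.
#' @param w_tiebreak Tiny attraction `w_tiebreak * weight * (d/d_max)^2` on
#'   positive edges so that FRET magnitude breaks ties between otherwise
#'   equivalent zero-penalty placements (stronger FRET ends up closer);
#'   magnitudes are never converted to distances.
#' @param layers Named list of `c(lo, hi)` nm intervals (ordered,
#'   non-overlapping) used to label coordinates.
#' @return An object of class `map_config`.
#' @export
map_config <- function(d_max_nm = 10,
                       negative_margin_nm = 2,
                       w_edge = 1, w_negative = 0.1, w_anchor = 10,
                       w_tiebreak = 1e-3,
                       layers = list(membrane_binding = c(0, 5),
                                     adaptor = c(5, 16),
                                     lattice = c(16, 28),
                                     actin_regulatory = c(28, Inf))) {
  if (d_max_nm <= 0) stop("d_max_nm must be > 0")
  lo <- vapply(layers, `[`, numeric(1), 1)
  hi <- vapply(layers, `[`, numeric(1), 2)
  if (any(lo >= hi) || is.unsorted(lo) || any(utils::head(hi, -1) > utils::tail(lo, -1)))
    stop("layer intervals must be ordered and non-overlapping")
  structure(list(d_max_nm = d_max_nm, negative_margin_nm = negative_margin_nm,
                 w_edge = w_edge, w_negative = w_negative, w_anchor = w_anchor,
                 w_tiebreak = w_tiebreak, layers = layers),
            class = "map_config")
}

terminus_label <- function(protein, terminus, variant = NA) {
  v <- ifelse(is.na(variant) | variant == "" | variant == "full", "",
              paste0("(", variant, ")"))
  paste0(protein, v, "-", terminus)
}

#' Build a terminus-level proximity graph from a classified screen
#'
#' Nodes are every tagged terminus tested in the screen records; undirected
#' edges connect the termini of FRET-positive pairs, weighted by the mean
#' FRET efficiency. Tested-but-negative pairs are retained alongside the
#' graph as weak distance evidence for [assign_layers()].
#'
#' @param screen Screen tibble with columns `donor_protein`,
#'   `donor_terminus`, `acceptor_protein`, `acceptor_terminus`, optional
#'   `donor_variant`/`acceptor_variant`, `compartment`, `mean_E_pct`,
#'   `verdict` (and optionally `ci95_halfwidth_pct`).
#' @param compartment Which compartment's records to use (default
#'   `"endocytic_sites"`).
#' @return An object of class `proximity_graph`: list with `graph`
#'   (igraph), `nodes`, `edges` (positive pairs) and `negatives`
#'   (tested-but-negative pairs).
#' @export
build_graph <- function(screen, compartment = "endocytic_sites") {
  req <- c("donor_protein", "donor_terminus", "acceptor_protein",
           "acceptor_terminus", "mean_E_pct", "verdict")
  stopifnot(all(req %in% names(screen)))
  if ("compartment" %in% names(screen))
    screen <- dplyr::filter(screen, .data$compartment == !!compartment)
  if (!"donor_variant" %in% names(screen)) screen$donor_variant <- NA_character_
  if (!"acceptor_variant" %in% names(screen)) screen$acceptor_variant <- NA_character_
  screen <- screen |>
    dplyr::mutate(
      from = terminus_label(.data$donor_protein, .data$donor_terminus,
                            .data$donor_variant),
      to = terminus_label(.data$acceptor_protein, .data$acceptor_terminus,
                          .data$acceptor_variant),
      pair_key = purrr::map2_chr(.data$from, .data$to,
                                 ~paste(sort(c(.x, .y)), collapse = "~")))
  dup <- screen |>
    dplyr::group_by(.data$pair_key) |>
    dplyr::filter(dplyr::n_distinct(.data$verdict) > 1)
  if (nrow(dup) > 0)
    stop("conflicting verdicts for pair(s): ",
         paste(unique(dup$pair_key), collapse = ", "))
  screen <- dplyr::distinct(screen, .data$pair_key, .keep_all = TRUE)
  nodes <- tibble::tibble(name = sort(unique(c(screen$from, screen$to))))
  edges <- screen |> dplyr::filter(.data$verdict == "positive") |>
    dplyr::select(dplyr::all_of(c("from", "to", "mean_E_pct")),
                  dplyr::any_of("ci95_halfwidth_pct"))
  negatives <- screen |> dplyr::filter(.data$verdict == "negative") |>
    dplyr::select(dplyr::all_of(c("from", "to")))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  structure(list(graph = g, nodes = nodes, edges = edges, negatives = negatives,
                 compartment = compartment),
            class = "proximity_graph")
}

#' @export
print.proximity_graph <- function(x, ...) {
  cat("<proximity_graph>", nrow(x$nodes), "termini,", nrow(x$edges),
      "positive edges,", nrow(x$negatives), "tested-negative pairs\n")
  invisible(x)
}

#' Decompose a proximity graph into networks and isolated pairs
#'
#' Connected components of the positive-edge graph, partitioned into
#' proximity networks (at least `min_size` termini), isolated pairs
#' (exactly two termini), and unconnected singletons.
#'
#' @param pgraph A [build_graph()] result.
#' @param min_size Minimum component size to count as a network (default 3).
#' @return List with `networks`, `isolated_pairs`, `singletons` (each a list
#'   of sorted character vectors of terminus labels) and a `membership`
#'   tibble.
#' @export
find_networks <- function(pgraph, min_size = 3) {
  stopifnot(inherits(pgraph, "proximity_graph"))
  comp <- igraph::components(pgraph$graph)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, function(v) sort(v))
  sizes <- lengths(members)
  ord <- order(-sizes)
  members <- members[ord]; sizes <- sizes[ord]
  list(
    networks = unname(members[sizes >= min_size]),
    isolated_pairs = unname(members[sizes == 2]),
    singletons = unname(members[sizes == 1]),
    membership = tibble::tibble(
      name = unlist(members, use.names = FALSE),
      component = rep(seq_along(members), lengths(members))))
}

#' Orientation of a protein's termini relative to a reference
#'
#' Compares the FRET of the protein's N- and C-termini to the same reference
#' terminus; the terminus with higher mean FRET is called closer, and the
#' call is confident only if a Welch test on the per-cell values reaches
#' `p < alpha`, otherwise it is `"unresolved"`. Without per-cell values the
#' comparison falls back to the means and is flagged low-confidence.
#'
#' @param values_n,values_c Per-cell FRET values (%) of the N- and
#'   C-terminus pairing with the reference; either may be `NULL` if only
#'   means are known.
#' @param mean_n,mean_c Means, required only when per-cell values are
#'   absent.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `closer` (`"N"`, `"C"` or `"unresolved"`),
#'   `mean_n`, `mean_c`, `p`, `confident`, `low_confidence`.
#' @export
infer_orientation <- function(values_n = NULL, values_c = NULL,
                              mean_n = NULL, mean_c = NULL, alpha = 0.05) {
  if (!is.null(values_n) && !is.null(values_c)) {
    mean_n <- mean(values_n); mean_c <- mean(values_c)
    tt <- welch_t_test(values_n, values_c)
    confident <- tt$p < alpha && mean_n != mean_c
    tibble::tibble(
      closer = if (!confident) "unresolved" else if (mean_n > mean_c) "N" else "C",
      mean_n = mean_n, mean_c = mean_c, p = tt$p,
      confident = confident, low_confidence = FALSE)
  } else {
    if (is.null(mean_n) || is.null(mean_c))
      stop("need either per-cell values or both means")
    tibble::tibble(
      closer = if (mean_n == mean_c) "unresolved" else if (mean_n > mean_c) "N" else "C",
      mean_n = mean_n, mean_c = mean_c, p = NA_real_,
      confident = FALSE, low_confidence = TRUE)
  }
}

#' Distance bounds from truncation (molecular-ruler) evidence
#'
#' For a terminus whose full-length construct is FRET-negative to a marker
#' but whose shortened construct is FRET-positive, the full-length terminus
#' must lie more than `d_max` from the marker and the shortened one within
#' `d_max`. Emits those bounds as relative distance constraints consumed by
#' [assign_layers()]. Contradictory evidence (full-length positive and
#' shortened negative to the same marker) is reported, not resolved.
#'
#' @param screen Screen tibble as in [build_graph()], containing records
#'   that differ only in `donor_variant`/`acceptor_variant`.
#' @param d_max_nm FRET proximity radius (default 10 nm).
#' @return Tibble of constraints: `node`, `marker`, `type`
#'   (`"min_dist"`/`"max_dist"`), `distance_nm`, plus a `contradictions`
#'   attribute.
#' @export
apply_ruler_evidence <- function(screen, d_max_nm = 10) {
  if (!"donor_variant" %in% names(screen)) screen$donor_variant <- NA_character_
  if (!"acceptor_variant" %in% names(screen)) screen$acceptor_variant <- NA_character_
  long <- screen |>
    dplyr::mutate(
      a = terminus_label(.data$donor_protein, .data$donor_terminus),
      b = terminus_label(.data$acceptor_protein, .data$acceptor_terminus),
      a_full = terminus_label(.data$donor_protein, .data$donor_terminus,
                              .data$donor_variant),
      b_full = terminus_label(.data$acceptor_protein, .data$acceptor_terminus,
                              .data$acceptor_variant),
      a_trunc = !is.na(.data$donor_variant) & .data$donor_variant != "" &
        .data$donor_variant != "full",
      b_trunc = !is.na(.data$acceptor_variant) & .data$acceptor_variant != "" &
        .data$acceptor_variant != "full")
  # orient each record as (subject terminus, partner terminus)
  recs <- dplyr::bind_rows(
    long |> dplyr::transmute(subject = .data$a, subject_node = .data$a_full,
                             truncated = .data$a_trunc, partner = .data$b_full,
                             verdict = .data$verdict),
    long |> dplyr::transmute(subject = .data$b, subject_node = .data$b_full,
                             truncated = .data$b_trunc, partner = .data$a_full,
                             verdict = .data$verdict))
  grp <- recs |>
    dplyr::group_by(.data$subject, .data$partner) |>
    dplyr::filter(dplyr::n_distinct(.data$truncated) > 1) |>
    dplyr::ungroup()
  out <- list(); contr <- list()
  for (key in unique(paste(grp$subject, grp$partner, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    gg <- grp[grp$subject == parts[1] & grp$partner == parts[2], ]
    full <- gg[!gg$truncated, ]; trunc <- gg[gg$truncated, ]
    if (nrow(full) == 0 || nrow(trunc) == 0) next
    full_neg <- all(full$verdict == "negative")
    if (full_neg && any(trunc$verdict == "positive")) {
      pos_nodes <- trunc$subject_node[trunc$verdict == "positive"]
      out[[length(out) + 1]] <- tibble::tibble(
        node = c(full$subject_node[1], pos_nodes),
        marker = parts[2],
        type = c("min_dist", rep("max_dist", length(pos_nodes))),
        distance_nm = d_max_nm)
    }
    if (!full_neg && all(trunc$verdict == "negative") && nrow(trunc) > 0) {
      contr[[length(contr) + 1]] <- tibble::tibble(subject = parts[1],
                                                   partner = parts[2])
    }
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(node = character(0), marker = character(0),
                   type = character(0), distance_nm = numeric(0))
  res <- dplyr::distinct(res)
  attr(res, "contradictions") <- if (length(contr)) dplyr::bind_rows(contr) else
    tibble::tibble(subject = character(0), partner = character(0))
  res
}

#' Anchor constraint table
#'
#' Helper to assemble absolute axial anchors (nm from the inner membrane
#' leaflet). `type = "hard"` fixes the coordinate; `type = "soft"` penalises
#' departure from `[lo, hi]` (use `lo == hi` for a point target).
#'
#' @param node Terminus labels (as produced by the screen columns, e.g.
#'   `"Sla2-N"`).
#' @param lo,hi Interval bounds in nm (`lo == hi` for a point).
#' @param type `"hard"` or `"soft"`.
#' @return Anchor tibble.
#' @export
anchor_constraints <- function(node, lo, hi = lo, type = "hard") {
  stopifnot(all(lo >= 0), all(hi >= lo))
  tibble::tibble(node = node, lo = lo, hi = hi,
                 type = rep(type, length.out = length(node)))
}

# Penalty pieces -------------------------------------------------------------

hinge_sq <- function(x) pmax(0, x)^2

layer_objective <- function(x, prm) {
  # positive edges: hinge beyond d_max, plus tiny weighted attraction
  d <- abs(x[prm$ei] - x[prm$ej])
  obj <- prm$w_edge * sum(hinge_sq(d - prm$d_max)) +
    prm$w_tiebreak * sum(prm$ew * (d / prm$d_max)^2)
  if (length(prm$ni) > 0) {
    dn <- abs(x[prm$ni] - x[prm$nj])
    obj <- obj + prm$w_negative * sum(hinge_sq(prm$d_max + prm$margin - dn))
  }
  if (length(prm$si) > 0) {
    obj <- obj + prm$w_anchor *
      sum(hinge_sq(prm$slo - x[prm$si]) + hinge_sq(x[prm$si] - prm$shi))
  }
  if (length(prm$ri) > 0) {
    dr <- abs(x[prm$ri] - x[prm$rj])
    obj <- obj + prm$w_anchor *
      sum(ifelse(prm$rtype == "min_dist", hinge_sq(prm$rd - dr),
                 hinge_sq(dr - prm$rd)))
  }
  if (length(prm$pi_) > 0) {
    dp <- x[prm$pj_] - x[prm$pi_] # signed ordered separation
    obj <- obj + prm$w_anchor *
      sum(hinge_sq(prm$plo - dp) + hinge_sq(dp - prm$phi))
  }
  obj
}

#' Assign axial coordinates and layers to termini
#'
#' Places every terminus reachable from the anchors on a 1-D axis
#' perpendicular to the plasma membrane by minimising a penalised objective:
#' positive FRET edges incur a hinge penalty `max(0, |xi - xj| - d_max)^2`;
#' tested-but-negative pairs a soft low-weight repulsion
#' `max(0, d_max + margin - |xi - xj|)^2`; interval anchors, ruler-derived
#' distance bounds, and ordered-pair separations (e.g. the clathrin
#' heavy/light-chain markers) quadratic hinge penalties. Hard anchors fix
#' coordinates exactly. Optimisation is deterministic multi-start L-BFGS-B
#' under a fixed seed. Nodes unreachable from any anchored node are reported
#' unplaced.
#'
#' @param pgraph A [build_graph()] result.
#' @param anchors Anchor tibble from [anchor_constraints()] (>= 2 rows with
#'   positions required).
#' @param cfg A [map_config()].
#' @param ruler Optional constraint tibble from [apply_ruler_evidence()].
#' @param ordered_pairs Optional tibble with `proximal`, `distal`, `lo`,
#'   `hi`: the signed separation `x[distal] - x[proximal]` is penalised
#'   outside `[lo, hi]`.
#' @param n_starts Number of random multi-start initialisations.
#' @param seed Seed for the multi-start draws (fixed default for
#'   reproducibility).
#' @return An object of class `coat_map`: list with `coordinates` (tibble:
#'   `node`, `x_nm`, `layer`, `anchored`), `unplaced`, `objective`, and the
#'   inputs.
#' @export
assign_layers <- function(pgraph, anchors, cfg = map_config(), ruler = NULL,
                          ordered_pairs = NULL, n_starts = 24L, seed = 1L) {
  stopifnot(inherits(pgraph, "proximity_graph"), inherits(cfg, "map_config"))
  if (nrow(anchors) < 2) stop("need at least 2 anchors with positions")
  extra_nodes <- unique(c(anchors$node,
                          if (!is.null(ruler)) c(ruler$node, ruler$marker),
                          if (!is.null(ordered_pairs))
                            c(ordered_pairs$proximal, ordered_pairs$distal)))
  nodes <- union(pgraph$nodes$name, extra_nodes)
  idx <- stats::setNames(seq_along(nodes), nodes)

  hard <- anchors[anchors$type == "hard", ]
  if (any(hard$lo != hard$hi)) stop("hard anchors must be points (lo == hi)")
  soft <- anchors[anchors$type == "soft", ]

  # reachability: nodes connected to any anchored/constrained node through
  # positive edges, negatives, ruler bounds or ordered pairs
  adj <- rbind(cbind(pgraph$edges$from, pgraph$edges$to),
               cbind(pgraph$negatives$from, pgraph$negatives$to),
               if (!is.null(ruler) && nrow(ruler) > 0)
                 cbind(ruler$node, ruler$marker),
               if (!is.null(ordered_pairs))
                 cbind(ordered_pairs$proximal, ordered_pairs$distal))
  if (is.null(adj)) adj <- matrix(character(0), 0, 2)
  gg <- igraph::graph_from_data_frame(
    as.data.frame(adj, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes))
  comp <- igraph::components(gg)$membership
  anchored_comps <- unique(comp[anchors$node])
  placed <- nodes[comp[nodes] %in% anchored_comps]
  unplaced <- setdiff(nodes, placed)

  keep <- idx[placed]
  remap <- stats::setNames(seq_along(placed), placed)
  sub_edges <- pgraph$edges[pgraph$edges$from %in% placed &
                              pgraph$edges$to %in% placed, ]
  sub_neg <- pgraph$negatives[pgraph$negatives$from %in% placed &
                                pgraph$negatives$to %in% placed, ]
  ew <- sub_edges$mean_E_pct
  med <- stats::median(ew, na.rm = TRUE)
  ew[is.na(ew)] <- if (is.finite(med)) med else 1
  prm <- list(
    d_max = cfg$d_max_nm, margin = cfg$negative_margin_nm,
    w_edge = cfg$w_edge, w_negative = cfg$w_negative,
    w_anchor = cfg$w_anchor, w_tiebreak = cfg$w_tiebreak,
    ei = remap[sub_edges$from], ej = remap[sub_edges$to], ew = ew,
    ni = remap[sub_neg$from], nj = remap[sub_neg$to],
    si = remap[soft$node[soft$node %in% placed]],
    slo = soft$lo[soft$node %in% placed],
    shi = soft$hi[soft$node %in% placed],
    ri = integer(0), rj = integer(0), rtype = character(0), rd = numeric(0),
    pi_ = integer(0), pj_ = integer(0), plo = numeric(0), phi = numeric(0))
  if (!is.null(ruler) && nrow(ruler) > 0) {
    rl <- ruler[ruler$node %in% placed & ruler$marker %in% placed, ]
    prm$ri <- remap[rl$node]; prm$rj <- remap[rl$marker]
    prm$rtype <- rl$type; prm$rd <- rl$distance_nm
  }
  if (!is.null(ordered_pairs)) {
    op <- ordered_pairs[ordered_pairs$proximal %in% placed &
                          ordered_pairs$distal %in% placed, ]
    prm$pi_ <- remap[op$proximal]; prm$pj_ <- remap[op$distal]
    prm$plo <- op$lo; prm$phi <- op$hi
  }

  n <- length(placed)
  fixed <- rep(NA_real_, n)
  fixed[remap[hard$node[hard$node %in% placed]]] <-
    hard$lo[hard$node %in% placed]
  free <- which(is.na(fixed))
  span <- max(c(hard$hi, soft$hi[is.finite(soft$hi)], 3 * cfg$d_max_nm), na.rm = TRUE) +
    2 * cfg$d_max_nm

  obj_free <- function(xf) {
    x <- fixed
    x[free] <- xf
    layer_objective(x, prm)
  }

  best <- NULL
  if (length(free) > 0) {
    starts <- withr_seed(seed, function() {
      lapply(seq_len(n_starts), function(i) stats::runif(length(free), 0, span))
    })
    # informed start: trilateration from the two most distant anchored
    # nodes using graph geodesics with edge length d_max - weight (strong
    # FRET ~ short). 1-D embeddings fold easily from random starts; this
    # start is near the unfolded configuration whenever edge magnitudes
    # decrease with distance.
    anchored_nodes <- hard$node[hard$node %in% placed]
    if (length(anchored_nodes) >= 2 && nrow(sub_edges) > 0) {
      xa <- fixed[remap[anchored_nodes]]
      pick <- order(xa)[c(1, length(xa))]
      a1 <- anchored_nodes[pick[1]]; a2 <- anchored_nodes[pick[2]]
      elen <- pmax(0.5, cfg$d_max_nm - ew)
      gdist <- igraph::graph_from_data_frame(
        data.frame(from = sub_edges$from, to = sub_edges$to, weight = elen),
        directed = FALSE, vertices = data.frame(name = placed))
      dmat <- igraph::distances(gdist, v = c(a1, a2), weights = igraph::E(gdist)$weight)
      d1 <- dmat[1, placed]; d2 <- dmat[2, placed]
      x1 <- fixed[remap[a1]]; x2 <- fixed[remap[a2]]
      L <- max(abs(x2 - x1), 1e-6)
      tpar <- (d1^2 - d2^2 + L^2) / (2 * L)
      xin <- x1 + tpar * (x2 - x1) / L
      xin[!is.finite(xin)] <- (x1 + x2) / 2
      xin <- pmin(pmax(xin, 0), span)
      starts <- c(list(unname(xin[free])), starts)
    }
    for (st in starts) {
      fit <- stats::optim(st, obj_free, method = "L-BFGS-B",
                          lower = rep(0, length(free)),
                          upper = rep(span, length(free)),
                          control = list(maxit = 500))
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    xbest <- fixed
    xbest[free] <- best$par
    objective <- best$value
  } else {
    xbest <- fixed
    objective <- layer_objective(xbest, prm)
  }

  layer_of <- function(x) {
    for (nm in names(cfg$layers)) {
      iv <- cfg$layers[[nm]]
      if (x >= iv[1] && x < iv[2]) return(nm)
    }
    NA_character_
  }
  coords <- tibble::tibble(
    node = placed,
    x_nm = as.numeric(xbest),
    layer = vapply(xbest, layer_of, character(1)),
    anchored = placed %in% hard$node)
  structure(list(coordinates = coords[order(coords$x_nm), ],
                 unplaced = unplaced, objective = objective,
                 config = cfg, anchors = anchors, graph = pgraph),
            class = "coat_map")
}

#' @export
print.coat_map <- function(x, ...) {
  cat("<coat_map>", nrow(x$coordinates), "termini placed",
      sprintf("(objective %.4g)", x$objective), "\n")
  if (length(x$unplaced) > 0)
    cat("  unplaced:", paste(x$unplaced, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname assign_layers
#' @param x,object A `coat_map` object.
#' @param ... Unused.
#' @export
tidy.coat_map <- function(x, ...) x$coordinates

#' @rdname assign_layers
#' @export
glance.coat_map <- function(x, ...) {
  tibble::tibble(n_placed = nrow(x$coordinates),
                 n_unplaced = length(x$unplaced),
                 objective = x$objective)
}

#' @rdname assign_layers
#' @export
autoplot.coat_map <- function(object, ...) {
  d <- object$coordinates
  d$rank <- rank(d$x_nm, ties.method = "first")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$x_nm,
                                  label = .data$node)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$anchored), size = 2) +
    ggplot2::geom_text(hjust = -0.1, vjust = 0.5, angle = 45, size = 3) +
    ggplot2::labs(x = NULL, y = "distance from plasma membrane (nm)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
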