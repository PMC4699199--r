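#' Parameters of the loop-subdivision growth model
#'
#' The model grows a minor venation network from a single rectangular
#' loop: areoles expand with the lamina and subdivide stochastically once
#' their area approaches a critical value. Its behaviour is controlled by
#' four dimensionless parameters:
#' \describe{
#'   \item{alpha}{relative growth rate of vein widths vs lengths: every
#'     existing vein's width increases by `alpha * growth_rate * w_0` per
#'     step;}
#'   \item{beta}{sigmoid width of the subdivision probability relative to
#'     the critical area, `beta = sigma_A / A_0`;}
#'   \item{rho}{in [0, 1], the split-position asymmetry: a new vein is
#'     placed at relative position `1/2 + rho * (u - 1/2)`, `u ~ U(0,1)`,
#'     across the areole;}
#'   \item{f_n}{terminal width-noise amplitude: after growth stops every
#'     width is multiplied by `1 + f_n * xi`, `xi ~ N(0,1)` (clipped so
#'     widths stay above `0.05 * w_0`).}
#' }
#'
#' @param alpha,beta,rho,f_n the dimensionless parameters above.
#' @param A_0 critical areole area (cm^2) at which subdivision becomes
#'   likely.
#' @param w_0 initial vein width (mm).
#' @param growth_rate per-step linear expansion factor of the lamina
#'   (coordinates are multiplied by `1 + growth_rate` each step).
#' @param target_areoles stop once at least this many areoles exist.
#' @param init_cm width and height (cm) of the initial rectangle; its
#'   area should be below `A_0`.
#' @param max_steps safety bound on the number of growth steps.
#' @param seed integer RNG seed; the simulation is fully reproducible.
#' @return a validated list of class `growth_params`.
#' @export
growth_params <- function(alpha = 0.25, beta = 0.5, rho = 0.2, f_n = 0.1,
                          A_0 = 0.01, w_0 = 0.02, growth_rate = 0.05,
                          target_areoles = 256,
                          init_cm = c(0.1, 0.08),
                          max_steps = 5000, seed = 0) {
  p <- list(alpha = alpha, beta = beta, rho = rho, f_n = f_n, A_0 = A_0,
            w_0 = w_0, growth_rate = growth_rate,
            target_areoles = as.integer(target_areoles),
            init_cm = init_cm, max_steps = as.integer(max_steps),
            seed = as.integer(seed))
  stopifnot(p$rho >= 0, p$rho <= 1, p$beta > 0, p$f_n >= 0, p$A_0 > 0,
            p$w_0 > 0, p$growth_rate > 0, p$target_areoles >= 1,
            length(init_cm) == 2, all(init_cm > 0))
  structure(p, class = "growth_params")
}

#' Areole subdivision probability
#'
#' The probability that an areole of area `A` subdivides in a growth
#' step: a logistic sigmoid of width `sigma_A` centered at the critical
#' area `A_0`, so `p = 1/2` exactly at `A = A_0`.
#'
#' @param A areole area (same units as `A_0`).
#' @param A_0 critical area.
#' @param sigma_A sigmoid width (> 0).
#' @return probability in (0, 1); vectorised over `A`.
#' @export
split_probability <- function(A, A_0, sigma_A) {
  stopifnot(sigma_A > 0)
  logistic((A - A_0) / sigma_A)
}

#' Simulate minor-vein development by stochastic loop subdivision
#'
#' Runs the growth model of [growth_params()]: starting from a single
#' rectangular loop of width-`w_0` veins, each step (i) scales all
#' coordinates by `1 + growth_rate`, (ii) thickens every existing vein by
#' `alpha * growth_rate * w_0`, and (iii) lets every areole independently
#' subdivide with probability [split_probability()]; a subdivision
#' inserts a new vein of width `w_0` perpendicular to the areole's longer
#' axis at relative position `1/2 + rho*(u - 1/2)`, so areoles remain
#' rectangles throughout. Growth stops once `target_areoles` areoles
#' exist, after which multiplicative Gaussian width noise of amplitude
#' `f_n` is applied.
#'
#' With `f_n = 0`, vein width is a strictly decreasing function of
#' creation time, so the nesting tree of the simulated network exactly
#' mirrors the recorded split genealogy.
#'
#' @param params a `growth_params` object.
#' @return object of class `vein_growth`: a list with
#'   \describe{
#'     \item{network}{the final `vein_network`;}
#'     \item{events}{data.frame of split events (`step`, `parent`,
#'       `child1`, `child2`, `edge_id`, `position`);}
#'     \item{areoles}{data.frame of final (leaf) areole rectangles
#'       (`id`, `x0`, `y0`, `x1`, `y1` in final cm coordinates);}
#'     \item{steps}{number of growth steps taken;}
#'     \item{params}{the input parameters.}
#'   }
#' @export
simulate_growth <- function(params) {
  stopifnot(inherits(params, "growth_params"))
  with_seed(params$seed, simulate_growth_impl(params))
}

simulate_growth_impl <- function(p) {
  eps <- 1e-9
  g <- p$growth_rate
  sigma_A <- p$beta * p$A_0
  # geometry kept in initial units; 'scale' accumulates lamina expansion
  nx <- c(0, p$init_cm[1], p$init_cm[1], 0)
  ny <- c(0, 0, p$init_cm[2], p$init_cm[2])
  ef <- c(1L, 2L, 3L, 4L)
  et <- c(2L, 3L, 4L, 1L)
  ew <- rep(p$w_0, 4)
  # areoles as rectangles; id 1 is the initial loop
  ax0 <- 0; ay0 <- 0; ax1 <- p$init_cm[1]; ay1 <- p$init_cm[2]
  alive <- TRUE
  next_areole <- 2L
  ev_step <- ev_parent <- ev_c1 <- ev_c2 <- ev_edge <- integer(0)
  ev_pos <- numeric(0)
  scale <- 1
  step <- 0L

  node_at <- function(x, y) {
    hit <- which(abs(nx - x) < eps & abs(ny - y) < eps)
    if (length(hit)) hit[1] else 0L
  }
  # split the boundary edge lying on the line through (x,y) in the given
  # axis and containing the point strictly inside; returns the new node
  cut_boundary <- function(x, y, horizontal) {
    nid <- node_at(x, y)
    if (nid) return(nid)
    if (horizontal) {  # edge along a horizontal side
      cand <- which(abs(ny[ef] - y) < eps & abs(ny[et] - y) < eps &
                    pmin(nx[ef], nx[et]) < x - eps &
                    pmax(nx[ef], nx[et]) > x + eps)
    } else {
      cand <- which(abs(nx[ef] - x) < eps & abs(nx[et] - x) < eps &
                    pmin(ny[ef], ny[et]) < y - eps &
                    pmax(ny[ef], ny[et]) > y + eps)
    }
    if (length(cand) != 1) stop("internal error: boundary edge not found")
    k <- cand[1]
    nx[length(nx) + 1] <<- x
    ny[length(ny) + 1] <<- y
    nid <- length(nx)
    old_to <- et[k]
    et[k] <<- nid
    ef[length(ef) + 1] <<- nid
    et[length(et) + 1] <<- old_to
    ew[length(ew) + 1] <<- ew[k]
    nid
  }

  while (sum(alive) < p$target_areoles && step < p$max_steps) {
    step <- step + 1L
    scale <- scale * (1 + g)
    ew <- ew + p$alpha * g * p$w_0
    live_idx <- which(alive)
    areas <- (ax1[live_idx] - ax0[live_idx]) *
             (ay1[live_idx] - ay0[live_idx]) * scale^2
    do_split <- stats::runif(length(live_idx)) <
      split_probability(areas, p$A_0, sigma_A)
    for (a in live_idx[do_split]) {
      u <- stats::runif(1)
      t <- 1 / 2 + p$rho * (u - 1 / 2)
      wx <- ax1[a] - ax0[a]; wy <- ay1[a] - ay0[a]
      if (wx >= wy) {  # cut perpendicular to the longer (x) axis
        xc <- ax0[a] + t * wx
        n1 <- cut_boundary(xc, ay0[a], horizontal = TRUE)
        n2 <- cut_boundary(xc, ay1[a], horizontal = TRUE)
        c1 <- c(ax0[a], ay0[a], xc, ay1[a])
        c2 <- c(xc, ay0[a], ax1[a], ay1[a])
      } else {
        yc <- ay0[a] + t * wy
        n1 <- cut_boundary(ax0[a], yc, horizontal = FALSE)
        n2 <- cut_boundary(ax1[a], yc, horizontal = FALSE)
        c1 <- c(ax0[a], ay0[a], ax1[a], yc)
        c2 <- c(ax0[a], yc, ax1[a], ay1[a])
      }
      ef[length(ef) + 1] <- n1
      et[length(et) + 1] <- n2
      ew[length(ew) + 1] <- p$w_0
      id1 <- next_areole; id2 <- next_areole + 1L
      next_areole <- next_areole + 2L
      ax0[c(id1, id2)] <- c(c1[1], c2[1]); ay0[c(id1, id2)] <- c(c1[2], c2[2])
      ax1[c(id1, id2)] <- c(c1[3], c2[3]); ay1[c(id1, id2)] <- c(c1[4], c2[4])
      alive[a] <- FALSE
      alive[c(id1, id2)] <- TRUE
      ev_step <- c(ev_step, step)
      ev_parent <- c(ev_parent, a)
      ev_c1 <- c(ev_c1, id1); ev_c2 <- c(ev_c2, id2)
      ev_edge <- c(ev_edge, length(ew))
      ev_pos <- c(ev_pos, t)
      if (sum(alive) >= p$target_areoles) break
    }
  }
  if (step >= p$max_steps && sum(alive) < p$target_areoles)
    warning("max_steps reached before target areole count")
  if (p$f_n > 0) {
    ew <- ew * (1 + p$f_n * stats::rnorm(length(ew)))
    ew <- pmax(ew, 0.05 * p$w_0)
  }
  net <- vein_network(
    data.frame(id = seq_along(nx), x = nx * scale, y = ny * scale),
    data.frame(from = ef, to = et, width = ew),
    validate = TRUE, check_crossings = FALSE)
  leaf <- which(alive)
  structure(list(
    network = net,
    events = data.frame(step = ev_step, parent = ev_parent, child1 = ev_c1,
                        child2 = ev_c2, edge_id = ev_edge, position = ev_pos),
    areoles = data.frame(id = leaf, x0 = ax0[leaf] * scale,
                         y0 = ay0[leaf] * scale, x1 = ax1[leaf] * scale,
                         y1 = ay1[leaf] * scale),
    steps = step,
    params = p),
    class = "vein_growth")
}

#' @export
print.vein_growth <- function(x, ...) {
  cat(sprintf(paste0("vein_growth: %d areoles after %d steps ",
                     "(alpha=%.3g beta=%.3g rho=%.3g f_n=%.3g seed=%d)\n"),
              nrow(x$areoles), x$steps, x$params$alpha, x$params$beta,
              x$params$rho, x$params$f_n, x$params$seed))
  print(x$network)
  invisible(x)
}

# Canonical clade strings (over final areole ids) of the recorded split
# genealogy; comparable to tree_clades() after facet-id relabelling.
genealogy_clades <- function(sim) {
  kids <- split(c(sim$events$child1, sim$events$child2),
                rep(sim$events$parent, 2))
  leaves_below <- function(a) {
    ch <- kids[[as.character(a)]]
    if (is.null(ch)) return(a)
    sort(c(leaves_below(ch[1]), leaves_below(ch[2])))
  }
  internal <- unique(sim$events$parent)
  sort(vapply(internal, function(a) paste(leaves_below(a), collapse = ","),
              character(1)))
}

# Map facet ids of extract_facets(sim$network) to simulator areole ids by
# rectangle containment of an interior point of each facet.
match_facets_to_areoles <- function(sim, facets = NULL) {
  fc <- facets %||% extract_facets(sim$network)
  net <- sim$network
  ar <- sim$areoles
  vapply(fc$facets, function(f) {
    px <- mean(net$nodes$x[match(f$nodes, net$nodes$id)])
    py <- mean(net$nodes$y[match(f$nodes, net$nodes$id)])
    hit <- which(px >= ar$x0 - 1e-9 & px <= ar$x1 + 1e-9 &
                 py >= ar$y0 - 1e-9 & py <= ar$y1 + 1e-9)
    if (length(hit) != 1) stop("facet does not match a unique areole")
    ar$id[hit]
  }, integer(1))
}

#' Compare a simulated network with a reference network
#'
#' Computes the three KS distances used to judge whether a simulated
#' network reproduces a reference (e.g. real leaf) network: between the
#' distributions of (1) areole areas normalized by their mean, (2) edge
#' topological lengths, and (3) nesting ratios.
#'
#' @param net_a,net_b `vein_network` objects (pruned internally).
#' @param max_degree subtree-degree threshold for the nesting ratios.
#' @return named numeric vector `c(area, L_top, q)` of KS distances.
#' @export
model_leaf_comparison <- function(net_a, net_b, max_degree = 256) {
  stats_of <- function(net) {
    net <- prune_to_cycles(net)
    if (is_empty_network(net)) stop("network has no cycles")
    fc <- extract_facets(net)
    ar <- areole_areas(fc)
    tree <- build_nesting_tree(fc, edge_widths = stats::setNames(
      net$edges$width, net$edges$id))
    list(area = ar / mean(ar),
         L = as.numeric(topological_lengths(net)),
         q = nesting_ratios(tree, max_degree))
  }
  a <- stats_of(net_a); b <- stats_of(net_b)
  c(area = ks_distance(a$area, b$area),
    L_top = ks_distance(a$L, b$L),
    q = ks_distance(a$q, b$q))
}
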