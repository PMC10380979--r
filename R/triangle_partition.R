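# Partition of the 2-D clinical space (triangle T) under the
# misclassification + rejection model.
#
# Pipeline: pairwise equal-cost boundary lines -> line arrangement inside T
# (vertices = triangle corners, line-line and line-side intersections;
# edges = maximal segments between consecutive vertices) -> face enumeration
# by rotation-system (half-edge) traversal -> cost-optimal classifier per
# face at the vertex-average point -> faces merged into regions by winner.
#
# All face interiors are crossed by no boundary line, so the winner at any
# interior point wins the whole face.

.TRI_CORNERS <- matrix(c(0, 0, 1, 0, 0, 1), ncol = 2, byrow = TRUE)

# --- line utilities ---------------------------------------------------------

# Normalize a*x + b*y + c = 0 to unit (a, b) with a canonical sign.
.normalize_lines <- function(lines) {
  nrm <- sqrt(lines$a^2 + lines$b^2)
  keep <- nrm > 1e-15
  lines <- lines[keep, , drop = FALSE]
  nrm <- nrm[keep]
  lines$a <- lines$a / nrm; lines$b <- lines$b / nrm; lines$c <- lines$c / nrm
  s <- ifelse(abs(lines$a) > 1e-12, sign(lines$a), sign(lines$b))
  lines$a <- lines$a * s; lines$b <- lines$b * s; lines$c <- lines$c * s
  lines
}

# Drop duplicate (coincident) lines and lines lying along a triangle side.
.dedup_lines <- function(lines, tol = 1e-9) {
  if (nrow(lines) == 0L) return(lines)
  on_side <-
    (abs(lines$a) <= tol & abs(lines$c) <= tol) |               # y = 0 axis? a*x+c with b=1: y const
    (abs(lines$b) <= tol & abs(lines$c) <= tol)
  # after normalization: x-axis is (0, 1, 0); y-axis is (1, 0, 0);
  # hypotenuse x + y - 1 = 0 normalizes to (r, r, -r), r = 1/sqrt(2)
  r <- 1 / sqrt(2)
  on_side <- on_side |
    (abs(lines$a - r) <= tol & abs(lines$b - r) <= tol & abs(lines$c + r) <= tol)
  lines <- lines[!on_side, , drop = FALSE]
  if (nrow(lines) == 0L) return(lines)
  key <- paste(round(lines$a, 9), round(lines$b, 9), round(lines$c, 9))
  lines[!duplicated(key), , drop = FALSE]
}

# Intersections of one line with the triangle boundary; returns the clipped
# segment endpoints (2 x 2 matrix) or NULL when the line misses T or only
# touches a corner.
.clip_line_to_triangle <- function(a, b, c, tol = 1e-12) {
  pts <- matrix(numeric(0), ncol = 2)
  if (abs(a) > tol) {            # side y = 0
    x <- -c / a
    if (x >= -tol && x <= 1 + tol) pts <- rbind(pts, c(x, 0))
  }
  if (abs(b) > tol) {            # side x = 0
    y <- -c / b
    if (y >= -tol && y <= 1 + tol) pts <- rbind(pts, c(0, y))
  }
  if (abs(a - b) > tol) {        # side x + y = 1
    x <- -(b + c) / (a - b)
    if (x >= -tol && x <= 1 + tol) pts <- rbind(pts, c(x, 1 - x))
  }
  if (nrow(pts) < 2L) return(NULL)
  # order along the line direction, take the extremes
  d <- c(-b, a)
  t <- pts %*% d
  seg <- pts[c(which.min(t), which.max(t)), , drop = FALSE]
  if (sqrt(sum((seg[1, ] - seg[2, ])^2)) <= 1e-12) return(NULL)
  # clamp tiny excursions outside T
  seg[seg < 0] <- 0
  seg[, 1] <- pmin(seg[, 1], 1); seg[, 2] <- pmin(seg[, 2], 1)
  seg
}

# --- arrangement ------------------------------------------------------------

#' Build the arrangement graph of boundary lines inside the triangle
#'
#' Vertices are the triangle corners, the line-side intersections and the
#' in-triangle line-line intersections (merged within a 1e-12 radius);
#' edges are the maximal segments between consecutive vertices along each
#' line and each triangle side.
#'
#' @param lines a data frame with columns `a`, `b`, `c` (one boundary line
#'   `a*rc0 + b*rc1 + c = 0` per row), or a list of [boundary_line()]
#'   objects. Coincident duplicates and lines missing the triangle are
#'   dropped.
#' @param merge_tol vertex-merge radius.
#' @return An object of class `arrangement_graph`: list with `vertices`
#'   (n x 2 matrix of (rc0, rc1) coordinates) and `edges` (m x 2 matrix of
#'   vertex indices).
#' @examples
#' g <- build_arrangement(data.frame(a = 1, b = 0, c = -0.4))
#' nrow(g$vertices)  # 5
#' @export
build_arrangement <- function(lines, merge_tol = 1e-12) {
  if (is.list(lines) && !is.data.frame(lines)) {
    lines <- do.call(rbind, lapply(lines, function(l) {
      if (inherits(l, "boundary_line") && l$coincident) return(NULL)
      data.frame(a = l$a, b = l$b, c = l$c)
    }))
    if (is.null(lines)) lines <- data.frame(a = numeric(0), b = numeric(0), c = numeric(0))
  }
  lines <- .dedup_lines(.normalize_lines(lines))

  segs <- vector("list", nrow(lines))
  keep <- logical(nrow(lines))
  for (i in seq_len(nrow(lines))) {
    s <- .clip_line_to_triangle(lines$a[i], lines$b[i], lines$c[i])
    if (!is.null(s)) { segs[[i]] <- s; keep[i] <- TRUE }
  }
  lines <- lines[keep, , drop = FALSE]
  segs <- segs[keep]
  nl <- nrow(lines)

  # line-line intersections inside T
  pts_per_line <- lapply(segs, function(s) s)
  if (nl >= 2L) {
    ij <- utils::combn(nl, 2L)
    a1 <- lines$a[ij[1, ]]; b1 <- lines$b[ij[1, ]]; c1 <- lines$c[ij[1, ]]
    a2 <- lines$a[ij[2, ]]; b2 <- lines$b[ij[2, ]]; c2 <- lines$c[ij[2, ]]
    D <- a1 * b2 - a2 * b1
    ok <- abs(D) > 1e-12
    if (any(ok)) {
      x <- (b1[ok] * c2[ok] - b2[ok] * c1[ok]) / D[ok]
      y <- (a2[ok] * c1[ok] - a1[ok] * c2[ok]) / D[ok]
      inside <- x >= -merge_tol & y >= -merge_tol & x + y <= 1 + merge_tol
      if (any(inside)) {
        xi <- pmax(0, pmin(1, x[inside])); yi <- pmax(0, pmin(1, y[inside]))
        li <- ij[1, ok][inside]; lj <- ij[2, ok][inside]
        for (r in seq_along(xi)) {
          p <- c(xi[r], yi[r])
          pts_per_line[[li[r]]] <- rbind(pts_per_line[[li[r]]], p)
          pts_per_line[[lj[r]]] <- rbind(pts_per_line[[lj[r]]], p)
        }
      }
    }
  }

  # global vertex table (merge radius via fixed-precision keys)
  vkey <- function(m) paste(round(m[, 1], 12), round(m[, 2], 12))
  allpts <- do.call(rbind, c(list(.TRI_CORNERS), pts_per_line))
  keys <- vkey(allpts)
  uk <- !duplicated(keys)
  verts <- cbind(round(allpts[uk, 1], 12), round(allpts[uk, 2], 12))
  ukeys <- keys[uk]
  vid <- function(m) match(vkey(m), ukeys)

  # edges along each boundary line
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nl)) {
    ids <- unique(vid(pts_per_line[[i]]))
    if (length(ids) < 2L) next
    d <- c(-lines$b[i], lines$a[i])
    t <- verts[ids, , drop = FALSE] %*% d
    ids <- ids[order(t)]
    edges <- rbind(edges, cbind(ids[-length(ids)], ids[-1]))
  }

  # edges along each triangle side
  corner_id <- vid(.TRI_CORNERS)
  sides <- list(
    list(on = function(v) abs(v[, 2]) <= merge_tol * 2, ord = 1),         # y = 0
    list(on = function(v) abs(v[, 1]) <= merge_tol * 2, ord = 2),         # x = 0
    list(on = function(v) abs(v[, 1] + v[, 2] - 1) <= merge_tol * 2, ord = 1)
  )
  for (s in sides) {
    ids <- which(s$on(verts))
    if (length(ids) < 2L) next
    ids <- ids[order(verts[ids, s$ord])]
    edges <- rbind(edges, cbind(ids[-length(ids)], ids[-1]))
  }

  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  ekey <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  edges <- edges[!duplicated(ekey), , drop = FALSE]

  structure(list(vertices = verts, edges = edges, n_lines = nl),
            class = "arrangement_graph")
}

#' @export
print.arrangement_graph <- function(x, ...) {
  cat("Arrangement graph: ", nrow(x$vertices), " vertices, ",
      nrow(x$edges), " edges (", x$n_lines, " boundary lines in T)\n", sep = "")
  invisible(x)
}

#' Enumerate the faces of an arrangement graph
#'
#' Traverses the planar rotation system of the graph (at each vertex,
#' incident edges ordered by angle) and returns every bounded face as a
#' convex polygon with counter-clockwise vertices. The faces tile the
#' triangle: their areas sum to 0.5.
#'
#' @param graph an [build_arrangement()] result.
#' @param sliver_tol faces with area below this are dropped.
#' @return List of faces; each face is an n x 2 matrix of (rc0, rc1)
#'   vertices in counter-clockwise order with an `area` attribute.
#' @examples
#' g <- build_arrangement(data.frame(a = 1, b = 0, c = -0.4))
#' length(enumerate_faces(g))  # 2
#' @export
enumerate_faces <- function(graph, sliver_tol = 1e-14) {
  V <- graph$vertices
  E <- graph$edges
  if (nrow(E) == 0L) stop("inconsistent arrangement graph: no edges")
  deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(V))
  if (any(deg[unique(c(E[, 1], E[, 2]))] < 2L)) {
    stop("inconsistent arrangement graph: dangling edge")
  }

  nE <- nrow(E)
  tails <- c(E[, 1], E[, 2])
  heads <- c(E[, 2], E[, 1])
  twin <- c(seq_len(nE) + nE, seq_len(nE))
  ang <- atan2(V[heads, 2] - V[tails, 2], V[heads, 1] - V[tails, 1])

  ord <- order(tails, ang)           # directed edges grouped by tail, CCW
  tl <- tails[ord]
  grp_start <- which(c(TRUE, tl[-1] != tl[-length(tl)]))
  grp_of <- cumsum(c(TRUE, tl[-1] != tl[-length(tl)]))
  grp_len <- tabulate(grp_of)
  pos_in_grp <- sequence(grp_len)
  # prev directed edge (clockwise neighbour) within the tail's rotation
  prev_pos <- ifelse(pos_in_grp > 1L,
                     seq_along(ord) - 1L,
                     grp_start[grp_of] + grp_len[grp_of] - 1L)
  prev_of <- integer(2L * nE)        # prev_of[d] = directed edge before d around its tail
  prev_of[ord] <- ord[prev_pos]
  # face successor: after traversing d = (u -> v), continue with the edge
  # that precedes twin(d) in the rotation around v
  nxt <- prev_of[twin]

  visited <- logical(2L * nE)
  faces <- list()
  for (start in seq_len(2L * nE)) {
    if (visited[start]) next
    cyc <- integer(0)
    d <- start
    repeat {
      visited[d] <- TRUE
      cyc <- c(cyc, d)
      d <- nxt[d]
      if (d == start) break
      if (length(cyc) > 2L * nE) stop("inconsistent arrangement graph: unclosed face walk")
    }
    vs <- tails[cyc]
    xs <- V[vs, 1]; ys <- V[vs, 2]
    area <- 0.5 * sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
    if (area > 0) {
      poly <- cbind(xs, ys)
      dimnames(poly) <- NULL
      attr(poly, "area") <- area
      faces[[length(faces) + 1L]] <- poly
    }
  }
  areas <- vapply(faces, attr, numeric(1), "area")
  faces <- faces[areas >= sliver_tol]
  if (abs(sum(vapply(faces, attr, numeric(1), "area")) - 0.5) > 1e-9) {
    stop("inconsistent arrangement graph: faces do not tile the triangle")
  }
  faces
}

# Signed (shoelace) area of a polygon matrix.
polygon_area <- function(poly) {
  xs <- poly[, 1]; ys <- poly[, 2]
  0.5 * sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)
}

# --- assignment and merging -------------------------------------------------

#' Cost-optimal classifier on one arrangement face
#'
#' Evaluates every classifier's rejection-model cost at the arithmetic mean
#' of the face's vertices (an interior point of the convex face) and returns
#' the minimizer. Since no boundary line crosses a face, that classifier is
#' optimal on the entire face.
#'
#' @param polygon an n x 2 vertex matrix (a face from [enumerate_faces()]).
#' @param profiles a [profile_set()].
#' @param rho pathogenic-variant frequency in (0, 1).
#' @param tol tie tolerance on cost values.
#' @return List with `predictor` (name, earliest in input order on ties) and
#'   `ties` (all co-optimal names when tied, else empty).
#' @export
assign_best_predictor <- function(polygon, profiles, rho, tol = 1e-12) {
  profiles <- as_profile_set(profiles)
  rho <- .check_rho(rho)
  rep_pt <- colMeans(polygon[, 1:2, drop = FALSE])
  cost <- .miscrej_cost_matrix(profiles, rho, rep_pt[1], rep_pt[2])[1, ]
  w <- which.min(cost)
  tied <- which(cost <= cost[w] + tol)
  list(predictor = profiles$name[w],
       ties = if (length(tied) > 1L) profiles$name[tied] else character(0))
}

#' Merge winner-labeled faces into regions
#'
#' Groups the faces of the triangle partition by their winning classifier
#' and computes each region's area and area fraction (against the triangle
#' area 0.5).
#'
#' @param faces list of face polygons (from [enumerate_faces()]).
#' @param winners character vector of winning-classifier names, one per face.
#' @param tol tolerance on the tiling check (total face area vs 0.5).
#' @return An object of class `region_partition` (see
#'   [partition_triangle()]).
#' @export
merge_regions <- function(faces, winners, tol = 1e-9) {
  stopifnot(length(faces) == length(winners))
  areas <- vapply(faces, function(p) {
    a <- attr(p, "area")
    if (is.null(a)) polygon_area(p) else a
  }, numeric(1))
  if (abs(sum(areas) - 0.5) > tol) {
    stop("faces do not tile the triangle (area deficit ",
         format(abs(sum(areas) - 0.5)), ")")
  }
  preds <- unique(winners)
  regions <- lapply(preds, function(p) faces[winners == p])
  names(regions) <- preds
  area <- vapply(regions, function(fs) sum(vapply(fs, function(p) {
    a <- attr(p, "area"); if (is.null(a)) polygon_area(p) else a
  }, numeric(1))), numeric(1))
  summary <- data.frame(predictor = preds,
                        area = as.numeric(area),
                        fraction = as.numeric(area) / 0.5,
                        n_polygons = vapply(regions, length, integer(1)),
                        stringsAsFactors = FALSE)
  summary <- summary[order(-summary$area), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary, regions = regions,
                 faces = faces, face_winners = winners),
            class = "region_partition")
}

#' Partition the 2-D clinical space among rejection classifiers
#'
#' Full pipeline of the rejection-model comparison: computes all pairwise
#' equal-cost boundary lines, builds their arrangement inside the triangle
#' T, enumerates the convex faces, assigns each face its cost-optimal
#' classifier and merges faces into regions. Each region's area fraction is
#' the fraction of clinical scenarios where its classifier is the cheapest
#' choice.
#'
#' @param profiles a [profile_set()] with coverages.
#' @param rho pathogenic-variant frequency in (0, 1). Default 0.5, the
#'   convention for headline analyses of clinically enriched variant sets.
#' @param tol tie tolerance on cost comparisons.
#' @return An object of class `region_partition`: list with `summary`
#'   (data frame: predictor, area, fraction, n_polygons), `regions` (named
#'   list of face-polygon lists), `faces`, `face_winners`, `ties` (named
#'   list of co-optimal sets seen during assignment), `rho` and `profiles`.
#' @examples
#' ps <- profile_set(c("A", "B"), se = c(0.9, 0.7), sp = c(0.7, 0.9))
#' partition_triangle(ps, rho = 0.5)
#' @export
partition_triangle <- function(profiles, rho = 0.5, tol = 1e-12) {
  profiles <- as_profile_set(profiles)
  rho <- .check_rho(rho)
  if (nrow(profiles) < 1L) stop("need at least one classifier profile")
  bl <- .all_boundary_lines(profiles, rho)
  bl <- bl[!bl$coincident, , drop = FALSE]
  graph <- build_arrangement(bl[, c("a", "b", "c")])
  faces <- enumerate_faces(graph)
  assigned <- lapply(faces, assign_best_predictor,
                     profiles = profiles, rho = rho, tol = tol)
  winners <- vapply(assigned, `[[`, "", "predictor")
  part <- merge_regions(faces, winners)
  tie_sets <- unique(Filter(length, lapply(assigned, `[[`, "ties")))
  part$ties <- tie_sets
  part$rho <- rho
  part$profiles <- profiles
  part$graph <- graph
  part
}

#' @export
print.region_partition <- function(x, ...) {
  cat("Clinical-space partition, misclassification+rejection model")
  if (!is.null(x$rho)) cat(" (rho = ", x$rho, ")", sep = "")
  cat("\n", length(x$faces), " faces merged into ",
      nrow(x$summary), " region", if (nrow(x$summary) != 1) "s", ":\n", sep = "")
  df <- x$summary
  df$fraction <- sprintf("%.1f%%", 100 * df$fraction)
  print(df, row.names = FALSE, ...)
  if (length(x$ties)) {
    cat("Ties observed at face assignment:",
        paste(vapply(x$ties, paste, "", collapse = "="), collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
scenario_fractions.region_partition <- function(x) {
  stats::setNames(x$summary$fraction, x$summary$predictor)
}

#' Partition a large classifier set by the group-splitting strategy
#'
#' For large classifier sets, partitions are computed on smaller groups;
#' classifiers that win no scenario in their group are eliminated, the
#' survivors are pooled, and the process repeats until one direct run covers
#' all remaining classifiers. A classifier dominated within its group can
#' never win a scenario of the full problem, so the survivor set and the
#' final fractions match the direct computation on well-conditioned inputs.
#'
#' @inheritParams partition_triangle
#' @param group_size maximal classifiers per individual run, in \[2, 10\].
#' @return A `region_partition` (see [partition_triangle()]); the final run
#'   covers all surviving classifiers.
#' @export
partition_grouped <- function(profiles, rho = 0.5, group_size = 8L, tol = 1e-12) {
  profiles <- as_profile_set(profiles)
  rho <- .check_rho(rho)
  if (group_size < 2L || group_size > 10L) {
    stop("group_size must be between 2 and 10")
  }
  current <- profiles
  while (nrow(current) > group_size) {
    idx <- seq_len(nrow(current))
    chunks <- split(idx, ceiling(idx / group_size))
    survivors <- unlist(lapply(chunks, function(ch) {
      if (length(ch) == 1L) return(current$name[ch])
      p <- partition_triangle(current[ch, , drop = FALSE], rho, tol = tol)
      p$summary$predictor[p$summary$fraction > 0]
    }), use.names = FALSE)
    survivors <- current$name[current$name %in% survivors]  # keep input order
    if (length(survivors) == nrow(current)) break           # no elimination
    current <- current[current$name %in% survivors, , drop = FALSE]
  }
  partition_triangle(current, rho, tol = tol)
}

# Convexity check used by the test-suite invariants.
is_convex_polygon <- function(poly, tol = 1e-10) {
  n <- nrow(poly)
  if (n < 3L) return(FALSE)
  nxt <- c(2:n, 1L)
  nxt2 <- nxt[nxt]
  e1 <- poly[nxt, ] - poly
  e2 <- poly[nxt2, ] - poly[nxt, ]
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  all(cross >= -tol)
}
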