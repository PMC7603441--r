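# The adapted Sassouni arcial construction: four horizontal cephalometric
# planes, theoretical convergence point O, anterior/posterior arcs, and the
# geometric estimation of gonion and pogonion as arc-mandibular-plane
# intersections. All inputs are landmark sets in frame coordinates (sella
# origin, true horizontal +x, superior +y, mm).

#' Build the four Sassouni planes from a landmark set
#'
#' * mandibular plane (MdP): through Go and Me (or a supplied line when the
#'   mandible is missing);
#' * occlusal plane: through the U1/L1 incisal midpoint and the U6/L6
#'   mesial-cusp midpoint (functional bisected occlusal plane);
#' * palatal plane: through ANS and PNS;
#' * basal plane: through Si (inferior sella) with the S-N direction, the
#'   anterior-cranial-base proxy.
#'
#' @param ls a [landmark_set()] in frame coordinates (mm).
#' @param mdp optional [line2d()] to use as the mandibular plane instead of
#'   Go-Me (missing-mandible mode).
#' @return Object of class `"sassouni_planes"`: a list with `mandibular`,
#'   `occlusal`, `palatal`, `basal` lines.
#' @export
build_planes <- function(ls, mdp = NULL) {
  stopifnot(inherits(ls, "landmark_set"))
  need <- c("S", "N", "ANS", "PNS", "Si", "U1", "L1", "U6", "L6")
  if (is.null(mdp)) need <- c(need, "Go", "Me")
  .check_required(ls, need)
  safe_line <- function(p, q, plane) {
    if (all(p == q)) stop("degenerate ", plane, " plane: defining landmarks coincide")
    line_through(p, q)
  }
  mand <- if (is.null(mdp)) {
    safe_line(get_landmark(ls, "Go"), get_landmark(ls, "Me"), "mandibular")
  } else {
    stopifnot(inherits(mdp, "line2d"))
    mdp
  }
  ant_occ <- (get_landmark(ls, "U1") + get_landmark(ls, "L1")) / 2
  post_occ <- (get_landmark(ls, "U6") + get_landmark(ls, "L6")) / 2
  occ <- safe_line(ant_occ, post_occ, "occlusal")
  pal <- safe_line(get_landmark(ls, "ANS"), get_landmark(ls, "PNS"), "palatal")
  s <- get_landmark(ls, "S"); n <- get_landmark(ls, "N")
  if (all(s == n)) stop("degenerate basal plane: S and N coincide")
  bas <- line2d(get_landmark(ls, "Si"),
                atan2(n[2] - s[2], n[1] - s[1]) * 180 / pi)
  structure(list(mandibular = mand, occlusal = occ, palatal = pal,
                 basal = bas), class = "sassouni_planes")
}

#' Locate the theoretical point O
#'
#' In a well-proportioned face all four planes converge at a single point;
#' in practice they do not, so a surrogate is used. `least_squares`
#' minimizes the sum of squared perpendicular distances to the planes
#' (coincides with the exact point under concurrency); `pairwise_mean`
#' takes the centroid of all pairwise plane intersections. Either way the
#' root-mean-square distance from O to the planes is reported as a
#' concurrency residual.
#'
#' @param planes a [build_planes()] result (or any list of `line2d`).
#' @param strategy `"least_squares"` (default) or `"pairwise_mean"`.
#' @return List with `point`, `residual` (rms, mm) and `strategy`.
#' @export
locate_point_O <- function(planes,
                           strategy = c("least_squares", "pairwise_mean")) {
  strategy <- match.arg(strategy)
  lines <- unclass(planes)
  lines <- lines[vapply(lines, inherits, logical(1), "line2d")]
  if (length(lines) < 2) stop("need at least two planes")
  if (strategy == "least_squares") {
    fit <- least_squares_point(lines)
    return(list(point = fit$point, residual = fit$residual,
                strategy = strategy))
  }
  pts <- list()
  for (i in seq_along(lines)) for (j in seq_along(lines)) {
    if (j <= i) next
    p <- intersect_lines(lines[[i]], lines[[j]])
    if (!is.null(p)) pts[[length(pts) + 1L]] <- p
  }
  if (!length(pts)) stop("degenerate configuration: no pairwise intersections")
  o <- colMeans(do.call(rbind, pts))
  res <- vapply(lines, function(l) perpendicular_distance(o, l)^2, numeric(1))
  list(point = unname(o), residual = sqrt(mean(res)), strategy = strategy)
}

#' Build the full arcial construction for one subject
#'
#' Locates point O, then draws the anterior arc (center O, radius O-ANS)
#' and the posterior arc (center O, radius O-Sp).
#'
#' @param ls a [landmark_set()] in frame coordinates (mm).
#' @param strategy point-O strategy, see [locate_point_O()].
#' @param mdp optional mandibular plane override (missing-mandible mode).
#' @return Object of class `"sassouni_construction"`: planes, `O`,
#'   `O_residual`, `anterior_arc`, `posterior_arc`, `strategy`, and the
#'   traced `Go`/`Me`/`Pog` when present.
#' @export
build_construction <- function(ls,
                               strategy = c("least_squares", "pairwise_mean"),
                               mdp = NULL) {
  strategy <- match.arg(strategy)
  planes <- build_planes(ls, mdp = mdp)
  o <- locate_point_O(planes, strategy)
  ans <- get_landmark(ls, "ANS"); sp <- get_landmark(ls, "Sp")
  r_ant <- sqrt(sum((o$point - ans)^2))
  r_post <- sqrt(sum((o$point - sp)^2))
  if (r_ant < 1e-9) stop("point O coincides with ANS: zero anterior radius")
  if (r_post < 1e-9) stop("point O coincides with Sp: zero posterior radius")
  traced <- ls$points[intersect(c("Go", "Me", "Pog"), names(ls$points))]
  structure(list(planes = planes, O = o$point, O_residual = o$residual,
                 anterior_arc = circle2d(o$point, r_ant),
                 posterior_arc = circle2d(o$point, r_post),
                 strategy = strategy, traced = traced,
                 subject_id = ls$subject_id),
            class = "sassouni_construction")
}

#' @export
print.sassouni_construction <- function(x, ...) {
  cat(sprintf(paste0("Sassouni construction '%s' (%s):\n",
                     "  O = (%.2f, %.2f) mm, concurrency rms %.3f mm\n",
                     "  anterior arc r = %.2f mm, posterior arc r = %.2f mm\n"),
              x$subject_id, x$strategy, x$O[1], x$O[2], x$O_residual,
              x$anterior_arc$radius, x$posterior_arc$radius))
  invisible(x)
}

# Intersections of an arc with the mandibular plane, restricted to the
# anterior side of O (the sector between the basal and mandibular planes
# where the arcs are actually drawn; the second quadratic root lies ~2r
# behind the head and is anatomically meaningless).
.arc_mdp_candidates <- function(con, arc) {
  pts <- intersect_line_circle(con$planes$mandibular, arc)
  Filter(function(p) p[1] > con$O[1], pts)
}

.pick_root <- function(cands, prefer = c("posterior", "anterior"), away_from) {
  prefer <- match.arg(prefer)
  if (!length(cands)) return(NULL)
  if (length(cands) == 1L) return(cands[[1]])
  xs <- vapply(cands, `[`, numeric(1), 1L)
  if (abs(diff(xs)) <= 1e-9 && !is.null(away_from)) {
    d <- vapply(cands, function(p) sum((p - away_from)^2), numeric(1))
    return(cands[[which.max(d)]])
  }
  if (prefer == "posterior") cands[[which.min(xs)]] else cands[[which.max(xs)]]
}

#' Estimate gonion from the construction
#'
#' The estimate is the intersection of the posterior arc with the
#' mandibular plane; when two intersections fall on the anterior side of O
#' the more posterior one (smaller frame x) is taken, with ties broken away
#' from Me.
#'
#' @param con a [build_construction()] result.
#' @return The estimated point, or `NULL` if the arc misses the mandibular
#'   plane (the radial shortfall is then attached as the `"shortfall"`
#'   attribute of the construction's miss diagnostic, see
#'   [arc_miss_shortfall()]).
#' @export
estimate_gonion <- function(con) {
  stopifnot(inherits(con, "sassouni_construction"))
  .pick_root(.arc_mdp_candidates(con, con$posterior_arc),
             "posterior", con$traced$Me)
}

#' Estimate pogonion from the construction
#'
#' Intersection of the anterior arc with the mandibular plane; the more
#' anterior root (larger frame x) is taken, ties broken away from Go.
#'
#' @inheritParams estimate_gonion
#' @return The estimated point or `NULL` on a geometric miss.
#' @export
estimate_pogonion <- function(con) {
  stopifnot(inherits(con, "sassouni_construction"))
  .pick_root(.arc_mdp_candidates(con, con$anterior_arc),
             "anterior", con$traced$Go)
}

#' Radial shortfall of an arc that misses the mandibular plane
#'
#' Positive values mean the perpendicular distance from O to the mandibular
#' plane exceeds the arc radius by that many mm (no intersection exists).
#'
#' @param con a [build_construction()] result.
#' @param which `"posterior"` (gonion) or `"anterior"` (pogonion).
#' @return Signed shortfall in mm.
#' @export
arc_miss_shortfall <- function(con, which = c("posterior", "anterior")) {
  which <- match.arg(which)
  arc <- if (which == "posterior") con$posterior_arc else con$anterior_arc
  perpendicular_distance(con$O, con$planes$mandibular) - arc$radius
}

#' Compare estimated with traced mandibular landmarks
#'
#' Differences use the estimated-minus-traced sign convention; gaps are the
#' Euclidean norms of the per-axis differences.
#'
#' @param est list with estimated `Go` and `Pog` (either may be `NULL` on a
#'   geometric miss).
#' @param traced list with traced `Go` and `Pog` points.
#' @return Object of class `"mandible_estimate"`: `est_Go`, `est_Pog`,
#'   `traced_Go`, `traced_Pog`, `dGo`, `dPog` (each `c(dx, dy)`), `gap_Go`,
#'   `gap_Pog` (`NA` when the estimate is missing) and a `flags` character
#'   vector.
#' @export
compare_estimates <- function(est, traced) {
  if (is.null(traced$Go) || is.null(traced$Pog))
    stop("traced Go and Pog are both required for comparison")
  one <- function(e, t) {
    if (is.null(e)) return(list(d = c(NA_real_, NA_real_), gap = NA_real_))
    d <- e - t
    list(d = d, gap = sqrt(sum(d^2)))
  }
  go <- one(est$Go, traced$Go); pog <- one(est$Pog, traced$Pog)
  flags <- character(0)
  if (is.null(est$Go)) flags <- c(flags, "gonion_arc_miss")
  if (is.null(est$Pog)) flags <- c(flags, "pogonion_arc_miss")
  structure(list(est_Go = est$Go, est_Pog = est$Pog,
                 traced_Go = .as_pt(traced$Go), traced_Pog = .as_pt(traced$Pog),
                 dGo = go$d, dPog = pog$d,
                 gap_Go = go$gap, gap_Pog = pog$gap, flags = flags),
            class = "mandible_estimate")
}

#' Estimate Go and Pog for one subject and compare with tracing
#'
#' Convenience wrapper: builds the construction, runs both arc
#' intersections and returns the comparison.
#'
#' @inheritParams build_construction
#' @return A list with `construction` and `estimate`
#'   (a [compare_estimates()] result).
#' @export
estimate_mandible <- function(ls, strategy = c("least_squares", "pairwise_mean")) {
  strategy <- match.arg(strategy)
  con <- build_construction(ls, strategy)
  est <- list(Go = estimate_gonion(con), Pog = estimate_pogonion(con))
  list(construction = con,
       estimate = compare_estimates(est, list(Go = get_landmark(ls, "Go"),
                                              Pog = get_landmark(ls, "Pog"))))
}

#' Shape labels for palate and mandible
#' @param palate one of `"concave"`, `"convex"`, `"horizontal"`.
#' @param mandible one of `"curved"`, `"oblique"`, `"horizontal"`.
#' @param source `"visual"` (externally supplied) or `"heuristic"`.
#' @return Object of class `"shape_labels"`.
#' @export
shape_labels <- function(palate, mandible, source = c("visual", "heuristic")) {
  palate <- match.arg(palate, c("concave", "convex", "horizontal"))
  mandible <- match.arg(mandible, c("curved", "oblique", "horizontal"))
  structure(list(palate = palate, mandible = mandible,
                 source = match.arg(source)), class = "shape_labels")
}

#' Heuristic palate/mandible shape classification
#'
#' The study's own labels were assigned visually; this heuristic exists
#' mainly to label synthetic cohorts. Palate: the signed perpendicular
#' deviation of the palatal vault point `PV` from the ANS-PNS chord,
#' normalized by chord length, with deviation toward inferior counted
#' positive; strictly above `+t` is convex, strictly below `-t` concave,
#' otherwise horizontal (boundaries fall in the non-extreme class).
#' Mandible: the divergence angle between the mandibular and basal planes;
#' strictly above `theta_hi` is oblique (hyperdivergent), strictly below
#' `theta_lo` horizontal, otherwise curved.
#'
#' @param ls a [landmark_set()] in frame coordinates.
#' @param t palate deviation threshold (fraction of chord length).
#' @param theta_lo,theta_hi mandibular divergence thresholds, degrees.
#' @return A [shape_labels()] with `source = "heuristic"`. If `PV` is
#'   absent the palate label is `"horizontal"` and a warning is issued.
#' @export
classify_shapes_heuristic <- function(ls, t = 0.05,
                                      theta_lo = 22, theta_hi = 32) {
  stopifnot(inherits(ls, "landmark_set"))
  planes <- build_planes(ls)
  div <- .dir_diff(planes$mandibular$direction, planes$basal$direction)
  mand <- if (div > theta_hi) "oblique"
          else if (div < theta_lo) "horizontal" else "curved"
  if (!"PV" %in% names(ls$points)) {
    warning("palatal vault point PV absent; palate labelled 'horizontal'")
    pal <- "horizontal"
  } else {
    ans <- get_landmark(ls, "ANS"); pns <- get_landmark(ls, "PNS")
    pv <- get_landmark(ls, "PV")
    chord <- ans - pns
    len <- sqrt(sum(chord^2))
    # cross > 0 means PV superior to the posterior-to-anterior chord;
    # inferior deviation is counted positive
    cross <- chord[1] * (pv[2] - pns[2]) - chord[2] * (pv[1] - pns[1])
    dev <- -cross / len / len
    pal <- if (dev > t) "convex" else if (dev < -t) "concave" else "horizontal"
  }
  shape_labels(pal, mand, source = "heuristic")
}
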