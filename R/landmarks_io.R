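# Landmark file I/O, magnification calibration, bilateral averaging and the
# standardized sella-origin reference frame.
#
# Internal axis convention: anterior = +x, superior = +y. Input files
# declare their raw orientation in the metadata header and are normalized
# on read.

# canonical landmark names used by the arcial analysis
SASSOUNI_LANDMARKS <- c("S", "N", "ANS", "PNS", "Go", "Me", "Pog",
                        "Sp", "Si", "U1", "L1", "U6", "L6")

# synonym table: common long names -> canonical short names
LANDMARK_SYNONYMS <- c(
  "Sella" = "S", "Nasion" = "N", "Gonion" = "Go", "Menton" = "Me",
  "Pogonion" = "Pog", "Gnathion" = "Gn",
  "AnteriorNasalSpine" = "ANS", "PosteriorNasalSpine" = "PNS",
  "SellaPosterior" = "Sp", "SellaInferior" = "Si",
  "PalatalVault" = "PV"
)

# names that are allowed but not required
KNOWN_EXTRA <- c("Gn", "PV", "RULER_A", "RULER_B")

#' Construct a landmark set
#'
#' One set holds the named 2-D points digitized from a single lateral
#' cephalometric radiograph, in either pixel or millimetre units.
#'
#' @param subject_id subject identifier (character scalar).
#' @param points named list of points (or a 2-column matrix with landmark
#'   row names), all finite, no duplicate names.
#' @param units `"px"` or `"mm"`.
#' @param side_pairs optional named list; each element is
#'   `list(L = point, R = point)` for a bilateral landmark that has not yet
#'   been averaged.
#' @return Object of class `"landmark_set"`.
#' @export
landmark_set <- function(subject_id, points, units = c("mm", "px"),
                         side_pairs = list()) {
  units <- match.arg(units)
  if (is.matrix(points)) {
    nm <- rownames(points)
    points <- lapply(seq_len(nrow(points)), function(i) unname(points[i, ]))
    names(points) <- nm
  }
  nm <- names(points)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    stop("all landmarks must be named")
  if (anyDuplicated(nm)) stop("duplicate landmark name: ",
                              nm[duplicated(nm)][1])
  points <- lapply(points, .as_pt)
  known <- c(SASSOUNI_LANDMARKS, KNOWN_EXTRA)
  structure(list(subject_id = as.character(subject_id),
                 points = points, units = units,
                 side_pairs = side_pairs,
                 unknown = setdiff(nm, known)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set '%s': %d points (%s)%s\n", x$subject_id,
              length(x$points), x$units,
              if (length(x$side_pairs))
                sprintf(", %d unresolved bilateral pairs",
                        length(x$side_pairs)) else ""))
  invisible(x)
}

#' Look up one landmark's coordinates
#' @param ls a [landmark_set()].
#' @param name canonical landmark name (synonyms accepted).
#' @return The point `c(x, y)`.
#' @export
get_landmark <- function(ls, name) {
  if (name %in% names(LANDMARK_SYNONYMS)) name <- LANDMARK_SYNONYMS[[name]]
  p <- ls$points[[name]]
  if (is.null(p)) stop("landmark '", name, "' not present for subject '",
                       ls$subject_id, "'")
  p
}

#' Euclidean distance between two landmarks of a set
#' @inheritParams get_landmark
#' @param a,b landmark names.
#' @return Distance in the set's units.
#' @export
landmark_dist <- function(ls, a, b) {
  sqrt(sum((get_landmark(ls, a) - get_landmark(ls, b))^2))
}

.check_required <- function(ls, need = SASSOUNI_LANDMARKS) {
  missing <- setdiff(need, names(ls$points))
  if (length(missing))
    stop("landmark set '", ls$subject_id, "' is missing required landmarks: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# CSV dialect:
#   # units=px|mm x_anterior=+1|-1 y_up=+1|-1 subject=<id>
#   landmark,x,y[,side]
# Comment lines start with '#'. Bilateral points carry side L/R either in
# the side column or as a _L/_R name suffix. The 10-mm calibration ruler is
# encoded as landmarks RULER_A and RULER_B.

.parse_meta <- function(line) {
  fields <- strsplit(trimws(sub("^#", "", line)), "[[:space:]]+")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  out <- list()
  for (f in kv) if (length(f) == 2) out[[f[1]]] <- f[2]
  out
}

#' Read a landmark CSV file
#'
#' Parses the landmark dialect (see Details), normalizes axis orientation
#' to anterior = +x / superior = +y, and collects unresolved bilateral
#' pairs. Unknown landmark names are preserved and listed in the set's
#' `unknown` field.
#'
#' @details The file holds comment lines starting with `#`, one metadata
#'   line `# units=px|mm x_anterior=+1|-1 y_up=+1|-1 subject=<id>`, a
#'   header `landmark,x,y[,side]` and one row per point. A 10-mm ruler is
#'   encoded as landmarks `RULER_A` / `RULER_B`.
#'
#' @param path file path.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path, warn = FALSE)
  meta <- list(units = "px", x_anterior = "+1", y_up = "+1",
               subject = basename(path))
  header_i <- NA_integer_
  for (i in seq_along(raw)) {
    ln <- trimws(raw[i])
    if (ln == "") next
    if (startsWith(ln, "#")) {
      m <- .parse_meta(ln)
      meta[names(m)] <- m
      next
    }
    header_i <- i
    break
  }
  if (is.na(header_i)) stop("no header row found in ", path)
  header <- tolower(trimws(strsplit(raw[header_i], ",")[[1]]))
  need <- c("landmark", "x", "y")
  if (!all(need %in% header))
    stop("missing required column(s) ",
         paste(setdiff(need, header), collapse = ", "),
         " in header (line ", header_i, ") of ", path)
  col <- match(c(need, "side"), header)
  sx <- as.numeric(meta$x_anterior)
  sy <- as.numeric(meta$y_up)
  if (!sx %in% c(-1, 1) || !sy %in% c(-1, 1))
    stop("x_anterior and y_up must each be +1 or -1 in ", path)

  points <- list(); pairs <- list()
  for (i in seq((header_i + 1L), length(raw))) {
    if (i > length(raw)) break
    ln <- trimws(raw[i])
    if (ln == "" || startsWith(ln, "#")) next
    f <- trimws(strsplit(ln, ",")[[1]])
    name <- f[col[1]]
    x <- suppressWarnings(as.numeric(f[col[2]]))
    y <- suppressWarnings(as.numeric(f[col[3]]))
    if (is.na(x) || is.na(y))
      stop("non-numeric coordinate at line ", i, " of ", path)
    side <- if (!is.na(col[4]) && length(f) >= col[4]) toupper(f[col[4]]) else ""
    if (side == "" && grepl("_[LR]$", name)) {
      side <- sub("^.*_", "", name)
      name <- sub("_[LR]$", "", name)
    }
    if (name %in% names(LANDMARK_SYNONYMS)) name <- LANDMARK_SYNONYMS[[name]]
    p <- c(sx * x, sy * y)
    if (side %in% c("L", "R")) {
      if (!is.null(pairs[[name]][[side]]))
        stop("duplicate landmark row for ", name, " side ", side,
             " at line ", i, " of ", path)
      pairs[[name]][[side]] <- p
    } else {
      if (!is.null(points[[name]]))
        stop("duplicate landmark row for ", name, " at line ", i,
             " of ", path)
      points[[name]] <- p
    }
  }
  if (!meta$units %in% c("px", "mm"))
    stop("units must be px or mm in ", path)
  landmark_set(meta$subject, points, units = meta$units, side_pairs = pairs)
}

#' Write a landmark set in the canonical CSV dialect
#'
#' Emits full-precision coordinates (`%.17g`, round-trip safe) in the
#' internal anterior = +x / superior = +y orientation.
#'
#' @param ls a [landmark_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ls, path) {
  fmt <- function(v) sprintf("%.17g", v)
  lines <- c(sprintf("# units=%s x_anterior=+1 y_up=+1 subject=%s",
                     ls$units, ls$subject_id),
             "landmark,x,y,side")
  for (nm in names(ls$points)) {
    p <- ls$points[[nm]]
    lines <- c(lines, sprintf("%s,%s,%s,", nm, fmt(p[1]), fmt(p[2])))
  }
  for (nm in names(ls$side_pairs)) {
    for (sd in c("L", "R")) {
      p <- ls$side_pairs[[nm]][[sd]]
      if (!is.null(p))
        lines <- c(lines, sprintf("%s,%s,%s,%s", nm, fmt(p[1]), fmt(p[2]), sd))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Calibration pair for pixel-to-millimetre scaling
#' @param ruler_a,ruler_b distinct ruler endpoints in pixels.
#' @param known_length true ruler length in mm (10 by default).
#' @return Object of class `"calibration"`.
#' @export
calibration <- function(ruler_a, ruler_b, known_length = 10) {
  a <- .as_pt(ruler_a); b <- .as_pt(ruler_b)
  if (all(a == b)) stop("ruler points are coincident")
  if (!is.finite(known_length) || known_length <= 0)
    stop("known_length must be positive")
  structure(list(ruler_a = a, ruler_b = b, known_length = known_length),
            class = "calibration")
}

#' Scale a pixel-space landmark set to millimetres
#'
#' Every coordinate is multiplied by `known_length / |ruler_a - ruler_b|`
#' (isotropic, so all angles are preserved).
#'
#' @param ls a [landmark_set()] with `units = "px"`.
#' @param cal a [calibration()]; if omitted, the set's `RULER_A` /
#'   `RULER_B` landmarks are used with a 10-mm known length.
#' @return The calibrated set, `units = "mm"`.
#' @export
calibrate <- function(ls, cal = NULL) {
  stopifnot(inherits(ls, "landmark_set"))
  if (ls$units != "px") stop("landmark set is already in mm")
  if (is.null(cal)) {
    cal <- calibration(get_landmark(ls, "RULER_A"),
                       get_landmark(ls, "RULER_B"))
  }
  stopifnot(inherits(cal, "calibration"))
  px <- sqrt(sum((cal$ruler_a - cal$ruler_b)^2))
  s <- cal$known_length / px
  ls$points <- lapply(ls$points, function(p) p * s)
  ls$side_pairs <- lapply(ls$side_pairs, function(pr) lapply(pr, function(p) p * s))
  ls$units <- "mm"
  ls
}

#' Average unresolved bilateral landmark pairs
#'
#' Each left/right pair is replaced by its arithmetic midpoint under the
#' pair's base name; already-single landmarks are untouched.
#'
#' @param ls a [landmark_set()].
#' @return The set with `side_pairs` resolved into `points`.
#' @export
average_bilateral <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  for (nm in names(ls$side_pairs)) {
    pr <- ls$side_pairs[[nm]]
    if (is.null(pr$L) || is.null(pr$R))
      stop("bilateral landmark ", nm, " has only one side digitized")
    if (!is.null(ls$points[[nm]]))
      stop("bilateral pair ", nm, " conflicts with an existing single point")
    ls$points[[nm]] <- (pr$L + pr$R) / 2
  }
  ls$side_pairs <- list()
  ls$unknown <- setdiff(ls$unknown, names(ls$points))
  ls
}

#' Build the standardized sella-origin reference frame
#'
#' The frame places sella at (0,0) with the +x axis along the 'true'
#' horizontal, defined as the S-N direction rotated 7.0 degrees clockwise
#' (so nasion sits 7 degrees above the frame's x axis); +y is superior.
#'
#' @param ls a [landmark_set()] in mm with distinct `S` and `N`.
#' @param true_horizontal_deg clockwise offset of the true horizontal from
#'   the S-N line, degrees (7.0 by convention).
#' @return Object of class `"ref_frame"` with `origin` and `x_axis_deg`
#'   (direction of the frame's +x axis in raw coordinates).
#' @export
build_frame <- function(ls, true_horizontal_deg = 7.0) {
  stopifnot(inherits(ls, "landmark_set"))
  if (ls$units != "mm") stop("calibrate to mm before building the frame")
  s <- get_landmark(ls, "S"); n <- get_landmark(ls, "N")
  if (all(s == n)) stop("S and N coincide; frame undefined")
  sn_deg <- atan2(n[2] - s[2], n[1] - s[1]) * 180 / pi
  structure(list(origin = s, x_axis_deg = sn_deg - true_horizontal_deg),
            class = "ref_frame")
}

#' Express a landmark set in frame coordinates
#'
#' Rigid transform: S maps to (0,0) and the frame's x axis becomes
#' horizontal; all distances are preserved.
#'
#' @param ls a [landmark_set()] in mm.
#' @param f a [build_frame()] result for the same subject.
#' @return The transformed set.
#' @export
to_frame <- function(ls, f) {
  stopifnot(inherits(ls, "landmark_set"), inherits(f, "ref_frame"))
  tf <- function(p) rotate_point(p - f$origin, c(0, 0), -f$x_axis_deg)
  ls$points <- lapply(ls$points, tf)
  ls$side_pairs <- lapply(ls$side_pairs, function(pr) lapply(pr, tf))
  ls
}
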