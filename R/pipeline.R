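# Study orchestration: per-subject arcial estimation, cohort-level
# agreement/association statistics, missing-mandible reconstruction, and a
# small command-line front end.

#' Study configuration
#'
#' @param strategy point-O strategy, `"least_squares"` or
#'   `"pairwise_mean"`.
#' @param alpha significance level for the normality gate and association
#'   tests.
#' @param repeat_n number of subjects re-digitized for the intra-examiner
#'   agreement table (12 in the reference protocol).
#' @param repeat_sd re-digitization noise, mm per axis.
#' @param bonferroni_m number of comparisons for the Bonferroni correction
#'   (nine one-vs-rest collapses of the 3x3 shape table).
#' @param palate_t,theta_lo,theta_hi heuristic shape thresholds, see
#'   [classify_shapes_heuristic()].
#' @param seed integer seed for the analysis-stage randomness (repeat
#'   digitization subset and noise).
#' @return Object of class `"study_config"`.
#' @export
study_config <- function(strategy = c("least_squares", "pairwise_mean"),
                         alpha = 0.05, repeat_n = 12, repeat_sd = 0.5,
                         bonferroni_m = 9, palate_t = 0.05,
                         theta_lo = 22, theta_hi = 32, seed = 1) {
  structure(list(strategy = match.arg(strategy), alpha = alpha,
                 repeat_n = as.integer(repeat_n), repeat_sd = repeat_sd,
                 bonferroni_m = as.integer(bonferroni_m),
                 palate_t = palate_t, theta_lo = theta_lo,
                 theta_hi = theta_hi, seed = as.integer(seed)),
            class = "study_config")
}

# read -> calibrate -> average bilaterals -> frame; returns frame-space set
.prepare_subject <- function(ls) {
  if (ls$units == "px") ls <- calibrate(ls)
  ls <- average_bilateral(ls)
  to_frame(ls, build_frame(ls))
}

.analyze_subject <- function(ls, strategy) {
  lsf <- .prepare_subject(ls)
  fit <- estimate_mandible(lsf, strategy)
  con <- fit$construction; me <- fit$estimate
  num <- function(p, i) if (is.null(p)) NA_real_ else p[i]
  data.frame(
    subject_id = ls$subject_id,
    est_go_x = num(me$est_Go, 1), est_go_y = num(me$est_Go, 2),
    traced_go_x = me$traced_Go[1], traced_go_y = me$traced_Go[2],
    est_pog_x = num(me$est_Pog, 1), est_pog_y = num(me$est_Pog, 2),
    traced_pog_x = me$traced_Pog[1], traced_pog_y = me$traced_Pog[2],
    dgo_x = me$dGo[1], dgo_y = me$dGo[2],
    dpog_x = me$dPog[1], dpog_y = me$dPog[2],
    gap_go = me$gap_Go, gap_pog = me$gap_Pog,
    o_x = con$O[1], o_y = con$O[2], o_residual = con$O_residual,
    sn = landmark_dist(lsf, "S", "N"),
    gome = landmark_dist(lsf, "Go", "Me"),
    flags = paste(me$flags, collapse = ";"),
    stringsAsFactors = FALSE)
}

.shape_table <- function(labels) {
  pal <- factor(labels$palate, levels = c("concave", "convex", "horizontal"))
  man <- factor(labels$mandible, levels = c("curved", "horizontal", "oblique"))
  contingency_table(unclass(table(man, pal)),
                    row_labels = levels(man), col_labels = levels(pal))
}

# Table-1-style intra-examiner agreement on a re-digitized subset:
# measurement series are the estimated/traced Go and Pog coordinates.
.agreement_block <- function(truth, config) {
  idx <- sample(seq_along(truth), min(config$repeat_n, length(truth)))
  one_pass <- function(ls) {
    d <- .analyze_subject(digitize_repeat(ls, config$repeat_sd),
                          config$strategy)
    d[, c("est_go_x", "est_go_y", "traced_go_x", "traced_go_y",
          "est_pog_x", "est_pog_y", "traced_pog_x", "traced_pog_y")]
  }
  first <- do.call(rbind, lapply(truth[idx], one_pass))
  second <- do.call(rbind, lapply(truth[idx], one_pass))
  list(table = agreement_table(first, second), subjects = idx)
}

#' Run the full validation study on a cohort
#'
#' For each subject: read, calibrate, average bilateral landmarks, build
#' the sella-origin frame, run the arcial construction and compare the
#' estimated with the traced Go and Pog. Cohort level: Euclidean-gap
#' summaries with a Ryan-Joiner normality gate, Spearman and OLS for SN
#' versus Go-Me, the 3x3 shape association (chi-squared) with the
#' convex-palate/oblique-mandible collapse (Fisher exact, Bonferroni), and
#' an intra-examiner agreement table from re-digitized subjects when the
#' cohort carries ground truth. Subjects whose arcs miss the mandibular
#' plane are flagged, not dropped; unreadable subjects are skipped with a
#' count, and more than 20% failures aborts the run.
#'
#' @param cohort a [generate_cohort()] result, a directory of landmark
#'   CSVs (see [write_cohort()]), or a list of [landmark_set()]s.
#' @param config a [study_config()].
#' @param labels optional data frame with `palate` and `mandible` columns
#'   (overrides cohort metadata labels).
#' @return Object of class `"study_report"`.
#' @export
run_validation_study <- function(cohort, config = study_config(),
                                 labels = NULL) {
  stopifnot(inherits(config, "study_config"))
  truth <- NULL; meta <- NULL
  if (inherits(cohort, "ceph_cohort")) {
    subjects <- cohort$subjects; truth <- cohort$truth; meta <- cohort$meta
  } else if (is.character(cohort)) {
    rc <- read_cohort(cohort)
    subjects <- rc$subjects; meta <- rc$meta
  } else {
    subjects <- cohort
  }
  n_input <- length(subjects)
  if (!n_input) stop("empty cohort")
  set.seed(config$seed)

  rows <- list(); skipped <- character(0)
  for (s in subjects) {
    r <- tryCatch(.analyze_subject(s, config$strategy),
                  error = function(e) conditionMessage(e))
    if (is.character(r)) skipped <- c(skipped, paste0(s$subject_id, ": ", r))
    else rows[[length(rows) + 1L]] <- r
  }
  if (length(skipped) > 0.2 * n_input)
    stop("more than 20% of subjects failed: ",
         paste(utils::head(skipped, 3), collapse = " | "))
  per_subject <- do.call(rbind, rows)
  if (!is.null(meta) && "class" %in% names(meta))
    per_subject$class <- meta$class[match(per_subject$subject_id,
                                          meta$subject_id)]

  gap_go <- tryCatch(gap_summary(per_subject$gap_go), error = function(e) NULL)
  gap_pog <- tryCatch(gap_summary(per_subject$gap_pog), error = function(e) NULL)

  sn_gome <- tryCatch(
    list(spearman = spearman_with_ci(per_subject$sn, per_subject$gome),
         ols = ols_fit(per_subject$sn, per_subject$gome)),
    error = function(e) NULL)

  if (is.null(labels) && !is.null(meta) &&
      all(c("palate", "mandible") %in% names(meta)))
    labels <- meta[, c("palate", "mandible")]
  shape_association <- NULL
  if (!is.null(labels)) {
    tab <- .shape_table(labels)
    chi <- tryCatch(chi_square_independence(tab), error = function(e) NULL)
    fis <- tryCatch(fisher_exact_2x2(collapse_to_2x2(tab, "oblique", "convex")),
                    error = function(e) NULL)
    shape_association <- list(
      table = tab, chi_square = chi, fisher_convex_oblique = fis,
      p_bonferroni = if (!is.null(fis))
        bonferroni_adjust(fis$p_two_sided, config$bonferroni_m) else NULL)
  }

  agreement <- if (!is.null(truth)) .agreement_block(truth, config) else NULL

  structure(list(per_subject = per_subject, n_input = n_input,
                 n_skipped = length(skipped), skipped = skipped,
                 gap_go = gap_go, gap_pog = gap_pog, sn_gome = sn_gome,
                 shape_association = shape_association,
                 agreement = agreement, config = config,
                 tool_version = as.character(utils::packageVersion("arcial"))),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Arcial validation study: %d subjects analysed, %d skipped\n",
              nrow(x$per_subject), x$n_skipped))
  if (!is.null(x$gap_go))
    cat(sprintf("  gonion gap:   mean %.2f mm (IQR %.2f-%.2f)%s\n",
                x$gap_go$mean, x$gap_go$q1, x$gap_go$q3,
                if (!is.null(x$gap_go$normality) && x$gap_go$normality$reject)
                  " [non-normal]" else ""))
  if (!is.null(x$gap_pog))
    cat(sprintf("  pogonion gap: mean %.2f mm (IQR %.2f-%.2f)%s\n",
                x$gap_pog$mean, x$gap_pog$q1, x$gap_pog$q3,
                if (!is.null(x$gap_pog$normality) && x$gap_pog$normality$reject)
                  " [non-normal]" else ""))
  if (!is.null(x$sn_gome))
    cat(sprintf("  SN ~ Go-Me: Spearman rho %.3f (%.3f-%.3f), Go-Me = %.2f + %.4f SN\n",
                x$sn_gome$spearman$rho, x$sn_gome$spearman$ci_low,
                x$sn_gome$spearman$ci_high, x$sn_gome$ols$intercept,
                x$sn_gome$ols$slope))
  if (!is.null(x$shape_association) && !is.null(x$shape_association$chi_square)) {
    sa <- x$shape_association
    cat(sprintf("  shape association: X^2 = %.3f (df %d, p %.3g)",
                sa$chi_square$statistic, sa$chi_square$df, sa$chi_square$p))
    if (!is.null(sa$fisher_convex_oblique))
      cat(sprintf("; convex/oblique Fisher p %.4g (Bonferroni %.4g)",
                  sa$fisher_convex_oblique$p_two_sided, sa$p_bonferroni))
    cat("\n")
  }
  invisible(x)
}

# plain-list view of a report for JSON serialization
.report_as_list <- function(x) {
  strip <- function(v) if (is.null(v)) NULL else
    lapply(unclass(v), function(e) if (is.object(e)) strip(e) else e)
  list(per_subject = x$per_subject, n_input = x$n_input,
       n_skipped = x$n_skipped, skipped = x$skipped,
       gap_go = strip(x$gap_go), gap_pog = strip(x$gap_pog),
       sn_gome = if (is.null(x$sn_gome)) NULL else
         list(spearman = strip(x$sn_gome$spearman),
              ols = strip(x$sn_gome$ols)),
       shape_association = if (is.null(x$shape_association)) NULL else
         list(table = unclass(x$shape_association$table),
              chi_square = strip(x$shape_association$chi_square),
              fisher_convex_oblique =
                strip(x$shape_association$fisher_convex_oblique),
              p_bonferroni = x$shape_association$p_bonferroni),
       agreement = if (is.null(x$agreement)) NULL else
         list(table = x$agreement$table, subjects = x$agreement$subjects),
       config = unclass(x$config), tool_version = x$tool_version)
}

#' Write a study report to disk
#'
#' Emits `report.json` (machine-readable, full precision) plus
#' `subjects.tsv`, `agreement.tsv` and `association.tsv` human-readable
#' tables.
#'
#' @param report a [run_validation_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.report_as_list(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  utils::write.table(report$per_subject, file.path(dir, "subjects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(report$agreement)) {
    at <- report$agreement$table
    utils::write.table(cbind(row = rownames(at), at),
                       file.path(dir, "agreement.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$shape_association) &&
      !is.null(report$shape_association$chi_square))
    write_association_tsv(report$shape_association$chi_square,
                          file.path(dir, "association.tsv"))
  invisible(dir)
}

#' Reconstruct mandibular landmarks when the mandible is missing
#'
#' Forensic/archaeological mode: the mandibular plane cannot be derived
#' from Go-Me, so its inclination must be supplied externally (estimating
#' it from cranial landmarks is an open problem). The plane is anchored
#' either at an explicit point or at the intersection of a provisional
#' anterior arc (built from the three cranial planes) with a configured
#' chin-height line; the full construction is then rebuilt with the
#' supplied plane and the arcs intersected as usual. The regression
#' prediction of Go-Me length from SN is reported alongside as an
#' independent check.
#'
#' @param ls a [landmark_set()] in frame coordinates with the cranial
#'   landmarks (S, N, ANS, PNS, Sp, Si, U1, L1, U6, L6).
#' @param mdp_inclination_deg mandibular plane direction, degrees (no
#'   default: the method refuses to guess).
#' @param mdp_anchor optional point the plane passes through.
#' @param chin_height_y frame y of the chin line used to anchor the plane
#'   when `mdp_anchor` is absent.
#' @param config a [study_config()].
#' @return List with `est_Go`, `est_Pog` (points or `NULL` on a geometric
#'   miss), `gome_arc` (distance between the two estimates, when both
#'   exist), `gome_regression` (from [predict_gome_from_sn()]), `sn`,
#'   `construction`, and `notes` (logged caveats).
#' @export
run_missing_mandible <- function(ls, mdp_inclination_deg,
                                 mdp_anchor = NULL, chin_height_y = NULL,
                                 config = study_config()) {
  stopifnot(inherits(ls, "landmark_set"))
  if (missing(mdp_inclination_deg) || is.null(mdp_inclination_deg))
    stop("mdp_inclination_deg must be supplied explicitly: the vertical ",
         "position and inclination of a missing mandible cannot be ",
         "inferred from cranial landmarks by this method")
  notes <- paste("mandibular plane supplied externally; vertical",
                 "positioning of a missing mandible is unsolved by this",
                 "construction")
  if (is.null(mdp_anchor)) {
    if (is.null(chin_height_y))
      stop("supply either mdp_anchor or chin_height_y to anchor the plane")
    cranial <- build_planes_cranial(ls)
    o3 <- locate_point_O(cranial, config$strategy)
    r_ant <- sqrt(sum((o3$point - get_landmark(ls, "ANS"))^2))
    hits <- intersect_line_circle(line2d(c(0, chin_height_y), 0),
                                  circle2d(o3$point, r_ant))
    hits <- Filter(function(p) p[1] > o3$point[1], hits)
    if (!length(hits))
      stop("no solution: the provisional anterior arc does not reach the ",
           "chin-height line y = ", chin_height_y)
    xs <- vapply(hits, `[`, numeric(1), 1L)
    mdp_anchor <- hits[[which.max(xs)]]
    notes <- c(notes, sprintf(
      "plane anchored at the anterior-arc/chin-line intersection (%.2f, %.2f)",
      mdp_anchor[1], mdp_anchor[2]))
  }
  mdp <- line2d(mdp_anchor, mdp_inclination_deg)
  con <- build_construction(ls, config$strategy, mdp = mdp)
  est_go <- estimate_gonion(con)
  est_pog <- estimate_pogonion(con)
  sn <- landmark_dist(ls, "S", "N")
  list(est_Go = est_go, est_Pog = est_pog,
       gome_arc = if (!is.null(est_go) && !is.null(est_pog))
         sqrt(sum((est_go - est_pog)^2)) else NA_real_,
       gome_regression = predict_gome_from_sn(sn), sn = sn,
       construction = con, notes = notes)
}

#' Build only the three cranial planes (no mandible required)
#' @param ls a [landmark_set()] in frame coordinates.
#' @return A list of `line2d` objects: `occlusal`, `palatal`, `basal`.
#' @export
build_planes_cranial <- function(ls) {
  .check_required(ls, c("S", "N", "ANS", "PNS", "Si", "U1", "L1", "U6", "L6"))
  ant_occ <- (get_landmark(ls, "U1") + get_landmark(ls, "L1")) / 2
  post_occ <- (get_landmark(ls, "U6") + get_landmark(ls, "L6")) / 2
  s <- get_landmark(ls, "S"); n <- get_landmark(ls, "N")
  list(occlusal = line_through(ant_occ, post_occ),
       palatal = line_through(get_landmark(ls, "ANS"),
                              get_landmark(ls, "PNS")),
       basal = line2d(get_landmark(ls, "Si"),
                      atan2(n[2] - s[2], n[1] - s[1]) * 180 / pi))
}

# ---------------------------------------------------------------------------
# command-line front end (thin layer over the functions above)

.cli_usage <- function() {
  paste(
    "usage: arcial <command> [options]",
    "",
    "commands:",
    "  simulate   --n N --seed S --out DIR [--sd MM] [--class-shift MM]",
    "  analyze    DIR --out DIR [--seed S] [--strategy least_squares|pairwise_mean]",
    "  reconstruct FILE --inclination DEG (--anchor-x X --anchor-y Y | --chin-y Y) [--out DIR]",
    "  report     REPORT.json --out DIR",
    sep = "\n")
}

.cli_parse_flags <- function(args) {
  flags <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      flags[[substring(a, 3)]] <- args[i + 1L]
      i <- i + 2L
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(flags = flags, pos = pos)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic cohort), `analyze` (run the
#' validation study on a cohort directory), `reconstruct` (missing-mandible
#' mode on one landmark file), `report` (re-render the TSV tables from an
#' existing `report.json`). Returns the process exit code: 0 on success,
#' 2 on a validation/usage error, 1 on a runtime error.
#'
#' @param argv character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit code, invisibly.
#' @export
cli_entry <- function(argv) {
  fail <- function(code, msg) {
    message(msg)
    invisible(code)
  }
  if (!length(argv)) return(fail(2L, .cli_usage()))
  cmd <- argv[1]
  parsed <- tryCatch(.cli_parse_flags(argv[-1]),
                     error = function(e) conditionMessage(e))
  if (is.character(parsed)) return(fail(2L, parsed))
  fl <- parsed$flags; pos <- parsed$pos
  known <- list(
    simulate = c("n", "seed", "out", "sd", "class-shift"),
    analyze = c("out", "seed", "strategy", "log-level"),
    reconstruct = c("inclination", "anchor-x", "anchor-y", "chin-y", "out",
                    "seed", "strategy"),
    report = c("out"))
  if (!cmd %in% names(known))
    return(fail(2L, paste0("unknown command: ", cmd, "\n", .cli_usage())))
  bad <- setdiff(names(fl), known[[cmd]])
  if (length(bad))
    return(fail(2L, paste0("unknown flag(s): ",
                           paste0("--", bad, collapse = ", "), "\n",
                           .cli_usage())))
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  res <- tryCatch(switch(cmd,
    simulate = {
      if (is.null(fl$out)) stop("simulate needs --out", call. = FALSE)
      spec <- cohort_spec(
        n = if (is.null(fl$n)) 100 else as.integer(fl$n),
        digitization_sd = if (is.null(fl$sd)) 0.5 else num(fl$sd),
        class_shift = if (is.null(fl[["class-shift"]])) 6
                      else num(fl[["class-shift"]]),
        seed = if (is.null(fl$seed)) 1L else as.integer(fl$seed))
      write_cohort(generate_cohort(spec), fl$out)
      message("wrote cohort of ", spec$n, " subjects to ", fl$out)
      0L
    },
    analyze = {
      if (length(pos) != 1) stop("analyze needs a cohort directory",
                                 call. = FALSE)
      if (is.null(fl$out)) stop("analyze needs --out", call. = FALSE)
      if (!dir.exists(pos[1]) ||
          !length(list.files(pos[1], pattern = "\\.csv$")))
        stop("no landmark CSV files in ", pos[1], call. = FALSE)
      cfg <- study_config(
        strategy = if (is.null(fl$strategy)) "least_squares" else fl$strategy,
        seed = if (is.null(fl$seed)) 1L else as.integer(fl$seed))
      rep <- run_validation_study(pos[1], cfg)
      write_report(rep, fl$out)
      message("report written to ", fl$out)
      0L
    },
    reconstruct = {
      if (length(pos) != 1) stop("reconstruct needs a landmark file",
                                 call. = FALSE)
      if (is.null(fl$inclination))
        stop("reconstruct needs --inclination", call. = FALSE)
      ls <- .prepare_subject(read_landmarks(pos[1]))
      anchor <- if (!is.null(fl[["anchor-x"]]))
        c(num(fl[["anchor-x"]]), num(fl[["anchor-y"]])) else NULL
      out <- run_missing_mandible(ls, num(fl$inclination),
                                  mdp_anchor = anchor,
                                  chin_height_y = num(fl[["chin-y"]]))
      txt <- jsonlite::toJSON(out[c("est_Go", "est_Pog", "gome_arc",
                                    "gome_regression", "sn", "notes")],
                              auto_unbox = TRUE, digits = NA, null = "null")
      if (!is.null(fl$out)) {
        dir.create(fl$out, recursive = TRUE, showWarnings = FALSE)
        writeLines(txt, file.path(fl$out, "reconstruction.json"))
      } else cat(txt, "\n")
      0L
    },
    report = {
      if (length(pos) != 1 || is.null(fl$out))
        stop("report needs a report.json and --out", call. = FALSE)
      rj <- jsonlite::read_json(pos[1], simplifyVector = TRUE)
      dir.create(fl$out, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(rj$per_subject, file.path(fl$out, "subjects.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(rj$shape_association$table))
        write_association_tsv(
          chi_square_independence(rj$shape_association$table),
          file.path(fl$out, "association.tsv"))
      0L
    }),
    error = function(e) {
      message("error: ", conditionMessage(e))
      # validation errors are raised with call. = FALSE; anything carrying
      # a call is treated as a runtime failure
      if (is.null(conditionCall(e))) 2L else 1L
    })
  invisible(res)
}
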