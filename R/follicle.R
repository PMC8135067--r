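## Follicle-stage classification and section morphometry.

STAGES <- c("I", "II", "III")

#' Classify a follicle growth stage from its diameter
#'
#' Ciona ovarian follicles grow through pre-vitellogenic (stage I, ~50 um),
#' vitellogenic (stage II, ~70 um) and post-vitellogenic (stage III, ~100 um)
#' stages; stage IV follicles are ovulated and absent from sections. Default
#' boundaries are the midpoints of the nominal diameters, half-open upward:
#' I if d < 60, II if 60 <= d < 85, III if d >= 85.
#'
#' @param diameter_um follicle diameter(s) in micrometres, > 0.
#' @param boundaries two increasing cut points (I/II and II/III), in um.
#' @return factor with levels I, II, III.
#' @export
classify_stage <- function(diameter_um, boundaries = c(60, 85)) {
  if (any(diameter_um <= 0)) stop_invalid("diameter must be > 0")
  if (length(boundaries) != 2L || diff(boundaries) <= 0)
    stop_invalid("boundaries must be two increasing values")
  cut(diameter_um, breaks = c(0, boundaries, Inf), labels = STAGES,
      right = FALSE)
}

#' Summarize one ovary section
#'
#' Computes the bench-table quantities for a histological section: follicle
#' counts per stage, total and stage-III densities (follicles/mm2) and the
#' stage-III proportion (%). Stages are taken from a `stage` column when
#' present, otherwise classified from `diameter_um`.
#'
#' @param follicles data.frame with `diameter_um` and/or `stage` columns (or
#'   a bare numeric vector of diameters).
#' @param area_mm2 section area in mm2, > 0.
#' @param boundaries stage boundaries for [classify_stage()].
#' @return object of class `section_summary`: `area`, `n_total`,
#'   `n_by_stage`, `density_total`, `density_stage3`, `prop_stage3` (NA with
#'   `prop_undefined = TRUE` for an empty section), plus rounded report
#'   values (`density_stage3_2dp`, `density_total_1dp`, `prop_stage3_1dp`).
#' @examples
#' wt <- data.frame(stage = rep(c("I", "II", "III"), c(160, 159, 35)))
#' summarize_section(wt, area_mm2 = 5.52)
#' @export
summarize_section <- function(follicles, area_mm2, boundaries = c(60, 85)) {
  if (length(area_mm2) != 1L || area_mm2 <= 0)
    stop_invalid("area_mm2 must be a single positive number")
  if (is.numeric(follicles))
    follicles <- data.frame(diameter_um = follicles)
  stage <- if ("stage" %in% names(follicles)) {
    factor(as.character(follicles$stage), levels = STAGES)
  } else if ("diameter_um" %in% names(follicles)) {
    classify_stage(follicles$diameter_um, boundaries)
  } else stop_invalid("follicles needs a 'stage' or 'diameter_um' column")
  if (anyNA(stage)) stop_invalid("unknown stage labels in follicle table")

  n_by_stage <- table(stage)
  n_total <- sum(n_by_stage)
  n3 <- as.integer(n_by_stage[["III"]])
  out <- list(
    area = area_mm2,
    n_total = n_total,
    n_by_stage = stats::setNames(as.integer(n_by_stage), names(n_by_stage)),
    density_total = n_total / area_mm2,
    density_stage3 = n3 / area_mm2,
    prop_stage3 = if (n_total > 0) 100 * n3 / n_total else NA_real_,
    prop_undefined = n_total == 0
  )
  ## report columns rounded as conventionally printed (half up)
  out$density_stage3_2dp <- round_half_up(out$density_stage3, 2)
  out$density_total_1dp <- round_half_up(out$density_total, 1)
  out$prop_stage3_1dp <- if (out$prop_undefined) NA_real_ else
    round_half_up(out$prop_stage3, 1)
  structure(out, class = "section_summary")
}

#' @export
print.section_summary <- function(x, ...) {
  cat("Ovary section summary\n")
  cat(sprintf("  area:               %.2f mm2\n", x$area))
  cat(sprintf("  follicles:          %d (%s)\n", x$n_total,
              paste(sprintf("%s: %d", names(x$n_by_stage), x$n_by_stage),
                    collapse = ", ")))
  cat(sprintf("  total density:      %.1f follicles/mm2\n", x$density_total))
  cat(sprintf("  stage III density:  %.2f follicles/mm2\n", x$density_stage3))
  if (x$prop_undefined) cat("  stage III fraction: undefined (empty section)\n")
  else cat(sprintf("  stage III fraction: %.1f%%\n", x$prop_stage3))
  invisible(x)
}

#' Fold-ratio comparison of two section summaries
#'
#' Ratios `a / b` of total density, stage-III density and stage-III
#' proportion, raw and rounded half-up to one decimal. A zero denominator
#' yields an undefined (NA) ratio, not an error.
#'
#' @param a,b `section_summary` objects (e.g. mutant and wildtype).
#' @return data.frame with `quantity`, `a`, `b`, `ratio`, `ratio_1dp`.
#' @export
compare_sections <- function(a, b) {
  stopifnot(inherits(a, "section_summary"), inherits(b, "section_summary"))
  one <- function(qa, qb) if (is.na(qb) || qb == 0) NA_real_ else qa / qb
  ratio <- c(one(a$density_total, b$density_total),
             one(a$density_stage3, b$density_stage3),
             one(a$prop_stage3, b$prop_stage3))
  data.frame(
    quantity = c("density_total", "density_stage3", "prop_stage3"),
    a = c(a$density_total, a$density_stage3, a$prop_stage3),
    b = c(b$density_total, b$density_stage3, b$prop_stage3),
    ratio = ratio,
    ratio_1dp = round_half_up(ratio, 1),
    stringsAsFactors = FALSE
  )
}

#' Read a follicle table (CSV)
#'
#' @param path CSV with `follicle_id` and `diameter_um` and/or `stage`.
#' @return data.frame.
#' @export
read_follicles <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
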