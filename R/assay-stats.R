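.welch <- function(a, b, welch = TRUE) {
  # degenerate noise-free groups: identical means are null, distinct ones
  # are "infinitely" significant
  if (stats::var(a) == 0 && stats::var(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = !welch)$p.value
}

#' Relative expression from qPCR Ct values (delta-delta-Ct)
#'
#' Per well, \code{dCt = target_ct - housekeeping_ct} (the housekeeping
#' gene plays the RPLP0 role); \code{ddCt = mean dCt(treated) - mean
#' dCt(control)}; relative expression is \code{2^-ddCt} and
#' \code{percent_change = (2^-ddCt - 1) * 100} (negative = knockdown).
#' The p-value is a two-sided Welch t test on the per-well dCt values.
#'
#' @param plate data frame with columns \code{group}
#'   (\code{"control"} / \code{"treated"}), \code{target_ct},
#'   \code{housekeeping_ct}; Ct values must lie in (0, 45) and each group
#'   needs >= 2 wells.
#' @param welch use Welch's unequal-variance t (default); \code{FALSE}
#'   for Student's t.
#' @return A list: \code{ddct}, \code{relative_expression},
#'   \code{percent_change}, \code{p}.
#' @export
ddctKnockdown <- function(plate, welch = TRUE) {
  need <- c("group", "target_ct", "housekeeping_ct")
  miss <- setdiff(need, names(plate))
  if (length(miss)) stop("plate missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(plate$housekeeping_ct)) stop("missing housekeeping well")
  if (anyNA(plate$target_ct)) stop("missing target well")
  ct <- c(plate$target_ct, plate$housekeeping_ct)
  if (any(ct <= 0 | ct >= 45)) stop("Ct values must lie in (0, 45)")
  if (!all(c("control", "treated") %in% plate$group))
    stop("both a control and a treated group are required")
  dct <- plate$target_ct - plate$housekeeping_ct
  dc <- dct[plate$group == "control"]
  dt <- dct[plate$group == "treated"]
  if (length(dc) < 2L || length(dt) < 2L)
    stop("each group needs >= 2 replicate wells")
  ddct <- mean(dt) - mean(dc)
  rel <- 2^(-ddct)
  list(ddct = ddct, relative_expression = rel,
       percent_change = (rel - 1) * 100, p = .welch(dt, dc, welch))
}

#' Transwell invasion assay summary
#'
#' Fields are averaged within each experiment first; the inference unit is
#' the experiment (the design expects 3 independent experiments with 9
#' imaged fields each; deviations are accepted). Reports per-group
#' experiment means, grand mean with SEM over experiment means, the
#' percent decrease of the treated group versus control, and a Welch t
#' p-value on the per-experiment means. A per-field analysis is available
#' as a sensitivity check.
#'
#' @param fields data frame with columns \code{experiment_id},
#'   \code{field_id}, \code{group} (\code{"control"} / \code{"treated"}),
#'   \code{cell_count} (non-negative integers).
#' @param unit \code{"experiment"} (default) or \code{"field"}.
#' @param welch Welch t (default) or Student's t.
#' @return A list: \code{experiment_means} (data frame), \code{mean} and
#'   \code{sem} per group, \code{percent_decrease}, \code{p}.
#' @export
invasionSummary <- function(fields, unit = c("experiment", "field"),
                            welch = TRUE) {
  unit <- match.arg(unit)
  need <- c("experiment_id", "field_id", "group", "cell_count")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(fields$cell_count < 0)) stop("cell counts must be >= 0")
  em <- stats::aggregate(cell_count ~ group + experiment_id, fields, mean)
  splitBy <- if (unit == "experiment") em else fields
  vc <- splitBy$cell_count[splitBy$group == "control"]
  vt <- splitBy$cell_count[splitBy$group == "treated"]
  if (length(vc) < 2L || length(vt) < 2L)
    stop("each group needs >= 2 ", unit, "s")
  mc <- mean(vc); mt <- mean(vt)
  if (mc == 0) stop("control mean is zero; percent decrease undefined")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  list(experiment_means = em,
       mean = c(control = mc, treated = mt),
       sem = c(control = sem(vc), treated = sem(vt)),
       percent_decrease = (1 - mt / mc) * 100,
       p = .welch(vt, vc, welch))
}

#' MTT proliferation signal and group comparison
#'
#' Background-subtracted viability signal \code{od570 - od650} per well,
#' compared between two groups with a Welch t test; the "no change in
#' proliferation" claim is operationalized as p >= 0.05.
#'
#' @param od570,od650 paired optical-density readings per well.
#' @param group per-well labels (\code{"control"} / \code{"treated"}).
#' @param welch Welch t (default) or Student's t.
#' @return A list: \code{signal}, group \code{means}, \code{p},
#'   \code{no_change}.
#' @export
mttSignal <- function(od570, od650, group, welch = TRUE) {
  if (length(od570) != length(od650) || length(od570) != length(group))
    stop("od570, od650 and group must be paired per well")
  sig <- od570 - od650
  sc <- sig[group == "control"]; st <- sig[group == "treated"]
  if (length(sc) < 2L || length(st) < 2L)
    stop("each group needs >= 2 wells")
  p <- .welch(st, sc, welch)
  list(signal = sig, means = c(control = mean(sc), treated = mean(st)),
       p = p, no_change = p >= 0.05)
}

#' Spheroid invasion-area comparison
#'
#' Percent decrease of the invaded area in the treated group versus
#' control, with a Welch t test on the per-spheroid areas.
#'
#' @param area positive invaded areas, one per spheroid.
#' @param group per-spheroid labels (\code{"control"} / \code{"treated"});
#'   >= 3 spheroids per group.
#' @param welch Welch t (default) or Student's t.
#' @return A list: group \code{means}, \code{percent_decrease}, \code{p}.
#' @export
spheroidInvasion <- function(area, group, welch = TRUE) {
  if (any(area <= 0)) stop("areas must be positive")
  ac <- area[group == "control"]; at <- area[group == "treated"]
  if (length(ac) < 3L || length(at) < 3L)
    stop("each group needs >= 3 spheroids")
  list(means = c(control = mean(ac), treated = mean(at)),
       percent_decrease = (1 - mean(at) / mean(ac)) * 100,
       p = .welch(at, ac, welch))
}
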