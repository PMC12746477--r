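#' Default dosimetric criteria for prostate MRgART plan evaluation
#'
#' The twelve per-structure dose-volume criteria with their clinical
#' tolerances used to decide whether a recalculated adapt-to-position plan
#' is still acceptable on the daily anatomy. Each row is a strict
#' inequality on one DVH metric plus a signed tolerance that relaxes the
#' limit: a "<" criterion relaxes upward (positive tolerance), a ">"
#' criterion relaxes downward (negative tolerance).
#'
#' @return `data.frame(structure, metric, comparator, limit, tolerance,
#'   unit)` with 12 rows.
#' @export
default_criteria <- function() {
  data.frame(
    structure = c("CTV4000", "PTV", "PTV", "Rectum", "Rectum", "Rectum",
                  "Rectum", "Bladder", "Bladder", "Femur R", "Femur L",
                  "Urethra"),
    metric = c("V40Gy", "V36.25Gy", "V34.40Gy", "Dmax", "V38Gy", "V36Gy",
               "V29Gy", "V37Gy", "V18.1Gy", "V14.5Gy", "V14.5Gy", "D50%"),
    comparator = c(">", ">", ">", "<", "<", "<", "<", "<", "<", "<", "<",
                   "<"),
    limit = c(95, 95, 98, 40, 0.1, 1, 20, 10, 50, 5, 5, 41),
    tolerance = c(-5, -5, -5, 0, 0, 1, 1, 0.5, 2.5, 0.5, 0.5, 1.5),
    unit = c("%", "%", "%", "Gy", "cc", "cc", "%", "cc", "%", "%", "%",
             "Gy"),
    stringsAsFactors = FALSE)
}

validate_criteria <- function(criteria) {
  needed <- c("structure", "metric", "comparator", "limit", "tolerance",
              "unit")
  if (!all(needed %in% names(criteria)))
    stop("criteria must have columns ", paste(needed, collapse = ", "))
  if (!all(criteria$comparator %in% c("<", ">")))
    stop("comparator must be '<' or '>'")
  bad <- (criteria$comparator == "<" & criteria$tolerance < 0) |
         (criteria$comparator == ">" & criteria$tolerance > 0)
  if (any(bad))
    stop("tolerance sign inconsistent with comparator for: ",
         paste(criteria$structure[bad], criteria$metric[bad], collapse = "; "))
  criteria
}

#' Evaluate a DVH metric table against dosimetric criteria
#'
#' Applies each criterion as a strict inequality: for a "<" criterion with tolerance
#' `t`, a value strictly below the limit passes strictly, a value in
#' `[limit, limit + t)` passes within tolerance, anything else (including
#' a value exactly at the relaxed limit) is violated; symmetric logic for
#' ">" criteria with their negative tolerances. The plan is acceptable iff
#' no criterion is violated.
#'
#' @param dvh `data.frame(structure, metric, value, unit)` covering every
#'   criterion's (structure, metric); a missing metric is an error naming
#'   it.
#' @param criteria criteria table, see [default_criteria()].
#' @return object of class `plan_evaluation`: list with `results` (the
#'   criteria table plus `value` and `status` in `pass_strict`,
#'   `pass_within_tolerance`, `violated`) and `acceptable`.
#' @export
evaluate_plan <- function(dvh, criteria = default_criteria()) {
  criteria <- validate_criteria(criteria)
  key_c <- paste(criteria$structure, criteria$metric)
  key_d <- paste(dvh$structure, dvh$metric)
  pos <- match(key_c, key_d)
  if (anyNA(pos))
    stop("DVH table is missing metric(s): ",
         paste(key_c[is.na(pos)], collapse = "; "))
  value <- dvh$value[pos]
  if (any(!is.finite(value)) || any(value < 0))
    stop("DVH values must be finite and non-negative")
  status <- character(nrow(criteria))
  for (i in seq_len(nrow(criteria))) {
    lim <- criteria$limit[i]; tol <- criteria$tolerance[i]
    v <- value[i]
    if (criteria$comparator[i] == "<") {
      status[i] <- if (v < lim) "pass_strict"
        else if (v < lim + tol) "pass_within_tolerance" else "violated"
    } else {
      status[i] <- if (v > lim) "pass_strict"
        else if (v > lim + tol) "pass_within_tolerance" else "violated"
    }
  }
  results <- cbind(criteria, value = value, status = status)
  structure(list(results = results,
                 acceptable = !any(status == "violated")),
            class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("<plan_evaluation> %s (%d strict / %d within tolerance / %d violated)\n",
              if (x$acceptable) "ACCEPTABLE" else "NOT acceptable",
              sum(x$results$status == "pass_strict"),
              sum(x$results$status == "pass_within_tolerance"),
              sum(x$results$status == "violated")))
  viol <- x$results[x$results$status == "violated", ]
  if (nrow(viol) > 0)
    for (i in seq_len(nrow(viol)))
      cat(sprintf("  violated: %s %s = %.3g (%s %.3g, tol %+.3g)\n",
                  viol$structure[i], viol$metric[i], viol$value[i],
                  viol$comparator[i], viol$limit[i], viol$tolerance[i]))
  invisible(x)
}

#' Dosimetric ground-truth strategy decision
#'
#' Codifies the labelling rule: if the recalculated ATP plan passes every
#' criterion (strictly or within tolerance) the fraction is labelled ATP;
#' otherwise ATS. If the ATS plan itself is unacceptable the label is
#' still ATS (there is no better option) but the case is flagged.
#'
#' @param dvh_atp,dvh_ats DVH metric tables of the two candidate plans.
#' @param criteria criteria table.
#' @return object of class `strategy_decision`: list with `label`
#'   (`"ATP"`/`"ATS"`), `flagged`, and the two `plan_evaluation`s.
#' @export
determine_strategy <- function(dvh_atp, dvh_ats,
                               criteria = default_criteria()) {
  ev_atp <- evaluate_plan(dvh_atp, criteria)
  ev_ats <- evaluate_plan(dvh_ats, criteria)
  label <- if (ev_atp$acceptable) "ATP" else "ATS"
  structure(list(label = label,
                 flagged = !ev_atp$acceptable && !ev_ats$acceptable,
                 atp = ev_atp, ats = ev_ats),
            class = "strategy_decision")
}

#' @export
print.strategy_decision <- function(x, ...) {
  cat(sprintf("<strategy_decision> %s%s\n", x$label,
              if (x$flagged) " (flagged: ATS plan also unacceptable)" else ""))
  invisible(x)
}

#' Read / write criteria as YAML
#'
#' Criteria tables round-trip through a YAML schema (one document with a
#' `criteria` list of row records).
#'
#' @param criteria criteria `data.frame`.
#' @param path file path.
#' @return `read_criteria()` returns the criteria `data.frame`.
#' @export
write_criteria <- function(criteria, path) {
  criteria <- validate_criteria(criteria)
  rows <- lapply(seq_len(nrow(criteria)), function(i) as.list(criteria[i, ]))
  yaml::write_yaml(list(criteria = rows), path)
  invisible(path)
}

#' @rdname write_criteria
#' @export
read_criteria <- function(path) {
  doc <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(doc$criteria, function(r)
    data.frame(structure = r$structure, metric = r$metric,
               comparator = r$comparator, limit = as.numeric(r$limit),
               tolerance = as.numeric(r$tolerance), unit = r$unit,
               stringsAsFactors = FALSE)))
  validate_criteria(out)
}
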