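#' Stimulation timepoints of the study design
#'
#' The IL-2 stimulation course: unstimulated baseline plus 0.5, 1, 2 and 4
#' hours. All per-patient analyses require all five.
#' @export
DNB_TIMEPOINTS <- c(0, 0.5, 1, 2, 4)

.hour_key <- function(h)
  vapply(h, function(x) format(x, trim = TRUE, scientific = FALSE), "")

#' One patient's stimulation time course
#'
#' Bundles the five per-timepoint expression matrices of one patient with
#' the patient id and clinical group. Every timepoint must be present (the
#' 2h-4h score difference and baseline-relative ranking leave no room for
#' imputation) and marker panels must agree across timepoints.
#'
#' @param patient_id character scalar.
#' @param group one of `"HC"`, `"aSLE"`, `"rSLE"`.
#' @param matrices named list of [dnb_expression], names the hours
#'   (`"0"`, `"0.5"`, `"1"`, `"2"`, `"4"`).
#' @return An object of class `dnb_sample`.
#' @export
dnb_sample <- function(patient_id, group = c("HC", "aSLE", "rSLE"), matrices) {
  group <- match.arg(group)
  want <- .hour_key(DNB_TIMEPOINTS)
  if (!setequal(names(matrices), want) || length(matrices) != length(want))
    stop(sprintf("patient %s: need matrices at exactly hours {%s}; got {%s}",
                 patient_id, paste(want, collapse = ", "),
                 paste(names(matrices), collapse = ", ")), call. = FALSE)
  matrices <- matrices[want]
  for (m in matrices) stopifnot(inherits(m, "dnb_expression"))
  panels <- lapply(matrices, `[[`, "marker_names")
  if (!all(vapply(panels, identical, logical(1), panels[[1]])))
    stop(sprintf("patient %s: marker panels differ across timepoints", patient_id),
         call. = FALSE)
  structure(list(patient_id = as.character(patient_id), group = group,
                 matrices = matrices),
            class = "dnb_sample")
}

#' @export
print.dnb_sample <- function(x, ...) {
  cat(sprintf("<dnb_sample> %s (%s): %d markers, cells per hour: %s\n",
              x$patient_id, x$group, length(x$matrices[[1]]$marker_names),
              paste(vapply(x$matrices, function(m) nrow(m$values), 0L),
                    collapse = "/")))
  invisible(x)
}

#' Marker panel of a sample
#' @param sample a [dnb_sample].
#' @return Character vector of marker names.
#' @export
sample_panel <- function(sample) {
  stopifnot(inherits(sample, "dnb_sample"))
  sample$matrices[[1]]$marker_names
}

#' Validate a clinical table
#'
#' Checks the clinical record contract: columns `patient_id`, `group`,
#' `SLEDAI`, `ESR`, `outcome`; SLEDAI non-negative; group consistency with
#' disease activity (aSLE means SLEDAI > 5, rSLE means SLEDAI <= 5).
#' Violations are reported as warnings, never silently repaired.
#'
#' @param clinical data.frame of clinical records.
#' @return The (unchanged) data.frame, invisibly, with outcome normalised to
#'   `remission` / `flare` / `unknown`.
#' @export
validate_clinical <- function(clinical) {
  need <- c("patient_id", "group", "SLEDAI", "ESR", "outcome")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(clinical$patient_id))
    stop("duplicated patient ids in clinical table", call. = FALSE)
  bad <- !clinical$group %in% c("HC", "aSLE", "rSLE")
  if (any(bad))
    stop("unknown group labels: ", paste(unique(clinical$group[bad]), collapse = ", "),
         call. = FALSE)
  s <- clinical$SLEDAI
  if (any(!is.na(s) & s < 0))
    warning("negative SLEDAI scores present", call. = FALSE)
  inc <- !is.na(s) &
    ((clinical$group == "aSLE" & s <= 5) | (clinical$group == "rSLE" & s > 5))
  if (any(inc))
    warning("group/SLEDAI inconsistency (aSLE requires SLEDAI > 5, rSLE <= 5) for: ",
            paste(clinical$patient_id[inc], collapse = ", "), call. = FALSE)
  clinical$outcome[is.na(clinical$outcome)] <- "unknown"
  bad_out <- !clinical$outcome %in% c("remission", "flare", "unknown")
  if (any(bad_out))
    stop("outcome must be remission/flare/unknown; got: ",
         paste(unique(clinical$outcome[bad_out]), collapse = ", "), call. = FALSE)
  invisible(clinical)
}
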