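#' Class-reference profile
#'
#' Feature-wise arithmetic mean of all samples of one class, optionally
#' excluding some samples (used to restrict references to the training fold
#' inside cross-validation).
#'
#' @param dataset an [expression_dataset()].
#' @param class_label 1 (disease) or -1 (control).
#' @param exclude_ids optional character vector of sample IDs to leave out.
#' @return Length-K numeric reference vector.
#' @export
build_reference <- function(dataset, class_label, exclude_ids = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"),
            class_label %in% c(1, -1))
  keep <- dataset$labels == class_label
  if (!is.null(exclude_ids))
    keep <- keep & !(dataset$sample_ids %in% exclude_ids)
  if (!any(keep))
    stop("build_reference: no samples of class ", class_label,
         " remain after exclusion")
  colMeans(dataset$values[keep, , drop = FALSE])
}

#' Decompose one reference/test mixture
#'
#' Runs the two-stage sparse component analysis on a single 2 x K linear
#' mixture model (row 1 = reference, row 2 = test sample): single-component
#' points are selected at tolerance `delta_theta`, their directions clustered
#' into M mixing columns, and the M x K source matrix recovered by [ist_solve()].
#'
#' @param reference length-K reference profile.
#' @param test length-K test sample.
#' @param M postulated number of components (grid \{2..5\}).
#' @param delta_theta SCP tolerance in degrees (grid \{1, 3, 5\}).
#' @param solver a [solver_config()].
#' @param max_scps cap on the number of SCP vectors clustered
#'   (see [cluster_mixing()]).
#' @return List with `mixing` (a `mixing_estimate`) and `sources`
#'   (a `source_estimate`).
#' @export
decompose_sample <- function(reference, test, M, delta_theta,
                             solver = solver_config(), max_scps = 500L) {
  rows <- rbind(as.numeric(reference), as.numeric(test))
  mix <- analytic_mixture(rows)
  scps <- select_scps(mix, delta_theta)
  vectors <- orient_scp_vectors(rows, scps)
  mixing <- cluster_mixing(vectors, M, max_points = max_scps)
  sources <- ist_solve(mixing$A, rows, solver)
  list(mixing = mixing, sources = sources)
}

#' Select disease- and control-specific components by mixing angle
#'
#' With a control reference (row 1 of the mixture is the control-group
#' profile), the component whose mixing column confines the maximal angle to
#' the reference axis is disease-specific and the minimal-angle component is
#' control-specific; with a disease reference the logic is the opposite.
#' Remaining components are neutral (none when M = 2). Angle ties are broken
#' toward the lowest column index with a warning.
#'
#' @param mixing a `mixing_estimate`.
#' @param sources a `source_estimate` from the same decomposition.
#' @param reference_role `"control"` or `"disease"` — the class of the
#'   reference sample in row 1.
#' @return An object of class `selected_components`: list with
#'   `disease_component`, `control_component` (length-K), `neutral_components`
#'   ((M-2) x K), `disease_angle`, `control_angle` and `provenance`.
#' @export
select_components <- function(mixing, sources, reference_role = c("control", "disease")) {
  reference_role <- match.arg(reference_role)
  angles <- mixing$angles
  if (length(angles) < 2L) stop("select_components: need M >= 2")
  if (sum(angles == max(angles)) > 1L || sum(angles == min(angles)) > 1L)
    warning("select_components: angle tie at the extremum; ",
            "lowest column index wins")
  i_max <- which.max(angles)
  i_min <- which.min(angles)
  if (reference_role == "control") {
    i_disease <- i_max; i_control <- i_min
  } else {
    i_disease <- i_min; i_control <- i_max
  }
  rest <- setdiff(seq_along(angles), c(i_disease, i_control))
  structure(list(
    disease_component = sources$S[i_disease, ],
    control_component = sources$S[i_control, ],
    neutral_components = sources$S[rest, , drop = FALSE],
    disease_angle = angles[i_disease],
    control_angle = angles[i_control],
    provenance = list(reference_role = reference_role)),
    class = "selected_components")
}

#' Extract the four labelled component sets from a dataset
#'
#' For every sample, builds the two reference-based mixtures (control
#' reference and disease reference), decomposes each and collects the
#' automatically selected components into four N x K sets:
#' `controlref_disease`, `controlref_control`, `diseaseref_control`,
#' `diseaseref_disease`, each carrying the sample labels.
#'
#' @param dataset an [expression_dataset()].
#' @param M,delta_theta,solver decomposition parameters
#'   (see [decompose_sample()]).
#' @param reference_policy `"train_only"` computes references from
#'   `train_ids` exclusively (no information from held-out samples leaks into
#'   the references); `"all"` averages over every sample of the class.
#' @param train_ids sample IDs of the training fold (required for
#'   `"train_only"`).
#' @param max_scps cap on clustered SCP vectors.
#' @return An object of class `component_sets`: list with `sets` (named list
#'   of four N x K matrices), `labels`, `feature_ids`, `sample_ids`, `angles`
#'   (N x 4 matrix of the selected disease/control angles per reference) and
#'   `params`.
#' @export
extract_feature_sets <- function(dataset, M = 3L, delta_theta = 3,
                                 solver = solver_config(),
                                 reference_policy = c("all", "train_only"),
                                 train_ids = NULL, max_scps = 500L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  reference_policy <- match.arg(reference_policy)
  if (reference_policy == "train_only") {
    if (is.null(train_ids))
      stop("extract_feature_sets: train_ids required for reference_policy = 'train_only'")
    exclude <- setdiff(dataset$sample_ids, train_ids)
  } else {
    exclude <- NULL
  }
  ref_control <- build_reference(dataset, -1, exclude_ids = exclude)
  ref_disease <- build_reference(dataset, 1, exclude_ids = exclude)

  n <- nrow(dataset$values); k <- ncol(dataset$values)
  set_names <- c("controlref_disease", "controlref_control",
                 "diseaseref_control", "diseaseref_disease")
  sets <- lapply(set_names, function(.) matrix(0, n, k))
  names(sets) <- set_names
  angles <- matrix(NA_real_, n, 4L,
                   dimnames = list(NULL, c("controlref_disease", "controlref_control",
                                           "diseaseref_disease", "diseaseref_control")))
  for (i in seq_len(n)) {
    x <- dataset$values[i, ]
    sel_c <- tryCatch({
      dec <- decompose_sample(ref_control, x, M, delta_theta, solver, max_scps)
      select_components(dec$mixing, dec$sources, "control")
    }, error = function(e)
      stop("sample ", dataset$sample_ids[i],
           " (control reference, M = ", M, ", delta_theta = ", delta_theta,
           "): ", conditionMessage(e), call. = FALSE))
    sel_d <- tryCatch({
      dec <- decompose_sample(ref_disease, x, M, delta_theta, solver, max_scps)
      select_components(dec$mixing, dec$sources, "disease")
    }, error = function(e)
      stop("sample ", dataset$sample_ids[i],
           " (disease reference, M = ", M, ", delta_theta = ", delta_theta,
           "): ", conditionMessage(e), call. = FALSE))
    sets$controlref_disease[i, ] <- sel_c$disease_component
    sets$controlref_control[i, ] <- sel_c$control_component
    sets$diseaseref_control[i, ] <- sel_d$control_component
    sets$diseaseref_disease[i, ] <- sel_d$disease_component
    angles[i, ] <- c(sel_c$disease_angle, sel_c$control_angle,
                     sel_d$disease_angle, sel_d$control_angle)
  }
  structure(list(sets = sets, labels = dataset$labels,
                 feature_ids = dataset$feature_ids,
                 sample_ids = dataset$sample_ids,
                 angles = angles,
                 references = list(control = ref_control, disease = ref_disease),
                 params = list(M = M, delta_theta = delta_theta,
                               lambda_multiplier = solver$lambda_multiplier,
                               nonnegative = solver$nonnegative,
                               reference_policy = reference_policy)),
            class = "component_sets")
}

#' @export
print.component_sets <- function(x, ...) {
  d <- dim(x$sets[[1L]])
  cat("Component sets (", paste(names(x$sets), collapse = ", "), ")\n", sep = "")
  cat(sprintf("  %d samples x %d features each; M = %s, delta_theta = %s deg, lambda = %g * lambda_max\n",
              d[1L], d[2L], x$params$M, x$params$delta_theta,
              x$params$lambda_multiplier))
  invisible(x)
}
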