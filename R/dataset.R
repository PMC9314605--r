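#' Aggregate contrast-level study
#'
#' A study contributing relative treatment effects on a continuous scale
#' (mean difference, SMD, log odds/risk/hazard ratio) with standard errors,
#' against a designated reference arm (the first arm listed).
#'
#' @param study_id study identifier.
#' @param combos list of \code{treatment_combination} (or label strings);
#'   the first is the reference arm.
#' @param y numeric vector of relative effects vs the reference arm, one per
#'   non-reference arm.
#' @param se positive standard errors, same length as \code{y}.
#' @param scale one of \code{"MD"}, \code{"SMD"}, \code{"logOR"},
#'   \code{"logRR"}, \code{"logHR"}.
#' @param catalog the \code{\link{component_catalog}}.
#' @param ref_se optional standard error of the reference arm, inducing the
#'   covariance \code{ref_se^2} between the contrasts of a multi-arm study.
#' @param covariate_means optional named numeric vector of study-mean
#'   covariates (for aggregate-data meta-regression in joint fits).
#' @return object of class \code{ad_contrast_study}.
#' @export
ad_contrast_study <- function(study_id, combos, y, se,
                              scale = c("MD", "SMD", "logOR", "logRR", "logHR"),
                              catalog, ref_se = NULL, covariate_means = NULL) {
  scale <- match.arg(scale)
  combos <- lapply(combos, as_combination, catalog = catalog)
  k <- length(combos)
  if (k < 2L) stop("study ", study_id, ": needs >= 2 arms")
  labs <- vapply(combos, combination_label, "")
  if (anyDuplicated(labs)) stop("study ", study_id, ": duplicated combination among arms")
  if (length(y) != k - 1L || length(se) != k - 1L)
    stop("study ", study_id, ": y and se must have one entry per non-reference arm")
  if (any(!is.finite(y)) || any(!is.finite(se)))
    stop("study ", study_id, ": non-finite y or se")
  if (any(se <= 0)) stop("study ", study_id, ": se must be > 0")
  if (!is.null(ref_se) && (!is.finite(ref_se) || ref_se < 0))
    stop("study ", study_id, ": ref_se must be >= 0")
  structure(list(study_id = as.character(study_id), combos = combos,
                 y = as.numeric(y), se = as.numeric(se), scale = scale,
                 ref_se = ref_se, covariate_means = covariate_means),
            class = "ad_contrast_study")
}

#' Aggregate arm-level study
#'
#' A study reporting per-arm summaries: events/size for a binary outcome, or
#' mean/SD/size for a continuous outcome, optionally with study-level
#' covariate means (for aggregate-data meta-regression).
#'
#' @param study_id study identifier.
#' @param combos list of combinations (first arm is the study baseline arm).
#' @param outcome \code{"binary"} or \code{"continuous"}.
#' @param r,n events and sizes per arm (binary).
#' @param mean,sd per-arm means and SDs (continuous; \code{n} also required).
#' @param covariate_means optional named numeric vector of study-mean
#'   covariate values.
#' @param catalog the \code{\link{component_catalog}}.
#' @return object of class \code{ad_arm_study}.
#' @export
ad_arm_study <- function(study_id, combos, outcome = c("binary", "continuous"),
                         r = NULL, n, mean = NULL, sd = NULL,
                         covariate_means = NULL, catalog) {
  outcome <- match.arg(outcome)
  combos <- lapply(combos, as_combination, catalog = catalog)
  k <- length(combos)
  if (k < 2L) stop("study ", study_id, ": needs >= 2 arms")
  labs <- vapply(combos, combination_label, "")
  if (anyDuplicated(labs)) stop("study ", study_id, ": duplicated combination among arms")
  if (length(n) != k || any(!is.finite(n)) || any(n <= 0))
    stop("study ", study_id, ": n must be positive, one per arm")
  if (outcome == "binary") {
    if (is.null(r) || length(r) != k) stop("study ", study_id, ": r required per arm")
    if (any(r < 0) || any(r > n)) stop("study ", study_id, ": invalid event count (need 0 <= r <= n)")
  } else {
    if (is.null(mean) || is.null(sd) || length(mean) != k || length(sd) != k)
      stop("study ", study_id, ": mean and sd required per arm")
    if (any(sd <= 0)) stop("study ", study_id, ": sd must be > 0")
  }
  structure(list(study_id = as.character(study_id), combos = combos,
                 outcome = outcome, r = r, n = as.numeric(n),
                 mean = mean, sd = sd, covariate_means = covariate_means),
            class = "ad_arm_study")
}

#' Individual-participant-data study
#'
#' One row per patient: continuous or binary outcome, assigned treatment
#' combination, and complete (pre-imputed) covariates.
#'
#' @param study_id study identifier.
#' @param patients data.frame with columns \code{patient_id}, \code{arm_label}
#'   (combination label), \code{y}, plus one column per covariate.
#' @param covariate_names character vector naming the covariate columns.
#' @param catalog the \code{\link{component_catalog}}.
#' @param outcome \code{"continuous"} (normal likelihood) or \code{"binary"}
#'   (Bernoulli-logit).
#' @return object of class \code{ipd_study}; \code{patients$arm_label} is
#'   rewritten in canonical form.
#' @export
ipd_study <- function(study_id, patients, covariate_names, catalog,
                      outcome = c("continuous", "binary")) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(patients))
  need <- c("arm_label", "y", covariate_names)
  miss <- setdiff(need, names(patients))
  if (length(miss)) stop("study ", study_id, ": missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(patients) == 0L) stop("study ", study_id, ": no patients")
  combos <- lapply(unique(patients$arm_label), parse_combination, catalog = catalog)
  canon <- vapply(combos, combination_label, "")
  names(canon) <- unique(patients$arm_label)
  patients$arm_label <- unname(canon[patients$arm_label])
  if (length(unique(patients$arm_label)) < 2L)
    stop("study ", study_id, ": needs >= 2 distinct combinations")
  for (v in c("y", covariate_names)) {
    if (any(!is.finite(patients[[v]])))
      stop("study ", study_id, ": non-finite or missing values in '", v,
           "' (covariates must be pre-imputed)")
  }
  if (outcome == "binary" && !all(patients$y %in% c(0, 1)))
    stop("study ", study_id, ": binary outcome must be 0/1")
  structure(list(study_id = as.character(study_id), patients = patients,
                 covariate_names = covariate_names, outcome = outcome),
            class = "ipd_study")
}

#' Assemble a component-network dataset
#'
#' Bundles aggregate contrast-level, aggregate arm-level and IPD studies with
#' a component catalog, and centers all covariates by their grand means.
#' Centering constants are the pooled means over all IPD patients (AD study
#' means are centered by the same constants); with aggregate data only, the
#' unweighted mean of the study means is used. The constants are recorded in
#' \code{covariate_means} so patient profiles can be centered consistently at
#' prediction time.
#'
#' @param catalog a \code{\link{component_catalog}}.
#' @param ad_contrast,ad_arm,ipd lists of studies (any may be empty).
#' @param center logical; center covariates (default TRUE).
#' @return object of class \code{network_dataset} with elements
#'   \code{catalog}, \code{ad_contrast}, \code{ad_arm}, \code{ipd},
#'   \code{covariate_names}, \code{covariate_means}.
#' @export
network_dataset <- function(catalog, ad_contrast = list(), ad_arm = list(),
                            ipd = list(), center = TRUE) {
  stopifnot(inherits(catalog, "component_catalog"))
  if (length(ad_contrast) + length(ad_arm) + length(ipd) == 0L)
    stop("empty dataset: at least one study required")
  ids <- c(vapply(ad_contrast, function(s) s$study_id, ""),
           vapply(ad_arm, function(s) s$study_id, ""),
           vapply(ipd, function(s) s$study_id, ""))
  if (anyDuplicated(ids))
    stop("duplicated study_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  cov_names <- character(0)
  if (length(ipd)) {
    cns <- lapply(ipd, function(s) s$covariate_names)
    if (length(unique(vapply(cns, paste, "", collapse = ","))) > 1L)
      stop("IPD studies disagree on covariate columns")
    cov_names <- cns[[1L]]
  } else {
    cms <- lapply(c(ad_arm, ad_contrast), function(s) names(s$covariate_means))
    cms <- unique(cms[!vapply(cms, is.null, TRUE)])
    if (length(cms) > 1L) stop("AD studies disagree on covariate-mean columns")
    if (length(cms)) cov_names <- cms[[1L]]
  }

  cov_means <- stats::setNames(numeric(length(cov_names)), cov_names)
  if (length(cov_names) && center) {
    if (length(ipd)) {
      pooled <- do.call(rbind, lapply(ipd, function(s) s$patients[cov_names]))
      cov_means <- colMeans(pooled)
    } else {
      sm <- do.call(rbind, lapply(c(ad_arm, ad_contrast), function(s)
        s$covariate_means[cov_names]))
      cov_means <- colMeans(sm)
    }
    ipd <- lapply(ipd, function(s) {
      s$patients[cov_names] <- sweep(s$patients[cov_names], 2L, cov_means)
      s
    })
    recenter <- function(s) {
      if (!is.null(s$covariate_means))
        s$covariate_means <- s$covariate_means[cov_names] - cov_means
      s
    }
    ad_arm <- lapply(ad_arm, recenter)
    ad_contrast <- lapply(ad_contrast, recenter)
  }

  structure(list(catalog = catalog, ad_contrast = ad_contrast, ad_arm = ad_arm,
                 ipd = ipd, covariate_names = cov_names,
                 covariate_means = cov_means),
            class = "network_dataset")
}

#' @export
print.network_dataset <- function(x, ...) {
  np <- sum(vapply(x$ipd, function(s) nrow(s$patients), 0L))
  cat("Component network dataset\n",
      "  components:       ", length(x$catalog), "\n",
      "  AD contrast studies: ", length(x$ad_contrast), "\n",
      "  AD arm studies:      ", length(x$ad_arm), "\n",
      "  IPD studies:         ", length(x$ipd), " (", np, " patients)\n", sep = "")
  if (length(x$covariate_names))
    cat("  covariates:          ", paste(x$covariate_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Internal: all studies as one list with an evidence-type tag.
all_studies <- function(dataset) {
  c(dataset$ad_contrast, dataset$ad_arm, dataset$ipd)
}

# Internal: distinct combinations used by a study, as a list.
study_combinations <- function(study, catalog) {
  if (inherits(study, "ipd_study")) {
    lapply(unique(study$patients$arm_label), parse_combination, catalog = catalog)
  } else {
    study$combos
  }
}
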