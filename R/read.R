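#' Read a component-network dataset from CSV files
#'
#' Reads the three study schemas plus the component catalog and returns a
#' validated, covariate-centered \code{\link{network_dataset}}. File formats:
#' \itemize{
#'   \item \code{catalog}: columns \code{code}, optional \code{description}.
#'   \item \code{ad_contrast}: \code{study_id, arm_label, y, se, scale},
#'     optional \code{ref_se}; the reference arm of each study is its first
#'     row and has empty \code{y}/\code{se}.
#'   \item \code{ad_arm}: \code{study_id, arm_label, r, n} (binary) or
#'     \code{study_id, arm_label, mean, sd, n} (continuous); optional
#'     \code{covmean_<name>} columns carry study-mean covariates.
#'   \item \code{ipd}: \code{study_id, patient_id, arm_label, y} plus one
#'     column per covariate; an optional \code{imputation} column (1..m)
#'     marks stacked pre-imputed copies of the data.
#' }
#'
#' @param catalog path to the catalog CSV.
#' @param ad_contrast,ad_arm,ipd optional paths to study CSVs.
#' @param covariate_means optional path to a \code{name,mean} CSV of
#'   pre-computed centering constants (as written by
#'   \code{\link{write_network_data}}); when supplied the covariates are
#'   assumed already centered and are not re-centered.
#' @param ipd_outcome \code{"auto"} (binary iff all outcomes are 0/1),
#'   \code{"continuous"} or \code{"binary"}.
#' @param quiet suppress the load report.
#' @return a \code{network_dataset}, or — when the IPD file carries an
#'   \code{imputation} column — a list of class \code{imputed_network_list}
#'   with one \code{network_dataset} per imputed copy.
#' @export
read_network_data <- function(catalog, ad_contrast = NULL, ad_arm = NULL,
                              ipd = NULL, covariate_means = NULL,
                              ipd_outcome = c("auto", "continuous", "binary"),
                              quiet = FALSE) {
  ipd_outcome <- match.arg(ipd_outcome)
  cat_df <- read_csv_checked(catalog, required = "code")
  cat_obj <- component_catalog(cat_df$code, cat_df$description)

  adc <- if (!is.null(ad_contrast)) read_ad_contrast_csv(ad_contrast, cat_obj) else list()
  ada <- if (!is.null(ad_arm)) read_ad_arm_csv(ad_arm, cat_obj) else list()
  ipd_stacks <- if (!is.null(ipd)) read_ipd_csv(ipd, cat_obj, ipd_outcome) else list(list())

  fixed_means <- NULL
  if (!is.null(covariate_means)) {
    cm <- read_csv_checked(covariate_means, required = c("name", "mean"))
    fixed_means <- stats::setNames(cm$mean, cm$name)
  }

  build <- function(ipd_list) {
    ds <- network_dataset(cat_obj, ad_contrast = adc, ad_arm = ada,
                          ipd = ipd_list, center = is.null(fixed_means))
    if (!is.null(fixed_means)) ds$covariate_means <- fixed_means[ds$covariate_names]
    ds
  }
  out <- lapply(ipd_stacks, build)

  if (!quiet) {
    np <- sum(vapply(out[[1L]]$ipd, function(s) nrow(s$patients), 0L))
    message(sprintf(
      "loaded %d AD contrast, %d AD arm, %d IPD studies (%d patients)%s",
      length(adc), length(ada), length(out[[1L]]$ipd), np,
      if (length(out) > 1L) sprintf(", %d imputed copies", length(out)) else ""))
  }
  if (length(out) == 1L) out[[1L]] else structure(out, class = "imputed_network_list")
}

read_csv_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, ": missing required column(s): ", paste(miss, collapse = ", "))
  df
}

read_ad_contrast_csv <- function(path, catalog) {
  df <- read_csv_checked(path, required = c("study_id", "arm_label", "y", "se", "scale"))
  covcols <- grep("^covmean_", names(df), value = TRUE)
  lapply(split(df, factor(df$study_id, levels = unique(df$study_id))), function(g) {
    ref <- g[1L, ]
    if (is.finite(suppressWarnings(as.numeric(ref$y))))
      stop("file ", path, ", study ", ref$study_id,
           ": first (reference) row must have empty y/se")
    rest <- g[-1L, , drop = FALSE]
    if (nrow(rest) == 0L)
      stop("file ", path, ", study ", ref$study_id, ": needs a non-reference arm")
    ref_se <- if ("ref_se" %in% names(g) && is.finite(suppressWarnings(as.numeric(ref$ref_se))))
      as.numeric(ref$ref_se) else NULL
    cm <- if (length(covcols))
      stats::setNames(as.numeric(ref[covcols]), sub("^covmean_", "", covcols)) else NULL
    ad_contrast_study(ref$study_id, as.list(g$arm_label),
                      y = as.numeric(rest$y), se = as.numeric(rest$se),
                      scale = ref$scale, catalog = catalog, ref_se = ref_se,
                      covariate_means = cm)
  })
}

read_ad_arm_csv <- function(path, catalog) {
  df <- read_csv_checked(path, required = c("study_id", "arm_label", "n"))
  binary <- "r" %in% names(df)
  if (!binary && !all(c("mean", "sd") %in% names(df)))
    stop("file ", path, ": need either an 'r' column (binary) or 'mean'+'sd' (continuous)")
  covcols <- grep("^covmean_", names(df), value = TRUE)
  lapply(split(df, factor(df$study_id, levels = unique(df$study_id))), function(g) {
    cm <- NULL
    if (length(covcols)) {
      cm <- stats::setNames(as.numeric(g[1L, covcols]), sub("^covmean_", "", covcols))
    }
    if (binary) {
      ad_arm_study(g$study_id[1L], as.list(g$arm_label), outcome = "binary",
                   r = as.numeric(g$r), n = as.numeric(g$n),
                   covariate_means = cm, catalog = catalog)
    } else {
      ad_arm_study(g$study_id[1L], as.list(g$arm_label), outcome = "continuous",
                   mean = as.numeric(g$mean), sd = as.numeric(g$sd),
                   n = as.numeric(g$n), covariate_means = cm, catalog = catalog)
    }
  })
}

read_ipd_csv <- function(path, catalog, ipd_outcome = "auto") {
  df <- read_csv_checked(path, required = c("study_id", "patient_id", "arm_label", "y"))
  covs <- setdiff(names(df), c("study_id", "patient_id", "arm_label", "y", "imputation"))
  if (ipd_outcome == "auto")
    ipd_outcome <- if (all(df$y %in% c(0, 1))) "binary" else "continuous"
  stacks <- if ("imputation" %in% names(df)) {
    split(df, factor(df$imputation, levels = sort(unique(df$imputation))))
  } else list(df)
  lapply(stacks, function(stack) {
    lapply(split(stack, factor(stack$study_id, levels = unique(stack$study_id))),
           function(g) {
             ipd_study(g$study_id[1L],
                       g[c("patient_id", "arm_label", "y", covs)],
                       covariate_names = covs, catalog = catalog,
                       outcome = ipd_outcome)
           })
  })
}

#' Write a network dataset to CSV files
#'
#' Writes the schemas read by \code{\link{read_network_data}} into a
#' directory: \code{catalog.csv} and, where the dataset has such studies,
#' \code{ad_contrast.csv}, \code{ad_arm.csv}, \code{ipd.csv}, plus
#' \code{covariate_means.csv} recording the centering constants (covariates
#' are written as stored, i.e. centered). Reading the files back reproduces
#' the dataset exactly.
#'
#' @param dataset a \code{network_dataset}.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_network_data <- function(dataset, dir) {
  stopifnot(inherits(dataset, "network_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(catalog = file.path(dir, "catalog.csv"))
  utils::write.csv(data.frame(code = unclass(dataset$catalog),
                              description = attr(dataset$catalog, "descriptions") %||%
                                rep("", length(dataset$catalog))),
                   paths[["catalog"]], row.names = FALSE)
  if (length(dataset$ad_contrast)) {
    rows <- do.call(rbind, lapply(dataset$ad_contrast, function(s) {
      base <- data.frame(study_id = s$study_id,
                         arm_label = vapply(s$combos, combination_label, ""),
                         y = c(NA, s$y), se = c(NA, s$se), scale = s$scale,
                         ref_se = c(if (is.null(s$ref_se)) NA else s$ref_se,
                                    rep(NA, length(s$y))))
      if (!is.null(s$covariate_means))
        for (nm in names(s$covariate_means))
          base[[paste0("covmean_", nm)]] <- s$covariate_means[[nm]]
      base
    }))
    paths["ad_contrast"] <- file.path(dir, "ad_contrast.csv")
    utils::write.csv(rows, paths[["ad_contrast"]], row.names = FALSE, na = "")
  }
  if (length(dataset$ad_arm)) {
    rows <- do.call(rbind, lapply(dataset$ad_arm, function(s) {
      base <- data.frame(study_id = s$study_id,
                         arm_label = vapply(s$combos, combination_label, ""))
      if (s$outcome == "binary") { base$r <- s$r } else { base$mean <- s$mean; base$sd <- s$sd }
      base$n <- s$n
      if (!is.null(s$covariate_means))
        for (nm in names(s$covariate_means))
          base[[paste0("covmean_", nm)]] <- s$covariate_means[[nm]]
      base
    }))
    paths["ad_arm"] <- file.path(dir, "ad_arm.csv")
    utils::write.csv(rows, paths[["ad_arm"]], row.names = FALSE, na = "")
  }
  if (length(dataset$ipd)) {
    rows <- do.call(rbind, lapply(dataset$ipd, function(s) {
      cbind(data.frame(study_id = s$study_id), s$patients)
    }))
    paths["ipd"] <- file.path(dir, "ipd.csv")
    utils::write.csv(rows, paths[["ipd"]], row.names = FALSE)
  }
  if (length(dataset$covariate_names)) {
    paths["covariate_means"] <- file.path(dir, "covariate_means.csv")
    utils::write.csv(data.frame(name = dataset$covariate_names,
                                mean = unname(dataset$covariate_means)),
                     paths[["covariate_means"]], row.names = FALSE)
  }
  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Diagnose the structure of a component network
#'
#' Reports the distinct treatment combinations, per-component usage counts,
#' treatment-level connected subnetworks (a component model can pool across
#' disconnected subnetworks so long as components are shared), and components
#' that never vary within any study — the classic source of an inestimable
#' main effect, since such a component cancels from every within-study
#' contrast.
#'
#' @param dataset a \code{network_dataset}.
#' @return object of class \code{network_validation} with elements
#'   \code{combinations}, \code{component_usage}, \code{subnetworks},
#'   \code{shared_components} (components appearing in more than one
#'   subnetwork), \code{never_varying} and \code{disconnected} (logical).
#' @export
validate_network <- function(dataset) {
  stopifnot(inherits(dataset, "network_dataset"))
  catalog <- dataset$catalog
  studies <- all_studies(dataset)
  combo_lists <- lapply(studies, study_combinations, catalog = catalog)
  labs <- unique(unlist(lapply(combo_lists, function(cl) vapply(cl, combination_label, ""))))

  usage <- stats::setNames(integer(length(catalog)), unclass(catalog))
  for (cl in combo_lists)
    for (cb in cl) usage[unclass(cb)] <- usage[unclass(cb)] + 1L

  # treatment-level connectivity: nodes = combination labels, edges within studies
  comp_id <- stats::setNames(seq_along(labs), labs)
  parent <- seq_along(labs)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (cl in combo_lists) {
    l <- vapply(cl, combination_label, "")
    for (j in seq_along(l)[-1L]) {
      a <- find(comp_id[[l[1L]]]); b <- find(comp_id[[l[j]]])
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(labs), find, 0L)
  subnetworks <- split(labs, roots)
  names(subnetworks) <- paste0("subnetwork_", seq_along(subnetworks))

  members_of <- function(ls) unique(unlist(lapply(ls, function(l) unclass(parse_combination(l, catalog)))))
  subnet_members <- lapply(subnetworks, members_of)
  shared <- character(0)
  if (length(subnetworks) > 1L) {
    all_m <- unlist(subnet_members)
    shared <- unique(all_m[duplicated(all_m)])
  }

  varies <- stats::setNames(logical(length(catalog)), unclass(catalog))
  for (cl in combo_lists) {
    for (q in unclass(catalog)) {
      inarm <- vapply(cl, function(cb) q %in% unclass(cb), TRUE)
      if (any(inarm) && !all(inarm)) varies[q] <- TRUE
    }
  }
  never_varying <- names(varies)[!varies & usage > 0L]

  structure(list(combinations = sort(labs), component_usage = usage,
                 subnetworks = subnetworks, shared_components = shared,
                 never_varying = never_varying,
                 disconnected = length(subnetworks) > 1L),
            class = "network_validation")
}

#' @export
print.network_validation <- function(x, ...) {
  cat("Network validation\n")
  cat("  distinct combinations:", length(x$combinations), "\n")
  cat("  component usage (arms):\n")
  print(x$component_usage)
  if (x$disconnected) {
    cat("  NETWORK IS DISCONNECTED at the treatment level (",
        length(x$subnetworks), " subnetworks)\n", sep = "")
    if (length(x$shared_components))
      cat("  components shared across subnetworks: ",
          paste(x$shared_components, collapse = ", "),
          " (component model can still pool)\n", sep = "")
  } else {
    cat("  network connected at the treatment level\n")
  }
  if (length(x$never_varying))
    cat("  never varies within any study (main effect inestimable): ",
        paste(x$never_varying, collapse = ", "), "\n", sep = "")
  invisible(x)
}
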