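#' Admitted two-way component interactions
#'
#' The set of unordered component pairs whose interaction terms enter a
#' model, with per-pair prior inclusion probabilities used by the
#' spike-and-slab (SSVS) prior. Pairs not listed are excluded up front
#' (their interaction fixed at zero), mirroring the recommended practice of
#' pre-selecting plausible interactions by expert opinion.
#'
#' @param pairs data.frame with columns \code{comp1}, \code{comp2} and
#'   optionally \code{prior_inclusion}, or a 2-column character matrix.
#' @param catalog a \code{\link{component_catalog}}.
#' @param prior_inclusion default prior inclusion probability for pairs
#'   without their own (default 0.5, i.e. equiprobable interactions).
#' @return object of class \code{interaction_set}: data.frame with columns
#'   \code{comp1}, \code{comp2}, \code{pair} (canonical \code{"p:q"} label)
#'   and \code{prior_inclusion}.
#' @export
interaction_set <- function(pairs, catalog, prior_inclusion = 0.5) {
  stopifnot(inherits(catalog, "component_catalog"))
  if (is.matrix(pairs)) pairs <- data.frame(comp1 = pairs[, 1L], comp2 = pairs[, 2L])
  if (is.null(pairs) || nrow(pairs) == 0L) {
    out <- data.frame(comp1 = character(0), comp2 = character(0),
                      pair = character(0), prior_inclusion = numeric(0))
    return(structure(out, class = c("interaction_set", "data.frame")))
  }
  c1 <- tolower(trimws(pairs$comp1)); c2 <- tolower(trimws(pairs$comp2))
  bad <- setdiff(c(c1, c2), unclass(catalog))
  if (length(bad)) stop("unknown component(s) in interaction pairs: ",
                        paste(unique(bad), collapse = ", "))
  if (any(c1 == c2)) stop("interaction pair with identical components")
  ord <- match(c1, catalog) > match(c2, catalog)
  tmp <- c1[ord]; c1[ord] <- c2[ord]; c2[ord] <- tmp
  p <- if ("prior_inclusion" %in% names(pairs)) pairs$prior_inclusion else
    rep(prior_inclusion, length(c1))
  p[is.na(p)] <- prior_inclusion
  if (any(p <= 0 | p >= 1)) stop("prior_inclusion must lie in (0, 1)")
  out <- data.frame(comp1 = c1, comp2 = c2, pair = paste0(c1, ":", c2),
                    prior_inclusion = p)
  if (anyDuplicated(out$pair))
    stop("duplicated interaction pair(s): ",
         paste(unique(out$pair[duplicated(out$pair)]), collapse = ", "))
  ord2 <- order(match(out$comp1, catalog), match(out$comp2, catalog))
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("interaction_set", "data.frame"))
}

#' All two-way pairs of a catalog
#'
#' @param catalog a \code{\link{component_catalog}}.
#' @param prior_inclusion prior inclusion probability applied to every pair.
#' @return an \code{\link{interaction_set}} containing every unordered pair.
#' @export
all_pairs <- function(catalog, prior_inclusion = 0.5) {
  cmb <- utils::combn(unclass(catalog), 2L)
  interaction_set(data.frame(comp1 = cmb[1L, ], comp2 = cmb[2L, ]),
                  catalog, prior_inclusion)
}

# Internal: 0/1 membership vector (components then admitted pairs).
membership_vector <- function(combo, catalog, interactions = NULL) {
  v <- as.numeric(unclass(catalog) %in% unclass(combo))
  names(v) <- unclass(catalog)
  if (!is.null(interactions) && nrow(interactions)) {
    pv <- as.numeric(interactions$comp1 %in% unclass(combo) &
                       interactions$comp2 %in% unclass(combo))
    names(pv) <- interactions$pair
    v <- c(v, pv)
  }
  v
}

#' Signed design row for a contrast between two combinations
#'
#' The coefficient vector of the relative effect of combination \code{y} vs
#' combination \code{x} under the component model: +1 for components in
#' \code{y} only, -1 for components in \code{x} only, 0 otherwise, and
#' analogously for admitted interaction pairs (an interaction counts for an
#' arm iff both its components are present in that arm).
#'
#' @param x,y \code{treatment_combination}s (or label strings).
#' @param catalog a \code{\link{component_catalog}}.
#' @param interactions optional \code{\link{interaction_set}}.
#' @return named numeric vector over components (and pairs).
#' @export
contrast_design_row <- function(x, y, catalog, interactions = NULL) {
  x <- as_combination(x, catalog); y <- as_combination(y, catalog)
  membership_vector(y, catalog, interactions) -
    membership_vector(x, catalog, interactions)
}

#' Build the design system of a network dataset
#'
#' Produces the combination-by-component membership matrix over all distinct
#' combinations in the network, and the stacked contrast design rows — one
#' row per non-reference arm per study (reference arm: first listed for AD
#' studies, earliest combination in canonical order for IPD studies). Columns
#' are the catalog components followed by admitted interaction pairs.
#'
#' @param dataset a \code{network_dataset}.
#' @param interactions optional \code{\link{interaction_set}}.
#' @return object of class \code{design_system}: list with
#'   \code{combination_matrix}, \code{contrast_rows} (matrix), \code{study_id}
#'   and \code{arm} indices per row, \code{interactions}, and
#'   \code{warnings} (e.g. admitted pairs that never co-occur in any arm).
#' @export
build_design <- function(dataset, interactions = NULL) {
  stopifnot(inherits(dataset, "network_dataset"))
  catalog <- dataset$catalog
  if (is.null(interactions)) interactions <- interaction_set(NULL, catalog)

  studies <- all_studies(dataset)
  rows <- list(); sid <- character(0); arm <- integer(0)
  combo_labs <- character(0)
  for (s in studies) {
    combos <- study_combinations(s, catalog)
    if (inherits(s, "ipd_study")) combos <- combos[order_combinations(combos, catalog)]
    labs <- vapply(combos, combination_label, "")
    combo_labs <- union(combo_labs, labs)
    for (j in seq_along(combos)[-1L]) {
      rows[[length(rows) + 1L]] <-
        contrast_design_row(combos[[1L]], combos[[j]], catalog, interactions)
      sid <- c(sid, s$study_id); arm <- c(arm, j)
    }
  }
  X <- do.call(rbind, rows)
  rownames(X) <- paste0(sid, ".arm", arm)

  cm <- t(vapply(combo_labs,
                 function(l) membership_vector(parse_combination(l, catalog),
                                               catalog, interactions),
                 numeric(length(catalog) + nrow(interactions))))
  rownames(cm) <- combo_labs

  warn <- character(0)
  if (nrow(interactions)) {
    pair_cols <- cm[, interactions$pair, drop = FALSE]
    dead <- interactions$pair[colSums(abs(pair_cols)) == 0]
    if (length(dead))
      warn <- c(warn, paste0("interaction pair(s) never co-occur in any arm: ",
                             paste(dead, collapse = ", ")))
  }
  structure(list(combination_matrix = cm, contrast_rows = X,
                 study_id = sid, arm = arm, catalog = catalog,
                 interactions = interactions, warnings = warn),
            class = "design_system")
}

# Internal: order of a list of combinations by canonical label, catalog-major.
order_combinations <- function(combos, catalog) {
  key <- vapply(combos, function(cb) {
    idx <- match(unclass(cb), catalog)
    paste(sprintf("%03d", idx), collapse = "")
  }, "")
  order(key)
}

#' Estimability diagnostics for a component design
#'
#' A parameter direction is estimable iff it lies in the row space of the
#' stacked contrast design; a relative effect between two combinations is
#' estimable iff its design row does. The rank is computed by singular value
#' decomposition; singular values below \code{tol} times the largest are
#' treated as zero (design entries are 0/±1, so the scale is well behaved).
#' Inestimable directions are reported (null-space basis labelled by
#' components/pairs), not dropped: a Bayesian fit still runs, but posteriors
#' in flat directions simply reproduce their priors.
#'
#' @param design a \code{\link{build_design}} result.
#' @param queries optional list of length-2 vectors/lists of combination
#'   labels \code{c(a, b)}; each is classified estimable or not.
#' @param tol relative singular-value tolerance (default \code{1e-8}).
#' @return object of class \code{estimability_report}: list with
#'   \code{rank}, \code{n_params}, \code{null_space} (matrix, columns are
#'   inestimable directions, rows labelled), \code{inestimable} (parameter
#'   names with any null-space loading), and \code{queries} data.frame.
#' @export
estimability <- function(design, queries = NULL, tol = 1e-8) {
  stopifnot(inherits(design, "design_system"))
  X <- design$contrast_rows
  p <- ncol(X)
  sv <- svd(X, nu = 0, nv = p)
  thresh <- tol * max(sv$d, 0)
  r <- sum(sv$d > thresh)
  null_space <- if (r < p) sv$v[, (r + 1L):p, drop = FALSE] else
    matrix(0, p, 0)
  rownames(null_space) <- colnames(X)
  inest <- colnames(X)[rowSums(abs(null_space)) > 1e-8]

  qdf <- NULL
  if (!is.null(queries) && length(queries)) {
    V1 <- sv$v[, seq_len(r), drop = FALSE]
    qdf <- do.call(rbind, lapply(queries, function(q) {
      row <- contrast_design_row(q[[1L]], q[[2L]], design$catalog,
                                 design$interactions)
      resid <- row - V1 %*% crossprod(V1, row)
      est <- sqrt(sum(resid^2)) <= max(tol * max(sqrt(sum(row^2)), 1), 1e-12)
      data.frame(a = combination_label(as_combination(q[[1L]], design$catalog)),
                 b = combination_label(as_combination(q[[2L]], design$catalog)),
                 estimable = est)
    }))
  }
  structure(list(rank = r, n_params = p, null_space = null_space,
                 inestimable = inest, queries = qdf, tol = tol),
            class = "estimability_report")
}

#' @export
print.estimability_report <- function(x, ...) {
  cat("Estimability report: rank ", x$rank, " of ", x$n_params,
      " parameters\n", sep = "")
  if (length(x$inestimable)) {
    cat("  inestimable direction(s) involve: ",
        paste(x$inestimable, collapse = ", "), "\n",
        "  (posteriors in these directions reproduce their priors)\n", sep = "")
  } else cat("  all parameters estimable\n")
  if (!is.null(x$queries)) {
    cat("  queried contrasts:\n")
    for (i in seq_len(nrow(x$queries)))
      cat(sprintf("    (%s) vs (%s): %s\n", x$queries$a[i], x$queries$b[i],
                  if (x$queries$estimable[i]) "estimable" else "INESTIMABLE"))
  }
  invisible(x)
}
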