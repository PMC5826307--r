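#' Load the architecture-model knowledge base
#'
#' The knowledge base is a YAML file describing the four Halle architecture
#' models relevant to boreal canopies (Massart, Rauh, Roux, Attim): their
#' qualitative trunk/branch/growth habits, a numeric prototype centre in a
#' feature-pair plane (by default P4-P7: point clustering vs stem-space
#' occupancy), and a quadrant rule configuration.  It also carries a second,
#' species-indexed reading of the growth habits; the two readings are kept
#' side by side deliberately and are not reconciled.
#'
#' The packaged file is an editable expert input, not a fitted constant:
#' users working in other forests are expected to adapt the centres.
#'
#' @param path YAML file; defaults to the packaged knowledge base.
#' @return object of class `ham_knowledge`.
#' @export
load_ham_knowledge <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ham_knowledge.yaml", package = "crownarch")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("HAM knowledge file not found: '", path, "'")
  }
  kb <- yaml::read_yaml(path)
  need <- c("Massart", "Rauh", "Roux", "Attim")
  miss <- setdiff(need, names(kb$models))
  if (length(miss)) {
    stop("knowledge base must define all four models; missing: ",
         paste(miss, collapse = ", "))
  }
  centers <- t(vapply(kb$models, function(m) as.numeric(m$center), numeric(2)))
  if (anyDuplicated(centers)) {
    stop("prototype centers must be pairwise distinct")
  }
  structure(kb, class = "ham_knowledge")
}

#' @export
print.ham_knowledge <- function(x, ...) {
  cat(sprintf("<ham_knowledge> %d models, feature pair (%s)\n",
              length(x$models), paste(x$feature_pair, collapse = ", ")))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-8s centre (%.3g, %.3g)  growth: %s\n",
                nm, m$center[1], m$center[2], m$growth))
  }
  invisible(x)
}

#' Feature-pair centre of a (classified) species group
#'
#' Arithmetic mean of a feature pair over the trees assigned to a species.
#' With `scope = "all_assigned"` (default, matching a realistic deployment
#' where truth is unknown) every tree predicted as the species contributes;
#' with `"correct_only"` only correctly classified trees do.
#'
#' @param table feature table.
#' @param species species label of interest.
#' @param pair character vector of two feature column names.
#' @param predictions predicted species per row (defaults to the true
#'   labels, i.e. ground-truth centres).
#' @param scope `"all_assigned"` or `"correct_only"`.
#' @return named numeric vector of length 2.
#' @export
species_center <- function(table, species, pair,
                           predictions = table$species,
                           scope = c("all_assigned", "correct_only")) {
  scope <- match.arg(scope)
  check_feature_columns(table, pair)
  stopifnot(length(pair) == 2L, length(predictions) == nrow(table))
  sel <- predictions == species
  if (scope == "correct_only") sel <- sel & table$species == species
  if (!any(sel)) {
    stop(sprintf("no trees in scope '%s' for species '%s'", scope, species))
  }
  colMeans(as.matrix(table[sel, pair, drop = FALSE]))
}

#' Assign an architecture model to a species centre
#'
#' With the default `nearest_center` rule the centre is compared to the four
#' prototype centres after per-axis min-max scaling over the prototypes
#' (making the assignment invariant to affine rescaling of either feature
#' axis), and the nearest prototype wins.  The alternative `quadrant` rule
#' splits the plane at configured cut lines and maps each quadrant to a
#' model via the knowledge base's quadrant map; a centre exactly on a cut
#' line is deterministically tie-broken to the lower quadrant with a
#' warning.
#'
#' @param center numeric length-2 feature-pair centre.
#' @param knowledge a [load_ham_knowledge()] object.
#' @param rule `"nearest_center"` (default) or `"quadrant"`.
#' @param thresholds quadrant cut lines (length 2); defaults to the
#'   knowledge base's.
#' @param quadrant_map named list `low_low`/`high_low`/`low_high`/
#'   `high_high` -> model; defaults to the knowledge base's.
#' @return object of class `ham_assignment`: list with `ham`, `center`,
#'   `margin` (distance gap to the second-best prototype, scaled units; NA
#'   for the quadrant rule), `rule` and `distances`.
#' @export
assign_ham <- function(center, knowledge,
                       rule = c("nearest_center", "quadrant"),
                       thresholds = NULL, quadrant_map = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(knowledge, "ham_knowledge"), length(center) == 2L)
  center <- as.numeric(center)

  if (rule == "nearest_center") {
    protos <- t(vapply(knowledge$models, function(m) as.numeric(m$center),
                       numeric(2)))
    lo <- apply(protos, 2, min)
    hi <- apply(protos, 2, max)
    spanv <- pmax(hi - lo, 1e-300)
    ps <- sweep(sweep(protos, 2, lo), 2, spanv, "/")
    cs <- (center - lo) / spanv
    d <- sqrt(rowSums(sweep(ps, 2, cs)^2))
    ord <- order(d, names(d))
    structure(list(ham = names(d)[ord[1]], center = center,
                   margin = unname(d[ord[2]] - d[ord[1]]),
                   rule = rule, distances = d),
              class = "ham_assignment")
  } else {
    if (is.null(thresholds)) thresholds <- as.numeric(knowledge$quadrant$thresholds)
    if (is.null(quadrant_map)) quadrant_map <- knowledge$quadrant$map
    stopifnot(length(thresholds) == 2L)
    on_line <- center == thresholds
    if (any(on_line)) {
      warning("centre lies exactly on a quadrant cut line; tie-broken to the lower quadrant",
              call. = FALSE)
    }
    side <- ifelse(center > thresholds, "high", "low")
    key <- paste(side, collapse = "_")
    ham <- quadrant_map[[key]]
    if (is.null(ham)) stop("quadrant map does not define quadrant '", key, "'")
    structure(list(ham = ham, center = center, margin = NA_real_,
                   rule = rule, distances = NULL),
              class = "ham_assignment")
  }
}

#' @export
print.ham_assignment <- function(x, ...) {
  cat(sprintf("<ham_assignment> %s at (%.4g, %.4g), rule %s%s\n",
              x$ham, x$center[1], x$center[2], x$rule,
              if (is.na(x$margin)) "" else sprintf(", margin %.3f", x$margin)))
  invisible(x)
}

#' Growth-habit record for an architecture model
#'
#' @param ham model name (`"Massart"`, `"Rauh"`, `"Roux"` or `"Attim"`).
#' @param knowledge a [load_ham_knowledge()] object.
#' @return list with `trunk`, `branches`, `growth` habit descriptions.
#' @export
habits_for <- function(ham, knowledge) {
  stopifnot(inherits(knowledge, "ham_knowledge"))
  if (!ham %in% names(knowledge$models)) {
    stop(sprintf("unknown architecture model '%s'; valid models: %s",
                 ham, paste(names(knowledge$models), collapse = ", ")))
  }
  m <- knowledge$models[[ham]]
  list(trunk = m$trunk, branches = m$branches, growth = m$growth)
}

#' Gaussian divergence summary of post-classification feature parameters
#'
#' For every species x parameter cell, fits a Gaussian by maximum
#' likelihood (`mu` = mean, `sigma` = population standard deviation) to the
#' predicted-label group (DP) and the true-label group (GT), and reports
#' the relative divergences `delta_mu_pct = (mu_GT - mu_DP) / mu_GT * 100`
#' and likewise for sigma (GT-minus-DP over GT; the sign convention is
#' fixed and documented here).
#'
#' @param table feature table with true `species` labels.
#' @param predictions predicted species per row.
#' @param parameters feature columns to summarize.
#' @return data frame of class `gaussian_summary` with columns `species`,
#'   `parameter`, `mu_dp`, `sigma_dp`, `mu_gt`, `sigma_gt`,
#'   `delta_mu_pct`, `delta_sigma_pct`.
#' @export
gaussian_summary <- function(table, predictions, parameters) {
  stopifnot(length(predictions) == nrow(table))
  check_feature_columns(table, parameters)
  species <- sort(unique(as.character(table$species)))
  fit_group <- function(x) {
    if (length(x) == 0L) return(c(mu = NA_real_, sigma = NA_real_))
    if (length(x) < 2L) {
      warning("group of size < 2: sigma reported as 0", call. = FALSE)
      return(c(mu = mean(x), sigma = 0))
    }
    c(mu = mean(x), sigma = pop_sd(x))
  }
  rows <- list()
  for (sp in species) {
    for (par in parameters) {
      gt <- fit_group(table[[par]][table$species == sp])
      dp <- fit_group(table[[par]][predictions == sp])
      dmu <- if (is.na(dp["mu"]) || gt["mu"] == 0) NA_real_ else
        (gt["mu"] - dp["mu"]) / gt["mu"] * 100
      dsd <- if (is.na(dp["sigma"]) || gt["sigma"] == 0) NA_real_ else
        (gt["sigma"] - dp["sigma"]) / gt["sigma"] * 100
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, parameter = par,
        mu_dp = unname(dp["mu"]), sigma_dp = unname(dp["sigma"]),
        mu_gt = unname(gt["mu"]), sigma_gt = unname(gt["sigma"]),
        delta_mu_pct = unname(dmu), delta_sigma_pct = unname(dsd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gaussian_summary", class(out))
  out
}

#' Identify the architecture model for every classified species
#'
#' Convenience wrapper running [species_center()] and [assign_ham()] for
#' each species present in the predictions and attaching the growth-habit
#' record of the winning model.
#'
#' @param table feature table.
#' @param predictions predicted species per row (use `table$species` for
#'   ground-truth identification).
#' @param knowledge a [load_ham_knowledge()] object.
#' @param pair feature pair; defaults to the knowledge base's
#'   `feature_pair`.
#' @param rule passed to [assign_ham()].
#' @param scope passed to [species_center()].
#' @return data frame with one row per species: centre coordinates,
#'   assigned model, margin and habit texts.
#' @export
identify_ham <- function(table, predictions = table$species, knowledge = NULL,
                         pair = NULL, rule = "nearest_center",
                         scope = "all_assigned") {
  if (is.null(knowledge)) knowledge <- load_ham_knowledge()
  if (is.null(pair)) pair <- as.character(knowledge$feature_pair)
  species <- sort(unique(as.character(predictions)))
  rows <- lapply(species, function(sp) {
    ctr <- species_center(table, sp, pair, predictions = predictions,
                          scope = scope)
    asg <- assign_ham(ctr, knowledge, rule = rule)
    hab <- habits_for(asg$ham, knowledge)
    data.frame(species = sp, f1 = unname(ctr[1]), f2 = unname(ctr[2]),
               ham = asg$ham, margin = asg$margin,
               trunk = hab$trunk, branches = hab$branches,
               growth = hab$growth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[2:3] <- pair
  out
}
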