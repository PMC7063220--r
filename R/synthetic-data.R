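#' Specification of a synthetic compound universe
#'
#' Parameters of the seeded generator that emulates a database extract for a
#' multi-herb formula: a compound table with ADMET values straddling the
#' screening thresholds, a compound-target interaction table with planted
#' hub compounds on a heavy-tailed background degree distribution, target
#' module labels, and target-pathway annotation sets with planted enriched
#' categories.
#'
#' @param n_herbs,n_compounds,n_targets,n_pathways Universe sizes (all >= 1).
#' @param frac_pass_admet Fraction of compounds that truly pass the ADMET
#'   gate, in \[0, 1\].
#' @param planted_hub_compounds Integer indices of compounds given elevated
#'   target degree (they are forced to pass the ADMET gate so that they
#'   survive screening).
#' @param planted_enriched_pathways Data frame with columns `pathway`
#'   (index) and `multiplier` (enrichment odds multiplier for hemorheology-
#'   module targets), or `NULL`.
#' @param hub_degree Target degree given to planted hub compounds. Default 30.
#' @param p_hemo,p_coag Probability that a target belongs to the
#'   hemorheology / coagulopathy module (independent; a target may carry
#'   both labels or neither).
#' @param pathway_size Mean pathway size. Default 15.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `universe_spec`.
#' @export
universe_spec <- function(n_herbs = 15, n_compounds = 200, n_targets = 150,
                          n_pathways = 25, frac_pass_admet = 0.5,
                          planted_hub_compounds = integer(),
                          planted_enriched_pathways = NULL,
                          hub_degree = 30, p_hemo = 0.35, p_coag = 0.40,
                          pathway_size = 15, seed = 1) {
  counts <- c(n_herbs = n_herbs, n_compounds = n_compounds,
              n_targets = n_targets, n_pathways = n_pathways)
  if (any(counts < 1)) {
    stop("all universe counts must be >= 1", call. = FALSE)
  }
  if (frac_pass_admet < 0 || frac_pass_admet > 1) {
    stop("frac_pass_admet must lie in [0, 1]", call. = FALSE)
  }
  if (length(planted_hub_compounds) &&
      (any(planted_hub_compounds < 1) || any(planted_hub_compounds > n_compounds))) {
    stop("planted hub indices out of range", call. = FALSE)
  }
  if (!is.null(planted_enriched_pathways)) {
    stopifnot(is.data.frame(planted_enriched_pathways),
              all(c("pathway", "multiplier") %in% names(planted_enriched_pathways)))
    if (any(planted_enriched_pathways$pathway < 1) ||
        any(planted_enriched_pathways$pathway > n_pathways)) {
      stop("planted pathway indices out of range", call. = FALSE)
    }
  }
  structure(list(n_herbs = n_herbs, n_compounds = n_compounds,
                 n_targets = n_targets, n_pathways = n_pathways,
                 frac_pass_admet = frac_pass_admet,
                 planted_hub_compounds = as.integer(planted_hub_compounds),
                 planted_enriched_pathways = planted_enriched_pathways,
                 hub_degree = hub_degree, p_hemo = p_hemo, p_coag = p_coag,
                 pathway_size = pathway_size, seed = as.integer(seed)),
            class = "universe_spec")
}

# Truncated power-law degrees (inverse-CDF sampling) with minimum dmin and
# cap dmax; alpha 2.5 gives the heavy tail seen in real compound-target maps.
.powerlaw_degrees <- function(n, dmin = 2, dmax = 15, alpha = 2.5) {
  u <- stats::runif(n)
  d <- floor(dmin * (1 - u)^(-1 / (alpha - 1)))
  pmin(pmax(d, dmin), dmax)
}

#' Generate a synthetic compound universe
#'
#' Produces every table the downstream stages consume, together with a
#' ground-truth record of the planted structure. Compounds are assigned
#' ADMET values conditional on a Bernoulli pass indicator (probability
#' `frac_pass_admet`), so the retained-set size is Binomial-consistent by
#' construction; failing compounds violate one to three criteria chosen at
#' random. Compound-target edges follow a truncated power-law degree
#' distribution with preferential target attachment, planted hubs receive
#' `hub_degree` distinct targets, and each edge is routed through a
#' prediction source (curated / SEA / Swiss) with passing scores, plus
#' decoy edges (failing scores or wrong species) that the prediction filter
#' must remove.
#'
#' @param spec A [universe_spec()].
#' @return List with elements `compounds` (data frame in the compound-table
#'   schema), `predictions` (compound-target table in the prediction
#'   schema, including decoys), `module_annotations` (data frame `target`,
#'   `module`), `collection` (an [annotation_collection()] of pathways) and
#'   `truth` (list: `admet_pass`, `hubs`, `enriched_pathways`,
#'   `true_edges`, module membership).
#' @export
generate_universe <- function(spec) {
  stopifnot(inherits(spec, "universe_spec"))
  set.seed(spec$seed)
  herbs <- sprintf("H%02d", seq_len(spec$n_herbs))
  comp_ids <- sprintf("C%04d", seq_len(spec$n_compounds))
  targets <- sprintf("T%04d", seq_len(spec$n_targets))
  pathways <- sprintf("PW%03d", seq_len(spec$n_pathways))

  ## -- compound table -------------------------------------------------
  pass <- stats::rbinom(spec$n_compounds, 1, spec$frac_pass_admet) == 1
  pass[spec$planted_hub_compounds] <- TRUE
  ob <- caco2 <- dl <- numeric(spec$n_compounds)
  for (i in seq_len(spec$n_compounds)) {
    if (pass[i]) {
      ob[i] <- stats::runif(1, 30, 100)
      caco2[i] <- stats::runif(1, -0.4, 1.5)
      dl[i] <- stats::runif(1, 0.18, 1)
    } else {
      # violate 1-3 criteria; the rest straddle the threshold from above
      viol <- sample(3, sample(3, 1))
      ob[i] <- if (1 %in% viol) stats::runif(1, 0, 29.9) else stats::runif(1, 30, 100)
      caco2[i] <- if (2 %in% viol) stats::runif(1, -2, -0.41) else stats::runif(1, -0.4, 1.5)
      dl[i] <- if (3 %in% viol) stats::runif(1, 0, 0.17) else stats::runif(1, 0.18, 1)
    }
  }
  n_attr <- sample(3, spec$n_compounds, replace = TRUE,
                   prob = c(0.6, 0.3, 0.1))
  herb_attr <- vapply(n_attr, function(k) {
    paste(sort(sample(herbs, min(k, length(herbs)))), collapse = ";")
  }, character(1))
  compounds <- data.frame(
    compound_id = comp_ids,
    name = paste0("cmpd-", comp_ids),
    herbs = herb_attr,
    ob = round(ob, 3), caco2 = round(caco2, 3), dl = round(dl, 4),
    whitelisted = FALSE, whitelist_reason = "",
    stringsAsFactors = FALSE)

  ## -- compound-target edges ------------------------------------------
  deg <- .powerlaw_degrees(spec$n_compounds)
  deg[spec$planted_hub_compounds] <- spec$hub_degree
  target_weight <- .powerlaw_degrees(spec$n_targets, dmin = 1, dmax = 50)
  edges <- lapply(seq_len(spec$n_compounds), function(i) {
    k <- min(deg[i], spec$n_targets)
    data.frame(compound_id = comp_ids[i],
               target = sample(targets, k, prob = target_weight),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)

  src <- sample(c("curated", "sea", "swiss"), nrow(edges), replace = TRUE,
                prob = c(0.5, 0.25, 0.25))
  predictions <- data.frame(
    compound_id = edges$compound_id, target = edges$target, source = src,
    max_tc = ifelse(src == "sea", round(stats::runif(nrow(edges), 0.58, 1), 3),
                    NA_real_),
    possibility = ifelse(src == "swiss",
                         round(stats::runif(nrow(edges), 0.01, 1), 3), NA_real_),
    species = "Homo sapiens", stringsAsFactors = FALSE)

  # decoys: sub-threshold scores and wrong-species records (~10% extra)
  n_decoy <- max(1L, round(0.1 * nrow(edges)))
  d_src <- sample(c("sea", "swiss", "curated"), n_decoy, replace = TRUE)
  decoys <- data.frame(
    compound_id = sample(comp_ids, n_decoy, replace = TRUE),
    target = sample(targets, n_decoy, replace = TRUE),
    source = d_src,
    max_tc = ifelse(d_src == "sea", round(stats::runif(n_decoy, 0, 0.57), 3),
                    NA_real_),
    possibility = ifelse(d_src == "swiss", 0, NA_real_),
    species = ifelse(d_src == "curated", "Rattus norvegicus", "Homo sapiens"),
    stringsAsFactors = FALSE)
  predictions <- rbind(predictions, decoys)
  predictions <- predictions[sample(nrow(predictions)), , drop = FALSE]
  rownames(predictions) <- NULL

  ## -- target module labels -------------------------------------------
  hemo <- targets[stats::runif(spec$n_targets) < spec$p_hemo]
  coag <- targets[stats::runif(spec$n_targets) < spec$p_coag]
  module_annotations <- rbind(
    if (length(hemo)) data.frame(target = hemo, module = "hemorheology"),
    if (length(coag)) data.frame(target = coag, module = "coagulopathy"))
  if (is.null(module_annotations)) {
    module_annotations <- data.frame(target = character(), module = character())
  }

  ## -- pathway annotation sets ----------------------------------------
  mult <- rep(1, spec$n_pathways)
  if (!is.null(spec$planted_enriched_pathways)) {
    mult[spec$planted_enriched_pathways$pathway] <-
      spec$planted_enriched_pathways$multiplier
  }
  sets <- lapply(seq_len(spec$n_pathways), function(j) {
    size <- min(max(2L, stats::rpois(1, spec$pathway_size)), spec$n_targets)
    w <- ifelse(targets %in% hemo, mult[j], 1)
    sort(sample(targets, size, prob = w))
  })
  names(sets) <- pathways
  collection <- annotation_collection(sets, name = "synthetic-pathways",
                                      background = targets)

  truth <- list(
    admet_pass = comp_ids[pass],
    hubs = comp_ids[spec$planted_hub_compounds],
    enriched_pathways = pathways[which(mult > 1)],
    hemorheology_targets = sort(hemo),
    coagulopathy_targets = sort(coag),
    true_edges = edges)

  list(compounds = compounds, predictions = predictions,
       module_annotations = module_annotations,
       collection = collection, truth = truth)
}

#' Per-group cohort specification
#'
#' Means and standard deviations of the ten physiological indices measured
#' on each animal: whole blood viscosity at shear rates 200, 100, 50, 5 and
#' 1 1/s (mPa.s), plasma viscosity (mPa.s), thrombin time, prothrombin time
#' and activated partial thromboplastin time (s), and fibrinogen (g/L) — in
#' that fixed order.
#'
#' @param group_name Group label (e.g. control, model, QXH-L, ...).
#' @param n Animals in the group (>= 2).
#' @param means,sds Numeric vectors of length 10 (sds strictly positive).
#' @return An object of class `group_spec`.
#' @export
group_spec <- function(group_name, n, means, sds) {
  if (length(means) != 10 || length(sds) != 10) {
    stop("means and sds must have length 10 (the fixed index panel)",
         call. = FALSE)
  }
  if (n < 2) stop("each group needs n >= 2", call. = FALSE)
  if (any(sds <= 0)) stop("all sds must be positive", call. = FALSE)
  structure(list(group_name = as.character(group_name), n = as.integer(n),
                 means = as.numeric(means), sds = as.numeric(sds)),
            class = "group_spec")
}

#' Names of the ten cohort indices, in canonical order
#' @export
cohort_index_names <- function() {
  c("WBV200", "WBV100", "WBV50", "WBV5", "WBV1",
    "PV", "TT", "PT", "APTT", "FIB")
}

#' Reference cohort parameters for the QS-BSS rat study
#'
#' Group means and standard deviations of the ten hemorheology/coagulation
#' indices reported for the six experimental groups of the Qixuehe-capsule
#' pharmacodynamic study (healthy control, QS-BSS model, three QXH dose
#' groups and the CDDP positive control). These are the generative defaults
#' of [generate_cohort()]; group size defaults to 8 animals and is
#' configurable because per-group attrition left 6-8 animals per group in
#' the source cohort.
#'
#' @param n Animals per group (recycled over groups). Default 8.
#' @param groups Which groups to include. Default all six.
#' @return List of [group_spec()] objects.
#' @export
qsbss_reference_groups <- function(n = 8,
                                   groups = c("control", "model", "QXH-L",
                                              "QXH-M", "QXH-H", "CDDP")) {
  tab <- list(
    #            WBV200 WBV100 WBV50 WBV5  WBV1   PV    TT     PT    APTT  FIB
    control = list(m = c(3.63, 4.01, 4.46, 8.66, 19.44, 1.24, 25.34, 12.21, 21.45, 2.94),
                   s = c(0.10, 0.15, 0.20, 0.50, 1.39, 0.07, 1.14, 1.17, 2.10, 0.40)),
    model   = list(m = c(4.22, 4.70, 5.44, 14.76, 33.61, 2.17, 21.70, 9.25, 16.64, 4.81),
                   s = c(0.14, 0.23, 0.29, 1.44, 3.19, 0.43, 1.51, 0.38, 0.96, 0.47)),
    `QXH-L` = list(m = c(3.77, 4.07, 4.49, 8.29, 18.07, 1.33, 25.21, 12.03, 18.24, 3.93),
                   s = c(0.17, 0.18, 0.21, 0.48, 1.34, 0.15, 1.69, 2.28, 2.66, 0.81)),
    `QXH-M` = list(m = c(3.93, 4.32, 4.88, 10.11, 24.39, 1.33, 27.98, 9.96, 21.78, 4.12),
                   s = c(0.10, 0.12, 0.17, 0.83, 3.03, 0.15, 0.56, 0.847, 3.10, 0.64)),
    `QXH-H` = list(m = c(3.74, 4.06, 4.54, 8.92, 20.60, 1.42, 28.20, 11.22, 19.05, 4.30),
                   s = c(0.15, 0.18, 0.22, 0.91, 3.24, 0.08, 1.29, 1.25, 1.90, 0.73)),
    CDDP    = list(m = c(3.84, 4.10, 4.64, 8.39, 17.94, 1.70, 24.36, 11.04, 25.5, 3.64),
                   s = c(0.22, 0.23, 0.38, 0.69, 1.62, 0.28, 3.74, 1.35, 1.33, 0.50)))
  unknown <- setdiff(groups, names(tab))
  if (length(unknown)) {
    stop("unknown group(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- rep_len(n, length(groups))
  out <- Map(function(g, ni) group_spec(g, ni, tab[[g]]$m, tab[[g]]$s),
             groups, n)
  names(out) <- groups
  out
}

#' Generate a synthetic animal cohort
#'
#' Draws each of the ten indices independently from Normal(mean, sd) per
#' group. The independence assumption reflects that only per-index summary
#' statistics are available for the source cohort; a correlation matrix can
#' be supplied to induce within-animal dependence (applied to all groups via
#' the Cholesky factor).
#'
#' @param groups List of [group_spec()] objects (>= 2).
#' @param seed Integer seed.
#' @param correlation Optional 10 x 10 positive-definite correlation matrix.
#' @return A data frame with a `group` factor column followed by the ten
#'   index columns (see [cohort_index_names()]).
#' @export
generate_cohort <- function(groups, seed = 1, correlation = NULL) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  L <- NULL
  if (!is.null(correlation)) {
    stopifnot(is.matrix(correlation), all(dim(correlation) == c(10, 10)))
    L <- chol(correlation)
  }
  set.seed(seed)
  rows <- lapply(groups, function(gs) {
    z <- matrix(stats::rnorm(gs$n * 10), gs$n, 10)
    if (!is.null(L)) z <- z %*% L
    x <- sweep(sweep(z, 2, gs$sds, "*"), 2, gs$means, "+")
    colnames(x) <- cohort_index_names()
    data.frame(group = gs$group_name, x, check.names = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$group <- factor(out$group, levels = vapply(groups, `[[`, character(1),
                                                 "group_name"))
  rownames(out) <- NULL
  out
}
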