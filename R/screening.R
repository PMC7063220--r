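#' Tanimoto-coefficient drug-likeness
#'
#' Drug-likeness (DL) of a compound is defined as the Tanimoto similarity
#' between its molecular-descriptor vector and a reference vector holding the
#' average descriptor values of known drugs (the DrugBank mean):
#' \deqn{T(A,B) = \frac{A \cdot B}{\|A\|^2 + \|B\|^2 - A \cdot B}}
#' Both vectors must share the same fixed, ordered descriptor schema and, by
#' convention, have non-negative entries, which bounds the coefficient in
#' \[0, 1\] with \eqn{T = 1} exactly when the two vectors coincide.
#'
#' @param a Numeric vector of molecular descriptors for the query compound.
#' @param b_ref Numeric reference vector (same length and schema as `a`),
#'   typically the average descriptor profile of approved drugs.
#' @return A single number in \[0, 1\].
#' @examples
#' drug_likeness(c(1, 2, 3), c(1, 2, 3)) # 1
#' drug_likeness(c(1, 0), c(0, 1))       # 0
#' drug_likeness(c(1, 1), c(1, 0))       # 0.5
#' @export
drug_likeness <- function(a, b_ref) {
  if (!is.numeric(a) || !is.numeric(b_ref)) {
    stop("descriptor vectors must be numeric", call. = FALSE)
  }
  if (length(a) != length(b_ref)) {
    stop(sprintf("descriptor length mismatch: %d vs %d (vectors must share one schema)",
                 length(a), length(b_ref)), call. = FALSE)
  }
  if (anyNA(a) || anyNA(b_ref) || any(!is.finite(a)) || any(!is.finite(b_ref))) {
    stop("descriptor vectors must be finite and complete", call. = FALSE)
  }
  if (any(a < 0) || any(b_ref < 0)) {
    stop("descriptors must be non-negative under the shared schema convention",
         call. = FALSE)
  }
  ab <- sum(a * b_ref)
  denom <- sum(a * a) + sum(b_ref * b_ref) - ab
  if (denom == 0) {
    stop("drug_likeness undefined for two all-zero descriptor vectors",
         call. = FALSE)
  }
  ab / denom
}

#' ADMET screening configuration
#'
#' Thresholds of the three-criterion gate used to select candidate active
#' compounds: oral bioavailability (OB, percent), Caco-2 permeability
#' (log scale) and drug-likeness (DL, Tanimoto fraction). The conventional
#' thresholds are OB >= 30 percent, Caco-2 >= -0.4 and DL >= 0.18, applied
#' inclusively; set `inclusive = FALSE` for strict inequalities.
#'
#' @param ob_min Minimum oral bioavailability in percent. Default 30.
#' @param caco2_min Minimum Caco-2 permeability score. Default -0.4.
#' @param dl_min Minimum drug-likeness in \[0, 1\]. Default 0.18.
#' @param inclusive Logical; if `TRUE` (default) the thresholds themselves
#'   pass the gate.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(ob_min = 30, caco2_min = -0.4, dl_min = 0.18,
                          inclusive = TRUE) {
  stopifnot(is.numeric(ob_min), is.numeric(caco2_min), is.numeric(dl_min),
            length(ob_min) == 1, length(caco2_min) == 1, length(dl_min) == 1,
            is.logical(inclusive), length(inclusive) == 1)
  if (dl_min < 0 || dl_min > 1) {
    stop("dl_min must lie in [0, 1]", call. = FALSE)
  }
  structure(list(ob_min = ob_min, caco2_min = caco2_min, dl_min = dl_min,
                 inclusive = inclusive),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  op <- if (x$inclusive) ">=" else ">"
  cat(sprintf("ADMET screen: OB %s %g%%, Caco-2 %s %g, DL %s %g\n",
              op, x$ob_min, op, x$caco2_min, op, x$dl_min))
  invisible(x)
}

#' Apply the three-criterion ADMET gate with whitelist
#'
#' A compound is retained when it passes all three criteria (OB, Caco-2, DL)
#' or when it is whitelisted — compounds with poor in-silico pharmacokinetics
#' may still be carried forward when they are the dominant constituents of a
#' herb or have documented biological activity (e.g. paeonolide, danshensu,
#' rosmarinic acid). Each retained compound carries a `pass_reason` of
#' `"criteria"` or `"whitelist"`.
#'
#' Missing `dl` values are computed from the compound's descriptor vector and
#' `b_ref` when both are available (a precomputed `dl` column always wins
#' unless `recompute_dl = TRUE`). Compounds whose ADMET values cannot be
#' established are excluded and reported in the `errors` attribute; the run
#' is never aborted by individual malformed records.
#'
#' @param compounds Data frame with columns `compound_id`, `ob`, `caco2`,
#'   `dl` and logical `whitelisted`; optionally `descriptor` (list column or
#'   comma-separated string of descriptor values) and `whitelist_reason`.
#' @param cfg A [screen_config()].
#' @param b_ref Optional reference descriptor vector used to compute missing
#'   DL values via [drug_likeness()].
#' @param recompute_dl Logical; if `TRUE`, DL is recomputed from descriptors
#'   even when a precomputed value is present.
#' @return The input data frame restricted to retained compounds, with added
#'   columns `pass_reason` (`"criteria"` or `"whitelist"`) and `dl` filled in
#'   where computed. Attribute `"errors"` holds a data frame of excluded
#'   malformed records (compound_id, message).
#' @export
apply_admet_filter <- function(compounds, cfg = screen_config(),
                               b_ref = NULL, recompute_dl = FALSE) {
  stopifnot(is.data.frame(compounds), inherits(cfg, "screen_config"))
  required <- c("compound_id", "ob", "caco2", "dl")
  missing_cols <- setdiff(required, names(compounds))
  if (length(missing_cols)) {
    stop("compounds table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(compounds$compound_id)) {
    stop("duplicate compound_id in compounds table", call. = FALSE)
  }
  if (is.null(compounds$whitelisted)) compounds$whitelisted <- FALSE
  compounds$whitelisted[is.na(compounds$whitelisted)] <- FALSE

  dl <- as.numeric(compounds$dl)
  errors <- list()
  for (i in seq_len(nrow(compounds))) {
    need_dl <- is.na(dl[i]) || recompute_dl
    if (need_dl) {
      desc <- .descriptor_of(compounds, i)
      if (!is.null(desc) && !is.null(b_ref)) {
        dl[i] <- tryCatch(drug_likeness(desc, b_ref), error = function(e) {
          errors[[length(errors) + 1L]] <<- data.frame(
            compound_id = compounds$compound_id[i], message = conditionMessage(e))
          NA_real_
        })
      }
    }
  }
  compounds$dl <- dl

  incomplete <- is.na(compounds$ob) | is.na(compounds$caco2) | is.na(compounds$dl)
  for (i in which(incomplete)) {
    errors[[length(errors) + 1L]] <- data.frame(
      compound_id = compounds$compound_id[i],
      message = "missing ADMET value and no usable descriptor; compound excluded")
  }

  ge <- if (cfg$inclusive) `>=` else `>`
  pass <- !incomplete &
    ge(compounds$ob, cfg$ob_min) &
    ge(compounds$caco2, cfg$caco2_min) &
    ge(compounds$dl, cfg$dl_min)
  keep <- (pass | compounds$whitelisted) & !(incomplete & !compounds$whitelisted)

  out <- compounds[keep, , drop = FALSE]
  out$pass_reason <- ifelse(pass[keep], "criteria", "whitelist")
  rownames(out) <- NULL
  attr(out, "errors") <- if (length(errors)) {
    do.call(rbind, errors)
  } else {
    data.frame(compound_id = character(), message = character())
  }
  out
}

# Extract compound i's descriptor vector from either a list column or a
# comma-separated string column; NULL when absent.
.descriptor_of <- function(compounds, i) {
  d <- compounds$descriptor
  if (is.null(d)) return(NULL)
  if (is.list(d)) {
    v <- d[[i]]
    if (is.null(v) || !length(v) || all(is.na(v))) return(NULL)
    return(as.numeric(v))
  }
  s <- d[i]
  if (is.na(s) || !nzchar(s)) return(NULL)
  as.numeric(strsplit(as.character(s), ",", fixed = TRUE)[[1]])
}

#' Filter predicted compound-target interactions
#'
#' Curated interactions (database or literature derived) are kept
#' unconditionally. Predictor-derived interactions are gated on their scores:
#' SEA edges require `max_tc > tc_min` (default 0.57) and Swiss Target
#' Prediction edges require `possibility > possibility_min` (default 0), both
#' strict. Interactions are restricted to one species (default Homo sapiens)
#' and deduplicated on the (compound, gene symbol) pair, merging provenance.
#'
#' @param preds Data frame with columns `compound_id`, `target`, `source`
#'   (`"curated"`, `"sea"` or `"swiss"`), `max_tc`, `possibility`, `species`.
#' @param species Species label to retain. Default `"Homo sapiens"`.
#' @param tc_min SEA Max TC threshold (strict). Default 0.57.
#' @param possibility_min Swiss possibility threshold (strict). Default 0.
#' @return Data frame with one row per retained (compound_id, target) pair
#'   and a `sources` column holding the merged, semicolon-separated
#'   provenance, ordered by compound then target.
#' @export
filter_predictions <- function(preds, species = "Homo sapiens",
                               tc_min = 0.57, possibility_min = 0) {
  stopifnot(is.data.frame(preds))
  required <- c("compound_id", "target", "source", "species")
  missing_cols <- setdiff(required, names(preds))
  if (length(missing_cols)) {
    stop("predictions table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(preds$max_tc)) preds$max_tc <- NA_real_
  if (is.null(preds$possibility)) preds$possibility <- NA_real_
  bad <- setdiff(unique(preds$source), c("curated", "sea", "swiss"))
  if (length(bad)) {
    stop("unknown prediction source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!nrow(preds)) {
    return(data.frame(compound_id = character(), target = character(),
                      sources = character()))
  }

  keep <- preds$species == species &
    (preds$source == "curated" |
       (preds$source == "sea" & !is.na(preds$max_tc) & preds$max_tc > tc_min) |
       (preds$source == "swiss" & !is.na(preds$possibility) &
          preds$possibility > possibility_min))
  kept <- preds[keep, , drop = FALSE]
  if (!nrow(kept)) {
    return(data.frame(compound_id = character(), target = character(),
                      sources = character()))
  }
  key <- paste(kept$compound_id, kept$target, sep = "\r")
  sources <- vapply(split(kept$source, key), function(s) {
    paste(sort(unique(s)), collapse = ";")
  }, character(1))
  pairs <- do.call(rbind, strsplit(names(sources), "\r", fixed = TRUE))
  out <- data.frame(compound_id = pairs[, 1], target = pairs[, 2],
                    sources = unname(sources), stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign targets to pathological modules
#'
#' Splits a target set into the hemorheology and coagulopathy modules using a
#' target-to-module annotation map. A target may belong to both modules;
#' targets absent from the map belong to neither and are returned under
#' `unassigned`.
#'
#' @param targets Character vector of target gene symbols.
#' @param module_annotations Data frame with columns `target` and `module`
#'   (values `"hemorheology"` / `"coagulopathy"`), or a named list of two
#'   character vectors.
#' @return List with character vectors `hemorheology`, `coagulopathy`,
#'   `shared` (the intersection) and `unassigned`, each sorted.
#' @export
assign_modules <- function(targets, module_annotations) {
  targets <- unique(as.character(targets))
  if (is.data.frame(module_annotations)) {
    stopifnot(all(c("target", "module") %in% names(module_annotations)))
    ann <- split(as.character(module_annotations$target),
                 as.character(module_annotations$module))
  } else {
    ann <- module_annotations
  }
  bad <- setdiff(names(ann), c("hemorheology", "coagulopathy"))
  if (length(bad)) {
    stop("unknown module label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  hemo <- sort(intersect(targets, ann[["hemorheology"]] %||% character()))
  coag <- sort(intersect(targets, ann[["coagulopathy"]] %||% character()))
  list(hemorheology = hemo,
       coagulopathy = coag,
       shared = sort(intersect(hemo, coag)),
       unassigned = sort(setdiff(targets, union(hemo, coag))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
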