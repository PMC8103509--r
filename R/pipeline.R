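# Orchestration of the four reproducibility-analysis approaches:
#   (i)   features from the original scans, pairwise CCC;
#   (ii)  as (i) with NZV filtering and pairwise ComBat before the CCC;
#   (iii) all scans of a model resampled to one target in-plane resolution
#         with one interpolation method, then extraction and pairwise CCC;
#   (iv)  as (iii) followed by pairwise ComBat.
# ComBat is always fitted pairwise (two batches = the two scans of the
# comparison), never as one multi-batch fit.

#' Scenario configuration
#'
#' @param approach one of `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param scanner_model scanner model tag selecting the 7-scan subset.
#' @param im interpolation method (required for approaches iii/iv).
#' @param nuir_mm target in-plane resolution in mm (required for iii/iv).
#' @param bin_width discretization bin width in HU.
#' @param cutoff CCC concordance cutoff (strict).
#' @param nzv_threshold near-zero-variance threshold for ComBat approaches.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(approach = c("i", "ii", "iii", "iv"),
                            scanner_model, im = NULL, nuir_mm = NULL,
                            bin_width = 25, cutoff = 0.9,
                            nzv_threshold = 0.95) {
  approach <- match.arg(approach)
  needs_resample <- approach %in% c("iii", "iv")
  if (needs_resample && (is.null(im) || is.null(nuir_mm)))
    stop("approaches iii/iv require `im` and `nuir_mm`", call. = FALSE)
  if (!needs_resample && (!is.null(im) || !is.null(nuir_mm)))
    stop("`im`/`nuir_mm` only apply to approaches iii/iv", call. = FALSE)
  if (!is.null(im) && !im %in% interpolation_methods())
    stop("unknown interpolation method: ", im, call. = FALSE)
  structure(list(approach = approach, scanner_model = scanner_model,
                 im = im, nuir_mm = nuir_mm, bin_width = bin_width,
                 cutoff = cutoff, nzv_threshold = nzv_threshold),
            class = "scenario_config")
}

select_scans <- function(dataset, scanner_model) {
  scans <- Filter(function(s) s$meta$scanner_model == scanner_model, dataset)
  if (length(scans) < 2)
    stop("dataset has fewer than 2 scans for model ", scanner_model,
         call. = FALSE)
  ord <- order(vapply(scans, function(s) s$meta$in_plane_spacing_mm, 0))
  scans[ord]
}

resample_scan <- function(scan, nuir_mm, im) {
  # LabelGaussian is mask-only; when it is the method under test, the
  # image goes through the plain Gaussian interpolator and the mask
  # through LabelGaussian. All other methods use NN for the mask.
  if (im == "LabelGaussian") {
    vol <- resample_volume(scan$volume, nuir_mm, "Gaussian")
    mask <- resample_mask(scan$mask, nuir_mm, "LabelGaussian")
  } else {
    vol <- resample_volume(scan$volume, nuir_mm, im)
    mask <- resample_mask(scan$mask, nuir_mm, "NN")
  }
  list(volume = vol, mask = mask, meta = scan$meta)
}

#' Run one reproducibility-analysis approach
#'
#' Executes the configured approach on the 7-scan subset of one scanner
#' model: optional in-plane resampling, feature extraction, optional
#' pairwise NZV + ComBat, the CCC over every scan pair, the all-pairs
#' intersection and the Spearman de-duplication of the intersection set.
#'
#' @param config a [scenario_config()].
#' @param dataset list of scans (see [make_dataset()]).
#' @param feature_table optional precomputed feature table for the original
#'   scans (approaches i and ii); avoids re-extraction across scenarios.
#' @return A `run_report` list with the pairwise results, count matrix,
#'   intersection, de-duplicated set, and provenance.
#' @export
run_approach <- function(config, dataset, feature_table = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  scans <- select_scans(dataset, config$scanner_model)
  needs_resample <- config$approach %in% c("iii", "iv")

  if (is.null(feature_table) || needs_resample) {
    if (needs_resample)
      scans <- lapply(scans, resample_scan, nuir_mm = config$nuir_mm,
                      im = config$im)
    tab <- extract_feature_table(scans, bin_width = config$bin_width)
  } else {
    tab <- feature_table
  }

  ids <- vapply(scans, function(s) s$meta$scan_id, "")
  spac <- stats::setNames(
    vapply(scans, function(s) s$meta$in_plane_spacing_mm, 0), ids)
  pairs <- utils::combn(ids, 2, simplify = FALSE)

  use_combat <- config$approach %in% c("ii", "iv")
  nzv_reports <- list()
  results <- lapply(pairs, function(p) {
    sub <- tab[tab$scan_id %in% p, , drop = FALSE]
    if (use_combat) {
      h <- harmonize_table(sub, nzv_threshold = config$nzv_threshold)
      nzv_reports[[paste(p, collapse = "|")]] <<- h$nzv
      sub <- h$table
    }
    pairwise_concordance(sub, p, cutoff = config$cutoff)
  })

  counts <- vapply(results, `[[`, 0, "count")
  inter <- all_pairs_intersection(results)
  dedup <- if (length(inter) > 0)
    spearman_dedup(tab, inter) else list(kept = character(0),
                                         dropped = character(0))
  structure(list(
    config = config, scan_ids = ids, spacings = spac,
    pairs = pairs, results = results, counts = counts,
    intersection = inter, dedup = dedup,
    nzv_reports = nzv_reports, feature_table = tab),
    class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf(
    "<run_report> approach (%s), %s%s: %d pairs, counts %d-%d (median %.0f), intersection %d\n",
    x$config$approach, x$config$scanner_model,
    if (!is.null(x$config$im))
      sprintf(", %s @ %.2f mm", x$config$im, x$config$nuir_mm) else "",
    length(x$pairs), min(x$counts), max(x$counts),
    stats::median(x$counts), length(x$intersection)))
  invisible(x)
}

#' Pairwise increments relative to a baseline report
#'
#' Aligns two reports pair-for-pair (same scanner model, same scan set)
#' and returns the per-pair change in concordant-feature count plus its
#' median, the way harmonization and resampling gains are summarized.
#'
#' @param report,baseline two [run_approach()] reports over the same pairs.
#' @return A list with the per-pair `increment` vector, `median_increment`,
#'   and the two intersection sizes.
#' @export
report_deltas <- function(report, baseline) {
  key <- function(r) vapply(r$pairs, paste, "", collapse = "|")
  if (!identical(key(report), key(baseline)))
    stop("reports are not over the same scan pairs", call. = FALSE)
  inc <- report$counts - baseline$counts
  list(increment = stats::setNames(inc, key(report)),
       median_increment = stats::median(inc),
       intersection = length(report$intersection),
       baseline_intersection = length(baseline$intersection))
}

#' Sweep interpolation methods and target resolutions
#'
#' Enumerates the scenario grid of one or more scanner models: the
#' original-resolution extraction (approach i) plus every combination of
#' interpolation method and target resolution (approach iii). With the
#' full default grid this is 1 + 10 x 7 = 71 extraction passes per scanner
#' model. With `dry_run = TRUE` only the plan is returned (no extraction),
#' which is how the combinatorics are audited cheaply.
#'
#' @param dataset list of scans.
#' @param scanner_models character vector of model tags.
#' @param ims interpolation methods to sweep.
#' @param nuirs target resolutions in mm.
#' @param bin_width,cutoff passed to [scenario_config()].
#' @param dry_run if `TRUE`, return the plan without running anything.
#' @return If `dry_run`, a `data.frame` plan with one row per extraction
#'   pass. Otherwise a list with the plan and a long-format `data.frame`
#'   of (scanner, im, nuir, pair, count, percentage) over all scenarios.
#' @export
sweep_grid <- function(dataset, scanner_models,
                       ims = setdiff(interpolation_methods(), character(0)),
                       nuirs = study_spacings(),
                       bin_width = 25, cutoff = 0.9, dry_run = FALSE) {
  plan <- do.call(rbind, lapply(scanner_models, function(sm) {
    rbind(data.frame(scanner_model = sm, approach = "i", im = NA_character_,
                     nuir_mm = NA_real_, stringsAsFactors = FALSE),
          expand.grid(scanner_model = sm, approach = "iii", im = ims,
                      nuir_mm = nuirs, stringsAsFactors = FALSE))
  }))
  rownames(plan) <- NULL
  if (dry_run) return(plan)

  rows <- list()
  for (r in seq_len(nrow(plan))) {
    cfg <- if (plan$approach[r] == "i")
      scenario_config("i", plan$scanner_model[r],
                      bin_width = bin_width, cutoff = cutoff)
    else
      scenario_config("iii", plan$scanner_model[r], im = plan$im[r],
                      nuir_mm = plan$nuir_mm[r], bin_width = bin_width,
                      cutoff = cutoff)
    rep <- run_approach(cfg, dataset)
    rows[[r]] <- data.frame(
      scanner_model = plan$scanner_model[r], approach = plan$approach[r],
      im = plan$im[r], nuir_mm = plan$nuir_mm[r],
      pair = vapply(rep$pairs, paste, "", collapse = "|"),
      count = rep$counts, percentage = rep$counts / 91 * 100,
      stringsAsFactors = FALSE)
  }
  list(plan = plan, long = do.call(rbind, rows))
}

#' Lower-triangular count matrix in the report-table layout
#'
#' Formats the 21 pairwise results of a 7-scan scenario as the standard
#' 6 x 6 lower-triangular matrix of `"N (P%)"` strings, rows = scans 2..7,
#' columns = scans 1..6, percentages of 91 to one decimal.
#'
#' @param report a [run_approach()] report.
#' @return A character matrix with scan-id dimnames.
#' @export
render_tables <- function(report) {
  ids <- report$scan_ids
  k <- length(ids)
  out <- matrix("", k - 1, k - 1,
                dimnames = list(ids[-1], ids[-k]))
  for (r in seq_along(report$pairs)) {
    p <- report$pairs[[r]]
    i <- match(p[1], ids)
    j <- match(p[2], ids)
    lo <- min(i, j); hi <- max(i, j)
    out[hi - 1, lo] <- sprintf("%d (%.1f%%)", report$counts[r],
                               report$counts[r] / 91 * 100)
  }
  out
}

#' Write run provenance as a JSON sidecar
#'
#' @param report a [run_approach()] report.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(report, path) {
  cfg <- report$config
  prov <- list(
    approach = cfg$approach, scanner_model = cfg$scanner_model,
    im = cfg$im, nuir_mm = cfg$nuir_mm, bin_width = cfg$bin_width,
    cutoff = cfg$cutoff, scan_ids = report$scan_ids,
    spacings_mm = as.list(report$spacings),
    package_version = as.character(utils::packageVersion("radstab")))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
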