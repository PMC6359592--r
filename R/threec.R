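# 3C-qPCR analysis: bait-anchored interaction profiles normalised to a
# control-locus junction, power-law distance-decay background with iterative
# peak exclusion, fold enrichments and loop calls.

#' Relative ligation frequency of one junction
#'
#' Per replicate, the junction quantity relative to the control-locus
#' (normaliser) junction is `2^(cq_normalizer - cq_junction)`, optionally
#' scaled by a per-assay calibration factor (random-ligation/BAC control;
#' default 1). Replicates are paired positionally when the two vectors have
#' equal length; otherwise each junction replicate is normalised against the
#' mean normaliser Cq.
#'
#' @param cq_junction Junction-assay Cq replicates.
#' @param cq_normalizer Normaliser-assay Cq replicates (same library).
#' @param calibration Per-assay calibration factor (default 1).
#' @return A list: `rel_frequency` (mean over replicates), `sd`, `n`,
#'   `rel_replicates`.
#' @export
interaction_frequency <- function(cq_junction, cq_normalizer,
                                  calibration = 1.0) {
  if (length(cq_normalizer) == 0L)
    stop("no normalizer wells supplied")
  if (length(cq_junction) == 0L)
    stop("no junction wells supplied")
  norm <- if (length(cq_normalizer) == length(cq_junction)) cq_normalizer
          else mean(cq_normalizer)
  rel <- 2^(norm - cq_junction) * calibration
  list(rel_frequency = mean(rel),
       sd = if (length(rel) > 1L) stats::sd(rel) else 0,
       n = length(rel),
       rel_replicates = rel)
}

#' Build a bait-anchored interaction profile
#'
#' Turns a 3C Cq plate into one interaction point per anchored fragment:
#' junction assays are mapped to fragments through the anchor map, normalised
#' to the control-locus junction, and ordered by TSS-relative distance. The
#' bait fragment itself is excluded.
#'
#' @param plates Plate `data.frame` (`sample`, `assay`, `replicate`, `cq`).
#' @param locus A [locus_model()].
#' @param anchor_map `data.frame` mapping `assay` to `fragment_id` (or to a
#'   genomic `position`, resolved via [locate_fragment()]).
#' @param normalizer_assay Assay label of the control-locus junction
#'   (default `"ERCC3"`).
#' @param library_id Optional library label; defaults to the unique `sample`
#'   in the plate.
#' @param calibration Named vector of per-assay calibration factors
#'   (unlisted assays use 1).
#' @return An object of class `interaction_profile`: a `data.frame` of points
#'   (`fragment_id`, `tss_distance_kb`, `rel_frequency`, `sd`, `n`) sorted by
#'   distance, with attributes `bait_fragment_id`, `normalizer_assay`,
#'   `library_id`.
#' @export
build_profile <- function(plates, locus, anchor_map,
                          normalizer_assay = "ERCC3", library_id = NULL,
                          calibration = NULL) {
  stopifnot(is.data.frame(plates), inherits(locus, "locus_model"))
  if (nrow(plates) == 0L) stop("empty plate")
  if (is.null(library_id)) {
    library_id <- unique(plates$sample)
    if (length(library_id) != 1L)
      stop("plate contains multiple samples; supply `library_id` and subset")
  }
  norm_cq <- plates$cq[plates$assay == normalizer_assay]
  if (length(norm_cq) == 0L)
    stop("no wells found for normalizer assay '", normalizer_assay, "'")
  junction_assays <- setdiff(unique(plates$assay), normalizer_assay)
  if (length(junction_assays) == 0L) stop("plate has no junction assays")
  if (is.null(anchor_map$fragment_id)) {
    if (is.null(anchor_map$position))
      stop("`anchor_map` needs a `fragment_id` or `position` column")
    anchor_map$fragment_id <- vapply(anchor_map$position, function(p)
      locate_fragment(locus, p), numeric(1))
  }
  unmapped <- setdiff(junction_assays, anchor_map$assay)
  if (length(unmapped))
    stop("junction assay(s) with no fragment mapping: ",
         paste(unmapped, collapse = ", "))
  pts <- lapply(junction_assays, function(a) {
    fid <- anchor_map$fragment_id[match(a, anchor_map$assay)]
    cal <- if (!is.null(calibration) && a %in% names(calibration))
      calibration[[a]] else 1.0
    ifq <- interaction_frequency(plates$cq[plates$assay == a], norm_cq, cal)
    data.frame(fragment_id = fid,
               tss_distance_kb =
                 locus$fragments$tss_distance_kb[
                   match(fid, locus$fragments$fragment_id)],
               rel_frequency = ifq$rel_frequency,
               sd = ifq$sd, n = ifq$n,
               stringsAsFactors = FALSE)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[pts$fragment_id != locus$bait_fragment_id, , drop = FALSE]
  pts <- pts[order(pts$tss_distance_kb), , drop = FALSE]
  rownames(pts) <- NULL
  structure(pts,
            bait_fragment_id = locus$bait_fragment_id,
            normalizer_assay = normalizer_assay,
            library_id = library_id,
            class = c("interaction_profile", "data.frame"))
}

#' Combine interaction profiles from independent libraries
#'
#' Libraries are combined by averaging per-fragment log relative frequencies
#' after each library's own normalisation, the scale on which ligation
#' ratios are approximately symmetric.
#'
#' @param profiles List of [build_profile()] results over the same anchors.
#' @return An `interaction_profile` with per-fragment geometric-mean
#'   frequencies; `n` sums the replicate counts.
#' @export
combine_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  if (length(profiles) == 1L) return(profiles[[1L]])
  fids <- lapply(profiles, function(p) p$fragment_id)
  if (length(unique(lapply(fids, sort))) != 1L)
    stop("profiles cover different fragment sets")
  base <- profiles[[1L]]
  logmat <- vapply(profiles, function(p)
    log(p$rel_frequency[match(base$fragment_id, p$fragment_id)]),
    numeric(nrow(base)))
  base$rel_frequency <- exp(rowMeans(logmat))
  base$sd <- apply(exp(logmat), 1L, stats::sd)
  base$n <- Reduce(`+`, lapply(profiles, function(p)
    p$n[match(base$fragment_id, p$fragment_id)]))
  attr(base, "library_id") <-
    paste(vapply(profiles, attr, "", "library_id"), collapse = "+")
  base
}

#' Fit a distance-decay background to an interaction profile
#'
#' Fits the power-law contact-decay model
#' `log(rel) = log_a - b * log|distance_kb|` by least squares. With
#' `iterative = TRUE` (default), candidate peaks are excluded before refit:
#' points whose residual exceeds `z_threshold` times a robust scale
#' (median-absolute-deviation of the kept residuals, floored at
#' `scale_floor` log-units) are dropped, up to `max_rounds` rounds. The
#' floor makes the rule insensitive both to masking by multiple peaks (which
#' inflates an RMS scale) and to over-triggering on quiet profiles (where the
#' MAD shrinks to replicate noise).
#'
#' `b` is constrained positive: a non-decaying fit falls back to a flat
#' background at the robust mean of the kept log frequencies, with a warning.
#'
#' @param profile An [build_profile()] result (or any `data.frame` with
#'   `fragment_id`, `tss_distance_kb`, `rel_frequency`).
#' @param iterative Exclude candidate peaks iteratively (default `TRUE`).
#' @param z_threshold Standardised-residual threshold (default 2).
#' @param scale_floor Floor on the residual scale, in natural-log units
#'   (default 0.25, i.e. a point must sit at least ~1.65-fold above the
#'   curve to be excludable at the default threshold).
#' @param max_rounds Maximum exclusion rounds (default 3).
#' @return An object of class `background_model`: `log_a`, `b`, `flat`,
#'   `excluded_fragments`, `fit_rmse`, `n_used`.
#' @export
fit_background <- function(profile, iterative = TRUE, z_threshold = 2,
                           scale_floor = 0.25, max_rounds = 3L) {
  d <- abs(profile$tss_distance_kb)
  ok <- is.finite(d) & d > 0 & is.finite(profile$rel_frequency) &
    profile$rel_frequency > 0
  if (sum(ok) < 4L || length(unique(d[ok])) < 4L)
    stop("need >= 4 usable points with distinct |distance| to fit background")
  x <- log(d[ok]); y <- log(profile$rel_frequency[ok])
  fid <- profile$fragment_id[ok]
  keep <- rep(TRUE, length(x))
  fit <- NULL
  for (round in seq_len(if (iterative) max_rounds else 1L)) {
    if (sum(keep) < 4L) break
    fit <- stats::lm(y ~ x, subset = keep)
    resid_all <- y - (stats::coef(fit)[1L] + stats::coef(fit)[2L] * x)
    s <- max(stats::mad(resid_all[keep]), scale_floor)
    out <- keep & (resid_all / s > z_threshold)
    if (!iterative || !any(out)) break
    keep <- keep & !out
  }
  log_a <- unname(stats::coef(fit)[1L])
  b <- unname(-stats::coef(fit)[2L])
  flat <- FALSE
  if (!is.finite(b) || b <= 0) {
    warning("fitted decay exponent b <= 0; using flat background at the ",
            "robust mean of kept points")
    flat <- TRUE
    log_a <- stats::median(y[keep])
    b <- 0
  }
  pred <- if (flat) rep(log_a, sum(keep)) else log_a - b * x[keep]
  structure(
    list(log_a = log_a, b = b, flat = flat,
         excluded_fragments = fid[!keep],
         fit_rmse = sqrt(mean((y[keep] - pred)^2)),
         n_used = sum(keep)),
    class = "background_model"
  )
}

#' Predict background interaction frequency at given distances
#'
#' @param object A [fit_background()] model.
#' @param distance_kb Signed or absolute TSS distances in kb.
#' @param ... Unused.
#' @return Predicted background relative frequency (positive for all
#'   `|distance| > 0`).
#' @export
predict.background_model <- function(object, distance_kb, ...) {
  d <- abs(distance_kb)
  if (object$flat) rep(exp(object$log_a), length(d))
  else exp(object$log_a - object$b * log(d))
}

#' @export
print.background_model <- function(x, ...) {
  if (x$flat) cat("background_model: flat at rel =", exp(x$log_a), "\n")
  else cat(sprintf("background_model: rel = %.4g * |d_kb|^-%.3f\n",
                   exp(x$log_a), x$b))
  cat("  fit RMSE (log):", signif(x$fit_rmse, 3),
      " points used:", x$n_used, "\n")
  if (length(x$excluded_fragments))
    cat("  excluded candidate peaks (fragment ids):",
        paste(x$excluded_fragments, collapse = ", "), "\n")
  invisible(x)
}

#' Fold enrichments over background and over the promoter-proximal fragment
#'
#' For every profile point computes `fold_over_background` (observed over the
#' fitted decay at that distance) and `fold_over_proximal` (observed over the
#' fragment nearest the promoter). The proximal reference is the smallest
#' `|distance|` point within `proximal_window_kb` (default 4 kb); when none
#' exists the nearest fragment is used with a warning.
#'
#' @param profile An interaction profile.
#' @param background A [fit_background()] model.
#' @param proximal_window_kb Window defining "close to the promoter".
#' @return A `data.frame` of class `loop_calls` (with `is_peak` unset,
#'   `NA`): `fragment_id`, `tss_distance_kb`, `rel_frequency`,
#'   `fold_over_background`, `fold_over_proximal`, `proximal_fragment_id`,
#'   `is_peak`.
#' @export
fold_enrichments <- function(profile, background, proximal_window_kb = 4) {
  stopifnot(inherits(background, "background_model"))
  d <- abs(profile$tss_distance_kb)
  in_win <- which(d < proximal_window_kb)
  if (length(in_win) == 0L) {
    warning("no fragment within ", proximal_window_kb,
            " kb of the promoter; using the nearest fragment as proximal ",
            "reference")
    in_win <- which.min(d)
  }
  prox <- in_win[which.min(d[in_win])]
  rel_prox <- profile$rel_frequency[prox]
  if (!is.finite(rel_prox) || rel_prox <= 0)
    stop("proximal reference fragment has zero/degenerate signal")
  bg <- predict(background, profile$tss_distance_kb)
  out <- data.frame(
    fragment_id = profile$fragment_id,
    tss_distance_kb = profile$tss_distance_kb,
    rel_frequency = profile$rel_frequency,
    fold_over_background = profile$rel_frequency / bg,
    fold_over_proximal = profile$rel_frequency / rel_prox,
    proximal_fragment_id = profile$fragment_id[prox],
    is_peak = NA,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("loop_calls", "data.frame"))
}

#' Call looping fragments
#'
#' A fragment is called a loop (peak) when it exceeds both fold thresholds:
#' over the fitted distance-decay background and over the promoter-proximal
#' reference. Defaults (3x background, 1.5x proximal) separate reported
#' loop profiles (6-9x background, 2-3x proximal) from no-loop profiles.
#'
#' @param enrichments A [fold_enrichments()] table.
#' @param min_fold_bg Minimum fold over background (default 3).
#' @param min_fold_prox Minimum fold over proximal (default 1.5).
#' @return The table with `is_peak` set; the proximal reference fragment is
#'   never called.
#' @export
call_loops <- function(enrichments, min_fold_bg = 3.0, min_fold_prox = 1.5) {
  stopifnot(nrow(enrichments) > 0L)
  enrichments$is_peak <-
    enrichments$fold_over_background >= min_fold_bg &
    enrichments$fold_over_proximal >= min_fold_prox &
    enrichments$fragment_id != enrichments$proximal_fragment_id
  enrichments
}

#' 3C library concentration from a genomic-DNA standard curve
#'
#' Fits `cq ~ log10(ng)` to standards of known amount and inverts the line
#' at the library's Cq. Values outside the standards' Cq range are returned
#' with an extrapolation flag.
#'
#' @param cq_library Cq of the library (vectorised).
#' @param standard_points `data.frame` with columns `ng` and `cq`
#'   (>= 2 points at distinct concentrations).
#' @return `data.frame`: `cq`, `ng`, `extrapolated`.
#' @export
library_concentration <- function(cq_library, standard_points) {
  stopifnot(is.data.frame(standard_points),
            all(c("ng", "cq") %in% names(standard_points)))
  if (nrow(standard_points) < 2L ||
      length(unique(standard_points$ng)) < 2L)
    stop("need >= 2 standards at distinct concentrations")
  fit <- stats::lm(cq ~ log10(ng), data = standard_points)
  sl <- stats::coef(fit)[["log10(ng)"]]
  ic <- stats::coef(fit)[["(Intercept)"]]
  ng <- 10^((cq_library - ic) / sl)
  rng <- range(standard_points$cq)
  data.frame(cq = cq_library, ng = ng,
             extrapolated = cq_library < rng[1L] | cq_library > rng[2L])
}
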