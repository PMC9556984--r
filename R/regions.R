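#' Blank the aneurysm-forming and para-aneurysm regions
#'
#' Assigns every face one of the labels `aneurysm`, `upstream`, `downstream`
#' or `other` by projecting its centroid onto the centerline: arclengths in
#' `[s1, s2)` are the aneurysm-forming area, the window immediately before is
#' upstream, immediately after is downstream. The default window length
#' equals the aneurysm interval length (symmetric, scale-free choice).
#'
#' @param mesh A [surface_mesh()].
#' @param line Its [centerline()].
#' @param interval Numeric `c(s1, s2)` aneurysm interval (m).
#' @param window Para-window length (m); default `s2 - s1`. Windows running
#'   past a vessel end are truncated with a warning.
#' @return Character vector of per-face labels (class `vaa_region_labels`).
#' @export
blank_regions <- function(mesh, line, interval, window = NULL) {
  stopifnot(inherits(mesh, "vaa_mesh"), inherits(line, "vaa_centerline"))
  s1 <- interval[1]; s2 <- interval[2]
  if (s2 <= s1) vaa_abort("interval must satisfy s1 < s2", "vaaflow_invalid_parameter")
  window <- window %||% (s2 - s1)
  if (window <= 0) vaa_abort("window must be positive", "vaaflow_invalid_parameter")
  smax <- line$arclength[length(line$arclength)]
  if (s1 - window < 0 || s2 + window > smax) {
    warning("para-aneurysm window extends beyond the vessel; truncated")
  }
  s <- project_onto_polyline(mesh$face_centroid, line$points, line$arclength)$s
  labels <- rep("other", nrow(mesh$faces))
  labels[s >= s1 & s < s2] <- "aneurysm"
  labels[s >= s1 - window & s < s1] <- "upstream"
  labels[s >= s2 & s < s2 + window] <- "downstream"
  structure(labels, class = "vaa_region_labels")
}

#' Area-weighted mean of a per-face map over a region
#'
#' `sum(value_i * area_i) / sum(area_i)` over the defined (non-`NA`) faces of
#' the region.
#'
#' @param values Per-face numeric map (`NA` = undefined, excluded).
#' @param labels Per-face labels from [blank_regions()].
#' @param region Label to average over.
#' @param mesh The [surface_mesh()] supplying face areas.
#' @return Scalar mean; `NA` with a warning when every face is undefined.
#' @export
area_weighted_mean <- function(values, labels, region, mesh) {
  sel <- which(labels == region)
  if (length(sel) == 0) {
    vaa_abort(sprintf("region '%s' is empty", region), "vaaflow_empty_region")
  }
  v <- values[sel]
  a <- mesh$face_area[sel]
  ok <- is.finite(v)
  if (!any(ok)) {
    warning(sprintf("region '%s': all faces undefined", region))
    return(NA_real_)
  }
  sum(v[ok] * a[ok]) / sum(a[ok])
}

#' Summarize hemodynamic maps per region
#'
#' Area-weighted means of TAWSS, OSI, WSSG and AFI plus the region-wise peak
#' wall shear maximum for the aneurysm, upstream and downstream regions, with
#' the para-aneurysm value of each metric defined as the plain average of the
#' upstream and downstream values.
#'
#' @param maps A `vaa_maps` data.frame from [compute_hemodynamic_maps()].
#' @param labels Labels from [blank_regions()].
#' @param mesh The [surface_mesh()].
#' @return A list of class `vaa_region_summary`: `metrics` (matrix, regions x
#'   metrics incl. `wssmax_pa`), `para` (named vector), `areas_m2`.
#' @export
summarize_regions <- function(maps, labels, mesh) {
  regions <- c("aneurysm", "upstream", "downstream")
  for (r in regions) {
    if (!any(labels == r)) {
      vaa_abort(sprintf("region '%s' is empty: cannot summarize", r), "vaaflow_empty_region")
    }
  }
  metric_cols <- c("tawss_pa", "osi", "wssg_nm3", "afi")
  metrics <- matrix(NA_real_, 3, length(metric_cols) + 1,
                    dimnames = list(regions, c(metric_cols, "wssmax_pa")))
  for (r in regions) {
    for (mc in metric_cols) {
      metrics[r, mc] <- area_weighted_mean(maps[[mc]], labels, r, mesh)
    }
    metrics[r, "wssmax_pa"] <- max(maps$wsspeak_pa[labels == r])
  }
  para <- (metrics["upstream", ] + metrics["downstream", ]) / 2
  areas <- vapply(regions, function(r) sum(mesh$face_area[labels == r]), numeric(1))
  structure(list(metrics = metrics, para = para, areas_m2 = areas),
            class = "vaa_region_summary")
}

#' @export
print.vaa_region_summary <- function(x, ...) {
  cat("<vaa_region_summary>\n")
  print(round(x$metrics, 4))
  cat("para:", paste(sprintf("%s=%.4g", names(x$para), x$para), collapse = ", "), "\n")
  invisible(x)
}

#' Classify a model into the high- or low-WSS group
#'
#' A model is `high` when the aneurysm-forming area's wall shear value is at
#' least the para-aneurysm value (ties classify high), otherwise `low`. The
#' area-mean TAWSS is the default classification metric; the peak wall shear
#' maximum is available as an option.
#'
#' @param summary A `vaa_region_summary`.
#' @param metric `"tawss_pa"` (default) or `"wssmax_pa"`.
#' @param id Optional model identifier carried through.
#' @return List of class `vaa_group`: `id`, `group`, `aneurysm_value`,
#'   `para_value`, `metric`.
#' @export
classify_wss_group <- function(summary, metric = c("tawss_pa", "wssmax_pa"), id = NA) {
  stopifnot(inherits(summary, "vaa_region_summary"))
  metric <- match.arg(metric)
  av <- summary$metrics["aneurysm", metric]
  pv <- summary$para[metric]
  if (!is.finite(av) || !is.finite(pv)) {
    vaa_abort("classification cells undefined", "vaaflow_unclassifiable")
  }
  structure(list(id = id, group = if (av >= pv) "high" else "low",
                 aneurysm_value = unname(av), para_value = unname(pv),
                 metric = metric),
            class = "vaa_group")
}

#' Write a region summary as tidy CSV
#'
#' Long format: `model_id, region, metric, value, area_m2`.
#'
#' @param summary A `vaa_region_summary`.
#' @param path Output path.
#' @param model_id Identifier written into the table.
#' @return The data.frame written, invisibly.
#' @export
write_region_summary_csv <- function(summary, path, model_id = "model") {
  m <- summary$metrics
  df <- data.frame(model_id = model_id,
                   region = rep(rownames(m), ncol(m)),
                   metric = rep(colnames(m), each = nrow(m)),
                   value = as.numeric(m),
                   area_m2 = rep(summary$areas_m2, ncol(m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
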