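## Consolidated reporting: a per-callset scorecard across metrics with
## within-metric min-max scaling, and a reproducibility manifest.

#' Consolidated scorecard across callsets and metrics
#'
#' Combines per-callset metric values into one table and adds within-metric
#' min-max scaled values in `[0, 1]`, oriented so that 1 is always best.
#' With a single callset, or a metric with no spread, scaled values are
#' defined as 1. Metrics absent for a callset (e.g. sequence accuracy for a
#' length-only caller) stay NA rather than zero.
#'
#' @param metrics data.frame with columns `callset`, `metric`, `value`.
#' @param higher_is_better Named logical vector per metric; metrics not
#'   named default to TRUE.
#' @return data.frame with columns `callset`, `metric`, `value`, `scaled`.
#' @export
summarize_scorecard <- function(metrics, higher_is_better = NULL) {
  stopifnot(all(c("callset", "metric", "value") %in% names(metrics)))
  out <- metrics
  out$scaled <- NA_real_
  for (m in unique(out$metric)) {
    idx <- which(out$metric == m & !is.na(out$value))
    if (!length(idx)) next
    v <- out$value[idx]
    hib <- if (!is.null(higher_is_better) && m %in% names(higher_is_better))
      higher_is_better[[m]] else TRUE
    rng <- range(v)
    s <- if (diff(rng) == 0) rep(1, length(v)) else (v - rng[1]) / diff(rng)
    if (!hib) s <- 1 - s
    if (diff(rng) == 0) s <- rep(1, length(v))
    out$scaled[idx] <- s
  }
  out
}

#' Write a reproducibility manifest
#'
#' Records the package version, the parameters of a run, seeds, and input
#' file checksums, as JSON.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters (seeds included).
#' @param inputs Character vector of input file paths to checksum.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, params = list(), inputs = character(0)) {
  manifest <- list(
    package = "trbench",
    version = as.character(utils::packageVersion("trbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    params = params,
    inputs = lapply(stats::setNames(as.list(inputs), basename(inputs)),
                    function(f) list(path = f,
                                     md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
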