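#' Per-replicate selection counts by truth category
#'
#' Crosses a method's selection vector with the generator's ground truth:
#' power counts on the differential features of each block (one proportion
#' per effect size), the correlated-non-null proportion per block (features
#' correlated with differential ones but themselves null - tracked
#' separately, never folded into Type I error), and the Type I error
#' proportion on the independent noise features.
#'
#' @param selection Logical vector, one entry per feature.
#' @param truth Ground-truth data frame from [build_block_structure()] (or
#'   the `truth` element of a `simulated_dataset`).
#' @return Data frame with columns `metric` (`"power"`, `"corr_select"`,
#'   `"type1"`), `delta_or_block` (the block's effect size for power rows,
#'   the block id for corr_select rows, `NA` for type1), `n_selected`,
#'   `n_features` and `proportion`.
#' @export
classify_outcomes <- function(selection, truth) {
  if (length(selection) != nrow(truth)) {
    stop("`selection` and `truth` must cover the same features (",
         length(selection), " vs ", nrow(truth), ")", call. = FALSE)
  }
  selection <- as.logical(selection)
  blocks <- sort(unique(truth$block[!is.na(truth$block)]))
  rows <- list()
  for (b in blocks) {
    idx <- which(truth$category == "differential" & truth$block == b)
    if (length(idx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "power", delta_or_block = truth$delta[idx[1]],
        n_selected = sum(selection[idx]), n_features = length(idx)
      )
    }
  }
  for (b in blocks) {
    idx <- which(truth$category == "correlated_nonnull" & truth$block == b)
    if (length(idx)) {
      rows[[length(rows) + 1L]] <- data.frame(
        metric = "corr_select", delta_or_block = b,
        n_selected = sum(selection[idx]), n_features = length(idx)
      )
    }
  }
  idx <- which(truth$category == "noise")
  if (length(idx)) {
    rows[[length(rows) + 1L]] <- data.frame(
      metric = "type1", delta_or_block = NA_real_,
      n_selected = sum(selection[idx]), n_features = length(idx)
    )
  }
  out <- do.call(rbind, rows)
  out$proportion <- out$n_selected / out$n_features
  out
}

#' Aggregate replicate outcomes into metric records
#'
#' Averages per-replicate selection proportions into one estimate per
#' metric, with a Monte-Carlo standard error computed from replicate-level
#' variation (`sd / sqrt(R)`) rather than pooled Bernoulli counts - features
#' within a replicate are correlated by design, so only replicates are
#' treated as independent.
#'
#' @param outcomes List of per-replicate data frames from
#'   [classify_outcomes()] (identical layouts).
#' @param scenario Scenario id carried into the output.
#' @param method Method label carried into the output.
#' @param alpha Elastic-net penalty split, or `NA` for ANOVA methods.
#' @return Data frame with one row per metric: `scenario`, `method`,
#'   `alpha`, `metric`, `delta_or_block`, `estimate`, `mc_se`,
#'   `n_replicates`.
#' @export
aggregate_metrics <- function(outcomes, scenario = NA_character_,
                              method = NA_character_, alpha = NA_real_) {
  if (length(outcomes) < 1) stop("need at least one replicate", call. = FALSE)
  props <- vapply(outcomes, function(o) o$proportion,
                  numeric(nrow(outcomes[[1]])))
  props <- matrix(props, nrow = nrow(outcomes[[1]]))
  est <- rowMeans(props)
  r <- length(outcomes)
  se <- if (r > 1) apply(props, 1, sd) / sqrt(r) else rep(0, nrow(props))
  data.frame(
    scenario = scenario, method = method, alpha = alpha,
    metric = outcomes[[1]]$metric,
    delta_or_block = outcomes[[1]]$delta_or_block,
    estimate = est, mc_se = se, n_replicates = r,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
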