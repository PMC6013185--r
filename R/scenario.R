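#' Define one simulation scenario
#'
#' A scenario fixes the dimensions and distributional parameters of a
#' synthetic two-group omics dataset: three correlated feature blocks with
#' compound-symmetry correlation `rho`, an independent noise block, and a
#' small number of planted differential features at the start of each
#' correlated block. Baseline feature means are drawn from a gamma
#' distribution (defaults give mean 1, variance 1/50) and samples from a
#' multivariate normal with unit diagonal variance, so the planted
#' differences `deltas` are on the Cohen's d scale (0.2 small, 0.5 medium,
#' 0.8 large).
#'
#' @param n_total Total number of samples across the two groups.
#' @param block_size Features per correlated block (35 or 350 in the
#'   standard grid).
#' @param noise_count Independent noise features (100 or 1000 in the
#'   standard grid).
#' @param rho Within-block correlation, in `[0, 1)`. Features in different
#'   blocks are uncorrelated.
#' @param deltas Numeric vector of length 3: the group-mean difference for
#'   the differential features of each correlated block.
#' @param n_diff_per_block Number of differential features planted at the
#'   start of each correlated block.
#' @param group_sizes Two positive integers summing to `n_total`. Defaults
#'   to a balanced split, which requires `n_total` to be even.
#' @param sigma2 Diagonal variance of every feature.
#' @param gamma_shape,gamma_scale Shape and scale of the gamma distribution
#'   the baseline feature means are drawn from.
#' @param seed Optional integer seed stored with the scenario and used by
#'   [simulate_dataset()] when no seed is passed there.
#'
#' @return An object of class `scenario_spec`: a list with the validated
#'   parameters plus `p` (total feature count) and `id` (a short label such
#'   as `"p205_rho0.4_n10"`).
#' @seealso [simulate_dataset()], [scenario_grid()], [build_block_structure()]
#' @export
#' @examples
#' spec <- scenario_spec(n_total = 10)
#' spec$p   # 3 * 35 + 100 = 205
scenario_spec <- function(n_total,
                          block_size = 35,
                          noise_count = 100,
                          rho = 0.4,
                          deltas = c(0.2, 0.5, 0.8),
                          n_diff_per_block = 4,
                          group_sizes = NULL,
                          sigma2 = 1,
                          gamma_shape = 50,
                          gamma_scale = 1 / 50,
                          seed = NULL) {
  n_blocks <- 3L
  if (length(n_total) != 1 || n_total < 4 || n_total != round(n_total)) {
    stop("`n_total` must be a single integer >= 4", call. = FALSE)
  }
  if (block_size < 1 || block_size != round(block_size)) {
    stop("`block_size` must be a positive integer", call. = FALSE)
  }
  if (noise_count < 0 || noise_count != round(noise_count)) {
    stop("`noise_count` must be a non-negative integer", call. = FALSE)
  }
  if (rho < 0 || rho >= 1) {
    stop("`rho` must lie in [0, 1): compound symmetry is positive definite ",
         "only on that range (with rho >= 0 for the shared-factor construction)",
         call. = FALSE)
  }
  if (length(deltas) != n_blocks) {
    stop("`deltas` must have one entry per correlated block (3)", call. = FALSE)
  }
  if (n_diff_per_block < 0 || n_diff_per_block > block_size) {
    stop("`n_diff_per_block` must lie in [0, block_size]", call. = FALSE)
  }
  if (sigma2 <= 0) stop("`sigma2` must be positive", call. = FALSE)
  if (gamma_shape <= 0 || gamma_scale <= 0) {
    stop("gamma shape and scale must be positive", call. = FALSE)
  }
  if (is.null(group_sizes)) {
    if (n_total %% 2 != 0) {
      stop("balanced groups need an even `n_total`; pass `group_sizes` ",
           "explicitly for an unbalanced design", call. = FALSE)
    }
    group_sizes <- c(n_total / 2, n_total / 2)
  }
  if (length(group_sizes) != 2 || any(group_sizes < 2) ||
      sum(group_sizes) != n_total) {
    stop("`group_sizes` must be two integers >= 2 summing to `n_total`",
         call. = FALSE)
  }
  p <- n_blocks * block_size + noise_count
  spec <- list(
    n_blocks = n_blocks,
    block_size = as.integer(block_size),
    noise_count = as.integer(noise_count),
    p = as.integer(p),
    rho = rho,
    n_total = as.integer(n_total),
    group_sizes = as.integer(group_sizes),
    deltas = as.numeric(deltas),
    n_diff_per_block = as.integer(n_diff_per_block),
    sigma2 = sigma2,
    gamma_shape = gamma_shape,
    gamma_scale = gamma_scale,
    seed = if (is.null(seed)) NULL else as.integer(seed),
    id = sprintf("p%d_rho%s_n%d", p, format(rho), n_total)
  )
  class(spec) <- "scenario_spec"
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario %s: p = %d (3 x %d correlated + %d noise), rho = %g,\n",
    x$id, x$p, x$block_size, x$noise_count, x$rho
  ))
  cat(sprintf(
    "  n = %d (%d + %d), deltas = %s, %d differential features per block\n",
    x$n_total, x$group_sizes[1], x$group_sizes[2],
    paste(x$deltas, collapse = "/"), x$n_diff_per_block
  ))
  invisible(x)
}

#' Expand the standard scenario grid
#'
#' Builds the full crossing of feature counts, correlation levels and sample
#' sizes used in the simulation study: `p` 205 or 2050 (three correlated
#' blocks of 35 or 350 features plus 100 or 1000 noise features), `rho` 0.4
#' or 0.8, and `n` from 10 to 100, i.e. 20 scenarios by default. Larger
#' sample sizes (200, 500, 1000) can be requested through `n`.
#'
#' @param p Feature counts; each must have a standard block layout
#'   (205 = 3x35 + 100, 2050 = 3x350 + 1000).
#' @param rho Within-block correlation levels.
#' @param n Total sample sizes.
#' @param ... Further arguments passed to [scenario_spec()] (e.g. `deltas`).
#' @return A list of `scenario_spec` objects, one per (p, rho, n) combination.
#' @export
#' @examples
#' length(scenario_grid())  # 20
scenario_grid <- function(p = c(205, 2050), rho = c(0.4, 0.8),
                          n = c(10, 20, 30, 50, 100), ...) {
  layout_for <- function(p) {
    switch(as.character(p),
      "205"  = c(35L, 100L),
      "2050" = c(350L, 1000L),
      stop("no standard block layout for p = ", p,
           "; build the scenario directly with scenario_spec()", call. = FALSE)
    )
  }
  combos <- expand.grid(n = n, rho = rho, p = p, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(combos)), function(i) {
    lay <- layout_for(combos$p[i])
    scenario_spec(n_total = combos$n[i], block_size = lay[1],
                  noise_count = lay[2], rho = combos$rho[i], ...)
  })
}

#' Read or write a scenario configuration file
#'
#' Scenarios serialize to JSON (default) or YAML, keyed by the
#' [scenario_spec()] argument names, so a simulation can be configured from
#' a plain-text file.
#'
#' @param spec A `scenario_spec`.
#' @param path File path; the extension (`.json`, `.yaml`/`.yml`) selects the
#'   format.
#' @return `write_scenario_config()` returns `path` invisibly;
#'   `read_scenario_config()` returns a `scenario_spec`.
#' @export
write_scenario_config <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  fields <- spec[c("n_total", "block_size", "noise_count", "rho", "deltas",
                   "n_diff_per_block", "group_sizes", "sigma2", "gamma_shape",
                   "gamma_scale", "seed")]
  fields <- fields[!vapply(fields, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    }
    yaml::write_yaml(fields, path)
  } else {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
    }
    fields <- yaml::read_yaml(path)
  } else {
    fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(scenario_spec, fields)
}
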