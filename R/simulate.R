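#' Draw baseline feature means from a gamma distribution
#'
#' Feature-level baseline intensities are i.i.d. gamma with shape `shape`
#' and scale `scale`; the defaults (50, 1/50) give mean `shape * scale = 1`
#' and variance `shape * scale^2 = 1/50`, i.e. intensities scattered tightly
#' around 1 on the standardized scale. Draws come from the session RNG, so
#' wrap the call in `set.seed()` (or use [simulate_dataset()]) for
#' reproducibility.
#'
#' @param p Number of features.
#' @param shape,scale Gamma shape and scale, both positive.
#' @return Numeric vector of `p` gamma draws.
#' @export
draw_feature_means <- function(p, shape = 50, scale = 1 / 50) {
  if (length(p) != 1 || p < 1 || p != round(p)) {
    stop("`p` must be a single positive integer", call. = FALSE)
  }
  if (shape <= 0 || scale <= 0) {
    stop("gamma `shape` and `scale` must be positive", call. = FALSE)
  }
  rgamma(p, shape = shape, scale = scale)
}

#' Deterministic feature layout and ground truth for a scenario
#'
#' Features are laid out as blocks 1-3 of `block_size` features each,
#' followed by the independent noise features. The first `n_diff_per_block`
#' features of each correlated block are the differential ones and carry
#' that block's effect size; the remaining block members are correlated
#' non-null features (correlated with differential features but with no mean
#' difference of their own). Features within a block are exchangeable, so
#' placing the effects first is without loss of generality.
#'
#' @param spec A [scenario_spec()].
#' @return A data frame with one row per feature and columns `feature_id`,
#'   `category` (`"differential"`, `"correlated_nonnull"` or `"noise"`),
#'   `block` (1-3, `NA` for noise) and `delta` (the block effect size for
#'   differential features, 0 otherwise).
#' @export
#' @examples
#' table(build_block_structure(scenario_spec(10))$category)
build_block_structure <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  bs <- spec$block_size
  nb <- spec$n_blocks
  block <- c(rep(seq_len(nb), each = bs), rep(NA_integer_, spec$noise_count))
  in_block_pos <- c(rep(seq_len(bs), times = nb), rep(NA_integer_, spec$noise_count))
  category <- ifelse(is.na(block), "noise",
                     ifelse(in_block_pos <= spec$n_diff_per_block,
                            "differential", "correlated_nonnull"))
  delta <- ifelse(category == "differential", spec$deltas[block], 0)
  delta[is.na(delta)] <- 0
  data.frame(
    feature_id = sprintf("F%0*d", nchar(spec$p), seq_len(spec$p)),
    category = category,
    block = block,
    delta = delta,
    stringsAsFactors = FALSE
  )
}

#' Simulate one two-group dataset
#'
#' Draws baseline means via [draw_feature_means()], then samples each
#' correlated block from a multivariate normal with compound-symmetry
#' covariance `sigma2 * ((1 - rho) I + rho J)` using the shared-factor
#' construction `sqrt(rho) * g + sqrt(1 - rho) * e` (one standard normal `g`
#' per sample shared across the block), and the noise features independently.
#' Blocks are independent of each other, so the full p x p covariance matrix
#' is never materialized. Group 2 samples of each differential feature are
#' shifted by that block's effect size.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer seed; defaults to the seed stored in `spec`. Required
#'   through one of the two routes for reproducibility.
#' @return An object of class `simulated_dataset`: a list with `values`
#'   (samples x features matrix), `labels` (integer group 1/2 per sample),
#'   `truth` (the [build_block_structure()] data frame), `means` (the drawn
#'   baseline mean vector), `spec` and `seed`.
#' @export
#' @examples
#' ds <- simulate_dataset(scenario_spec(10, seed = 1))
#' dim(ds$values)
simulate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(seed)) {
    stop("no seed: set `seed` here or in the scenario spec", call. = FALSE)
  }
  set.seed(as.integer(seed))
  n <- spec$n_total
  p <- spec$p
  bs <- spec$block_size
  sd0 <- sqrt(spec$sigma2)
  truth <- build_block_structure(spec)

  mu <- draw_feature_means(p, spec$gamma_shape, spec$gamma_scale)
  values <- matrix(0, nrow = n, ncol = p)
  for (b in seq_len(spec$n_blocks)) {
    cols <- ((b - 1) * bs + 1):(b * bs)
    shared <- rnorm(n)
    eps <- matrix(rnorm(n * bs), nrow = n, ncol = bs)
    values[, cols] <- sd0 * (sqrt(spec$rho) * shared + sqrt(1 - spec$rho) * eps)
  }
  if (spec$noise_count > 0) {
    cols <- (spec$n_blocks * bs + 1):p
    values[, cols] <- sd0 * matrix(rnorm(n * spec$noise_count),
                                   nrow = n, ncol = spec$noise_count)
  }
  values <- sweep(values, 2, mu, "+")

  labels <- rep(1:2, times = spec$group_sizes)
  g2 <- labels == 2L
  diff_idx <- which(truth$category == "differential")
  for (i in diff_idx) values[g2, i] <- values[g2, i] + truth$delta[i]

  dimnames(values) <- list(sprintf("S%0*d", nchar(n), seq_len(n)),
                           truth$feature_id)
  structure(
    list(values = values, labels = labels, truth = truth, means = mu,
         spec = spec, seed = as.integer(seed)),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("simulated dataset (%s): %d samples x %d features, seed %d\n",
              x$spec$id, nrow(x$values), ncol(x$values), x$seed))
  print(table(x$truth$category))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes `<prefix>_values.csv` (samples in rows, header = feature ids,
#' first column = sample id), `<prefix>_labels.tsv` (sample_id, group) and
#' `<prefix>_truth.tsv` (feature_id, category, effect_size).
#'
#' @param ds A `simulated_dataset`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_dataset <- function(ds, dir, prefix = "dataset") {
  stopifnot(inherits(ds, "simulated_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_values.csv", "_labels.tsv",
                                           "_truth.tsv")))
  values <- data.frame(sample_id = rownames(ds$values), ds$values,
                       check.names = FALSE)
  write.csv(values, paths[1], row.names = FALSE, quote = FALSE)
  write.table(
    data.frame(sample_id = rownames(ds$values), group = ds$labels),
    paths[2], sep = "\t", row.names = FALSE, quote = FALSE
  )
  write.table(
    data.frame(feature_id = ds$truth$feature_id, category = ds$truth$category,
               effect_size = ds$truth$delta),
    paths[3], sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(paths)
}

#' Derive a reproducible child seed
#'
#' Hashes an arbitrary sequence of ids (scenario id, replicate number, ...)
#' together with a base seed into an integer in `[1, 2^31 - 86)`, via a
#' polynomial rolling hash. Used throughout the experiment runner so that
#' any single replicate can be re-run in isolation: the replicate seed
#' depends only on (base seed, scenario id, replicate index), never on
#' execution order.
#'
#' @param ... Values coerced to character and hashed in order.
#' @return A single integer seed.
#' @export
#' @examples
#' child_seed(1, "p205_rho0.4_n10", 7)
child_seed <- function(...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483563
  as.integer(h + 1)
}
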