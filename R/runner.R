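#' @title Method rosters
#' @description Methods are named by short labels: `"anova_raw05"`
#'   (unadjusted p < 0.05), `"anova_fdr05"` and `"anova_fdr20"` (BH-adjusted
#'   p < 0.05 / 0.20), and `"enet:<alpha>"` (elastic-net penalized logistic
#'   regression with 10-fold cross-validated lambda; `enet:0` is ridge,
#'   `enet:1` is LASSO).
#' @name method_roster
NULL

.parse_method <- function(m) {
  if (m %in% c("anova_raw05", "anova_fdr05", "anova_fdr20")) {
    return(list(label = m, type = "anova", alpha = NA_real_))
  }
  if (grepl("^enet:", m)) {
    a <- suppressWarnings(as.numeric(sub("^enet:", "", m)))
    if (is.na(a) || a < 0 || a > 1) {
      stop("bad elastic-net method label: ", m, call. = FALSE)
    }
    return(list(label = m, type = "enet", alpha = a))
  }
  stop("unknown method: ", m, call. = FALSE)
}

.anova_selection <- function(screen, label) {
  switch(label,
    anova_raw05 = screen$p_raw < 0.05,
    anova_fdr05 = screen$p_adj < 0.05,
    anova_fdr20 = screen$p_adj < 0.20
  )
}

#' Run one scenario of the simulation study
#'
#' For each replicate: simulate a dataset with a deterministic child seed
#' derived from `(base_seed, scenario id, replicate)`, apply every method in
#' the roster, and classify the selections against the ground truth; then
#' aggregate to one estimate per (method, metric). A method failure on a
#' replicate is reported (with its child seed) and that replicate is
#' excluded from the failing method's aggregation only.
#'
#' @param spec A [scenario_spec()].
#' @param methods Character vector of method labels (see [method_roster]).
#' @param replicates Number of simulated datasets.
#' @param base_seed Base seed of the seed hierarchy.
#' @param enet An [enet_config()] used for all `enet:` methods (its `alpha`
#'   and `seed` are overridden per method/replicate).
#' @param verbose Print per-scenario progress.
#' @return Tidy data frame of metric records: `scenario`, `p`, `rho`, `n`,
#'   `method`, `alpha`, `metric`, `delta_or_block`, `estimate`, `mc_se`,
#'   `n_replicates`. Excluded-replicate counts are attached as attribute
#'   `"failures"` (named integer vector) when any occurred.
#' @export
#' @examples
#' run_scenario(scenario_spec(10), methods = "anova_raw05",
#'              replicates = 3, base_seed = 1)
run_scenario <- function(spec, methods = c("anova_raw05", "anova_fdr20", "enet:0.5"),
                         replicates = 200, base_seed = 1,
                         enet = enet_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  parsed <- lapply(methods, .parse_method)
  names(parsed) <- methods
  outcomes <- lapply(methods, function(m) vector("list", replicates))
  names(outcomes) <- methods
  failures <- setNames(integer(length(methods)), methods)
  need_anova <- any(vapply(parsed, function(x) x$type == "anova", logical(1)))

  for (r in seq_len(replicates)) {
    rep_seed <- child_seed(base_seed, spec$id, r)
    ds <- simulate_dataset(spec, seed = rep_seed)
    screen <- if (need_anova) anova_screen(ds$values, ds$labels) else NULL
    y01 <- as.integer(ds$labels == 2L)
    for (m in methods) {
      pm <- parsed[[m]]
      sel <- tryCatch({
        if (pm$type == "anova") {
          .anova_selection(screen, pm$label)
        } else {
          cfg <- enet
          cfg$alpha <- pm$alpha
          cfg$seed <- child_seed(rep_seed, "cv", pm$label)
          selected_set(cv_enet(ds$values, y01, cfg))
        }
      }, error = function(e) {
        warning("method ", m, " failed on replicate ", r, " (seed ", rep_seed,
                "): ", conditionMessage(e), call. = FALSE)
        NULL
      })
      if (!is.null(sel)) {
        outcomes[[m]][[r]] <- classify_outcomes(sel, ds$truth)
      } else {
        failures[m] <- failures[m] + 1L
      }
    }
    if (verbose && (r %% 50 == 0 || r == replicates)) {
      message(spec$id, ": replicate ", r, "/", replicates)
    }
  }

  records <- lapply(methods, function(m) {
    done <- Filter(Negate(is.null), outcomes[[m]])
    if (!length(done)) return(NULL)
    rec <- aggregate_metrics(done, scenario = spec$id, method = m,
                             alpha = parsed[[m]]$alpha)
    rec
  })
  out <- do.call(rbind, Filter(Negate(is.null), records))
  out <- cbind(
    scenario = out$scenario, p = spec$p, rho = spec$rho, n = spec$n_total,
    out[, setdiff(names(out), "scenario"), drop = FALSE]
  )
  rownames(out) <- NULL
  if (any(failures > 0)) attr(out, "failures") <- failures[failures > 0]
  out
}

#' Run a grid of scenarios
#'
#' Applies [run_scenario()] to every scenario in a grid (see
#' [scenario_grid()]), optionally persisting one CSV per scenario so an
#' interrupted run can be resumed: with `resume = TRUE` completed scenario
#' files are read back instead of recomputed; without it, an existing
#' partial output directory is an error. A JSON manifest records the
#' configuration and base seed.
#'
#' @param scenarios List of [scenario_spec()] objects.
#' @param methods,replicates,base_seed,enet,verbose As in [run_scenario()].
#' @param out_dir Optional output directory for per-scenario CSVs, the
#'   combined `metrics.csv` and `manifest.json`.
#' @param resume Reuse completed per-scenario outputs in `out_dir`.
#' @return Combined tidy data frame of all metric records.
#' @export
run_grid <- function(scenarios, methods = c("anova_raw05", "anova_fdr20", "enet:0.5"),
                     replicates = 200, base_seed = 1, enet = enet_config(),
                     out_dir = NULL, resume = FALSE, verbose = TRUE) {
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  persist <- !is.null(out_dir)
  if (persist) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    existing <- list.files(out_dir, pattern = "^scenario-.*\\.csv$")
    if (length(existing) && !resume) {
      stop("output directory already holds ", length(existing),
           " scenario file(s); pass resume = TRUE to reuse them",
           call. = FALSE)
    }
    manifest <- list(
      base_seed = base_seed, replicates = replicates, methods = methods,
      scenarios = vapply(scenarios, function(s) s$id, character(1)),
      enet = enet[c("n_lambda", "cv_folds", "lambda_rule", "cv_loss",
                    "tol", "standardize")],
      package_version = as.character(utils::packageVersion("omicscreen"))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  results <- lapply(scenarios, function(spec) {
    path <- if (persist) file.path(out_dir, paste0("scenario-", spec$id, ".csv"))
    if (persist && resume && file.exists(path)) {
      if (verbose) message("reusing ", path)
      return(read.csv(path, stringsAsFactors = FALSE))
    }
    res <- run_scenario(spec, methods = methods, replicates = replicates,
                        base_seed = base_seed, enet = enet, verbose = verbose)
    if (persist) write.csv(res, path, row.names = FALSE)
    res
  })
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  if (persist) write.csv(out, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  out
}

.read_table_file <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- ids
  mat
}

#' Apply the method roster to a real feature table
#'
#' Runs the ANOVA screen and the penalized-logistic methods on a wide
#' feature table (features x samples) with a two-group label file, the same
#' interface used for e.g. untargeted metabolomics intensity matrices. When
#' a feature-to-stratum map is given (e.g. positive/negative ion mode), the
#' BH adjustment is applied separately within each stratum.
#'
#' @param table Features x samples numeric matrix with feature ids as row
#'   names, or the path of a wide CSV/TSV whose first column holds the
#'   feature ids and whose header holds sample ids.
#' @param labels Data frame with columns `sample_id` and `group` (two
#'   groups), or the path of a two-column TSV.
#' @param methods Character vector of method labels (see [method_roster]).
#' @param strata Optional data frame with columns `feature_id` and
#'   `stratum`, or the path of a two-column TSV; BH is applied per stratum.
#' @param enet An [enet_config()] shared by the `enet:` methods.
#' @param base_seed Seed for the CV folds.
#' @return A list with `selected` (named list of feature-id vectors, one
#'   per method), `overlap` (methods x methods matrix of intersection
#'   counts), and `screen` (the per-feature ANOVA table, when an ANOVA
#'   method was requested).
#' @export
apply_to_table <- function(table, labels, methods = c("anova_fdr20", "enet:0.5", "enet:1"),
                           strata = NULL, enet = enet_config(), base_seed = 1) {
  mat <- if (is.character(table)) .read_table_file(table) else as.matrix(table)
  if (is.null(rownames(mat))) {
    stop("the feature table needs feature ids (row names or first column)",
         call. = FALSE)
  }
  if (!is.numeric(mat)) stop("non-numeric cells in the feature table", call. = FALSE)
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate feature ids: ",
         paste(utils::head(unique(rownames(mat)[duplicated(rownames(mat))]), 5),
               collapse = ", "), call. = FALSE)
  }
  if (is.character(labels)) {
    labels <- read.delim(labels, sep = "\t", stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "group") %in% names(labels))) {
    stop("`labels` needs columns sample_id and group", call. = FALSE)
  }
  # expected orientation is features x samples; accept a samples x features
  # table (e.g. a simulate output) when its row ids are the labeled samples
  if (!any(colnames(mat) %in% labels$sample_id) &&
      all(rownames(mat) %in% labels$sample_id)) {
    message("table looks like samples x features; transposing")
    mat <- t(mat)
  }
  samples <- colnames(mat)
  missing <- setdiff(samples, labels$sample_id)
  if (length(missing)) {
    stop("label file is missing sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  grp <- labels$group[match(samples, labels$sample_id)]
  groups <- sort(unique(grp))
  if (length(groups) != 2) {
    stop("exactly two groups are required, got ", length(groups), call. = FALSE)
  }

  X <- t(mat)                      # samples x features
  y01 <- as.integer(grp == groups[2])
  parsed <- lapply(methods, .parse_method)
  names(parsed) <- methods
  need_anova <- any(vapply(parsed, function(x) x$type == "anova", logical(1)))

  screen <- NULL
  if (need_anova) {
    screen <- anova_screen(X, grp, adjust = FALSE)
    if (is.null(strata)) {
      screen$p_adj <- bh_adjust(screen$p_raw)
    } else {
      if (is.character(strata)) {
        strata <- read.delim(strata, sep = "\t", stringsAsFactors = FALSE)
      }
      if (!all(c("feature_id", "stratum") %in% names(strata))) {
        stop("`strata` needs columns feature_id and stratum", call. = FALSE)
      }
      s <- strata$stratum[match(screen$feature_id, strata$feature_id)]
      if (anyNA(s)) {
        stop("strata map is missing feature(s): ",
             paste(utils::head(screen$feature_id[is.na(s)], 5), collapse = ", "),
             call. = FALSE)
      }
      screen$p_adj <- NA_real_
      for (st in unique(s)) {
        idx <- s == st
        screen$p_adj[idx] <- bh_adjust(screen$p_raw[idx])
      }
    }
    screen$selected_raw05 <- screen$p_raw < 0.05
    screen$selected_fdr05 <- screen$p_adj < 0.05
    screen$selected_fdr20 <- screen$p_adj < 0.20
  }

  selected <- lapply(methods, function(m) {
    pm <- parsed[[m]]
    sel <- if (pm$type == "anova") {
      .anova_selection(screen, pm$label)
    } else {
      cfg <- enet
      cfg$alpha <- pm$alpha
      cfg$seed <- child_seed(base_seed, "apply", pm$label)
      selected_set(cv_enet(X, y01, cfg))
    }
    rownames(mat)[sel]
  })
  names(selected) <- methods

  overlap <- outer(methods, methods, Vectorize(function(a, b) {
    length(intersect(selected[[a]], selected[[b]]))
  }))
  dimnames(overlap) <- list(methods, methods)
  list(selected = selected, overlap = overlap, screen = screen)
}
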