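# End-to-end orchestration: load the trait table, apply the transforms and
# coding rules, and emit the phylogenetic-signal and PGLS model batteries
# for one or two phylogenies.

.binary_cols <- c("parasitoid", "egg_parasitoid", "specialist",
                  "para_hemiptera", "para_sternorrhyncha",
                  "para_other_hemiptera", "para_diptera",
                  "para_lepidoptera", "para_coleoptera", "para_hymenoptera")

.continuous_default <- c("log_body_length", "log_host_species",
                         "host_orders", "plant_genera")

#' Add log-transformed analysis columns to a trait table
#'
#' Adds `log_body_length` (from `body_length_mm`), `log_antennal_area` (from
#' `antennal_area_mm2`), and `log_host_species` (from `host_species`) where
#' the source columns are present. Non-positive values passed to the log
#' raise an error naming the offending species.
#'
#' @param data Trait table with a `species` column.
#' @param log_base Base of the logarithm (natural log by default; slopes,
#'   R^2 and evidence ratios are base-invariant, intercepts are not).
#' @return The tibble with the log columns appended.
#' @export
add_log_traits <- function(data, log_base = exp(1)) {
  data <- tibble::as_tibble(data)
  pairs <- c(body_length_mm = "log_body_length",
             antennal_area_mm2 = "log_antennal_area",
             host_species = "log_host_species")
  for (raw in names(pairs)) {
    if (!raw %in% names(data)) next
    v <- data[[raw]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop("non-positive '", raw, "' cannot be log-transformed for species: ",
           paste(data$species[bad], collapse = ", "), call. = FALSE)
    }
    data[[pairs[[raw]]]] <- log(v, base = log_base)
  }
  data
}

#' Load a species-by-trait table
#'
#' Reads a comma-delimited table with a header and a `species` column,
#' validates that the known 0/1 columns are binary, and applies the log
#' transforms used in analysis via [add_log_traits()].
#'
#' @param path Path to a CSV file (first column `species`).
#' @inheritParams add_log_traits
#' @return A tibble, one row per species.
#' @export
load_traits <- function(path, log_base = exp(1)) {
  df <- tibble::as_tibble(read.csv(path, check.names = FALSE))
  if (!"species" %in% names(df)) {
    stop("trait table must have a 'species' column", call. = FALSE)
  }
  df$species <- trimws(as.character(df$species))
  if (anyDuplicated(df$species)) {
    stop("duplicate species in trait table: ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(.binary_cols, names(df))) {
    v <- df[[col]]
    if (!all(is.na(v) | v %in% c(0, 1))) {
      stop("column '", col, "' must be binary (0/1); offending values: ",
           paste(unique(v[!is.na(v) & !v %in% c(0, 1)]), collapse = ", "),
           call. = FALSE)
    }
  }
  add_log_traits(df, log_base = log_base)
}

# Reconcile a trait table with a tree for a set of variables: keep species
# present in both with complete values, prune the tree, order rows to match.
.reconcile <- function(data, tree, vars, species = "species",
                       quiet = FALSE) {
  sp <- as.character(data[[species]])
  cc <- complete.cases(data[vars])
  used <- intersect(tree$tip.label, sp[cc])
  n_drop <- length(union(tree$tip.label, sp)) - length(used)
  if (!quiet && n_drop > 0L) {
    message("reconciliation for [", paste(vars, collapse = ", "), "]: ",
            length(used), " species used, ", n_drop, " dropped")
  }
  tr <- if (length(used) < ape::Ntip(tree)) ape::keep.tip(tree, used)
  else tree
  list(tree = tr, data = data[match(tr$tip.label, sp), , drop = FALSE])
}

#' Phylogenetic-signal battery for a trait table
#'
#' Computes Pagel's lambda (with a likelihood-ratio test against
#' `lambda = 0`) for each continuous trait and the Fritz-Purvis D statistic
#' (with a permutation test against `D = 1`) for each binary trait. When an
#' allometry formula is supplied (by default
#' `log_antennal_area ~ log_body_length` when both columns exist), the
#' signal of the size-corrected response is computed from the PGLS
#' residuals and reported as `residual_<response>`.
#'
#' @param data Trait table (one row per species) with a `species` column.
#' @param tree A `phylo` with branch lengths.
#' @param continuous Character vector of continuous trait columns; defaults
#'   to the standard set present in `data`.
#' @param binary Character vector of 0/1 trait columns; defaults to the
#'   standard set present in `data`.
#' @param allometry Formula for the size-corrected residual row; `"auto"`
#'   (the default) uses `log_antennal_area ~ log_body_length` when both
#'   columns are present, `NULL` skips the row.
#' @param n_sim Simulations per null for D.
#' @param seed Optional integer seed (D simulations are stochastic).
#' @param alpha Significance threshold for the `significant` flag.
#' @return A tibble of class `signal_battery` with columns `trait`,
#'   `statistic`, `estimate`, `p_value`, `significant`, `n`, `n_sim`, `note`.
#' @export
signal_battery <- function(data, tree, continuous = NULL, binary = NULL,
                           allometry = "auto", n_sim = 1000, seed = NULL,
                           alpha = 0.05) {
  stopifnot(inherits(tree, "phylo"))
  data <- tibble::as_tibble(data)
  if (is.null(continuous)) {
    continuous <- intersect(.continuous_default, names(data))
  }
  if (is.null(binary)) binary <- intersect(.binary_cols, names(data))
  if (identical(allometry, "auto")) {
    allometry <- if (all(c("log_antennal_area", "log_body_length") %in%
                           names(data))) {
      log_antennal_area ~ log_body_length
    }
  }
  if (!is.null(seed)) set.seed(seed)

  lambda_row <- function(trait, tr, y) {
    out <- tibble::tibble(trait = trait, statistic = "lambda",
                          estimate = NA_real_, p_value = NA_real_,
                          significant = NA, n = length(y),
                          n_sim = NA_integer_, note = NA_character_)
    if (length(unique(y)) < 2L || length(y) < 4L) {
      out$note <- "unidentifiable (constant or too few species)"
      return(out)
    }
    f <- fit_lambda(tr, y)
    out$estimate <- f$lambda
    out$p_value <- f$p_value
    out$significant <- f$p_value < alpha
    out
  }

  rows <- purrr::map(continuous, function(trait) {
    rec <- .reconcile(data, tree, trait)
    y <- setNames(as.numeric(rec$data[[trait]]), rec$tree$tip.label)
    lambda_row(trait, rec$tree, y)
  })

  if (!is.null(allometry)) {
    resp <- all.vars(allometry)[1L]
    fit <- fit_pgls(data, allometry, tree)
    res <- residuals_of(fit)
    tr <- ape::keep.tip(tree, names(res))
    rows <- c(rows, list(lambda_row(paste0("residual_", resp), tr,
                                    res[tr$tip.label])))
  }

  d_rows <- purrr::map(binary, function(trait) {
    rec <- .reconcile(data, tree, trait)
    st <- setNames(as.integer(rec$data[[trait]]), rec$tree$tip.label)
    out <- tibble::tibble(trait = trait, statistic = "D",
                          estimate = NA_real_, p_value = NA_real_,
                          significant = NA, n = length(st),
                          n_sim = as.integer(n_sim), note = NA_character_)
    if (length(unique(st)) < 2L) {
      out$note <- "unidentifiable (constant trait)"
      return(out)
    }
    f <- fit_d(rec$tree, st, n_sim = n_sim)
    out$estimate <- f$D
    out$p_value <- f$p_random
    out$significant <- f$p_random < alpha
    out
  })

  out <- dplyr::bind_rows(c(rows, d_rows))
  class(out) <- c("signal_battery", class(out))
  out
}

#' PGLS model battery against a null model
#'
#' Fits one PGLS model per battery entry (each a predictor, or a character
#' vector of predictors for a joint model), plus the null model
#' (intercept-only, or covariate-only when a covariate such as body size is
#' declared), each with its own maximum-likelihood lambda. Evidence ratios
#' against the null are always computed; the display column shows `"-"`
#' when the model's AIC is not below the null's, mirroring the table
#' convention of reporting support only for models that beat the null.
#'
#' @inheritParams signal_battery
#' @param response Response column name.
#' @param predictors Character vector (or list) of battery entries.
#' @param covariate Optional covariate column included in every model and in
#'   the null (e.g. `log_body_length` for antennal-size models).
#' @param lambda `"ML"` or a fixed value in `[0, 1]`, passed to
#'   [fit_pgls()].
#' @return A tibble of class `model_battery` with one row per coefficient of
#'   interest: columns `model`, `term`, `lambda`, `beta`, `se`, `r_squared`,
#'   `aic`, `delta_aic`, `er`, `er_shown`, `n`, `note`. The null AIC is
#'   stored in the `aic_null` attribute.
#' @export
model_battery <- function(data, tree, response, predictors,
                          covariate = NULL, lambda = "ML") {
  stopifnot(inherits(tree, "phylo"))
  data <- tibble::as_tibble(data)
  null_formula <- if (is.null(covariate)) {
    stats::reformulate("1", response)
  } else {
    stats::reformulate(covariate, response)
  }
  null_fit <- fit_pgls(data, null_formula, tree, lambda = lambda)
  aic_null <- null_fit$AIC
  null_term <- if (is.null(covariate)) "(Intercept)" else covariate
  null_row <- tibble::tibble(
    model = "(null)", term = null_term,
    lambda = null_fit$lambda,
    beta = if (is.null(covariate)) NA_real_
           else unname(coef(null_fit)[covariate]),
    se = if (is.null(covariate)) NA_real_ else unname(null_fit$se[covariate]),
    r_squared = null_fit$r.squared, aic = aic_null, delta_aic = 0,
    er = 1, er_shown = "1", n = null_fit$n, note = NA_character_)

  entries <- if (is.list(predictors)) predictors else as.list(predictors)
  rows <- purrr::map(entries, function(preds) {
    label <- paste(preds, collapse = " + ")
    blank <- tibble::tibble(model = label, term = preds[1L],
                            lambda = NA_real_, beta = NA_real_,
                            se = NA_real_, r_squared = NA_real_,
                            aic = NA_real_, delta_aic = NA_real_,
                            er = NA_real_, er_shown = "-", n = NA_integer_,
                            note = NA_character_)
    f <- stats::reformulate(c(covariate, preds), response)
    vars <- all.vars(f)
    cc <- complete.cases(data[vars])
    degenerate <- vapply(preds, function(pp) {
      length(unique(data[[pp]][cc])) < 2L
    }, logical(1))
    if (any(degenerate)) {
      blank$note <- paste("constant predictor after filtering:",
                          paste(preds[degenerate], collapse = ", "))
      return(blank)
    }
    fit <- tryCatch(fit_pgls(data, f, tree, lambda = lambda),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      blank$note <- conditionMessage(fit)
      return(blank)
    }
    er <- evidence_ratio(aic_null, fit$AIC)
    tibble::tibble(model = label, term = preds,
                   lambda = fit$lambda,
                   beta = unname(coef(fit)[preds]),
                   se = unname(fit$se[preds]),
                   r_squared = fit$r.squared, aic = fit$AIC,
                   delta_aic = aic_null - fit$AIC, er = er,
                   er_shown = if (fit$AIC < aic_null) {
                     format(round(er, 2))
                   } else {
                     "-"
                   },
                   n = fit$n, note = NA_character_)
  })
  out <- dplyr::bind_rows(c(rows, list(null_row)))
  attr(out, "aic_null") <- aic_null
  class(out) <- c("model_battery", class(out))
  out
}

#' Fitch parsimony origin counts for binary traits
#'
#' @inheritParams signal_battery
#' @param binary Character vector of 0/1 trait columns.
#' @return Tibble with `trait`, `origins` (minimum number of state changes),
#'   and `n`.
#' @export
origins_battery <- function(data, tree, binary = NULL) {
  stopifnot(inherits(tree, "phylo"))
  data <- tibble::as_tibble(data)
  if (is.null(binary)) binary <- intersect(.binary_cols, names(data))
  purrr::map_dfr(binary, function(trait) {
    rec <- .reconcile(data, tree, trait, quiet = TRUE)
    st <- setNames(as.integer(rec$data[[trait]]), rec$tree$tip.label)
    tibble::tibble(trait = trait,
                   origins = count_origins_fitch(rec$tree, st),
                   n = length(st))
  })
}

#' Configuration for a full comparative study run
#'
#' @param trees Named list of phylogenies: `phylo` objects or paths to
#'   Newick files. One entry per phylogeny (the dual-phylogeny design uses
#'   two).
#' @param traits A trait table (data frame) or path to a CSV file.
#' @param continuous,binary Trait columns for the signal battery (`NULL`
#'   uses the standard sets present in the data).
#' @param include_joint_egg_hemiptera Add the joint two-predictor antennal
#'   model (egg parasitoid + other Hemiptera) to the antennal battery.
#' @param n_sim Simulations per null for D.
#' @param seed Integer seed controlling all stochastic steps.
#' @param log_base Base of the log transforms.
#' @param out_dir Output directory for result tables and logs.
#' @return A list of class `study_config`.
#' @export
study_config <- function(trees, traits, continuous = NULL, binary = NULL,
                         include_joint_egg_hemiptera = FALSE, n_sim = 1000,
                         seed = 1, log_base = exp(1), out_dir = "results") {
  if (inherits(trees, "phylo")) trees <- list(tree = trees)
  if (is.null(names(trees)) || any(!nzchar(names(trees)))) {
    names(trees) <- paste0("phylogeny", seq_along(trees))
  }
  structure(list(trees = trees, traits = traits, continuous = continuous,
                 binary = binary,
                 include_joint_egg_hemiptera = include_joint_egg_hemiptera,
                 n_sim = n_sim, seed = seed, log_base = log_base,
                 out_dir = out_dir),
            class = "study_config")
}

#' Run the full comparative study
#'
#' For each configured phylogeny: the phylogenetic-signal battery, the
#' body-size model battery, the antennal-size model battery (with body size
#' as covariate and a body-size-only null), and Fitch origin counts for each
#' binary trait. Result tables are written as CSV under the configured
#' output directory together with a run log (seed, versions, species
#' reconciliation counts) and the resolved configuration; reruns with the
#' same seed produce byte-identical result tables. A stage that fails is
#' recorded in the log and skipped; partial outputs are retained.
#'
#' @param config A [study_config()] object.
#' @return Invisibly, a nested list of result tibbles, one element per
#'   phylogeny.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  traits <- if (is.character(config$traits)) {
    load_traits(config$traits, log_base = config$log_base)
  } else {
    add_log_traits(config$traits, log_base = config$log_base)
  }
  log_lines <- c(paste("package chalcomp",
                       as.character(utils::packageVersion("chalcomp"))),
                 R.version.string,
                 paste("seed:", config$seed),
                 paste("n_sim:", config$n_sim),
                 paste("log base:", format(config$log_base)))
  results <- list()
  body_preds <- intersect(c("log_host_species", "host_orders",
                            "plant_genera", .binary_cols), names(traits))
  ant_entries <- as.list(setdiff(body_preds, character(0)))
  if (isTRUE(config$include_joint_egg_hemiptera) &&
      all(c("egg_parasitoid", "para_other_hemiptera") %in% names(traits))) {
    ant_entries <- c(ant_entries,
                     list(c("egg_parasitoid", "para_other_hemiptera")))
  }
  for (nm in names(config$trees)) {
    tr <- config$trees[[nm]]
    if (is.character(tr)) tr <- parse_newick(paste(readLines(tr),
                                                   collapse = ""))
    set.seed(config$seed)
    res <- list()
    stage <- function(label, expr) {
      out <- tryCatch(expr, error = function(e) e)
      if (inherits(out, "error")) {
        log_lines <<- c(log_lines, paste0("[", nm, "] stage '", label,
                                          "' FAILED: ",
                                          conditionMessage(out)))
        NULL
      } else {
        log_lines <<- c(log_lines, paste0("[", nm, "] stage '", label,
                                          "' ok"))
        out
      }
    }
    res$signal <- stage("signal", suppressMessages(
      signal_battery(traits, tr, continuous = config$continuous,
                     binary = config$binary, n_sim = config$n_sim)))
    res$body_models <- stage("body_models", suppressMessages(
      model_battery(traits, tr, response = "log_body_length",
                    predictors = body_preds)))
    res$antenna_models <- stage("antenna_models", suppressMessages(
      model_battery(traits, tr, response = "log_antennal_area",
                    predictors = ant_entries,
                    covariate = "log_body_length")))
    res$origins <- stage("origins", suppressMessages(
      origins_battery(traits, tr, binary = config$binary)))
    for (what in names(res)) {
      if (is.null(res[[what]])) next
      write.csv(res[[what]],
                file.path(config$out_dir, paste0(nm, "_", what, ".csv")),
                row.names = FALSE)
    }
    results[[nm]] <- res
  }
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  resolved <- config
  resolved$trees <- lapply(config$trees, function(x) {
    if (is.character(x)) x else "(in-memory phylo)"
  })
  resolved$traits <- if (is.character(config$traits)) config$traits
  else "(in-memory table)"
  yaml::write_yaml(unclass(resolved),
                   file.path(config$out_dir, "config.yml"))
  invisible(results)
}
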