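# Synthetic-data generators: Yule trees, Brownian / lambda-structured
# continuous traits, binary traits under random and Brownian-threshold
# models, and a full study emulator producing a species-by-trait table with
# the structure of the chalcidoid data set.

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: while `j` lineages are
#' extant the time to the next speciation is `Exp(j * birth)`; the lineage
#' that splits is chosen uniformly. After the `n`th lineage appears one more
#' exponential interval is added so tips have positive pendant branches. The
#' result is ultrametric with expected root-to-tip depth
#' `sum(1 / (2:n)) / birth`.
#'
#' @param n_tips Number of tips (at least 2).
#' @param birth Per-lineage speciation rate.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return An ultrametric `phylo` with tips labelled `t1 ... tn`.
#' @export
yule_tree <- function(n_tips, birth = 1, seed = NULL) {
  if (!is.numeric(n_tips) || length(n_tips) != 1L || n_tips < 2) {
    stop("`n_tips` must be a single integer >= 2", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  n_int <- n - 1L
  int_parent <- integer(n_int)   # parent internal node (0 for root)
  int_time <- numeric(n_int)     # split time of each internal node
  int_time[1L] <- 0
  # active lineages: parent internal node id and its split time
  act_parent <- c(1L, 1L)
  t_now <- 0
  k <- 1L # internal nodes created
  while (k < n_int) {
    j <- length(act_parent)
    t_now <- t_now + rexp(1L, j * birth)
    i <- sample.int(j, 1L)
    k <- k + 1L
    int_parent[k] <- act_parent[i]
    int_time[k] <- t_now
    act_parent <- c(act_parent[-i], k, k)
  }
  t_end <- t_now + rexp(1L, n * birth)
  # assemble phylo: tips 1..n, internal node m -> n + m
  tip_par <- n + act_parent
  if (n_int > 1L) {
    int_edge <- cbind(n + int_parent[-1L], n + seq.int(2L, n_int))
    int_len <- int_time[-1L] - int_time[int_parent[-1L]]
  } else {
    int_edge <- matrix(integer(0), ncol = 2L)
    int_len <- numeric(0)
  }
  edge <- rbind(int_edge, cbind(tip_par, seq_len(n)))
  edge_len <- c(int_len, t_end - int_time[act_parent])
  tree <- list(edge = unname(edge), edge.length = edge_len,
               tip.label = paste0("t", seq_len(n)), Nnode = n_int)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

# Draw one multivariate-normal deviate with covariance Sigma via Cholesky,
# adding a jitter of 1e-10 * trace/n on the diagonal if the factorization
# fails (near-singular V(lambda) for lambda -> 1 with tiny terminal edges).
.rmvn_chol <- function(Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) {
    jit <- 1e-10 * mean(diag(Sigma))
    R <- chol(Sigma + diag(jit, nrow(Sigma)))
  }
  drop(crossprod(R, rnorm(nrow(Sigma))))
}

#' Simulate a continuous trait under Brownian motion
#'
#' Tip values are multivariate normal with mean `root_state` and covariance
#' `sigma2 * V` where `V` is the phylogenetic covariance matrix of the tree.
#'
#' @param tree A `phylo` with branch lengths.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param root_state Trait value at the root.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
brownian_trait <- function(tree, sigma2 = 1, root_state = 0, seed = NULL) {
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  V <- phylo_vcv(tree)
  setNames(root_state + .rmvn_chol(sigma2 * V), rownames(V))
}

#' Simulate a continuous trait with intermediate phylogenetic signal
#'
#' As [brownian_trait()] but with covariance `sigma2 * V(lambda)`, where
#' `V(lambda)` has its off-diagonal entries multiplied by `lambda`
#' (diagonal unchanged). `lambda = 1` is Brownian motion; `lambda = 0` gives
#' independent tips with variance `sigma2` times their depths.
#'
#' @inheritParams brownian_trait
#' @param lambda Signal strength in `[0, 1]`.
#' @return Named numeric vector of tip values.
#' @export
lambda_trait <- function(tree, lambda, sigma2 = 1, root_state = 0,
                         seed = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 ||
      lambda > 1) {
    stop("`lambda` must be in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sigma2) || sigma2 <= 0) {
    stop("`sigma2` must be positive", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  V <- lambda_vcv(phylo_vcv(tree), lambda)
  setNames(root_state + .rmvn_chol(sigma2 * V), rownames(V))
}

#' Simulate a phylogenetically clumped binary trait (Brownian threshold)
#'
#' Simulates a Brownian liability on the tree and assigns state 1 to the
#' `n_ones` tips with the largest liabilities, so the trait is clumped on the
#' phylogeny while the prevalence is fixed exactly. This is the generating
#' model of the Brownian null used by the D statistic.
#'
#' @inheritParams brownian_trait
#' @param n_ones Number of tips assigned state 1 (strictly between 0 and the
#'   number of tips).
#' @return Named integer vector of 0/1 states.
#' @export
threshold_binary <- function(tree, n_ones, seed = NULL) {
  n <- ape::Ntip(tree)
  if (!is.numeric(n_ones) || n_ones <= 0 || n_ones >= n) {
    stop("`n_ones` must be strictly between 0 and the number of tips",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  liab <- brownian_trait(tree, sigma2 = 1, root_state = 0)
  out <- integer(n)
  out[order(liab, decreasing = TRUE)[seq_len(n_ones)]] <- 1L
  setNames(out, names(liab))
}

#' Assign a binary trait uniformly at random across tips
#'
#' Exactly `n_ones` tips receive state 1, chosen uniformly; equivalent to a
#' prevalence-preserving shuffle. This is the phylogenetically random null of
#' the D statistic.
#'
#' @param labels Character vector of tip labels, or a `phylo` object.
#' @param n_ones Number of tips assigned state 1.
#' @param seed Optional integer seed.
#' @return Named integer vector of 0/1 states.
#' @export
random_binary <- function(labels, n_ones, seed = NULL) {
  if (inherits(labels, "phylo")) labels <- labels$tip.label
  n <- length(labels)
  if (!is.numeric(n_ones) || n_ones <= 0 || n_ones >= n) {
    stop("`n_ones` must be strictly between 0 and the number of tips",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- integer(n)
  out[sample.int(n, n_ones)] <- 1L
  setNames(out, labels)
}

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the structure of the chalcidoid trait table: 126 species;
#' log body length evolving by Brownian motion; log antennal area tied to
#' body length allometrically (slope 1.7) with a lambda-structured residual;
#' strongly right-skewed host-species counts (lognormal latent, rounded up);
#' host-order and plant-genus counts with mild dependence on host breadth;
#' and phylogenetically clumped 0/1 host-use flags. Prevalences follow the
#' counts stated for the real data where available (20/126 egg parasitoids,
#' 9/126 parasitizing hemipteran suborders other than Sternorrhyncha); the
#' rest are field-realistic choices, not estimates.
#'
#' @param n_species Number of species (tips).
#' @param birth_rate Yule speciation rate for the tree.
#' @param sigma2 Brownian rate of log body length.
#' @param root_log_length Root state of log body length (log mm).
#' @param allometry_intercept,allometry_slope Allometry of log antennal area
#'   (log mm^2) on log body length.
#' @param lambda_resid,sigma2_resid Signal and rate of the residual of the
#'   antennal allometry.
#' @param host_log_mean,host_log_sd Lognormal latent for host-species counts.
#' @param plant_log_mean,plant_log_sd Lognormal latent for plant-genus counts.
#' @param prevalence Named vector of prevalences in (0, 1) for the binary
#'   flags `parasitoid`, `egg_parasitoid`, `para_sternorrhyncha`,
#'   `para_other_hemiptera`, `para_diptera`, `para_lepidoptera`,
#'   `para_coleoptera`, `para_hymenoptera`.
#' @param clumping Named character vector (same names) with values
#'   `"brownian"` (Brownian-threshold clumping) or `"random"`.
#' @param seed Optional integer seed; fixed seed reproduces the study
#'   bit-identically.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 126,
                       birth_rate = 1,
                       sigma2 = 0.25,
                       root_log_length = 0.5,
                       allometry_intercept = -2.45,
                       allometry_slope = 1.7,
                       lambda_resid = 0.5,
                       sigma2_resid = 0.02,
                       host_log_mean = 1.0,
                       host_log_sd = 1.2,
                       plant_log_mean = 0.7,
                       plant_log_sd = 1.0,
                       prevalence = NULL,
                       clumping = NULL,
                       seed = NULL) {
  flags <- c(parasitoid = 0.88, egg_parasitoid = 20 / 126,
             para_sternorrhyncha = 0.22, para_other_hemiptera = 9 / 126,
             para_diptera = 0.15, para_lepidoptera = 0.20,
             para_coleoptera = 0.15, para_hymenoptera = 0.12)
  if (!is.null(prevalence)) {
    bad <- setdiff(names(prevalence), names(flags))
    if (length(bad)) stop("unknown binary traits: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    flags[names(prevalence)] <- prevalence
  }
  cl <- setNames(rep("brownian", length(flags)), names(flags))
  if (!is.null(clumping)) {
    bad <- setdiff(names(clumping), names(cl))
    if (length(bad)) stop("unknown binary traits: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (!all(clumping %in% c("brownian", "random"))) {
      stop("`clumping` values must be 'brownian' or 'random'", call. = FALSE)
    }
    cl[names(clumping)] <- clumping
  }
  cfg <- list(n_species = as.integer(n_species), birth_rate = birth_rate,
              sigma2 = sigma2, root_log_length = root_log_length,
              allometry_intercept = allometry_intercept,
              allometry_slope = allometry_slope,
              lambda_resid = lambda_resid, sigma2_resid = sigma2_resid,
              host_log_mean = host_log_mean, host_log_sd = host_log_sd,
              plant_log_mean = plant_log_mean, plant_log_sd = plant_log_sd,
              prevalence = flags, clumping = cl, seed = seed)
  if (cfg$n_species < 3) stop("`n_species` must be >= 3", call. = FALSE)
  if (cfg$sigma2 <= 0 || cfg$sigma2_resid < 0) {
    stop("Brownian rates must be positive", call. = FALSE)
  }
  if (cfg$lambda_resid < 0 || cfg$lambda_resid > 1) {
    stop("`lambda_resid` must be in [0, 1]", call. = FALSE)
  }
  if (any(flags <= 0 | flags >= 1)) {
    stop("prevalences must lie strictly in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Generate a full synthetic study (tree plus trait table)
#'
#' Emulates the study design end to end: a Yule tree of `n_species`; log body
#' length evolving by Brownian motion; log antennal area as an allometric
#' function of body length plus a lambda-structured residual; right-skewed
#' host-species counts; host-order and plant-genus counts; clumped or random
#' binary host-use flags at their configured prevalences, with
#' `para_hemiptera` the union of the two hemipteran suborder flags; and the
#' specialist flag derived from the host-breadth rule (parasitoid with fewer
#' than 10 host species confined to a single order).
#'
#' Morphometric columns are stored raw (mm, mm^2); [load_traits()] /
#' [add_log_traits()] apply the log transforms used in analysis.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `synthetic_study` with elements `tree` (`phylo`)
#'   and `traits` (tibble, one row per species).
#' @export
synthetic_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_species
  tree <- yule_tree(n, birth = config$birth_rate)
  log_bl <- brownian_trait(tree, config$sigma2, config$root_log_length)
  resid <- if (config$sigma2_resid > 0) {
    lambda_trait(tree, config$lambda_resid, config$sigma2_resid)
  } else {
    setNames(numeric(n), tree$tip.label)
  }
  log_aa <- config$allometry_intercept +
    config$allometry_slope * log_bl + resid
  host_species <- as.integer(ceiling(
    exp(rnorm(n, config$host_log_mean, config$host_log_sd))))
  host_orders <- 1L + stats::rbinom(n, 4L,
                                    stats::plogis((log(host_species) - 2) / 1.5))
  plant_genera <- as.integer(ceiling(
    exp(rnorm(n, config$plant_log_mean, config$plant_log_sd))))
  gen_flag <- function(name) {
    p <- config$prevalence[[name]]
    n_ones <- min(max(1L, round(p * n)), n - 1L)
    if (config$clumping[[name]] == "brownian") {
      threshold_binary(tree, n_ones)
    } else {
      random_binary(tree$tip.label, n_ones)
    }
  }
  flags <- lapply(setNames(nm = names(config$prevalence)), gen_flag)
  para_hemiptera <- pmax(flags$para_sternorrhyncha,
                         flags$para_other_hemiptera)
  specialist <- as.integer(flags$parasitoid == 1L &
                             host_species < 10L & host_orders == 1L)
  traits <- tibble::tibble(
    species = tree$tip.label,
    body_length_mm = exp(unname(log_bl)),
    antennal_area_mm2 = exp(unname(log_aa)),
    host_species = host_species,
    host_orders = host_orders,
    plant_genera = plant_genera,
    parasitoid = unname(flags$parasitoid),
    egg_parasitoid = unname(flags$egg_parasitoid),
    specialist = specialist,
    para_hemiptera = unname(para_hemiptera),
    para_sternorrhyncha = unname(flags$para_sternorrhyncha),
    para_other_hemiptera = unname(flags$para_other_hemiptera),
    para_diptera = unname(flags$para_diptera),
    para_lepidoptera = unname(flags$para_lepidoptera),
    para_coleoptera = unname(flags$para_coleoptera),
    para_hymenoptera = unname(flags$para_hymenoptera)
  )
  structure(list(tree = tree, traits = traits, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic comparative study:", nrow(x$traits), "species,",
      ncol(x$traits) - 1L, "traits\n")
  print(x$traits, n = 5)
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Writes the tree as Newick and the trait table as a comma-delimited file
#' with a header whose first column is `species`.
#'
#' @param study A `synthetic_study` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree_path <- file.path(dir, "tree.nwk")
  traits_path <- file.path(dir, "traits.csv")
  write_newick(study$tree, tree_path)
  write.csv(study$traits, traits_path, row.names = FALSE)
  invisible(c(tree = tree_path, traits = traits_path))
}
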