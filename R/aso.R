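#' Atom search optimization configuration
#'
#' Physics-inspired swarm optimiser: candidate solutions are atoms moving
#' in the unit box under a Lennard-Jones-style interaction force between
#' neighbours and a bond-length constraint force toward the best atom.
#' Heavier (fitter) atoms move less and refine locally; lighter atoms
#' explore. Used here as a wrapper feature selector: positions above
#' `selection_threshold` switch a feature on.
#'
#' @param n_atoms swarm size `N` (>= 2).
#' @param n_iterations iteration budget `T` (>= 1).
#' @param depth_weight interaction-force depth weight (alpha).
#' @param multiplier_weight constraint-force multiplier weight (beta).
#' @param selection_threshold position threshold mapping atoms to feature
#'   masks, in (0, 1).
#' @param fitness_penalty sparsity penalty added per selected-feature
#'   fraction in the wrapper objective.
#' @param seed RNG seed; every run is fully reproducible from it.
#' @return an `aso_config` list.
#' @export
aso_config <- function(n_atoms = 20, n_iterations = 50, depth_weight = 50,
                       multiplier_weight = 0.2, selection_threshold = 0.5,
                       fitness_penalty = 0.01, seed = 1L) {
  if (n_atoms < 2) abort("need at least 2 atoms")
  if (n_iterations < 1) abort("need at least 1 iteration")
  if (selection_threshold <= 0 || selection_threshold >= 1) {
    abort("selection_threshold must lie in (0, 1)")
  }
  structure(list(n_atoms = as.integer(n_atoms),
                 n_iterations = as.integer(n_iterations),
                 depth_weight = depth_weight,
                 multiplier_weight = multiplier_weight,
                 selection_threshold = selection_threshold,
                 fitness_penalty = fitness_penalty,
                 seed = as.integer(seed)),
            class = "aso_config")
}

# Fresh swarm with uniform positions in [0,1]^d, zero velocities and
# fitness evaluated once. Assumes the caller controls the RNG state.
aso_init <- function(objective, d, cfg) {
  n <- cfg$n_atoms
  positions <- matrix(runif(n * d), nrow = n)
  fitness <- apply(positions, 1L, objective)
  best <- which.min(fitness)
  swarm <- structure(
    list(positions = positions,
         velocities = matrix(0, nrow = n, ncol = d),
         fitness = fitness,
         masses = rep(1 / n, n),
         t = 0L, T = cfg$n_iterations,
         best_position = positions[best, ],
         best_fitness = fitness[best],
         trace = numeric(0)),
    class = "aso_swarm"
  )
  update_masses(swarm)
}

#' Update atomic masses from fitness
#'
#' `M_i = exp(-(Fit_i - Fit_best) / (Fit_worst - Fit_best))`, normalised to
#' `m_i = M_i / sum(M)`. When all atoms share one fitness the masses are
#' uniform `1/N`. Better (lower) fitness always gives a larger mass.
#'
#' @param swarm an `aso_swarm`.
#' @return the swarm with its `masses` field refreshed.
#' @export
update_masses <- function(swarm) {
  f <- swarm$fitness
  fb <- min(f); fw <- max(f)
  M <- if (fw > fb) exp(-(f - fb) / (fw - fb)) else rep(1, length(f))
  swarm$masses <- M / sum(M)
  swarm
}

#' One atom search optimization iteration
#'
#' Advances the swarm by a full step: the `K(t) = ceil(N - (N-2) sqrt(t/T))`
#' fittest atoms form the neighbour set; each atom feels the sum of scaled
#' Lennard-Jones-style forces from the neighbours (depth
#' `eta(t) = alpha (1 - (t-1)/T)^3 exp(-20 t / T)`, scaled distances
#' clipped to `[1.1 + 0.1 sin(pi t / (2T)), 1.24]`) plus the bond-length
#' constraint force `lambda(t) (x_best - x_i)` with
#' `lambda(t) = beta exp(-20 t / T)`. Accelerations are mass-weighted,
#' velocities are randomly damped per component, and positions are clipped
#' to the unit box before the objective is re-evaluated. The best-so-far
#' record never worsens.
#'
#' @param swarm an `aso_swarm`.
#' @param cfg an [aso_config()].
#' @param objective function mapping a position vector to a scalar fitness
#'   (lower is better).
#' @return the advanced swarm.
#' @export
aso_step <- function(swarm, cfg, objective) {
  n <- nrow(swarm$positions); d <- ncol(swarm$positions)
  t <- swarm$t + 1L; T <- swarm$T
  swarm <- update_masses(swarm)

  K <- as.integer(ceiling(n - (n - 2) * sqrt(t / T)))
  kbest <- order(swarm$fitness)[seq_len(K)]
  kmean <- colMeans(swarm$positions[kbest, , drop = FALSE])

  eta <- cfg$depth_weight * (1 - (t - 1) / T)^3 * exp(-20 * t / T)
  lambda <- cfg$multiplier_weight * exp(-20 * t / T)
  h_min <- 1.1 + 0.1 * sin(pi / 2 * t / T)
  h_max <- 1.24
  eps <- .Machine$double.eps

  acc <- matrix(0, nrow = n, ncol = d)
  for (i in seq_len(n)) {
    xi <- swarm$positions[i, ]
    sigma_scale <- sqrt(sum((xi - kmean)^2))
    Fi <- numeric(d)
    for (j in kbest) {
      if (j == i) next
      xj <- swarm$positions[j, ]
      rij <- sqrt(sum((xj - xi)^2))
      h <- if (sigma_scale > eps) rij / sigma_scale else h_max
      h <- min(max(h, h_min), h_max)
      fmag <- -eta * (2 * h^(-13) - h^(-7))
      Fi <- Fi + runif(1) * fmag * (xj - xi) / (rij + eps)
    }
    Gi <- lambda * (swarm$best_position - xi)
    acc[i, ] <- (Fi + Gi) / swarm$masses[i]
  }

  swarm$velocities <- matrix(runif(n * d), nrow = n) * swarm$velocities + acc
  swarm$positions <- clip01(swarm$positions + swarm$velocities)
  swarm$fitness <- apply(swarm$positions, 1L, objective)
  swarm$t <- t

  ib <- which.min(swarm$fitness)
  if (swarm$fitness[ib] < swarm$best_fitness) {
    swarm$best_fitness <- swarm$fitness[ib]
    swarm$best_position <- swarm$positions[ib, ]
  }
  swarm$trace <- c(swarm$trace, swarm$best_fitness)
  update_masses(swarm)
}

#' Minimise a continuous objective over the unit box
#'
#' Generic driver used both by the feature selector and directly on
#' benchmark objectives. Fully reproducible from `cfg$seed`.
#'
#' @param objective function of a position in `[0,1]^d` returning a scalar
#'   to minimise.
#' @param d problem dimension.
#' @param cfg an [aso_config()].
#' @return list with `best_position`, `best_fitness` and the per-iteration
#'   best-so-far `trace` (non-increasing).
#' @export
aso_optimize <- function(objective, d, cfg = aso_config()) {
  with_seed(cfg$seed, {
    swarm <- aso_init(objective, d, cfg)
    for (t in seq_len(cfg$n_iterations)) {
      swarm <- aso_step(swarm, cfg, objective)
    }
    list(best_position = swarm$best_position,
         best_fitness = swarm$best_fitness,
         trace = swarm$trace,
         swarm = swarm)
  })
}

#' Wrapper-selection fitness of a feature mask
#'
#' `fitness = (1 - acc_cv) + fitness_penalty * n_selected / n_features`,
#' where `acc_cv` is the stratified 5-fold cross-validated accuracy of a
#' fixed-seed 100-tree random forest restricted to the masked columns.
#' Deterministic given `(fm, mask, seed)`; lower is better.
#'
#' @param fm a z-scored [feature_matrix()].
#' @param mask logical/0-1 vector over feature columns; at least one
#'   feature must be selected.
#' @param seed RNG seed controlling folds and forest.
#' @param penalty sparsity penalty weight.
#' @return scalar fitness.
#' @export
mask_fitness <- function(fm, mask, seed = 1L, penalty = 0.01) {
  mask <- as.logical(mask)
  if (!any(mask)) abort("mask selects no features")
  x <- feature_values(fm)[, mask, drop = FALSE]
  y <- feature_labels(fm)
  acc <- rf_cv_accuracy(x, y, k = 5L, seed = seed)
  (1 - acc) + penalty * sum(mask) / length(mask)
}

# Stratified k-fold CV accuracy of a fixed-seed random forest.
rf_cv_accuracy <- function(x, y, k = 5L, seed = 1L, num_trees = 100L) {
  folds <- stratified_folds(y, k, seed)
  correct <- 0L
  for (i in seq_len(k)) {
    tr <- folds != i
    fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                          y = factor(y[tr], levels = c(0, 1)),
                          num.trees = num_trees, seed = seed,
                          num.threads = 1L, verbose = FALSE)
    pred <- predict(fit, data = x[!tr, , drop = FALSE],
                    seed = seed, num.threads = 1L)$predictions
    correct <- correct + sum(pred == factor(y[!tr], levels = c(0, 1)))
  }
  correct / length(y)
}

#' Wrapper feature selection by atom search optimization
#'
#' Runs [aso_optimize()] over the unit box with the [mask_fitness()]
#' objective: each atom position is thresholded at
#' `cfg$selection_threshold` into a feature mask (repaired to the single
#' largest component if empty). Returns the selected sub-matrix, the mask,
#' and the non-increasing best-fitness trace.
#'
#' @param fm a z-scored [feature_matrix()] with >= 10 samples and both
#'   classes present.
#' @param cfg an [aso_config()].
#' @return list with `mask` (named logical), `features` (selected
#'   [feature_matrix()]), `trace`, and `config`.
#' @export
select_features <- function(fm, cfg = aso_config()) {
  if (nrow(fm) < 10) abort("need at least 10 samples for wrapper selection")
  if (length(unique(feature_labels(fm))) < 2) abort("need both classes present")
  d <- length(feature_names(fm))
  to_mask <- function(pos) {
    m <- pos > cfg$selection_threshold
    if (!any(m)) m[which.max(pos)] <- TRUE
    m
  }
  objective <- function(pos) {
    mask_fitness(fm, to_mask(pos), seed = cfg$seed, penalty = cfg$fitness_penalty)
  }
  res <- aso_optimize(objective, d, cfg)
  mask <- setNames(to_mask(res$best_position), feature_names(fm))
  sel <- feature_matrix(feature_values(fm)[, mask, drop = FALSE],
                        feature_names(fm)[mask], feature_labels(fm),
                        modality = attr(fm, "modality"),
                        domain = attr(fm, "domain"))
  list(mask = mask, features = sel, trace = res$trace, config = cfg)
}

#' Persist a selection mask as JSON
#' @param selection result of [select_features()].
#' @param path output JSON path.
#' @export
write_selection <- function(selection, path) {
  jsonlite::write_json(
    list(selected = names(selection$mask)[selection$mask],
         threshold = selection$config$selection_threshold,
         seed = selection$config$seed,
         trace = selection$trace),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(selection)
}
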