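#' Configuration for the synthetic state-switching cohort generator
#'
#' The generator emulates a two-group resting-state cohort in which each
#' participant's ROI signal switches between a small number of latent
#' connectivity states. Each state is a block (module) structured correlation
#' matrix; switching follows a first-order Markov chain at time-point
#' resolution, so sliding windows that span a switch are naturally mixed.
#' Observations are zero-mean multivariate normal draws given the current
#' state, plus white observation noise; states differ by correlation
#' structure only, since windowed Pearson correlation is mean-invariant.
#'
#' Defaults describe a 20+20 cohort of 135 time points (TR = 3 s) over 60
#' regions with three states of increasing overall connectivity strength:
#' a weakly connected baseline state, a moderately connected state that the
#' patient group dwells in, and a rare strongly connected "spiking" state.
#' The two groups share the state repertoire but differ in transition
#' dynamics (patients are stickier in state 2 and switch more often) and,
#' optionally, in specific edges of one state via `patient_edge_effects`.
#'
#' @param n_per_group participants per group.
#' @param n_regions number of regions (default 60; supports up to 625).
#' @param n_timepoints time points per participant (default 135).
#' @param n_states number of latent states (default 3).
#' @param tr repetition time in seconds (default 3).
#' @param module_partition list (one element per state) of integer vectors
#'   assigning each region to a functional module.
#' @param within_r,between_r numeric vectors (one value per state) of target
#'   correlations inside and across modules, each in (-1, 1).
#' @param transition_control,transition_patient row-stochastic
#'   `n_states x n_states` transition matrices for the two groups.
#' @param initial_distribution initial state probabilities; default is the
#'   stationary distribution of each group's transition matrix.
#' @param patient_edge_effects list of effects, each
#'   `list(i =, j =, state =, delta_r =)`, added to the patient group's
#'   state correlation matrix on edge (i, j).
#' @param observation_noise_sd standard deviation of white observation noise
#'   added on top of the state-conditional signal (default 0.1).
#' @param seed integer master seed; the same seed reproduces the cohort
#'   byte for byte.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_per_group = 20,
                             n_regions = 60,
                             n_timepoints = 135,
                             n_states = 3,
                             tr = 3,
                             module_partition = NULL,
                             within_r = NULL,
                             between_r = NULL,
                             transition_control = NULL,
                             transition_patient = NULL,
                             initial_distribution = NULL,
                             patient_edge_effects = list(),
                             observation_noise_sd = 0.1,
                             seed = 1L) {
  stopifnot(n_per_group >= 1, n_regions >= 2, n_timepoints >= 2, n_states >= 1,
            observation_noise_sd >= 0)

  if (is.null(module_partition)) {
    module_partition <- default_partitions(n_regions, n_states)
  }
  if (is.null(within_r)) {
    within_r <- default_levels(n_states, c(0.6, 0.7, 0.8), fallback = 0.7)
  }
  if (is.null(between_r)) {
    between_r <- default_levels(n_states, c(0.0, 0.0, 0.0), fallback = 0.0)
  }
  if (is.null(transition_control)) {
    transition_control <- default_transition_matrix(n_states, group = "control")
  }
  if (is.null(transition_patient)) {
    transition_patient <- default_transition_matrix(n_states, group = "patient")
  }

  cfg <- structure(list(
    n_per_group = as.integer(n_per_group),
    n_regions = as.integer(n_regions),
    n_timepoints = as.integer(n_timepoints),
    n_states = as.integer(n_states),
    tr = tr,
    module_partition = module_partition,
    within_r = within_r,
    between_r = between_r,
    transition_control = transition_control,
    transition_patient = transition_patient,
    initial_distribution = initial_distribution,
    patient_edge_effects = patient_edge_effects,
    observation_noise_sd = observation_noise_sd,
    seed = as.integer(seed)
  ), class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

default_levels <- function(n_states, first_three, fallback) {
  if (n_states <= 3) first_three[seq_len(n_states)] else
    c(first_three, rep(fallback, n_states - 3))
}

# genuinely distinct three-module partitions per state, chosen so the
# within-module pair sets of any two states overlap only at the chance
# level (~1/3): contiguous thirds, region-index interleaving, and a
# stride permutation (stride coprime with p, so it cycles all regions)
default_partitions <- function(p, n_states) {
  m <- min(3, p)
  block <- ceiling(p / m)
  stride <- c(7, 11, 13, 17, 19, 23)
  stride <- stride[vapply(stride, function(s) p %% s != 0 && s %% m != 0,
                          logical(1))][1]
  if (is.na(stride)) stride <- 1
  pats <- list(
    function(i) (i - 1) %/% block %% m + 1,
    function(i) (i - 1) %% m + 1,
    function(i) (((i - 1) * stride) %% p) %/% block %% m + 1,
    function(i) ((i - 1) %/% 2) %% m + 1,
    function(i) (((i - 1) * stride + 1) %% p) %/% block %% m + 1
  )
  lapply(seq_len(n_states), function(s) {
    pats[[(s - 1) %% length(pats) + 1]](seq_len(p))
  })
}

# transition matrices of the form (1-r) I + r 1 pi^T, so the stationary
# distribution is exactly pi and the switching rate is set by r.
# control: mostly in the baseline state, ~4 transitions per 135 time points;
# patient: sticky state 2 and more frequent switching (~6 transitions)
default_transition_matrix <- function(n_states, group) {
  if (n_states == 1) return(matrix(1, 1, 1))
  if (n_states == 3) {
    if (group == "patient") {
      pi <- c(0.20, 0.50, 0.30)
      r <- 0.085
    } else {
      pi <- c(0.45, 0.25, 0.30)
      r <- 0.050
    }
    return((1 - r) * diag(3) + r * matrix(pi, 3, 3, byrow = TRUE))
  }
  stay <- 0.92
  m <- matrix((1 - stay) / (n_states - 1), n_states, n_states)
  diag(m) <- stay
  m
}

validate_generator_config <- function(cfg) {
  k <- cfg$n_states
  p <- cfg$n_regions
  stopifnot(length(cfg$module_partition) == k,
            length(cfg$within_r) == k, length(cfg$between_r) == k)
  for (s in seq_len(k)) {
    part <- cfg$module_partition[[s]]
    if (length(part) != p) stop("module partition for state ", s,
                                " must cover all ", p, " regions")
    if (abs(cfg$within_r[s]) >= 1 || abs(cfg$between_r[s]) >= 1) {
      stop("target correlations must lie in (-1, 1)")
    }
  }
  for (m in list(cfg$transition_control, cfg$transition_patient)) {
    check_stochastic(m, k)
  }
  if (!is.null(cfg$initial_distribution)) {
    d <- cfg$initial_distribution
    if (length(d) != k || any(d < 0) || abs(sum(d) - 1) > 1e-12) {
      stop("initial distribution must be a probability vector over states")
    }
  }
  for (eff in cfg$patient_edge_effects) {
    if (!all(c("i", "j", "state", "delta_r") %in% names(eff))) {
      stop("each edge effect needs fields i, j, state, delta_r")
    }
    if (eff$i < 1 || eff$j < 1 || eff$i > p || eff$j > p || eff$i == eff$j) {
      stop("edge effect references absent edge (", eff$i, ",", eff$j, ")")
    }
    if (eff$state < 1 || eff$state > k) stop("edge effect references absent state")
  }
  invisible(cfg)
}

check_stochastic <- function(m, k) {
  if (!is.matrix(m) || nrow(m) != k || ncol(m) != k) {
    stop("transition matrix must be ", k, " x ", k)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("transition matrix rows must be nonnegative and sum to 1")
  }
  invisible(m)
}

#' Planted group-difference edge effects for one state
#'
#' Builds a set of patient-vs-control edge effects mirroring the two
#' directions reported in case-control dynamic-FC studies: connections
#' strengthened in patients (placed on between-module edges, where the
#' baseline correlation is low) and connections weakened in patients
#' (placed on within-module edges). Edges are chosen with all regions
#' distinct so the positive-semidefinite repair of the perturbed state
#' matrix shrinks every planted effect by the same small amount.
#'
#' @param n_regions number of regions.
#' @param module_partition module assignment of the target state (defaults
#'   to the state's default partition).
#' @param state target state index (default 2).
#' @param n_increased,n_decreased number of strengthened / weakened edges.
#' @param delta_r effect magnitude (added on increased edges, subtracted on
#'   decreased edges).
#' @return list of effects suitable for `patient_edge_effects`, with the
#'   chosen edges in attributes `increased` and `decreased` (two-column
#'   matrices of region indices).
#' @export
default_edge_effects <- function(n_regions, module_partition = NULL,
                                 state = 2, n_increased = 12,
                                 n_decreased = 12, delta_r = 0.4) {
  if (is.null(module_partition)) {
    module_partition <- default_partitions(n_regions, max(state, 2))[[state]]
  }
  used <- integer(0)
  pick <- function(n_pairs, same_module) {
    out <- matrix(integer(0), 0, 2)
    for (i in seq_len(n_regions)) {
      if (nrow(out) == n_pairs) break
      if (i %in% used) next
      ok <- if (same_module) {
        module_partition == module_partition[i]
      } else {
        module_partition != module_partition[i]
      }
      j <- setdiff(which(ok), c(used, seq_len(i)))
      if (length(j) == 0) next
      out <- rbind(out, c(i, j[1]))
      used <<- c(used, i, j[1])
    }
    if (nrow(out) < n_pairs) stop("not enough regions for disjoint edges")
    out
  }
  up <- pick(n_increased, same_module = FALSE)
  down <- pick(n_decreased, same_module = TRUE)
  eff <- c(
    lapply(seq_len(nrow(up)), function(a)
      list(i = up[a, 1], j = up[a, 2], state = state, delta_r = delta_r)),
    lapply(seq_len(nrow(down)), function(a)
      list(i = down[a, 1], j = down[a, 2], state = state,
           delta_r = -delta_r))
  )
  attr(eff, "increased") <- up
  attr(eff, "decreased") <- down
  eff
}

#' Build a module-structured correlation matrix
#'
#' Entries are `within_r` for region pairs in the same module and `between_r`
#' across modules, with a unit diagonal. If the raw matrix is not positive
#' semi-definite it is repaired by eigenvalue clipping (floor 1e-8) followed
#' by rescaling the diagonal back to 1 — the standard nearest-correlation
#' shortcut, which is exact for feasible block designs.
#'
#' @param module_partition integer module assignment per region.
#' @param within_r,between_r target correlations in (-1, 1).
#' @return correlation matrix, PSD within 1e-10.
#' @export
build_state_correlation <- function(module_partition, within_r, between_r) {
  if (abs(within_r) >= 1 || abs(between_r) >= 1) {
    stop("correlation levels must lie in (-1, 1)")
  }
  p <- length(module_partition)
  same <- outer(module_partition, module_partition, "==")
  m <- ifelse(same, within_r, between_r)
  diag(m) <- 1
  ensure_psd_correlation(m)
}

# eigenvalue clipping + diagonal rescale; errors if the result still has a
# materially negative eigenvalue
ensure_psd_correlation <- function(m, clip = 1e-8, tol = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) return(m)
  vals <- pmax(e$values, clip)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  r <- (r + t(r)) / 2
  lam <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (lam < -tol) {
    stop("correlation levels remain non-PSD after projection (eigenvalue ",
         fmt_num(lam), ")")
  }
  r
}

#' Sample a latent state sequence from a first-order Markov chain
#'
#' @param transition_matrix row-stochastic `k x k` matrix.
#' @param n_timepoints sequence length.
#' @param initial_distribution probability vector over states; default is the
#'   chain's stationary distribution.
#' @return integer vector of state labels in `1..k`.
#' @export
sample_state_sequence <- function(transition_matrix, n_timepoints,
                                  initial_distribution = NULL) {
  k <- nrow(transition_matrix)
  check_stochastic(transition_matrix, k)
  if (is.null(initial_distribution)) {
    initial_distribution <- stationary_distribution(transition_matrix)
  }
  if (length(initial_distribution) != k || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-12) {
    stop("initial distribution must be a probability vector over states")
  }
  s <- integer(n_timepoints)
  s[1] <- sample.int(k, 1, prob = initial_distribution)
  for (t in seq_len(n_timepoints - 1)) {
    s[t + 1] <- sample.int(k, 1, prob = transition_matrix[s[t], ])
  }
  s
}

stationary_distribution <- function(m) {
  k <- nrow(m)
  a <- rbind(t(m) - diag(k), rep(1, k))
  b <- c(rep(0, k), 1)
  pi <- qr.solve(a, b)
  pi <- pmax(pi, 0)
  pi / sum(pi)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Writes one tab-separated time-series file per participant (rows = time
#' points, columns = region labels `R001`, ...), a `manifest.csv` with
#' demographics and clinical scores, and a `truth.json` with the latent state
#' sequences and a config echo. The same seed reproduces the files byte for
#' byte.
#'
#' @param config a [generator_config()].
#' @param dir output directory (created if needed).
#' @return (invisibly) list with `dir`, `manifest`, and `truth`; `truth`
#'   carries per-participant latent state sequences, the per-group per-state
#'   ground-truth correlation matrices, and the group assignment.
#' @export
generate_cohort <- function(config, dir) {
  validate_generator_config(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", dir)
  }

  p <- config$n_regions
  k <- config$n_states
  region_labels <- sprintf("R%03d", seq_len(p))

  # group- and state-specific truth matrices
  state_corr <- list(control = vector("list", k), patient = vector("list", k))
  for (s in seq_len(k)) {
    base <- build_state_correlation(config$module_partition[[s]],
                                    config$within_r[s], config$between_r[s])
    state_corr$control[[s]] <- base
    pat <- base
    for (eff in config$patient_edge_effects) {
      if (eff$state == s) {
        r <- pat[eff$i, eff$j] + eff$delta_r
        if (abs(r) >= 1) stop("edge effect pushes correlation outside (-1, 1)")
        pat[eff$i, eff$j] <- r
        pat[eff$j, eff$i] <- r
      }
    }
    state_corr$patient[[s]] <- ensure_psd_correlation(pat)
  }

  # eigen-based factors L with L %*% t(L) = R (works for semidefinite R)
  factors <- lapply(state_corr, function(group) lapply(group, corr_factor))

  n_total <- 2L * config$n_per_group
  ids <- sprintf("sub%03d", seq_len(n_total))
  groups <- rep(c("control", "patient"), each = config$n_per_group)

  set.seed(config$seed)
  subseeds <- draw_subseeds(n_total + 1L)
  manifest <- make_manifest(ids, groups, subseeds[n_total + 1L])

  trans <- list(control = config$transition_control,
                patient = config$transition_patient)
  sequences <- vector("list", n_total)
  names(sequences) <- ids

  for (idx in seq_len(n_total)) {
    set.seed(subseeds[idx])
    g <- groups[idx]
    seq_s <- sample_state_sequence(trans[[g]], config$n_timepoints,
                                   config$initial_distribution)
    sequences[[idx]] <- seq_s
    x <- matrix(0, config$n_timepoints, p)
    z <- matrix(rnorm(config$n_timepoints * p), config$n_timepoints, p)
    for (s in unique(seq_s)) {
      rows <- which(seq_s == s)
      x[rows, ] <- z[rows, , drop = FALSE] %*% t(factors[[g]][[s]])
    }
    if (config$observation_noise_sd > 0) {
      x <- x + config$observation_noise_sd *
        matrix(rnorm(length(x)), nrow(x), ncol(x))
    }
    write_timeseries_tsv(file.path(dir, paste0(ids[idx], ".tsv")),
                         x, region_labels)
  }

  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
            quote = FALSE)
  truth <- list(sequences = sequences, state_corr = state_corr,
                groups = setNames(groups, ids), config = config)
  jsonlite::write_json(
    list(sequences = sequences,
         groups = as.list(setNames(groups, ids)),
         config = config_echo(config)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(dir = dir, manifest = manifest, truth = truth))
}

corr_factor <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(r))
}

# demographics mimic an elderly memory-clinic cohort: matched age/sex,
# depressed MMSE and elevated NPI in patients
make_manifest <- function(ids, groups, seed) {
  set.seed(seed)
  n <- length(ids)
  age <- round(rnorm(n, 75, 6.4), 1)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  mmse <- ifelse(groups == "patient",
                 pmin(30, pmax(5, round(rnorm(n, 21.2, 3.2)))),
                 pmin(30, pmax(24, round(rnorm(n, 29.0, 1.3)))))
  npi <- ifelse(groups == "patient",
                pmax(0, round(rnorm(n, 4.6, 3.9), 1)),
                pmax(0, round(rnorm(n, 0.7, 1.3), 1)))
  data.frame(id = ids, group = groups, age = age, sex = sex,
             MMSE = mmse, NPI = npi, stringsAsFactors = FALSE)
}

config_echo <- function(cfg) {
  out <- unclass(cfg)
  out$transition_control <- apply(cfg$transition_control, 1, identity, simplify = FALSE)
  out$transition_patient <- apply(cfg$transition_patient, 1, identity, simplify = FALSE)
  out
}

write_timeseries_tsv <- function(path, x, labels) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  body <- apply(x, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(body, con)
}
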