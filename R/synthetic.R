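#' Default network partition and state coupling specification
#'
#' Builds the block specification consumed by [make_state_covariances]: a
#' partition of the `C` components into named functional networks and, per
#' latent state, a within-block coupling level for every block plus a
#' symmetric between-block coupling matrix.  For `C = 53` the partition
#' mirrors the seven canonical resting-state domains (SCN 5, ADN 2, SMN 8,
#' VSN 10, CCN 17, DMN 7, CBN 4 components); other `C` are split into up to
#' seven contiguous blocks of near-equal size.
#'
#' The default states share strong within-coupling in the sensory blocks
#' (auditory, sensorimotor, visual) and differ mainly in the
#' sensorimotor-visual between-block coupling, which ramps from negative in
#' state 1 to strongly positive in the last state; the last state
#' additionally has mildly negative coupling between the sensory blocks and
#' the rest of the brain.  Each state also has one block with elevated
#' within-coupling, cycled across states, so any two states are clearly
#' distinguishable (pairwise correlation of the vectorised matrices < 0.9).
#'
#' @param C number of components.
#' @param K number of latent states.
#' @return List with `blocks` (named list of component index vectors) and
#'   `states` (length-`K` list; each element has `within`, a named
#'   per-block coupling vector, and `between`, a symmetric `B x B` matrix
#'   of between-block couplings).
#' @export
default_state_spec <- function(C, K) {
  if (C == 53L || C == 53) {
    sizes <- c(SCN = 5L, ADN = 2L, SMN = 8L, VSN = 10L, CCN = 17L,
               DMN = 7L, CBN = 4L)
  } else {
    B <- max(2L, min(7L, C %/% 2L))
    base <- C %/% B
    sizes <- rep(base, B)
    sizes[seq_len(C - base * B)] <- base + 1L
    names(sizes) <- paste0("N", seq_len(B))
  }
  ends <- cumsum(sizes)
  blocks <- Map(function(a, b) seq.int(a, b), ends - sizes + 1L, ends)
  names(blocks) <- names(sizes)
  B <- length(blocks)
  states <- vector("list", K)
  if (C == 53L) {
    # mirror the canonical three-state structure: strong within-coupling
    # in the sensory domains everywhere; the SMN-VSN between-coupling
    # ramps from negative (state 1) to strongly positive (last state),
    # which also decouples the sensory domains from the rest
    sensory <- c(2L, 3L, 4L)
    pair <- c(3L, 4L)
    within_base <- rep(0.3, B)
    within_base[sensory] <- 0.5
    ramp <- if (K == 1L) 0 else seq(-0.3, 0.5, length.out = K)
    for (k in seq_len(K)) {
      wk <- within_base
      wk[((k - 1L) %% B) + 1L] <- wk[((k - 1L) %% B) + 1L] + 0.15
      names(wk) <- names(blocks)
      bet <- matrix(0, B, B, dimnames = list(names(blocks), names(blocks)))
      bet[pair[1L], pair[2L]] <- bet[pair[2L], pair[1L]] <- ramp[k]
      if (k == K && K > 1L) {
        others <- setdiff(seq_len(B), sensory)
        bet[sensory, others] <- bet[sensory, others] - 0.2
        bet[others, sensory] <- t(bet[sensory, others])
        bet[pair[1L], pair[2L]] <- bet[pair[2L], pair[1L]] <- ramp[k]
      }
      states[[k]] <- list(within = wk, between = bet)
    }
  } else {
    # generic C: each state elevates one block and couples one rotating
    # block pair strongly, so states stay clearly distinguishable even
    # with few components
    for (k in seq_len(K)) {
      wk <- rep(0.45, B)
      b1 <- ((k - 1L) %% B) + 1L
      b2 <- (k %% B) + 1L
      wk[b1] <- min(0.75, wk[b1] + 0.2)
      names(wk) <- names(blocks)
      bet <- matrix(0, B, B, dimnames = list(names(blocks), names(blocks)))
      if (b1 != b2) {
        level <- 0.5 - 0.3 * ((k - 1L) %/% B)  # weakens if pairs recycle
        bet[b1, b2] <- bet[b2, b1] <- level
      }
      states[[k]] <- list(within = wk, between = bet)
    }
  }
  list(blocks = blocks, states = states)
}

#' Construct latent-state covariance (correlation) matrices
#'
#' Builds one `C x C` unit-diagonal covariance per latent connectivity
#' state from a block template (within-network and between-network coupling
#' levels), repaired to the nearest positive-definite matrix by eigenvalue
#' clipping at `eig_floor` followed by re-normalisation to unit diagonal.
#'
#' @param C number of components (>= 2).
#' @param K number of states (>= 1).
#' @param block_spec specification as returned by [default_state_spec];
#'   `NULL` uses the default for this `C` and `K`.
#' @param eig_floor eigenvalue floor for the positive-definite repair
#'   (default 1e-3).
#' @return List of `K` objects of class `state_covariance`, each with
#'   `state_id`, `matrix` (symmetric positive definite, unit diagonal) and
#'   `network_blocks`.  A warning is raised if any two states have
#'   vectorised correlation >= 0.9 (insufficiently distinguishable).
#' @examples
#' sc <- make_state_covariances(C = 10, K = 2)
#' sc[[1]]$matrix[1:4, 1:4]
#' @export
make_state_covariances <- function(C, K, block_spec = NULL,
                                   eig_floor = 1e-3) {
  C <- as.integer(C); K <- as.integer(K)
  if (C < 2L) stop("make_state_covariances: C must be >= 2")
  if (K < 1L) stop("make_state_covariances: K must be >= 1")
  if (is.null(block_spec)) block_spec <- default_state_spec(C, K)
  blocks <- block_spec$blocks
  if (!setequal(unlist(blocks), seq_len(C)))
    stop("make_state_covariances: blocks must partition 1..C")
  if (length(block_spec$states) != K)
    stop("make_state_covariances: block_spec has ",
         length(block_spec$states), " states, expected K = ", K)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    st <- block_spec$states[[k]]
    if (any(abs(unlist(st)) >= 1))
      stop("make_state_covariances: coupling levels must lie in (-1, 1) ",
           "(state ", k, ")")
    S <- matrix(0, C, C)
    B <- length(blocks)
    for (b in seq_len(B)) S[blocks[[b]], blocks[[b]]] <- st$within[b]
    for (b1 in seq_len(B - 1L)) for (b2 in (b1 + 1L):B) {
      S[blocks[[b1]], blocks[[b2]]] <- st$between[b1, b2]
      S[blocks[[b2]], blocks[[b1]]] <- st$between[b1, b2]
    }
    diag(S) <- 1
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < eig_floor) {
      vals <- pmax(e$values, eig_floor)
      S <- e$vectors %*% (vals * t(e$vectors))
      S <- (S + t(S)) / 2
      S <- stats::cov2cor(S)
    }
    e2 <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (!is.finite(e2) || e2 <= 0)
      stop("make_state_covariances: state ", k,
           " template could not be repaired to positive definite at floor ",
           eig_floor)
    out[[k]] <- structure(list(state_id = k, matrix = S,
                               network_blocks = blocks),
                          class = "state_covariance")
  }
  if (K > 1L) {
    vecs <- vapply(out, function(s) vectorize_fnc(s$matrix),
                   numeric(C * (C - 1L) / 2L))
    cc <- stats::cor(vecs)
    mx <- max(cc[upper.tri(cc)])
    if (mx >= 0.9)
      warning("make_state_covariances: states are weakly distinguishable ",
              "(max pairwise centroid correlation ", signif(mx, 3), ")")
  }
  out
}

#' @export
print.state_covariance <- function(x, ...) {
  cat(sprintf("State covariance %d: %d x %d, %d network blocks\n",
              x$state_id, nrow(x$matrix), ncol(x$matrix),
              length(x$network_blocks)))
  invisible(x)
}

#' Stationary distribution of a column-stochastic transition matrix
#'
#' @param transition `K x K` column-stochastic matrix
#'   (`a[i, j] = p(next = i | current = j)`).
#' @return Probability vector of length `K` with `transition %*% pi = pi`.
#' @export
stationary_distribution <- function(transition) {
  check_column_stochastic(transition)
  e <- eigen(transition)
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Build a sticky transition matrix with a given stationary distribution
#'
#' Returns `a = s * I + (1 - s) * pi 1'` (column-stochastic), whose
#' stationary distribution is exactly `pi` and whose self-transition for
#' state `i` is `s + (1 - s) * pi[i]`.  The stickiness `s` controls the
#' mean dwell time.
#'
#' @param pi target stationary distribution (non-negative, sums to 1).
#' @param stickiness mixing weight in `[0, 1)` (default 0.85).
#' @return `K x K` column-stochastic matrix.
#' @export
transition_from_stationary <- function(pi, stickiness = 0.85) {
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-9)
    stop("transition_from_stationary: pi must be a probability vector")
  if (stickiness < 0 || stickiness >= 1)
    stop("transition_from_stationary: stickiness must be in [0, 1)")
  K <- length(pi)
  stickiness * diag(K) + (1 - stickiness) * matrix(pi, K, K)
}

check_column_stochastic <- function(transition, tol = 1e-9) {
  transition <- as.matrix(transition)
  if (nrow(transition) != ncol(transition))
    stop("transition matrix must be square")
  if (any(transition < -tol))
    stop("transition matrix has negative entries")
  cs <- colSums(transition)
  bad <- which(abs(cs - 1) > tol)
  if (length(bad))
    stop("transition matrix column(s) ", paste(bad, collapse = ", "),
         " do not sum to 1 (sums: ",
         paste(signif(cs[bad], 6), collapse = ", "), ")")
  invisible(transition)
}

#' Simulate a latent state sequence from a Markov chain
#'
#' @param transition `K x K` column-stochastic matrix,
#'   `a[i, j] = p(s(t+1) = i | s(t) = j)`.
#' @param L sequence length (>= 1).
#' @param initial initial distribution over states, a single starting state
#'   index, or `NULL` for the stationary distribution.
#' @return Integer vector of length `L` with entries in `1..K`.
#' @examples
#' a <- transition_from_stationary(c(.2, .5, .3), stickiness = 0.9)
#' s <- simulate_state_sequence(a, 500)
#' table(s) / 500
#' @export
simulate_state_sequence <- function(transition, L, initial = NULL) {
  transition <- check_column_stochastic(transition)
  L <- as.integer(L)
  if (L < 1L) stop("simulate_state_sequence: L must be >= 1")
  K <- nrow(transition)
  if (is.null(initial)) {
    p0 <- stationary_distribution(transition)
  } else if (length(initial) == 1L && initial == round(initial)) {
    p0 <- rep(0, K); p0[as.integer(initial)] <- 1
  } else {
    if (length(initial) != K || any(initial < 0) ||
        abs(sum(initial) - 1) > 1e-9)
      stop("simulate_state_sequence: initial must be a state index or a ",
           "probability vector of length K")
    p0 <- initial
  }
  cum <- apply(transition, 2L, cumsum)
  cum[K, ] <- 1  # guard accumulated rounding
  s <- integer(L)
  u <- stats::runif(L)
  s[1L] <- findInterval(u[1L], cumsum(p0), left.open = TRUE) + 1L
  s[1L] <- min(s[1L], K)
  if (L > 1L) for (t in 2:L) {
    s[t] <- min(findInterval(u[t], cum[, s[t - 1L]], left.open = TRUE) + 1L, K)
  }
  s
}

#' Simulate component time courses under a switching covariance regime
#'
#' Each regime step of the latent state sequence contributes
#' `samples_per_step` consecutive time points drawn zero-mean from that
#' state's covariance, plus independent Gaussian observation noise.
#'
#' @param covariances list of `state_covariance` objects (or plain
#'   matrices), one per state id used in `state_sequence`.
#' @param state_sequence integer regime sequence (one entry per regime
#'   step).
#' @param samples_per_step time points per regime step (default 10).
#' @param obs_noise_sd standard deviation of added white observation noise
#'   (default 0.2).
#' @param tr_seconds repetition time recorded in the output (default 2.2).
#' @param scan_id scan identifier.
#' @return List with `tc` (a [component_tc] of `length(state_sequence) *
#'   samples_per_step` rows) and `regime` (ground-truth per-time-point
#'   state labels).
#' @export
simulate_timecourses <- function(covariances, state_sequence,
                                 samples_per_step = 10L, obs_noise_sd = 0.2,
                                 tr_seconds = 2.2, scan_id = "sim") {
  mats <- lapply(covariances, function(s)
    if (inherits(s, "state_covariance")) s$matrix else as.matrix(s))
  state_sequence <- as.integer(state_sequence)
  if (any(state_sequence < 1L) || any(state_sequence > length(mats)))
    stop("simulate_timecourses: state_sequence labels without a covariance")
  samples_per_step <- as.integer(samples_per_step)
  if (samples_per_step < 1L)
    stop("simulate_timecourses: samples_per_step must be >= 1")
  C <- ncol(mats[[1L]])
  chols <- lapply(mats, function(m) chol(m))
  L <- length(state_sequence)
  Tn <- L * samples_per_step
  X <- matrix(NA_real_, Tn, C)
  for (step in seq_len(L)) {
    rows <- ((step - 1L) * samples_per_step + 1L):(step * samples_per_step)
    Z <- matrix(stats::rnorm(samples_per_step * C), samples_per_step, C)
    X[rows, ] <- Z %*% chols[[state_sequence[step]]]
  }
  if (obs_noise_sd > 0)
    X <- X + matrix(stats::rnorm(Tn * C, sd = obs_noise_sd), Tn, C)
  list(tc = component_tc(X, scan_id = scan_id, tr_seconds = tr_seconds),
       regime = rep(state_sequence, each = samples_per_step))
}

#' Generate a synthetic cohort with group-dependent state dynamics
#'
#' Emulates the data structure the state analysis assumes: each scan's
#' component time courses are driven by a subject-level Markov chain over
#' `K` latent covariance states, with group-dependent occupancy structure,
#' demographic covariates, and a clinical severity score (CDR-SOB) linked
#' to the occupancy of a designated state.
#'
#' Healthy subjects have CDR-SOB exactly 0; impaired subjects' scores are
#' `baseline + slope * (occupancy - expected occupancy) + noise`, truncated
#' to `[0.5, 9]`.  Group occupancy profiles default to the impaired group
#' spending more time in state 1 and less in state `K` than the healthy
#' group; pass identical profiles (or `slope = 0`) for null cohorts.  The
#' association's direction is therefore a parameter, not a constant.
#'
#' @param n_healthy,n_impaired group sizes.
#' @param K,C number of latent states and components.
#' @param occupancy_healthy,occupancy_impaired stationary occupancy
#'   profiles per group (length `K`); defaults approximate
#'   (0.22, 0.52, 0.26) and (0.30, 0.52, 0.18) for `K = 3`.
#' @param transition_healthy,transition_impaired optional explicit
#'   column-stochastic transition matrices; when given they override the
#'   occupancy profiles.
#' @param stickiness dwell-time parameter for
#'   [transition_from_stationary] (default 0.85 at the regime-step
#'   granularity).
#' @param score_model list with `state` (occupancy-linked state, default 1),
#'   `slope` (CDR-SOB change per unit occupancy, default 12), `noise_sd`
#'   (default 1.5) and `baseline` (default 2.68).
#' @param covariate_model list with `age_mean`, `age_sd`, `male_prob`, each
#'   a length-2 vector (healthy, impaired); defaults 69.83/75.10,
#'   8.64/7.85, 0.404/0.602.
#' @param scan_length_tp time points per scan after trimming (default 159,
#'   i.e. 164 volumes minus 5 dummy scans).
#' @param samples_per_step time points per regime step (default 10).
#' @param obs_noise_sd observation noise (default 0.2).
#' @param state_spec block specification for [make_state_covariances].
#' @param timecourses simulate component time courses (default `TRUE`);
#'   `FALSE` generates only state sequences, features and metadata (fast,
#'   for statistical simulations).
#' @return Object of class `dfnc_cohort`: list with `metadata` (data frame:
#'   subject_id, scan_id, group, age, gender, cdr_sob), `truth` (per scan:
#'   transition matrix, regime sequence, true window labels, occupancy),
#'   `states` (the latent covariances), `timecourses` (named list of
#'   [component_tc] or `NULL`) and `params`.
#' @export
generate_cohort <- function(n_healthy = 30L, n_impaired = 30L, K = 3L,
                            C = 53L,
                            occupancy_healthy = NULL,
                            occupancy_impaired = NULL,
                            transition_healthy = NULL,
                            transition_impaired = NULL,
                            stickiness = 0.85,
                            score_model = list(),
                            covariate_model = list(),
                            scan_length_tp = 159L,
                            samples_per_step = 10L,
                            obs_noise_sd = 0.2,
                            state_spec = NULL,
                            timecourses = TRUE) {
  n_healthy <- as.integer(n_healthy); n_impaired <- as.integer(n_impaired)
  if (n_healthy + n_impaired < 1L)
    stop("generate_cohort: need at least one subject")
  K <- as.integer(K); C <- as.integer(C)
  sm <- utils::modifyList(
    list(state = 1L, slope = 12, noise_sd = 1.5, baseline = 2.68),
    score_model)
  if (!is.finite(sm$slope)) stop("generate_cohort: score slope must be finite")
  cm <- utils::modifyList(
    list(age_mean = c(69.83, 75.10), age_sd = c(8.64, 7.85),
         male_prob = c(0.404, 0.602)),
    covariate_model)
  if (is.null(occupancy_healthy))
    occupancy_healthy <- default_occupancy(K, tilt = +1)
  if (is.null(occupancy_impaired))
    occupancy_impaired <- default_occupancy(K, tilt = -1)
  if (is.null(transition_healthy))
    transition_healthy <- transition_from_stationary(occupancy_healthy,
                                                     stickiness)
  if (is.null(transition_impaired))
    transition_impaired <- transition_from_stationary(occupancy_impaired,
                                                      stickiness)
  check_column_stochastic(transition_healthy)
  check_column_stochastic(transition_impaired)

  states <- make_state_covariances(C, K, block_spec = state_spec)
  n_steps <- as.integer(ceiling((scan_length_tp + 1L) / samples_per_step))
  window_trs <- 20L
  n <- n_healthy + n_impaired
  group <- rep(c("healthy", "impaired"), c(n_healthy, n_impaired))
  gi <- ifelse(group == "healthy", 1L, 2L)
  subject_id <- sprintf("S%04d", seq_len(n))
  scan_id <- sprintf("%s_scan1", subject_id)

  age <- stats::rnorm(n, cm$age_mean[gi], cm$age_sd[gi])
  gender <- stats::rbinom(n, 1L, cm$male_prob[gi])

  truth <- vector("list", n)
  names(truth) <- scan_id
  tcs <- if (timecourses) stats::setNames(vector("list", n), scan_id) else NULL
  occ_link <- numeric(n)
  for (s in seq_len(n)) {
    tm <- if (group[s] == "healthy") transition_healthy else transition_impaired
    seq_s <- simulate_state_sequence(tm, n_steps)
    regime_tp <- rep(seq_s, each = samples_per_step)[seq_len(scan_length_tp)]
    # true label of window w (0-based start) = regime at the window centre
    centres <- seq.int(0L, scan_length_tp - window_trs - 1L) + window_trs %/% 2L
    win_labels <- regime_tp[centres + 1L]
    occ <- tabulate(win_labels, nbins = K) / length(win_labels)
    truth[[s]] <- list(transition = tm, regime_steps = seq_s,
                       regime_tp = regime_tp, window_labels = win_labels,
                       occupancy = occ)
    occ_link[s] <- occ[sm$state]
    if (timecourses) {
      sim <- simulate_timecourses(states, seq_s,
                                  samples_per_step = samples_per_step,
                                  obs_noise_sd = obs_noise_sd,
                                  scan_id = scan_id[s])
      tc <- sim$tc
      tc$data <- tc$data[seq_len(scan_length_tp), , drop = FALSE]
      tcs[[s]] <- tc
    }
  }
  pi_imp <- stationary_distribution(transition_impaired)
  cdr <- numeric(n)
  imp <- group == "impaired"
  if (any(imp)) {
    raw <- sm$baseline + sm$slope * (occ_link[imp] - pi_imp[sm$state]) +
      stats::rnorm(sum(imp), sd = sm$noise_sd)
    cdr[imp] <- pmin(9, pmax(0.5, raw))
  }
  metadata <- data.frame(subject_id = subject_id, scan_id = scan_id,
                         group = group, age = age, gender = gender,
                         cdr_sob = cdr, stringsAsFactors = FALSE)
  structure(list(metadata = metadata, truth = truth, states = states,
                 timecourses = tcs,
                 params = list(K = K, C = C, stickiness = stickiness,
                               score_model = sm, covariate_model = cm,
                               occupancy_healthy = occupancy_healthy,
                               occupancy_impaired = occupancy_impaired,
                               transition_healthy = transition_healthy,
                               transition_impaired = transition_impaired,
                               scan_length_tp = scan_length_tp,
                               samples_per_step = samples_per_step,
                               obs_noise_sd = obs_noise_sd,
                               window_trs = window_trs)),
            class = "dfnc_cohort")
}

# Occupancy defaults: state 2 (of 3) dominant as the baseline state; the
# healthy tilt favours the last state, the impaired tilt the first.
default_occupancy <- function(K, tilt = 0) {
  if (K == 1L) return(1)
  if (K == 3L) {
    if (tilt > 0) return(c(0.22, 0.52, 0.26))
    if (tilt < 0) return(c(0.30, 0.52, 0.18))
    return(c(0.26, 0.52, 0.22))
  }
  w <- rep(1, K)
  if (tilt > 0) w <- seq(0.8, 1.2, length.out = K)
  if (tilt < 0) w <- seq(1.2, 0.8, length.out = K)
  w / sum(w)
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  tab <- table(x$metadata$group)
  cat(sprintf("Synthetic dFNC cohort: %d scans (%s), K = %d states, C = %d components\n",
              nrow(x$metadata),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$params$K, x$params$C))
  cat(sprintf("  time courses: %s\n",
              if (is.null(x$timecourses)) "not simulated"
              else sprintf("%d x %d per scan", x$params$scan_length_tp,
                           x$params$C)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes one delimited time-course file per scan (when simulated), a
#' comma-separated metadata table, and a JSON ground-truth sidecar (state
#' sequences and transition matrices) for testing.
#'
#' @param cohort a `dfnc_cohort` from [generate_cohort].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfnc_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cohort$timecourses)) {
    tcdir <- file.path(dir, "timecourses")
    dir.create(tcdir, showWarnings = FALSE)
    for (tc in cohort$timecourses)
      write_timecourses(tc, file.path(tcdir, paste0(tc$scan_id, ".csv")))
  }
  gt <- lapply(cohort$truth, function(t)
    list(transition = t$transition, regime_steps = t$regime_steps,
         window_labels = t$window_labels, occupancy = t$occupancy))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a labelled feature table for imbalanced classification
#'
#' Two Gaussian clouds with identity covariance whose means are separated
#' by `effect_size` (Mahalanobis distance), sized like the conversion
#' analysis (85 majority, 40 minority by default).
#'
#' @param n_major,n_minor class sizes (`n_major >= n_minor >= 2`).
#' @param n_features feature dimension (default 20).
#' @param effect_size mean separation in Mahalanobis units (default 1.5).
#' @return List with `x` (feature matrix, `n_major + n_minor` rows) and
#'   `labels` (factor with levels `uc_hc` = majority, `c_hc` = minority).
#' @export
generate_classification_cohort <- function(n_major = 85L, n_minor = 40L,
                                           n_features = 20L,
                                           effect_size = 1.5) {
  n_major <- as.integer(n_major); n_minor <- as.integer(n_minor)
  if (n_minor < 2L || n_major < n_minor)
    stop("generate_classification_cohort: need n_major >= n_minor >= 2")
  shift <- rep(effect_size / sqrt(n_features), n_features)
  x <- rbind(
    matrix(stats::rnorm(n_major * n_features), n_major, n_features),
    sweep(matrix(stats::rnorm(n_minor * n_features), n_minor, n_features),
          2L, shift, "+"))
  colnames(x) <- sprintf("f%02d", seq_len(n_features))
  labels <- factor(rep(c("uc_hc", "c_hc"), c(n_major, n_minor)),
                   levels = c("uc_hc", "c_hc"))
  list(x = x, labels = labels)
}
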