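#' Default cohort specification for a four-group emotion-dysregulation sample
#'
#' Builds the specification used by [generate_cohort()]. The defaults describe
#' a multi-site cohort of 166 participants — healthy controls (HC, n = 64) and
#' patients with bipolar disorder (BD, n = 63), attention-deficit/hyperactivity
#' disorder (ADHD, n = 20) and borderline personality disorder (BPD, n = 19) —
#' with group-wise moments for three clinical scales (ALS affective lability,
#' MADRS depression, YMRS mania), ages, sex ratios, scanner assignment
#' probabilities and mean framewise displacement. The demographic structure is
#' deliberately confounded with group (patient groups are younger, have skewed
#' sex ratios and uneven scanner coverage) so that the deconfounding and
#' group-restricted resampling machinery downstream has realistic work to do.
#'
#' @param group_sizes Named integer vector of participants per group.
#' @param behavior_moments Data frame with columns `group`, `measure`, `mean`,
#'   `sd` giving the target moments per group and clinical scale.
#' @param confound_model Data frame with one row per group and columns
#'   `age_mean`, `age_sd`, `sex_f_prop`, `fd_mean`, `fd_sd`, plus `scanner1`
#'   ... `scanner4` assignment probabilities (rows sum to 1).
#' @param seed Default integer seed used by [generate_cohort()] when no seed
#'   is passed explicitly.
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(HC = 64L, BD = 63L, ADHD = 20L, BPD = 19L),
                        behavior_moments = default_behavior_moments(),
                        confound_model = default_confound_model(),
                        seed = 1L) {
  if (any(group_sizes <= 0)) {
    stop("all group sizes must be positive; got zero/negative for: ",
         paste(names(group_sizes)[group_sizes <= 0], collapse = ", "))
  }
  if (is.null(names(group_sizes)) || any(!nzchar(names(group_sizes)))) {
    stop("group_sizes must be a named vector")
  }
  if (any(behavior_moments$sd < 0)) {
    stop("behavioral SDs must be non-negative")
  }
  if (any(confound_model$sex_f_prop < 0 | confound_model$sex_f_prop > 1)) {
    stop("sex proportions must lie in [0, 1]")
  }
  sc <- as.matrix(confound_model[, grep("^scanner", names(confound_model))])
  if (any(abs(rowSums(sc) - 1) > 1e-8)) {
    stop("scanner assignment probabilities must sum to 1 within each group")
  }
  structure(list(group_sizes = group_sizes,
                 behavior_moments = behavior_moments,
                 confound_model = confound_model,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_behavior_moments <- function() {
  data.frame(
    group   = rep(c("BD", "ADHD", "BPD", "HC"), each = 3),
    measure = rep(c("als", "madrs", "ymrs"), times = 4),
    mean    = c(1.04, 4.84, 1.68,
                1.12, 3.55, 0.00,
                1.80, 7.68, 1.47,
                0.42, 1.23, 0.66),
    sd      = c(0.64, 4.51, 1.87,
                0.48, 3.44, 0.00,
                0.46, 3.45, 1.39,
                0.40, 2.17, 1.39),
    stringsAsFactors = FALSE
  )
}

#' @rdname cohort_spec
#' @export
default_confound_model <- function() {
  data.frame(
    group      = c("BD", "ADHD", "BPD", "HC"),
    age_mean   = c(37.22, 24.00, 27.05, 35.06),
    age_sd     = c(11.61, 3.45, 4.67, 12.01),
    sex_f_prop = c(30 / 63, 7 / 20, 19 / 19, 37 / 64),
    fd_mean    = c(0.17, 0.14, 0.13, 0.17),
    fd_sd      = c(0.09, 0.05, 0.04, 0.07),
    scanner1   = c(16 / 63, 1, 1, 16 / 64),
    scanner2   = c(21 / 63, 0, 0, 48 / 64),
    scanner3   = c(10 / 63, 0, 0, 0),
    scanner4   = c(16 / 63, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# Affinely rescale standard-normal draws so the realized sample hits the
# requested mean and population SD exactly. sd = 0 yields a constant column.
match_moments <- function(n, mean, sd) {
  if (n == 1 || sd == 0) return(rep(mean, n))
  repeat {
    z <- stats::rnorm(n)
    zc <- z - base::mean(z)
    s <- sqrt(base::mean(zc^2))
    if (s > 1e-12) break
  }
  mean + sd * zc / s
}

# Integer allocation of n slots to category probabilities (largest remainder).
allocate_counts <- function(n, probs) {
  raw <- probs * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic cohort table
#'
#' Draws a cohort matching a [cohort_spec()] with *moment-matched* sampling:
#' within every group, each clinical scale and age/mean-FD column is affinely
#' rescaled so the realized group mean and population SD equal the specified
#' moments exactly (not just in expectation). Sex and scanner are assigned as
#' deterministic counts (largest-remainder rounding of the specified
#' proportions) in a randomly shuffled order.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed; defaults to the spec's seed. All randomness is
#'   local to this call.
#' @param clip_at_zero If `TRUE`, negative clinical scores are set to 0 after
#'   moment matching (this biases realized moments away from the targets and
#'   is off by default).
#'
#' @return Data frame with columns `participant_id`, `group`, `age`, `sex`,
#'   `scanner`, `mean_fd`, `als`, `madrs`, `ymrs`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_spec(), seed = 7)
#' mean(coh$als[coh$group == "BPD"]) # 1.80 by construction
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed,
                            clip_at_zero = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  groups <- names(spec$group_sizes)
  rows <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    n <- spec$group_sizes[[g]]
    cm <- spec$confound_model[spec$confound_model$group == g, , drop = FALSE]
    if (nrow(cm) != 1) stop("confound_model must have exactly one row for group ", g)
    bm <- spec$behavior_moments[spec$behavior_moments$group == g, , drop = FALSE]

    age <- match_moments(n, cm$age_mean, cm$age_sd)
    fd  <- match_moments(n, cm$fd_mean, cm$fd_sd)
    n_f <- as.integer(round(cm$sex_f_prop * n))
    sex <- sample(rep(c("F", "M"), c(n_f, n - n_f)))
    sc_probs <- as.numeric(cm[, paste0("scanner", 1:4)])
    sc_counts <- allocate_counts(n, sc_probs)
    scanner <- sample(rep(paste0("scanner", 1:4), sc_counts))

    beh <- lapply(c("als", "madrs", "ymrs"), function(m) {
      row <- bm[bm$measure == m, , drop = FALSE]
      if (nrow(row) != 1) stop("missing behavior moments for ", g, " x ", m)
      v <- match_moments(n, row$mean, row$sd)
      if (clip_at_zero) v <- pmax(v, 0)
      v
    })

    rows[[gi]] <- data.frame(
      participant_id = sprintf("sub-%s%03d", g, seq_len(n)),
      group = g, age = age, sex = sex, scanner = scanner, mean_fd = fd,
      als = beh[[1]], madrs = beh[[2]], ymrs = beh[[3]],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planted latent brain-behavior structure for recovery experiments
#'
#' Defines the ground truth injected by [generate_variability_maps()]: a
#' unit-norm brain salience supported on a contiguous block of voxels (first
#' half of the support positive, second half negative, mimicking paired
#' increases/decreases of variability), a unit-norm behavior salience
#' weighting the three clinical scales, the fraction of imaging variance the
#' planted component carries, and optional per-group offsets and confound
#' effects.
#'
#' @param n_voxels Number of voxels V.
#' @param behavior_salience Length-3 weight vector over (ALS, MADRS, YMRS);
#'   normalized internally. The default loads ALS and MADRS heavily and YMRS
#'   barely at all.
#' @param support_fraction Fraction of voxels carrying the planted brain
#'   pattern (contiguous block starting at voxel 1).
#' @param effect_size Fraction of total imaging variance carried by the
#'   planted component, in \[0, 1).
#' @param group_offsets Optional named list `group -> list(x = V-vector,
#'   y = 3-vector)` of additive offsets.
#' @param confound_effects Optional K x V matrix of confound effects paired
#'   with a K-column confound matrix at generation time.
#'
#' @return A list of class `synthetic_truth` with unit-norm saliences and the
#'   voxel indices of the planted support.
#' @export
synthetic_truth <- function(n_voxels,
                            behavior_salience = c(0.70, 0.70, 0.10),
                            support_fraction = 0.10,
                            effect_size = 0.5,
                            group_offsets = NULL,
                            confound_effects = NULL) {
  stopifnot(n_voxels >= 1, length(behavior_salience) == 3)
  if (effect_size < 0 || effect_size >= 1) {
    stop("effect_size must lie in [0, 1)")
  }
  n_sup <- max(1L, as.integer(ceiling(support_fraction * n_voxels)))
  if (n_sup > n_voxels) stop("support exceeds voxel count")
  v <- numeric(n_voxels)
  half <- ceiling(n_sup / 2)
  v[seq_len(half)] <- 1
  if (n_sup > half) v[(half + 1):n_sup] <- -1
  v <- v / sqrt(sum(v^2))
  u <- behavior_salience / sqrt(sum(behavior_salience^2))
  structure(list(brain_salience_true = v,
                 behavior_salience_true = u,
                 support = seq_len(n_sup),
                 effect_size = effect_size,
                 group_offsets = group_offsets,
                 confound_effects = confound_effects),
            class = "synthetic_truth")
}

#' Generate variability maps with a planted latent component
#'
#' Simulates the stacked participant-by-voxel matrix the PLS stage consumes:
#' `X = latent_score %*% t(brain_salience) * scale + confounds + group offsets
#' + iid Gaussian noise`. The latent score is the (unit-variance) projection
#' of the standardized behavior matrix onto the true behavior salience, so the
#' planted brain pattern covaries with behavior by construction. `scale` is
#' set from `truth$effect_size` so the planted component carries exactly that
#' fraction of the average per-entry variance relative to the noise.
#'
#' @param cohort Cohort table from [generate_cohort()] (supplies ALS, MADRS,
#'   YMRS and the group labels).
#' @param truth A [synthetic_truth()] whose brain salience has length
#'   `n_voxels`.
#' @param n_voxels Number of voxels V.
#' @param noise_sd SD of the iid Gaussian voxel noise.
#' @param seed Integer seed.
#' @param confounds Optional N x K matrix multiplied with
#'   `truth$confound_effects`.
#'
#' @return List with `X` (N x V), `latent_score` (the exact N-vector used),
#'   `Y` (N x 3 behavior matrix), and `truth`.
#' @export
generate_variability_maps <- function(cohort, truth, n_voxels,
                                      noise_sd = 1, seed = 1L,
                                      confounds = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (length(truth$brain_salience_true) != n_voxels) {
    stop("truth brain salience has length ", length(truth$brain_salience_true),
         " but n_voxels = ", n_voxels)
  }
  if (n_voxels < sum(truth$brain_salience_true != 0)) {
    stop("n_voxels smaller than the planted support")
  }
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  Y <- as.matrix(cohort[, c("als", "madrs", "ymrs")])

  f <- truth$effect_size
  if (f > 0) {
    Yz <- standardize_columns(Y, allow_constant = TRUE)$z
    latent <- as.vector(Yz %*% truth$behavior_salience_true)
    ls <- sqrt(mean((latent - mean(latent))^2))
    if (ls < 1e-12) stop("behavior projection is constant; cannot plant effect")
    latent <- (latent - mean(latent)) / ls
    # noise-relative scale; with zero noise the planted component is the only
    # signal, so any positive scale does (kept at the noise_sd = 1 value)
    scale_factor <- if (noise_sd > 0) {
      noise_sd * sqrt(f / (1 - f) * n_voxels)
    } else {
      sqrt(f / (1 - f) * n_voxels)
    }
  } else {
    latent <- numeric(n)
    scale_factor <- 0
  }

  X <- latent %*% t(truth$brain_salience_true) * scale_factor
  if (!is.null(truth$confound_effects)) {
    if (is.null(confounds)) stop("truth has confound_effects but no confounds given")
    X <- X + as.matrix(confounds) %*% truth$confound_effects
  }
  if (!is.null(truth$group_offsets)) {
    for (g in names(truth$group_offsets)) {
      idx <- which(cohort$group == g)
      off <- truth$group_offsets[[g]]
      if (!is.null(off$x)) X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, off$x, "+")
      if (!is.null(off$y)) Y[idx, ] <- sweep(Y[idx, , drop = FALSE], 2, off$y, "+")
    }
  }
  X <- X + matrix(stats::rnorm(n * n_voxels, sd = noise_sd), n, n_voxels)
  list(X = X, latent_score = latent, Y = Y, truth = truth)
}

#' Generate a synthetic BOLD run with controllable motion spikes
#'
#' Synthesizes band-limited (0.01-0.10 Hz) Gaussian voxel time-courses whose
#' per-voxel SD equals `target_sd` exactly (the signal is built in the
#' frequency domain, so all of its power sits inside the band), together with
#' six rigid-body motion parameters. Baseline motion is a bounded random walk
#' whose framewise displacement never exceeds ~0.15 mm; each frame listed in
#' `spike_frames` receives a persistent 0.7 mm translation step so the FD
#' trace exceeds the conventional 0.5 mm scrubbing threshold at exactly those
#' frames.
#'
#' @param n_frames Number of frames T (>= 10).
#' @param n_voxels Number of voxels V.
#' @param TR Repetition time in seconds.
#' @param target_sd Length-V vector of per-voxel signal SDs.
#' @param spike_frames Integer frame indices (1-based, >= 2) at which to plant
#'   motion spikes. Frame 1 cannot carry a spike because FD is defined as 0
#'   there.
#' @param seed Integer seed.
#' @param f_lo,f_hi Passband in Hz for the synthesized signal.
#'
#' @return A list of class `bold_run` with elements `data` (T x V), `TR`,
#'   `motion` (T x 6: mm, mm, mm, rad, rad, rad) and `participant_id`.
#' @export
generate_bold_run <- function(n_frames, n_voxels, TR, target_sd,
                              spike_frames = integer(), seed = 1L,
                              f_lo = 0.01, f_hi = 0.10) {
  if (n_frames < 10) stop("n_frames must be at least 10")
  stopifnot(TR > 0, length(target_sd) == n_voxels, all(target_sd >= 0))
  spike_frames <- as.integer(spike_frames)
  if (length(spike_frames) &&
      (any(spike_frames < 2) || any(spike_frames > n_frames))) {
    stop("spike_frames must lie in [2, n_frames]: frame 1 has FD 0 by definition")
  }
  set.seed(as.integer(seed))
  T <- as.integer(n_frames)

  freq <- seq_len(floor(T / 2)) / (T * TR)     # positive-frequency bins
  band <- which(freq >= f_lo & freq <= f_hi)
  if (!length(band)) stop("no Fourier bin falls inside the requested band")

  data <- matrix(0, T, n_voxels)
  half <- floor(T / 2)
  for (v in seq_len(n_voxels)) {
    coef <- complex(length.out = T)
    amp <- stats::rnorm(length(band)) + 1i * stats::rnorm(length(band))
    # avoid the Nyquist bin (must be real for even T); keep construction simple
    bb <- band[band < half | T %% 2 == 1]
    amp <- amp[seq_along(bb)]
    coef[bb + 1] <- amp
    coef[T - bb + 1] <- Conj(amp)
    x <- Re(stats::fft(coef, inverse = TRUE)) / T
    s <- sqrt(mean((x - mean(x))^2))
    data[, v] <- if (s > 0 && target_sd[v] > 0) {
      (x - mean(x)) / s * target_sd[v]
    } else {
      rep(0, T)
    }
  }

  trans_inc <- matrix(stats::runif(T * 3, -0.02, 0.02), T, 3)
  rot_inc <- matrix(stats::runif(T * 3, -3e-4, 3e-4), T, 3)
  trans_inc[1, ] <- 0
  rot_inc[1, ] <- 0
  motion <- cbind(apply(trans_inc, 2, cumsum), apply(rot_inc, 2, cumsum))
  for (s in spike_frames) {
    motion[s:T, 1] <- motion[s:T, 1] + 0.7  # persistent step: FD spike at s only
  }
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  structure(list(data = data, TR = TR, motion = motion,
                 participant_id = "sub-synthetic"),
            class = "bold_run")
}
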