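#' Simulate a wide-format symptom dataset with planted sudden gains
#'
#' Generates bounded-integer weekly symptom scores (BDI-like by default)
#' for `n_subjects` over `n_sessions`, with a gently declining mean,
#' AR(1)-correlated session-to-session noise, optional missingness, an
#' optional correlated secondary measure, and *planted* sudden gains whose
#' locations and magnitudes are returned as ground truth. Each planted
#' gain is a persistent downward step between its pre-gain session and the
#' next session.
#'
#' Feasibility of every plant is validated on the noise-free skeleton: the
#' trajectory must stay inside `score_range`, the planted magnitude must
#' reach both the absolute cutoff and the criterion-2 percentage of the
#' pre-gain score, plants of one subject must be at least three sessions
#' apart, and the background decline must stay well below the cutoff. With
#' `noise_sd = 0` every planted gain then satisfies all three criteria at
#' its interval and no other interval of that subject is flagged.
#'
#' @param n_subjects Number of subjects (rows).
#' @param n_sessions Number of sessions (score columns per measure).
#' @param score_range Integer `c(min, max)`; scores are rounded and clipped
#'   to this range (default `c(0, 63)`).
#' @param baseline_mean,baseline_sd Distribution of subject baselines.
#' @param baseline_override Optional named numeric vector mapping subject
#'   index (as character) to a fixed baseline, e.g. `c("3" = 54)`.
#' @param decline_per_session Deterministic improvement per session in the
#'   background trajectory (score units; default 0.4).
#' @param noise_sd Stationary standard deviation of the AR(1) session
#'   noise; 0 gives the deterministic skeleton.
#' @param ar AR(1) coefficient of the session noise (default 0.3).
#' @param planted_gains Data frame with columns `subject` (row index),
#'   `session_n` (pre-gain session, in `[2, n_sessions - 2]`) and
#'   `magnitude` (drop in score units, at least `sg_crit1_cutoff`).
#' @param planted_reversals Data frame with columns `subject`, `session_n`
#'   (a planted gain of that subject) and `rebound_session`
#'   (`>= session_n + 4`): the score at `rebound_session` is raised to just
#'   above the gain's reversal threshold.
#' @param sg_crit1_cutoff,sg_crit2_pct The identification settings the
#'   plants are validated against (defaults 7 and 0.25).
#' @param missing_rate Fraction of cells set missing.
#' @param missing_pattern `"random"` (independent cells) or
#'   `"monotone_dropout"` (subjects drop out from a random session onwards;
#'   calibrated so the expected missing fraction matches `missing_rate`).
#' @param secondary Also generate a correlated secondary measure
#'   (rumination-questionnaire-like, range 0-40)?
#' @param measure_prefix,secondary_prefix Column name prefixes; columns are
#'   `<prefix>_s1 ... <prefix>_s<n_sessions>`.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#'
#' @return A list with elements `data` (tibble: `id` plus score columns),
#'   `truth` (tibble: `id`, `sg_session_n`, `sg_magnitude` of every planted
#'   gain), `reversals` (tibble: `id`, `sg_session_n`, `rebound_session`)
#'   and `n_clipped` (count of range-clipped cells).
#' @export
#' @examples
#' sim <- sg_generate(n_subjects = 5, n_sessions = 12, noise_sd = 0,
#'                    planted_gains = data.frame(subject = 1, session_n = 5,
#'                                               magnitude = 12),
#'                    seed = 1)
#' sim$truth
sg_generate <- function(n_subjects,
                        n_sessions,
                        score_range = c(0, 63),
                        baseline_mean = 30,
                        baseline_sd = 7,
                        baseline_override = NULL,
                        decline_per_session = 0.4,
                        noise_sd = 2,
                        ar = 0.3,
                        planted_gains = NULL,
                        planted_reversals = NULL,
                        sg_crit1_cutoff = 7,
                        sg_crit2_pct = 0.25,
                        missing_rate = 0,
                        missing_pattern = c("random", "monotone_dropout"),
                        secondary = TRUE,
                        measure_prefix = "bdi",
                        secondary_prefix = "rq",
                        seed) {
  missing_pattern <- match.arg(missing_pattern)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer so the dataset is reproducible.",
         call. = FALSE)
  }
  if (n_sessions < 4L) {
    stop("`n_sessions` must be at least 4.", call. = FALSE)
  }
  if (decline_per_session < 0 ||
      decline_per_session + 1 >= sg_crit1_cutoff) {
    stop("`decline_per_session` must be non-negative and more than one ",
         "point below `sg_crit1_cutoff`, or background intervals could ",
         "mimic planted gains.", call. = FALSE)
  }
  plants <- if (is.null(planted_gains)) {
    data.frame(subject = integer(0), session_n = integer(0),
               magnitude = numeric(0))
  } else {
    as.data.frame(planted_gains)
  }
  revs <- if (is.null(planted_reversals)) {
    data.frame(subject = integer(0), session_n = integer(0),
               rebound_session = integer(0))
  } else {
    as.data.frame(planted_reversals)
  }

  withr::local_seed(as.integer(round(seed) %% .Machine$integer.max))

  baselines <- stats::rnorm(n_subjects, baseline_mean, baseline_sd)
  if (!is.null(baseline_override)) {
    idx <- as.integer(names(baseline_override))
    baselines[idx] <- as.numeric(baseline_override)
  }

  # noise-free skeleton, with plants as persistent downward steps
  skeleton <- matrix(0, n_subjects, n_sessions)
  for (i in seq_len(n_subjects)) {
    traj <- baselines[i] - decline_per_session * (seq_len(n_sessions) - 1)
    pl <- plants[plants$subject == i, , drop = FALSE]
    if (nrow(pl) > 0L) {
      pl <- pl[order(pl$session_n), , drop = FALSE]
      if (any(pl$session_n < 2L | pl$session_n > n_sessions - 2L)) {
        stop("Infeasible plant: pre-gain sessions must lie in [2, ",
             n_sessions - 2L, "].", call. = FALSE)
      }
      if (nrow(pl) > 1L && any(diff(pl$session_n) < 3L)) {
        stop("Infeasible plant: gains of one subject must be at least ",
             "three sessions apart so their criterion-3 windows do not ",
             "overlap.", call. = FALSE)
      }
      if (any(pl$magnitude < sg_crit1_cutoff)) {
        stop("Infeasible plant: magnitudes must be at least the intended ",
             "criterion-1 cutoff (", sg_crit1_cutoff, ").", call. = FALSE)
      }
      for (k in seq_len(nrow(pl))) {
        n <- pl$session_n[k]
        x_n_skel <- traj[n]
        if (pl$magnitude[k] < sg_crit2_pct * (x_n_skel + 0.5)) {
          stop("Infeasible plant: a drop of ", pl$magnitude[k],
               " from a pre-gain score near ", round(x_n_skel, 1),
               " cannot satisfy criterion 2 at sg_crit2_pct = ",
               sg_crit2_pct, ".", call. = FALSE)
        }
        traj[(n + 1L):n_sessions] <- traj[(n + 1L):n_sessions] -
          pl$magnitude[k]
      }
    }
    # plant-free subjects may drift against the bounds and simply clip,
    # but a plant pushed outside the range would be destroyed by clipping
    if (nrow(pl) > 0L &&
        any(traj < score_range[1] | traj > score_range[2])) {
      stop("Infeasible plant: the noise-free trajectory of subject ", i,
           " leaves the score range [", score_range[1], ", ",
           score_range[2], "].", call. = FALSE)
    }
    skeleton[i, ] <- traj
  }

  # AR(1) noise with stationary sd = noise_sd
  noise <- matrix(0, n_subjects, n_sessions)
  if (noise_sd > 0) {
    innov_sd <- noise_sd * sqrt(1 - ar^2)
    noise[, 1L] <- stats::rnorm(n_subjects, 0, noise_sd)
    for (t in 2:n_sessions) {
      noise[, t] <- ar * noise[, t - 1L] +
        stats::rnorm(n_subjects, 0, innov_sd)
    }
  }

  raw <- skeleton + noise
  clipped <- raw < score_range[1] | raw > score_range[2]
  scores <- pmin(pmax(round(raw), score_range[1]), score_range[2])

  # planted reversal rebounds, pinned just above the realised threshold
  if (nrow(revs) > 0L) {
    for (k in seq_len(nrow(revs))) {
      i <- revs$subject[k]
      n <- revs$session_n[k]
      r <- revs$rebound_session[k]
      hit <- plants$subject == i & plants$session_n == n
      if (!any(hit)) {
        stop("Planted reversal refers to subject ", i, ", session ", n,
             ", where no gain is planted.", call. = FALSE)
      }
      if (r < n + 4L || r > n_sessions) {
        stop("`rebound_session` must lie in [session_n + 4, n_sessions] ",
             "so the rebound stays clear of the gain's criterion-3 window.",
             call. = FALSE)
      }
      thr <- reversal_value(scores[i, n], scores[i, n + 1L])
      scores[i, r] <- min(score_range[2], ceiling(thr) + 1)
    }
  }

  # missingness
  if (missing_rate > 0) {
    if (missing_pattern == "random") {
      mask <- matrix(stats::runif(n_subjects * n_sessions) < missing_rate,
                     n_subjects, n_sessions)
    } else {
      # each subject drops out from a uniform session with probability
      # 2 * missing_rate, censoring half the series on average
      mask <- matrix(FALSE, n_subjects, n_sessions)
      drops <- stats::runif(n_subjects) < min(1, 2 * missing_rate)
      start <- sample(2:n_sessions, n_subjects, replace = TRUE)
      for (i in seq_len(n_subjects)) {
        if (drops[i]) mask[i, start[i]:n_sessions] <- TRUE
      }
    }
  } else {
    mask <- matrix(FALSE, n_subjects, n_sessions)
  }

  primary <- scores
  primary[mask] <- NA_real_

  data <- tibble::tibble(id = seq_len(n_subjects))
  for (t in seq_len(n_sessions)) {
    data[[paste0(measure_prefix, "_s", t)]] <- primary[, t]
  }
  if (isTRUE(secondary)) {
    sec <- round(10 + 0.5 * scores +
                   matrix(stats::rnorm(n_subjects * n_sessions, 0, 2),
                          n_subjects, n_sessions))
    sec <- pmin(pmax(sec, 0), 40)
    sec[mask] <- NA_real_
    for (t in seq_len(n_sessions)) {
      data[[paste0(secondary_prefix, "_s", t)]] <- sec[, t]
    }
  }

  truth <- tibble::tibble(
    id = as.integer(plants$subject),
    sg_session_n = as.integer(plants$session_n),
    sg_magnitude = as.numeric(plants$magnitude)
  )
  truth <- truth[order(truth$id, truth$sg_session_n), ]

  list(
    data = data,
    truth = truth,
    reversals = tibble::tibble(id = as.integer(revs$subject),
                               sg_session_n = as.integer(revs$session_n),
                               rebound_session = as.integer(revs$rebound_session)),
    n_clipped = sum(clipped)
  )
}

# Plant schedule for the demo dataset. Magnitudes are derived from the
# noise-free skeleton so that each drop clears the 25% criterion with a
# five-point margin (and the 7-point cutoff), leaving room for session
# noise without breaking any criterion at the planted interval.
demo_plants <- function(subject, baseline, sessions,
                        decline = 0.4, pct = 0.25, margin = 5) {
  x <- baseline
  prev <- 1L
  mags <- numeric(length(sessions))
  for (k in seq_along(sessions)) {
    x <- x - decline * (sessions[k] - prev)
    mags[k] <- max(7, ceiling(pct * x + margin))
    prev <- sessions[k]
    x <- x - mags[k]
  }
  data.frame(subject = subject, session_n = sessions, magnitude = mags)
}

#' Demo dataset: 43 subjects, 12 weekly sessions, known ground truth
#'
#' A synthetic stand-in for a typical sudden-gains demo dataset: weekly
#' BDI-like scores (`bdi_s1 ... bdi_s12`, range 0-63) for 43 subjects in a
#' 12-session intervention, plus a parallel rumination-like secondary
#' measure (`rq_s1 ... rq_s12`). Sixteen subjects carry planted sudden
#' gains, nine of them more than one (eight with two, one with three), for
#' 26 gains in total; three gains later reverse; six subjects have missing
#' sessions, one of them so sparsely observed that no interval can be
#' classified. The dataset is generated at a fixed seed and is identical
#' on every call.
#'
#' @return A 43 x 25 tibble (`id` + 24 score columns) with attributes
#'   `"ground_truth"` (tibble `id`, `sg_session_n`, `sg_magnitude`) and
#'   `"planted_reversals"` (tibble `id`, `sg_session_n`,
#'   `rebound_session`).
#' @export
#' @examples
#' demo <- sg_demo_data()
#' dim(demo)
#' head(attr(demo, "ground_truth"))
sg_demo_data <- function() {
  plants <- rbind(
    demo_plants(3L, 54, c(2L, 5L, 9L)),
    demo_plants(5L, 46, c(3L, 7L)),
    demo_plants(9L, 46, c(4L, 8L)),
    demo_plants(14L, 46, c(2L, 6L)),
    demo_plants(17L, 46, c(5L, 9L)),
    demo_plants(22L, 46, c(3L, 8L)),
    demo_plants(26L, 46, c(4L, 9L)),
    demo_plants(31L, 46, c(2L, 7L)),
    demo_plants(39L, 46, c(6L, 10L)),
    demo_plants(7L, 38, 3L),
    demo_plants(11L, 38, 4L),
    demo_plants(16L, 38, 9L),
    demo_plants(19L, 38, 5L),
    demo_plants(25L, 38, 8L),
    demo_plants(33L, 38, 6L),
    demo_plants(40L, 38, 7L)
  )
  reversals <- data.frame(
    subject = c(7L, 19L, 33L),
    session_n = c(3L, 5L, 6L),
    rebound_session = c(7L, 9L, 10L)
  )
  overrides <- c("3" = 54,
                 "5" = 46, "9" = 46, "14" = 46, "17" = 46, "22" = 46,
                 "26" = 46, "31" = 46, "39" = 46,
                 "7" = 38, "11" = 38, "16" = 38, "19" = 38, "25" = 38,
                 "33" = 38, "40" = 38)
  sim <- sg_generate(
    n_subjects = 43L,
    n_sessions = 12L,
    baseline_mean = 28,
    baseline_sd = 6,
    baseline_override = overrides,
    decline_per_session = 0.4,
    noise_sd = 1.5,
    ar = 0.3,
    planted_gains = plants,
    planted_reversals = reversals,
    missing_rate = 0,
    secondary = TRUE,
    seed = 8675309L
  )
  data <- sim$data
  # curated missingness on subjects without plants, including one subject
  # observed too sparsely for any interval to be classified
  blank <- function(d, id, sessions) {
    for (t in sessions) {
      d[[paste0("bdi_s", t)]][d$id == id] <- NA_real_
      d[[paste0("rq_s", t)]][d$id == id] <- NA_real_
    }
    d
  }
  data <- blank(data, 1L, 5L)
  data <- blank(data, 12L, c(2L, 7L))
  data <- blank(data, 20L, 9:12)
  data <- blank(data, 28L, c(3L, 4L))
  data <- blank(data, 36L, c(11L, 12L))
  data <- blank(data, 42L, 2:11)
  attr(data, "ground_truth") <- sim$truth
  attr(data, "planted_reversals") <- sim$reversals
  data
}
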