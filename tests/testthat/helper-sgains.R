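# Build a wide one-measure dataset from a list of score vectors.
wide_data <- function(..., prefix = "bdi_s") {
  series <- list(...)
  s <- length(series[[1L]])
  out <- tibble::tibble(id = seq_along(series))
  for (t in seq_len(s)) {
    out[[paste0(prefix, t)]] <- vapply(series, `[`, numeric(1), t)
  }
  out
}

session_vars <- function(s, prefix = "bdi_s") paste0(prefix, seq_len(s))

# A 12-session series with a clean planted gain at the n -> n+1 interval:
# three-point plateaus around the gain, gentle tails elsewhere.
gain_series <- function(pre = c(30, 29, 28), post = c(18, 17, 16), n = 5,
                        s = 12) {
  x <- numeric(s)
  x[(n - 2):n] <- pre
  x[(n + 1):(n + 3)] <- post
  if (n - 3 >= 1) x[1:(n - 3)] <- pre[1L] + rev(seq_len(n - 3))
  if (n + 4 <= s) x[(n + 4):s] <- post[3L] - seq_len(s - n - 3)
  x
}

# Positions (row id, pre-gain session) of all 1-flags in an identify_sg()
# flag table, recovered independently of the package's internals.
flagged_positions <- function(flags, prefix = "sg") {
  comb <- grep(paste0("^", prefix, "_[0-9]+to[0-9]+$"), names(flags),
               value = TRUE)
  out <- NULL
  for (col in comb) {
    n <- as.integer(sub("to.*", "", sub(paste0(prefix, "_"), "", col)))
    hit <- which(!is.na(flags[[col]]) & flags[[col]] == 1L)
    if (length(hit)) {
      out <- rbind(out, data.frame(id = flags[[1L]][hit], session_n = n))
    }
  }
  if (is.null(out)) {
    return(data.frame(id = integer(0), session_n = integer(0)))
  }
  out[order(out$id, out$session_n), , drop = FALSE]
}

# Random plant schedule over a noise-free skeleton, guaranteed feasible:
# magnitudes track the declining skeleton so criterion 2 clears with margin.
random_plant_spec <- function(n_subjects, n_sessions, decline = 0.4) {
  baselines <- stats::runif(n_subjects, 42, 55)
  plants <- NULL
  for (i in seq_len(n_subjects)) {
    k <- sample(0:2, 1L, prob = c(0.3, 0.4, 0.3))
    if (k == 0L) next
    candidates <- 2:(n_sessions - 2)
    sessions <- sort(sample(candidates, 1L))
    if (k == 2L) {
      later <- candidates[candidates >= sessions + 3L]
      if (length(later) == 0L) {
        k <- 1L
      } else {
        sessions <- c(sessions, sample(rep(later, 2L), 1L))
      }
    }
    x <- baselines[i]
    prev <- 1L
    for (n in sessions) {
      x <- x - decline * (n - prev)
      mag <- max(7, ceiling(0.25 * (x + 0.5)) + 1)
      plants <- rbind(plants, data.frame(subject = i, session_n = n,
                                         magnitude = mag))
      x <- x - mag
      prev <- n
    }
  }
  list(baselines = stats::setNames(baselines, seq_len(n_subjects)),
       plants = plants)
}
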