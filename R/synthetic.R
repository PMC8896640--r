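# Seeded generators emulating three quality-score regimes (NovaSeq-like
# 4-value, HiSeq-2000-like 40-value, PacBio-CLR-like 0..93) and
# Illumina-style read names in name-sorted or position-scrambled order.
# All generators are deterministic given their seed and leave the caller's
# RNG state untouched.

with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Describe a synthetic quality-score regime
#'
#' `novaseq` emulates patterned-flowcell data quantized to the four Phred
#' values 2/12/23/37: each read carries a hidden, slowly switching
#' good/bad cluster state; the good state emits almost exclusively Q37
#' (long same-value runs, high RLE benefit) while the bad state emits a
#' skewed mix centred on Q23.  The burstiness makes several preceding
#' values and the history of quality changes genuinely informative beyond
#' the single previous value, as in real data.  `hiseq` uses 40 observable
#' values (2..41) with a smooth random-walk transition matrix pulled
#' toward the high thirties.  `pacbio` draws each of the 94 values 0..93
#' independently (negligible lag-1 autocorrelation).  The Illumina-like
#' regimes add a mild late-cycle degradation: the probability of replacing
#' a value by a low-quality draw ramps up over the final cycles.
#'
#' @param kind One of `"novaseq"`, `"hiseq"`, `"pacbio"`.
#' @param n_records Number of reads.
#' @param record_length Read length (cycles).
#' @param seed Integer seed; same profile and seed give identical output.
#' @return A `quality_profile` list with the alphabet, initial
#'   distribution, transition matrix (over hidden states for `novaseq`,
#'   over observed values otherwise), emission matrix (hidden-state
#'   regimes only) and position-effect parameters.
#' @export
quality_profile <- function(kind = c("novaseq", "hiseq", "pacbio"),
                            n_records = 1000L, record_length = 100L,
                            seed = 1L) {
  kind <- match.arg(kind)
  emission <- NULL
  if (kind == "novaseq") {
    alphabet <- c(2L, 12L, 23L, 37L)
    # hidden good/bad cluster state; rows: from-good, from-bad
    trans <- rbind(c(0.997, 0.003),
                   c(0.050, 0.950))
    emission <- rbind(c(0.001, 0.004, 0.020, 0.975),   # good
                      c(0.008, 0.100, 0.780, 0.112))   # bad
    init <- c(0.85, 0.15)
    low <- c(0.00, 0.30, 0.70, 0.00)
    ramp <- 0.02
  } else if (kind == "hiseq") {
    alphabet <- 2:41
    mu <- 0.80 * seq_along(alphabet) + 0.20 * 36
    trans <- t(vapply(mu, function(m) {
      w <- exp(-abs(seq_along(alphabet) - m) / 2.5)
      w / sum(w)
    }, numeric(length(alphabet))))
    w0 <- exp(-abs(seq_along(alphabet) - 36) / 4)
    init <- w0 / sum(w0)
    low <- rev(seq_along(alphabet)) / sum(seq_along(alphabet))
    ramp <- 0.08
  } else {
    alphabet <- 0:93
    w <- 1 + 0.5 * sin(seq(0, pi, length.out = 94))  # mildly non-uniform
    trans <- matrix(rep(w / sum(w), each = 94), nrow = 94, byrow = FALSE)
    trans <- t(apply(trans, 1, function(r) r / sum(r)))
    init <- w / sum(w)
    low <- w / sum(w)
    ramp <- 0
  }
  if (any(abs(rowSums(trans) - 1) > 1e-9)) stop("invalid transition matrix")
  structure(list(kind = kind, alphabet = alphabet, transition = trans,
                 emission = emission, init = init, low = low, ramp = ramp,
                 n_records = as.integer(n_records),
                 record_length = as.integer(record_length),
                 seed = as.integer(seed)),
            class = "quality_profile")
}

#' Generate synthetic quality records from a profile
#'
#' @param profile A [quality_profile()].
#' @return A [quality_records()] object with `n_records` reads of
#'   `record_length` values each.
#' @export
gen_qualities <- function(profile) {
  stopifnot(inherits(profile, "quality_profile"))
  if (any(profile$transition < 0) ||
      any(abs(rowSums(profile$transition) - 1) > 1e-9))
    stop("invalid transition matrix")
  n <- profile$n_records
  L <- profile$record_length
  k <- length(profile$alphabet)
  with_local_seed(profile$seed, {
    cum <- t(apply(profile$transition, 1, cumsum))
    nh <- nrow(profile$transition)
    state <- matrix(0L, nrow = n, ncol = L)
    state[, 1L] <- findInterval(runif(n), cumsum(profile$init)) + 1L
    for (j in seq_len(L - 1L)) {
      u <- runif(n)
      s <- state[, j]
      nxt <- integer(n)
      for (v in unique(s)) {
        idx <- s == v
        nxt[idx] <- findInterval(u[idx], cum[v, ]) + 1L
      }
      state[, j + 1L] <- pmin(nxt, nh)
    }
    if (!is.null(profile$emission)) {
      # hidden-state regime: draw observed symbols from the per-state
      # emission distributions
      ecum <- t(apply(profile$emission, 1, cumsum))
      obs <- matrix(0L, nrow = n, ncol = L)
      for (h in seq_len(nh)) {
        idx <- state == h
        obs[idx] <- findInterval(runif(sum(idx)), ecum[h, ]) + 1L
      }
      state <- pmin(obs, k)
    }
    if (profile$ramp > 0) {
      # late-cycle degradation: replacement probability ramps linearly over
      # the final cycles
      pos_p <- pmax(0, (seq_len(L) / L - 0.85) / 0.15) * profile$ramp
      hit <- matrix(runif(n * L), n, L) <
        matrix(pos_p, n, L, byrow = TRUE)
      nhit <- sum(hit)
      if (nhit > 0) {
        state[hit] <- findInterval(runif(nhit), cumsum(profile$low)) + 1L
      }
    }
    quality_records(lapply(seq_len(n), function(i)
      profile$alphabet[state[i, ]]))
  })
}

#' Describe a synthetic Illumina-style read-name corpus
#'
#' Names follow the `instrument:run:flowcell:lane:tile:x:y` template.  In
#' `name_sorted` order the y field increases by a small random step, with an
#' occasional bump of x (resetting y), so consecutive names differ in at
#' most two numeric fields and the list is lexicographically
#' non-decreasing (all numeric fields keep a fixed digit width).
#' `position_scrambled` applies a seeded uniform permutation of the sorted
#' list, standing in for position-sorted read order.
#'
#' @param n_names Number of names.
#' @param order `"name_sorted"` or `"position_scrambled"`.
#' @param seed Integer seed.
#' @param prefix Instrument/run/flowcell/lane prefix shared by all names.
#' @return A `name_profile` list.
#' @export
name_profile <- function(n_names = 1000L,
                         order = c("name_sorted", "position_scrambled"),
                         seed = 1L, prefix = "SIM001:23:ABCD7EFXX:5") {
  order <- match.arg(order)
  structure(list(n_names = as.integer(n_names), order = order,
                 seed = as.integer(seed), prefix = prefix,
                 tile = 1101L),
            class = "name_profile")
}

#' Generate synthetic read names from a profile
#'
#' @param profile A [name_profile()].
#' @return Character vector of `n_names` read names.
#' @export
gen_names <- function(profile) {
  stopifnot(inherits(profile, "name_profile"))
  n <- profile$n_names
  with_local_seed(profile$seed, {
    x <- integer(n)
    y <- integer(n)
    cx <- 10000L + sample.int(200L, 1L)
    cy <- 100000L + sample.int(500L, 1L)
    for (i in seq_len(n)) {
      x[i] <- cx
      y[i] <- cy
      bump_x <- cy > 999000L || runif(1) < 0.01
      if (bump_x) {
        cx <- cx + sample.int(20L, 1L)
        if (cx > 99999L) cx <- 10000L + sample.int(200L, 1L)  # wraps only
                                                  # beyond desk-scale sizes
        cy <- 100000L + sample.int(500L, 1L)
      } else {
        cy <- cy + sample.int(40L, 1L)
      }
    }
    names <- sprintf("%s:%d:%d:%d", profile$prefix, profile$tile, x, y)
    if (profile$order == "position_scrambled") names <- names[sample.int(n)]
    names
  })
}
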