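# Constant-rate birth-death simulation over a fixed duration ------------

#' Birth-death simulation parameters
#'
#' Rates are continuous-time hazards per lineage per time unit: each living
#' lineage waits an exponential time with total rate `S + E`; the event is a
#' speciation with probability `S / (S + E)`, otherwise an extinction.  The
#' diversification rate `D = S - E` is always derived, never stored.
#'
#' @param speciation Speciation rate `S` (>= 0).  The classical replication
#'   grids never exceed 0.9, but the simulator itself accepts any rate.
#' @param extinction Extinction rate `E` (>= 0).
#' @param duration Duration `T` of the simulation in time units (> 0); the
#'   origin split sits at time 0 and the present at `T`.
#' @param seed Optional integer seed; when set, [simulate_tree()] is
#'   bit-reproducible and [simulate_surviving()] derives an independent
#'   substream for every tree index.
#' @param max_lineages Safety cap on the number of lineages a single tree may
#'   create; exceeding it raises a condition of class `crownsim_overflow`.
#'   Supercritical rates over long durations are expected to hit this cap.
#' @return An object of class `bd_params`.
#' @export
bd_params <- function(speciation, extinction, duration, seed = NULL,
                      max_lineages = 1e6) {
  stopifnot(is.numeric(speciation), length(speciation) == 1L, speciation >= 0,
            is.numeric(extinction), length(extinction) == 1L, extinction >= 0,
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(max_lineages), max_lineages >= 2)
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(speciation = speciation, extinction = extinction,
                 duration = duration, seed = seed,
                 max_lineages = max_lineages),
            class = "bd_params")
}

#' @export
print.bd_params <- function(x, ...) {
  cat(sprintf("bd_params: S = %g, E = %g (D = %g), T = %g%s\n",
              x$speciation, x$extinction, x$speciation - x$extinction,
              x$duration,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Survival-conditioning policy
#'
#' Controls the rejection sampling in [simulate_surviving()]: trees are
#' generated in sets of `batch_size` and those with fewer than
#' `min_extant_tips` lineages alive at the present are discarded, until
#' `n_keep` survivors have been collected.
#'
#' @param batch_size Trees per batch (default 100, the classical protocol).
#' @param n_keep Number of surviving trees to keep (default 50).
#' @param min_extant_tips Minimum extant lineages for a tree to count as
#'   surviving.  Default 2: the crown group (MRCA of living members) is
#'   undefined for a single survivor, so such trees are counted separately
#'   and excluded.
#' @param max_batches Guard against near-certain-extinction regimes; at most
#'   `max_batches * batch_size` trees are generated before giving up.
#' @return An object of class `survival_policy`.
#' @export
survival_policy <- function(batch_size = 100L, n_keep = 50L,
                            min_extant_tips = 2L, max_batches = 1000L) {
  stopifnot(batch_size >= 1, n_keep >= 1, min_extant_tips >= 1,
            max_batches >= 1)
  structure(list(batch_size = as.integer(batch_size),
                 n_keep = as.integer(n_keep),
                 min_extant_tips = as.integer(min_extant_tips),
                 max_batches = as.integer(max_batches)),
            class = "survival_policy")
}

# Deterministic substream seed for tree `k` of a run seeded with `seed`.
# Exact in double arithmetic (all intermediates < 2^53); result < 2^31.
substream_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 8191 + 1) %% 2147483563)
}

#' Simulate one birth-death tree of fixed duration
#'
#' The tree starts at time 0 with a split into two origin lineages.  Each
#' living lineage is processed independently: an exponential waiting time
#' with rate `S + E` is drawn; if the event falls beyond the present the
#' lineage is marked extant, otherwise it either speciates (probability
#' `S / (S + E)`), dying and leaving two daughters, or goes extinct.
#'
#' @param params A [bd_params()].  When `params$seed` is non-`NULL` the RNG
#'   is seeded first and output is bit-reproducible; otherwise the current
#'   RNG stream is used.
#' @return A [bd_tree()] spanning `[0, T]` with extinct and extant lineages.
#' @export
#' @examples
#' tr <- simulate_tree(bd_params(0.5, 0.5, duration = 10, seed = 42))
#' n_extant(tr)
simulate_tree <- function(params) {
  stopifnot(inherits(params, "bd_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  S <- params$speciation; E <- params$extinction
  Tend <- params$duration; cap <- params$max_lineages
  rate <- S + E
  nmax <- 64L
  birth <- numeric(nmax); death <- rep(NA_real_, nmax)
  parent <- rep(NA_integer_, nmax); extant <- logical(nmax)
  n <- 2L
  if (rate == 0) {
    extant[1:2] <- TRUE
  } else {
    p_spec <- S / rate
    todo <- 1:2
    while (length(todo)) {
      tend <- birth[todo] + rexp(length(todo), rate)
      alive <- tend >= Tend
      extant[todo] <- alive
      death[todo] <- ifelse(alive, NA_real_, tend)
      ev <- todo[!alive]
      if (length(ev) == 0L) break
      sp <- ev[runif(length(ev)) < p_spec]
      nk <- 2L * length(sp)
      if (nk == 0L) break
      if (n + nk > cap)
        stop_crownsim(sprintf(
          "lineage cap exceeded (%d lineages, cap %g) at S = %g, E = %g, T = %g",
          n + nk, cap, S, E, Tend), "crownsim_overflow")
      while (n + nk > nmax) {
        grow <- nmax
        birth <- c(birth, numeric(grow))
        death <- c(death, rep(NA_real_, grow))
        parent <- c(parent, rep(NA_integer_, grow))
        extant <- c(extant, logical(grow))
        nmax <- nmax + grow
      }
      kid <- (n + 1L):(n + nk)
      birth[kid] <- rep(death[sp], each = 2L)
      parent[kid] <- rep(sp, each = 2L)
      n <- n + nk
      todo <- kid
    }
  }
  idx <- seq_len(n)
  bd_tree(birth[idx], death[idx], parent[idx], extant[idx], Tend,
          validate = FALSE)
}

#' Simulate trees conditioned on survival to the present
#'
#' Rejection sampler: trees are generated with per-tree substream seeds
#' derived from `(params$seed, tree index)`, so discarding non-survivors can
#' never desynchronize reproducibility; trees with fewer than
#' `min_extant_tips` extant lineages are discarded; the first `n_keep`
#' survivors in generation order are returned together with the realized
#' acceptance rate.
#'
#' @param params A [bd_params()].  If `seed` is `NULL` a base seed is drawn
#'   from the current RNG stream.
#' @param policy A [survival_policy()].
#' @return An object of class `bd_sample`: list with `trees` (the survivors),
#'   `tree_ids` (their generation indices), `n_generated`, `n_single`
#'   (trees discarded with exactly one extant lineage), `acceptance_rate`,
#'   `params` and `policy`.
#' @export
simulate_surviving <- function(params, policy = survival_policy()) {
  stopifnot(inherits(params, "bd_params"), inherits(policy, "survival_policy"))
  base_seed <- params$seed
  if (is.null(base_seed)) base_seed <- sample.int(2147483562L, 1L)
  total_max <- as.numeric(policy$max_batches) * policy$batch_size
  trees <- vector("list", policy$n_keep)
  tree_ids <- integer(policy$n_keep)
  found <- 0L; idx <- 0L; n_single <- 0L
  while (found < policy$n_keep && idx < total_max) {
    idx <- idx + 1L
    p <- params
    p$seed <- substream_seed(base_seed, idx)
    tr <- simulate_tree(p)
    ne <- n_extant(tr)
    if (ne == 1L) n_single <- n_single + 1L
    if (ne >= policy$min_extant_tips) {
      found <- found + 1L
      trees[[found]] <- tr
      tree_ids[found] <- idx
    }
  }
  if (found < policy$n_keep)
    stop_crownsim(sprintf(
      "only %d of %d surviving trees found after %d generated (max_batches = %d exhausted); near-certain extinction regime?",
      found, policy$n_keep, idx, policy$max_batches),
      "crownsim_survival_shortfall")
  structure(list(trees = trees, tree_ids = tree_ids,
                 n_generated = idx, n_single = n_single,
                 acceptance_rate = found / idx,
                 params = params, policy = policy),
            class = "bd_sample")
}

#' @export
print.bd_sample <- function(x, ...) {
  cat(sprintf(
    "bd_sample: %d surviving trees of %d generated (acceptance %.3f) at S = %g, E = %g, T = %g\n",
    length(x$trees), x$n_generated, x$acceptance_rate,
    x$params$speciation, x$params$extinction, x$params$duration))
  invisible(x)
}
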