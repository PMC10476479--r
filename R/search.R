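#' Configuration for the population-based threshold search
#'
#' @param m Number of thresholds (>= 1).
#' @param population_size Individuals per generation (>= 2). Default 30.
#' @param max_generations Hard generation cap. Default 100.
#' @param crossover_rate Probability an offspring is produced by uniform
#'   crossover of two parents (else cloned). Default 0.9.
#' @param mutation_rate Per-gene mutation probability. Default 0.1.
#' @param patience Generations without improvement before early stop.
#'   Default 20.
#' @param seed Integer RNG seed; a fixed seed makes the run fully
#'   reproducible (Mersenne-Twister).
#' @param base Logarithm base for the objective.
#' @return Object of class `search_config`.
#' @export
search_config <- function(m, population_size = 30L, max_generations = 100L,
                          crossover_rate = 0.9, mutation_rate = 0.1,
                          patience = 20L, seed = 1L, base = 2) {
  m <- as.integer(m)
  population_size <- as.integer(population_size)
  max_generations <- as.integer(max_generations)
  patience <- as.integer(patience)
  seed <- as.integer(seed)
  if (m < 1L) abort_domain("`m` must be >= 1")
  if (population_size < 2L) abort_domain("`population_size` must be >= 2")
  if (max_generations < 1L) abort_domain("`max_generations` must be >= 1")
  if (crossover_rate < 0 || crossover_rate > 1 ||
      mutation_rate < 0 || mutation_rate > 1) {
    abort_domain("rates must lie in [0, 1]")
  }
  check_base(base)
  structure(
    list(
      m = m, population_size = population_size,
      max_generations = max_generations, crossover_rate = crossover_rate,
      mutation_rate = mutation_rate, patience = patience, seed = seed,
      base = base
    ),
    class = "search_config"
  )
}

search_result <- function(best_cuts, best_value, evaluations, generations_run,
                          history, seed, method, n_levels, base) {
  structure(
    list(
      best_thresholds = threshold_vector(best_cuts, n_levels = n_levels),
      best_value = best_value,
      evaluations = evaluations,
      generations_run = generations_run,
      history = history,
      seed = seed,
      method = method,
      base = base
    ),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "<search_result:%s> u* = (%s), J = %.6f (base %s), %d evaluations\n",
    x$method, paste(x$best_thresholds$cuts, collapse = ", "),
    x$best_value, format(x$base), x$evaluations
  ))
  invisible(x)
}

# Levels with nonzero mass, needed to decide whether any feasible partition
# into m + 1 classes exists.
check_feasible <- function(hist, m) {
  support <- sum(hist$probs > 0)
  if (support < m + 1L) {
    abort_feasibility(sprintf(
      "no feasible partition: %d thresholds need %d distinct nonzero-mass gray levels, histogram has %d",
      m, m + 1L, support
    ))
  }
  invisible(support)
}

#' Exhaustive (oracle) threshold search
#'
#' Enumerates every feasible threshold vector and returns the global
#' maximizer of the entropy objective.  Objective values within 1e-10 of
#' the maximum are treated as exact ties (mathematically tied vectors
#' differ by rounding noise of order 1e-15) and broken toward the
#' lexicographically smallest vector.  Exact but combinatorial: guarded
#' at `max_evals` enumerated vectors.
#'
#' @inheritParams objective_landscape
#' @return A `search_result` with the globally optimal thresholds.
#' @examples
#' h <- gray_histogram(rep(0.25, 4))
#' exhaustive_search(h, m = 1)$best_thresholds$cuts  # 2
#' @export
exhaustive_search <- function(hist, m, base = 2, max_evals = 2e6) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  check_base(base)
  m <- as.integer(m)
  Z <- hist$n_levels
  if (m < 1L || m > Z - 1L) abort_domain("need 1 <= m <= Z - 1")
  check_feasible(hist, m)
  n_comb <- choose(Z - 1L, m)
  if (n_comb > max_evals) {
    abort_resource(sprintf(
      "exhaustive enumeration of %g vectors exceeds guard %g; reduce Z or m, or raise max_evals",
      n_comb, max_evals
    ))
  }
  cuts <- utils::combn(seq_len(Z - 1L), m)
  J <- kapur_eval(entropy_tables(hist$probs), cuts, Z) / log(base)
  if (all(is.na(J))) {
    abort_feasibility("no feasible threshold vector exists")
  }
  # combn enumerates in lexicographic order; the first vector within the
  # tie tolerance of the maximum is the lexicographically smallest optimum.
  best <- which(J >= max(J, na.rm = TRUE) - 1e-10)[1]
  search_result(
    best_cuts = cuts[, best], best_value = J[best],
    evaluations = ncol(cuts), generations_run = 1L,
    history = J[best], seed = NA_integer_, method = "exhaustive",
    n_levels = Z, base = base
  )
}

#' Population-based (genetic) threshold search
#'
#' Stochastic global search over integer-coded sorted threshold vectors,
#' following the usual metaheuristic flow: the entropy objective serves as
#' the fitness function (infeasible candidates score worst), an elitist
#' generational loop applies tournament selection, uniform crossover of cut
#' points, and per-gene mutation (a local gray-level step mixed with a
#' uniform reset), repairing chromosomes only by re-sorting and replacing
#' duplicate cuts.  Identical seed, config and histogram give an identical
#' result.
#'
#' @inheritParams exhaustive_search
#' @param config A [search_config()].
#' @return A `search_result`; `history` holds the per-generation best
#'   objective (non-decreasing under elitism).
#' @export
population_search <- function(hist, config) {
  if (!is_gray_histogram(hist)) abort_domain("`hist` must be a gray_histogram")
  if (!inherits(config, "search_config")) {
    abort_domain("`config` must be a search_config")
  }
  m <- config$m
  Z <- hist$n_levels
  if (m > Z - 1L) abort_domain("need m <= Z - 1")
  check_feasible(hist, m)

  # Run on a private RNG stream; restore the caller's state afterwards.
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed, kind = "Mersenne-Twister")

  tab <- entropy_tables(hist$probs)
  log_base <- log(config$base)
  pop_n <- config$population_size

  repair <- function(v) {
    v <- sort.int(v)
    dup <- duplicated(v)
    if (any(dup)) {
      free <- setdiff(seq_len(Z - 1L), v)
      v[dup] <- if (length(free) == 1L) free else {
        sample(free, sum(dup))
      }
      v <- sort.int(v)
    }
    v
  }

  # Distinct objective values arise only from cuts that regroup occupied
  # gray levels, so random draws (initialization, immigrants, resets) are
  # taken from the canonical candidates: support levels that can serve as a
  # feasible class boundary.  Local mutation steps still roam all integers.
  support <- which(hist$probs > 0) - 1L
  cand <- support[support > min(support) & support >= 1L]
  draw_cand <- function(k) {
    if (length(cand) == 1L) rep(cand, k) else sample(cand, k, replace = FALSE)
  }
  new_individual <- function() sort.int(draw_cand(m))

  pop <- matrix(0L, nrow = m, ncol = pop_n)
  for (j in seq_len(pop_n)) pop[, j] <- new_individual()

  fitness_of <- function(P) {
    f <- kapur_eval(tab, P, Z) / log_base
    f[is.na(f)] <- -Inf
    f
  }

  lex_less <- function(a, b) {
    d <- a - b
    nz <- which(d != 0L)
    length(nz) > 0L && d[nz[1]] < 0L
  }

  cand_sorted <- sort(cand)
  # Adjacent-boundary neighbors of a vector: each cut moved to the next
  # lower / next higher candidate level (then re-sorted), skipping collisions.
  neighbor_set <- function(v) {
    out <- list()
    for (g in seq_len(m)) {
      pos <- findInterval(v[g], cand_sorted)
      lo <- if (pos >= 1L && cand_sorted[pos] == v[g]) {
        if (pos > 1L) cand_sorted[pos - 1L] else NA_integer_
      } else if (pos >= 1L) cand_sorted[pos] else NA_integer_
      hi <- if (pos + 1L <= length(cand_sorted)) cand_sorted[pos + 1L] else NA_integer_
      for (w in c(lo, hi)) {
        if (!is.na(w) && !(w %in% v)) {
          out[[length(out) + 1L]] <- sort.int(replace(v, g, w))
        }
      }
    }
    out
  }
  # Deterministic steepest-ascent polish of the incumbent: ensures the
  # returned vector is locally optimal over adjacent candidate boundaries.
  polish <- function(v, f) {
    n_evals <- 0L
    repeat {
      nbrs <- neighbor_set(v)
      if (length(nbrs) == 0L) break
      nb_mat <- matrix(unlist(nbrs), nrow = m)
      nf <- fitness_of(nb_mat)
      n_evals <- n_evals + ncol(nb_mat)
      j <- which.max(nf)
      if (nf[j] > f) {
        v <- nb_mat[, j]
        f <- nf[j]
      } else {
        break
      }
    }
    list(v = v, f = f, evals = n_evals)
  }

  fit <- fitness_of(pop)
  evaluations <- pop_n
  best_idx <- which.max(fit)
  best_cuts <- pop[, best_idx]
  best_fit <- fit[best_idx]
  if (is.finite(best_fit)) {
    p <- polish(best_cuts, best_fit)
    best_cuts <- p$v
    best_fit <- p$f
    evaluations <- evaluations + p$evals
  }
  history <- best_fit
  stagnant <- 0L
  restart_every <- max(3L, config$patience %/% 3L)
  gen <- 1L

  while (gen < config$max_generations && stagnant < config$patience) {
    gen <- gen + 1L
    offspring <- matrix(0L, nrow = m, ncol = pop_n)
    for (j in seq_len(pop_n)) {
      # tournament selection, size 2
      pick <- function() {
        c2 <- sample.int(pop_n, 2L)
        if (fit[c2[1]] >= fit[c2[2]]) c2[1] else c2[2]
      }
      p1 <- pop[, pick()]
      child <- if (stats::runif(1) < config$crossover_rate) {
        p2 <- pop[, pick()]
        if (stats::runif(1) < 0.5) {
          # uniform exchange of cut points
          sel <- stats::runif(m) < 0.5
          ifelse(sel, p1, p2)
        } else {
          # arithmetic blend: interpolates between parents per gene, which
          # refines cuts to adjacent gray levels once the population converges
          a <- stats::runif(m)
          as.integer(round(a * p1 + (1 - a) * p2))
        }
      } else {
        p1
      }
      mut <- stats::runif(m) < config$mutation_rate
      if (any(mut)) {
        for (g in which(mut)) {
          u <- stats::runif(1)
          child[g] <- if (u < 2 / 3) {
            # local step: geometric magnitude (mostly +/- 1..3), random sign,
            # reflected into [1, Z-1]
            step <- (1L + stats::rgeom(1, 0.5)) *
              (if (stats::runif(1) < 0.5) -1L else 1L)
            v <- child[g] + step
            if (v < 1L) v <- 2L - v
            if (v > Z - 1L) v <- 2L * (Z - 1L) - v
            min(max(v, 1L), Z - 1L)
          } else {
            draw_cand(1L)  # reset to a random candidate boundary
          }
        }
      }
      offspring[, j] <- repair(child)
    }
    off_fit <- fitness_of(offspring)
    evaluations <- evaluations + pop_n
    # elitist (mu + lambda) survivor selection: parents and offspring
    # compete; the worst two survivors are replaced by random immigrants to
    # keep exploring after the population has converged
    merged <- cbind(pop, offspring)
    merged_fit <- c(fit, off_fit)
    keep <- order(merged_fit, decreasing = TRUE)[seq_len(pop_n)]
    pop <- merged[, keep, drop = FALSE]
    fit <- merged_fit[keep]
    if (pop_n > 3L) {
      for (j in (pop_n - 1L):pop_n) pop[, j] <- new_individual()
      imm_fit <- fitness_of(pop[, (pop_n - 1L):pop_n, drop = FALSE])
      fit[(pop_n - 1L):pop_n] <- imm_fit
      evaluations <- evaluations + 2L
    }
    gi <- which.max(fit)
    improved <- FALSE
    if (is.finite(fit[gi])) {
      # steepest-ascent polish of the generation best over adjacent
      # candidate boundaries; the local optimum competes with the incumbent
      p <- polish(pop[, gi], fit[gi])
      evaluations <- evaluations + p$evals
      if (p$f > best_fit) {
        improved <- TRUE
        best_fit <- p$f
        best_cuts <- p$v
      } else if (p$f == best_fit && lex_less(p$v, best_cuts)) {
        best_cuts <- p$v
      }
    }
    if (improved) {
      stagnant <- 0L
    } else {
      stagnant <- stagnant + 1L
      if (stagnant %% restart_every == 0L && stagnant < config$patience) {
        # full restart: repopulate with fresh random candidate vectors so the
        # remaining generation budget probes independent basins; the global
        # best is retained outside the population (elitism on the result)
        for (j in seq_len(pop_n)) pop[, j] <- new_individual()
        fit <- fitness_of(pop)
        evaluations <- evaluations + pop_n
      }
    }
    history <- c(history, best_fit)
  }

  if (!is.finite(best_fit)) {
    abort_feasibility("search found no feasible threshold vector")
  }
  search_result(
    best_cuts = best_cuts, best_value = best_fit,
    evaluations = evaluations, generations_run = gen,
    history = history, seed = config$seed, method = "population",
    n_levels = Z, base = config$base
  )
}

#' End-to-end segmentation of a gray image
#'
#' Composes histogram computation, threshold search (exact exhaustive
#' oracle or the population-based search) and threshold application.
#'
#' @param image A [gray_image()].
#' @param m Number of thresholds.
#' @param method `"exhaustive"` or `"population"`.
#' @param config A [search_config()] (used by the population method;
#'   built from `m` and `seed` when omitted).
#' @param base Logarithm base for the objective.
#' @param dialect Interval dialect passed to [apply_thresholds()].
#' @param seed Seed used when `config` is omitted.
#' @return List with elements `thresholds` ([threshold_vector()]),
#'   `labels` ([label_map()]) and `result` (`search_result`).
#' @export
segment <- function(image, m, method = c("exhaustive", "population"),
                    config = NULL, base = 2,
                    dialect = c("partition", "exclude-zero"), seed = 1L) {
  method <- match.arg(method)
  dialect <- match.arg(dialect)
  if (!is_gray_image(image)) abort_domain("`image` must be a gray_image")
  hist <- compute_histogram(image)
  res <- if (method == "exhaustive") {
    exhaustive_search(hist, m, base = base)
  } else {
    if (is.null(config)) config <- search_config(m, seed = seed, base = base)
    if (config$m != m) abort_domain("`config$m` disagrees with `m`")
    population_search(hist, config)
  }
  labels <- apply_thresholds(image, res$best_thresholds, dialect = dialect)
  list(thresholds = res$best_thresholds, labels = labels, result = res)
}
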