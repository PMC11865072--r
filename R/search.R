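#' @title Exchange-type search for exact optimal designs
#' @description
#' The information matrix of the gBLUP model is not additive in the
#' experimental units (the support-restricted GRM changes with every swap),
#' so classical convex design theory does not apply and every candidate
#' exchange requires a full criterion recomputation. The algorithms here are
#' therefore compared by criterion-evaluation counts, a hardware-independent
#' cost metric, rather than wall-clock time.
#' @name search
NULL

# strict-improvement threshold guarding float-noise cycles
.improve_tol <- 1e-12

# evaluate a criterion, treating numerical failure (e.g. a singular
# support-restricted GRM) as non-improving rather than aborting the search
try_evaluate <- function(criterion, grm_obj, spec, des, counter) {
  tryCatch(
    evaluate_criterion(criterion, grm_obj, spec, des, counter),
    error = function(e) {
      warning(sprintf("criterion evaluation failed for a candidate swap (skipped): %s",
                      conditionMessage(e)), call. = FALSE)
      -Inf
    }
  )
}

check_search_design <- function(grm_obj, spec, des) {
  check_design(grm_obj, spec, des)
  if (length(des$candidates) == 0) {
    stop("exchange search needs a nonempty candidate set (n < N)", call. = FALSE)
  }
  invisible(TRUE)
}

swap_design <- function(des, sup_pos, cand_idx) {
  sup <- des$support
  sup[sup_pos] <- cand_idx
  new_design(sup, des$N)
}

new_search_result <- function(des, value, trace_rows, algorithm, ordering,
                              converged, counter, seed = NA_integer_) {
  trace <- do.call(rbind, trace_rows)
  structure(
    list(
      design = des,
      value = value,
      trace = trace,
      seed = seed,
      algorithm = algorithm,
      ordering = ordering,
      converged = converged,
      n_evals = counter$n,
      n_accepted = nrow(trace) - 1L
    ),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf(
    "%s%s: value %.6g after %d accepted swaps, %d criterion evaluations%s\n",
    x$algorithm,
    if (!is.na(x$ordering)) paste0(" (", x$ordering, ")") else "",
    x$value, x$n_accepted, x$n_evals,
    if (isTRUE(x$converged)) " (converged)" else ""
  ))
  invisible(x)
}

trace_row <- function(iteration, value, evals, out = NA_integer_, in_ = NA_integer_) {
  data.frame(
    iteration = iteration, value = value, evals = evals,
    swap_out = out, swap_in = in_
  )
}

#' Classical Fedorov exchange
#'
#' At each pass the criterion is evaluated for all `n * (N - n)` single
#' exchanges between the support and the candidate set and the best strictly
#' improving swap is applied; the algorithm stops when no exchange improves
#' the criterion, so the returned design is swap-local optimal. Ties for the
#' best swap are broken by the lowest (support position, candidate position)
#' pair, making the run deterministic given the start design.
#'
#' @inheritParams build_mme
#' @param criterion a [criterion_spec()].
#' @param start the initial [design()].
#' @param counter an [eval_counter()] accumulating criterion evaluations.
#' @param max_passes safety cap on full passes (default effectively
#'   unlimited; the natural stopping rule fires first).
#' @return a `"search_result"`: final design, final value, the per-accepted-
#'   swap trace (iteration, value, cumulative evaluations, exchanged pair),
#'   evaluation and acceptance counts, and a convergence flag.
#' @export
fedorov_exchange <- function(grm_obj, spec, criterion, start,
                             counter = eval_counter(), max_passes = 10000L) {
  check_search_design(grm_obj, spec, start)
  cur <- start
  cur_val <- try_evaluate(criterion, grm_obj, spec, cur, counter)
  if (!is.finite(cur_val)) {
    stop("criterion is not computable on the starting design", call. = FALSE)
  }
  rows <- list(trace_row(0L, cur_val, counter$n))
  converged <- FALSE
  iter <- 0L
  for (pass in seq_len(max_passes)) {
    best_val <- cur_val
    best_pos <- NULL
    for (si in seq_len(cur$n)) {
      for (cj in seq_along(cur$candidates)) {
        val <- try_evaluate(criterion, grm_obj, spec,
                            swap_design(cur, si, cur$candidates[cj]), counter)
        if (val > best_val + .improve_tol) {
          best_val <- val
          best_pos <- c(si, cj)
        }
      }
    }
    if (is.null(best_pos)) {
      converged <- TRUE
      break
    }
    out_idx <- cur$support[best_pos[1]]
    in_idx <- cur$candidates[best_pos[2]]
    cur <- swap_design(cur, best_pos[1], in_idx)
    cur_val <- best_val
    iter <- iter + 1L
    rows[[length(rows) + 1L]] <- trace_row(iter, cur_val, counter$n, out_idx, in_idx)
  }
  new_search_result(cur, cur_val, rows, "fedorov", NA_character_, converged, counter)
}

#' Per-unit scores used to order the exchange scan
#'
#' For the D-criterion the scores are prediction variances: the observed-unit
#' variance on the support set and the unobserved-unit variance on the
#' candidate set (removing a high-variance unit removes its whole
#' individual-specific effect from the model, and a high-variance candidate
#' is informative to add). For the CD criteria the scores are the per-unit
#' CD values on both sets: a support unit that is already well predicted is
#' a removal candidate, a poorly predicted candidate is an addition
#' candidate.
#'
#' @inheritParams fedorov_exchange
#' @param des current [design()].
#' @return list with numeric vectors `support` (aligned with `des$support`)
#'   and `candidates` (aligned with `des$candidates`).
#' @export
unit_scores <- function(grm_obj, spec, des, criterion) {
  if (criterion$name == "D") {
    blocks <- build_mme(grm_obj, spec, des)
    list(
      support = prediction_variance_observed(blocks, spec, des),
      candidates = prediction_variance_candidates(grm_obj, spec, des, blocks)
    )
  } else {
    cd <- cd_matrix(grm_obj, spec, des, targets = seq_len(grm_obj$N))
    list(support = cd[des$support], candidates = cd[des$candidates])
  }
}

# scan order of the candidate set is fixed per criterion: for D, decreasing
# prediction variance (most informative first); for CD criteria, increasing
# CD (worst-predicted first)
order_candidates <- function(scores, criterion_name) {
  if (criterion_name == "D") order(scores, decreasing = TRUE) else order(scores)
}

order_support <- function(scores, ordering) {
  switch(ordering,
    increasing = order(scores),
    decreasing = order(scores, decreasing = TRUE),
    random = sample.int(length(scores)),
    stop(sprintf("unknown ordering '%s'", ordering), call. = FALSE)
  )
}

#' Modified (greedy) Fedorov exchange with scan orderings
#'
#' Scans support/candidate pairs in a heuristic order and applies the first
#' strictly improving swap immediately; scores and orderings are recomputed
#' after every accepted swap. The candidate-set order is fixed per criterion
#' (see [unit_scores()]); the support-set order is user-chosen among
#' increasing, decreasing and random score order. Terminates, like the
#' classical algorithm, when a complete scan finds no improving exchange, so
#' the result is swap-local optimal; a single scan costs at most
#' `n * (N - n)` criterion evaluations and usually far fewer.
#'
#' @inheritParams fedorov_exchange
#' @param ordering support-set scan order: `"increasing"`, `"decreasing"` or
#'   `"random"` (drawn from the current RNG stream; seed for
#'   reproducibility).
#' @return a `"search_result"`.
#' @export
modified_fedorov_exchange <- function(grm_obj, spec, criterion, start,
                                      ordering = c("decreasing", "increasing", "random"),
                                      counter = eval_counter(),
                                      max_accepts = 100000L) {
  ordering <- match.arg(ordering)
  check_search_design(grm_obj, spec, start)
  cur <- start
  cur_val <- try_evaluate(criterion, grm_obj, spec, cur, counter)
  if (!is.finite(cur_val)) {
    stop("criterion is not computable on the starting design", call. = FALSE)
  }
  rows <- list(trace_row(0L, cur_val, counter$n))
  converged <- FALSE
  iter <- 0L
  while (iter < max_accepts) {
    scores <- unit_scores(grm_obj, spec, cur, criterion)
    sup_order <- order_support(scores$support, ordering)
    cand_order <- order_candidates(scores$candidates, criterion$name)
    accepted <- FALSE
    for (si in sup_order) {
      for (cj in cand_order) {
        in_idx <- cur$candidates[cj]
        val <- try_evaluate(criterion, grm_obj, spec,
                            swap_design(cur, si, in_idx), counter)
        if (val > cur_val + .improve_tol) {
          out_idx <- cur$support[si]
          cur <- swap_design(cur, si, in_idx)
          cur_val <- val
          iter <- iter + 1L
          rows[[length(rows) + 1L]] <- trace_row(iter, cur_val, counter$n, out_idx, in_idx)
          accepted <- TRUE
          break
        }
      }
      if (accepted) break
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
  }
  new_search_result(cur, cur_val, rows, "modified_fedorov", ordering, converged, counter)
}

#' Random-swap hill climbing (naive baseline)
#'
#' The brute-force strategy used in earlier training-set optimization work:
#' propose a uniformly random (support, candidate) exchange, recompute the
#' criterion, and keep the swap only if it improves. No neighborhood is ever
#' scanned exhaustively, so termination is by budget: after `max_iter`
#' proposals, or earlier once `max_stall` consecutive proposals were
#' rejected.
#'
#' @inheritParams fedorov_exchange
#' @param max_iter total proposal budget (>= 1).
#' @param max_stall consecutive rejections before stopping early; default
#'   `Inf` (run the full budget).
#' @return a `"search_result"`; `converged` is `TRUE` only when the stall
#'   rule fired (the budget running out proves nothing about optimality).
#' @export
random_swap_hillclimb <- function(grm_obj, spec, criterion, start,
                                  max_iter = 1000L, max_stall = Inf,
                                  counter = eval_counter()) {
  check_search_design(grm_obj, spec, start)
  if (max_iter < 1) stop("'max_iter' must be at least 1", call. = FALSE)
  cur <- start
  cur_val <- try_evaluate(criterion, grm_obj, spec, cur, counter)
  if (!is.finite(cur_val)) {
    stop("criterion is not computable on the starting design", call. = FALSE)
  }
  rows <- list(trace_row(0L, cur_val, counter$n))
  iter <- 0L
  stall <- 0L
  converged <- FALSE
  for (k in seq_len(max_iter)) {
    si <- sample.int(cur$n, 1L)
    cj <- sample.int(length(cur$candidates), 1L)
    in_idx <- cur$candidates[cj]
    val <- try_evaluate(criterion, grm_obj, spec,
                        swap_design(cur, si, in_idx), counter)
    if (val > cur_val + .improve_tol) {
      out_idx <- cur$support[si]
      cur <- swap_design(cur, si, in_idx)
      cur_val <- val
      iter <- iter + 1L
      rows[[length(rows) + 1L]] <- trace_row(iter, cur_val, counter$n, out_idx, in_idx)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= max_stall) {
        converged <- TRUE
        break
      }
    }
  }
  new_search_result(cur, cur_val, rows, "random_swap", NA_character_, converged, counter)
}

#' Multi-restart driver
#'
#' Runs one of the search algorithms from `restarts` independent
#' uniform-random starting designs. A master seed spawns one child seed per
#' restart, so the full output is a pure function of `(config, seed)`; the
#' best final criterion value wins, ties broken by the lowest restart index.
#'
#' @inheritParams fedorov_exchange
#' @param n design size for the random starts.
#' @param algorithm `"fedorov"`, `"modified_fedorov"` or `"random_swap"`.
#' @param ordering support ordering for the modified algorithm.
#' @param restarts number of restarts (>= 1).
#' @param seed master seed (integer).
#' @param ... passed to the underlying algorithm (e.g. `max_iter`).
#' @return list with `results` (one `"search_result"` per restart, each
#'   carrying its child seed), `best` and `best_index`.
#' @export
multi_restart <- function(grm_obj, spec, criterion, n,
                          algorithm = c("fedorov", "modified_fedorov", "random_swap"),
                          ordering = "decreasing", restarts = 10L, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  if (restarts < 1) stop("'restarts' must be at least 1", call. = FALSE)
  set.seed(as.integer(seed))
  child_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  results <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    set.seed(child_seeds[r])
    start <- random_design(grm_obj$N, n)
    counter <- eval_counter()
    res <- switch(algorithm,
      fedorov = fedorov_exchange(grm_obj, spec, criterion, start,
                                 counter = counter, ...),
      modified_fedorov = modified_fedorov_exchange(grm_obj, spec, criterion, start,
                                                   ordering = ordering,
                                                   counter = counter, ...),
      random_swap = random_swap_hillclimb(grm_obj, spec, criterion, start,
                                          counter = counter, ...)
    )
    res$seed <- child_seeds[r]
    results[[r]] <- res
  }
  finals <- vapply(results, `[[`, numeric(1), "value")
  best_index <- which.max(finals)
  list(results = results, best = results[[best_index]], best_index = best_index)
}

#' Exhaustive enumeration oracle
#'
#' Evaluates the criterion on every size-`n` subset of the candidates and
#' returns the global maximizer together with the complete value table.
#' Only feasible for small `choose(N, n)`; refuses above `cap`.
#'
#' @inheritParams multi_restart
#' @param cap maximum number of subsets enumerated (default `1e6`).
#' @return list with `best_design`, `best_value` and `table` (a data frame
#'   with one row per design: comma-separated support indices and value).
#' @export
exhaustive_search <- function(grm_obj, spec, criterion, n, cap = 1e6,
                              counter = eval_counter()) {
  n_designs <- choose(grm_obj$N, n)
  if (n_designs > cap) {
    stop(sprintf(
      "choose(N = %d, n = %d) = %.0f exceeds the enumeration cap %.0f",
      grm_obj$N, n, n_designs, cap
    ), call. = FALSE)
  }
  subsets <- utils::combn(grm_obj$N, n)
  values <- numeric(ncol(subsets))
  for (k in seq_len(ncol(subsets))) {
    values[k] <- try_evaluate(criterion, grm_obj, spec,
                              new_design(subsets[, k], grm_obj$N), counter)
  }
  best_k <- which.max(values)
  list(
    best_design = new_design(subsets[, best_k], grm_obj$N),
    best_value = values[best_k],
    table = data.frame(
      support = apply(subsets, 2, paste, collapse = ","),
      value = values
    )
  )
}

#' Verify swap-local optimality of a design
#'
#' Independent full re-scan of the single-exchange neighborhood: returns
#' `TRUE` when no support/candidate swap improves the criterion by more than
#' the strict-improvement tolerance. This is the stopping condition of both
#' Fedorov variants, checked from scratch.
#'
#' @inheritParams fedorov_exchange
#' @param des the design to check.
#' @return logical.
#' @export
is_swap_local_optimum <- function(grm_obj, spec, criterion, des) {
  cur_val <- evaluate_criterion(criterion, grm_obj, spec, des)
  for (si in seq_len(des$n)) {
    for (cand in des$candidates) {
      val <- tryCatch(
        evaluate_criterion(criterion, grm_obj, spec, swap_design(des, si, cand)),
        error = function(e) -Inf
      )
      if (val > cur_val + .improve_tol) return(FALSE)
    }
  }
  TRUE
}
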