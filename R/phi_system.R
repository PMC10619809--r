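#' System-level integrated conceptual information
#'
#' Phi of a candidate system in a state is the extended earth mover's
#' distance between its intact conceptual structure and the conceptual
#' structure under the minimum-information unidirectional system cut.
#' Cuts sever the connections from one part of the candidate to the rest
#' (inputs noised to maximum entropy); every ordered bipartition is
#' evaluated. Concept transport cost is the Hamming-ground EMD between
#' the expanded cause repertoires plus that between the expanded effect
#' repertoires; transported mass is mechanism phi, with surplus mass
#' moved to the null concept (the unconstrained repertoires of the intact
#' candidate).
#'
#' @name big_phi
NULL

null_concept <- function(tpm) {
  k <- tpm$n
  list(phi = 0,
       exp_cause = rep(1 / 2^k, 2^k),
       exp_eff_marg = colMeans(tpm$probs))
}

concept_distance <- function(c1, c2, k) {
  emd_hamming_cpp(c1$exp_cause, c2$exp_cause, k) +
    sum(abs(c1$exp_eff_marg - c2$exp_eff_marg))
}

#' Extended EMD between two conceptual structures
#'
#' @param c1,c2 concept lists as returned by [constellation()].
#' @param null the null concept of the intact candidate (used as the
#'   sink/source for unmatched phi mass on both sides).
#' @param k candidate size in nodes.
#' @return the transport distance (>= 0).
#' @keywords internal
constellation_distance <- function(c1, c2, null, k) {
  n1 <- length(c1); n2 <- length(c2)
  if (n1 == 0L && n2 == 0L) return(0)
  phi1 <- vapply(c1, `[[`, numeric(1), "phi")
  phi2 <- vapply(c2, `[[`, numeric(1), "phi")
  s1 <- sum(phi1); s2 <- sum(phi2)
  supply <- c(phi1, max(0, s2 - s1))
  demand <- c(phi2, max(0, s1 - s2))
  pts1 <- c(c1, list(null)); pts2 <- c(c2, list(null))
  cost <- matrix(0, n1 + 1L, n2 + 1L)
  for (i in seq_len(n1 + 1L))
    for (j in seq_len(n2 + 1L))
      cost[i, j] <- concept_distance(pts1[[i]], pts2[[j]], k)
  emd_flow_cpp(supply, demand, cost)
}

#' Integrated conceptual information of a candidate system
#'
#' @param tpm a conditioned `tpm` from [condition_tpm()].
#' @param state current candidate-system state (index or bit vector over
#'   `tpm$nodes`).
#' @return a `phi_result`: list with `nodes`, `state`, `phi`,
#'   `constellation` (intact concepts), `n_concepts`, `cut` (the
#'   minimum-information cut as `list(from, to)`, or `NULL` when the
#'   constellation is empty).
#' @export
big_phi <- function(tpm, state) {
  stopifnot(inherits(tpm, "tpm"))
  bits <- candidate_state_bits(tpm, state)
  k <- tpm$n
  intact <- constellation(tpm, bits)
  res <- list(nodes = tpm$nodes, state = bits, phi = 0,
              constellation = intact, n_concepts = length(intact),
              cut = NULL)
  if (length(intact) == 0L || k == 1L) {
    # a single node cannot be partitioned at the system level; its Phi
    # is the summed distance of its concepts to the null structure
    if (length(intact) > 0L && k == 1L) {
      nullc <- null_concept(tpm)
      res$phi <- constellation_distance(intact, list(), nullc, k)
      res$cut <- list(from = tpm$nodes, to = integer(0))
    }
    class(res) <- "phi_result"
    return(res)
  }
  nullc <- null_concept(tpm)
  best <- Inf
  for (am in 1:(2^k - 2L)) {
    fpos <- mask_to_pos(am, k)
    from <- tpm$nodes[fpos]
    to <- setdiff(tpm$nodes, from)
    ct <- cut_tpm(tpm, from, to)
    ccut <- constellation(ct, bits)
    d <- constellation_distance(intact, ccut, nullc, k)
    if (d < best - 1e-12) {
      best <- d
      res$cut <- list(from = from, to = to)
      if (best < PHI_EPS) break
    }
  }
  res$phi <- if (best < PHI_EPS) 0 else best
  class(res) <- "phi_result"
  res
}

#' @export
print.phi_result <- function(x, ...) {
  cat("Phi =", format(x$phi, digits = 6), "over nodes {",
      paste(x$nodes, collapse = ","), "} in state",
      paste(x$state, collapse = ""), "with", x$n_concepts, "concepts\n")
  invisible(x)
}

.main_complex_cache <- new.env(parent = emptyenv())

#' Search for the main complex
#'
#' Evaluates every nonempty candidate subset of the eligible nodes (for
#' a brain: the hidden and motor nodes; sensors are always background,
#' clamped to their current state) and returns the candidate with
#' maximal Phi. Ties are broken in favor of the larger candidate, then
#' the first in ascending-mask enumeration order. Candidates containing
#' a node with no incoming or no outgoing connection inside the
#' candidate have Phi = 0 and are skipped analytically. Results are
#' memoized by (genome, state, options).
#'
#' @param network a [markov_brain()] or [logic_network()].
#' @param state full network state: index or 0/1 vector over all nodes.
#' @param include_motors for brains, whether motor nodes may join
#'   candidate systems (default TRUE).
#' @param candidates optional list of integer node-id vectors to restrict
#'   the search (e.g. for smoke tests).
#' @param use_cache memoize by (genome, state, options).
#' @return the maximal-Phi `phi_result`, with `$is_main_complex = TRUE`.
#' @export
main_complex <- function(network, state, include_motors = TRUE,
                         candidates = NULL, use_cache = TRUE) {
  n <- network_size(network)
  if (length(state) == 1L) state <- state_to_bits(state, n)
  key <- NULL
  if (use_cache) {
    gate_key <- if (inherits(network, "markov_brain")) brain_key(network)
      else paste(vapply(network$gates, function(g)
        paste0(paste(g$inputs, collapse = ","), ":",
               paste(g$table, collapse = "")), character(1)),
        collapse = "|")
    key <- paste0(gate_key, "#", paste(state, collapse = ""), "#",
                  include_motors, "#",
                  paste(vapply(candidates %||% list(), paste,
                               character(1), collapse = ","),
                        collapse = ";"))
    hit <- .main_complex_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  eligible <- if (inherits(network, "markov_brain")) {
    if (include_motors) NON_SENSOR_NODES else HIDDEN_NODES
  } else seq_len(n)
  if (is.null(candidates)) {
    ne <- length(eligible)
    candidates <- lapply(1:(2^ne - 1L), function(m)
      eligible[mask_to_pos(m, ne)])
  }
  ftpm <- full_tpm(network)
  best <- NULL
  for (cand in candidates) {
    ctpm <- condition_tpm(ftpm, cand, state)
    k <- ctpm$n
    # every member needs an in- and an out-connection within the candidate
    has_io <- all(vapply(seq_len(k), function(j)
      any(ctpm$conn[, j]) && any(ctpm$conn[j, ]), logical(1)))
    res <- if (!has_io) {
      structure(list(nodes = ctpm$nodes, state = state[ctpm$nodes],
                     phi = 0, constellation = list(), n_concepts = 0L,
                     cut = NULL),
                class = "phi_result")
    } else {
      big_phi(ctpm, state[ctpm$nodes])
    }
    if (is.null(best) || res$phi > best$phi + 1e-10 ||
        (abs(res$phi - best$phi) <= 1e-10 &&
         length(res$nodes) > length(best$nodes)))
      best <- res
  }
  best$is_main_complex <- TRUE
  if (use_cache) assign(key, best, envir = .main_complex_cache)
  best
}

#' Phi time series over trial records
#'
#' Phi of the main complex at each analyzed timestep's full network
#' state. State repetition within and across trials is exploited through
#' the memo cache, so the cost scales with the number of *distinct*
#' states an animat visits.
#'
#' @param brain a `markov_brain`.
#' @param records trial records from [run_trials()].
#' @param ... passed to [main_complex()].
#' @return the records tibble with columns `phi` and `complex_nodes`
#'   appended (only `trial_id`, `t` and the state columns are retained).
#' @export
phi_timeseries <- function(brain, records, ...) {
  state_cols <- c("sL", "sR", "h1", "h2", "h3", "h4", "mL", "mR")
  sm <- as.matrix(records[, state_cols])
  keys <- apply(sm, 1L, paste, collapse = "")
  uk <- unique(keys)
  vals <- lapply(uk, function(kk) {
    st <- as.integer(strsplit(kk, "")[[1]])
    res <- main_complex(brain, st, ...)
    list(phi = res$phi, nodes = paste(res$nodes, collapse = ","))
  })
  names(vals) <- uk
  tibble::tibble(
    trial_id = records$trial_id, t = records$t,
    records[, state_cols],
    phi = vapply(keys, function(kk) vals[[kk]]$phi, numeric(1),
                 USE.NAMES = FALSE),
    complex_nodes = vapply(keys, function(kk) vals[[kk]]$nodes,
                           character(1), USE.NAMES = FALSE)
  )
}

#' Reset the main-complex memo cache
#' @export
clear_phi_cache <- function() {
  rm(list = ls(.main_complex_cache), envir = .main_complex_cache)
  invisible(NULL)
}
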